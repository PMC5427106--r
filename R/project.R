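#' Create a project
#'
#' A project (protocol) bundles everything for one experiment: its
#' ethograms (behavioral tests), a database of subjects with free-form
#' descriptors (sex, age, origin, ...), experimental group labels
#' (vehicle, treatment, stress, ...), and the scored trials keyed by
#' (subject, test, session, trial, rater). Group assignment may happen at
#' any time, including after scoring.
#'
#' @param name Project name.
#' @return A `project` object.
#' @seealso [add_subject()], [record_trial()], [export_results()],
#'   [save_project()]
#' @export
project <- function(name) {
  if (!is_string(name) || !nzchar(name))
    abort_etho("validation", "project name must be a non-empty string")
  structure(list(name = name, ethograms = list(), subjects = list(),
                 groups = list(), trials = list()),
            class = "ethoscore_project")
}

#' Register an ethogram, subject or group with a project
#'
#' @param proj A [project()].
#' @param etho An ethogram; its `test_name` becomes the test key.
#' @return The updated project (projects are immutable values; reassign).
#' @export
add_ethogram <- function(proj, etho) {
  validate_ethogram(etho)
  if (etho$test_name %in% names(proj$ethograms))
    abort_etho("conflict", "test '%s' already registered", etho$test_name)
  proj$ethograms[[etho$test_name]] <- etho
  proj
}

#' @rdname add_ethogram
#' @param subject_id Unique subject identifier.
#' @param descriptors Named list/vector of subject descriptors.
#' @export
add_subject <- function(proj, subject_id, descriptors = list()) {
  if (subject_id %in% names(proj$subjects))
    abort_etho("conflict", "subject '%s' already registered", subject_id)
  proj$subjects[[subject_id]] <-
    list(subject_id = subject_id, group = NULL,
         descriptors = as.list(descriptors))
  proj
}

#' @rdname add_ethogram
#' @param label Group label.
#' @param description Free-text group description.
#' @export
add_group <- function(proj, label, description = "") {
  if (label %in% names(proj$groups))
    abort_etho("conflict", "group '%s' already registered", label)
  proj$groups[[label]] <- list(label = label, description = description)
  proj
}

#' Assign a subject to an experimental group
#'
#' May be called at any time, including after scoring; the latest
#' assignment wins and re-exports reflect it.
#'
#' @param proj A project.
#' @param subject_id A registered subject.
#' @param group_label A registered group label.
#' @return The updated project.
#' @export
assign_group <- function(proj, subject_id, group_label) {
  if (!(subject_id %in% names(proj$subjects)))
    abort_etho("referential", "unknown subject '%s'", subject_id)
  if (!(group_label %in% names(proj$groups)))
    abort_etho("referential", "unknown group '%s'", group_label)
  proj$subjects[[subject_id]]$group <- group_label
  proj
}

trial_key <- function(subject, test, session, trial, rater) {
  paste(subject, test, session, trial, rater, sep = "|")
}

#' Record a scored trial in a project
#'
#' @param proj A project.
#' @param trial A validated [scored_trial()]; its subject must be
#'   registered and the (subject, test, session, trial, rater) key unused.
#' @param test_name The test (registered ethogram) the trial belongs to.
#' @return The updated project.
#' @export
record_trial <- function(proj, trial, test_name) {
  if (!(test_name %in% names(proj$ethograms)))
    abort_etho("referential", "unknown test '%s'", test_name)
  if (!(trial$subject_id %in% names(proj$subjects)))
    abort_etho("referential", "unknown subject '%s'", trial$subject_id)
  validate_trial(trial, proj$ethograms[[test_name]])
  key <- trial_key(trial$subject_id, test_name, trial$session_index,
                   trial$trial_index, trial$rater_id)
  if (key %in% names(proj$trials))
    abort_etho("conflict", "trial already recorded for key %s", key)
  proj$trials[[key]] <- list(test_name = test_name, trial = trial)
  proj
}

#' Fetch a recorded trial by key
#' @inheritParams record_trial
#' @param subject_id,session_index,trial_index,rater_id Trial key fields.
#' @return The stored [scored_trial()], or an error if absent.
#' @export
get_trial <- function(proj, subject_id, test_name, session_index = 1L,
                      trial_index = 1L, rater_id = "") {
  key <- trial_key(subject_id, test_name, session_index, trial_index,
                   rater_id)
  if (!(key %in% names(proj$trials)))
    abort_etho("referential", "no trial recorded for key %s", key)
  proj$trials[[key]]$trial
}

# ---- persistence: canonical JSON, deterministic emission -------------------

etho_to_list <- function(e) {
  list(test_name = e$test_name,
       scheme = unclass(e$scheme),
       behaviors = lapply(e$behaviors, unclass),
       novel_designation = e$novel_designation,
       object_pair = as.list(e$object_pair %||% list()))
}

etho_from_list <- function(l) {
  ethogram(l$test_name,
           lapply(l$behaviors, function(b)
             behavior(b$name, b$kind, b$key, b$color)),
           session_scheme(l$scheme$n_sessions, l$scheme$trials_per_session,
                          l$scheme$trial_duration_s),
           novel_designation = l$novel_designation,
           object_pair = if (length(l$object_pair))
             unlist(l$object_pair) else NULL)
}

trial_to_list <- function(tr) {
  list(subject_id = tr$subject_id, session_index = tr$session_index,
       trial_index = tr$trial_index, rater_id = tr$rater_id,
       duration_s = tr$duration_s,
       bouts = list(behavior = as.list(tr$bouts$behavior),
                    start = as.list(tr$bouts$start),
                    end = as.list(tr$bouts$end)),
       points = list(behavior = as.list(tr$points$behavior),
                     t = as.list(tr$points$t)))
}

trial_from_list <- function(l) {
  scored_trial(
    data.frame(behavior = unlist(c(l$bouts$behavior, list(character(0)))),
               start = unlist(c(l$bouts$start, list(numeric(0)))),
               end = unlist(c(l$bouts$end, list(numeric(0)))),
               stringsAsFactors = FALSE),
    data.frame(behavior = unlist(c(l$points$behavior, list(character(0)))),
               t = unlist(c(l$points$t, list(numeric(0)))),
               stringsAsFactors = FALSE),
    l$duration_s, l$subject_id, l$session_index, l$trial_index, l$rater_id)
}

#' Save / load a project file
#'
#' The on-disk store is a single canonical-JSON text file with a fixed
#' field order and full-precision numbers, so `save -> load -> save`
#' produces byte-identical files; the same file doubles as the portable
#' text export for diffing and sharing.
#'
#' @param proj A project.
#' @param path File path (conventionally `*.ethoproj.json`).
#' @return `save_project()` returns `path` invisibly; `load_project()`
#'   returns the project.
#' @export
save_project <- function(proj, path) {
  doc <- list(
    format = "ethoscore-project",
    version = 1L,
    name = proj$name,
    ethograms = lapply(proj$ethograms, etho_to_list),
    groups = proj$groups,
    subjects = lapply(proj$subjects, function(s)
      list(subject_id = s$subject_id, group = s$group,
           descriptors = s$descriptors)),
    trials = lapply(proj$trials, function(rec)
      list(test_name = rec$test_name, trial = trial_to_list(rec$trial))))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path))
    abort_etho("io", "project file not found: %s", path)
  doc <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8"),
                            simplifyVector = FALSE)
  if (!identical(doc$format, "ethoscore-project"))
    abort_etho("io", "not an ethoscore project file: %s", path)
  proj <- project(doc$name)
  proj$ethograms <- lapply(doc$ethograms, etho_from_list)
  proj$groups <- doc$groups
  proj$subjects <- lapply(doc$subjects, function(s)
    list(subject_id = s$subject_id, group = s$group,
         descriptors = s$descriptors))
  proj$trials <- lapply(doc$trials, function(rec)
    list(test_name = rec$test_name, trial = trial_from_list(rec$trial)))
  proj
}

# ---- CSV + map export ------------------------------------------------------

segment_sets_for <- function(trial, etho, segments) {
  if (identical(segments, "whole"))
    return(list(summarize_trial(trial, etho)))
  if (is.list(segments) && !is.null(segments$bins))
    return(segment_summaries(trial, etho, segments$bins))
  if (is.list(segments) && !is.null(segments$window)) {
    w <- segments$window
    ms <- summarize_trial(slice_segment(trial, w[1], w[2]), etho)
    ms$segment <- c(w[1], w[2])
    return(list(ms))
  }
  abort_etho("range",
             "segments must be \"whole\", list(bins = w) or list(window = c(a, b))")
}

fmt_num <- function(x) {
  # 6 decimal places for seconds-valued columns; sub-ms precision exceeds
  # human keystroke accuracy
  ifelse(is.na(x), NA_character_, sprintf("%.6f", x))
}

csv_escape <- function(x) {
  x <- ifelse(is.na(x), "", x)
  need <- grepl("[\",\n\r]", x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Export results to CSV (plus per-animal visual maps)
#'
#' Writes one RFC-4180 CSV row per (subject, session, trial, rater,
#' segment): project, subject, group (empty when unassigned), descriptor
#' columns, segment bounds, then per-behavior
#' `total_s`/`count`/`latency_s`/`latency_censored` blocks, `n_events`,
#' and index columns. Seconds use 6 decimal places, `.` decimal separator,
#' UTF-8, header row. With `maps = TRUE` a PNG visual map is written per
#' trial, named `<project>_<subject>_<test>_s<session>t<trial>_<rater>.png`.
#'
#' @param proj A project.
#' @param test_name Which test to export.
#' @param segments `"whole"` (default), `list(bins = w)` for consecutive
#'   bins of width `w` seconds, or `list(window = c(a, b))`.
#' @param dir Output directory (created if needed).
#' @param maps Write per-animal PNG maps as well?
#' @param style [map_style()] for the maps.
#' @return Invisibly, a list with `csv` (path), `table` (the exported
#'   `data.frame`) and `maps` (paths).
#' @export
export_results <- function(proj, test_name, segments = "whole",
                           dir = ".", maps = FALSE, style = map_style()) {
  if (!(test_name %in% names(proj$ethograms)))
    abort_etho("referential", "unknown test '%s'", test_name)
  etho <- proj$ethograms[[test_name]]
  recs <- Filter(function(r) r$test_name == test_name, proj$trials)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  desc_keys <- sort(unique(unlist(lapply(proj$subjects, function(s)
    names(s$descriptors)))))
  rows <- list()
  map_paths <- character(0)
  if (!length(recs))
    warning(sprintf("no trials recorded for test '%s'; writing header only",
                    test_name))
  for (rec in recs) {
    tr <- rec$trial
    subj <- proj$subjects[[tr$subject_id]]
    for (ms in segment_sets_for(tr, etho, segments)) {
      row <- as.data.frame(ms)
      meta <- data.frame(project = proj$name,
                         subject_id = tr$subject_id,
                         group = subj$group %||% NA_character_,
                         stringsAsFactors = FALSE)
      for (k in desc_keys)
        meta[[k]] <- as.character(subj$descriptors[[k]] %||% NA)
      rows[[length(rows) + 1L]] <- cbind(meta, row[-1L])
    }
    if (maps) {
      mp <- file.path(dir, sprintf("%s_%s_%s_s%dt%d_%s.png", proj$name,
                                   tr$subject_id, test_name,
                                   tr$session_index, tr$trial_index,
                                   tr$rater_id))
      render_map(tr, etho, style, file = mp)
      map_paths <- c(map_paths, mp)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    ms0 <- summarize_trial(
      scored_trial(duration_s = etho$scheme$trial_duration_s), etho)
    skel <- as.data.frame(ms0)[0, , drop = FALSE]
    cbind(data.frame(project = character(0), subject_id = character(0),
                     group = character(0), stringsAsFactors = FALSE),
          skel[-1L])
  }
  csv_path <- file.path(dir, sprintf("%s_%s_results.csv", proj$name,
                                     test_name))
  out <- tab
  for (j in seq_along(out)) {
    cl <- names(out)[j]
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]) &&
        grepl("_s$|_index$|^segment", cl))
      out[[j]] <- fmt_num(out[[j]])
    else if (is.logical(out[[j]]))
      out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
    else out[[j]] <- as.character(out[[j]])
  }
  lines <- c(paste(csv_escape(names(out)), collapse = ","),
             if (nrow(out)) vapply(seq_len(nrow(out)), function(i)
               paste(csv_escape(unlist(out[i, ], use.names = FALSE)),
                     collapse = ","), character(1)))
  con <- file(csv_path, open = "wb")
  writeLines(lines, con, sep = "\r\n", useBytes = TRUE)
  close(con)
  invisible(list(csv = csv_path, table = tab, maps = map_paths))
}

#' @export
print.ethoscore_project <- function(x, ...) {
  cat(sprintf("<project> %s: %d test(s), %d subject(s), %d group(s), %d trial(s)\n",
              x$name, length(x$ethograms), length(x$subjects),
              length(x$groups), length(x$trials)))
  invisible(x)
}
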