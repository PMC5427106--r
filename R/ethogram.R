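#' Define a behavior
#'
#' A behavior is either a *state* (mutually exclusive, has duration; e.g.
#' immobility) or a *point* event (instantaneous, counted; e.g. a head
#' shake). Each behavior is bound to a single keyboard key used during
#' scoring and to a display color used in visual maps.
#'
#' @param name Behavior name, non-empty string, unique within an ethogram.
#' @param kind `"state"` or `"point"`.
#' @param key Single printable character; unique within an ethogram.
#' @param color RGB hex string, e.g. `"#0000FF"`.
#' @return A `behavior` object.
#' @examples
#' behavior("immobility", "state", "i", "#0000FF")
#' @export
behavior <- function(name, kind = c("state", "point"), key, color) {
  kind <- match.arg(kind)
  if (!is_string(name) || !nzchar(name))
    abort_etho("validation", "behavior name must be a non-empty string")
  if (!is_string(key) || nchar(key) != 1L)
    abort_etho("validation", "key for '%s' must be a single character", name)
  if (!is_hex_color(color))
    abort_etho("validation",
               "color for '%s' must be a 6-hex-digit RGB string, got '%s'",
               name, as.character(color)[1])
  structure(list(name = name, kind = kind, key = key, color = color),
            class = "ethoscore_behavior")
}

#' Define a session/trial scheme
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param trials_per_session Trials per session (>= 1).
#' @param trial_duration_s Trial duration in seconds (> 0).
#' @return A `session_scheme` object.
#' @export
session_scheme <- function(n_sessions = 1L, trials_per_session = 1L,
                           trial_duration_s = 300) {
  if (!is_count(n_sessions))
    abort_etho("validation", "n_sessions must be a positive integer")
  if (!is_count(trials_per_session))
    abort_etho("validation", "trials_per_session must be a positive integer")
  if (!is_pos_scalar(trial_duration_s))
    abort_etho("validation", "trial_duration_s must be > 0")
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 trial_duration_s = as.numeric(trial_duration_s)),
            class = "ethoscore_scheme")
}

#' Construct an ethogram
#'
#' An ethogram is the catalogue of behaviors scored in one behavioral test:
#' a named, ordered list of [behavior()]s, a [session_scheme()], and (for
#' novel-object designs) an optional designation of which explored object
#' is the novel one.
#'
#' @param test_name Name of the behavioral test (e.g. `"FST"`).
#' @param behaviors List of [behavior()] objects; at least one state
#'   behavior is required.
#' @param scheme A [session_scheme()].
#' @param novel_designation Optional name of the state behavior scored on
#'   the novel object (NOR). May be overridden per analysis for
#'   counterbalanced designs.
#' @param object_pair Optional character vector of the two state behaviors
#'   that represent object exploration (NOR); used to resolve the familiar
#'   object when computing discrimination/preference indices.
#' @return An `ethogram` object.
#' @seealso [builtin_template()], [customize_template()],
#'   [read_ethogram()], [write_ethogram()]
#' @export
ethogram <- function(test_name, behaviors, scheme = session_scheme(),
                     novel_designation = NULL, object_pair = NULL) {
  etho <- structure(
    list(test_name = test_name, behaviors = behaviors, scheme = scheme,
         novel_designation = novel_designation, object_pair = object_pair),
    class = "ethoscore_ethogram")
  validate_ethogram(etho)
}

#' Validate an ethogram
#'
#' Checks all structural invariants: at least one state behavior, key and
#' name uniqueness, color syntax, scheme positivity, and that
#' `novel_designation` / `object_pair` reference existing state behaviors.
#'
#' @param etho An ethogram.
#' @return `etho`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_ethogram <- function(etho) {
  if (!inherits(etho, "ethoscore_ethogram"))
    abort_etho("validation", "not an ethogram object")
  if (!is_string(etho$test_name) || !nzchar(etho$test_name))
    abort_etho("validation", "test_name must be a non-empty string")
  if (!inherits(etho$scheme, "ethoscore_scheme"))
    abort_etho("validation", "scheme must be a session_scheme object")
  bs <- etho$behaviors
  if (length(bs) == 0L)
    abort_etho("validation", "ethogram has no behaviors")
  ok <- vapply(bs, inherits, logical(1), "ethoscore_behavior")
  if (!all(ok))
    abort_etho("validation", "behaviors must all be behavior objects")
  nm <- vapply(bs, `[[`, character(1), "name")
  ky <- vapply(bs, `[[`, character(1), "key")
  kd <- vapply(bs, `[[`, character(1), "kind")
  if (anyDuplicated(nm))
    abort_etho("validation", "duplicate behavior name: '%s'",
               nm[duplicated(nm)][1])
  if (anyDuplicated(ky))
    abort_etho("validation", "duplicate key binding: '%s' (%s)",
               ky[duplicated(ky)][1],
               paste(nm[ky == ky[duplicated(ky)][1]], collapse = ", "))
  if (!any(kd == "state"))
    abort_etho("validation", "ethogram must contain >= 1 state behavior")
  st <- nm[kd == "state"]
  if (!is.null(etho$novel_designation)) {
    if (!is_string(etho$novel_designation) ||
        !(etho$novel_designation %in% st))
      abort_etho("dangling_reference",
                 "novel_designation '%s' is not a state behavior",
                 as.character(etho$novel_designation)[1])
  }
  if (!is.null(etho$object_pair)) {
    op <- etho$object_pair
    if (!is.character(op) || length(op) != 2L || !all(op %in% st) ||
        op[1] == op[2])
      abort_etho("dangling_reference",
                 "object_pair must name two distinct state behaviors")
  }
  invisible(etho)
}

behavior_names <- function(etho) {
  vapply(etho$behaviors, `[[`, character(1), "name")
}

behavior_kinds <- function(etho) {
  vapply(etho$behaviors, `[[`, character(1), "kind")
}

behavior_keys <- function(etho) {
  vapply(etho$behaviors, `[[`, character(1), "key")
}

behavior_colors <- function(etho) {
  stats::setNames(vapply(etho$behaviors, `[[`, character(1), "color"),
                  behavior_names(etho))
}

#' State / point behavior names of an ethogram
#' @param etho An ethogram.
#' @return Character vector of behavior names.
#' @export
state_behaviors <- function(etho) {
  behavior_names(etho)[behavior_kinds(etho) == "state"]
}

#' @rdname state_behaviors
#' @export
point_behaviors <- function(etho) {
  behavior_names(etho)[behavior_kinds(etho) == "point"]
}

# Default palette used where the source test has no conventional colors.
.default_palette <- c("#FF8C00", "#4B0082", "#808080", "#2E8B57",
                      "#8B4513", "#FF1493")

#' Built-in test templates
#'
#' Returns a ready-to-use ethogram for one of the three supported tests:
#'
#' * `FST` (forced swim test): state behaviors immobility (blue, key `i`),
#'   swimming (red, `s`), climbing (black, `c`); point behavior head_shake
#'   (green, `h`). Scheme: 2 sessions x 1 trial x 300 s (the classic
#'   two-session design scored on the 5-minute second session).
#' * `NOR` (novel object recognition): state behaviors explore_A (red,
#'   `a`), explore_B (black, `b`), general_area (blue, `g`). Scheme:
#'   1 session x 2 trials x 300 s. `explore_A`/`explore_B` form the object
#'   pair; no novel designation is preset (set it per your counterbalancing).
#' * `EPM` (elevated plus maze): state behaviors open_arm (`o`),
#'   closed_arm (`c`), center (`x`); colors from the package's default
#'   palette. Scheme: 1 session x 1 trial x 300 s.
#'
#' Key bindings and the EPM colors are package defaults (documented, not
#' field conventions); remap them with [customize_template()].
#'
#' @param test_name One of `"FST"`, `"NOR"`, `"EPM"`.
#' @return An ethogram.
#' @examples
#' fst <- builtin_template("FST")
#' state_behaviors(fst)
#' @export
builtin_template <- function(test_name) {
  if (!is_string(test_name))
    abort_etho("unsupported_template", "test_name must be a string")
  switch(test_name,
    FST = ethogram("FST",
      list(behavior("immobility", "state", "i", "#0000FF"),
           behavior("swimming",   "state", "s", "#FF0000"),
           behavior("climbing",   "state", "c", "#000000"),
           behavior("head_shake", "point", "h", "#008000")),
      session_scheme(2L, 1L, 300)),
    NOR = ethogram("NOR",
      list(behavior("explore_A",    "state", "a", "#FF0000"),
           behavior("explore_B",    "state", "b", "#000000"),
           behavior("general_area", "state", "g", "#0000FF")),
      session_scheme(1L, 2L, 300),
      object_pair = c("explore_A", "explore_B")),
    EPM = ethogram("EPM",
      list(behavior("open_arm",   "state", "o", .default_palette[1]),
           behavior("closed_arm", "state", "c", .default_palette[2]),
           behavior("center",     "state", "x", .default_palette[3])),
      session_scheme(1L, 1L, 300)),
    abort_etho("unsupported_template",
               "no built-in template for '%s' (supported: FST, NOR, EPM)",
               test_name)
  )
}

#' Customize an ethogram template
#'
#' Applies a set of edits to a base ethogram and re-validates all
#' invariants. The base ethogram is never modified; an empty edit set
#' returns an ethogram equal to the base.
#'
#' @param base Base ethogram.
#' @param remap_keys Named character vector `c(behavior = new_key)`.
#' @param recolor Named character vector `c(behavior = "#RRGGBB")`.
#' @param rename_test New test name.
#' @param scheme Replacement [session_scheme()].
#' @param add List of [behavior()]s to append.
#' @param remove Character vector of behavior names to drop.
#' @param novel_designation New novel designation, or `NA` to clear it.
#' @param object_pair New object pair, or `NA` to clear it.
#' @return A new, validated ethogram.
#' @examples
#' fst <- builtin_template("FST")
#' customize_template(fst, remap_keys = c(immobility = "z"))
#' @export
customize_template <- function(base, remap_keys = NULL, recolor = NULL,
                               rename_test = NULL, scheme = NULL,
                               add = NULL, remove = NULL,
                               novel_designation = NULL,
                               object_pair = NULL) {
  validate_ethogram(base)
  etho <- base
  idx_of <- function(name) {
    i <- match(name, behavior_names(etho))
    if (is.na(i))
      abort_etho("dangling_reference", "no behavior named '%s'", name)
    i
  }
  if (!is.null(remove)) {
    for (nm in remove) {
      i <- idx_of(nm)
      etho$behaviors[[i]] <- NULL
      if (identical(etho$novel_designation, nm))
        abort_etho("dangling_reference",
                   "cannot remove '%s': referenced by novel_designation", nm)
      if (!is.null(etho$object_pair) && nm %in% etho$object_pair)
        abort_etho("dangling_reference",
                   "cannot remove '%s': referenced by object_pair", nm)
    }
  }
  if (!is.null(add))
    etho$behaviors <- c(etho$behaviors,
                        if (inherits(add, "ethoscore_behavior")) list(add)
                        else add)
  if (!is.null(remap_keys))
    for (nm in names(remap_keys)) {
      i <- idx_of(nm)
      etho$behaviors[[i]]$key <- unname(remap_keys[[nm]])
    }
  if (!is.null(recolor))
    for (nm in names(recolor)) {
      i <- idx_of(nm)
      b <- etho$behaviors[[i]]
      etho$behaviors[[i]] <- behavior(b$name, b$kind, b$key,
                                      unname(recolor[[nm]]))
    }
  if (!is.null(rename_test)) etho$test_name <- rename_test
  if (!is.null(scheme)) etho$scheme <- scheme
  if (!is.null(novel_designation))
    etho$novel_designation <-
      if (length(novel_designation) == 1L && is.na(novel_designation)) NULL
      else novel_designation
  if (!is.null(object_pair))
    etho$object_pair <-
      if (length(object_pair) == 1L && is.na(object_pair)) NULL
      else object_pair
  validate_ethogram(etho)
  etho
}

#' Read / write an ethogram file
#'
#' Ethogram files are human-editable UTF-8 text in Debian-control (DCF)
#' style: a header record with `test_name`, scheme fields and optional
#' `novel_designation` / `object_pair`, followed by one record per
#' behavior (`behavior`, `kind`, `key`, `color`), records separated by
#' blank lines. `write_ethogram()` then `read_ethogram()` round-trips
#' field-by-field.
#'
#' @param etho An ethogram.
#' @param path File path (conventionally `*.etho`).
#' @return `read_ethogram()` returns an ethogram; `write_ethogram()`
#'   returns `path` invisibly.
#' @export
write_ethogram <- function(etho, path) {
  validate_ethogram(etho)
  hdr <- c(test_name = etho$test_name,
           n_sessions = as.character(etho$scheme$n_sessions),
           trials_per_session = as.character(etho$scheme$trials_per_session),
           trial_duration_s = format(etho$scheme$trial_duration_s,
                                     digits = 15))
  if (!is.null(etho$novel_designation))
    hdr <- c(hdr, novel_designation = etho$novel_designation)
  if (!is.null(etho$object_pair))
    hdr <- c(hdr, object_pair = paste(etho$object_pair, collapse = ","))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.dcf(t(as.matrix(hdr)), con)
  for (b in etho$behaviors) {
    writeLines("", con)
    write.dcf(t(as.matrix(c(behavior = b$name, kind = b$kind,
                            key = b$key, color = b$color))), con)
  }
  invisible(path)
}

#' @rdname write_ethogram
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path))
    abort_etho("io", "ethogram file not found: %s", path)
  recs <- read.dcf(path)
  if (nrow(recs) < 2L || !("test_name" %in% colnames(recs)))
    abort_etho("validation", "malformed ethogram file: %s", path)
  g <- function(row, field) {
    if (!(field %in% colnames(recs))) return(NA_character_)
    unname(recs[row, field])
  }
  scheme <- session_scheme(as.integer(g(1, "n_sessions")),
                           as.integer(g(1, "trials_per_session")),
                           as.numeric(g(1, "trial_duration_s")))
  behaviors <- lapply(2:nrow(recs), function(i) {
    if (is.na(g(i, "behavior")))
      abort_etho("validation", "behavior record %d lacks a name", i - 1L)
    behavior(g(i, "behavior"), g(i, "kind"), g(i, "key"), g(i, "color"))
  })
  nd <- g(1, "novel_designation")
  op <- g(1, "object_pair")
  ethogram(g(1, "test_name"), behaviors, scheme,
           novel_designation = if (is.na(nd)) NULL else nd,
           object_pair = if (is.na(op)) NULL
                         else strsplit(op, ",", fixed = TRUE)[[1]])
}

#' @export
print.ethoscore_ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %s: %d sessions x %d trials x %g s\n",
              x$test_name, x$scheme$n_sessions,
              x$scheme$trials_per_session, x$scheme$trial_duration_s))
  for (b in x$behaviors)
    cat(sprintf("  [%s] %-14s %-5s %s\n", b$key, b$name, b$kind, b$color))
  if (!is.null(x$novel_designation))
    cat("  novel:", x$novel_designation, "\n")
  invisible(x)
}
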