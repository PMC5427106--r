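#' Summarize a scored trial
#'
#' Computes, for every behavior of the ethogram, the total scored time
#' (state behaviors only), the number of bouts or occurrences, and the
#' latency to the first bout/occurrence. Behaviors that never occur get a
#' censored latency, reported as the trial duration with
#' `latency_censored = TRUE` (the usual convention for e.g. immobility
#' latency in the forced swim test, and it keeps exported tables
#' rectangular). Test-specific indices are attached according to
#' `etho$test_name`: percent open-arm time/entries for EPM, discrimination
#' and preference indices for NOR.
#'
#' @param trial A [scored_trial()].
#' @param etho The governing ethogram.
#' @param novel Optional override of the novel-object designation (NOR);
#'   defaults to `etho$novel_designation`.
#' @param epm_include_center If `TRUE`, center time enters the denominator
#'   of percent open-arm time (default `FALSE`: `open / (open + closed)`).
#' @return A `measure_set` object: trial metadata, a `measures`
#'   `data.frame` (one row per behavior), `n_events` (total state bouts +
#'   point occurrences) and a named numeric vector `indices` (possibly with
#'   `NA` for undefined indices).
#' @examples
#' fst <- builtin_template("FST")
#' tr <- keystrokes_to_timeline(key_events(c(0, 120), c("s", "i")), fst, 300)
#' summarize_trial(tr, fst)
#' @export
summarize_trial <- function(trial, etho, novel = NULL,
                            epm_include_center = FALSE) {
  validate_trial(trial, etho)
  d <- trial$duration_s
  nms <- behavior_names(etho)
  kinds <- behavior_kinds(etho)
  total <- count <- lat <- numeric(length(nms))
  cens <- logical(length(nms))
  bb <- trial$bouts$behavior; bs <- trial$bouts$start; be <- trial$bouts$end
  pb <- trial$points$behavior; ptt <- trial$points$t
  for (i in seq_along(nms)) {
    if (kinds[i] == "state") {
      sel <- bb == nms[i]
      total[i] <- sum(be[sel] - bs[sel])
      count[i] <- sum(sel)
      first <- if (count[i]) min(bs[sel]) else NA_real_
    } else {
      sel <- pb == nms[i]
      total[i] <- 0
      count[i] <- sum(sel)
      first <- if (count[i]) min(ptt[sel]) else NA_real_
    }
    cens[i] <- is.na(first)
    lat[i] <- if (cens[i]) d else first
  }
  ms <- structure(
    list(subject_id = trial$subject_id,
         session_index = trial$session_index,
         trial_index = trial$trial_index,
         rater_id = trial$rater_id,
         duration_s = d,
         measures = fast_df(behavior = unname(nms), kind = unname(kinds),
                            total_s = total, count = as.integer(count),
                            latency_s = lat, latency_censored = cens),
         n_events = as.integer(sum(count)),
         indices = numeric(0),
         segment = NULL),
    class = "ethoscore_measures")
  ms$indices <- switch(etho$test_name,
    EPM = epm_measures(ms, include_center = epm_include_center),
    NOR = {
      nv <- novel %||% etho$novel_designation
      if (is.null(nv) || is.null(etho$object_pair))
        c(discrimination_index = NA_real_, preference_index = NA_real_)
      else nor_indices(ms, novel = nv,
                       familiar = setdiff(etho$object_pair, nv)[1])
    },
    numeric(0))
  ms
}

measure_row <- function(ms, behavior) {
  i <- match(behavior, ms$measures$behavior)
  if (is.na(i))
    abort_etho("schema_mismatch", "behavior '%s' not in measure set",
               behavior)
  ms$measures[i, , drop = FALSE]
}

#' Elevated plus maze indices
#'
#' Computes `pct_open_time`, `open_entries`, `closed_entries` and
#' `pct_open_entries` from a measure set containing `open_arm` and
#' `closed_arm` behaviors. An "entry" is the start of an arm bout (no
#' minimum-duration debounce; manual scoring already debounces). By
#' default center time is excluded from the percent-time denominator:
#' `100 * open / (open + closed)`. When no arm time (or no arm entry) was
#' scored the corresponding percentage is undefined and reported as `NA`,
#' never as 0.
#'
#' @param ms A measure set from [summarize_trial()].
#' @param include_center Include center time in the time denominator.
#' @return Named numeric vector of the four indices.
#' @export
epm_measures <- function(ms, include_center = FALSE) {
  op <- measure_row(ms, "open_arm")
  cl <- measure_row(ms, "closed_arm")
  ct_total <- if ("center" %in% ms$measures$behavior)
    measure_row(ms, "center")$total_s else 0
  den_t <- op$total_s + cl$total_s + if (include_center) ct_total else 0
  den_e <- op$count + cl$count
  c(pct_open_time = if (den_t > 0) 100 * op$total_s / den_t else NA_real_,
    open_entries = as.numeric(op$count),
    closed_entries = as.numeric(cl$count),
    pct_open_entries = if (den_e > 0) 100 * op$count / den_e else NA_real_)
}

#' Novel object recognition indices
#'
#' Discrimination index `DI = (T_novel - T_familiar) / (T_novel +
#' T_familiar)` in `[-1, 1]` and preference index `PI = 100 * T_novel /
#' (T_novel + T_familiar)` in `[0, 100]`; the identity `PI = 50 * (DI + 1)`
#' holds exactly. If neither object was explored both indices are
#' undefined (`NA`).
#'
#' @param ms A measure set from [summarize_trial()].
#' @param novel Name of the state behavior scored on the novel object.
#' @param familiar Name of the state behavior scored on the familiar
#'   object.
#' @return Named numeric vector `c(discrimination_index, preference_index)`.
#' @export
nor_indices <- function(ms, novel, familiar) {
  tn <- measure_row(ms, novel)$total_s
  tf <- measure_row(ms, familiar)$total_s
  den <- tn + tf
  if (den <= 0)
    return(c(discrimination_index = NA_real_, preference_index = NA_real_))
  di <- (tn - tf) / den
  # PI derived from DI so the identity PI = 50 (DI + 1) is bitwise exact
  c(discrimination_index = di, preference_index = 50 * (di + 1))
}

#' Per-segment summaries
#'
#' Splits the trial into consecutive bins `[k*bin_s, (k+1)*bin_s)` covering
#' `[0, duration)` (final partial bin included) and summarizes each via
#' [slice_segment()] + [summarize_trial()]. Per-behavior totals across the
#' bins sum to the whole-trial totals. Each returned measure set carries
#' its absolute window in `$segment = c(start, end)`; latencies are
#' relative to the bin start.
#'
#' @param trial A scored trial.
#' @param etho The governing ethogram.
#' @param bin_s Bin width in seconds (> 0).
#' @param ... Passed on to [summarize_trial()].
#' @return List of measure sets, one per bin, in time order.
#' @export
segment_summaries <- function(trial, etho, bin_s, ...) {
  if (!is_pos_scalar(bin_s))
    abort_etho("range", "bin_s must be > 0")
  d <- trial$duration_s
  n_bins <- ceiling(d / bin_s - EPS_T)
  starts <- (seq_len(n_bins) - 1) * bin_s
  lapply(starts, function(a) {
    b <- min(a + bin_s, d)
    ms <- summarize_trial(slice_segment(trial, a, b), etho, ...)
    ms$duration_s <- b - a
    ms$segment <- c(a, b)
    ms
  })
}

#' Flatten measure sets to a one-row-per-set data frame
#'
#' Wide layout used for CSV export: metadata and segment bounds, then per
#' behavior `<behavior>_total_s` / `_count` / `_latency_s` /
#' `_latency_censored`, then `n_events` and one column per index.
#'
#' @param x A measure set or list of measure sets.
#' @param ... Unused.
#' @return A `data.frame` with one row per measure set.
#' @export
as.data.frame.ethoscore_measures <- function(x, ...) {
  seg <- x$segment %||% c(0, x$duration_s)
  row <- data.frame(subject_id = x$subject_id,
                    session_index = x$session_index,
                    trial_index = x$trial_index,
                    rater_id = x$rater_id,
                    segment_start_s = seg[1], segment_end_s = seg[2],
                    stringsAsFactors = FALSE)
  m <- x$measures
  for (i in seq_len(nrow(m))) {
    row[[paste0(m$behavior[i], "_total_s")]] <- m$total_s[i]
    row[[paste0(m$behavior[i], "_count")]] <- m$count[i]
    row[[paste0(m$behavior[i], "_latency_s")]] <- m$latency_s[i]
    row[[paste0(m$behavior[i], "_latency_censored")]] <- m$latency_censored[i]
  }
  row$n_events <- x$n_events
  for (nm in names(x$indices)) row[[nm]] <- unname(x$indices[[nm]])
  row
}

#' @export
print.ethoscore_measures <- function(x, ...) {
  cat(sprintf("<measure_set> subject=%s s%dt%d rater=%s (%g s)\n",
              x$subject_id, x$session_index, x$trial_index, x$rater_id,
              x$duration_s))
  print(x$measures, row.names = FALSE)
  if (length(x$indices)) {
    cat("indices:\n")
    print(x$indices)
  }
  invisible(x)
}
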