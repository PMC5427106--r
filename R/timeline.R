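#' Keystroke events
#'
#' Builds the validated event table consumed by
#' [keystrokes_to_timeline()]: one row per keystroke, time in seconds from
#' trial start. Times must be non-decreasing; ties keep input order.
#'
#' @param t Numeric vector of event times (seconds, >= 0).
#' @param key Character vector of single-character keys.
#' @return A `data.frame` with columns `t`, `key`.
#' @export
key_events <- function(t, key) {
  if (length(t) != length(key))
    abort_etho("validation", "t and key must have equal length")
  t <- as.numeric(t)
  key <- as.character(key)
  if (length(t) && (anyNA(t) || any(t < 0)))
    abort_etho("validation", "event times must be finite and >= 0")
  if (length(key) && any(nchar(key) != 1L))
    abort_etho("validation", "keys must be single characters")
  data.frame(t = t, key = key, stringsAsFactors = FALSE)
}

#' Read a keystroke log file
#'
#' Log format: UTF-8 text, one event per line as
#' `<t_seconds><TAB><key>`, decimal point `.`, `#` starts a comment,
#' blank lines ignored.
#'
#' @param path Path to the log file.
#' @return A `data.frame` as returned by [key_events()].
#' @export
read_keylog <- function(path) {
  if (!file.exists(path))
    abort_etho("io", "keystroke log not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(key_events(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    abort_etho("io", "malformed log line %d: expected <t><TAB><key>", bad[1])
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  if (anyNA(t))
    abort_etho("io", "non-numeric time on log line %d", which(is.na(t))[1])
  key_events(t, trimws(vapply(parts, `[[`, "", 2L)))
}

#' Construct a scored trial
#'
#' A scored trial is the timeline for one animal in one trial: an ordered
#' list of pairwise-disjoint state bouts (half-open intervals
#' `[start, end)`), point-event occurrences, and the trial duration. Time
#' before the first state keystroke (or between explicitly unscored
#' stretches) is an unscored gap, not a bout.
#'
#' @param bouts `data.frame` with columns `behavior`, `start`, `end`.
#' @param points `data.frame` with columns `behavior`, `t`.
#' @param duration_s Trial duration in seconds.
#' @param subject_id,session_index,trial_index,rater_id Trial metadata.
#' @param etho Optional ethogram to validate behavior names/kinds against.
#' @return A `scored_trial` object.
#' @export
scored_trial <- function(bouts = NULL, points = NULL, duration_s,
                         subject_id = "", session_index = 1L,
                         trial_index = 1L, rater_id = "", etho = NULL) {
  if (is.null(bouts))
    bouts <- fast_df(behavior = character(0), start = numeric(0),
                     end = numeric(0))
  if (is.null(points))
    points <- fast_df(behavior = character(0), t = numeric(0))
  bouts <- fast_df(behavior = as.character(bouts$behavior),
                   start = as.numeric(bouts$start),
                   end = as.numeric(bouts$end))
  points <- fast_df(behavior = as.character(points$behavior),
                    t = as.numeric(points$t))
  trial <- structure(
    list(subject_id = subject_id,
         session_index = as.integer(session_index),
         trial_index = as.integer(trial_index),
         rater_id = rater_id,
         duration_s = as.numeric(duration_s),
         bouts = bouts, points = points),
    class = "ethoscore_trial")
  validate_trial(trial, etho)
}

#' Validate a scored trial
#'
#' Checks all trial invariants: bouts sorted by start, pairwise disjoint,
#' within `[0, duration_s]`, total bout time not exceeding the duration,
#' points within range, and (if an ethogram is supplied) that every bout
#' names a state behavior and every point a point behavior of that
#' ethogram, with session/trial indices inside the scheme.
#'
#' @param trial A scored trial.
#' @param etho Optional governing ethogram.
#' @return `trial` invisibly if valid, otherwise an error.
#' @export
validate_trial <- function(trial, etho = NULL) {
  if (!inherits(trial, "ethoscore_trial"))
    abort_etho("validation", "not a scored_trial object")
  d <- trial$duration_s
  if (!is_pos_scalar(d))
    abort_etho("validation", "duration_s must be > 0")
  b <- trial$bouts
  if (nrow(b)) {
    if (any(b$start < -EPS_T) || any(b$end > d + EPS_T))
      abort_etho("validation", "bout outside [0, duration_s]")
    if (any(b$end - b$start <= 0))
      abort_etho("validation", "bout with non-positive length")
    if (is.unsorted(b$start, strictly = FALSE))
      abort_etho("validation", "bouts must be sorted by start")
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)] - EPS_T))
      abort_etho("validation", "bouts must be pairwise disjoint")
    if (sum(b$end - b$start) > d + 1e-6)
      abort_etho("validation", "total bout time exceeds duration")
  }
  p <- trial$points
  if (nrow(p) && (any(p$t < -EPS_T) || any(p$t > d + EPS_T)))
    abort_etho("validation", "point occurrence outside [0, duration_s]")
  if (!is.null(etho)) {
    st <- state_behaviors(etho); pt <- point_behaviors(etho)
    if (nrow(b) && !all(b$behavior %in% st))
      abort_etho("schema_mismatch", "bout behavior '%s' is not a state behavior of '%s'",
                 setdiff(b$behavior, st)[1], etho$test_name)
    if (nrow(p) && !all(p$behavior %in% pt))
      abort_etho("schema_mismatch", "point behavior '%s' is not a point behavior of '%s'",
                 setdiff(p$behavior, pt)[1], etho$test_name)
    if (trial$session_index > etho$scheme$n_sessions ||
        trial$trial_index > etho$scheme$trials_per_session)
      abort_etho("validation",
                 "session/trial index outside the ethogram scheme")
  }
  invisible(trial)
}

#' Convert keystrokes to a bout timeline
#'
#' Toggle semantics: a state-behavior keystroke at time `t` closes any open
#' bout at `t` and opens a bout of that behavior; the final open bout
#' closes at `duration_s`. Time before the first state keystroke is an
#' unscored gap. Point-behavior keystrokes insert an occurrence without
#' disturbing the open bout. Re-pressing the key of the currently open
#' behavior is a no-op (a bout is one contiguous episode, so bout counts
#' measure behavior transitions). Two state keys at the same instant
#' produce a zero-length bout, which is dropped: the later keystroke wins.
#'
#' @param events Event table from [key_events()] / [read_keylog()], sorted
#'   by time (ties keep input order).
#' @param etho Governing ethogram; keys are resolved against its bindings.
#' @param duration_s Trial duration in seconds; events after it are
#'   rejected, not clamped.
#' @param subject_id,session_index,trial_index,rater_id Trial metadata.
#' @param skip_unknown If `TRUE`, events with unbound keys are dropped with
#'   a warning instead of raising an error.
#' @param strict If `TRUE`, require full coverage (no unscored gap before
#'   the first state keystroke).
#' @return A validated [scored_trial()].
#' @examples
#' fst <- builtin_template("FST")
#' ev <- key_events(c(0, 5, 20), c("s", "h", "i"))
#' keystrokes_to_timeline(ev, fst, duration_s = 30)
#' @export
keystrokes_to_timeline <- function(events, etho, duration_s,
                                   subject_id = "", session_index = 1L,
                                   trial_index = 1L, rater_id = "",
                                   skip_unknown = FALSE, strict = FALSE) {
  validate_ethogram(etho)
  if (!is_pos_scalar(duration_s))
    abort_etho("validation", "duration_s must be > 0")
  if (!is.data.frame(events) || !all(c("t", "key") %in% names(events)))
    abort_etho("validation", "events must have columns t and key")
  if (nrow(events)) {
    if (is.unsorted(events$t, strictly = FALSE))
      abort_etho("ordering", "events must be sorted by time")
    if (any(events$t > duration_s + EPS_T))
      abort_etho("out_of_range",
                 "event at t=%g exceeds trial duration %g s",
                 events$t[events$t > duration_s + EPS_T][1], duration_s)
    if (any(events$t < 0))
      abort_etho("out_of_range", "negative event time")
  }
  keys <- behavior_keys(etho)
  nms <- behavior_names(etho)
  kinds <- behavior_kinds(etho)
  idx <- match(events$key, keys)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    if (!skip_unknown)
      abort_etho("unknown_key", "unknown key '%s' at t=%g s",
                 events$key[bad[1]], events$t[bad[1]])
    warning(sprintf("dropping %d event(s) with unbound keys (e.g. '%s')",
                    length(bad), events$key[bad[1]]))
    events <- events[-bad, , drop = FALSE]
    idx <- idx[-bad]
  }
  beh <- nms[idx]
  kind <- kinds[idx]

  pts <- fast_df(behavior = beh[kind == "point"],
                 t = events$t[kind == "point"])
  pts <- pts[pts$t < duration_s | abs(pts$t - duration_s) <= EPS_T, ,
             drop = FALSE]

  st_t <- events$t[kind == "state"]
  st_b <- beh[kind == "state"]
  starts <- ends <- numeric(0); labs <- character(0)
  open_b <- NA_character_; open_t <- NA_real_
  for (i in seq_along(st_t)) {
    if (!is.na(open_b) && identical(st_b[i], open_b)) next  # no-op repeat
    if (!is.na(open_b) && st_t[i] > open_t) {               # close; drop 0-len
      starts <- c(starts, open_t); ends <- c(ends, st_t[i])
      labs <- c(labs, open_b)
    }
    open_b <- st_b[i]; open_t <- st_t[i]
  }
  if (!is.na(open_b) && duration_s > open_t) {
    starts <- c(starts, open_t); ends <- c(ends, duration_s)
    labs <- c(labs, open_b)
  }
  if (strict && (!length(starts) || starts[1] > EPS_T))
    abort_etho("validation", "strict mode: trial has an unscored gap")
  scored_trial(fast_df(behavior = labs, start = starts, end = ends),
               pts, duration_s, subject_id, session_index, trial_index,
               rater_id, etho = etho)
}

#' Slice a time segment out of a trial
#'
#' Returns a new trial covering the window `[a, b)`: bouts are intersected
#' with the window and shifted so the segment starts at 0; point
#' occurrences with `a <= t < b` are kept and shifted likewise. The input
#' trial is unmodified.
#'
#' @param trial A scored trial.
#' @param a,b Window bounds in seconds, `0 <= a < b <= duration_s`.
#' @return A new scored trial of duration `b - a`.
#' @export
slice_segment <- function(trial, a, b) {
  validate_trial(trial)
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      a < 0 || b > trial$duration_s + EPS_T || a >= b)
    abort_etho("range", "need 0 <= a < b <= duration (got a=%s, b=%s)",
               format(a), format(b))
  bo <- trial$bouts
  s <- pmax(bo$start, a); e <- pmin(bo$end, b)
  keep <- e - s > EPS_T
  bo <- fast_df(behavior = bo$behavior[keep], start = s[keep] - a,
                end = e[keep] - a)
  po <- trial$points
  keep <- po$t >= a & po$t < b
  po <- fast_df(behavior = po$behavior[keep], t = po$t[keep] - a)
  scored_trial(bo, po, b - a, trial$subject_id, trial$session_index,
               trial$trial_index, trial$rater_id)
}

#' Fraction of the trial covered by scored bouts
#'
#' Quality-control measure: `sum(bout durations) / duration_s`. 1 means
#' the whole trial is scored; less than 1 flags unscored gaps.
#'
#' @param trial A scored trial.
#' @return A fraction in `[0, 1]`.
#' @export
coverage <- function(trial) {
  validate_trial(trial)
  if (!nrow(trial$bouts)) return(0)
  sum(trial$bouts$end - trial$bouts$start) / trial$duration_s
}

# label each time in `times` with the state behavior whose bout contains it,
# or "gap"; vectorized via findInterval over bout starts.
state_at <- function(trial, times) {
  b <- trial$bouts
  if (!nrow(b)) return(rep("gap", length(times)))
  i <- findInterval(times, b$start)
  lab <- rep("gap", length(times))
  hit <- i >= 1L
  hit[hit] <- times[hit] < b$end[i[hit]]
  lab[hit] <- b$behavior[i[hit]]
  lab
}

#' @export
print.ethoscore_trial <- function(x, ...) {
  cat(sprintf("<scored_trial> subject=%s s%dt%d rater=%s duration=%gs\n",
              x$subject_id, x$session_index, x$trial_index, x$rater_id,
              x$duration_s))
  cat(sprintf("  %d bout(s), %d point(s), coverage %.3f\n",
              nrow(x$bouts), nrow(x$points), coverage(x)))
  invisible(x)
}
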