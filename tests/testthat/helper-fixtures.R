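# Shared fixtures and independent oracles.

fst_etho <- function() builtin_template("FST")

# Random keystroke log over an ethogram's keys; times sorted within [0, d].
random_events <- function(etho, duration_s, n = NULL) {
  keys <- vapply(etho$behaviors, `[[`, character(1), "key")
  n <- n %||% sample(0:25, 1)
  if (n == 0) return(key_events(numeric(0), character(0)))
  # times on the oracle's 10-ms grid: keeps the one-sample-width bound
  # exact (off-grid boundaries would each contribute up to one sample of
  # error) and still exceeds human keystroke timing precision
  key_events(sort(floor(runif(n, 0, duration_s) * 100) / 100),
             sample(keys, n, replace = TRUE))
}

# Independent sampling oracle: label each sample (10 ms grid midpoints) by
# the last *state* keystroke at or before it; per-behavior time = samples
# x step; counts/latency recomputed from the raw keystroke stream, not
# from the timeline path under test.
sampling_oracle <- function(events, etho, duration_s, step = 0.01) {
  keys <- vapply(etho$behaviors, `[[`, character(1), "key")
  nms <- vapply(etho$behaviors, `[[`, character(1), "name")
  kinds <- vapply(etho$behaviors, `[[`, character(1), "kind")
  idx <- match(events$key, keys)
  st <- kinds[idx] == "state"
  stt <- events$t[st]; stb <- nms[idx][st]
  # last state keystroke at or before each sample midpoint
  mids <- seq(step / 2, duration_s, by = step)
  lab <- rep("gap", length(mids))
  if (length(stt)) {
    j <- findInterval(mids, stt)
    lab[j >= 1] <- stb[j[j >= 1]]
  }
  totals <- vapply(nms, function(nm) sum(lab == nm) * step, numeric(1))
  # transition counts from the keystroke stream (repeat of open state is
  # a no-op; simultaneous keys: later wins)
  counts <- stats::setNames(numeric(length(nms)), nms)
  lats <- stats::setNames(rep(NA_real_, length(nms)), nms)
  open <- NA_character_; open_t <- NA_real_
  for (i in seq_along(stt)) {
    if (!is.na(open) && identical(stb[i], open)) next
    if (!is.na(open) && stt[i] > open_t) {
      counts[open] <- counts[open] + 1
      if (is.na(lats[open])) lats[open] <- open_t
    }
    open <- stb[i]; open_t <- stt[i]
  }
  if (!is.na(open) && duration_s > open_t) {
    counts[open] <- counts[open] + 1
    if (is.na(lats[open])) lats[open] <- open_t
  }
  ptt <- events$t[!st & events$t <= duration_s]
  ptb <- nms[idx][!st & events$t <= duration_s]
  for (nm in nms[kinds == "point"]) {
    counts[nm] <- sum(ptb == nm)
    if (counts[nm] > 0 && is.na(lats[nm])) lats[nm] <- min(ptt[ptb == nm])
  }
  list(totals = totals, counts = counts, latencies = lats, labels = lab)
}

# Two-bout toy trial used across modules.
toy_trial <- function(duration = 300) {
  scored_trial(data.frame(behavior = c("swimming", "immobility"),
                          start = c(0, 120), end = c(120, 300)),
               data.frame(behavior = rep("head_shake", 4),
                          t = c(10, 50, 100, 200)),
               duration_s = duration, subject_id = "R1", rater_id = "A")
}
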