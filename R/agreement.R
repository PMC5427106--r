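#' A paired measure vector for two raters
#'
#' One measure (e.g. immobility total time), with one value per animal for
#' each of two raters, aligned by subject.
#'
#' @param measure Measure name.
#' @param a,b Numeric vectors of equal length (rater A, rater B).
#' @param subjects Optional subject ids (same length).
#' @return A `measure_pair` object.
#' @export
measure_pair <- function(measure, a, b, subjects = NULL) {
  if (length(a) != length(b))
    abort_etho("validation", "rater vectors for '%s' differ in length",
               measure)
  if (!is.null(subjects) && length(subjects) != length(a))
    abort_etho("validation", "subjects must match vector length")
  structure(list(measure = measure, a = as.numeric(a), b = as.numeric(b),
                 subjects = subjects),
            class = "ethoscore_pair")
}

#' Per-measure inter-rater correlation
#'
#' For each measure pair, the Pearson product-moment correlation between
#' the two raters' per-animal values and its two-tailed p-value from the t
#' reference distribution with `n - 2` degrees of freedom — the analysis
#' used to validate manual scoring across raters. Pairs where either
#' rater's vector has zero variance have an undefined correlation and are
#' reported as `NA` with a reason, not as 0.
#'
#' @param pairs A [measure_pair()] or list of them.
#' @return A `data.frame` with columns `measure`, `n`, `r`, `p`, `note`.
#' @examples
#' measure_agreement(measure_pair("immobility_s", c(1, 2, 3, 4),
#'                                c(1.1, 2.2, 2.9, 4.3)))
#' @export
measure_agreement <- function(pairs) {
  if (inherits(pairs, "ethoscore_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    n <- length(p$a)
    if (n < 3L)
      abort_etho("insufficient_n",
                 "measure '%s': need n >= 3 animals, got %d", p$measure, n)
    if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
      return(data.frame(measure = p$measure, n = n, r = NA_real_,
                        p = NA_real_, note = "zero variance",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(p$a, p$b, method = "pearson",
                          alternative = "two.sided")
    data.frame(measure = p$measure, n = n, r = unname(ct$estimate),
               p = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build measure pairs from two raters' trials
#'
#' Aligns two lists of scored trials by `subject_id` and extracts, for
#' every ethogram behavior, paired per-animal vectors of total time (state
#' behaviors) and count (all behaviors; point behaviors enter as counts
#' only), plus the total number of recorded events. Animals present in
#' only one rater's list are dropped pairwise with a warning.
#'
#' @param trials_a,trials_b Lists of scored trials (one per animal) from
#'   raters A and B.
#' @param etho The governing ethogram.
#' @return List of [measure_pair()]s.
#' @export
trial_measure_pairs <- function(trials_a, trials_b, etho) {
  sa <- vapply(trials_a, `[[`, character(1), "subject_id")
  sb <- vapply(trials_b, `[[`, character(1), "subject_id")
  common <- intersect(sa, sb)
  if (length(common) < length(sa) || length(common) < length(sb))
    warning(sprintf("dropping %d animal(s) present for only one rater",
                    length(sa) + length(sb) - 2L * length(common)))
  msa <- lapply(trials_a[match(common, sa)], summarize_trial, etho = etho)
  msb <- lapply(trials_b[match(common, sb)], summarize_trial, etho = etho)
  col <- function(sets, behavior, what)
    vapply(sets, function(ms) measure_row(ms, behavior)[[what]], numeric(1))
  pairs <- list()
  for (bn in behavior_names(etho)) {
    kind <- behavior_kinds(etho)[match(bn, behavior_names(etho))]
    if (kind == "state")
      pairs[[paste0(bn, "_total_s")]] <-
        measure_pair(paste0(bn, "_total_s"), col(msa, bn, "total_s"),
                     col(msb, bn, "total_s"), common)
    pairs[[paste0(bn, "_count")]] <-
      measure_pair(paste0(bn, "_count"), col(msa, bn, "count"),
                   col(msb, bn, "count"), common)
  }
  pairs[["n_events"]] <- measure_pair(
    "n_events", vapply(msa, `[[`, numeric(1), "n_events"),
    vapply(msb, `[[`, numeric(1), "n_events"), common)
  pairs
}

cohen_kappa <- function(la, lb) {
  labs <- union(unique(la), unique(lb))
  ta <- factor(la, levels = labs); tb <- factor(lb, levels = labs)
  cm <- table(ta, tb)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)  # single label: undefined
  (po - pe) / (1 - pe)
}

#' Timeline concordance between two scorings
#'
#' Samples both timelines at the midpoints of consecutive `step_s` windows
#' covering `[0, duration)`, labels each sample with its state behavior
#' (or `"gap"`), and reports the percentage of matching samples plus
#' Cohen's kappa over the label confusion matrix. This turns the visual
#' side-by-side comparison of two raters' maps into a number. Point
#' behaviors are excluded (instantaneous events have no duration to
#' match). Kappa is `NA` when only a single label occurs in both
#' timelines (chance agreement is then 1 and kappa is undefined).
#'
#' @param a,b Scored trials of the same animal with equal durations.
#' @param step_s Sampling step in seconds (default 0.1).
#' @return List with `percent_agreement` (0-100), `kappa`, `n_samples`,
#'   `step_s`.
#' @export
timeline_concordance <- function(a, b, step_s = 0.1) {
  validate_trial(a); validate_trial(b)
  if (abs(a$duration_s - b$duration_s) > EPS_T)
    abort_etho("input", "trials have different durations (%g vs %g s)",
               a$duration_s, b$duration_s)
  if (!is_pos_scalar(step_s))
    abort_etho("range", "step_s must be > 0")
  d <- a$duration_s
  n_full <- floor(d / step_s + EPS_T)
  mids <- (seq_len(n_full) - 0.5) * step_s
  if (n_full * step_s < d - EPS_T)
    mids <- c(mids, (n_full * step_s + d) / 2)  # final partial window
  la <- state_at(a, mids); lb <- state_at(b, mids)
  list(percent_agreement = 100 * mean(la == lb),
       kappa = cohen_kappa(la, lb),
       n_samples = length(mids), step_s = step_s)
}
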