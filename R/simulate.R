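#' Semi-Markov behavior model
#'
#' Generative model for synthetic scoring sessions: an alternating-renewal
#' (semi-Markov) process over the state behaviors — bout lengths drawn per
#' state from an exponential or gamma distribution with the given mean,
#' transitions from a zero-diagonal stochastic matrix `P`, initial state
#' from `pi` — plus independent homogeneous Poisson processes for point
#' behaviors.
#'
#' @param states Character vector of state behavior names.
#' @param mean_s Mean bout duration per state (seconds), recycled.
#' @param dist `"exponential"` or `"gamma"`.
#' @param shape Gamma shape (used when `dist = "gamma"`).
#' @param P Transition matrix over states (zero diagonal, rows sum to 1);
#'   default: uniform over the other states.
#' @param pi0 Initial state distribution; default uniform.
#' @param point_rates Named numeric vector of Poisson rates (events per
#'   second) for point behaviors; may be empty.
#' @return A `behavior_model` object.
#' @export
behavior_model <- function(states, mean_s, dist = c("exponential", "gamma"),
                           shape = 2, P = NULL, pi0 = NULL,
                           point_rates = numeric(0)) {
  dist <- match.arg(dist)
  k <- length(states)
  if (k < 1L) abort_etho("validation", "need >= 1 state")
  mean_s <- rep_len(as.numeric(mean_s), k)
  if (any(mean_s <= 0)) abort_etho("validation", "mean durations must be > 0")
  if (is.null(P)) {
    P <- matrix(if (k > 1) 1 / (k - 1) else 0, k, k)
    diag(P) <- 0
  }
  P <- as.matrix(P)
  if (k > 1 && (any(abs(rowSums(P) - 1) > 1e-9) || any(diag(P) != 0)))
    abort_etho("validation",
               "P must have zero diagonal and rows summing to 1")
  pi0 <- pi0 %||% rep(1 / k, k)
  if (abs(sum(pi0) - 1) > 1e-9)
    abort_etho("validation", "pi0 must sum to 1")
  if (length(point_rates) && (is.null(names(point_rates)) ||
                              any(point_rates < 0)))
    abort_etho("validation", "point_rates must be named and >= 0")
  structure(list(states = states, mean_s = mean_s, dist = dist,
                 shape = shape, P = P, pi0 = pi0,
                 point_rates = point_rates),
            class = "ethoscore_model")
}

#' Default forced-swim-test behavior model
#'
#' A realistic 3-state FST session for a 5-minute trial: immobility bouts
#' mean 15 s, swimming 10 s, climbing 5 s (exponential), uniform
#' transitions, and head shakes at 0.02 events/s (about 6 per trial).
#' Parameter choices are documented in the methods vignette.
#'
#' @return A [behavior_model()] matching [builtin_template]`("FST")`.
#' @export
fst_model <- function() {
  behavior_model(c("immobility", "swimming", "climbing"),
                 mean_s = c(15, 10, 5),
                 point_rates = c(head_shake = 0.02))
}

draw_bout_length <- function(model, i) {
  switch(model$dist,
         exponential = stats::rexp(1, rate = 1 / model$mean_s[i]),
         gamma = stats::rgamma(1, shape = model$shape,
                               scale = model$mean_s[i] / model$shape))
}

#' Simulate a scored trial
#'
#' Generates one fully scored trial (coverage 1) from a [behavior_model()]:
#' draw the initial state from `pi0`, draw a bout length, transition via
#' `P`, repeat until the duration is reached, clipping the final bout;
#' point events come from homogeneous Poisson processes. Deterministic
#' given `seed`.
#'
#' @param model A [behavior_model()] consistent with `etho`.
#' @param etho The governing ethogram.
#' @param duration_s Trial duration; defaults to the ethogram scheme.
#' @param seed Integer seed.
#' @param subject_id,session_index,trial_index,rater_id Trial metadata.
#' @return A validated [scored_trial()].
#' @examples
#' tr <- simulate_trial(fst_model(), builtin_template("FST"), seed = 42)
#' coverage(tr)
#' @export
simulate_trial <- function(model, etho, duration_s = NULL, seed = 1L,
                           subject_id = "sim", session_index = 1L,
                           trial_index = 1L, rater_id = "simA") {
  validate_ethogram(etho)
  if (!all(model$states %in% state_behaviors(etho)) ||
      !all(names(model$point_rates) %in% point_behaviors(etho)))
    abort_etho("schema_mismatch",
               "model behaviors do not match the ethogram")
  d <- duration_s %||% etho$scheme$trial_duration_s
  set.seed(as.integer(seed))
  k <- length(model$states)
  s <- sample.int(k, 1L, prob = model$pi0)
  t0 <- 0; starts <- ends <- numeric(0); labs <- character(0)
  while (t0 < d) {
    len <- draw_bout_length(model, s)
    t1 <- min(t0 + len, d)
    if (t1 > t0) {
      starts <- c(starts, t0); ends <- c(ends, t1)
      labs <- c(labs, model$states[s])
    }
    t0 <- t1
    if (k > 1) s <- sample.int(k, 1L, prob = model$P[s, ])
  }
  pts <- data.frame(behavior = character(0), t = numeric(0),
                    stringsAsFactors = FALSE)
  for (pb in names(model$point_rates)) {
    n <- stats::rpois(1, model$point_rates[[pb]] * d)
    if (n > 0)
      pts <- rbind(pts, data.frame(behavior = pb,
                                   t = sort(stats::runif(n, 0, d)),
                                   stringsAsFactors = FALSE))
  }
  pts <- pts[order(pts$t), , drop = FALSE]
  scored_trial(data.frame(behavior = labs, start = starts, end = ends,
                          stringsAsFactors = FALSE),
               pts, d, subject_id, session_index, trial_index, rater_id,
               etho = etho)
}

#' Simulate a cohort of animals
#'
#' One trial per animal; animal `i` uses seed `seed + i - 1` (documented
#' counter-based sub-streams, so cohorts are reproducible and animals
#' independent). Keep `seed + n_subjects` below `2^31`.
#'
#' @param model,etho,duration_s As in [simulate_trial()].
#' @param n_subjects Number of animals.
#' @param seed Base seed.
#' @param rater_id Rater label attached to every trial.
#' @return List of scored trials with subject ids `"S01"`, `"S02"`, ...
#' @export
simulate_cohort <- function(model, etho, n_subjects, seed = 1L,
                            duration_s = NULL, rater_id = "simA") {
  lapply(seq_len(n_subjects), function(i)
    simulate_trial(model, etho, duration_s, seed = seed + i - 1L,
                   subject_id = sprintf("S%02d", i), rater_id = rater_id))
}

#' Rater noise model
#'
#' Error model for a synthetic second rater, mimicking trainee mistakes:
#' zero-mean Gaussian jitter of each behavior-transition instant
#' (order-preserving, clamped to the trial), per-bout mislabeling to a
#' uniformly random other state, missed point events, and spurious point
#' events at a constant rate.
#'
#' @param sigma_s Boundary jitter SD in seconds (>= 0).
#' @param mislabel_p Per-bout mislabel probability in `[0, 1]`.
#' @param point_miss_p Per-point miss probability in `[0, 1]`.
#' @param false_point_rate Spurious point events per second (>= 0).
#' @param seed Integer seed.
#' @return A `rater_noise` object.
#' @export
rater_noise <- function(sigma_s = 0, mislabel_p = 0, point_miss_p = 0,
                        false_point_rate = 0, seed = 1L) {
  if (sigma_s < 0 || false_point_rate < 0 ||
      mislabel_p < 0 || mislabel_p > 1 ||
      point_miss_p < 0 || point_miss_p > 1)
    abort_etho("validation", "invalid noise parameters")
  structure(list(sigma_s = sigma_s, mislabel_p = mislabel_p,
                 point_miss_p = point_miss_p,
                 false_point_rate = false_point_rate,
                 seed = as.integer(seed)),
            class = "ethoscore_noise")
}

#' Derive a noisy second-rater scoring
#'
#' Applies a [rater_noise()] model to a trial: transition instants (shared
#' boundaries between consecutive timeline segments, including gaps) are
#' jittered, re-sorted and clamped to `[0, duration]`, so the perturbed
#' timeline remains a partition — jitter alone can never create overlaps
#' or new gaps; zero-length bouts are dropped; each bout is relabeled with
#' probability `mislabel_p` to a uniformly random other state of the
#' ethogram; point events are deleted with probability `point_miss_p` and
#' spurious ones added at `false_point_rate` per second. Deterministic
#' given `noise$seed`. With all noise parameters zero the output equals
#' the input.
#'
#' @param trial The first rater's scored trial.
#' @param noise A [rater_noise()].
#' @param etho The governing ethogram (needed for the relabel universe and
#'   point-behavior names).
#' @param rater_id Rater label for the derived trial.
#' @return A validated [scored_trial()].
#' @export
simulate_second_rater <- function(trial, noise, etho, rater_id = "simB") {
  validate_trial(trial, etho)
  set.seed(noise$seed)
  d <- trial$duration_s
  b <- trial$bouts
  # timeline as labeled segments over [0, d], gaps explicit
  segs <- data.frame(label = character(0), start = numeric(0),
                     end = numeric(0), stringsAsFactors = FALSE)
  cur <- 0
  for (i in seq_len(nrow(b))) {
    if (b$start[i] > cur + EPS_T)
      segs <- rbind(segs, data.frame(label = "gap", start = cur,
                                     end = b$start[i]))
    segs <- rbind(segs, data.frame(label = b$behavior[i], start = b$start[i],
                                   end = b$end[i]))
    cur <- b$end[i]
  }
  if (cur < d - EPS_T)
    segs <- rbind(segs, data.frame(label = "gap", start = cur, end = d))
  nseg <- nrow(segs)
  bounds <- c(0, if (nseg > 1) segs$end[-nseg], d)
  if (noise$sigma_s > 0 && nseg > 1) {
    interior <- bounds[2:nseg] + stats::rnorm(nseg - 1L, 0, noise$sigma_s)
    bounds <- c(0, sort(pmin(pmax(interior, 0), d)), d)
  }
  labs <- segs$label
  st <- state_behaviors(etho)
  if (noise$mislabel_p > 0 && length(st) > 1) {
    flip <- stats::runif(nseg) < noise$mislabel_p & labs != "gap"
    for (i in which(flip))
      labs[i] <- sample(setdiff(st, labs[i]), 1L)
  }
  keep <- (bounds[-1] - bounds[-(nseg + 1L)]) > EPS_T & labs != "gap"
  nb <- data.frame(behavior = labs[keep], start = bounds[-(nseg + 1L)][keep],
                   end = bounds[-1][keep], stringsAsFactors = FALSE)
  # merge adjacent equal labels (a bout is one contiguous episode)
  if (nrow(nb) > 1L) {
    i <- 2L
    while (i <= nrow(nb)) {
      if (nb$behavior[i] == nb$behavior[i - 1L] &&
          abs(nb$start[i] - nb$end[i - 1L]) <= EPS_T) {
        nb$end[i - 1L] <- nb$end[i]
        nb <- nb[-i, , drop = FALSE]
      } else i <- i + 1L
    }
  }
  p <- trial$points
  if (nrow(p) && noise$point_miss_p > 0)
    p <- p[stats::runif(nrow(p)) >= noise$point_miss_p, , drop = FALSE]
  pbs <- point_behaviors(etho)
  if (noise$false_point_rate > 0 && length(pbs)) {
    n <- stats::rpois(1, noise$false_point_rate * d)
    if (n > 0)
      p <- rbind(p, data.frame(
        behavior = sample(pbs, n, replace = TRUE),
        t = stats::runif(n, 0, d), stringsAsFactors = FALSE))
  }
  p <- p[order(p$t), , drop = FALSE]
  scored_trial(nb, p, d, trial$subject_id, trial$session_index,
               trial$trial_index, rater_id, etho = etho)
}
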