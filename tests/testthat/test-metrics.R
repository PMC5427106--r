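test_that("summarize_trial computes totals, counts, latencies, censoring", {
  fst <- fst_etho()

  # degenerate single-bout trial
  tr <- keystrokes_to_timeline(key_events(0, "i"), fst, 300)
  ms <- summarize_trial(tr, fst)
  imm <- ms$measures[ms$measures$behavior == "immobility", ]
  swi <- ms$measures[ms$measures$behavior == "swimming", ]
  expect_equal(imm$total_s, 300)
  expect_equal(imm$count, 1L)
  expect_equal(imm$latency_s, 0)
  expect_false(imm$latency_censored)
  expect_equal(swi$count, 0L)
  expect_equal(swi$latency_s, 300)
  expect_true(swi$latency_censored)

  # hand-counted example: swim then immobility plus 4 head shakes
  ms <- summarize_trial(toy_trial(), fst)
  expect_equal(ms$measures$latency_s[ms$measures$behavior == "immobility"],
               120)
  expect_equal(ms$n_events, 6L)
  expect_equal(sum(ms$measures$count), ms$n_events)

  # empty trial: everything censored, totals zero
  ms <- summarize_trial(scored_trial(duration_s = 300), fst)
  expect_true(all(ms$measures$total_s == 0))
  expect_true(all(ms$measures$latency_censored))
  expect_true(all(ms$measures$latency_s == 300))

  # trial with a behavior foreign to the ethogram
  bad <- scored_trial(data.frame(behavior = "grooming", start = 0, end = 10),
                      duration_s = 300)
  expect_error(summarize_trial(bad, fst),
               class = "ethoscore_schema_mismatch")
})

test_that("summarize_trial agrees with the sampling oracle on random trials", {
  fst <- fst_etho()
  set.seed(202)
  for (rep in 1:30) {
    d <- runif(1, 60, 300)
    ev <- random_events(fst, d)
    tr <- keystrokes_to_timeline(ev, fst, d)
    ms <- summarize_trial(tr, fst)
    orc <- sampling_oracle(ev, fst, d)
    for (i in seq_len(nrow(ms$measures))) {
      nm <- ms$measures$behavior[i]
      if (ms$measures$kind[i] == "state")
        expect_lt(abs(ms$measures$total_s[i] - orc$totals[[nm]]), 0.011)
      expect_equal(ms$measures$count[i], as.integer(orc$counts[[nm]]))
      if (!is.na(orc$latencies[[nm]]))
        expect_equal(ms$measures$latency_s[i], orc$latencies[[nm]])
      else
        expect_true(ms$measures$latency_censored[i])
    }
  }
})

test_that("EPM indices follow the open/(open+closed) convention", {
  epm <- builtin_template("EPM")
  tr <- scored_trial(data.frame(
    behavior = c("open_arm", "closed_arm", "center"),
    start = c(0, 60, 180), end = c(60, 180, 300)), duration_s = 300)
  ms <- summarize_trial(tr, epm)
  expect_equal(unname(ms$indices["pct_open_time"]), 100 * 60 / 180)
  expect_equal(unname(ms$indices["open_entries"]), 1)
  expect_equal(unname(ms$indices["pct_open_entries"]), 50)

  # center time can optionally enter the denominator
  ms2 <- summarize_trial(tr, epm, epm_include_center = TRUE)
  expect_equal(unname(ms2$indices["pct_open_time"]), 100 * 60 / 300)

  # symmetric arm times give exactly 50%
  tr <- scored_trial(data.frame(behavior = c("open_arm", "closed_arm"),
                                start = c(0, 100), end = c(100, 200)),
                     duration_s = 300)
  expect_equal(unname(summarize_trial(tr, epm)$indices["pct_open_time"]), 50)

  # no arm time at all: undefined, reported missing (never 0)
  tr <- scored_trial(data.frame(behavior = "center", start = 0, end = 300),
                     duration_s = 300)
  ms <- summarize_trial(tr, epm)
  expect_true(is.na(ms$indices["pct_open_time"]))
  expect_true(is.na(ms$indices["pct_open_entries"]))
})

test_that("NOR discrimination/preference indices and their identity", {
  nor <- customize_template(builtin_template("NOR"),
                            novel_designation = "explore_A")
  mk <- function(ta, tb) {
    b <- data.frame(behavior = c("explore_A", "explore_B"),
                    start = c(0, ta), end = c(ta, ta + tb))
    summarize_trial(scored_trial(b[b$end > b$start, ], duration_s = 300),
                    nor)
  }
  ms <- mk(30, 10)
  expect_equal(unname(ms$indices["discrimination_index"]), 0.5)
  expect_equal(unname(ms$indices["preference_index"]), 75)

  expect_equal(unname(mk(20, 20)$indices["discrimination_index"]), 0)
  expect_equal(unname(mk(20, 20)$indices["preference_index"]), 50)
  expect_equal(unname(mk(15, 0)$indices["discrimination_index"]), 1)
  expect_equal(unname(mk(15, 0)$indices["preference_index"]), 100)

  # PI = 50 (DI + 1) exactly, and per-trial novel override wins
  set.seed(3)
  for (rep in 1:20) {
    ms <- mk(runif(1, 0, 100), runif(1, 0, 100))
    di <- ms$indices[["discrimination_index"]]
    pi_ <- ms$indices[["preference_index"]]
    expect_identical(pi_, 50 * (di + 1))
    expect_gte(di, -1); expect_lte(di, 1)
  }
  ms_b <- summarize_trial(
    scored_trial(data.frame(behavior = c("explore_A", "explore_B"),
                            start = c(0, 30), end = c(30, 40)),
                 duration_s = 300),
    nor, novel = "explore_B")
  expect_equal(unname(ms_b$indices["discrimination_index"]), -0.5)

  # nothing explored: both indices missing
  ms0 <- summarize_trial(
    scored_trial(data.frame(behavior = "general_area", start = 0, end = 300),
                 duration_s = 300), nor)
  expect_true(all(is.na(ms0$indices)))
})

test_that("segment summaries bin correctly and totals are additive", {
  fst <- fst_etho()
  segs <- segment_summaries(toy_trial(), fst, 60)
  expect_length(segs, 5L)
  expect_equal(segs[[1]]$segment, c(0, 60))
  expect_equal(segs[[5]]$segment, c(240, 300))

  segs <- segment_summaries(toy_trial(), fst, 90)
  expect_length(segs, 4L)
  expect_equal(vapply(segs, function(s) diff(s$segment), numeric(1)),
               c(90, 90, 90, 30))

  one <- segment_summaries(toy_trial(), fst, 300)
  expect_length(one, 1L)
  expect_equal(one[[1]]$measures$total_s,
               summarize_trial(toy_trial(), fst)$measures$total_s)

  # additivity on randomized trials and bin widths
  set.seed(44)
  for (rep in 1:10) {
    ev <- random_events(fst, 300, n = 25)
    tr <- keystrokes_to_timeline(ev, fst, 300)
    w <- runif(1, 5, 400)
    segs <- segment_summaries(tr, fst, w)
    binned <- Reduce(`+`, lapply(segs, function(s) s$measures$total_s))
    expect_equal(binned, summarize_trial(tr, fst)$measures$total_s,
                 tolerance = 1e-9)
  }
  expect_error(segment_summaries(toy_trial(), fst, 0),
               class = "ethoscore_range")
})

test_that("latency only grows (or censors) when the trial start is cut off", {
  fst <- fst_etho()
  set.seed(55)
  for (rep in 1:10) {
    tr <- keystrokes_to_timeline(random_events(fst, 300, n = 15), fst, 300)
    a <- runif(1, 0, 299)
    full <- summarize_trial(tr, fst)$measures
    cut <- summarize_trial(slice_segment(tr, a, 300), fst)$measures
    for (i in seq_len(nrow(full))) {
      if (cut$latency_censored[i]) next
      expect_gte(cut$latency_s[i] + a, full$latency_s[i] - 1e-9)
    }
  }
})
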