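test_that("toggle semantics produce the expected bouts", {
  fst <- fst_etho()

  # single keystroke at t=0 spans the whole 5-min test
  tr <- keystrokes_to_timeline(key_events(0, "i"), fst, 300)
  expect_equal(tr$bouts,
               data.frame(behavior = "immobility", start = 0, end = 300))

  # simultaneous state keys: zero-length bout dropped, later keystroke wins
  tr <- keystrokes_to_timeline(key_events(c(0, 10, 10), c("s", "i", "c")),
                               fst, 60)
  expect_equal(tr$bouts$behavior, c("swimming", "climbing"))
  expect_equal(tr$bouts$start, c(0, 10))
  expect_equal(tr$bouts$end, c(10, 60))

  # point key does not disturb the open bout
  tr <- keystrokes_to_timeline(key_events(c(0, 5, 20), c("s", "h", "i")),
                               fst, 30)
  expect_equal(tr$bouts$behavior, c("swimming", "immobility"))
  expect_equal(tr$points, data.frame(behavior = "head_shake", t = 5))
  expect_equal(sum(tr$bouts$end - tr$bouts$start), 30)

  # repeated key of the open behavior is a no-op: still one bout
  tr <- keystrokes_to_timeline(key_events(c(0, 7, 19), c("i", "i", "i")),
                               fst, 30)
  expect_equal(nrow(tr$bouts), 1L)

  # time before the first state keystroke is an unscored gap
  tr <- keystrokes_to_timeline(key_events(12, "s"), fst, 60)
  expect_equal(tr$bouts$start, 12)
  expect_equal(coverage(tr), 48 / 60)
  expect_error(keystrokes_to_timeline(key_events(12, "s"), fst, 60,
                                      strict = TRUE),
               class = "ethoscore_validation")
})

test_that("bad inputs are rejected, not repaired", {
  fst <- fst_etho()
  expect_error(keystrokes_to_timeline(key_events(c(5, 1), c("i", "s")),
                                      fst, 60),
               class = "ethoscore_ordering")
  expect_error(keystrokes_to_timeline(key_events(70, "i"), fst, 60),
               class = "ethoscore_out_of_range")
  err <- expect_error(
    keystrokes_to_timeline(key_events(c(0, 3), c("i", "q")), fst, 60),
    class = "ethoscore_unknown_key")
  expect_match(conditionMessage(err), "'q' at t=3")
  expect_warning(
    tr <- keystrokes_to_timeline(key_events(c(0, 3), c("i", "q")), fst, 60,
                                 skip_unknown = TRUE),
    "unbound")
  expect_equal(nrow(tr$bouts), 1L)
})

test_that("timeline path matches the 10-ms sampling oracle on random logs", {
  fst <- fst_etho()
  set.seed(101)
  for (rep in 1:50) {
    d <- runif(1, 30, 300)
    ev <- random_events(fst, d)
    tr <- keystrokes_to_timeline(ev, fst, d)
    orc <- sampling_oracle(ev, fst, d)
    for (nm in state_behaviors(fst)) {
      got <- sum(with(tr$bouts, end - start)[tr$bouts$behavior == nm])
      expect_lt(abs(got - orc$totals[[nm]]), 0.011)
      expect_equal(sum(tr$bouts$behavior == nm),
                   unname(orc$counts[[nm]]))
    }
    # conservation: bout + gap time = duration
    gap <- d - sum(tr$bouts$end - tr$bouts$start)
    expect_gte(gap, -1e-9)
    expect_equal(coverage(tr) * d + gap, d, tolerance = 1e-9)
  }
})

test_that("slice_segment intersects, shifts and preserves the original", {
  tr <- scored_trial(data.frame(behavior = "immobility", start = 50,
                                end = 250),
                     duration_s = 300, subject_id = "R1")
  s <- slice_segment(tr, 100, 200)
  expect_equal(s$duration_s, 100)
  expect_equal(s$bouts, data.frame(behavior = "immobility", start = 0,
                                   end = 100))
  expect_equal(tr$bouts$start, 50)  # input untouched

  # identity window
  full <- slice_segment(toy_trial(), 0, 300)
  expect_equal(full$bouts, toy_trial()$bouts)
  expect_equal(full$points, toy_trial()$points)

  # half-open convention at the left edge
  tr <- scored_trial(points = data.frame(behavior = "head_shake", t = 99.9),
                     bouts = data.frame(behavior = "swimming", start = 0,
                                        end = 300),
                     duration_s = 300)
  expect_equal(nrow(slice_segment(tr, 100, 200)$points), 0L)
  expect_equal(nrow(slice_segment(tr, 99, 100)$points), 1L)

  expect_error(slice_segment(toy_trial(), 200, 100),
               class = "ethoscore_range")
  expect_error(slice_segment(toy_trial(), 0, 400),
               class = "ethoscore_range")
})

test_that("slicing commutes with concatenation for summaries", {
  fst <- fst_etho()
  set.seed(11)
  for (rep in 1:10) {
    ev <- random_events(fst, 300, n = 20)
    tr <- keystrokes_to_timeline(ev, fst, 300)
    b <- runif(1, 50, 250)
    whole <- summarize_trial(tr, fst)$measures
    left <- summarize_trial(slice_segment(tr, 0, b), fst)$measures
    right <- summarize_trial(slice_segment(tr, b, 300), fst)$measures
    expect_equal(left$total_s + right$total_s, whole$total_s,
                 tolerance = 1e-9)
  }
})

test_that("coverage handles empty and partial trials", {
  expect_equal(coverage(scored_trial(duration_s = 40)), 0)
  tr <- scored_trial(data.frame(behavior = c("a", "b"), start = c(0, 20),
                                end = c(10, 30)),
                     duration_s = 40)
  expect_equal(coverage(tr), 0.5)
})

test_that("keystroke log files parse with comments and blank lines", {
  withr::with_tempdir({
    writeLines(c("# rat R1, session 2", "0.0\ts", "", "12.5\th  # shake",
                 "20\ti"), "log.tsv")
    ev <- read_keylog("log.tsv")
    expect_equal(ev$t, c(0, 12.5, 20))
    expect_equal(ev$key, c("s", "h", "i"))
    writeLines("not a log line", "bad.tsv")
    expect_error(read_keylog("bad.tsv"), class = "ethoscore_io")
  })
})
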