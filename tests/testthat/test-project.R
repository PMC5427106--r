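demo_project <- function() {
  fst <- fst_etho()
  p <- project("demo")
  p <- add_ethogram(p, fst)
  p <- add_group(p, "vehicle")
  p <- add_group(p, "stress", "chronic mild stress")
  p <- add_subject(p, "R1", list(sex = "male", age = "10w"))
  p <- add_subject(p, "R2", list(sex = "female"))
  t1 <- keystrokes_to_timeline(key_events(c(0, 120), c("s", "i")), fst, 300,
                               subject_id = "R1", session_index = 2L,
                               rater_id = "A")
  t2 <- simulate_trial(fst_model(), fst, seed = 9, subject_id = "R2",
                       session_index = 2L, rater_id = "A")
  p <- record_trial(p, t1, "FST")
  record_trial(p, t2, "FST")
}

test_that("record_trial enforces keys and referential integrity", {
  p <- demo_project()
  expect_length(p$trials, 2L)
  tr <- get_trial(p, "R1", "FST", session_index = 2L, rater_id = "A")
  expect_equal(tr$bouts$start, c(0, 120))

  dup <- get_trial(p, "R2", "FST", session_index = 2L, rater_id = "A")
  expect_error(record_trial(p, dup, "FST"), class = "ethoscore_conflict")
  ghost <- simulate_trial(fst_model(), fst_etho(), seed = 1,
                          subject_id = "R99", session_index = 2L)
  expect_error(record_trial(p, ghost, "FST"),
               class = "ethoscore_referential")
  expect_error(record_trial(p, dup, "EPM"), class = "ethoscore_referential")

  # 5 subjects x 2 raters -> 10 retrievable trials
  q <- project("many")
  q <- add_ethogram(q, fst_etho())
  for (i in 1:5) q <- add_subject(q, sprintf("S%d", i))
  for (i in 1:5) for (r in c("A", "B"))
    q <- record_trial(q, simulate_trial(fst_model(), fst_etho(),
                                        seed = 10 * i + (r == "B"),
                                        subject_id = sprintf("S%d", i),
                                        session_index = 2L, rater_id = r),
                      "FST")
  expect_length(q$trials, 10L)
  for (i in 1:5) for (r in c("A", "B"))
    expect_s3_class(get_trial(q, sprintf("S%d", i), "FST",
                              session_index = 2L, rater_id = r),
                    "ethoscore_trial")
})

test_that("group assignment is deferred, re-assignable, and referential", {
  p <- demo_project()
  p <- assign_group(p, "R1", "stress")
  expect_equal(p$subjects$R1$group, "stress")
  p <- assign_group(p, "R1", "vehicle")  # latest assignment wins
  expect_equal(p$subjects$R1$group, "vehicle")
  expect_error(assign_group(p, "R9", "vehicle"),
               class = "ethoscore_referential")
  expect_error(assign_group(p, "R1", "ketamine"),
               class = "ethoscore_referential")
})

test_that("project store round-trips: save -> load -> save is byte-identical", {
  withr::with_tempdir({
    p <- assign_group(demo_project(), "R1", "stress")
    save_project(p, "p1.json")
    q <- load_project("p1.json")
    save_project(q, "p2.json")
    expect_identical(readBin("p1.json", "raw", file.size("p1.json")),
                     readBin("p2.json", "raw", file.size("p2.json")))
    # trials reload field-by-field
    expect_equal(get_trial(q, "R2", "FST", session_index = 2L,
                           rater_id = "A"),
                 get_trial(p, "R2", "FST", session_index = 2L,
                           rater_id = "A"))
    expect_equal(q$ethograms$FST, p$ethograms$FST)
    expect_equal(q$subjects$R1$group, "stress")
  })
})

test_that("CSV export has the documented schema and re-imports to 1e-6", {
  withr::with_tempdir({
    p <- assign_group(demo_project(), "R1", "stress")
    res <- export_results(p, "FST", dir = "out", maps = TRUE)
    expect_true(file.exists(res$csv))
    expect_setequal(basename(res$maps),
                    c("demo_R1_FST_s2t1_A.png", "demo_R2_FST_s2t1_A.png"))
    tab <- utils::read.csv(res$csv, check.names = FALSE)
    expect_equal(nrow(tab), 2L)
    expect_true(all(c("project", "subject_id", "group", "age", "sex",
                      "immobility_total_s", "immobility_count",
                      "immobility_latency_s", "immobility_latency_censored",
                      "n_events") %in% names(tab)))
    # unassigned group stays empty, not the text "NA"
    expect_identical(tab$group[tab$subject_id == "R2"], "")
    raw <- readLines(res$csv)
    expect_false(grepl("NA", raw[1 + which(tab$subject_id == "R2")],
                       fixed = TRUE))
    # re-imported numbers reproduce the measure sets to 1e-6
    for (sid in c("R1", "R2")) {
      tr <- get_trial(p, sid, "FST", session_index = 2L, rater_id = "A")
      ms <- summarize_trial(tr, p$ethograms$FST)
      row <- tab[tab$subject_id == sid, ]
      for (i in seq_len(nrow(ms$measures))) {
        bn <- ms$measures$behavior[i]
        expect_equal(row[[paste0(bn, "_total_s")]], ms$measures$total_s[i],
                     tolerance = 1e-6)
        expect_equal(row[[paste0(bn, "_latency_s")]],
                     ms$measures$latency_s[i], tolerance = 1e-6)
        expect_equal(row[[paste0(bn, "_count")]], ms$measures$count[i])
      }
      expect_equal(row$n_events, ms$n_events)
    }

    # 60 s bins: 5 rows per trial, totals additive to the whole-trial export
    res60 <- export_results(p, "FST", segments = list(bins = 60),
                            dir = "out60")
    tab60 <- utils::read.csv(res60$csv, check.names = FALSE)
    expect_equal(nrow(tab60), 10L)
    agg <- stats::aggregate(immobility_total_s ~ subject_id, tab60, sum)
    m <- merge(agg, tab[, c("subject_id", "immobility_total_s")],
               by = "subject_id")
    expect_equal(m[[2]], m[[3]], tolerance = 1e-6)

    # window export
    resw <- export_results(p, "FST", segments = list(window = c(60, 180)),
                           dir = "outw")
    tw <- utils::read.csv(resw$csv, check.names = FALSE)
    expect_equal(unique(tw$segment_start_s), 60)
    expect_equal(unique(tw$segment_end_s), 180)

    # empty export warns but writes a header
    p2 <- add_ethogram(project("empty"), builtin_template("EPM"))
    expect_warning(r0 <- export_results(p2, "EPM", dir = "out0"),
                   "header only")
    expect_true(file.exists(r0$csv))
    expect_equal(nrow(utils::read.csv(r0$csv)), 0L)
  })
})

test_that("referential integrity survives randomized operation sequences", {
  set.seed(123)
  p <- add_ethogram(project("fuzz"), fst_etho())
  p <- add_group(p, "g1")
  subjects <- character(0)
  for (step in 1:60) {
    op <- sample(3, 1)
    if (op == 1) {
      sid <- sprintf("S%03d", step)
      p <- add_subject(p, sid); subjects <- c(subjects, sid)
    } else if (op == 2 && length(subjects)) {
      p <- assign_group(p, sample(subjects, 1), "g1")
    } else if (op == 3 && length(subjects)) {
      tr <- simulate_trial(fst_model(), fst_etho(), seed = step,
                          subject_id = sample(subjects, 1),
                          session_index = sample(1:2, 1),
                          rater_id = sample(c("A", "B"), 1))
      key_exists <- tryCatch({
        get_trial(p, tr$subject_id, "FST", tr$session_index,
                  tr$trial_index, tr$rater_id); TRUE
      }, error = function(e) FALSE)
      if (key_exists)
        expect_error(record_trial(p, tr, "FST"),
                     class = "ethoscore_conflict")
      else p <- record_trial(p, tr, "FST")
    }
  }
  for (rec in p$trials) {
    expect_true(rec$trial$subject_id %in% names(p$subjects))
    expect_true(rec$test_name %in% names(p$ethograms))
  }
})
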