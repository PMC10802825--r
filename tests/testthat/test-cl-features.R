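test_that("worked example window reproduces hand-derived feature values", {
  w <- fig1_window
  bs <- basic_stats(w)
  expect_equal(bs$mean, 370.25)
  expect_equal(bs$sd, sqrt(142.75 / 3), tolerance = 1e-12)
  expect_equal(bs$min, 360)
  sdm <- successive_diff_metrics(w)
  expect_equal(sdm$rmssd, sqrt(398 / 3), tolerance = 1e-12)
  expect_equal(sdm$nn50, 0)
  expect_equal(sdm$pnn50, 0)
  pc <- poincare(w)
  expect_equal(pc$sd1, sqrt(99.5), tolerance = 1e-12)
  expect_equal(pc$sd2, o_sd2(w), tolerance = 1e-12)
  its <- initiation_to_shortest(make_episode(w))
  expect_equal(its$time_to_min_s, 1.108)
  expect_equal(its$pct_beats_to_min, 75)
  expect_equal(its$pct_change_first_to_min, 100 * 13 / 373, tolerance = 1e-12)
  expect_equal(episode_sd(make_episode(w)), sqrt(142.75 / 3), tolerance = 1e-12)
})

test_that("degenerate and symmetric windows behave as defined", {
  const <- rep(300, 10)
  expect_equal(basic_stats(const), list(mean = 300, sd = 0, min = 300))
  expect_equal(successive_diff_metrics(const),
               list(rmssd = 0, nn50 = 0L, pnn50 = 0))
  expect_equal(basic_stats(c(300, 400)),
               list(mean = 350, sd = sqrt(5000), min = 300))
  sdm <- successive_diff_metrics(c(300, 360, 300))
  expect_equal(sdm$rmssd, 60)
  expect_equal(sdm$nn50, 2)
  expect_equal(sdm$pnn50, 100)
  pc <- poincare(const)
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  alt <- rep(c(300, 400), 5)
  expect_equal(poincare(alt)$sd1, o_sd1(alt), tolerance = 1e-12)
  expect_error(basic_stats(300), "at least 2")
  expect_error(poincare(c(300, 310)), "at least 3")
  expect_error(first_segment(make_episode(fig1_window), 10), "cannot take")
  expect_error(first_segment(make_episode(fig1_window), 0), "at least 1")
  expect_identical(first_segment(make_episode(fig1_window), 4), fig1_window)
})

test_that("initiation-to-shortest handles monotone and first-beat minima", {
  mono <- make_episode(seq(400, 300, by = -10))
  its <- initiation_to_shortest(mono)
  expect_equal(its$pct_beats_to_min, 100)
  expect_equal(its$time_to_min_s, sum(mono$cl_ms) / 1000)
  first_min <- make_episode(c(300, 310, 320, 305))
  its2 <- initiation_to_shortest(first_min)
  expect_equal(its2$time_to_min_s, 0.3)
  expect_equal(its2$pct_change_first_to_min, 0)
  ties <- initiation_to_shortest(make_episode(c(320, 300, 310, 300)))
  expect_equal(ties$pct_beats_to_min, 50)  # first occurrence wins
})

test_that("TINN is one bin wide on single-bin windows and respects bounds", {
  expect_equal(tinn(rep(300, 10)), 7.8125)
  expect_equal(tinn(rep(300, 10), bin_width = 5), 5)
  withr::with_seed(21, {
    for (i in 1:50) {
      w <- rand_window(n = sample(5:20, 1), sd = runif(1, 1, 40))
      v <- tinn(w)
      expect_gte(v, 7.8125)
      expect_lte(v, diff(range(w)) + 2 * 7.8125)
    }
  })
})

test_that("every feature formula matches its brute-force oracle", {
  withr::with_seed(31, {
    for (i in 1:300) {
      w <- rand_window(n = sample(4:15, 1), sd = runif(1, 2, 40))
      expect_equal(basic_stats(w)$sd, o_sd(w), tolerance = 1e-9)
      expect_equal(successive_diff_metrics(w)$rmssd, o_rmssd(w), tolerance = 1e-9)
      expect_equal(successive_diff_metrics(w)$nn50, o_nn50(w))
      expect_equal(poincare(w)$sd1, o_sd1(w), tolerance = 1e-9)
      expect_equal(poincare(w)$sd2, o_sd2(w), tolerance = 1e-9)
      expect_equal(tinn(w), o_tinn(w), tolerance = 1e-9)
      its <- initiation_to_shortest(make_episode(w))
      o <- o_init_to_shortest(w)
      expect_equal(its$time_to_min_s, o$time_to_min_s, tolerance = 1e-9)
      expect_equal(its$pct_change_first_to_min, o$pct_change_first_to_min,
                   tolerance = 1e-9)
    }
  })
})

test_that("basic stats are permutation-invariant, successive-diff metrics are not", {
  withr::with_seed(8, {
    w <- rand_window(10)
    p <- sample(w)
    expect_equal(basic_stats(w), basic_stats(p))
    expect_equal(episode_sd(make_episode(w)), basic_stats(w)$sd)
  })
})

test_that("extract_features fills all fields, deterministically, label-blind", {
  cl <- withr::with_seed(5, rand_window(16))
  e <- episode("E1", "P1", "terminating", cl)
  fv <- extract_features(e)
  expect_identical(names(fv), c("episode_id", "patient_id", "label",
                                vtcycle:::FEATURE_NAMES))
  nums <- unlist(fv[vtcycle:::FEATURE_NAMES])
  expect_true(all(is.finite(nums)))
  expect_identical(extract_features(e), fv)
  relabeled <- episode("X9", "P7", "sustained", cl)
  fv2 <- extract_features(relabeled)
  expect_equal(fv2[vtcycle:::FEATURE_NAMES], fv[vtcycle:::FEATURE_NAMES])
  expect_equal(fv$cl10th, cl[10])
  expect_error(extract_features(make_episode(fig1_window)), "eligible")
})

test_that("constant episodes yield zero variability and missing AR features", {
  e <- make_episode(rep(330, 12))
  expect_message(fv <- extract_features(e), "degenerate")
  expect_equal(fv$sd_cl10, 0)
  expect_equal(fv$rmssd10, 0)
  expect_true(is.na(fv$ar_phi))
  expect_error(extract_features(e, on_degenerate = "error"))
})

test_that("cohort_features skips short episodes and keeps eligible ones", {
  ch <- cohort(list(make_episode(rep(320, 11) + 1:11, id = "A"),
                    make_episode(fig1_window, id = "B")))
  expect_message(ft <- cohort_features(ch), "skipping")
  expect_identical(ft$episode_id, "A")
})
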