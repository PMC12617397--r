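test_that("absolute bounds use strict inequalities", {
  expect_equal(flag_absolute_bounds(c(800, 250, 800)), 2L)
  expect_length(flag_absolute_bounds(c(300, 2000)), 0)
  expect_equal(flag_absolute_bounds(c(299.9, 800, 2000.1)), c(1L, 3L))
  set.seed(1)
  expect_length(flag_absolute_bounds(runif(500, 600, 1200)), 0)
})

test_that("norm categories and thresholds follow the reference cutoffs", {
  cases <- list(
    list(42.9, "normal", 0.40), list(60, "high", 0.45),
    list(75, "very_high", 0.50), list(10, "very_low", 0.40),
    list(20, "low", 0.40),
    # values exactly at a cutoff take the higher category
    list(16.1, "low", 0.40), list(29.5, "normal", 0.40),
    list(56.3, "high", 0.45), list(69.7, "very_high", 0.50)
  )
  for (cs in cases) {
    got <- assign_norm_category(cs[[1]])
    expect_equal(got$category, cs[[2]], info = paste("rmssd", cs[[1]]))
    expect_equal(got$threshold, cs[[3]])
  }
  expect_error(assign_norm_category(-1), ">= 0")
})

test_that("threshold is monotone non-decreasing in preliminary RMSSD", {
  grid <- seq(0, 120, by = 0.5)
  thr <- vapply(grid, function(r) assign_norm_category(r)$threshold,
                numeric(1))
  expect_true(all(diff(thr) >= 0))
  expect_true(all(thr %in% c(0.40, 0.45, 0.50)))
})

test_that("local-mean detection flags a hand-computable spike", {
  expect_length(detect_karlsson(rep(800, 10), 0.4), 0)
  # deviation of the middle beat is 800/800 = 1 > 0.4
  expect_equal(detect_karlsson(c(800, 800, 1600, 800, 800), 0.4), 3L)
  expect_error(detect_karlsson(c(800, 800), 0.4), "too short")
})

test_that("detection matches the brute-force rescanning oracle", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(50:400, 1)
    thr <- runif(1, 0.40, 0.50)
    s <- simulate_hp_series(mean_hp = runif(1, 600, 1100),
                            noise_sd = runif(1, 10, 40),
                            duration = n * 1.1, seed = 5000 + rep)
    s$hp <- s$hp[seq_len(min(n, length(s$hp)))]
    s <- hp_series(s$hp)
    corrupted <- inject_artifacts(
      s, n_spikes = sample(0:4, 1), n_missed = sample(0:2, 1),
      n_extra = sample(0:2, 1), spike_factor = runif(1, 1.5, 3)
    )$series
    expect_identical(detect_karlsson(corrupted, thr),
                     karlsson_oracle(corrupted$hp, thr))
  }
})

test_that("interpolation replaces only flagged beats and keeps length", {
  s <- hp_series(c(800, 1600, 820))
  fixed <- correct_artifacts(s, 2L)
  expect_equal(fixed$hp, c(800, 810, 820))

  expect_identical(correct_artifacts(s, integer(0))$hp, s$hp)

  s2 <- hp_series(c(3000, 800, 820, 790))
  fixed2 <- correct_artifacts(s2, 1L)
  expect_equal(fixed2$hp, c(800, 800, 820, 790))  # end copies nearest clean

  set.seed(9)
  hp <- runif(100, 700, 900)
  flags <- sample(100, 10)
  out <- correct_artifacts(hp_series(hp), flags)
  expect_length(out$hp, 100)
  expect_identical(out$hp[-flags], hp[-flags])

  expect_error(correct_artifacts(hp_series(c(800, 810)), 1:2),
               "fewer than 2")
})

test_that("quality gate applies the artifact, duration and beat-count rules", {
  s <- simulate_hp_series(mean_hp = 850, noise_sd = 20, duration = 300,
                          seed = 2)
  rep10 <- hrvequiv:::artifact_report(flagged_karlsson = 1:10)
  expect_false(apply_quality_gate(rep10, s)$excluded)  # exactly 10: keep
  rep11 <- hrvequiv:::artifact_report(flagged_karlsson = 1:11)
  gated <- apply_quality_gate(rep11, s)
  expect_true(gated$excluded)
  expect_equal(gated$exclusion_reason, "too_many_artifacts")

  short <- simulate_hp_series(mean_hp = 850, noise_sd = 20, duration = 200,
                              seed = 3)
  g2 <- apply_quality_gate(hrvequiv:::artifact_report(), short)
  expect_equal(g2$exclusion_reason, "too_short")

  sparse <- hp_series(rep(1900, 140))  # 266 s but only 140 beats
  g3 <- apply_quality_gate(hrvequiv:::artifact_report(), sparse)
  expect_equal(g3$exclusion_reason, "implausible_beat_count")
})

test_that("RMSSD matches hand arithmetic and the brute-force oracle", {
  expect_equal(compute_rmssd(rep(700, 50)), 0)
  expect_equal(compute_rmssd(c(800, 810, 790)), sqrt(250))
  set.seed(31)
  for (i in 1:25) {
    hp <- runif(sample(10:300, 1), 500, 1200)
    expect_equal(compute_rmssd(hp), rmssd_oracle(hp), tolerance = 1e-12)
    # invariant under time reversal
    expect_equal(compute_rmssd(hp), compute_rmssd(rev(hp)), tolerance = 1e-12)
  }
  expect_error(compute_rmssd(800), "at least 2")
})

test_that("mean HR is 60000 over the mean heart period", {
  expect_equal(compute_mean_hr(rep(1000, 10)), 60)
  expect_equal(compute_mean_hr(rep(800, 10)), 75)
  expect_equal(compute_mean_hr(c(600, 1200)), 60000 / 900)
})

test_that("minute-wise RMSSD partitions by the time a beat ends", {
  expect_equal(compute_minutewise_rmssd(hp_series(rep(1000, 300))),
               rep(0, 5))
  # stationary series: each window near the full-series value
  s <- simulate_hp_series(mean_hp = 850, noise_sd = 30, ar_coef = 0,
                          duration = 300, seed = 8)
  mw <- compute_minutewise_rmssd(s)
  expect_length(mw, 5)
  full <- compute_rmssd(s)
  expect_true(all(abs(mw - full) / full < 0.35))
  # oracle partition: recompute window 2 by hand from cumulative time
  ts <- s$timestamp
  in2 <- which(ts > 60000 & ts <= 120000)
  expect_equal(mw[2], compute_rmssd(s$hp[in2]))
  short <- simulate_hp_series(mean_hp = 850, noise_sd = 10, duration = 150,
                              seed = 9)
  expect_warning(mw_s <- compute_minutewise_rmssd(short), "shorter")
  expect_length(mw_s, 2)
})

test_that("HF power concentrates at the respiratory frequency and scales as amplitude squared", {
  s <- simulate_hp_series(mean_hp = 800, rsa_amplitude = 40, resp_freq = 0.25,
                          noise_sd = 0, duration = 300)
  hf <- compute_hf_power(s)
  total <- compute_hf_power(s, band = c(0.01, 1.99))
  expect_gt(hf / total, 0.90)

  s2 <- simulate_hp_series(mean_hp = 800, rsa_amplitude = 80,
                           resp_freq = 0.25, noise_sd = 0, duration = 300)
  ratio <- compute_hf_power(s2) / hf
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)

  flat <- compute_hf_power(hp_series(rep(800, 300)))
  expect_lt(flat, 1e-8)
  expect_error(compute_hf_power(hp_series(rep(800, 50))), "too short")
})

test_that("the full preprocessing chain recovers injected artifacts", {
  clean <- simulate_hp_series(mean_hp = 850, noise_sd = 25, duration = 300,
                              seed = 17)
  pp0 <- preprocess_participant(clean)
  expect_false(pp0$report$excluded)
  expect_equal(pp0$report$n_artifacts, 0)
  expect_true(is.finite(pp0$features$log_rmssd))

  few <- inject_artifacts(clean, n_spikes = 3, spike_factor = 2, seed = 18)
  pp3 <- preprocess_participant(few$series)
  expect_true(all(few$truth %in% pp3$report$flagged_karlsson))
  expect_lt(abs(pp3$features$rmssd - pp0$features$rmssd) /
              pp0$features$rmssd, 0.05)

  many <- inject_artifacts(clean, n_spikes = 12, spike_factor = 2, seed = 19)
  pp12 <- preprocess_participant(many$series)
  expect_true(pp12$report$excluded)
  expect_equal(pp12$report$exclusion_reason, "too_many_artifacts")
  expect_null(pp12$features)
})
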