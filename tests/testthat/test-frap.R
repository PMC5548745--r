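# FRAP generator, double normalization, mobile-fraction estimation,
# inclusion screens and two-phase recovery fitting.

test_that("noiseless generator hits its analytic landmarks", {
  # full recovery with fast kinetics plateaus at the pre-bleach level
  rec <- simulate_frap_record(F_m = 1, k_fast = 2, k_slow = 1,
                              noise_sd = 0, seed = 1)
  expect_equal(tail(rec$roi, 1), rec$roi[1], tolerance = 1e-6)
  # immobile pool: post-bleach trace constant at the bleach floor
  # (measured intensities include the constant background)
  rec0 <- simulate_frap_record(F_m = 0, noise_sd = 0, seed = 1)
  post <- rec0$roi[rec0$bleach_index:length(rec0$roi)]
  I0 <- rec0$meta$I_pre * (1 - rec0$meta$bleach_depth) + rec0$meta$bg
  expect_equal(post, rep(I0, length(post)))
  # half-mobile with fast rates: plateau midway between floor and pre
  rec5 <- simulate_frap_record(F_m = 0.5, k_fast = 5, k_slow = 3,
                               noise_sd = 0, seed = 1)
  expect_equal(tail(rec5$roi, 1), (rec5$roi[1] + I0) / 2,
               tolerance = 1e-4)
  expect_error(simulate_frap_record(F_m = 0.5, noise_sd = -1),
               "noise_sd")
})

test_that("generator is seed-deterministic", {
  a <- simulate_frap_record(F_m = 0.6, noise_sd = 2, seed = 11)
  b <- simulate_frap_record(F_m = 0.6, noise_sd = 2, seed = 11)
  expect_identical(a$roi, b$roi)
  expect_identical(a$reference, b$reference)
})

test_that("double normalization cancels whole-field decay exactly", {
  base <- simulate_frap_record(F_m = 0.5, noise_sd = 0,
                               acq_bleach_rate = 0, seed = 1)
  faded <- simulate_frap_record(F_m = 0.5, noise_sd = 0,
                                acq_bleach_rate = 0.001, seed = 1)
  n0 <- normalize_recovery(base)
  n1 <- normalize_recovery(faded)
  expect_equal(n1$value, n0$value, tolerance = 1e-9)
  # pre-bleach segment is identically 1
  expect_equal(n0$value[seq_len(n0$bleach_index - 1)],
               rep(1, n0$bleach_index - 1))
})

test_that("normalization rejects a reference below background", {
  rec <- simulate_frap_record(F_m = 0.5, noise_sd = 0, seed = 1)
  rec$background <- rec$background + max(rec$reference)
  expect_error(normalize_recovery(rec), "background")
})

test_that("mobile fraction reproduces the defining formula", {
  # direct worked case: I_I = 100, I_0 = 20, I_P = 60 -> 0.5, built as a
  # synthetic normalized curve
  curve <- list(time = seq(0, 101, 0.5), value = NULL, bleach_index = 31)
  curve$value <- c(rep(100, 30), rep(20, 10), rep(60, length(curve$time) - 40))
  expect_equal(mobile_fraction(curve)$F_m, 0.5)
  # boundary cases
  curve$value <- c(rep(100, 30), 20, rep(100, length(curve$time) - 31))
  expect_equal(mobile_fraction(curve)$F_m, 1)
  curve$value <- c(rep(100, 30), rep(20, length(curve$time) - 30))
  expect_equal(mobile_fraction(curve)$F_m, 0)
  curve$value <- rep(100, length(curve$time))
  expect_error(mobile_fraction(curve), "no bleach")
})

test_that("mobile fraction is invariant under affine intensity rescaling", {
  rec <- simulate_frap_record(F_m = 0.7, noise_sd = 1, seed = 3)
  f1 <- mobile_fraction(normalize_recovery(rec))$F_m
  rec2 <- rec
  gain <- 2.7
  # same gain applies to all ROIs of the detector
  rec2$roi <- gain * rec2$roi
  rec2$reference <- gain * rec2$reference
  rec2$background <- gain * rec2$background
  f2 <- mobile_fraction(normalize_recovery(rec2))$F_m
  expect_equal(f2, f1, tolerance = 1e-9)
})

test_that("window-mean and plateau-fit estimates agree on clean records", {
  for (fm in c(0.3, 0.6, 0.9)) {
    rec <- simulate_frap_record(F_m = fm, noise_sd = 0, seed = 2)
    nc <- normalize_recovery(rec)
    wf <- mobile_fraction(nc)$F_m
    pf <- fit_two_phase(nc)
    expect_true(pf$converged)
    expect_equal(pf$F_m_implied, wf, tolerance = 5e-3,
                 info = sprintf("F_m = %g", fm))
    expect_equal(wf, fm, tolerance = 5e-3)
  }
})

test_that("two-phase fit recovers generator kinetics and flags degeneracy", {
  rec <- simulate_frap_record(F_m = 0.8, k_fast = 0.3, k_slow = 0.05,
                              amp_split = 0.6, noise_sd = 0, seed = 4)
  nc <- normalize_recovery(rec)
  fit <- fit_two_phase(nc)
  expect_equal(fit$k_fast, 0.3, tolerance = 5e-3)
  expect_equal(fit$k_slow, 0.05, tolerance = 5e-3)
  expect_equal(fit$amp_split, 0.6, tolerance = 5e-3)
  expect_false(fit$degenerate)
  # single-exponential input: degenerate two-phase decomposition
  rec1 <- simulate_frap_record(F_m = 0.8, k_fast = 0.1, k_slow = 0.1,
                               amp_split = 0.5, noise_sd = 0, seed = 4)
  f1 <- fit_two_phase(normalize_recovery(rec1))
  expect_true(f1$degenerate)
})

test_that("mobile-fraction estimation is nearly unbiased across noise levels", {
  # reduced grid here (the full grid runs in the acceptance suite)
  for (fm in c(0.25, 0.75)) {
    for (nsd in c(1, 3)) {
      est <- vapply(1:40, function(i) {
        rec <- simulate_frap_record(F_m = fm, noise_sd = nsd,
                                    seed = 5000 + i)
        mobile_fraction(normalize_recovery(rec))$F_m
      }, 1)
      expect_lt(abs(mean(est) - fm), 0.02)
    }
  }
})

test_that("crosslink screen applies immobilization and stoichiometry cutoffs", {
  ok <- crosslink_screen(0.45, 0.80, intensity_ratio = 1.2)
  expect_true(ok$included)
  weak <- crosslink_screen(0.52, 0.80, intensity_ratio = 1.2)  # 35 %
  expect_false(weak$included)
  expect_true("insufficient_immobilization" %in% weak$reasons)
  excess <- crosslink_screen(0.45, 0.80, intensity_ratio = 1.7)
  expect_false(excess$included)
  expect_true("stoichiometry" %in% excess$reasons)
  expect_error(crosslink_screen(0.45, NA, 1.2), "baseline")
})

test_that("condition summaries report mean, sem and n", {
  one <- summarize_condition(0.5)
  expect_equal(one$mean, 0.5)
  expect_equal(one$sem, 0)
  expect_true("single_roi" %in% one$flags)
  two <- summarize_condition(c(0.4, 0.6))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sem, sd(c(0.4, 0.6)) / sqrt(2))
  set.seed(42)
  many <- summarize_condition(rnorm(100, 0.7, 0.02))
  expect_lt(abs(many$mean - 0.7), 0.006)
})
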