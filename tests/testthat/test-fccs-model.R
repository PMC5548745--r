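# Analytic identities of the global two-color correlation model and the
# single-component transit-time fit.

test_that("displacement factor is 1 at zero displacement and non-decreasing in lag", {
  tau <- exp(seq(log(1e-4), log(10), length.out = 50))
  expect_equal(displacement_factor(tau, r0 = 0), rep(1, 50))
  d <- displacement_factor(tau, r0 = 120, D = 0.25)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d > 0 & d <= 1))
})

test_that("diffusion factor halves at the transit time and decreases in lag", {
  for (D in c(0.1, 0.4, 2)) {
    for (omega in c(222, 272)) {
      tau_d <- (omega / 1000)^2 / (4 * D)
      expect_equal(diffusion_factor(tau_d, D, omega), 0.5)
    }
  }
  tau <- exp(seq(log(1e-4), log(10), length.out = 50))
  expect_true(all(diff(diffusion_factor(tau, 0.4)) < 0))
})

test_that("single green species reduces to the standard one-species 2D model", {
  geom <- default_geom(r0 = 0)
  m <- species_model(c_g = 100, D_g = 0.4)
  lags <- exp(seq(log(1e-4), log(1), length.out = 30))
  curves <- model_correlations(m, geom, lags)
  # amplitude 1/(pi omega^2 c) at tau -> 0
  expect_equal(model_correlations(m, geom, 1e-9)$GG,
               1 / (pi * 0.222^2 * 100), tolerance = 1e-5)
  # full curve equals amplitude times the diffusion factor
  expect_equal(curves$GG,
               diffusion_factor(lags, 0.4, 222) / (pi * 0.222^2 * 100),
               tolerance = 1e-12)
  # no complex, no crosstalk: cross-correlation identically zero
  expect_equal(curves$GR, rep(0, 30))
  expect_equal(model_correlations(
    species_model(c_g = 50, c_r = 70, D_g = 0.4, D_r = 0.3),
    default_geom(130), lags)$GR, rep(0, 30))
})

test_that("background strictly suppresses the autocorrelation amplitude", {
  geom <- default_geom()
  lags <- c(1e-3, 1e-2)
  bgs <- c(0, 500, 1000, 2000, 5000)
  amps <- vapply(bgs, function(bg) {
    model_correlations(species_model(c_g = 100, bg_g = bg), geom,
                       lags)$GG[1]
  }, 1)
  expect_true(all(diff(amps) < 0))
})

test_that("cross-section ratio x enters amplitudes as in the printed model", {
  geom <- default_geom()
  # a homodimer-labeled single-color species (x = 2) keeps G(0) = 1/(A c)
  a1 <- model_correlations(species_model(c_g = 100, x_g = 1), geom, 1e-9)$GG
  a2 <- model_correlations(species_model(c_g = 100, x_g = 2), geom, 1e-9)$GG
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("model rejects an all-zero species composition", {
  expect_error(model_correlations(species_model(), default_geom(), 1e-3),
               "zero")
})

test_that("complex and crosstalk terms are mutually consistent at tau -> 0", {
  geom <- default_geom(r0 = 0)
  m <- species_model(c_g = 40, c_r = 30, c_gr = 20, D_g = 0.4,
                     D_r = 0.35, D_gr = 0.25, K = 0.05)
  g0 <- model_correlations(m, geom, 1e-9)
  A_g <- pi * 0.222^2; A_r <- pi * 0.272^2
  A_gr <- pi * (0.222^2 + 0.272^2) / 2
  green_mean <- A_g * (m$c_g + m$c_gr)
  red_mean <- A_r * (m$c_r + m$c_gr) + A_g * m$K * (m$c_g + m$c_gr)
  expect_equal(g0$GG, A_g * (m$c_g + m$c_gr) / green_mean^2,
               tolerance = 1e-6)
  gr_expect <- ((A_g * A_r / A_gr) * m$c_gr +
                  A_g * m$K * (m$c_g + m$c_gr)) / (green_mean * red_mean)
  expect_equal(g0$GR, gr_expect, tolerance = 1e-6)
})

test_that("transit-time fit is exact on noiseless model curves", {
  geom <- default_geom()
  lags <- exp(seq(log(2e-4), log(2), length.out = 60))
  # tau_D = 30 ms corresponds to D = omega^2/(4 tau_D)
  D <- (0.222)^2 / (4 * 0.030)
  y <- model_correlations(species_model(c_g = 100, D_g = D), geom,
                          lags)$GG
  cv <- structure(list(pair = "GG", lags = lags, values = y,
                       n_samples = rep(1, 60), sd = NULL, meta = list()),
                  class = "correlation_curve")
  fit <- fit_fcs_tauD(cv)
  expect_equal(fit$tau_D_ms, 30, tolerance = 1e-3)
  expect_equal(fit$G0, 1 / (pi * 0.222^2 * 100), tolerance = 1e-3)
  expect_gt(fit$r2, 0.9999)
  # lags below 1 ms are excluded: pre-truncated curve gives same answer
  cv_trunc <- cv
  keep <- lags >= 1e-3
  cv_trunc$lags <- lags[keep]; cv_trunc$values <- y[keep]
  cv_trunc$n_samples <- cv_trunc$n_samples[keep]
  expect_equal(fit_fcs_tauD(cv_trunc)$tau_D_ms, fit$tau_D_ms,
               tolerance = 1e-9)
  expect_error(fit_fcs_tauD(structure(list(pair = "GG", lags = c(2, 3) * 1e-3,
    values = c(1, 1), n_samples = c(1, 1), sd = NULL, meta = list()),
    class = "correlation_curve")), "5 lags")
})

test_that("fit objective is locally optimal at the generating parameters", {
  geom <- default_geom(120)
  m <- species_model(c_g = 30, c_r = 30, c_gr = 40, D_g = 0.4,
                     D_r = 0.35, D_gr = 0.25, K = 0.05)
  lags <- exp(seq(log(1e-3), log(2), length.out = 40))
  truth <- model_correlations(m, geom, lags)
  ssr_at <- function(mod) {
    pred <- model_correlations(mod, geom, lags)
    sum((pred$GG - truth$GG)^2 + (pred$RR - truth$RR)^2 +
          (pred$GR - truth$GR)^2)
  }
  base <- ssr_at(m)
  expect_equal(base, 0)
  for (fld in c("c_g", "c_gr", "D_gr", "K")) {
    for (fac in c(0.8, 1.2)) {
      m2 <- m
      m2[[fld]] <- m[[fld]] * fac
      expect_gt(ssr_at(m2), base, label = sprintf("%s x %g", fld, fac))
    }
  }
})

test_that("measurement QC screen applies every exclusion window", {
  ok <- list(tau_D_ms = 50, r2 = 0.95, cpm_g_khz = 1, cpm_r_khz = 1)
  expect_true(apply_qc(ok, total_time = 40)$included)
  fast <- ok; fast$tau_D_ms <- 0.5
  v <- apply_qc(fast, 40)
  expect_false(v$included)
  expect_equal(v$reasons, "transit_time")
  dim_cpm <- ok; dim_cpm$cpm_g_khz <- 0.1
  expect_true("brightness" %in% apply_qc(dim_cpm, 40)$reasons)
  lopsided <- ok; lopsided$cpm_g_khz <- 2.4; lopsided$cpm_r_khz <- 0.8
  expect_true("brightness_ratio" %in% apply_qc(lopsided, 40)$reasons)
  poor <- ok; poor$r2 <- 0.85
  expect_true("fit_r2" %in% apply_qc(poor, 40)$reasons)
  expect_true("time_range" %in% apply_qc(ok, 10)$reasons)
  expect_true("time_range" %in% apply_qc(ok, 90)$reasons)
  # boundary values are inside the windows
  edge <- list(tau_D_ms = 1, r2 = 0.9, cpm_g_khz = 0.2, cpm_r_khz = 0.2)
  expect_true(apply_qc(edge, 20)$included)
})
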