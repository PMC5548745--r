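# Brownian-dynamics trace generator: background statistics, determinism,
# brute-force intensity reconstruction, the dynamic dissociation schedule
# and its conservation law.

test_that("background-only traces are Poisson at the requested rate", {
  geom <- default_geom()
  mod <- species_model(c_g = 0, bg_g = 1000, bg_r = 400)
  tr <- simulate_membrane_traces(mod, geom, duration = 10, dt = 1e-3,
                                 box_size = 3, seed = 1)
  expect_equal(mean(tr$counts_green), 1.0, tolerance = 0.05)
  expect_equal(mean(tr$counts_red), 0.4, tolerance = 0.1)
  # index of dispersion of a Poisson stream is 1
  expect_gt(var(tr$counts_green) / mean(tr$counts_green), 0.9)
  expect_lt(var(tr$counts_green) / mean(tr$counts_green), 1.1)
})

test_that("identical seeds give bit-identical traces", {
  geom <- default_geom(120)
  mod <- species_model(c_g = 40, c_r = 30, c_gr = 20, K = 0.05)
  a <- simulate_membrane_traces(mod, geom, 2, 1e-3, 3, seed = 99)
  b <- simulate_membrane_traces(mod, geom, 2, 1e-3, 3, seed = 99)
  expect_identical(a$counts_green, b$counts_green)
  expect_identical(a$counts_red, b$counts_red)
  c <- simulate_membrane_traces(mod, geom, 2, 1e-3, 3, seed = 100)
  expect_false(identical(a$counts_green, c$counts_green))
})

test_that("invalid sampling or geometry is rejected", {
  geom <- default_geom()
  mod <- species_model(c_g = 10)
  expect_error(simulate_membrane_traces(mod, geom, 0, 1e-3, 3, 1),
               "positive")
  expect_error(simulate_membrane_traces(mod, geom, 1, -1, 3, 1),
               "positive")
  expect_error(simulate_membrane_traces(mod, geom, 1, 1e-3,
                                        box_size = 1, seed = 1),
               "box_size")
  expect_error(simulate_membrane_traces(mod, geom, 1e-3, 1e-3, 3, 1),
               "2 bins")
})

test_that("per-bin expected rates equal the explicit Gaussian profile sum", {
  geom <- default_geom(120)
  mod <- species_model(c_g = 3, c_r = 2, c_gr = 2, q_g = 5000,
                       q_r = 4000, K = 0.06)
  tr <- simulate_membrane_traces(mod, geom, duration = 0.05, dt = 1e-3,
                                 box_size = 3, seed = 5,
                                 keep_positions = TRUE)
  wg <- geom$omega_g / 1000; wr <- geom$omega_r / 1000
  lam_g <- 0; lam_r <- 0
  for (nm in names(tr$detail)) {
    d <- tr$detail[[nm]]
    if (is.null(d$x)) next  # species with zero particles
    fg <- d$focus_green; fr <- d$focus_red
    w_g <- exp(-2 * ((d$x - fg[1])^2 + (d$y - fg[2])^2) / wg^2)
    w_r <- exp(-2 * ((d$x - fr[1])^2 + (d$y - fr[2])^2) / wr^2)
    p <- d$params
    lam_g <- lam_g + rowSums(p$qg * w_g) * tr$dt
    lam_r <- lam_r + rowSums(p$qr * w_r + p$qx * w_g) * tr$dt
  }
  expect_equal(lam_g, as.numeric(tr$detail$g$lambda_green +
                                   tr$detail$r$lambda_green +
                                   tr$detail$gr$lambda_green),
               tolerance = 1e-12)
  expect_equal(lam_r, as.numeric(tr$detail$g$lambda_red +
                                   tr$detail$r$lambda_red +
                                   tr$detail$gr$lambda_red),
               tolerance = 1e-12)
})

test_that("dissociation schedule interpolates between its anchor points", {
  s <- dissociation_schedule(t_stim = 0, f_min = 0.5, t_min = 300,
                             t_recover = 900)
  expect_equal(dimer_fraction_at(s, c(-100, 0)), c(1, 1))
  expect_equal(dimer_fraction_at(s, 150), 0.75)
  expect_equal(dimer_fraction_at(s, 300), 0.5)
  expect_equal(dimer_fraction_at(s, 600), 0.75)
  expect_equal(dimer_fraction_at(s, c(900, 2000)), c(1, 1))
  expect_error(dissociation_schedule(0, 1.2, 300, 900))
  expect_error(dissociation_schedule(500, 0.5, 300, 900))
})

test_that("dynamic experiment conserves label totals and follows the schedule", {
  geom <- default_geom(120)
  mod <- species_model(c_g = 10, c_r = 10, c_gr = 20, K = 0.05)
  sched <- dissociation_schedule(0, 0.5, 300, 900)
  exp_out <- simulate_dynamic_experiment(mod, geom, sched,
                                         time_points = c(-60, 150, 300,
                                                         600, 900),
                                         segment_length = 0.5,
                                         n_segments_per_point = 1,
                                         dt = 1e-3, seed = 8)
  fr <- vapply(exp_out, function(tp) tp$model_at$c_gr / mod$c_gr, 1)
  expect_equal(fr, c(1, 0.75, 0.5, 0.75, 1))
  # green and red label totals per unit area are conserved exactly
  for (tp in exp_out) {
    expect_equal(tp$model_at$c_g + tp$model_at$c_gr, mod$c_g + mod$c_gr)
    expect_equal(tp$model_at$c_r + tp$model_at$c_gr, mod$c_r + mod$c_gr)
  }
  # f_min = 1 leaves the model untouched at every time point
  flat <- simulate_dynamic_experiment(mod, geom,
    dissociation_schedule(0, 1, 300, 900),
    time_points = c(-60, 300, 900), segment_length = 0.5,
    n_segments_per_point = 1, dt = 1e-3, seed = 8)
  for (tp in flat) expect_equal(tp$model_at$c_gr, mod$c_gr)
  # full dissociation at the minimum: no complex left
  zero <- simulate_dynamic_experiment(mod, geom,
    dissociation_schedule(0, 0, 300, 900), time_points = 300,
    segment_length = 0.5, n_segments_per_point = 1, dt = 1e-3, seed = 8)
  expect_equal(zero[[1]]$model_at$c_gr, 0)
})

test_that("single-species traces match the closed-form FCS amplitude and transit time", {
  # small-median smoke check; the 20-seed version runs in the acceptance
  # suite (per-seed transit-time estimates scatter widely by nature)
  geom <- default_geom()
  D <- 0.4
  mod <- species_model(c_g = 100, D_g = D)
  est <- t(vapply(2024:2026, function(s) {
    tr <- simulate_membrane_traces(mod, geom, duration = 30, dt = 1e-3,
                                   box_size = 3, seed = s)
    fit <- fit_fcs_tauD(fccs_curves(tr, segment_length = 10)$GG)
    c(fit$G0, fit$tau_D_ms)
  }, c(0, 0)))
  expect_equal(median(est[, 1]), 1 / (pi * 0.222^2 * 100),
               tolerance = 0.2)
  expect_equal(median(est[, 2]), 0.222^2 / (4 * D) * 1000,
               tolerance = 0.3)
})

test_that("enumerate_pairings input contract", {
  expect_error(enumerate_pairings(1, 2), "even")
  expect_equal(enumerate_pairings(0, 4), 0)
  expect_equal(enumerate_pairings(40, 40),
               2 * 1600 / (80 * 79))
})
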