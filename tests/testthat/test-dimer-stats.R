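# Combinatorial dimer statistics: random-pairing probabilities, expected
# mixed-dimer concentrations, model RMS, amplitude ratios and crosstalk
# correction of amplitudes.

test_that("pairing enumeration matches hand counts and the closed form", {
  # 2 green + 2 red: pairings {gg,rr}, {gr,gr}, {gr,gr} -> mean 2/3
  expect_equal(enumerate_pairings(2, 2), 2 / 3)
  expect_equal(enumerate_pairings(2, 0), 0)
  expect_equal(enumerate_pairings(6, 2), 24 / 56)
  # enumeration and closed form agree exactly for all small totals
  for (tot in seq(2, 10, by = 2)) {
    for (M in 0:tot) {
      N <- tot - M
      expect_equal(enumerate_pairings(M, N, method = "enumerate"),
                   2 * M * N / (tot * (tot - 1)),
                   info = sprintf("M=%d N=%d", M, N))
    }
  }
  expect_error(enumerate_pairings(3, 2), "even")
  expect_error(enumerate_pairings(0, 0), "at least 2")
})

test_that("pairing enumeration agrees with the independent pairing walker", {
  for (case in list(c(2, 2), c(6, 2), c(4, 4), c(5, 3), c(8, 2))) {
    expect_equal(enumerate_pairings(case[1], case[2]),
                 oracle_mixed_fraction(case[1], case[2]),
                 tolerance = 1e-12,
                 info = paste(case, collapse = "/"))
  }
})

test_that("approximate pair probability is within 1/(M+N) of the exact value", {
  for (tot in seq(2, 12, by = 2)) {
    for (M in 0:tot) {
      N <- tot - M
      # express (M, N) as dimer-class counts: put mixed pairs first
      gr <- min(M, N)
      approx <- pair_probability(pairing_count(
        c_gg = (M - gr) / 2, c_gr = gr, c_rr = (N - gr) / 2))
      exact <- enumerate_pairings(M, N)
      expect_lte(abs(approx - exact), 1 / (M + N) + 1e-12)
    }
  }
})

test_that("pair probability has the stated symmetries and maximum", {
  expect_equal(pair_probability(pairing_count(c_gg = 1, c_rr = 1)), 0.5)
  expect_equal(pair_probability(pairing_count(c_gr = 5)), 0.5)
  expect_equal(pair_probability(pairing_count(3, 0, 1)), 0.375)
  # symmetric under label swap; maximal at M = N
  for (i in 1:20) {
    ct <- pairing_count(c_gg = runif(1, 0, 5), c_gr = runif(1, 0, 5),
                        c_rr = runif(1, 0, 5))
    swapped <- pairing_count(ct$c_rr, ct$c_gr, ct$c_gg)
    expect_equal(pair_probability(ct), pair_probability(swapped))
    expect_lte(pair_probability(ct), 0.5 + 1e-12)
  }
  expect_error(pair_probability(pairing_count(0, 0, 0)), "zero")
})

test_that("expected cross-dimer concentration obeys the random-pairing identity", {
  # binomial split is the fixed point: c_gr / c'_gr = 1 at any fraction
  for (f in c(0.1, 0.25, 0.5, 0.77, 0.9)) {
    tot <- 7.3
    ct <- pairing_count(c_gg = f^2 * tot, c_gr = 2 * f * (1 - f) * tot,
                        c_rr = (1 - f)^2 * tot)
    expect_equal(expected_crossdimer(ct), ct$c_gr, tolerance = 1e-12)
  }
  expect_equal(expected_crossdimer(pairing_count(c_gr = 5)), 2.5)
  # identity c'_gr = p_gr * total holds for arbitrary counts
  set.seed(7)
  for (i in 1:100) {
    ct <- pairing_count(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 10))
    expect_equal(expected_crossdimer(ct),
                 pair_probability(ct) * (ct$c_gg + ct$c_gr + ct$c_rr),
                 tolerance = 1e-12)
  }
})

test_that("model agreement RMS behaves as a root mean square", {
  cts <- lapply(1:5, function(i) pairing_count(1, 2, 1))
  pred <- pair_probability(cts[[1]])
  perfect <- model_agreement_rms(rep(pred, 5), cts, "all-dimer")
  expect_equal(perfect$rms, 0)
  offset <- model_agreement_rms(rep(pred + 0.1, 5), cts, "all-dimer")
  expect_equal(offset$rms, 0.1)
  zero <- model_agreement_rms(c(0.05, -0.05), cts[1:2], "zero-dimer")
  expect_equal(zero$rms, 0.05)
  expect_error(model_agreement_rms(numeric(0), list()), "no cells")
})

test_that("bound fraction is the amplitude ratio with guarded input", {
  expect_equal(bound_fraction(0.02, 0.10), 0.2)
  expect_equal(bound_fraction(0, 0.1), 0)
  expect_equal(bound_fraction(0.07, 0.07), 1)
  expect_error(bound_fraction(0.02, 0), "positive")
})

test_that("crosstalk amplitude correction is identity at kappa 0 and zeroes pure bleed", {
  expect_equal(correct_crosstalk_amplitude(0.02, 0.1, 100, 80, 0), 0.02)
  # analytic pure-bleed case: red channel = kappa * green + background;
  # the measured cross amplitude is Gg0 * kappa*I_g / I_r, which must
  # correct to exactly zero
  kappa <- 0.051; I_g <- 100; I_r <- kappa * I_g + 40; Gg0 <- 0.08
  Gx0 <- Gg0 * kappa * I_g / I_r
  expect_equal(correct_crosstalk_amplitude(Gx0, Gg0, I_g, I_r, kappa), 0,
               tolerance = 1e-12)
  expect_error(correct_crosstalk_amplitude(0.01, 0.1, 100, 5, 0.051),
               "crosstalk floor")
})

test_that("dynamic series normalizations hit their reference points", {
  s <- dynamic_series(0:2, bound_fraction = c(0.10, 0.05, 0.12))
  expect_equal(normalize_dynamic_series(s)$bound_fraction, c(1, 0.5, 1.2))
  s2 <- dynamic_series(0:2, N_g = c(50, 60, 55), N_r = c(40, 44, 38))
  n2 <- normalize_dynamic_series(s2, "particles")
  expect_equal(n2$N_g, c(100, 120, 110))
  expect_equal(n2$N_r[1], 100)
  expect_error(normalize_dynamic_series(
    dynamic_series(0:1, bound_fraction = c(0, 1))), "reference")
})

test_that("intensity-ratio screen deselects green-dominated cells", {
  expect_true(intensity_ratio_screen(80, 100))
  expect_false(intensity_ratio_screen(120, 100))
  expect_false(intensity_ratio_screen(180, 100, threshold = 1.6))
  expect_true(intensity_ratio_screen(150, 100, threshold = 1.6))
})
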