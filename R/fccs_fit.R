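# Global least-squares fitting of the two-color FCCS model and the
# single-component FCS transit-time fit, with the acquisition-level
# quality-control screens applied before any measurement enters the
# dimerization statistics.

# Per-lag weights: inverse across-segment standard deviation when enough
# segments contributed for the sd estimate to be usable (>= 8; with fewer
# segments the noisy sd estimates overweight the long-lag tail and the
# global fit chases tail noise), floored so no lag dominates.
.curve_weights <- function(curve) {
  if (!is.null(curve$sd) && (curve$meta$n_segments %||% 1) >= 8) {
    s <- pmax(curve$sd, 0.3 * median(curve$sd), 1e-12)
    1 / s
  } else rep(1, length(curve$lags))
}

# theta is the free-parameter vector on the fitting scale: log scale for
# concentrations and diffusion coefficients, natural scale for K and r0.
.theta_to_model <- function(theta, fixed, geom) {
  p <- fixed
  for (nm in names(theta)) {
    val <- theta[[nm]]
    p[[nm]] <- if (grepl("^(c_|D_)", nm)) exp(val) else val
  }
  model <- species_model(c_g = p$c_g, c_r = p$c_r, c_gr = p$c_gr,
                         D_g = p$D_g, D_r = p$D_r, D_gr = p$D_gr,
                         q_g = p$q_g, q_r = p$q_r,
                         x_g = p$x_g, x_r = p$x_r, K = p$K,
                         bg_g = p$bg_g, bg_r = p$bg_r)
  geom2 <- detection_geometry(geom$omega_g, geom$omega_r, p$r0)
  list(model = model, geom = geom2)
}

.fccs_residuals <- function(theta, names_free, fixed, geom, curves,
                            weights) {
  th <- as.list(theta)
  names(th) <- names_free
  offs <- th[grep("^off_", names(th))]
  th <- th[!grepl("^off_", names(th))]
  mg <- .theta_to_model(th, fixed, geom)
  res <- numeric(0)
  for (pair in c("GG", "RR", "GR")) {
    cv <- curves[[pair]]
    if (is.null(cv)) next
    mod <- model_correlations(mg$model, mg$geom, cv$lags)[[pair]] +
      (offs[[paste0("off_", pair)]] %||% 0)
    res <- c(res, weights[[pair]] * (mod - cv$values))
  }
  res
}

# Moment-based starting values from the curve amplitudes and half-decay
# lags; robust enough that a handful of jittered restarts converges.
.fccs_init <- function(curves, geom, x_g, x_r, K, r0) {
  amp <- function(cv) mean(head(cv$values, 3))
  half_decay <- function(cv, omega_um2) {
    a <- amp(cv)
    if (a <= 0) return(0.3)
    i <- which(cv$values <= a / 2)
    tau_half <- if (length(i)) cv$lags[min(i)] else max(cv$lags)
    max(omega_um2 / (4 * tau_half), 1e-3)
  }
  wg2 <- (geom$omega_g / 1000)^2
  wr2 <- (geom$omega_r / 1000)^2
  n_g_tot <- 1 / max(amp(curves$GG), 1e-4)
  n_r_tot <- 1 / max(amp(curves$RR), 1e-4)
  displ0 <- displacement_factor(1e-4, r0, geom$omega_g, geom$omega_r)
  c_gr <- max(amp(curves$GR), 0) * n_g_tot * n_r_tot *
    geom$A_gr / (geom$A_g * geom$A_r) / displ0
  c_gr <- max(min(c_gr, 0.9 * min(n_g_tot / geom$A_g,
                                  n_r_tot / geom$A_r)), 0.5)
  c_g <- max((n_g_tot / geom$A_g - c_gr) / x_g, 0.5)
  c_r <- max((n_r_tot / geom$A_r - c_gr) / x_r, 0.5)
  list(c_g = c_g, c_r = c_r, c_gr = c_gr,
       D_g = half_decay(curves$GG, wg2),
       D_r = half_decay(curves$RR, wr2),
       D_gr = half_decay(curves$GG, wg2) / 2, K = K, r0 = r0)
}

.fccs_bounds <- function(names_free, r0_bounds, curves = NULL) {
  # offsets are bounded by the physical size of the finite-segment
  # normalization bias, which scales with each curve's own amplitude
  # (~2 G0 tau_D log(T/tau_D)/T, a few percent of G0 for membrane
  # transit times and >= 10 s segments); a fixed generous bound would
  # let the cross-curve offset absorb a small genuine crosstalk or
  # co-diffusion amplitude outright
  off_bound <- function(nm) {
    pair <- sub("^off_", "", nm)
    amp <- if (!is.null(curves[[pair]]))
      abs(mean(head(curves[[pair]]$values, 3))) else 0.05
    min(max(0.1 * amp, 2e-4), 0.005)
  }
  lower <- vapply(names_free, function(nm) {
    if (grepl("^off_", nm)) return(-off_bound(nm))
    if (grepl("^D_", nm)) return(log(1e-3))
    switch(nm, K = 0, r0 = r0_bounds[1], log(1e-3))
  }, 1)
  upper <- vapply(names_free, function(nm) {
    if (grepl("^off_", nm)) return(off_bound(nm))
    if (grepl("^D_", nm)) return(log(100))
    switch(nm, K = 0.99, r0 = r0_bounds[2], log(1e4))
  }, 1)
  list(lower = lower, upper = upper)
}

.fit_fccs_global <- function(curves, geom, free, fixed, r0_bounds,
                             n_starts = 5, jitter_sd = 0.4) {
  weights <- list(GG = .curve_weights(curves$GG),
                  RR = .curve_weights(curves$RR),
                  GR = .curve_weights(curves$GR))
  init <- .fccs_init(curves, geom, fixed$x_g, fixed$x_r,
                     fixed$K %||% 0.05, fixed$r0 %||% mean(r0_bounds))
  theta0 <- vapply(free, function(nm) {
    if (grepl("^off_", nm)) return(0)
    v <- init[[nm]]
    if (grepl("^(c_|D_)", nm)) log(max(v, 1e-4)) else v
  }, 1)
  names(theta0) <- free
  b <- .fccs_bounds(free, r0_bounds, curves)
  theta0 <- pmin(pmax(theta0, b$lower), b$upper)

  best <- NULL
  starts <- list(theta0)
  if (n_starts > 1) {
    # deterministic jitters so a fit is reproducible without a seed
    set <- seq_len(n_starts - 1)
    for (i in set) {
      jit <- theta0
      h <- (i %% 5) - 2
      for (j in seq_along(jit)) {
        nm <- free[j]
        jit[j] <- if (nm == "K") min(max(theta0[j] + 0.02 * h, 0), 0.5)
        else if (nm == "r0") mean(r0_bounds) + h * diff(r0_bounds) / 5
        else if (grepl("^off_", nm)) 0
        else theta0[j] + jitter_sd * h * (1 + 0.3 * j / length(jit))
      }
      starts[[i + 1]] <- pmin(pmax(jit, b$lower), b$upper)
    }
  }
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = b$lower, upper = b$upper,
        fn = .fccs_residuals, names_free = free, fixed = fixed,
        geom = geom, curves = curves, weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(NULL)
  best
}

.fit_r2 <- function(curves, fitted_curves) {
  vapply(c("GG", "RR", "GR"), function(pair) {
    y <- curves[[pair]]$values
    f <- fitted_curves[[pair]]
    1 - sum((y - f)^2) / sum((y - mean(y))^2)
  }, 1)
}

.make_fccs_fit <- function(best, free, fixed, geom, curves, r0_bounds) {
  th <- as.list(best$fit$par)
  names(th) <- free
  offs <- th[grep("^off_", names(th))]
  th <- th[!grepl("^off_", names(th))]
  mg <- .theta_to_model(th, fixed, geom)
  m <- mg$model
  fitted_curves <- lapply(c(GG = "GG", RR = "RR", GR = "GR"), function(p)
    model_correlations(m, mg$geom, curves[[p]]$lags)[[p]] +
      (offs[[paste0("off_", p)]] %||% 0))
  resid <- lapply(c(GG = "GG", RR = "RR", GR = "GR"), function(p)
    curves[[p]]$values - fitted_curves[[p]])
  r2 <- .fit_r2(curves, fitted_curves)
  flags <- character(0)
  if (best$fit$info %in% c(0, 9)) flags <- c(flags, "non_convergence")
  # structured residuals in the cross curve indicate an unmodeled
  # co-diffusing component (e.g. a control fit applied to dimer data);
  # require the residuals to be both smooth and large compared with the
  # across-segment noise (or, lacking a noise estimate, the curve range)
  gr_res <- resid$GR
  if (length(gr_res) > 3) {
    ac1 <- suppressWarnings(cor(gr_res[-1], gr_res[-length(gr_res)]))
    cv <- curves$GR
    big <- if (!is.null(cv$sd) && (cv$meta$n_segments %||% 1) >= 3) {
      se <- pmax(cv$sd / sqrt(cv$meta$n_segments), 1e-12)
      median(abs(gr_res) / se) > 3
    } else {
      sqrt(mean(gr_res^2)) / max(abs(range(cv$values)), 1e-12) > 0.05 &&
        is.finite(ac1) && ac1 > 0.9
    }
    if (is.finite(ac1) && ac1 > 0.7 && big)
      flags <- c(flags, "gr_residual_structure")
  }
  wg2 <- (mg$geom$omega_g / 1000)^2
  wr2 <- (mg$geom$omega_r / 1000)^2
  total <- m$c_g + m$c_r + m$c_gr
  derived <- list(
    tau_d_ms = c(g_G = wg2 / (4 * m$D_g), r_R = wr2 / (4 * m$D_r),
                 gr_G = wg2 / (4 * m$D_gr)) * 1000,
    N_g = geom$A_g * m$c_g, N_r = geom$A_r * m$c_r,
    N_gr = geom$A_gr * m$c_gr,
    dimer_fraction = if (total > 0) m$c_gr / total else NA_real_)
  structure(
    list(model = m, geom = mg$geom, free = free,
         x_g = fixed$x_g, x_r = fixed$x_r, K = m$K,
         offsets = offs,
         ssr = best$ssr, r2 = r2, converged = !("non_convergence" %in% flags),
         flags = flags, fitted = fitted_curves, residuals = resid,
         curves = curves, derived = derived),
    class = "fccs_fit")
}

#' @export
print.fccs_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("FCCS global fit (x_g = %d, x_r = %d)%s\n", x$x_g, x$x_r,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                collapse = ","), "]") else ""))
  cat(sprintf("  c_g = %.3g, c_r = %.3g, c_gr = %.3g /um^2 (dimer fraction %.3f)\n",
              m$c_g, m$c_r, m$c_gr, x$derived$dimer_fraction))
  cat(sprintf("  D_g = %.3g, D_r = %.3g, D_gr = %.3g um^2/s; K = %.4f; r0 = %.1f nm\n",
              m$D_g, m$D_r, m$D_gr, m$K, x$geom$r0))
  cat(sprintf("  R^2: GG %.3f, RR %.3f, GR %.3f\n",
              x$r2["GG"], x$r2["RR"], x$r2["GR"]))
  invisible(x)
}

#' Step one of the two-step FCCS procedure: control fit for crosstalk
#'
#' Fits the global correlation model to a single-construct (control)
#' measurement in which no dual-labeled complex exists: the complex
#' concentration is fixed to zero, the detection radii are fixed to their
#' calibration values, and the concentrations, diffusion coefficients and
#' the crosstalk parameter `K` are free.  Because the cross-section ratios
#' cannot be determined from a control measurement, the fit is repeated for
#' every requested `(x_g, x_r)` combination, yielding one crosstalk
#' estimate per combination.
#'
#' @param curves List with `correlation_curve` elements `GG`, `RR`, `GR`
#'   (e.g. from [fccs_curves()]).
#' @param geom A [detection_geometry()] with calibrated radii.
#' @param x_choices List of `c(x_g, x_r)` combinations; default all four.
#' @param q Per-label molecular brightness assumed for background
#'   conversion (counts/s); backgrounds default to zero.
#' @param n_starts Number of optimizer restarts.
#' @param fit_offsets Fit a small additive baseline per curve.  Default
#'   `FALSE` for control fits: the crosstalk signal in the cross curve is
#'   itself baseline-sized, and on synthetic control batches the
#'   offset-free fit centers the recovered crosstalk markedly better
#'   (the offsets mainly matter where a large co-diffusion amplitude is
#'   being quantified, as in [fit_dimerization()], where the default is
#'   `TRUE`).
#' @return A list of `fccs_fit` objects, one per x-combination, each with
#'   a `$K` estimate.  Fits that fail to converge carry a
#'   `"non_convergence"` flag; a control fit applied to data containing a
#'   co-diffusing species raises `"gr_residual_structure"`.
#' @export
fit_control <- function(curves, geom,
                        x_choices = list(c(1, 1), c(1, 2),
                                         c(2, 1), c(2, 2)),
                        q = 3000, n_starts = 5, fit_offsets = FALSE) {
  stopifnot(!is.null(curves$GG), !is.null(curves$RR), !is.null(curves$GR))
  lapply(x_choices, function(xc) {
    fixed <- list(c_gr = 0, x_g = xc[1], x_r = xc[2],
                  D_gr = 0.25, r0 = 125,
                  q_g = q, q_r = q, bg_g = 0, bg_r = 0)
    free <- c("c_g", "c_r", "D_g", "D_r", "K")
    if (fit_offsets) free <- c(free, "off_GG", "off_RR", "off_GR")
    best <- .fit_fccs_global(curves, geom, free, fixed,
                             r0_bounds = c(100, 150), n_starts = n_starts)
    if (is.null(best)) return(structure(list(
      x_g = xc[1], x_r = xc[2], K = NA_real_,
      flags = "non_convergence", converged = FALSE), class = "fccs_fit"))
    .make_fccs_fit(best, free, fixed, geom, curves, c(100, 150))
  })
}

#' Median crosstalk across control cells
#'
#' @param control_fits List (one element per control cell) of lists of
#'   `fccs_fit` objects as returned by [fit_control()].
#' @return Named numeric vector of median `K` per x-combination.
#' @export
median_control_K <- function(control_fits) {
  stopifnot(length(control_fits) >= 1)
  combos <- vapply(control_fits[[1]],
                   function(f) sprintf("x%d%d", f$x_g, f$x_r), "")
  ks <- vapply(combos, function(cb) {
    vals <- vapply(control_fits, function(cell) {
      i <- which(vapply(cell, function(f)
        sprintf("x%d%d", f$x_g, f$x_r), "") == cb)
      if (length(i)) cell[[i]]$K else NA_real_
    }, 1)
    vals <- vals[is.finite(vals)]
    if (!length(vals)) stop("no converged control fits for ", cb)
    median(vals)
  }, 1)
  names(ks) <- combos
  ks
}

#' Step two of the two-step FCCS procedure: dimerization fit
#'
#' Fits the global correlation model to a two-construct measurement with
#' the crosstalk parameter fixed to the median value from the control
#' fits, the detection radii fixed to their calibration values, the focal
#' displacement restricted to `r0_bounds`, and equal cross-section ratios
#' for the two single-color species.  The three concentrations and three
#' diffusion coefficients are free.
#'
#' @inheritParams fit_control
#' @param K_fixed Crosstalk parameter from [median_control_K()]; must lie
#'   in \[0, 1).
#' @param r0_bounds Allowed focal-displacement range (nm).
#' @param x Common cross-section ratio `x_g = x_r`, 1 or 2.
#' @return An `fccs_fit`; `$derived$dimer_fraction` is
#'   \eqn{c_{gr} / (c_g + c_r + c_{gr})}.
#' @export
fit_dimerization <- function(curves, geom, K_fixed,
                             r0_bounds = c(100, 150), x = 1,
                             q = 3000, n_starts = 5, fit_offsets = TRUE) {
  if (!is.finite(K_fixed) || K_fixed < 0 || K_fixed >= 1)
    stop("K_fixed must lie in [0, 1)")
  stopifnot(x %in% c(1, 2))
  fixed <- list(K = K_fixed, x_g = x, x_r = x,
                q_g = q, q_r = q, bg_g = 0, bg_r = 0)
  free <- c("c_g", "c_r", "c_gr", "D_g", "D_r", "D_gr", "r0")
  if (fit_offsets) free <- c(free, "off_GG", "off_RR", "off_GR")
  best <- .fit_fccs_global(curves, geom, free, fixed, r0_bounds,
                           n_starts = n_starts)
  if (is.null(best))
    return(structure(list(x_g = x, x_r = x, K = K_fixed,
                          flags = "non_convergence", converged = FALSE),
                     class = "fccs_fit"))
  .make_fccs_fit(best, free, fixed, geom, curves, r0_bounds)
}

#' Single-component FCS transit-time fit
#'
#' Fits the one-species 2D diffusion model
#' \eqn{G(\tau) - 1 = G_0 (1 + \tau/\tau_D)^{-1}} to a correlation curve by
#' least squares, excluding lags shorter than `min_lag` (default 1 ms).
#'
#' A small additive baseline is fitted alongside amplitude and transit
#' time (`offset = TRUE`, the default): estimating the mean intensity from
#' the same finite segment that is being correlated depresses the long-lag
#' correlation by a near-constant amount of order
#' \eqn{2 G_0 \tau_D \ln(T/\tau_D)/T}, and absorbing it in a baseline term
#' removes the resulting transit-time bias.
#'
#' @param curve A `correlation_curve`.
#' @param min_lag Shortest lag included in the fit (s).
#' @param weights `"none"` (default) for an unweighted fit, `"auto"` to
#'   use inverse across-segment standard deviations when available.
#' @param offset Fit an additive baseline (default `TRUE`).
#' @return List with `tau_D_ms` (transit time, ms), `tau_D_se_ms`, `G0`
#'   (amplitude above baseline), `G0_se`, `offset`, `r2`, `converged`,
#'   `n_lags` and the lag window used.
#' @examples
#' g <- detection_geometry()
#' lags <- exp(seq(log(1e-3), log(1), length.out = 40))
#' y <- model_correlations(species_model(c_g = 100), g, lags)$GG
#' cv <- structure(list(pair = "GG", lags = lags, values = y,
#'                      n_samples = rep(1, 40), sd = NULL,
#'                      meta = list()), class = "correlation_curve")
#' fit_fcs_tauD(cv)$tau_D_ms  # omega^2/(4 D) = 30.8 ms
#' @export
fit_fcs_tauD <- function(curve, min_lag = 1e-3, weights = "none",
                         offset = TRUE) {
  stopifnot(inherits(curve, "correlation_curve"))
  keep <- curve$lags >= min_lag
  if (sum(keep) < 5) stop("need at least 5 lags above min_lag")
  lags <- curve$lags[keep]
  y <- curve$values[keep]
  w <- rep(1, length(y))
  if (identical(weights, "auto") && !is.null(curve$sd) &&
      (curve$meta$n_segments %||% 1) >= 3) {
    s <- curve$sd[keep]
    w <- 1 / pmax(s, 0.05 * max(s, 1e-12))
  }
  g0_init <- max(mean(head(y, 3)), 1e-4)
  i_half <- which(y <= g0_init / 2)
  tau_init <- if (length(i_half)) lags[min(i_half)] else max(lags) / 4
  resid_fn <- function(p) {
    off <- if (offset) p[3] else 0
    w * (exp(p[1]) / (1 + lags / exp(p[2])) + off - y)
  }
  par0 <- c(log(g0_init), log(tau_init))
  if (offset) par0 <- c(par0, 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_D_ms = NA_real_, converged = FALSE))
  g0 <- exp(fit$par[1]); tau_d <- exp(fit$par[2])
  off <- if (offset) fit$par[3] else 0
  fitted <- g0 / (1 + lags / tau_d) + off
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par0)))
  list(tau_D_ms = tau_d * 1000, tau_D_se_ms = tau_d * se[2] * 1000,
       G0 = g0, G0_se = g0 * se[1], offset = off, r2 = r2,
       converged = !(fit$info %in% c(0, 9)),
       n_lags = length(lags), lag_window = range(lags))
}

#' Per-measurement quality metrics from single-species fits
#'
#' Computes the quantities entering the inclusion screen: the transit time
#' and fit quality from a single-component fit of each autocorrelation, and
#' the molecular brightness (counts per molecule) of each channel from the
#' mean count rate, the background and the particle number implied by the
#' fitted amplitude.
#'
#' @param trace The `intensity_trace` the curves came from.
#' @param curves List with `GG` and `RR` `correlation_curve`s.
#' @param min_lag Shortest lag used in the single-component fits (s).
#' @param bg_g,bg_r Channel background rates (counts/s).
#' @return List with `tau_D_ms` (green channel), `r2`, `cpm_g_khz`,
#'   `cpm_r_khz`, `N_g`, `N_r` and the per-channel fits.
#' @export
qc_metrics <- function(trace, curves, min_lag = 1e-3, bg_g = 0, bg_r = 0) {
  fg <- fit_fcs_tauD(curves$GG, min_lag = min_lag)
  fr <- fit_fcs_tauD(curves$RR, min_lag = min_lag)
  rate_g <- mean(trace$counts_green) / trace$dt
  rate_r <- mean(trace$counts_red) / trace$dt
  n_g <- 1 / fg$G0
  n_r <- 1 / fr$G0
  list(tau_D_ms = fg$tau_D_ms, r2 = fg$r2,
       cpm_g_khz = (rate_g - bg_g) / n_g / 1000,
       cpm_r_khz = (rate_r - bg_r) / n_r / 1000,
       N_g = n_g, N_r = n_r, fit_green = fg, fit_red = fr)
}

#' Measurement inclusion screen
#'
#' Applies the exclusion criteria under which a measurement enters the
#' dimerization analysis: total included acquisition time between 20 and
#' 80 s, transit time between 1 and 150 ms, single-species fit
#' \eqn{R^2} between 0.9 and 1, molecular brightness between 0.2 and
#' 2.5 kHz per molecule in each channel, and a green/red brightness ratio
#' between 0.5 and 2.5.  Every failure is reported with a reason code.
#'
#' @param metrics List as returned by [qc_metrics()] (fields `tau_D_ms`,
#'   `r2`, `cpm_g_khz`, `cpm_r_khz`).
#' @param total_time Total included acquisition time (s).
#' @param time_range,tau_range,r2_range,cpm_range,ratio_range Screen
#'   windows; defaults are the standard acquisition criteria.
#' @return List with `included` (logical) and `reasons` (character vector
#'   of codes among `"time_range"`, `"transit_time"`, `"fit_r2"`,
#'   `"brightness"`, `"brightness_ratio"`).
#' @examples
#' m <- list(tau_D_ms = 50, r2 = 0.95, cpm_g_khz = 1, cpm_r_khz = 1)
#' apply_qc(m, total_time = 40)$included
#' @export
apply_qc <- function(metrics, total_time,
                     time_range = c(20, 80), tau_range = c(1, 150),
                     r2_range = c(0.9, 1), cpm_range = c(0.2, 2.5),
                     ratio_range = c(0.5, 2.5)) {
  inside <- function(x, rng) is.finite(x) && x >= rng[1] && x <= rng[2]
  reasons <- character(0)
  if (!inside(total_time, time_range)) reasons <- c(reasons, "time_range")
  if (!inside(metrics$tau_D_ms, tau_range))
    reasons <- c(reasons, "transit_time")
  if (!inside(metrics$r2, r2_range)) reasons <- c(reasons, "fit_r2")
  if (!inside(metrics$cpm_g_khz, cpm_range) ||
      !inside(metrics$cpm_r_khz, cpm_range))
    reasons <- c(reasons, "brightness")
  if (!inside(metrics$cpm_g_khz / metrics$cpm_r_khz, ratio_range))
    reasons <- c(reasons, "brightness_ratio")
  list(included = length(reasons) == 0, reasons = reasons)
}
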