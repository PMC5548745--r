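# End-to-end orchestration: simulate (or load) a batch of cells, screen
# and correlate the traces, run the two-step global fit, apply the
# measurement QC and assemble the per-cell dimerization table.

#' Analyze one FCCS measurement end to end
#'
#' Screens and correlates a two-channel trace, runs the dimerization fit
#' with a fixed crosstalk value, computes the quality metrics and returns
#' the per-cell summary row.
#'
#' @param trace An `intensity_trace`.
#' @param geom A [detection_geometry()].
#' @param K_fixed Crosstalk parameter (from [median_control_K()]).
#' @param x Common cross-section ratio for the single-color species.
#' @param segment_length Acquisition segment length (s).
#' @param n_starts Optimizer restarts for the global fit.
#' @param qc Apply the measurement inclusion screen (default `TRUE`).
#' @return List with `fit` (`fccs_fit`), `curves`, `metrics`, `qc` and
#'   `summary` (a one-row data frame).
#' @export
analyze_fccs_cell <- function(trace, geom, K_fixed, x = 1,
                              segment_length = 10, n_starts = 5,
                              qc = TRUE) {
  cur <- fccs_curves(trace, segment_length = segment_length)
  if (is.null(cur$GG))
    return(list(fit = NULL, curves = cur, metrics = NULL,
                qc = list(included = FALSE, reasons = "no_kept_segments"),
                summary = NULL))
  fit <- fit_dimerization(cur, geom, K_fixed, x = x, n_starts = n_starts)
  metrics <- qc_metrics(trace, cur)
  verdict <- if (qc) apply_qc(metrics, cur$included_time)
  else list(included = TRUE, reasons = character(0))
  m <- fit$model
  summary <- data.frame(
    c_g = m$c_g, c_r = m$c_r, c_gr = m$c_gr,
    dimer_fraction = fit$derived$dimer_fraction,
    D_g = m$D_g, D_r = m$D_r, D_gr = m$D_gr, r0 = fit$geom$r0,
    tau_D_ms = metrics$tau_D_ms, cpm_g_khz = metrics$cpm_g_khz,
    cpm_r_khz = metrics$cpm_r_khz, r2_fcs = metrics$r2,
    included_time = cur$included_time,
    qc_included = verdict$included,
    qc_reasons = paste(verdict$reasons, collapse = ";"))
  list(fit = fit, curves = cur, metrics = metrics, qc = verdict,
       summary = summary)
}

#' Run the synthetic FCCS dimerization pipeline
#'
#' Simulates a batch of control cells (single-color constructs, no
#' dual-labeled complex) and measurement cells, then executes the full
#' analysis chain: segment screening, multiple-tau correlation, the
#' two-step global fit (control crosstalk estimation, then dimerization
#' fits with the median crosstalk fixed), measurement QC, and the
#' random-pairing dimerization statistics.
#'
#' @param control_model [species_model()] for the control cells (should
#'   have `c_gr = 0` and the crosstalk `K` of the instrument).
#' @param measure_model [species_model()] for the measurement cells.
#' @param geom A [detection_geometry()].
#' @param n_controls,n_cells Numbers of control and measurement cells.
#' @param duration Trace duration per cell (s).
#' @param dt Sampling interval (s).
#' @param x Cross-section ratio for the measurement fits.
#' @param seed Master seed; all per-cell seeds derive from it.
#' @param box_size Membrane patch side (µm).
#' @param n_starts Optimizer restarts.
#' @return List with `K_median`, `control_fits`, `cells` (per-cell
#'   analysis results) and `summary` (data frame, one row per measurement
#'   cell).
#' @export
run_pipeline <- function(control_model, measure_model, geom,
                         n_controls = 5, n_cells = 5, duration = 30,
                         dt = 1e-3, x = 1, seed = 1, box_size = 3,
                         n_starts = 5) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_controls + n_cells))
  control_fits <- lapply(seq_len(max(n_controls, 0)), function(i) {
    tr <- simulate_membrane_traces(control_model, geom, duration, dt,
                                   box_size, seed = seeds[i])
    cur <- fccs_curves(tr)
    fit_control(cur, geom, x_choices = list(c(x, x)))
  })
  K_med <- if (n_controls > 0) median_control_K(control_fits)[1]
  else control_model$K
  cells <- lapply(seq_len(max(n_cells, 0)), function(i) {
    tr <- simulate_membrane_traces(measure_model, geom, duration, dt,
                                   box_size, seed = seeds[n_controls + i])
    analyze_fccs_cell(tr, geom, K_fixed = unname(K_med), x = x,
                      n_starts = n_starts)
  })
  rows <- Filter(Negate(is.null), lapply(cells, `[[`, "summary"))
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(c_g = numeric(0), c_r = numeric(0), c_gr = numeric(0),
               dimer_fraction = numeric(0), D_g = numeric(0),
               D_r = numeric(0), D_gr = numeric(0), r0 = numeric(0),
               tau_D_ms = numeric(0), cpm_g_khz = numeric(0),
               cpm_r_khz = numeric(0), r2_fcs = numeric(0),
               included_time = numeric(0), qc_included = logical(0),
               qc_reasons = character(0))
  list(K_median = unname(K_med), control_fits = control_fits,
       cells = cells, summary = summary)
}

#' Amplitude series of a dynamic dissociation experiment
#'
#' Reduces the output of [simulate_dynamic_experiment()] (or an equivalent
#' list of per-time-point trace batches) to a [dynamic_series()]: per time
#' point, the segment correlation curves are averaged, one-component
#' models fitted to the green autocorrelation and the cross-correlation,
#' and the bound fraction taken as the amplitude ratio
#' \eqn{(G_{cc}(0)-1)/(G_g(0)-1)}.  The green and red particle numbers
#' are the inverse autocorrelation amplitudes.
#'
#' Because the series is interpreted relative to its pre-stimulation
#' value, the amplitude fits deliberately omit the additive baseline used
#' elsewhere: the finite-segment normalization bias is common to all time
#' points and cancels in the normalization, whereas a free baseline
#' parameter trades against the amplitude and inflates point-to-point
#' variance.  Lags beyond `max_lag` (default 1 s) carry correlated
#' low-frequency noise and are excluded.
#'
#' @param experiment List of time-point entries (`time`, `traces`).
#' @param m Multiple-tau points per octave.
#' @param min_lag Shortest lag used in the amplitude fits (s).
#' @param max_lag Longest lag used in the amplitude fits (s).
#' @return A [dynamic_series()].
#' @export
dynamic_amplitude_series <- function(experiment, m = 16, min_lag = 1e-3,
                                     max_lag = 1) {
  times <- vapply(experiment, `[[`, 1, "time")
  est <- lapply(experiment, function(tp) {
    mg <- mean(unlist(lapply(tp$traces, `[[`, "counts_green")))
    mr <- mean(unlist(lapply(tp$traces, `[[`, "counts_red")))
    gg <- average_correlations(lapply(tp$traces, autocorrelate,
                                      channel = "G", m = m,
                                      mean_value = mg))
    rr <- average_correlations(lapply(tp$traces, autocorrelate,
                                      channel = "R", m = m,
                                      mean_value = mr))
    gr <- average_correlations(lapply(tp$traces, crosscorrelate, m = m,
                                      mean_green = mg, mean_red = mr))
    trim <- function(cv) {
      k <- cv$lags <= max_lag
      cv$lags <- cv$lags[k]; cv$values <- cv$values[k]
      cv$n_samples <- cv$n_samples[k]
      if (!is.null(cv$sd)) cv$sd <- cv$sd[k]
      cv
    }
    gg <- trim(gg); rr <- trim(rr); gr <- trim(gr)
    fg <- fit_fcs_tauD(gg, min_lag = min_lag, offset = FALSE)
    fr <- fit_fcs_tauD(rr, min_lag = min_lag, offset = FALSE)
    # cross amplitude: same one-component shape with the diffusion time
    # from the green fit; projection, since the amplitude may be ~0
    tau_x <- fg$tau_D_ms / 1000
    lags <- gr$lags[gr$lags >= min_lag]
    y <- gr$values[gr$lags >= min_lag]
    shape <- 1 / (1 + lags / tau_x)
    gcc0 <- sum(shape * y) / sum(shape^2)
    c(gcc0 = gcc0, gg0 = fg$G0, rr0 = fr$G0)
  })
  est <- do.call(rbind, est)
  dynamic_series(times,
                 bound_fraction = bound_fraction(est[, "gcc0"],
                                                 est[, "gg0"]),
                 N_g = 1 / est[, "gg0"], N_r = 1 / est[, "rr0"])
}
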