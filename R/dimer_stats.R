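# Combinatorial random-pairing statistics for two-color dimer populations,
# model-agreement summaries, amplitude-based bound-fraction estimation with
# crosstalk correction, and the normalizations used for dynamic
# (time-lapse) dissociation series.

#' Probability that a dimer is mixed under random pairing
#'
#' Given concentrations of green–green, green–red and red–red dimers, the
#' numbers of green and red molecules are \eqn{M = 2c_{gg} + c_{gr}} and
#' \eqn{N = 2c_{rr} + c_{gr}}.  If all molecules pair at random, the
#' probability that a dimer carries one label of each color is, in the
#' large-population approximation,
#' \deqn{p_{gr} = \frac{2MN}{(M+N)^2}
#'   = \frac{(2c_{gg}+c_{gr})(2c_{rr}+c_{gr})}{2(c_{gg}+c_{gr}+c_{rr})^2}.}
#' The exact finite-population value \eqn{2MN/((M+N)(M+N-1))} is available
#' from [enumerate_pairings()]; the two differ by at most \eqn{1/(M+N)}.
#'
#' @param counts A [pairing_count()] with a positive dimer total.
#' @return The mixed-dimer probability, in \[0, 1\].
#' @examples
#' pair_probability(pairing_count(c_gg = 1, c_rr = 1))  # 0.5
#' @export
pair_probability <- function(counts) {
  stopifnot(inherits(counts, "pairing_count"))
  tot <- counts$c_gg + counts$c_gr + counts$c_rr
  if (tot <= 0) stop("all-zero pairing counts")
  counts$M * counts$N / (2 * tot^2)
}

#' Expected mixed-dimer concentration under random pairing
#'
#' The concentration of mixed dimers predicted if every molecule pairs at
#' random: \eqn{c'_{gr} = p_{gr} (c_{gg} + c_{gr} + c_{rr})}.  The ratio
#' \eqn{c_{gr}/c'_{gr}} equals 1 exactly when the observed dimer classes
#' follow the binomial split \eqn{f^2 : 2f(1-f) : (1-f)^2}.
#'
#' @inheritParams pair_probability
#' @return Expected mixed-dimer concentration \eqn{c'_{gr}}.
#' @examples
#' expected_crossdimer(pairing_count(0.25, 0.5, 0.25))  # 0.5
#' @export
expected_crossdimer <- function(counts) {
  stopifnot(inherits(counts, "pairing_count"))
  tot <- counts$c_gg + counts$c_gr + counts$c_rr
  if (tot <= 0) stop("all-zero pairing counts")
  counts$M * counts$N / (2 * tot)
}

#' Root-mean-square deviation from a dimerization model
#'
#' Compares per-cell measured dimerization fractions with the prediction
#' of a pairing model and returns the RMS deviation.  Under the
#' `"all-dimer"` model every molecule is paired, so the predicted mixed
#' fraction for a cell is the random-pairing probability computed from its
#' green/red molecule numbers; under `"zero-dimer"` the prediction is 0.
#'
#' @param measured Numeric vector of measured mixed-dimer fractions, one
#'   per cell (e.g. \eqn{c_{gr}} over total dimer concentration from
#'   [fit_dimerization()]).
#' @param counts List of [pairing_count()] objects, one per cell, giving
#'   the label composition used for the model prediction.
#' @param model `"all-dimer"` or `"zero-dimer"`.
#' @return List with `rms`, and per-cell `predicted` and `deviation`.
#' @export
model_agreement_rms <- function(measured, counts,
                                model = c("all-dimer", "zero-dimer")) {
  model <- match.arg(model)
  if (length(measured) < 1) stop("no cells supplied")
  stopifnot(length(measured) == length(counts))
  predicted <- vapply(counts, function(ct) {
    if (model == "all-dimer") pair_probability(ct) else 0
  }, 1)
  dev <- measured - predicted
  list(rms = sqrt(mean(dev^2)), predicted = predicted, deviation = dev)
}

#' Bound fraction from correlation amplitudes
#'
#' The fraction of red diffusing units that also carry a green label,
#' estimated from the ratio of the cross-correlation amplitude to the
#' green autocorrelation amplitude:
#' \eqn{N_{gr}/N_r = (G_{cc}(0)-1)/(G_g(0)-1)}.
#'
#' @param Gcc0_minus1 Cross-correlation amplitude \eqn{G_{cc}(0)-1}.
#' @param Gg0_minus1 Green autocorrelation amplitude \eqn{G_g(0)-1};
#'   must be positive.
#' @return The bound fraction \eqn{N_{gr}/N_r}.
#' @examples
#' bound_fraction(0.02, 0.10)  # 0.2
#' @export
bound_fraction <- function(Gcc0_minus1, Gg0_minus1) {
  if (!all(Gg0_minus1 > 0)) stop("green amplitude must be positive")
  Gcc0_minus1 / Gg0_minus1
}

#' Crosstalk correction of the cross-correlation amplitude
#'
#' Spectral crosstalk lets green emission leak into the red channel and
#' produces a spurious cross-correlation amplitude even for fully
#' independent species.  Using the intensity-bleed model
#' \eqn{I_r^{meas} = I_r^{true} + \kappa I_g}, the corrected amplitude is
#' \deqn{G_{x,corr} - 1 = \frac{(G_{x0}-1) I_r^{meas} -
#'   \kappa I_g (G_{g0}-1)}{I_r^{meas} - \kappa I_g}.}
#' Applied to a cell expressing only the green species (plus red-channel
#' background), the corrected amplitude is zero in expectation.
#'
#' @param Gx0_minus1 Measured cross-correlation amplitude.
#' @param Gg0_minus1 Green autocorrelation amplitude.
#' @param I_g,I_r Mean channel intensities (red as measured, including
#'   bleed-through).
#' @param kappa Crosstalk coefficient (red/green intensity ratio of a
#'   green-only cell), in \[0, 1).
#' @return The corrected cross-correlation amplitude.
#' @examples
#' correct_crosstalk_amplitude(0.02, 0.1, I_g = 100, I_r = 80, kappa = 0)
#' @export
correct_crosstalk_amplitude <- function(Gx0_minus1, Gg0_minus1, I_g, I_r,
                                        kappa) {
  stopifnot(kappa >= 0, kappa < 1)
  if (any(I_r <= kappa * I_g))
    stop("red intensity not above crosstalk floor (I_r <= kappa * I_g)")
  (Gx0_minus1 * I_r - kappa * I_g * Gg0_minus1) / (I_r - kappa * I_g)
}

#' Dynamic dissociation series
#'
#' Container for a time-lapse series of amplitude-derived quantities:
#' bound fractions \eqn{N_{gr}/N_r} and particle numbers per time point.
#'
#' @param time Time points (s or min, relative to stimulation).
#' @param bound_fraction \eqn{N_{gr}/N_r} values.
#' @param N_g,N_r Particle numbers in the detection area (optional).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(time, bound_fraction = NULL, N_g = NULL,
                           N_r = NULL) {
  structure(list(time = time, bound_fraction = bound_fraction,
                 N_g = N_g, N_r = N_r),
            class = "dynamic_series")
}

#' Normalize a dynamic dissociation series
#'
#' Two presentation normalizations for time-lapse series: `"fraction"`
#' divides the bound-fraction values by the value at the reference
#' (pre-stimulation) time point, so the series starts at 1;
#' `"particles"` rescales each particle-number series so its first value
#' is 100.
#'
#' @param series A [dynamic_series()].
#' @param mode `"fraction"` or `"particles"`.
#' @param reference Index of the reference time point (default 1, the
#'   pre-stimulation measurement).
#' @return The normalized `dynamic_series`.
#' @examples
#' s <- dynamic_series(0:2, bound_fraction = c(0.10, 0.05, 0.12))
#' normalize_dynamic_series(s)$bound_fraction  # 1.0 0.5 1.2
#' @export
normalize_dynamic_series <- function(series,
                                     mode = c("fraction", "particles"),
                                     reference = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "dynamic_series"))
  if (mode == "fraction") {
    ref <- series$bound_fraction[reference]
    if (!is.finite(ref) || ref <= 0) stop("zero or invalid reference value")
    series$bound_fraction <- series$bound_fraction / ref
  } else {
    for (nm in c("N_g", "N_r")) {
      v <- series[[nm]]
      if (is.null(v)) next
      if (!is.finite(v[1]) || v[1] <= 0)
        stop("zero or invalid first value in ", nm)
      series[[nm]] <- 100 * v / v[1]
    }
  }
  series
}

#' Intensity-ratio deselection for dynamic measurements
#'
#' Cells whose green/red mean intensity ratio exceeds the threshold are
#' deselected from dynamic series (default threshold 1: the immobile or
#' reference red population must not be outnumbered by green signal).
#'
#' @param I_g,I_r Mean channel intensities.
#' @param threshold Maximum tolerated \eqn{I_g/I_r}.
#' @return Logical: `TRUE` if the cell is kept.
#' @export
intensity_ratio_screen <- function(I_g, I_r, threshold = 1) {
  stopifnot(I_r > 0)
  (I_g / I_r) <= threshold
}
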