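#' Two-color membrane FCCS correlation model
#'
#' Evaluates the global two-dimensional diffusion model for the three
#' correlation curves of a dual-color measurement: the green and red
#' autocorrelations and the green–red cross-correlation.  Three molecular
#' species contribute — a green-only species (concentration `c_g`), a
#' red-only species (`c_r`) and the dual-labeled complex (`c_gr`) — with
#' spectral crosstalk `K` from the green labels into the red channel,
#' channel backgrounds, and a displacement factor for the non-perfect
#' overlap of the two detection areas:
#' \deqn{\mathrm{Displ}(\tau) = \exp\!\left(\frac{-2 r_0^2}
#'   {\omega_G^2 + \omega_R^2 + 8 D_{gr}\tau}\right)}
#' The 2D diffusion factors are
#' \eqn{\mathrm{Diff}^G_u(\tau) = (1 + 4 D_u \tau/\omega_G^2)^{-1}} (and
#' analogously for the red and the cross detection areas).
#'
#' Backgrounds are supplied in counts/s in the [species_model()] and
#' converted internally to molecule-equivalent units using the per-label
#' brightness (`2 bg / q`, since a molecule at the focus center emitting at
#' rate `q` contributes `q/2` counts/s on average over the detection area).
#' The model assumes equal per-label brightness in each channel; brightness
#' differences between labeled species enter through the cross-section
#' ratios `x_g`, `x_r`.
#'
#' @param model A [species_model()]; at least one concentration must be
#'   positive.
#' @param geom A [detection_geometry()]; `geom$r0` is the focal
#'   displacement used in `Displ`.
#' @param lags Positive lag times (s).
#' @return List with numeric vectors `GG`, `RR`, `GR`: model values of
#'   \eqn{G(\tau) - 1} at each lag.
#' @examples
#' g <- detection_geometry(222, 272, r0 = 0)
#' m <- species_model(c_g = 100)
#' model_correlations(m, g, 1e-3)$GG  # ~ 1 / (pi * 0.222^2 * 100)
#' @export
model_correlations <- function(model, geom, lags) {
  stopifnot(inherits(model, "species_model"),
            inherits(geom, "detection_geometry"), all(lags > 0))
  if (model$c_g + model$c_r + model$c_gr <= 0)
    stop("all species concentrations are zero: amplitudes undefined")
  wg2 <- (geom$omega_g / 1000)^2
  wr2 <- (geom$omega_r / 1000)^2
  r0 <- geom$r0 / 1000
  A_g <- geom$A_g; A_r <- geom$A_r; A_gr <- geom$A_gr
  m <- model
  diff_g <- function(D) 1 / (1 + 4 * D * lags / wg2)
  diff_r <- function(D) 1 / (1 + 4 * D * lags / wr2)
  diff_x <- function(D) 1 / (1 + 4 * D * lags / ((wg2 + wr2) / 2))
  displ <- exp(-2 * r0^2 / (wg2 + wr2 + 8 * m$D_gr * lags))

  bgg <- if (m$q_g > 0) 2 * m$bg_g / m$q_g else 0
  bgr <- if (m$q_r > 0) 2 * m$bg_r / m$q_r else 0

  green_var <- m$x_g^2 * m$c_g * diff_g(m$D_g) + m$c_gr * diff_g(m$D_gr)
  green_mean <- A_g * (m$x_g * m$c_g + m$c_gr) + bgg
  red_mean <- A_r * (m$x_r * m$c_r + m$c_gr) +
    A_g * m$K * (m$x_g * m$c_g + m$c_gr) + bgr

  # a channel with no signal at all has zero numerator and zero mean;
  # its curves are identically zero, not 0/0
  safe_ratio <- function(num, den) ifelse(num == 0, 0, num / den)
  gg <- safe_ratio(A_g * green_var, green_mean^2)
  rr <- safe_ratio(
    A_r * (m$x_r^2 * m$c_r * diff_r(m$D_r) + m$c_gr * diff_r(m$D_gr)) +
      2 * (A_g * A_r / A_gr) * m$K * m$c_gr * displ * diff_x(m$D_gr) +
      A_g * m$K^2 * green_var,
    red_mean^2)
  gr <- safe_ratio(
    (A_g * A_r / A_gr) * m$c_gr * displ * diff_x(m$D_gr) +
      A_g * m$K * green_var,
    green_mean * red_mean)
  list(GG = gg, RR = rr, GR = gr)
}

#' Displacement factor for non-overlapping foci
#'
#' @param tau Lag times (s).
#' @param r0 Focal displacement (nm).
#' @param omega_g,omega_r Detection radii (nm).
#' @param D Diffusion coefficient of the co-diffusing species (µm²/s).
#' @return \eqn{\exp(-2 r_0^2/(\omega_G^2 + \omega_R^2 + 8 D \tau))}.
#' @export
displacement_factor <- function(tau, r0, omega_g = 222, omega_r = 272,
                                D = 0.25) {
  wg2 <- (omega_g / 1000)^2
  wr2 <- (omega_r / 1000)^2
  exp(-2 * (r0 / 1000)^2 / (wg2 + wr2 + 8 * D * tau))
}

#' Two-dimensional diffusion factor
#'
#' @param tau Lag times (s).
#' @param D Diffusion coefficient (µm²/s).
#' @param omega Detection radius (nm).
#' @return \eqn{(1 + 4 D \tau / \omega^2)^{-1}}; equals 1/2 at the transit
#'   time \eqn{\tau_D = \omega^2 / (4D)}.
#' @export
diffusion_factor <- function(tau, D, omega = 222) {
  1 / (1 + 4 * D * tau / (omega / 1000)^2)
}
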