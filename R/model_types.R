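#' Confocal detection geometry for two-color membrane FCCS
#'
#' Describes the two laterally displaced Gaussian detection areas of a
#' dual-color confocal setup.  The lateral radii are the \eqn{1/e^2}
#' radii of the detected brightness distributions; the effective detection
#' areas follow as \eqn{A_G = \pi \omega_G^2}, \eqn{A_R = \pi \omega_R^2}
#' and, for the cross-correlation volume,
#' \eqn{A_{GR} = \pi(\omega_G^2 + \omega_R^2)/2}.
#'
#' @param omega_g Lateral radius of the green detection area (nm).
#' @param omega_r Lateral radius of the red detection area (nm).
#' @param r0 Lateral displacement between the centers of the two foci (nm).
#'
#' @return An object of class `detection_geometry` with fields `omega_g`,
#'   `omega_r`, `r0` (nm) and derived areas `A_g`, `A_r`, `A_gr` (µm²).
#' @examples
#' geom <- detection_geometry(omega_g = 222, omega_r = 272, r0 = 120)
#' geom$A_g  # pi * 0.222^2
#' @export
detection_geometry <- function(omega_g = 222, omega_r = 272, r0 = 0) {
  stopifnot(omega_g > 0, omega_r > 0, r0 >= 0)
  wg <- omega_g / 1000  # µm
  wr <- omega_r / 1000
  g <- list(
    omega_g = omega_g, omega_r = omega_r, r0 = r0,
    A_g = pi * wg^2, A_r = pi * wr^2, A_gr = pi * (wg^2 + wr^2) / 2
  )
  stopifnot(g$A_gr >= min(g$A_g, g$A_r))
  structure(g, class = "detection_geometry")
}

#' Three-species membrane fluorescence model
#'
#' Parameterizes the population of fluorescent molecules diffusing in the
#' plasma membrane: a green-only species (g), a red-only species (r), and a
#' dual-labeled complex (gr) carrying one label of each color.  Surface
#' concentrations are in molecules/µm², diffusion coefficients in µm²/s and
#' molecular brightnesses in counts/s at the focus center.
#'
#' `x_g` and `x_r` are the absorption cross-section ratios of the g vs gr
#' and r vs gr species: 2 when the single-color species is itself a
#' homodimer carrying two labels, 1 when it is a monomer.  `K` is the
#' spectral crosstalk parameter, the brightness ratio with which green-label
#' emission is detected in the red channel.  `bg_g` and `bg_r` are channel
#' background count rates (counts/s).
#'
#' @param c_g,c_r,c_gr Surface concentrations (molecules/µm²).
#' @param D_g,D_r,D_gr Diffusion coefficients (µm²/s).
#' @param q_g,q_r Molecular brightness of one green / red label (counts/s).
#' @param x_g,x_r Absorption cross-section ratios, 1 or 2.
#' @param K Crosstalk parameter, in \[0, 1).
#' @param bg_g,bg_r Background count rates (counts/s).
#'
#' @return An object of class `species_model`.
#' @examples
#' species_model(c_g = 100, c_r = 0, c_gr = 0)
#' @export
species_model <- function(c_g = 0, c_r = 0, c_gr = 0,
                          D_g = 0.4, D_r = 0.4, D_gr = 0.25,
                          q_g = 3000, q_r = 3000,
                          x_g = 1, x_r = 1, K = 0,
                          bg_g = 0, bg_r = 0) {
  stopifnot(
    c_g >= 0, c_r >= 0, c_gr >= 0,
    D_g > 0, D_r > 0, D_gr > 0,
    q_g >= 0, q_r >= 0,
    x_g %in% c(1, 2), x_r %in% c(1, 2),
    K >= 0, K < 1, bg_g >= 0, bg_r >= 0
  )
  structure(
    list(c_g = c_g, c_r = c_r, c_gr = c_gr,
         D_g = D_g, D_r = D_r, D_gr = D_gr,
         q_g = q_g, q_r = q_r, x_g = x_g, x_r = x_r,
         K = K, bg_g = bg_g, bg_r = bg_r),
    class = "species_model"
  )
}

#' @export
print.detection_geometry <- function(x, ...) {
  cat(sprintf(
    "Detection geometry: omega_G = %g nm, omega_R = %g nm, r0 = %g nm\n",
    x$omega_g, x$omega_r, x$r0))
  cat(sprintf("  A_G = %.4f, A_R = %.4f, A_GR = %.4f um^2\n",
              x$A_g, x$A_r, x$A_gr))
  invisible(x)
}

#' @export
print.species_model <- function(x, ...) {
  cat("Three-species membrane model (molecules/um^2, um^2/s):\n")
  cat(sprintf("  g : c = %-8g D = %-6g x = %g\n", x$c_g, x$D_g, x$x_g))
  cat(sprintf("  r : c = %-8g D = %-6g x = %g\n", x$c_r, x$D_r, x$x_r))
  cat(sprintf("  gr: c = %-8g D = %-6g\n", x$c_gr, x$D_gr))
  cat(sprintf("  q_g = %g, q_r = %g counts/s; K = %g; BG = (%g, %g)\n",
              x$q_g, x$q_r, x$K, x$bg_g, x$bg_r))
  invisible(x)
}

#' Dissociation/re-association schedule for dynamic experiments
#'
#' Describes an agonist-induced transient loss of the dual-labeled complex:
#' the complex concentration stays at baseline until `t_stim`, falls
#' linearly to `f_min` times baseline at `t_min`, and returns linearly to
#' baseline at `t_recover`.
#'
#' @param t_stim Stimulation time (s).
#' @param f_min Minimum complex fraction reached, in \[0, 1\].
#' @param t_min Time of the minimum (s).
#' @param t_recover Time of return to baseline (s).
#' @return An object of class `dissociation_schedule`.
#' @examples
#' sched <- dissociation_schedule(t_stim = 0, f_min = 0.5,
#'                                t_min = 300, t_recover = 900)
#' dimer_fraction_at(sched, c(-60, 150, 300, 600, 1200))
#' @export
dissociation_schedule <- function(t_stim, f_min, t_min, t_recover) {
  stopifnot(f_min >= 0, f_min <= 1, t_stim < t_min, t_min < t_recover)
  structure(list(t_stim = t_stim, f_min = f_min, t_min = t_min,
                 t_recover = t_recover),
            class = "dissociation_schedule")
}

#' Complex fraction programmed by a schedule
#'
#' @param schedule A [dissociation_schedule()].
#' @param t Times (s) at which to evaluate the schedule.
#' @return Fraction of the baseline complex concentration at each time.
#' @export
dimer_fraction_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "dissociation_schedule"))
  s <- schedule
  f <- rep(1, length(t))
  down <- t > s$t_stim & t <= s$t_min
  up <- t > s$t_min & t < s$t_recover
  f[down] <- 1 - (1 - s$f_min) * (t[down] - s$t_stim) / (s$t_min - s$t_stim)
  f[up] <- s$f_min + (1 - s$f_min) * (t[up] - s$t_min) / (s$t_recover - s$t_min)
  f
}

#' Dimer pairing count
#'
#' Counts (or concentrations) of the three dimer classes in a two-color
#' labeling experiment: green–green, green–red and red–red.  The derived
#' totals `M = 2 c_gg + c_gr` and `N = 2 c_rr + c_gr` are the numbers of
#' green and red molecules.
#'
#' @param c_gg,c_gr,c_rr Non-negative counts or concentrations.
#' @return An object of class `pairing_count` with fields `c_gg`, `c_gr`,
#'   `c_rr`, `M`, `N`.
#' @examples
#' pairing_count(c_gg = 3, c_gr = 0, c_rr = 1)
#' @export
pairing_count <- function(c_gg = 0, c_gr = 0, c_rr = 0) {
  stopifnot(c_gg >= 0, c_gr >= 0, c_rr >= 0)
  structure(list(c_gg = c_gg, c_gr = c_gr, c_rr = c_rr,
                 M = 2 * c_gg + c_gr, N = 2 * c_rr + c_gr),
            class = "pairing_count")
}
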