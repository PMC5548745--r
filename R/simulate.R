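#' Simulate a two-channel membrane fluorescence fluctuation trace
#'
#' Brownian-dynamics generator of photon-count traces with the statistical
#' structure assumed by two-color membrane FCCS: three molecular species
#' (green-only, red-only, dual-labeled complex) diffuse on a periodic square
#' membrane patch and are detected through two laterally displaced Gaussian
#' detection areas (green focus at the patch center, red focus displaced by
#' `r0` along x).  Per sampling bin, the expected count in each channel is
#' the sum over particles of brightness times the detection-profile value at
#' the particle position; green-label emission additionally contributes
#' `K`-scaled counts to the red channel (spectral crosstalk).  Channel
#' backgrounds are added and photon counts drawn from a Poisson law.
#'
#' Particle numbers are Poisson-distributed around `concentration × box
#' area` and fixed for the duration of the trace (particles wrap around the
#' periodic boundary).  All randomness flows from `seed`; identical inputs
#' give bit-identical traces.
#'
#' @param model A [species_model()].
#' @param geom A [detection_geometry()].
#' @param duration Trace duration (s).
#' @param dt Sampling interval (s); default 0.5 ms.
#' @param box_size Side of the periodic membrane patch (µm); must be at
#'   least 10 detection radii.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param keep_positions If `TRUE`, also return per-bin particle positions
#'   and expected count rates (intended for small validation systems only).
#'
#' @return An object of class `intensity_trace`: fields `dt`, `duration`,
#'   `counts_green`, `counts_red` (integer counts per bin), `time`
#'   (bin start times) and `meta` (seed, generating model and geometry).
#'   With `keep_positions = TRUE`, a `detail` field holds expected rates and
#'   positions per species.
#' @examples
#' geom <- detection_geometry()
#' mod <- species_model(c_g = 50)
#' tr <- simulate_membrane_traces(mod, geom, duration = 0.5, seed = 1,
#'                                box_size = 3)
#' mean(tr$counts_green)
#' @export
simulate_membrane_traces <- function(model, geom, duration, dt = 5e-4,
                                     box_size = 3, seed = NULL,
                                     keep_positions = FALSE) {
  stopifnot(inherits(model, "species_model"),
            inherits(geom, "detection_geometry"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0)
    stop("duration and dt must be positive")
  n_bins <- round(duration / dt)
  if (n_bins < 2) stop("duration/dt must give at least 2 bins")
  w_max <- max(geom$omega_g, geom$omega_r) / 1000
  if (box_size < 10 * w_max)
    stop(sprintf("box_size (%g um) too small: need >= 10 detection radii (%g um)",
                 box_size, 10 * w_max))

  with_seed(seed, {
    area <- box_size^2
    n_g <- rpois(1, model$c_g * area)
    n_r <- rpois(1, model$c_r * area)
    n_gr <- rpois(1, model$c_gr * area)
    wg <- geom$omega_g / 1000
    wr <- geom$omega_r / 1000
    r0 <- geom$r0 / 1000

    # per-species brightness: x doubles the label count of the
    # single-color species (homodimer scenario)
    spec <- list(
      g  = list(n = n_g, D = model$D_g,
                qg = model$x_g * model$q_g, qr = 0,
                qx = model$K * model$x_g * model$q_g),
      r  = list(n = n_r, D = model$D_r,
                qg = 0, qr = model$x_r * model$q_r, qx = 0),
      gr = list(n = n_gr, D = model$D_gr,
                qg = model$q_g, qr = model$q_r,
                qx = model$K * model$q_g)
    )
    lam_g <- rep(0, n_bins)
    lam_r <- rep(0, n_bins)
    detail <- if (keep_positions) list() else NULL
    for (nm in names(spec)) {
      s <- spec[[nm]]
      out <- .sim_species_kernel(s$n, n_bins, dt, s$D, box_size,
                                 s$qg, s$qr, s$qx, wg, wr, r0,
                                 keep_positions)
      lam_g <- lam_g + out$lambda_green
      lam_r <- lam_r + out$lambda_red
      if (keep_positions) detail[[nm]] <- c(out, list(params = s))
    }
    lam_g <- lam_g + model$bg_g * dt
    lam_r <- lam_r + model$bg_r * dt
    counts_g <- rpois(n_bins, lam_g)
    counts_r <- rpois(n_bins, lam_r)

    structure(
      list(dt = dt, duration = n_bins * dt,
           time = (seq_len(n_bins) - 1) * dt,
           counts_green = counts_g, counts_red = counts_r,
           meta = list(seed = seed, model = model, geom = geom,
                       box_size = box_size,
                       n_particles = c(g = n_g, r = n_r, gr = n_gr)),
           detail = detail),
      class = "intensity_trace")
  })
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "Two-channel intensity trace: %d bins of %g ms (%.3g s)\n",
    length(x$counts_green), x$dt * 1000, x$duration))
  cat(sprintf("  mean rates: green %.3g kHz, red %.3g kHz\n",
              mean(x$counts_green) / x$dt / 1000,
              mean(x$counts_red) / x$dt / 1000))
  invisible(x)
}

#' Simulate a dynamic dissociation/re-association experiment
#'
#' Emulates a time-lapse FCCS protocol: at each measurement time point a
#' small batch of fluctuation traces is simulated from a cell whose
#' dual-labeled complex concentration follows a programmed transient
#' (see [dissociation_schedule()]).  Dissociated complexes are converted to
#' equal increments of the green-only and red-only concentrations, so the
#' total number of green and of red labels per unit area is conserved
#' exactly across the schedule.
#'
#' @param model Baseline [species_model()]; `c_gr` is the pre-stimulation
#'   complex concentration.
#' @param geom A [detection_geometry()].
#' @param schedule A [dissociation_schedule()].
#' @param time_points Measurement times (s); default spans the schedule
#'   from one pre-stimulation point through recovery.
#' @param segment_length Duration of each acquisition segment (s).
#' @param n_segments_per_point Number of segments per time point.
#' @param dt,box_size,seed Passed to [simulate_membrane_traces()].
#'
#' @return A list with one element per time point: `time` (s),
#'   `model_at` (the instantaneous [species_model()]) and `traces`
#'   (list of `intensity_trace` segments).
#' @export
simulate_dynamic_experiment <- function(model, geom, schedule,
                                        time_points = NULL,
                                        segment_length = 10,
                                        n_segments_per_point = 3,
                                        dt = 1e-3, box_size = 3,
                                        seed = NULL) {
  stopifnot(inherits(schedule, "dissociation_schedule"),
            n_segments_per_point >= 1)
  s <- schedule
  if (is.null(time_points)) {
    time_points <- c(
      s$t_stim - (s$t_min - s$t_stim),
      s$t_stim + (s$t_min - s$t_stim) * c(0.5, 1),
      s$t_min + (s$t_recover - s$t_min) * c(1 / 3, 2 / 3, 1),
      s$t_recover + (s$t_min - s$t_stim))
  }
  with_seed(seed, {
    lapply(time_points, function(tp) {
      f <- dimer_fraction_at(s, tp)
      delta <- (1 - f) * model$c_gr
      m_t <- model
      m_t$c_gr <- f * model$c_gr
      m_t$c_g <- model$c_g + delta
      m_t$c_r <- model$c_r + delta
      traces <- lapply(seq_len(n_segments_per_point), function(i) {
        simulate_membrane_traces(m_t, geom, duration = segment_length,
                                 dt = dt, box_size = box_size, seed = NULL)
      })
      list(time = tp, model_at = m_t, traces = traces)
    })
  })
}

#' Simulate a FRAP recovery record
#'
#' Generates one bleach-region intensity time series (together with a
#' reference region and a background region) following a two-phase
#' association recovery with a mobile and an immobile pool:
#' \deqn{I(t') = I_0 + F_m (I_I - I_0)\left[s(1 - e^{-k_1 t'}) +
#'   (1 - s)(1 - e^{-k_2 t'})\right]}
#' where \eqn{t'} is time since the bleach, \eqn{I_0 = I_I(1 -
#' \mathrm{bleach\_depth})}, and \eqn{F_m} is the mobile fraction.  A
#' whole-field acquisition-bleaching decay \eqn{e^{-\lambda t}} multiplies
#' the bleach and reference regions, and independent Gaussian noise is
#' added to every series.  The first post-bleach frame is sampled exactly
#' at \eqn{t' = 0}.
#'
#' @param F_m Mobile fraction, in \[0, 1\].
#' @param k_fast,k_slow Recovery rate constants (1/s), fast and slow phase.
#' @param amp_split Fraction of the mobile amplitude in the fast phase.
#' @param I_pre Pre-bleach region intensity (arbitrary units).
#' @param bleach_depth Fractional intensity loss at the bleach, in (0, 1].
#' @param noise_sd Gaussian noise standard deviation (same units as
#'   `I_pre`).
#' @param acq_bleach_rate Whole-field acquisition bleaching rate (1/s).
#' @param duration Total record length (s).
#' @param pre_bleach Pre-bleach acquisition span (s).
#' @param dt_frame Frame interval (s).
#' @param bg Background region intensity.
#' @param channel Label stored with the record (e.g. `"GFP"`).
#' @param condition Condition flag (e.g. `"crosslinked"`).
#' @param seed Integer seed.
#'
#' @return An object of class `frap_record` with fields `time`, `roi`,
#'   `reference`, `background`, `bleach_index`, `channel`, `condition`
#'   and `meta` (the generating parameters).
#' @examples
#' rec <- simulate_frap_record(F_m = 0.8, noise_sd = 0, seed = 1)
#' rec$roi[rec$bleach_index]  # post-bleach floor
#' @export
simulate_frap_record <- function(F_m, k_fast = 0.25, k_slow = 0.08,
                                 amp_split = 0.5, I_pre = 100,
                                 bleach_depth = 0.8, noise_sd = 0,
                                 acq_bleach_rate = 0, duration = 101,
                                 pre_bleach = 15, dt_frame = 0.5,
                                 bg = 5, channel = "GFP",
                                 condition = "none", seed = NULL) {
  stopifnot(F_m >= 0, F_m <= 1, bleach_depth > 0, bleach_depth <= 1,
            k_fast > 0, k_slow > 0, amp_split >= 0, amp_split <= 1,
            duration > pre_bleach, pre_bleach > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    time <- seq(0, duration, by = dt_frame)
    n <- length(time)
    bleach_index <- which(time >= pre_bleach)[1]
    tp <- time - time[bleach_index]           # time since bleach
    I0 <- I_pre * (1 - bleach_depth)
    roi <- ifelse(
      time < time[bleach_index], I_pre,
      I0 + F_m * (I_pre - I0) *
        (amp_split * (1 - exp(-k_fast * tp)) +
           (1 - amp_split) * (1 - exp(-k_slow * tp))))
    decay <- exp(-acq_bleach_rate * time)
    # measured intensities = decaying signal + constant background, so
    # background subtraction followed by the reference ratio cancels the
    # whole-field decay exactly
    roi <- roi * decay + bg
    reference <- I_pre * decay + bg
    background <- rep(bg, n)
    if (noise_sd > 0) {
      roi <- roi + rnorm(n, 0, noise_sd)
      reference <- reference + rnorm(n, 0, noise_sd)
      background <- background + rnorm(n, 0, noise_sd)
    }
    structure(
      list(time = time, roi = roi, reference = reference,
           background = background, bleach_index = bleach_index,
           channel = channel, condition = condition,
           meta = list(F_m = F_m, k_fast = k_fast, k_slow = k_slow,
                       amp_split = amp_split, I_pre = I_pre,
                       bleach_depth = bleach_depth, noise_sd = noise_sd,
                       acq_bleach_rate = acq_bleach_rate, bg = bg,
                       seed = seed)),
      class = "frap_record")
  })
}

#' Expected mixed-pair fraction under random pairing (exact)
#'
#' Computes the expected fraction of mixed (green–red) pairs when `M` green
#' and `N` red molecules assemble into dimers uniformly at random.  For
#' small totals the result is obtained by exhaustive enumeration of all
#' perfect pairings; for larger totals the exact closed form
#' \eqn{2MN / ((M+N)(M+N-1))} is used (the two agree identically).
#'
#' @param M,N Non-negative integer molecule counts; `M + N` must be even
#'   and at least 2.
#' @param method `"auto"` (enumerate when `M + N <= 12`), `"enumerate"`,
#'   or `"closed_form"`.
#' @return Expected fraction of mixed pairs.
#' @examples
#' enumerate_pairings(2, 2)   # 2/3
#' enumerate_pairings(6, 2)   # 24/56
#' @export
enumerate_pairings <- function(M, N, method = c("auto", "enumerate",
                                                "closed_form")) {
  method <- match.arg(method)
  stopifnot(M >= 0, N >= 0, M == round(M), N == round(N))
  tot <- M + N
  if (tot < 2 || tot %% 2 != 0)
    stop("M + N must be even and at least 2")
  if (method == "auto")
    method <- if (tot <= 12) "enumerate" else "closed_form"
  if (method == "closed_form")
    return(2 * M * N / (tot * (tot - 1)))

  # exhaustive: count pairings and total mixed pairs by recursion --
  # pair the first unpaired molecule with each remaining partner
  count_pairings <- function(labels) {
    n <- length(labels)
    if (n == 0) return(c(pairings = 1, mixed = 0))
    acc <- c(pairings = 0, mixed = 0)
    for (j in 2:n) {
      sub <- count_pairings(labels[-c(1, j)])
      acc["pairings"] <- acc["pairings"] + sub["pairings"]
      acc["mixed"] <- acc["mixed"] + sub["mixed"] +
        (labels[1] != labels[j]) * sub["pairings"]
    }
    acc
  }
  res <- count_pairings(c(rep(TRUE, M), rep(FALSE, N)))
  unname(res["mixed"] / (res["pairings"] * tot / 2))
}
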