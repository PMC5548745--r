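#' @title Multiple-tau correlation estimation
#' @description Internal core shared by [autocorrelate()] and
#'   [crosscorrelate()].  Computes the symmetric-normalization estimate
#'   \deqn{\hat G(k) - 1 = \frac{\langle x(t)\,y(t+k)\rangle}
#'     {\langle x(t)\rangle_k \langle y(t+k)\rangle_k} - 1}
#'   where the means in the denominator run over the same overlap window as
#'   the numerator (symmetric normalization).  Lags 1..m are evaluated at
#'   the native resolution; the trace is then repeatedly coarsened by
#'   averaging adjacent bins and lags m/2+1..m evaluated at each level, the
#'   standard multiple-tau scheme.  With `m >= length(x)` no coarsening
#'   occurs and every lag equals the direct quadratic-time sum exactly.
#' @noRd
.multiple_tau <- function(x, y, dt, m = 16, max_lag = NULL,
                          mean_x = NULL, mean_y = NULL) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n, m >= 2, m %% 2 == 0)
  if (is.null(max_lag)) max_lag <- n * dt / 2
  if (max_lag > n * dt / 2) stop("max_lag exceeds half the trace duration")

  lag_s <- numeric(0); vals <- numeric(0); npairs <- integer(0)
  bw <- dt
  xl <- x; yl <- y
  level <- 0L
  repeat {
    ks <- if (level == 0L) seq_len(min(m, length(xl) - 2)) else
      seq.int(m / 2 + 1, m)
    ks <- ks[ks <= length(xl) - 2 & ks * bw <= max_lag]
    if (length(ks)) {
      s <- .lag_sums_kernel(xl, yl, as.integer(ks))
      g <- if (is.null(mean_x))
        (s$sxy / s$n) / ((s$sx / s$n) * (s$sy / s$n)) - 1
      else (s$sxy / s$n) / (mean_x * mean_y) - 1
      lag_s <- c(lag_s, ks * bw)
      vals <- c(vals, g)
      npairs <- c(npairs, s$n)
    }
    # coarsen by 2 until the next level has no admissible lags
    if (length(xl) < 2 * (m + 2) || m / 2 * 2 * bw > max_lag) break
    n2 <- floor(length(xl) / 2)
    idx <- seq_len(n2) * 2L
    xl <- (xl[idx - 1L] + xl[idx]) / 2
    yl <- (yl[idx - 1L] + yl[idx]) / 2
    bw <- 2 * bw
    level <- level + 1L
  }
  list(lags = lag_s, values = vals, n_samples = npairs)
}

.new_curve <- function(pair, lags, values, n_samples, sd = NULL,
                       meta = list()) {
  stopifnot(all(diff(lags) > 0), all(lags > 0), all(is.finite(values)))
  structure(list(pair = pair, lags = lags, values = values,
                 n_samples = n_samples, sd = sd, meta = meta),
            class = "correlation_curve")
}

#' Autocorrelation curve of one channel of a fluctuation trace
#'
#' Multiple-tau estimate of \eqn{G(\tau) - 1 =
#' \langle\delta F(t)\,\delta F(t+\tau)\rangle / \langle F\rangle^2} with
#' symmetric normalization.  The zero-lag bin (shot-noise dominated) is
#' never reported; lags start at one sampling interval.
#'
#' @param trace An `intensity_trace`.
#' @param channel `"G"` or `"R"`.
#' @param m Points per octave of the multiple-tau scheme (default 16).
#'   Setting `m >=` the number of bins disables coarsening, in which case
#'   every reported lag equals the direct quadratic-time estimate.
#' @param max_lag Largest lag to evaluate (s); at most half the trace.
#' @param mean_value Optional externally supplied mean count per bin used
#'   for normalization instead of the per-window means.  When a
#'   measurement is split into short segments, normalizing each segment
#'   curve by the global mean over all kept segments avoids the
#'   \eqn{O(1/T)} normalization bias of per-segment means (used by
#'   [fccs_curves()]).
#' @return A `correlation_curve` with fields `pair` (`"GG"` or `"RR"`),
#'   `lags` (s), `values` (\eqn{G(\tau)-1}) and `n_samples` per lag.
#' @examples
#' tr <- simulate_membrane_traces(species_model(c_g = 50),
#'   detection_geometry(), duration = 1, seed = 1, box_size = 3)
#' ac <- autocorrelate(tr, "G")
#' @export
autocorrelate <- function(trace, channel = c("G", "R"), m = 16,
                          max_lag = NULL, mean_value = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(trace, "intensity_trace"))
  x <- if (channel == "G") trace$counts_green else trace$counts_red
  if (length(x) == 0) stop("empty trace")
  if (all(x == 0))
    stop("all-zero trace: correlation normalization undefined")
  out <- .multiple_tau(as.numeric(x), as.numeric(x), trace$dt, m = m,
                       max_lag = max_lag, mean_x = mean_value,
                       mean_y = mean_value)
  .new_curve(if (channel == "G") "GG" else "RR",
             out$lags, out$values, out$n_samples,
             meta = list(total_time = trace$duration, m = m))
}

#' Cross-correlation curve between the two channels of a trace
#'
#' As [autocorrelate()], with numerator
#' \eqn{\langle\delta F_G(t)\,\delta F_R(t+\tau)\rangle} and normalization
#' \eqn{\langle F_G\rangle \langle F_R\rangle}.
#'
#' @inheritParams autocorrelate
#' @param mean_green,mean_red Optional externally supplied channel means
#'   (see `mean_value` in [autocorrelate()]).
#' @return A `correlation_curve` with `pair = "GR"`.
#' @export
crosscorrelate <- function(trace, m = 16, max_lag = NULL,
                           mean_green = NULL, mean_red = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- as.numeric(trace$counts_green)
  y <- as.numeric(trace$counts_red)
  if (length(x) == 0) stop("empty trace")
  if (all(x == 0) || all(y == 0))
    stop("all-zero channel: correlation normalization undefined")
  out <- .multiple_tau(x, y, trace$dt, m = m, max_lag = max_lag,
                       mean_x = mean_green, mean_y = mean_red)
  .new_curve("GR", out$lags, out$values, out$n_samples,
             meta = list(total_time = trace$duration, m = m))
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve %s: %d lags, %.3g ms .. %.3g s\n",
              x$pair, length(x$lags), min(x$lags) * 1000, max(x$lags)))
  cat(sprintf("  G(tau_min)-1 = %.4g\n", x$values[1]))
  invisible(x)
}

#' Average correlation curves across acquisition segments
#'
#' @param curves List of `correlation_curve` objects sharing the same lag
#'   grid (e.g. one per kept 10-s segment).
#' @return A single `correlation_curve` with per-lag mean, standard
#'   deviation across segments (`sd`, `NULL` if fewer than 2 curves) and
#'   summed sample counts.
#' @export
average_correlations <- function(curves) {
  stopifnot(length(curves) >= 1)
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (!isTRUE(all.equal(cv$lags, lags)))
      stop("curves have differing lag grids")
  vals <- vapply(curves, function(cv) cv$values, numeric(length(lags)))
  vals <- matrix(vals, nrow = length(lags))
  m <- rowMeans(vals)
  s <- if (ncol(vals) >= 2) apply(vals, 1, sd) else NULL
  ns <- Reduce(`+`, lapply(curves, function(cv) cv$n_samples))
  .new_curve(curves[[1]]$pair, lags, m, ns, sd = s,
             meta = list(n_segments = length(curves),
                         total_time = sum(vapply(curves, function(cv)
                           cv$meta$total_time %||% NA_real_, 1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen acquisition segments before correlation
#'
#' Splits a trace into fixed-length segments and flags segments whose
#' fluorescence behaves abnormally: intensity spikes (a bin exceeding the
#' segment mean by `spike_z` standard deviations, typical of aggregates),
#' monotone decay (a fitted relative intensity loss over the segment larger
#' than `decay_slope`, typical of membrane movements), or low molecular
#' brightness (below `min_cpm` kHz per molecule, evaluated only when a
#' molecule-number estimate is supplied).  A trailing partial segment is
#' dropped.
#'
#' @param trace An `intensity_trace`.
#' @param segment_length Segment duration (s), default 10.
#' @param spike_z Spike threshold in within-segment standard deviations.
#' @param decay_slope Maximum tolerated fractional decay per segment.
#' @param min_cpm Minimum molecular brightness (kHz per molecule).
#' @param n_molecules Optional length-2 vector (green, red) of fluorescent
#'   molecule numbers in the detection area, used for the brightness
#'   screen.
#' @return An object of class `segment_screen`: a data frame of per-segment
#'   verdicts with reason codes, plus attributes `included_time` (s) and
#'   `kept` (indices of kept segments).
#' @export
screen_segments <- function(trace, segment_length = 10, spike_z = 8,
                            decay_slope = 0.3, min_cpm = 0.2,
                            n_molecules = NULL) {
  stopifnot(inherits(trace, "intensity_trace"), segment_length > 0)
  bins_per <- round(segment_length / trace$dt)
  n_seg <- floor(length(trace$counts_green) / bins_per)
  if (n_seg < 1) stop("trace shorter than one segment")
  res <- lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * bins_per + 1):(i * bins_per)
    reasons <- character(0)
    for (ch in c("G", "R")) {
      v <- as.numeric(
        if (ch == "G") trace$counts_green[idx] else trace$counts_red[idx])
      mu <- mean(v); sdv <- sd(v)
      if (sdv > 0 && max(v) > mu + spike_z * sdv)
        reasons <- union(reasons, "spike")
      if (mu > 0) {
        tt <- seq_along(v) * trace$dt
        sl <- coef(lm(v ~ tt))[2]
        if (sl * segment_length / mu < -decay_slope)
          reasons <- union(reasons, "decay")
        if (!is.null(n_molecules)) {
          nm <- n_molecules[if (ch == "G") 1 else min(2, length(n_molecules))]
          cpm_khz <- (mu / trace$dt) / nm / 1000
          if (cpm_khz <= min_cpm)
            reasons <- union(reasons, "low_brightness")
        }
      }
    }
    data.frame(segment = i, kept = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, res)
  structure(rep_df, class = c("segment_screen", "data.frame"),
            included_time = sum(rep_df$kept) * segment_length,
            segment_length = segment_length,
            kept = rep_df$segment[rep_df$kept])
}

#' Segment-screened correlation curves for one FCCS measurement
#'
#' Splits the trace into segments, applies [screen_segments()], correlates
#' each kept segment (GG and RR autocorrelations, GR cross-correlation) and
#' averages the per-segment curves.  The per-lag standard deviation across
#' segments is retained for weighting in the model fits.
#'
#' @inheritParams screen_segments
#' @param m Multiple-tau points per octave.
#' @param max_lag Largest lag (s); default half a segment.
#' @param screen If `FALSE`, keep every segment.
#' @param normalization `"global"` (default) normalizes every segment
#'   curve by the mean count rates over all kept segments, which keeps the
#'   small-amplitude cross-correlation free of the \eqn{O(1/T)} bias that
#'   per-segment means introduce; `"segment"` uses the per-segment
#'   symmetric normalization.
#' @return List with elements `GG`, `RR`, `GR` (`correlation_curve`),
#'   `screen` (the `segment_screen` report) and `included_time` (s).
#' @export
fccs_curves <- function(trace, segment_length = 10, m = 16, max_lag = NULL,
                        screen = TRUE, spike_z = 8, decay_slope = 0.3,
                        min_cpm = 0.2, n_molecules = NULL,
                        normalization = c("global", "segment")) {
  normalization <- match.arg(normalization)
  rep <- screen_segments(trace, segment_length, spike_z, decay_slope,
                         min_cpm, n_molecules)
  kept <- if (screen) attr(rep, "kept") else rep$segment
  if (length(kept) == 0) {
    return(list(GG = NULL, RR = NULL, GR = NULL, screen = rep,
                included_time = 0))
  }
  bins_per <- round(segment_length / trace$dt)
  if (is.null(max_lag)) max_lag <- segment_length / 2
  sub_trace <- function(i) {
    idx <- ((i - 1) * bins_per + 1):(i * bins_per)
    structure(list(dt = trace$dt, duration = segment_length,
                   time = trace$time[idx],
                   counts_green = trace$counts_green[idx],
                   counts_red = trace$counts_red[idx]),
              class = "intensity_trace")
  }
  subs <- lapply(kept, sub_trace)
  mg <- mr <- NULL
  if (normalization == "global") {
    mg <- mean(unlist(lapply(subs, `[[`, "counts_green")))
    mr <- mean(unlist(lapply(subs, `[[`, "counts_red")))
  }
  # a channel that recorded nothing yields no curves for its pairs
  # (single-color measurements are legitimate)
  green_on <- any(trace$counts_green > 0)
  red_on <- any(trace$counts_red > 0)
  gg <- if (green_on)
    average_correlations(lapply(subs, autocorrelate, channel = "G",
                                m = m, max_lag = max_lag,
                                mean_value = mg))
  rr <- if (red_on)
    average_correlations(lapply(subs, autocorrelate, channel = "R",
                                m = m, max_lag = max_lag,
                                mean_value = mr))
  gr <- if (green_on && red_on)
    average_correlations(lapply(subs, crosscorrelate, m = m,
                                max_lag = max_lag, mean_green = mg,
                                mean_red = mr))
  list(GG = gg, RR = rr, GR = gr, screen = rep,
       included_time = attr(rep, "included_time"))
}
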