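# Plain-text interchange: tab-separated tables with JSON sidecars carrying
# acquisition metadata.  Round-trips preserve values up to the documented
# float formatting (15 significant digits).

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".json")

#' Write / read a two-channel intensity trace
#'
#' Traces are stored as a TSV with columns `time_s`, `counts_green`,
#' `counts_red` plus a JSON sidecar (same basename, `.json`) holding `dt`,
#' `duration`, `seed` and the generating parameters when the trace is
#' synthetic.
#'
#' @param trace An `intensity_trace`.
#' @param path Path of the `.tsv` file to write.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   `intensity_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  df <- data.frame(time_s = format(trace$time, digits = 15),
                   counts_green = trace$counts_green,
                   counts_red = trace$counts_red)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dt = trace$dt, duration = trace$duration,
               seed = trace$meta$seed)
  if (!is.null(trace$meta$model)) meta$model <- unclass(trace$meta$model)
  if (!is.null(trace$meta$geom))
    meta$geom <- unclass(trace$meta$geom)[c("omega_g", "omega_r", "r0")]
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @param path Path of the `.tsv` file to read.
#' @export
read_trace <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_s", "counts_green", "counts_red")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trace file missing column(s): ", paste(missing, collapse = ", "))
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column in ", path)
  if (any(df$counts_green < 0) || any(df$counts_red < 0))
    stop("negative counts in ", path)
  sc <- .sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc,
    simplifyVector = TRUE) else list()
  dt <- meta$dt %||% stats::median(diff(df$time_s))
  structure(list(dt = dt, duration = length(df$time_s) * dt,
                 time = df$time_s,
                 counts_green = as.integer(df$counts_green),
                 counts_red = as.integer(df$counts_red),
                 meta = list(seed = meta$seed,
                             model = if (!is.null(meta$model))
                               do.call(species_model, meta$model),
                             geom = if (!is.null(meta$geom))
                               do.call(detection_geometry, meta$geom))),
            class = "intensity_trace")
}

#' Write / read a correlation curve
#'
#' Curves are stored as a TSV with columns `lag_s`, `G_minus_1`, `pair`,
#' `n_samples` plus a JSON sidecar with segment metadata and per-lag
#' standard deviations when available.
#'
#' @param curve A `correlation_curve`.
#' @param path Path of the `.tsv` file.
#' @return `write_curve` returns `path` invisibly; `read_curve` a
#'   `correlation_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = format(curve$lags, digits = 15),
                   G_minus_1 = format(curve$values, digits = 15),
                   pair = curve$pair, n_samples = curve$n_samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(meta = curve$meta, sd = curve$sd),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("lag_s", "G_minus_1", "pair")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("curve file missing column(s): ", paste(missing, collapse = ", "))
  pair <- unique(df$pair)
  if (length(pair) != 1 || !pair %in% c("GG", "RR", "GR"))
    stop("curve file must carry a single pair label among GG/RR/GR")
  sc <- .sidecar_path(path)
  side <- if (file.exists(sc)) jsonlite::read_json(sc,
    simplifyVector = TRUE) else list()
  .new_curve(pair, df$lag_s, df$G_minus_1,
             df$n_samples %||% rep(NA_integer_, nrow(df)),
             sd = side$sd, meta = as.list(side$meta))
}

#' Write / read a FRAP record
#'
#' Records are stored as a TSV with columns `time_s`, `roi`, `reference`,
#' `background` plus a JSON sidecar with `bleach_time_s`, `channel` and
#' `condition`.
#'
#' @param record A `frap_record`.
#' @param path Path of the `.tsv` file.
#' @return `write_frap` returns `path` invisibly; `read_frap` a
#'   `frap_record`.
#' @export
write_frap <- function(record, path) {
  stopifnot(inherits(record, "frap_record"))
  df <- data.frame(time_s = format(record$time, digits = 15),
                   roi = format(record$roi, digits = 15),
                   reference = format(record$reference, digits = 15),
                   background = format(record$background, digits = 15))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(bleach_time_s = record$time[record$bleach_index],
         channel = record$channel, condition = record$condition,
         meta = record$meta),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frap
#' @export
read_frap <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_s", "roi", "reference", "background")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("FRAP file missing column(s): ", paste(missing, collapse = ", "))
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column in ", path)
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  bleach_index <- which(df$time_s >= side$bleach_time_s)[1]
  if (is.na(bleach_index) || bleach_index < 2)
    stop("bleach time outside the record or no pre-bleach frames")
  structure(list(time = df$time_s, roi = df$roi,
                 reference = df$reference, background = df$background,
                 bleach_index = bleach_index,
                 channel = side$channel %||% NA_character_,
                 condition = side$condition %||% NA_character_,
                 meta = as.list(side$meta)),
            class = "frap_record")
}
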