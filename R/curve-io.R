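#' Read a surrogate breathing-curve log
#'
#' Three plain-text dialects are supported:
#'
#' * `csv` — the package's native format: header `time_s,amplitude_mm,xray_on`,
#'   one sample per row, `xray_on` coded 0/1.
#' * `vxp_like` — a gating-log dialect: header lines of the form
#'   `key=value` (notably `amplitude_units=cm` or `mm`), followed by
#'   comma-separated data rows
#'   `amplitude,phase,timestamp_ms,valid_flag,ttl_in,mark`. Only amplitude,
#'   timestamp and `ttl_in` (the beam-status pulse) are consumed;
#'   amplitudes declared in cm are converted to mm.
#' * `tracker_log` — a multi-tool optical tracker export with rows
#'   `time_s,tool,displacement_mm`. A single-tool file is read as a curve;
#'   files with several tools must be read with [read_multitool()].
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"vxp_like"`, `"tracker_log"`.
#' @param system_label label for the curve; defaults to the file name.
#' @return A [breathing_curve()].
#' @export
read_curve <- function(path, dialect = c("csv", "vxp_like", "tracker_log"),
                       system_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  label <- system_label %||% basename(path)
  switch(dialect,
         csv = read_curve_csv(path, label),
         vxp_like = read_curve_vxp(path, label),
         tracker_log = {
           curves <- read_multitool(path)
           if (length(curves) > 1)
             stop("tracker log contains ", length(curves),
                  " tools; use read_multitool()", call. = FALSE)
           c0 <- curves[[1]]
           c0$system_label <- label
           c0
         })
}

read_curve_csv <- function(path, label) {
  df <- utils::read.csv(path)
  need <- c("time_s", "amplitude_mm", "xray_on")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("CSV curve file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("non-monotone timestamps in ", path, call. = FALSE)
  breathing_curve(df$time_s, df$amplitude_mm, xray_on = df$xray_on != 0,
                  system_label = label, strict_grid = FALSE)
}

read_curve_vxp <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_header <- grepl("=", lines, fixed = TRUE)
  header <- lines[is_header]
  keys <- sub("=.*$", "", header)
  vals <- sub("^[^=]*=", "", header)
  hdr <- stats::setNames(as.list(vals), tolower(trimws(keys)))
  data_lines <- lines[!is_header]
  if (length(data_lines) == 0) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || ncol < 5)
    stop("vxp_like data rows need the comma-separated fields ",
         "amplitude, phase, timestamp_ms, valid, ttl_in[, mark]", call. = FALSE)
  m <- do.call(rbind, fields)
  num <- function(x) suppressWarnings(as.numeric(x))  # NAs flagged below
  amp <- num(m[, 1])
  ts_ms <- num(m[, 3])
  ttl <- num(m[, 5])
  if (anyNA(amp) || anyNA(ts_ms))
    stop("non-numeric amplitude or timestamp in ", path, call. = FALSE)
  if (anyNA(ttl))
    stop("missing or non-numeric beam-status column 'ttl_in' in ", path,
         call. = FALSE)
  if (is.unsorted(ts_ms, strictly = TRUE))
    stop("non-monotone timestamps in ", path, call. = FALSE)
  units <- tolower(hdr[["amplitude_units"]] %||% "mm")
  if (units == "cm") amp <- amp * 10
  breathing_curve(ts_ms / 1000, amp, xray_on = ttl != 0, system_label = label,
                  strict_grid = FALSE)
}

#' Read a multi-tool tracker log
#'
#' @param path file with rows `time_s,tool,displacement_mm` (header
#'   optional) as exported from a multi-tool optical tracker; typically one
#'   tool on the phantom and one on the couch.
#' @return A named list of [breathing_curve()]s, one per tool.
#' @export
read_multitool <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("time", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("time_s", "tool", "displacement_mm"))
  df$time_s <- as.numeric(df$time_s)
  df$displacement_mm <- as.numeric(df$displacement_mm)
  if (anyNA(df$time_s) || anyNA(df$displacement_mm))
    stop("non-numeric fields in tracker log ", path, call. = FALSE)
  split_df <- split(df, df$tool)
  lapply(split_df, function(d) {
    if (is.unsorted(d$time_s, strictly = TRUE))
      stop("non-monotone timestamps for tool ", d$tool[1], call. = FALSE)
    breathing_curve(d$time_s, d$displacement_mm,
                    system_label = as.character(d$tool[1]), strict_grid = FALSE)
  })
}

#' Write a breathing curve as CSV
#'
#' Columns `time_s, amplitude_mm, xray_on` (0/1), header row, '.' decimal
#' separator, UTF-8. The round trip through [read_curve()] is lossless to
#' full double precision.
#'
#' @param curve a [breathing_curve()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "breathing_curve"))
  df <- as.data.frame(curve)
  # full precision so that write -> read is lossless
  df$time_s <- format(df$time_s, digits = 17, trim = TRUE, scientific = FALSE)
  df$amplitude_mm <- format(df$amplitude_mm, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Resample a curve onto a uniform grid
#'
#' Amplitudes are linearly interpolated onto a uniform grid of spacing `dt`
#' spanning the curve's time range; the X-ray status channel is resampled
#' by nearest neighbour. A curve already on the target grid is returned
#' unchanged.
#'
#' @param curve a [breathing_curve()] with at least 2 samples.
#' @param dt target spacing in seconds (default 0.020, the standard
#'   analysis grid).
#' @return A [breathing_curve()] on the new grid.
#' @export
resample_curve <- function(curve, dt = 0.020) {
  stopifnot(inherits(curve, "breathing_curve"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  t0 <- curve$t[1]
  t1 <- curve$t[length(curve$t)]
  grid <- seq(t0, t1, by = dt)
  if (length(grid) == length(curve$t) &&
      max(abs(grid - curve$t)) < 1e-9) return(curve)
  amp <- interp_lin(curve$t, curve$amp, grid)
  xr <- interp_nn(curve$t, curve$xray_on, grid)
  breathing_curve(grid, amp, xray_on = xr, system_label = curve$system_label,
                  units_normalized = curve$units_normalized)
}

#' Bundle of curves from several surrogate systems
#'
#' @param ... named [breathing_curve()]s, or a single named list of them.
#' @param aligned,normalized bookkeeping flags set by [align_and_trim()]
#'   and [normalize_amplitude()].
#' @return A `curve_bundle` object.
#' @export
curve_bundle <- function(..., aligned = FALSE, normalized = FALSE) {
  curves <- list(...)
  if (length(curves) == 1 && !inherits(curves[[1]], "breathing_curve"))
    curves <- curves[[1]]
  if (length(curves) == 0) stop("empty bundle", call. = FALSE)
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    names(curves) <- vapply(curves, function(x) x$system_label, character(1))
  lapply(curves, function(x) stopifnot(inherits(x, "breathing_curve")))
  structure(list(curves = curves, aligned = aligned, normalized = normalized),
            class = "curve_bundle")
}

#' @export
print.curve_bundle <- function(x, ...) {
  cat(sprintf("<curve_bundle> %d curve(s): %s\n", length(x$curves),
              paste(names(x$curves), collapse = ", ")))
  cat(sprintf("  aligned: %s, normalized: %s\n", x$aligned, x$normalized))
  invisible(x)
}

#' Align curves by their first X-ray-on edge and trim to a common window
#'
#' Each curve is time-shifted so that its first X-ray-on rising edge sits
#' at t = 0, then all curves are cropped to the maximal common time window
#' and resampled onto one shared grid. Signal before t = 0 (the training
#' period) is kept wherever all systems cover it.
#'
#' @param bundle a [curve_bundle()] (or named list of curves) in which
#'   every curve has at least one X-ray-on rising edge.
#' @param dt shared grid spacing, seconds.
#' @return An aligned `curve_bundle`.
#' @export
align_and_trim <- function(bundle, dt = 0.020) {
  if (!inherits(bundle, "curve_bundle")) bundle <- curve_bundle(bundle)
  shifted <- lapply(bundle$curves, function(cv) {
    edge <- first_rising_edge(cv)
    if (is.na(edge))
      stop("curve '", cv$system_label, "' has no X-ray-on edge", call. = FALSE)
    cv$t <- cv$t - edge
    cv
  })
  starts <- vapply(shifted, function(cv) cv$t[1], numeric(1))
  ends <- vapply(shifted, function(cv) cv$t[length(cv$t)], numeric(1))
  lo <- max(starts)
  hi <- min(ends)
  if (hi - lo < dt)
    stop("curves share no common time window after alignment", call. = FALSE)
  grid <- seq(ceiling(lo / dt - 1e-9) * dt, hi + 1e-9, by = dt)
  grid <- grid[grid <= hi + 1e-9]
  out <- lapply(shifted, function(cv) {
    amp <- interp_lin(cv$t, cv$amp, grid)
    xr <- interp_nn(cv$t, cv$xray_on, grid)
    breathing_curve(grid, amp, xray_on = xr, system_label = cv$system_label,
                    units_normalized = cv$units_normalized)
  })
  curve_bundle(out, aligned = TRUE, normalized = bundle$normalized)
}

#' Normalize a curve to its reference cycle
#'
#' Shifts and scales the amplitude so that the first local minimum after
#' the first X-ray-on has value 0 and the immediately following local
#' maximum has value 1. Any affine convention is admissible for
#' relative-amplitude processing as long as it is applied uniformly; this
#' one pins the reference exhale/inhale pair right after irradiation
#' starts. Idempotent and invariant under affine transformations of the
#' input.
#'
#' @param curve an aligned [breathing_curve()]; when the curve carries no
#'   X-ray status, t = 0 is used as the reference point.
#' @param min_prom_frac prominence fraction (of the global range) below
#'   which extrema are ignored.
#' @return The normalized curve (`units_normalized = TRUE`).
#' @export
normalize_amplitude <- function(curve, min_prom_frac = 0.2) {
  stopifnot(inherits(curve, "breathing_curve"))
  t0 <- first_rising_edge(curve)
  if (is.na(t0)) t0 <- 0
  ext <- significant_extrema(curve$amp,
                             min_prom_frac * diff(range(curve$amp)))
  if (nrow(ext) == 0)
    stop("no local extrema found; cannot normalize", call. = FALSE)
  ext$time <- curve$t[ext$index]
  mins <- ext[ext$type == "valley" & ext$time >= t0 - 1e-9, , drop = FALSE]
  if (nrow(mins) == 0)
    stop("no local minimum after the first X-ray-on", call. = FALSE)
  m_idx <- mins$index[1]
  maxs <- ext[ext$type == "peak" & ext$index > m_idx, , drop = FALSE]
  if (nrow(maxs) == 0)
    stop("no local maximum following the reference minimum", call. = FALSE)
  m <- curve$amp[m_idx]
  M <- curve$amp[maxs$index[1]]
  if (M - m <= 0) stop("degenerate reference cycle (max <= min)", call. = FALSE)
  curve$amp <- (curve$amp - m) / (M - m)
  curve$units_normalized <- TRUE
  curve
}
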