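# Device-log ingestion and preprocessing.
#
# Two CSV dialects are supported: a wrist-temperature log (thermochron-style,
# ~10-min cadence) and a tilt log (pendant-accelerometer-style, ~30-s
# cadence). Both carry a comment/header block followed by a column-header
# row, then data rows. Motor activity is derived from the tilt channel as
# the rate of angle change in degrees per minute; body position is the tilt
# angle itself (X-axis to horizontal plane).

.TS_FMT <- "%Y-%m-%d %H:%M:%S"

parse_dt <- function(x) as.POSIXct(x, format = .TS_FMT, tz = "UTC")

read_device_csv <- function(path, header_row, value_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- which(lines == header_row)
  if (length(hdr) == 0)
    stop("format error: header row '", header_row, "' not found in ", path)
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  ncol_exp <- 1 + length(value_cols)
  ok_shape <- lengths(parts) == ncol_exp
  dt <- .POSIXct(rep(NA_real_, length(body)), tz = "UTC")
  vals <- matrix(NA_real_, length(body), length(value_cols))
  if (any(ok_shape)) {
    m <- do.call(rbind, parts[ok_shape])
    dt[ok_shape] <- parse_dt(m[, 1])
    for (j in seq_along(value_cols))
      vals[ok_shape, j] <- suppressWarnings(as.numeric(m[, j + 1]))
  }
  ok <- !is.na(dt) & rowSums(is.na(vals)) == 0
  n_skip <- sum(!ok)
  if (sum(ok) == 0) stop("format error: no parseable data rows in ", path)
  if (n_skip > 0)
    message("read_device_csv: skipped ", n_skip, " malformed row(s) in ",
            basename(path))
  out <- data.frame(datetime = dt[ok])
  for (j in seq_along(value_cols)) out[[value_cols[j]]] <- vals[ok, j]
  o <- order(out$datetime)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  out
}

#' Read a wrist-temperature log
#'
#' Expects a header block, a `datetime,temperature_C` column row, then data
#' rows. Malformed rows are counted, reported via [message()], and skipped.
#'
#' @param path path to the CSV file.
#' @return data.frame with `datetime` (POSIXct) and `temp_c`, ordered by
#'   time; attribute `n_skipped` counts dropped rows.
#' @export
read_wt_log <- function(path) {
  out <- read_device_csv(path, "datetime,temperature_C", "temp_c")
  out
}

#' Read a tilt-angle log
#'
#' Expects `datetime,angle_deg` rows (angle between the accelerometer X-axis
#' and the horizontal plane). Angles are clamped to \[0, 90\] degrees.
#'
#' @param path path to the CSV file.
#' @return data.frame with `datetime` and `angle_deg`.
#' @export
read_tilt_log <- function(path) {
  out <- read_device_csv(path, "datetime,angle_deg", "angle_deg")
  out$angle_deg <- pmin(pmax(out$angle_deg, 0), 90)
  out
}

#' Read a 3-axis acceleration log and convert to tilt angle
#'
#' For `datetime,ax,ay,az` rows (static gravity components in device units),
#' the tilt angle of the X-axis with respect to the horizontal plane is
#' `asin(|ax| / sqrt(ax^2+ay^2+az^2))` in degrees.
#'
#' @param path path to the CSV file.
#' @return data.frame with `datetime` and `angle_deg` in \[0, 90\].
#' @export
read_tilt_xyz_log <- function(path) {
  out <- read_device_csv(path, "datetime,ax,ay,az", c("ax", "ay", "az"))
  norm <- sqrt(out$ax^2 + out$ay^2 + out$az^2)
  if (any(norm == 0)) stop("zero acceleration vector in ", path)
  ang <- asin(pmin(abs(out$ax) / norm, 1)) * 180 / pi
  data.frame(datetime = out$datetime, angle_deg = ang)
}

#' Write a wrist-temperature log
#'
#' @param samples data.frame with `datetime`, `temp_c`.
#' @param path output path.
#' @param subject_id identifier written into the header block.
#' @return invisibly, `path`.
#' @export
write_wt_log <- function(samples, path, subject_id = "unknown") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# synthetic wrist temperature log (thermochron-style export)",
    paste0("# subject_id: ", subject_id),
    "# sampling: 10 min",
    "datetime,temperature_C",
    sprintf("%s,%.6f", format(samples$datetime, .TS_FMT, tz = "UTC"),
            samples$temp_c)), con)
  invisible(path)
}

#' Write a tilt-angle log
#'
#' @param samples data.frame with `datetime`, `angle_deg`.
#' @param path output path.
#' @param subject_id identifier written into the header block.
#' @return invisibly, `path`.
#' @export
write_tilt_log <- function(samples, path, subject_id = "unknown") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# synthetic tilt log (pendant-accelerometer-style export)",
    paste0("# subject_id: ", subject_id),
    "# sampling: 30 s",
    "datetime,angle_deg",
    sprintf("%s,%.6f", format(samples$datetime, .TS_FMT, tz = "UTC"),
            samples$angle_deg)), con)
  invisible(path)
}

#' Derive motor activity and body position from tilt samples
#'
#' Activity is the rate of angle change, `|angle_i - angle_(i-1)| / dt`
#' in degrees per minute; position is the tilt angle itself. The first
#' activity sample has no predecessor and is masked (NA).
#'
#' @param tilt data.frame with `datetime` (strictly increasing) and
#'   `angle_deg`.
#' @return data.frame with `datetime`, `activity` (deg/min, first NA) and
#'   `position` (deg).
#' @export
derive_activity_position <- function(tilt) {
  if (nrow(tilt) < 2) stop("need at least 2 tilt samples")
  dt_min <- as.numeric(diff(tilt$datetime), units = "mins")
  if (any(dt_min <= 0)) stop("tilt timestamps must be strictly increasing")
  data.frame(datetime = tilt$datetime,
             activity = c(NA_real_, abs(diff(tilt$angle_deg)) / dt_min),
             position = tilt$angle_deg)
}

#' Filter wrist-temperature samples
#'
#' Two rules mask artifactual samples: (1) values outside `wt_range`
#' (off-wrist or ambient readings); (2) isolated spikes, i.e. a jump larger
#' than `spike_delta` degrees C relative to the last valid sample that
#' returns to within `spike_delta` of that level within `spike_return`
#' subsequent samples — the intervening samples are masked. Filtering is
#' total: it never fails, it only masks.
#'
#' @param samples data.frame with `datetime`, `temp_c`, time-ordered.
#' @param wt_range plausible on-wrist range, degrees C.
#' @param spike_delta jump threshold per ~10-min step, degrees C.
#' @param spike_return look-ahead, in samples, for the return to baseline.
#' @return `samples` with a logical `mask` column (TRUE = valid) and
#'   attribute `masked_fraction`.
#' @export
filter_wt <- function(samples, wt_range = c(20, 40), spike_delta = 2,
                      spike_return = 2) {
  x <- samples$temp_c
  n <- length(x)
  mask <- is.finite(x) & x >= wt_range[1] & x <= wt_range[2]
  i <- 2L
  while (i <= n) {
    if (mask[i]) {
      prev <- max(which(mask[seq_len(i - 1L)]), -Inf)
      if (is.finite(prev) && abs(x[i] - x[prev]) > spike_delta && i < n) {
        ret <- NULL
        for (j in (i + 1L):min(i + spike_return, n)) {
          if (mask[j] && abs(x[j] - x[prev]) <= spike_delta) { ret <- j; break }
        }
        if (!is.null(ret)) {
          mask[i:(ret - 1L)] <- FALSE
          i <- ret
          next
        }
      }
    }
    i <- i + 1L
  }
  out <- samples
  out$mask <- mask
  attr(out, "masked_fraction") <- mean(!mask)
  out
}

#' Regularize samples onto a fixed-width bin grid
#'
#' Assigns each unmasked sample to the half-open bin
#' `[bin_start, bin_start + bin_minutes)` containing its timestamp (bin 0
#' starts at local midnight), averages within bins, masks empty bins, and
#' trims partial leading/trailing days so the series spans whole days.
#'
#' @param samples data.frame with `datetime`, a value column, and optionally
#'   a logical `mask` column (TRUE = valid).
#' @param value name of the value column.
#' @param bin_minutes bin width, minutes (default 10).
#' @param units,channel passed through to the resulting series.
#' @return a [regular_series()].
#' @export
regularize <- function(samples, value, bin_minutes = 10, units = "",
                       channel = "") {
  dt <- samples$datetime
  if (is.unsorted(dt)) stop("samples must be time-ordered")
  v <- samples[[value]]
  keep <- if ("mask" %in% names(samples)) samples$mask else TRUE
  keep <- keep & is.finite(v)

  day0 <- trunc(dt[1], units = "days")
  if (dt[1] > day0) day0 <- day0 + 86400  # first complete day
  t_end <- dt[length(dt)]
  # a trailing day is complete when data reach into its last bin
  last_cov <- as.numeric(difftime(t_end, day0, units = "mins")) + 1e-9
  n_days <- floor((last_cov + bin_minutes) / 1440)
  if (n_days < 1) stop("span shorter than 1 whole day after trimming")
  bpd <- 1440L %/% as.integer(bin_minutes)
  n_bins <- n_days * bpd

  off_min <- as.numeric(difftime(dt, day0, units = "mins"))
  bin <- floor(off_min / bin_minutes) + 1
  in_range <- keep & bin >= 1 & bin <= n_bins
  sums <- tapply(v[in_range], bin[in_range], sum)
  cnts <- tapply(rep(1, sum(in_range)), bin[in_range], sum)
  values <- rep(NA_real_, n_bins)
  idx <- as.integer(names(sums))
  values[idx] <- as.numeric(sums) / as.numeric(cnts)
  regular_series(values, start = day0, bin_minutes = bin_minutes,
                 units = units, channel = channel)
}

#' Write channels as a long-format tidy CSV
#'
#' One row per subject x channel x bin: `subject_id, channel, datetime,
#' value, mask`.
#'
#' @param channels named list of [regular_series()] for one subject.
#' @param subject_id subject identifier.
#' @param path output path; when NULL the data.frame is returned unwritten.
#' @return the tidy data.frame, invisibly when written.
#' @export
write_tidy_channels <- function(channels, subject_id, path = NULL) {
  rows <- lapply(names(channels), function(nm) {
    s <- channels[[nm]]
    data.frame(subject_id = subject_id, channel = nm,
               datetime = format(s$start + (seq_along(s$values) - 1) *
                                   s$bin_minutes * 60, .TS_FMT, tz = "UTC"),
               value = s$values, mask = s$mask)
  })
  out <- do.call(rbind, rows)
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
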