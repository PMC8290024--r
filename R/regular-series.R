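#' Regular 10-minute time series
#'
#' The common currency of all circadian metrics: one value per fixed-width
#' time-of-day bin (default 10 min, 144 bins/day), a validity mask, and a
#' start timestamp aligned to local midnight. Masked bins carry no value
#' semantics and are excluded from every sum and variance downstream.
#'
#' @param values numeric vector, one value per bin; may contain NA at masked
#'   bins.
#' @param mask logical vector, same length as `values`; TRUE = valid bin.
#'   Defaults to `!is.na(values)`.
#' @param start POSIXct timestamp of the first bin, aligned to midnight.
#' @param bin_minutes bin width in minutes; must divide 1440.
#' @param units unit string of the channel (e.g. `"degC"`, `"deg/min"`).
#' @param channel channel name (e.g. `"activity"`, `"wt"`, `"tap"`).
#' @return an object of class `regular_series`.
#' @export
regular_series <- function(values, mask = !is.na(values),
                           start = as.POSIXct("2024-01-01", tz = "UTC"),
                           bin_minutes = 10, units = "", channel = "") {
  values <- as.numeric(values)
  mask <- as.logical(mask)
  stopifnot(length(mask) == length(values))
  if (1440 %% bin_minutes != 0)
    stop("bin_minutes must divide 1440")
  mask[!is.finite(values)] <- FALSE
  values[!mask] <- NA_real_
  bpd <- 1440L %/% as.integer(bin_minutes)
  if (length(values) %% bpd != 0)
    stop("series length (", length(values), ") is not a whole number of days (",
         bpd, " bins/day)")
  structure(
    list(values = values, mask = mask, start = start,
         bin_minutes = as.integer(bin_minutes), units = units,
         channel = channel),
    class = "regular_series"
  )
}

#' @export
length.regular_series <- function(x) length(x$values)

#' Bins per day of a regular series
#' @param x a `regular_series`.
#' @return integer number of bins in 24 h.
#' @export
bins_per_day <- function(x) 1440L %/% x$bin_minutes

#' Number of whole days spanned by a regular series
#' @param x a `regular_series`.
#' @return integer day count.
#' @export
n_days <- function(x) length(x$values) %/% bins_per_day(x)

#' Fraction of bins that are masked (invalid)
#' @param x a `regular_series`.
#' @return fraction in \[0, 1\].
#' @export
masked_fraction <- function(x) mean(!x$mask)

#' @export
print.regular_series <- function(x, ...) {
  cat(sprintf("<regular_series> channel=%s units=%s %d days x %d bins/day (%d-min bins), %.1f%% masked\n",
              x$channel, x$units, n_days(x), bins_per_day(x), x$bin_minutes,
              100 * masked_fraction(x)))
  invisible(x)
}

#' Reshape a regular series to a days x bins matrix
#'
#' @param x a `regular_series`.
#' @return numeric matrix with one row per day and one column per
#'   time-of-day bin; masked bins are NA.
#' @export
as_day_matrix <- function(x) {
  matrix(x$values, nrow = n_days(x), ncol = bins_per_day(x), byrow = TRUE)
}

#' Re-bin a regular series to wider bins
#'
#' Averages unmasked values within each coarser bin; a coarse bin is masked
#' when all of its fine bins are masked. Used to compute IS/IV on the
#' classical 60-min grid instead of the native 10-min grid.
#'
#' @param x a `regular_series`.
#' @param bin_minutes target bin width; must be a multiple of `x$bin_minutes`
#'   and divide 1440.
#' @return a `regular_series` on the coarser grid.
#' @export
rebin <- function(x, bin_minutes) {
  if (bin_minutes == x$bin_minutes) return(x)
  if (bin_minutes %% x$bin_minutes != 0)
    stop("target bin width must be a multiple of the native bin width")
  k <- bin_minutes %/% x$bin_minutes
  grp <- rep(seq_len(length(x$values) %/% k), each = k)
  v <- tapply(x$values, grp, function(v) mean(v, na.rm = TRUE))
  v[!is.finite(v)] <- NA_real_
  regular_series(as.numeric(v), start = x$start, bin_minutes = bin_minutes,
                 units = x$units, channel = x$channel)
}

# minutes since midnight -> "HH:MM"
format_clock <- function(minutes) {
  minutes <- round(minutes) %% 1440
  sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)
}
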