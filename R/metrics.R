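# Non-parametric circadian rhythm analysis.
#
# IS (interdaily stability), IV (intradaily variability), RA (relative
# amplitude), CFI (circadian function index), the mean daily waveform, and
# the M10/L5 activity windows with their phase markers TM10/TL5. Undefined
# statistics (zero variance, constant waveforms where a ratio degenerates)
# are reported as NA, never silently coerced to 0 or 1.

#' Mean daily waveform of a regular series
#'
#' Averages unmasked values per time-of-day bin across days.
#'
#' @param series a [regular_series()] spanning >= 1 whole day.
#' @return an object of class `daily_waveform`: `values` (one per
#'   time-of-day bin, NA where no day contributes), `counts` (contributing
#'   days per bin), `bin_minutes`, `units`, `channel`.
#' @export
mean_waveform <- function(series) {
  m <- as_day_matrix(series)
  counts <- colSums(!is.na(m))
  if (all(counts == 0)) stop("all bins are masked")
  values <- suppressWarnings(colMeans(m, na.rm = TRUE))
  values[counts == 0] <- NA_real_
  structure(list(values = values, counts = counts,
                 bin_minutes = series$bin_minutes, units = series$units,
                 channel = series$channel),
            class = "daily_waveform")
}

#' @export
print.daily_waveform <- function(x, ...) {
  cat(sprintf("<daily_waveform> channel=%s, %d bins (%d-min), %d-%d days/bin\n",
              x$channel, length(x$values), x$bin_minutes,
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Interdaily stability (IS)
#'
#' The constancy of the 24-h pattern across days: the fraction of total
#' variance explained by the mean daily waveform,
#' \deqn{IS = \frac{N \sum_b (\bar x_b - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' with p time-of-day bins and N samples. With missing data the
#' between-bin sum of squares is count-weighted, which reduces to the
#' formula above for complete data and keeps IS in \[0, 1\]. IS = 1 iff
#' every day is identical; white noise gives IS ~ 1/n_days.
#'
#' @param series a [regular_series()] spanning >= 2 whole days.
#' @return IS in \[0, 1\], or NA when the series has zero variance.
#' @export
interdaily_stability <- function(series) {
  if (n_days(series) < 2) stop("IS needs >= 2 whole days")
  m <- as_day_matrix(series)
  x <- m[!is.na(m)]
  n <- length(x)
  if (n < 2) stop("IS needs >= 2 unmasked samples")
  gm <- mean(x)
  ss_tot <- sum((x - gm)^2)
  if (ss_tot == 0) return(NA_real_)
  counts <- colSums(!is.na(m))
  bmeans <- suppressWarnings(colMeans(m, na.rm = TRUE))
  ok <- counts > 0
  ss_between <- sum(counts[ok] * (bmeans[ok] - gm)^2)
  # between-SS <= total-SS analytically; guard the rounding at the boundary
  min(1, max(0, ss_between / ss_tot))
}

#' Intradaily variability (IV)
#'
#' Rhythm fragmentation: the normalized mean square of consecutive
#' differences,
#' \deqn{IV = \frac{N \sum_{i \ge 2} (x_i - x_{i-1})^2}{(N-1) \sum_i (x_i - \bar x)^2}.}
#' Differences are never taken across masked gaps; with m valid consecutive
#' pairs the denominator count N-1 generalizes to m. Smooth slow signals
#' give IV near 0; strict alternation between two extremes gives IV near 4;
#' white noise gives IV near 2.
#'
#' @param series a [regular_series()].
#' @return IV >= 0, or NA when the series has zero variance.
#' @export
intradaily_variability <- function(series) {
  x <- series$values
  valid <- series$mask
  pair <- valid[-1] & valid[-length(valid)]
  if (!any(pair)) stop("IV needs at least one unmasked consecutive pair")
  d <- diff(x)[pair]
  xs <- x[valid]
  n <- length(xs)
  ss_tot <- sum((xs - mean(xs))^2)
  if (ss_tot == 0) return(NA_real_)
  (n * sum(d^2)) / (sum(pair) * ss_tot)
}

#' Locate the M10 and L5 windows of a daily waveform
#'
#' M10 is the mean over the 10 consecutive hours of maximum values, L5 the
#' mean over the 5 consecutive hours of minimum values; both windows are
#' searched circularly over every possible onset bin (wrapping across
#' midnight). Window means are weighted by the per-bin day counts; masked
#' bins are excluded. TM10/TL5 are the onset clock times of the winning
#' windows; ties resolve to the earliest onset.
#'
#' @param waveform a `daily_waveform` from [mean_waveform()].
#' @param m_hours,l_hours window lengths in hours (defaults 10 and 5).
#' @return list with `M10`, `TM10` (minutes after midnight), `L5`, `TL5`.
#' @export
find_m10_l5 <- function(waveform, m_hours = 10, l_hours = 5) {
  v <- waveform$values
  w <- waveform$counts
  p <- length(v)
  m_bins <- as.integer(m_hours * 60 / waveform$bin_minutes)
  l_bins <- as.integer(l_hours * 60 / waveform$bin_minutes)
  if (sum(w > 0) < m_bins)
    stop("fewer valid bins (", sum(w > 0), ") than the ", m_hours, "-h window")
  v2 <- c(v, v); w2 <- c(w, w)
  v2[w2 == 0] <- 0  # weight 0 removes them from the weighted mean
  window_means <- function(len) {
    vw <- cumsum(c(0, v2 * w2))
    ww <- cumsum(c(0, w2))
    on <- seq_len(p)
    num <- vw[on + len] - vw[on]
    den <- ww[on + len] - ww[on]
    ifelse(den > 0, num / den, NA_real_)
  }
  mm <- window_means(m_bins)
  lm_ <- window_means(l_bins)
  i_m <- which.max(mm)  # which.max/min return the first (earliest) maximizer
  i_l <- which.min(lm_)
  list(M10 = mm[i_m], TM10 = (i_m - 1) * waveform$bin_minutes,
       L5 = lm_[i_l], TL5 = (i_l - 1) * waveform$bin_minutes)
}

#' Relative amplitude (RA)
#'
#' Day-night contrast `(M10 - L5) / (M10 + L5)`, defined for non-negative
#' channels with a daytime acrophase.
#'
#' @param m10,l5 the M10 and L5 window means; requires `m10 >= l5 >= 0`.
#' @return RA in \[0, 1\], or NA when `m10 + l5 == 0`.
#' @export
relative_amplitude <- function(m10, l5) {
  if (is.na(m10) || is.na(l5)) return(NA_real_)
  if (l5 < 0 || m10 < l5) stop("relative amplitude requires M10 >= L5 >= 0")
  if (m10 + l5 == 0) return(NA_real_)
  (m10 - l5) / (m10 + l5)
}

#' Circadian function index (CFI)
#'
#' Composite of stability, inverted-rescaled fragmentation, and amplitude:
#' `CFI = (IS + (2 - min(IV, 2)) / 2 + RA) / 3`, spanning 0 (absent
#' circadian rhythmicity) to 1 (robust rhythm). IV is clipped at 2 (its
#' white-noise level) so each term, and hence CFI, lies in \[0, 1\].
#'
#' @param is_,iv,ra interdaily stability in \[0, 1\], intradaily
#'   variability >= 0, relative amplitude in \[0, 1\].
#' @return CFI in \[0, 1\]; NA if any input is NA.
#' @export
circadian_function_index <- function(is_, iv, ra) {
  if (anyNA(c(is_, iv, ra))) return(NA_real_)
  if (is_ < 0 || is_ > 1) stop("IS must be in [0, 1]")
  if (ra < 0 || ra > 1) stop("RA must be in [0, 1]")
  if (iv < 0) stop("IV must be >= 0")
  (is_ + (2 - pmin(iv, 2)) / 2 + ra) / 3
}

#' Non-parametric circadian summary of one series
#'
#' Composes [mean_waveform()], [interdaily_stability()],
#' [intradaily_variability()], [find_m10_l5()], [relative_amplitude()] and
#' [circadian_function_index()] into the per-subject parameter block.
#'
#' @param series a [regular_series()] spanning at least `min_days` whole
#'   days.
#' @param min_days minimum span for a reliable non-parametric analysis
#'   (default 6).
#' @param np_bin_minutes bin width for the IS/IV computation; `NULL` (the
#'   default) uses the series' native grid, 60 selects the classical
#'   hourly variant.
#' @return an object of class `np_summary`: list with `IS`, `IV`, `RA`,
#'   `CFI`, `M10`, `L5`, `TM10`, `TL5` (minutes after midnight), `n_days`,
#'   `masked_fraction`, `channel`, `units`.
#' @export
np_summary <- function(series, min_days = 6, np_bin_minutes = NULL) {
  if (n_days(series) < min_days)
    stop("series spans ", n_days(series), " days; need >= ", min_days)
  s_np <- if (is.null(np_bin_minutes)) series else rebin(series, np_bin_minutes)
  is_ <- interdaily_stability(s_np)
  iv <- intradaily_variability(s_np)
  wf <- mean_waveform(series)
  ml <- find_m10_l5(wf)
  ra <- relative_amplitude(ml$M10, ml$L5)
  structure(
    list(IS = is_, IV = iv, RA = ra,
         CFI = circadian_function_index(is_, iv, ra),
         M10 = ml$M10, L5 = ml$L5, TM10 = ml$TM10, TL5 = ml$TL5,
         n_days = n_days(series), masked_fraction = masked_fraction(series),
         channel = series$channel, units = series$units),
    class = "np_summary"
  )
}

#' @export
print.np_summary <- function(x, ...) {
  cat(sprintf(
    "<np_summary> %s: IS=%.3f IV=%.3f RA=%.3f CFI=%.3f M10=%.3f L5=%.3f TM10=%s TL5=%s (%d days, %.1f%% masked)\n",
    x$channel, x$IS, x$IV, x$RA, x$CFI, x$M10, x$L5,
    format_clock(x$TM10), format_clock(x$TL5), x$n_days,
    100 * x$masked_fraction))
  invisible(x)
}

#' @export
as.data.frame.np_summary <- function(x, ...) {
  data.frame(channel = x$channel, IS = x$IS, IV = x$IV, RA = x$RA,
             CFI = x$CFI, M10 = x$M10, L5 = x$L5,
             TM10 = format_clock(x$TM10), TL5 = format_clock(x$TL5),
             TM10_min = x$TM10, TL5_min = x$TL5,
             n_days = x$n_days, masked_fraction = x$masked_fraction)
}
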