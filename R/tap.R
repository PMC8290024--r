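# The integrated TAP variable: per-subject normalized wrist Temperature
# (inverted), Activity and Position averaged bin-wise. TAP = 1 marks the
# coldest wrist, highest activity and standing posture (active wake);
# TAP = 0 the warmest wrist, stillness and horizontal posture (sleep).

#' Normalize a channel to \[0, 1\] per subject
#'
#' Values are clipped to the subject's `[lo_pct, hi_pct]` percentile range
#' and mapped linearly onto \[0, 1\]; with `invert = TRUE` the result is
#' reflected (`1 - mapped`), which is how wrist temperature enters TAP.
#' Percentile clipping (default 5th-95th) makes the map robust to isolated
#' bursts; `lo_pct = 0, hi_pct = 100` recovers plain min-max scaling.
#'
#' @param series a [regular_series()] with >= 2 distinct unmasked values.
#' @param invert reflect the normalized values (for inverse-phase channels).
#' @param lo_pct,hi_pct clipping percentiles in \[0, 100\].
#' @return a [regular_series()] with unmasked values in \[0, 1\] and
#'   `units = "norm"`.
#' @export
normalize_channel <- function(series, invert = FALSE, lo_pct = 5,
                              hi_pct = 95) {
  if (lo_pct >= hi_pct) stop("lo_pct must be < hi_pct")
  x <- series$values[series$mask]
  if (length(unique(x)) < 2)
    stop("cannot normalize a constant channel (", series$channel, ")")
  q <- stats::quantile(x, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  if (q[2] == q[1])
    stop("degenerate percentile range for channel ", series$channel,
         "; widen lo_pct/hi_pct")
  v <- (pmin(pmax(series$values, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  if (invert) v <- 1 - v
  regular_series(v, mask = series$mask, start = series$start,
                 bin_minutes = series$bin_minutes, units = "norm",
                 channel = paste0(series$channel, "_norm"))
}

#' Integrate normalized channels into the TAP series
#'
#' Bin-wise arithmetic mean of the three normalized channels (wrist
#' temperature already inverted). Under the default `missing = "mask"`
#' policy a bin is masked whenever any channel is masked there;
#' `missing = "renormalize"` instead averages whichever channels remain.
#'
#' @param wt_n inverted-normalized wrist temperature ([normalize_channel()]
#'   with `invert = TRUE`).
#' @param act_n,pos_n normalized activity and position.
#' @param missing `"mask"` or `"renormalize"`.
#' @return a [regular_series()] with `channel = "tap"`, values in \[0, 1\].
#' @export
integrate_tap <- function(wt_n, act_n, pos_n,
                          missing = c("mask", "renormalize")) {
  missing <- match.arg(missing)
  chans <- list(wt_n, act_n, pos_n)
  n <- length(wt_n$values)
  same_grid <- all(vapply(chans, function(s)
    length(s$values) == n && s$bin_minutes == wt_n$bin_minutes &&
      identical(as.numeric(s$start), as.numeric(wt_n$start)), logical(1)))
  if (!same_grid) stop("channels are not on the same grid")
  m <- cbind(wt_n$values, act_n$values, pos_n$values)
  if (missing == "mask") {
    values <- rowMeans(m)
  } else {
    values <- rowMeans(m, na.rm = TRUE)
    values[!is.finite(values)] <- NA_real_
  }
  regular_series(values, start = wt_n$start, bin_minutes = wt_n$bin_minutes,
                 units = "a.u.", channel = "tap")
}
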