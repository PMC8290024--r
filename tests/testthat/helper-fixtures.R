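# Shared fixture builders: tiny in-code series and brute-force oracles.

# regular_series from a plain vector, choosing the bin width from bins/day
series_of <- function(values, bins_per_day = length(values), ...) {
  regular_series(values, bin_minutes = 1440 / bins_per_day, ...)
}

# square-wave series: `high` for day_bins bins, `low` for the rest, `days` days
square_series <- function(days = 7, bins = 144, high = 100, low = 0,
                          day_start = 48, day_len = 96) {
  one <- rep(low, bins)
  one[((day_start + seq_len(day_len) - 1) %% bins) + 1] <- high
  series_of(rep(one, days), bins_per_day = bins)
}

# timestamp grid helper for io tests
ts_grid <- function(n, step_s = 600, start = "2024-03-04 00:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * step_s
}

# brute-force circular window search over every onset (the M10/L5 oracle)
brute_m10_l5 <- function(values, counts, bin_minutes, m_bins, l_bins) {
  p <- length(values)
  wmean <- function(onset, len) {
    idx <- ((onset + seq_len(len) - 2) %% p) + 1
    w <- counts[idx]
    if (sum(w) == 0) return(NA_real_)
    sum(values[idx][w > 0] * w[w > 0]) / sum(w)
  }
  mm <- vapply(seq_len(p), wmean, numeric(1), len = m_bins)
  ll <- vapply(seq_len(p), wmean, numeric(1), len = l_bins)
  list(M10 = max(mm), TM10 = (which.max(mm) - 1) * bin_minutes,
       L5 = min(ll), TL5 = (which.min(ll) - 1) * bin_minutes)
}

# direct-formula IS on a complete days x bins matrix (the IS oracle)
brute_is <- function(m) {
  x <- as.vector(m)
  gm <- mean(x)
  num <- length(x) * sum((colMeans(m) - gm)^2)
  den <- ncol(m) * sum((x - gm)^2)
  if (den == 0) NA_real_ else num / den
}

# pair-counting AUC oracle: U / (n1 n2), ties counted one half
brute_auc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# exhaustive midpoint enumeration oracle for the information-gain stump
brute_best_cut <- function(values, labels, positive) {
  h <- function(k, n) {
    if (n == 0) return(0)
    p <- k / n
    s <- 0
    if (p > 0) s <- s - p * log2(p)
    if (p < 1) s <- s - (1 - p) * log2(1 - p)
    s
  }
  y <- labels == positive
  v <- sort(unique(values))
  cuts <- (v[-1] + v[-length(v)]) / 2
  n <- length(y)
  h0 <- h(sum(y), n)
  best <- NULL
  for (cut in cuts) {
    l <- values < cut
    gain <- h0 - (sum(l) / n) * h(sum(y[l]), sum(l)) -
      (sum(!l) / n) * h(sum(y[!l]), sum(!l))
    agree <- max((sum(!l & y) + sum(l & !y)) / n,
                 (sum(l & y) + sum(!l & !y)) / n)
    if (is.null(best) || gain > best$gain + 1e-12 ||
        (abs(gain - best$gain) <= 1e-12 && agree > best$agree + 1e-12)) {
      best <- list(cut = cut, gain = gain, agree = agree)
    }
  }
  best
}
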