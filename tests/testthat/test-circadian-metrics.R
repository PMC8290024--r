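# Non-parametric circadian parameters: hand-computable cases, brute-force
# oracles, and the defining invariants.

test_that("mean waveform averages per time-of-day bin and honours masks", {
  s <- series_of(rep(c(1, 3), each = 2), bins_per_day = 2)  # 2 days x 2 bins
  wf <- mean_waveform(s)
  expect_equal(wf$values, c(2, 2))
  expect_equal(wf$counts, c(2L, 2L))

  v <- rep(c(1, 3), each = 2)
  v[1] <- NA  # mask day-1 bin-0: bin-0 mean uses day 2 only
  wf2 <- mean_waveform(series_of(v, bins_per_day = 2))
  expect_equal(wf2$values, c(3, 2))
  expect_equal(wf2$counts, c(1L, 2L))

  week <- square_series(days = 7)
  expect_equal(mean_waveform(week)$values, week$values[1:144])
})

test_that("interdaily stability hits its exact anchor values", {
  expect_equal(interdaily_stability(series_of(c(0, 2, 0, 2), 2)), 1)
  expect_equal(interdaily_stability(series_of(c(0, 2, 2, 0), 2)), 0)
  # identical days => IS = 1, regardless of the waveform
  set.seed(9)
  day <- runif(144)
  expect_equal(interdaily_stability(series_of(rep(day, 7), 144)), 1)
  # zero variance is undefined, not 0 or 1
  expect_true(is.na(interdaily_stability(series_of(rep(5, 288), 144))))
  expect_error(interdaily_stability(series_of(runif(144), 144)), "2 whole days")
})

test_that("IS of white noise concentrates near 1/n_days", {
  set.seed(41)
  vals <- replicate(300, interdaily_stability(series_of(rnorm(7 * 24), 24)))
  expect_equal(mean(vals), 1 / 7, tolerance = 0.05)
})

test_that("IS equals the direct-formula oracle, and IS = 1 iff days are identical", {
  # exhaustive 2-day x 4-bin integer series over {0,1,2}
  grids <- as.matrix(expand.grid(rep(list(0:2), 8)))
  for (i in seq_len(nrow(grids))) {
    v <- grids[i, ]
    m <- matrix(v, nrow = 2, byrow = TRUE)
    if (stats::var(v) == 0) next
    is_ <- interdaily_stability(series_of(v, 4))
    expect_equal(is_, brute_is(m), tolerance = 1e-12)
    expect_identical(isTRUE(all.equal(is_, 1)), all(m[1, ] == m[2, ]))
    expect_gte(is_, 0); expect_lte(is_, 1 + 1e-12)
  }
})

test_that("intradaily variability matches hand-computed values", {
  expect_equal(intradaily_variability(series_of(c(1, -1, 1, -1), 4)), 4)
  expect_equal(intradaily_variability(series_of(c(0, 1, 2, 3), 4)), 0.8)
  expect_true(is.na(intradaily_variability(series_of(rep(2, 4), 4))))
  # densely sampled sinusoid: IV -> 0 as the step shrinks
  iv_at <- function(bins) {
    t <- seq(0, 2 * pi, length.out = bins + 1)[-1]
    intradaily_variability(series_of(sin(t), bins))
  }
  expect_lt(iv_at(288), iv_at(24))
  expect_lt(iv_at(288), 0.01)
})

test_that("IV skips differences across masked gaps", {
  v <- c(0, 1, NA, 100, 101, 102)  # the 1 -> 100 jump must not be differenced
  s <- series_of(v, 6)
  d2 <- c(1, 1, 1)^2  # pairs (1,2), (4,5), (5,6)
  xs <- v[!is.na(v)]
  expected <- (5 * sum(d2)) / (3 * sum((xs - mean(xs))^2))
  expect_equal(intradaily_variability(s), expected)
})

test_that("M10/L5 windows match the exhaustive circular search", {
  # square wave: 100 for 16 h (08:00-24:00), 0 for 8 h
  wf <- mean_waveform(square_series(days = 7))
  ml <- find_m10_l5(wf)
  expect_equal(ml$M10, 100)
  expect_equal(ml$L5, 0)
  expect_true(ml$TL5 >= 0 && ml$TL5 <= 3 * 60)  # night block 00:00-08:00
  # constant waveform: tie rule puts both onsets at midnight
  mlc <- find_m10_l5(mean_waveform(series_of(rep(7, 144), 144)))
  expect_equal(mlc$M10, 7); expect_equal(mlc$L5, 7)
  expect_equal(mlc$TM10, 0); expect_equal(mlc$TL5, 0)

  set.seed(7)
  for (i in 1:500) {
    v <- rnorm(144)
    counts <- sample(c(0L, rep(6:7, 20)), 144, replace = TRUE)
    if (sum(counts > 0) < 60) counts[counts == 0] <- 6L
    wf <- structure(list(values = ifelse(counts > 0, v, NA), counts = counts,
                         bin_minutes = 10, units = "", channel = "x"),
                    class = "daily_waveform")
    got <- find_m10_l5(wf)
    want <- brute_m10_l5(ifelse(counts > 0, v, 0), counts, 10, 60, 30)
    expect_equal(got$M10, want$M10, tolerance = 1e-12)
    expect_equal(got$L5, want$L5, tolerance = 1e-12)
    expect_equal(got$TM10, want$TM10)
    expect_equal(got$TL5, want$TL5)
  }
})

test_that("relative amplitude follows (M10-L5)/(M10+L5)", {
  expect_equal(relative_amplitude(0.64, 0.16), 0.60)
  expect_equal(relative_amplitude(5, 5), 0)
  expect_equal(relative_amplitude(3, 0), 1)
  expect_true(is.na(relative_amplitude(0, 0)))
  expect_error(relative_amplitude(1, 2), "M10 >= L5")
  # strictly increasing in M10 at fixed L5
  m10s <- seq(0.2, 5, length.out = 30)
  ras <- vapply(m10s, relative_amplitude, numeric(1), l5 = 0.2)
  expect_true(all(diff(ras) > 0))
})

test_that("the circadian function index combines IS, IV and RA linearly", {
  expect_equal(circadian_function_index(1, 0, 1), 1)
  expect_equal(circadian_function_index(0, 2, 0), 0)
  expect_equal(circadian_function_index(0, 3, 0), 0)  # IV clipped at 2
  expect_equal(circadian_function_index(0.56, 0.31, 0.52), 1.925 / 3)
  expect_error(circadian_function_index(1.2, 0.3, 0.5), "IS")
  expect_error(circadian_function_index(0.5, -1, 0.5), "IV")
  # CFI in [0,1] over a grid
  g <- expand.grid(is_ = c(0, .3, 1), iv = c(0, 1, 2, 3.5), ra = c(0, .6, 1))
  cfi <- mapply(circadian_function_index, g$is_, g$iv, g$ra)
  expect_true(all(cfi >= 0 & cfi <= 1))
})

test_that("np_summary composes the metrics and enforces the 6-day minimum", {
  s <- square_series(days = 7)
  out <- np_summary(s)
  expect_equal(out$IS, 1)
  expect_equal(out$RA, 1)
  expect_lt(out$IV, 0.5)
  expect_gt(out$CFI, 0.9)
  expect_equal(out$n_days, 7)
  expect_error(np_summary(square_series(days = 5)), "need >= 6")

  # whole-day rotation leaves every parameter unchanged
  rot <- series_of(c(s$values[145:1008], s$values[1:144]), 144)
  out2 <- np_summary(rot)
  for (f in c("IS", "IV", "RA", "CFI", "M10", "L5", "TM10", "TL5"))
    expect_equal(out2[[f]], out[[f]])
})

test_that("within-day shuffling strictly lowers IS of a rhythmic series", {
  set.seed(11)
  base <- square_series(days = 7, high = 10, low = 1)
  noisy <- series_of(base$values + rnorm(length(base$values), 0, 0.5), 144)
  is0 <- interdaily_stability(noisy)
  m <- as_day_matrix(noisy)
  worse <- 0
  for (k in 1:100) {
    shuf <- t(apply(m, 1, sample))
    worse <- worse + (brute_is(shuf) < is0)
  }
  expect_gte(worse, 99)
})

test_that("IS/IV can be computed on the classical 60-min grid via rebinning", {
  set.seed(3)
  s <- series_of(square_series(7, high = 8, low = 1)$values +
                   rnorm(1008, 0, 0.3), 144)
  out10 <- np_summary(s)
  out60 <- np_summary(s, np_bin_minutes = 60)
  expect_false(isTRUE(all.equal(out10$IS, out60$IS)))
  # hourly averaging removes within-hour noise, so stability rises
  expect_gt(out60$IS, out10$IS)
  # M10/L5 are grid-independent (computed on the native waveform)
  expect_equal(out60$M10, out10$M10)
})
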