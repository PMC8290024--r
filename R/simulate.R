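# Seeded simulator of week-long ACM recordings.
#
# The generative model (fully specified in the methods vignette): wake tilt
# fluctuates around a raised baseline, sleep tilt is near-horizontal, and
# nocturnal arousals form a homogeneous Poisson process within each night's
# sleep window at arousal_rate * cpap_factor events/hour. Each burst raises
# the tilt angle for 1-3 consecutive 30-s samples (exponential amplitude) and
# triggers a transient wrist-temperature drop (0.5 degC, 20-min exponential
# decay), emulating sympathetic activation. Wrist temperature follows the
# inverse circadian profile: high during the sleep window, low during wake.

.SIM_START <- function() as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

#' Simulate one subject's ambulatory circadian monitoring week
#'
#' Generates a wrist-temperature channel at 10-min cadence and a tilt-angle
#' channel at 30-s cadence spanning `days` whole days, with nightly sleep
#' windows (nominal onset plus Gaussian day-to-day jitter), optional
#' afternoon naps, and AHI-linked nocturnal arousal bursts. The same
#' `(spec, days, seed)` always yields a bit-identical recording.
#'
#' @param spec a [phenotype_spec()].
#' @param days whole days to simulate (>= 1).
#' @param seed integer seed.
#' @param subject_id identifier carried in the recording and its exports.
#' @return an object of class `acm_recording`: list with `subject_id`,
#'   `wt` (data.frame `datetime`, `temp_c`), `tilt` (data.frame `datetime`,
#'   `angle_deg`), and `metadata`.
#' @examples
#' rec <- generate_subject(phenotype_spec("severe"), days = 7, seed = 42)
#' head(rec$wt)
#' @export
generate_subject <- function(spec, days, seed, subject_id = "S1") {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (days < 1) stop("days must be >= 1")
  set.seed(as.integer(seed))

  onset_min <- clock_to_minutes(spec$sleep_onset)
  dur_min <- spec$sleep_duration * 60
  t0 <- .SIM_START()

  # sleep windows for nights -1 .. days-1 (night -1 covers the first morning)
  nights <- -1:(days - 1)
  onsets <- nights * 1440 + onset_min +
    stats::rnorm(length(nights), 0, spec$phase_jitter_sd)
  windows <- cbind(start = onsets, end = onsets + dur_min)

  # optional afternoon naps (position only): ~14:30 onset, ~60 min
  nap_flag <- stats::runif(days) < spec$nap_probability
  nap_on <- (seq_len(days) - 1) * 1440 + 870 + stats::rnorm(days, 0, 30)
  nap_dur <- pmax(20, stats::rnorm(days, 60, 10))
  naps <- cbind(start = nap_on[nap_flag], end = (nap_on + nap_dur)[nap_flag])

  in_windows <- function(t_min, win) {
    res <- rep(FALSE, length(t_min))
    if (nrow(win) > 0)
      for (k in seq_len(nrow(win)))
        res <- res | (t_min >= win[k, 1] & t_min < win[k, 2])
    res
  }

  ## tilt channel: 30-s cadence
  n_tilt <- days * 2880L
  t_tilt <- (seq_len(n_tilt) - 1) * 0.5  # minutes since start
  asleep <- in_windows(t_tilt, windows)
  napping <- in_windows(t_tilt, naps) & !asleep

  angle <- numeric(n_tilt)
  wake_noise <- stats::rnorm(n_tilt, 0, spec$noise_sd$tilt)
  sleep_noise <- abs(stats::rnorm(n_tilt, 0, 0.05 * spec$noise_sd$tilt))
  # tile one day's time-of-day vector so the diel profile is bitwise
  # identical across days
  tod_h <- rep((0:2879) * 0.5 / 60, days)
  wake_base <- 45 + 8 * sin(2 * pi * (tod_h - 10) / 24)
  angle[!asleep & !napping] <- (wake_base + wake_noise)[!asleep & !napping]
  angle[asleep] <- 5 + sleep_noise[asleep]
  angle[napping] <- 8 + 2 * sleep_noise[napping]

  # nocturnal arousal bursts: Poisson within each sleep window
  rate <- spec$arousal_rate * spec$cpap_factor  # events per hour of sleep
  event_times <- numeric(0)
  for (k in seq_len(nrow(windows))) {
    w0 <- max(windows[k, 1], 0)
    w1 <- min(windows[k, 2], days * 1440)
    if (w1 <= w0) next
    n_ev <- stats::rpois(1, rate * (w1 - w0) / 60)
    if (n_ev == 0) next
    te <- sort(stats::runif(n_ev, w0, w1))
    amp <- stats::rexp(n_ev, rate = 1 / 30)
    len <- sample.int(3, n_ev, replace = TRUE)
    for (j in seq_len(n_ev)) {
      i0 <- floor(te[j] / 0.5) + 1
      idx <- i0:min(i0 + len[j] - 1, n_tilt)
      angle[idx] <- angle[idx] + amp[j]
    }
    event_times <- c(event_times, te)
  }
  angle <- pmin(pmax(angle, 0), 90)

  ## wrist temperature channel: 10-min cadence, inverse circadian profile
  n_wt <- days * 144L
  t_wt <- (seq_len(n_wt) - 1) * 10
  asleep_wt <- in_windows(t_wt + 5, windows)  # bin midpoints
  sleep_level <- smooth_running_mean(as.numeric(asleep_wt), 3)
  tod_wt <- rep((0:143) / 6, days)
  wt <- 33.5 + 2.0 * sleep_level +
    0.3 * cos(2 * pi * (tod_wt - 5) / 24) +
    stats::rnorm(n_wt, 0, spec$noise_sd$wt)
  for (te in event_times) {
    after <- t_wt >= te
    wt[after] <- wt[after] - 0.5 * exp(-(t_wt[after] - te) / 20)
  }
  wt <- pmin(pmax(wt, 20), 40)

  structure(
    list(subject_id = subject_id,
         wt = data.frame(datetime = t0 + t_wt * 60, temp_c = wt),
         tilt = data.frame(datetime = t0 + t_tilt * 60, angle_deg = angle),
         metadata = list(group = spec$label, days = days, seed = seed,
                         ahi = spec$ahi)),
    class = "acm_recording"
  )
}

#' @export
print.acm_recording <- function(x, ...) {
  cat(sprintf("<acm_recording> %s (%s): %d WT samples, %d tilt samples\n",
              x$subject_id, x$metadata$group, nrow(x$wt), nrow(x$tilt)))
  invisible(x)
}

#' Simulate a cohort of recordings
#'
#' Per-subject seeds are drawn deterministically from the cohort seed, so the
#' whole cohort (recordings and manifest) is reproducible. Demographics are
#' decorative covariates: drawn per group but never used by the generative
#' model.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (named list of `acm_recording`) and
#'   `manifest` (data.frame: subject_id, group, age, sex, bmi, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  total <- sum(vapply(spec$groups, function(g) g$n, numeric(1)))
  seeds <- sample.int(.Machine$integer.max - 1L, total)

  default_demo <- function(label) {
    if (label == "healthy")
      list(age = c(40, 62), female_frac = 0.44, bmi = c(22, 27))
    else
      list(age = c(45, 65), female_frac = 0.27, bmi = c(26, 36))
  }

  rows <- list(); recs <- list(); i <- 0L
  for (g in spec$groups) {
    demo <- spec$demographics[[g$spec$label]]
    if (is.null(demo)) demo <- default_demo(g$spec$label)
    age <- round(stats::runif(g$n, demo$age[1], demo$age[2]), 1)
    sex <- ifelse(stats::runif(g$n) < demo$female_frac, "F", "M")
    bmi <- round(stats::runif(g$n, demo$bmi[1], demo$bmi[2]), 1)
    for (j in seq_len(g$n)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", g$spec$label, j)
      rows[[i]] <- data.frame(subject_id = sid, group = g$spec$label,
                              age = age[j], sex = sex[j], bmi = bmi[j],
                              seed = seeds[i])
    }
  }
  manifest <- do.call(rbind, rows)
  # generate after all demographic draws so per-subject streams are isolated
  for (i in seq_len(nrow(manifest))) {
    g_label <- manifest$group[i]
    g <- Filter(function(x) x$spec$label == g_label, spec$groups)[[1]]
    recs[[manifest$subject_id[i]]] <-
      generate_subject(g$spec, spec$days, manifest$seed[i],
                       subject_id = manifest$subject_id[i])
  }
  list(recordings = recs, manifest = manifest)
}

#' Write a cohort to device-dialect CSV files
#'
#' Emits, per subject, the same CSV dialects that [read_wt_log()] and
#' [read_tilt_log()] ingest, plus a `manifest.csv`, so `simulate` and
#' `ingest` pipeline modes are round-trip equivalent.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest with `wt_path`/`tilt_path` columns added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$wt_path <- file.path(dir, paste0(manifest$subject_id, "_wt.csv"))
  manifest$tilt_path <- file.path(dir, paste0(manifest$subject_id, "_tilt.csv"))
  for (i in seq_len(nrow(manifest))) {
    rec <- cohort$recordings[[manifest$subject_id[i]]]
    write_wt_log(rec$wt, manifest$wt_path[i], subject_id = rec$subject_id)
    write_tilt_log(rec$tilt, manifest$tilt_path[i], subject_id = rec$subject_id)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# centered running mean (window = 2k+1 bins); edges are padded by constant
# extension so a day-periodic input stays day-periodic after smoothing
smooth_running_mean <- function(x, k) {
  n <- length(x)
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  cs <- cumsum(c(0, xp))
  (cs[seq_len(n) + 2 * k + 1] - cs[seq_len(n)]) / (2 * k + 1)
}

clock_to_minutes <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}
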