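#' Simulator phenotype specification
#'
#' Parameters of one simulated subject class. Severity is encoded through the
#' apnoea-hypopnoea index (AHI, respiratory events per hour of sleep) using
#' the conventional strata: snorer/mild below 15 events/h, moderate 15-30,
#' severe above 30. Nocturnal arousal bursts occur as a homogeneous Poisson
#' process during the sleep window at `arousal_rate * cpap_factor` events per
#' hour, with `arousal_rate = arousal_per_event * ahi` by default.
#'
#' @param label one of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`,
#'   `"cpap"`. When only `label` is given, the remaining parameters take the
#'   phenotype defaults listed in the methods vignette.
#' @param ahi apnoea-hypopnoea index, events/hour (non-negative).
#' @param arousal_rate nocturnal activity-burst rate, events/hour of sleep.
#'   Default `arousal_per_event * ahi`.
#' @param arousal_per_event bursts per AHI event-hour (default 0.25).
#' @param phase_jitter_sd day-to-day SD of sleep-onset time, minutes.
#' @param sleep_onset nominal sleep-onset clock time, `"HH:MM"`.
#' @param sleep_duration sleep-window length, hours.
#' @param nap_probability probability of an afternoon nap on any day.
#' @param cpap_factor multiplier in \[0, 1\] applied to `arousal_rate`;
#'   must be 1 unless `label == "cpap"`.
#' @param noise_sd named list of channel noise SDs: `wt` (degrees C, 10-min
#'   samples) and `tilt` (degrees, 30-s samples, wake state).
#' @return an object of class `phenotype_spec`.
#' @examples
#' phenotype_spec("severe")
#' phenotype_spec("mild", ahi = 5)
#' @export
phenotype_spec <- function(label = c("healthy", "mild", "moderate", "severe", "cpap"),
                           ahi = NULL, arousal_rate = NULL,
                           arousal_per_event = 0.25,
                           phase_jitter_sd = NULL,
                           sleep_onset = "23:30", sleep_duration = 8,
                           nap_probability = 0.3,
                           cpap_factor = NULL,
                           noise_sd = list(wt = 0.3, tilt = 15)) {
  label <- match.arg(label)
  defaults <- list(
    healthy  = list(ahi = 2,  jitter = 15),
    mild     = list(ahi = 7,  jitter = 20),
    moderate = list(ahi = 22, jitter = 25),
    severe   = list(ahi = 40, jitter = 30),
    cpap     = list(ahi = 40, jitter = 30)
  )[[label]]
  if (is.null(ahi)) ahi <- defaults$ahi
  if (is.null(phase_jitter_sd)) phase_jitter_sd <- defaults$jitter
  if (is.null(cpap_factor)) cpap_factor <- if (label == "cpap") 0.3 else 1
  if (is.null(arousal_rate)) arousal_rate <- arousal_per_event * ahi

  if (!is.numeric(ahi) || ahi < 0) stop("ahi must be non-negative")
  if (!is.numeric(arousal_rate) || arousal_rate < 0)
    stop("arousal_rate must be non-negative")
  if (phase_jitter_sd < 0) stop("phase_jitter_sd must be non-negative")
  if (sleep_duration <= 0 || sleep_duration >= 24)
    stop("sleep_duration must be in (0, 24) hours")
  if (nap_probability < 0 || nap_probability > 1)
    stop("nap_probability must be in [0, 1]")
  if (cpap_factor < 0 || cpap_factor > 1) stop("cpap_factor must be in [0, 1]")
  if (label != "cpap" && cpap_factor != 1)
    stop("cpap_factor must be 1 unless label is 'cpap'")
  if (any(unlist(noise_sd) < 0)) stop("noise_sd entries must be non-negative")
  if (label == "mild" && ahi >= 15) stop("mild phenotype requires ahi < 15")
  if (label == "moderate" && (ahi < 15 || ahi > 30))
    stop("moderate phenotype requires 15 <= ahi <= 30")
  if (label == "severe" && ahi <= 30) stop("severe phenotype requires ahi > 30")
  if (label == "healthy" && ahi >= 15) stop("healthy phenotype requires ahi < 15")

  structure(
    list(label = label, ahi = ahi, arousal_rate = arousal_rate,
         phase_jitter_sd = phase_jitter_sd,
         sleep_onset = sleep_onset, sleep_duration = sleep_duration,
         nap_probability = nap_probability, cpap_factor = cpap_factor,
         noise_sd = noise_sd),
    class = "phenotype_spec"
  )
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf(
    "<phenotype_spec> %s: AHI=%.1f, arousal %.2f/h x cpap_factor %.2f, onset %s +/- %.0f min, %g h sleep\n",
    x$label, x$ahi, x$arousal_rate, x$cpap_factor, x$sleep_onset,
    x$phase_jitter_sd, x$sleep_duration))
  invisible(x)
}

#' Derive a CPAP-treated phenotype
#'
#' Returns a copy of `spec` relabelled `"cpap"` with the nocturnal arousal
#' rate attenuated by `factor` (the effective burst rate becomes
#' `arousal_rate * factor`). All other parameters are preserved, emulating
#' treatment of the same subject.
#'
#' @param spec a `phenotype_spec` (typically moderate or severe).
#' @param factor attenuation multiplier in \[0, 1\]; 1 leaves the arousal
#'   process unchanged, 0 removes nocturnal bursts entirely.
#' @return a `phenotype_spec` with `label = "cpap"` and
#'   `cpap_factor = factor`.
#' @export
apply_cpap <- function(spec, factor) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0 || factor > 1)
    stop("factor must be a single number in [0, 1]")
  spec$label <- "cpap"
  spec$cpap_factor <- factor
  spec
}

#' Cohort specification for the simulator
#'
#' @param groups list of groups, each `list(spec = <phenotype_spec>, n = <int>)`.
#' @param days whole days per recording; at least 6 for a reliable
#'   non-parametric analysis.
#' @param seed integer master seed; per-subject seeds are derived from it
#'   deterministically.
#' @param demographics named list per group label of
#'   `list(age = c(lo, hi), female_frac = f, bmi = c(lo, hi))`; decorative
#'   covariates, not used by generation.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, days = 7, seed = 1, demographics = NULL) {
  if (length(groups) == 0) stop("groups must be a non-empty list")
  for (g in groups) {
    if (!inherits(g$spec, "phenotype_spec")) stop("each group needs a phenotype_spec")
    if (is.null(g$n) || g$n < 2) stop("each group needs n >= 2 subjects")
  }
  if (days < 6) stop("days must be >= 6 for a reliable non-parametric analysis")
  structure(list(groups = groups, days = as.integer(days),
                 seed = as.integer(seed), demographics = demographics),
            class = "cohort_spec")
}
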