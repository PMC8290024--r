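# Full-cohort orchestration: simulate or ingest recordings, preprocess,
# integrate TAP, summarize per subject, tabulate per group (mean +/- SEM),
# and run the one-decision screening protocol on configured contrasts.

#' Preprocess one recording into regularized channels
#'
#' Filters wrist temperature, derives activity/position from tilt,
#' regularizes every channel onto the common 10-min grid, crops all
#' channels to their shared whole days, and appends the integrated TAP
#' channel.
#'
#' @param rec an `acm_recording`.
#' @param bin_minutes grid width, minutes (default 10).
#' @param wt_range,wt_spike_delta wrist-temperature filter parameters, see
#'   [filter_wt()].
#' @param lo_pct,hi_pct normalization percentiles, see
#'   [normalize_channel()].
#' @param tap_missing missing-channel policy for [integrate_tap()].
#' @return named list of [regular_series()]: `wt`, `activity`, `position`,
#'   `tap`.
#' @export
process_recording <- function(rec, bin_minutes = 10, wt_range = c(20, 40),
                              wt_spike_delta = 2, lo_pct = 5, hi_pct = 95,
                              tap_missing = "mask") {
  wt_f <- filter_wt(rec$wt, wt_range = wt_range,
                    spike_delta = wt_spike_delta)
  wt <- regularize(wt_f, "temp_c", bin_minutes, units = "degC",
                   channel = "wt")
  ap <- derive_activity_position(rec$tilt)
  act <- regularize(ap, "activity", bin_minutes, units = "deg/min",
                    channel = "activity")
  pos <- regularize(ap, "position", bin_minutes, units = "deg",
                    channel = "position")
  ch <- align_channels(list(wt = wt, activity = act, position = pos))
  ch$tap <- integrate_tap(
    normalize_channel(ch$wt, invert = TRUE, lo_pct = lo_pct, hi_pct = hi_pct),
    normalize_channel(ch$activity, lo_pct = lo_pct, hi_pct = hi_pct),
    normalize_channel(ch$position, lo_pct = lo_pct, hi_pct = hi_pct),
    missing = tap_missing)
  ch
}

# crop a list of regular_series to the whole days they all cover
align_channels <- function(channels) {
  starts <- vapply(channels, function(s) as.numeric(s$start), numeric(1))
  ends <- vapply(channels, function(s)
    as.numeric(s$start) + length(s$values) * s$bin_minutes * 60, numeric(1))
  s0 <- max(starts); e0 <- min(ends)
  if (e0 - s0 < 86400) stop("channels share less than one whole day")
  lapply(channels, function(s) {
    i0 <- (s0 - as.numeric(s$start)) / (s$bin_minutes * 60) + 1
    i1 <- (e0 - as.numeric(s$start)) / (s$bin_minutes * 60)
    regular_series(s$values[i0:i1], mask = s$mask[i0:i1],
                   start = as.POSIXct(s0, origin = "1970-01-01", tz = "UTC"),
                   bin_minutes = s$bin_minutes, units = s$units,
                   channel = s$channel)
  })
}

#' Summarize a set of recordings subject-by-subject
#'
#' @param recordings named list of `acm_recording`.
#' @param manifest data.frame with at least `subject_id` and `group`.
#' @param min_days,np_bin_minutes passed to [np_summary()].
#' @param ... passed to [process_recording()].
#' @return data.frame, one row per subject x channel, with the
#'   non-parametric parameter block and manifest columns.
#' @export
summarize_cohort <- function(recordings, manifest, min_days = 6,
                             np_bin_minutes = NULL, ...) {
  rows <- list()
  for (sid in names(recordings)) {
    ch <- process_recording(recordings[[sid]], ...)
    meta <- manifest[manifest$subject_id == sid, , drop = FALSE]
    for (nm in names(ch)) {
      s <- as.data.frame(np_summary(ch[[nm]], min_days = min_days,
                                    np_bin_minutes = np_bin_minutes))
      s$subject_id <- sid
      s$group <- if (nrow(meta)) meta$group[1] else NA_character_
      rows[[length(rows) + 1]] <- s
    }
  }
  out <- do.call(rbind, rows)
  front <- c("subject_id", "group", "channel")
  out[, c(front, setdiff(names(out), front))]
}

#' Group table of circadian parameters (mean +/- SEM)
#'
#' @param summaries output of [summarize_cohort()].
#' @return data.frame, one row per group x channel, with `<param>_mean`,
#'   `<param>_sem` columns and the group size `n`.
#' @export
group_table <- function(summaries) {
  params <- c("IS", "IV", "RA", "CFI", "M10", "L5", "TM10_min", "TL5_min")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  keys <- unique(summaries[, c("group", "channel")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- summaries[summaries$group == keys$group[i] &
                       summaries$channel == keys$channel[i], ]
    row <- data.frame(group = keys$group[i], channel = keys$channel[i],
                      n = nrow(sub))
    for (p in params) {
      x <- sub[[p]][is.finite(sub[[p]])]
      row[[paste0(p, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0(p, "_sem")]] <- if (length(x) > 1) sem(x) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Across-subject group waveforms (mean +/- SEM per bin)
#'
#' Averages individual mean daily waveforms per group, per time-of-day bin.
#' Singleton groups get an NA SEM and a warning.
#'
#' @param waveforms named list (subject_id -> `daily_waveform`) for one
#'   channel.
#' @param grouping named character vector or factor mapping subject_id to
#'   group.
#' @return data.frame: `group`, `bin`, `clock` (HH:MM onset), `mean`,
#'   `sem`, `n`.
#' @export
group_waveforms <- function(waveforms, grouping) {
  grouping <- grouping[names(waveforms)]
  out <- list()
  for (g in unique(grouping)) {
    ids <- names(grouping)[grouping == g]
    m <- do.call(rbind, lapply(waveforms[ids], function(w) w$values))
    if (nrow(m) == 1) warning("singleton group '", g, "': SEM undefined")
    bm <- waveforms[[ids[1]]]$bin_minutes
    out[[g]] <- data.frame(
      group = g, bin = seq_len(ncol(m)) - 1,
      clock = format_clock((seq_len(ncol(m)) - 1) * bm),
      mean = colMeans(m, na.rm = TRUE),
      sem = if (nrow(m) > 1) apply(m, 2, function(x)
        stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x)))) else NA_real_,
      n = nrow(m))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

default_config <- function() {
  list(mode = "simulate",
       cohort = list(days = 7, seed = 101,
                     groups = list(list(label = "healthy", n = 8),
                                   list(label = "severe", n = 8))),
       bin_minutes = 10, np_bin_minutes = NULL,
       wt_range = c(20, 40), wt_spike_delta = 2,
       normalization = list(lo_pct = 5, hi_pct = 95),
       min_days = 6,
       screening = list(list(name = "healthy_vs_severe",
                             groups = c("healthy", "severe"),
                             positive = "severe",
                             variables = c("wt_IS", "wt_CFI", "tap_CFI",
                                           "activity_L5"))),
       protocol = list(n_iter = 100, train_frac = 0.66, seed = 7),
       out_dir = NULL)
}

# one-level merge: user keys replace defaults wholesale, except the named
# sub-lists cohort/normalization/protocol whose own keys merge one level
# (so a partial `protocol:` override keeps the remaining defaults)
merge_config <- function(def, cfg) {
  out <- def
  for (nm in names(cfg)) {
    if (nm %in% c("cohort", "normalization", "protocol") &&
        is.list(cfg[[nm]]) && is.list(def[[nm]])) {
      sub <- def[[nm]]
      for (k in names(cfg[[nm]])) sub[[k]] <- cfg[[nm]][[k]]
      out[[nm]] <- sub
    } else {
      out[nm] <- list(cfg[[nm]])  # wholesale, NULL-safe
    }
  }
  out
}

#' Run the full ACM analysis pipeline
#'
#' Simulates (or ingests) a cohort, preprocesses every recording,
#' integrates TAP, writes per-subject summaries, group tables (mean +/-
#' SEM), group waveforms, and runs the one-decision screening protocol on
#' each configured contrast. Deterministic given the config: every output
#' file carries the config hash.
#'
#' @param config a named list, or path to a YAML/JSON config file. Keys
#'   missing from the config take the defaults of `default_config()`:
#'   `mode` (`"simulate"` or `"ingest"`), `cohort` (days, seed, groups as
#'   `label`/`n` pairs) or `manifest` (CSV path with subject_id, group,
#'   wt_path, tilt_path), `bin_minutes`, `np_bin_minutes`, `wt_range`,
#'   `wt_spike_delta`, `normalization` (lo_pct/hi_pct), `min_days`,
#'   `screening` (list of contrasts: name, groups, positive, variables as
#'   `<channel>_<PARAM>`), `protocol` (n_iter, train_frac, seed),
#'   `out_dir`.
#' @return list with `summaries`, `group_table`, `waveforms`, `screening`,
#'   `manifest`, `config`, `config_hash`; files are written when `out_dir`
#'   is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  hash <- config_hash(config)

  if (config$mode == "simulate") {
    groups <- lapply(config$cohort$groups, function(g)
      list(spec = phenotype_spec(g$label), n = g$n))
    cs <- cohort_spec(groups, days = config$cohort$days,
                      seed = config$cohort$seed)
    cohort <- generate_cohort(cs)
  } else if (config$mode == "ingest") {
    cohort <- ingest_cohort(config$manifest)
  } else stop("unknown mode: ", config$mode)

  processed <- lapply(names(cohort$recordings), function(sid)
    tryCatch(process_recording(cohort$recordings[[sid]],
                               bin_minutes = config$bin_minutes,
                               wt_range = config$wt_range,
                               wt_spike_delta = config$wt_spike_delta,
                               lo_pct = config$normalization$lo_pct,
                               hi_pct = config$normalization$hi_pct),
             error = function(e) stop("preprocess stage failed for subject ",
                                      sid, ": ", conditionMessage(e),
                                      call. = FALSE)))
  names(processed) <- names(cohort$recordings)

  rows <- list()
  for (sid in names(processed)) {
    meta <- cohort$manifest[cohort$manifest$subject_id == sid, , drop = FALSE]
    for (nm in names(processed[[sid]])) {
      s <- tryCatch(
        as.data.frame(np_summary(processed[[sid]][[nm]],
                                 min_days = config$min_days,
                                 np_bin_minutes = config$np_bin_minutes)),
        error = function(e) stop("summarize stage failed for subject ", sid,
                                 ", channel ", nm, ": ",
                                 conditionMessage(e), call. = FALSE))
      s$subject_id <- sid
      s$group <- if (nrow(meta)) meta$group[1] else NA_character_
      rows[[length(rows) + 1]] <- s
    }
  }
  summaries <- do.call(rbind, rows)
  front <- c("subject_id", "group", "channel")
  summaries <- summaries[, c(front, setdiff(names(summaries), front))]
  gt <- group_table(summaries)

  # group waveforms per channel
  wf_rows <- list()
  grouping <- stats::setNames(cohort$manifest$group,
                              cohort$manifest$subject_id)
  for (chan in c("wt", "activity", "position", "tap")) {
    wfs <- lapply(processed, function(ch) mean_waveform(ch[[chan]]))
    d <- group_waveforms(wfs, grouping)
    d$channel <- chan
    wf_rows[[chan]] <- d
  }
  waveforms <- do.call(rbind, c(wf_rows, list(make.row.names = FALSE)))

  screening <- lapply(config$screening, function(sc)
    screen_contrast(summaries, sc, config$protocol))
  names(screening) <- vapply(config$screening, function(sc) sc$name, "")

  result <- list(summaries = summaries, group_table = gt,
                 waveforms = waveforms, screening = screening,
                 manifest = cohort$manifest, config = config,
                 config_hash = hash)
  if (!is.null(config$out_dir)) write_bundle(result, config$out_dir)
  result
}

screen_contrast <- function(summaries, sc, protocol) {
  sub <- summaries[summaries$group %in% sc$groups, ]
  out <- list()
  for (v in sc$variables) {
    parts <- strsplit(v, "_", fixed = TRUE)[[1]]
    chan <- paste(parts[-length(parts)], collapse = "_")
    param <- parts[length(parts)]
    rows <- sub[sub$channel == chan, ]
    if (nrow(rows) == 0 || !param %in% names(rows))
      stop("screening variable not in summary schema: ", v)
    out[[v]] <- split_protocol(rows[[param]], rows$group,
                               n_iter = protocol$n_iter,
                               train_frac = protocol$train_frac,
                               seed = protocol$seed,
                               positive = sc$positive, variable = v)
  }
  # rank candidates by best test agreement; pairwise Wilcoxon vs the winner
  best_agree <- vapply(out, function(r) r$best_report$agreement, numeric(1))
  winner <- names(out)[which.max(best_agree)]
  comparisons <- lapply(setdiff(names(out), winner), function(v)
    c(list(variable = v, against = winner),
      compare_variables(out[[v]], out[[winner]])))
  list(name = sc$name, groups = sc$groups, positive = sc$positive,
       results = out, winner = winner, comparisons = comparisons)
}

ingest_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "wt_path", "tilt_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    recs[[sid]] <- structure(
      list(subject_id = sid,
           wt = read_wt_log(resolve(manifest$wt_path[i])),
           tilt = read_tilt_log(resolve(manifest$tilt_path[i])),
           metadata = list(group = manifest$group[i])),
      class = "acm_recording")
  }
  list(recordings = recs, manifest = manifest)
}

read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore it
  if (!is.null(cfg$cohort$groups))
    cfg$cohort$groups <- lapply(cfg$cohort$groups, function(g) {
      names(g)[names(g) == "FALSE"] <- "n"
      g
    })
  cfg
}

# hash of the analysis-relevant config (output location excluded, so the
# same analysis written to two directories carries the same hash)
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- paste0("# config_hash: ", result$config_hash)
  write_stamped <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = ",", append = TRUE,
                                        row.names = FALSE, qmethod = "double"))
  }
  write_stamped(result$summaries, "summaries.csv")
  write_stamped(result$group_table, "group_table.csv")
  write_stamped(result$waveforms, "waveforms.csv")
  write_stamped(result$manifest, "manifest.csv")
  scr <- lapply(result$screening, function(s) {
    list(name = s$name, groups = s$groups, positive = s$positive,
         winner = s$winner,
         rules = lapply(s$results, function(r) list(
           variable = r$best_rule$variable,
           cutoff_best_split = r$best_rule$cutoff,
           cutoff_refit = r$refit_rule$cutoff,
           direction = r$best_rule$direction,
           test_agreement = r$best_report$agreement,
           test_auc = r$best_report$auc,
           best_iteration = r$best_iteration,
           seed = r$seed)),
         comparisons = s$comparisons)
  })
  jsonlite::write_json(list(config_hash = result$config_hash,
                            contrasts = scr),
                       file.path(out_dir, "screening.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(stamp,
                 paste0("subjects: ", nrow(result$manifest)),
                 paste0("channels: wt, activity, position, tap"),
                 paste0("contrasts: ",
                        paste(names(result$screening), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
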