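# End-to-end analysis drivers: single trials, experiments (trial averages)
# and cohorts (experiment averages), plus the manifest-driven pipeline and
# report generation.

#' Analyze one recording end to end
#'
#' Runs alignment, the integration cascade, 19 Hz resampling, Morlet
#' spectrograms, ridge frequency (trimmed and normalized), inter-channel
#' phase for the standard pairs, burst tables per channel, and (optionally)
#' the tonic mask.
#'
#' @param rec a \code{raw_recording}.
#' @param mode "drug" or "evoked".
#' @param band rhythm band, Hz (mode default when NULL).
#' @param trim edge trim, seconds (10 for drug, 1.5 for evoked).
#' @param reference reference channel (first flexor-dominated by default).
#' @param tonic_mask compute the tonic mask and mask epoch frequency means.
#' @param threshold_fraction burst-boundary threshold (0.40).
#' @return list with the envelope, frequency series (Hz and % change),
#'   phase series per pair, burst tables, epoch frequency means, and mask.
#' @export
analyze_trial <- function(rec, mode = c("drug", "evoked"), band = NULL,
                          trim = NULL, reference = NULL, tonic_mask = FALSE,
                          threshold_fraction = 0.4) {
  mode <- match.arg(mode)
  trial <- align_trials(rec, mode)
  ineg <- integrate_neurogram(trial, mode)
  env19 <- resample_envelope(ineg, 19)
  if (is.null(trim)) trim <- if (mode == "drug") 10 else 1.5
  chans <- env19$channels$name
  if (is.null(reference)) {
    flex <- chans[env19$channels$role == "flexor"]
    reference <- if (length(flex)) flex[1] else chans[1]
  }
  specs <- lapply(chans, function(ch) wavelet_spectrogram(env19, ch, band))
  names(specs) <- chans
  freq <- trim_edges(extract_frequency(specs[[reference]]), trim)
  mask <- NULL
  exclude <- NULL
  if (tonic_mask) {
    # the tonic clamp is preparation-wide: a bin is tonic only when no
    # channel oscillates there, so the per-channel masks are intersected
    # (channels whose detector found nothing are uninformative and skipped)
    per_ch <- lapply(chans, function(ch) flag_tonic(env19, specs[[ch]]))
    nonempty <- which(vapply(per_ch, function(m) any(m$mask$tonic),
                             logical(1)))
    mask <- per_ch[[if (length(nonempty)) nonempty[1] else 1L]]
    if (length(nonempty) > 1)
      for (k in nonempty[-1])
        mask$mask$tonic <- mask$mask$tonic & per_ch[[k]]$mask$tonic
    if (any(mask$mask$tonic)) {
      r <- rle(mask$mask$tonic)
      ends <- cumsum(r$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      exclude <- lapply(which(r$values), function(i)
        c(mask$mask$time[starts[i]], mask$mask$time[ends[i]]))
    }
  }
  freq_pct <- if (mode == "drug" && !is.null(env19$epochs) &&
                  "pre" %in% env19$epochs$label)
    normalize_percent_change(freq, "pre") else NULL

  # standard pairs: bilateral flexor-dominated; ipsilateral flexor-extensor
  pairs <- list()
  flex <- chans[env19$channels$role == "flexor"]
  ext <- chans[env19$channels$role == "extensor"]
  if (length(flex) >= 2) pairs[["bilateral_flexor"]] <- c(flex[1], flex[2])
  if (length(flex) >= 1 && length(ext) >= 1)
    pairs[["flexor_extensor"]] <- c(flex[1], ext[1])
  phases <- lapply(pairs, function(pr)
    trim_edges(extract_phase(specs[[pr[1]]], specs[[pr[2]]]), trim))

  bursts <- lapply(chans, function(ch)
    burst_table(env19, ch, threshold_fraction, exclude = exclude))
  names(bursts) <- chans

  # tonic extent estimate: the wavelet mask end lower-bounds the resumption
  # (temporal smearing) while the first detected burst onset upper-bounds
  # it (the oscillator can resume up to a cycle before its first burst);
  # their midpoint is reported
  extent <- NA_real_
  if (!is.null(mask)) {
    extent <- 0
    lon <- env19$epochs$start[env19$epochs$label == "light"]
    raw_ext <- tonic_extent(mask, lon)
    if (raw_ext > 0) {
      t_end <- lon + raw_ext
      ons <- unlist(lapply(bursts, function(b)
        b$onset_time[b$onset_time > t_end - 1]))
      f_lit <- mask$params$f_light
      per <- if (!is.null(f_lit) && is.finite(f_lit)) 1 / f_lit else Inf
      first_on <- if (length(ons)) min(ons) else NA
      extent <- if (!is.na(first_on) && first_on - t_end < 1.5 * per)
        0.5 * (t_end + first_on) - lon else raw_ext
    }
  }

  fmeans <- epoch_means(freq, mask, guard_efold = 1)
  list(envelope = env19, spectra = specs, frequency = freq,
       frequency_pct = freq_pct, phases = phases, bursts = bursts,
       mask = mask, tonic_extent = extent, freq_epoch_means = fmeans,
       reference = reference, mode = mode)
}

#' Analyze a drug-mode experiment (several trials)
#'
#' Trial-level series are averaged within the experiment; burst tables are
#' summarized across trials per epoch.
#'
#' @param trials list of simulate_neurograms outputs or raw_recordings.
#' @param ... passed to \code{\link{analyze_trial}}.
#' @return list(freq_epoch (Hz), freq_pct_series (trial-averaged), bursts
#'   (epoch_summary per channel), phase_epoch, tonic_extent).
#' @export
analyze_experiment <- function(trials, ...) {
  recs <- lapply(trials, function(x) if (!is.null(x$recording)) x$recording else x)
  res <- lapply(recs, analyze_trial, ...)
  chans <- names(res[[1]]$bursts)

  fme <- lapply(res, function(r) r$freq_epoch_means)
  freq_epoch <- fme[[1]]
  freq_epoch$mean <- rowMeans(sapply(fme, function(m) m$mean), na.rm = TRUE)

  pct <- NULL
  if (!is.null(res[[1]]$frequency_pct)) {
    g <- aggregate_series(list(lapply(res, function(r) r$frequency_pct)))
    pct <- rhythm_series(g$time, as.numeric(g$values[1, ]), "percent-change",
                         "%", attr(res[[1]]$frequency_pct, "channel"),
                         attr(res[[1]]$frequency_pct, "epochs"))
  }
  bursts <- lapply(chans, function(ch)
    epoch_summary(lapply(res, function(r) r$bursts[[ch]])))
  names(bursts) <- chans

  phase_epoch <- NULL
  if (length(res[[1]]$phases)) {
    phase_epoch <- lapply(names(res[[1]]$phases), function(pn) {
      per_tr <- sapply(res, function(r) {
        s <- r$phases[[pn]]
        lab <- assign_epoch(s$time, attr(s, "epochs"))
        vapply(unique(lab[!is.na(lab)]), function(ep)
          circ_mean_r(s$value[lab == ep & !is.na(s$value)])$mean, numeric(1))
      })
      per_tr <- matrix(per_tr, ncol = length(res))
      apply(per_tr, 1, function(v) circ_mean_r(v[!is.na(v)])$mean)
    })
    names(phase_epoch) <- names(res[[1]]$phases)
  }

  extent <- NA_real_
  if (!is.null(res[[1]]$mask)) {
    # average over trials in which a tonic segment was detected: a zero is
    # a failed detection on a weak trial, not a zero-length estimate
    ee <- vapply(res, `[[`, numeric(1), "tonic_extent")
    extent <- if (any(ee > 0)) mean(ee[ee > 0]) else 0
  }
  list(freq_epoch = freq_epoch, freq_pct_series = pct, bursts = bursts,
       phase_epoch = phase_epoch, tonic_extent = extent, trials = res)
}

#' Analyze an evoked experiment (paired control / lit episodes)
#'
#' @param control_trials,light_trials lists of simulated evoked episodes.
#' @param ... passed to \code{\link{analyze_trial}}.
#' @return list(freq_control, freq_light (Hz), pct_change (%)).
#' @export
analyze_evoked_experiment <- function(control_trials, light_trials, ...) {
  mfreq <- function(x) {
    rec <- if (!is.null(x$recording)) x$recording else x
    r <- analyze_trial(rec, mode = "evoked", ...)
    mean(r$frequency$value, na.rm = TRUE)
  }
  fc <- mean(vapply(control_trials, mfreq, numeric(1)))
  fl <- mean(vapply(light_trials, mfreq, numeric(1)))
  list(freq_control = fc, freq_light = fl,
       pct_change = 100 * (fl / fc - 1))
}

#' Analyze a simulated cohort
#'
#' Experiment-level results are averaged across experiments (trial ->
#' experiment -> group order throughout).
#'
#' @param cohort a \code{loco_cohort} from \code{\link{simulate_cohort}}.
#' @param tonic_mask compute tonic masks (hemicord scenario).
#' @param ... passed down to the per-trial analysis.
#' @return For drug cohorts: list(freq_epoch (cross-experiment Hz means),
#'   burst_summary (\code{\link{aggregate_epoch_summaries}} per channel),
#'   masked_light_freq, tonic_extent, per_experiment). For evoked cohorts:
#'   list(pct_change_mean, per_experiment).
#' @export
analyze_cohort <- function(cohort, tonic_mask = FALSE, ...) {
  stopifnot(inherits(cohort, "loco_cohort"))
  if (cohort$experiments[[1]]$mode == "evoked") {
    per <- lapply(cohort$experiments, function(e)
      analyze_evoked_experiment(e$control_trials, e$light_trials, ...))
    return(list(
      pct_change_mean = mean(vapply(per, `[[`, numeric(1), "pct_change")),
      freq_control_mean = mean(vapply(per, `[[`, numeric(1), "freq_control")),
      freq_light_mean = mean(vapply(per, `[[`, numeric(1), "freq_light")),
      per_experiment = per))
  }
  per <- lapply(cohort$experiments, function(e)
    analyze_experiment(e$trials, tonic_mask = tonic_mask, ...))
  fe <- per[[1]]$freq_epoch
  fe$mean <- rowMeans(sapply(per, function(p) p$freq_epoch$mean), na.rm = TRUE)
  chans <- names(per[[1]]$bursts)
  burst_summary <- lapply(chans, function(ch)
    aggregate_epoch_summaries(lapply(per, function(p) p$bursts[[ch]])))
  names(burst_summary) <- chans
  list(freq_epoch = fe,
       burst_summary = burst_summary,
       tonic_extent = mean(vapply(per, `[[`, numeric(1), "tonic_extent")),
       per_experiment = per)
}

#' Run the full pipeline from a manifest
#'
#' The manifest (a list, or path to a JSON file) names either recordings on
#' disk or a preset cohort to simulate, the analysis parameters and the
#' output directory. All referenced files are validated before any
#' computation; outputs are a machine-readable \code{summary.json}, burst
#' and series tables as delimited text, and a line-delimited JSON run log
#' with parameters and seeds. Reruns with the same manifest and seeds are
#' byte-identical.
#'
#' @param manifest list or path to JSON manifest. Fields: \code{mode}
#'   ("drug"/"evoked"), \code{groups} (each with \code{label} and either
#'   \code{preset}/\code{n}/\code{trials} or \code{experiments} = list of
#'   trial file paths), \code{parameters} (band, trim, threshold_fraction,
#'   iterations), \code{seed}, \code{out_dir}.
#' @return Invisibly, the result bundle (per-group analyses and, with two
#'   groups, the bootstrap comparison).
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  stopifnot(!is.null(manifest$groups), !is.null(manifest$out_dir))
  seed <- if (is.null(manifest$seed)) 1L else as.integer(manifest$seed)
  pars <- manifest$parameters
  mode <- if (is.null(manifest$mode)) "drug" else manifest$mode

  # validate every referenced file before any computation
  for (g in manifest$groups) {
    for (ex in g$experiments)
      for (f in unlist(ex))
        if (!file.exists(f)) stop("manifest references missing file: ", f)
  }
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(manifest$out_dir, "run_log.jsonl")
  log_line <- function(...) {
    cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  unlink(logf)
  log_line(stage = "start", seed = seed, mode = mode,
           package_version = as.character(utils::packageVersion("locorhythm")),
           parameters = pars)

  results <- list()
  for (gi in seq_along(manifest$groups)) {
    g <- manifest$groups[[gi]]
    log_line(stage = "group", label = g$label)
    if (!is.null(g$preset)) {
      cohort <- simulate_cohort(g$preset, n = g$n,
                                seed = split_seed(seed, gi),
                                trials = g$trials,
                                sampling_rate = if (is.null(g$sampling_rate))
                                  10000 else g$sampling_rate)
      res <- analyze_cohort(cohort,
                            tonic_mask = isTRUE(g$preset == "hemicord-arch"))
    } else {
      exps <- lapply(g$experiments, function(paths)
        lapply(unlist(paths), read_recording))
      per <- lapply(exps, analyze_experiment, mode = mode)
      fe <- per[[1]]$freq_epoch
      fe$mean <- rowMeans(sapply(per, function(p) p$freq_epoch$mean),
                          na.rm = TRUE)
      chans <- names(per[[1]]$bursts)
      bs <- lapply(chans, function(ch)
        aggregate_epoch_summaries(lapply(per, function(p) p$bursts[[ch]])))
      names(bs) <- chans
      res <- list(freq_epoch = fe, burst_summary = bs, per_experiment = per)
    }
    results[[g$label]] <- res
    for (ch in names(res$burst_summary))
      utils::write.table(res$burst_summary[[ch]],
                         file.path(manifest$out_dir,
                                   paste0("bursts_", g$label, "_", ch, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  comparison <- NULL
  if (length(results) == 2 && mode == "drug") {
    grp <- lapply(seq_along(results), function(gi) {
      series <- lapply(results[[gi]]$per_experiment, `[[`, "freq_pct_series")
      series <- Filter(Negate(is.null), series)
      aggregate_series(series, names(results)[gi])
    })
    iters <- if (is.null(pars$iterations)) 10000 else pars$iterations
    comparison <- bootstrap_timeseries_test(grp[[1]], grp[[2]],
                                            iterations = iters,
                                            seed = split_seed(seed, 999L))
    utils::write.table(comparison$table,
                       file.path(manifest$out_dir, "bootstrap_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_line(stage = "bootstrap", iterations = iters)
  }

  summary <- list(
    seed = seed, mode = mode,
    groups = lapply(names(results), function(lb) {
      r <- results[[lb]]
      out <- list(label = lb)
      if (!is.null(r$freq_epoch))
        out$frequency_hz <- stats::setNames(as.list(r$freq_epoch$mean),
                                            r$freq_epoch$epoch)
      if (!is.null(r$pct_change_mean))
        out$frequency_pct_change <- r$pct_change_mean
      if (!is.null(r$burst_summary))
        out$duty_cycle <- lapply(r$burst_summary, function(bs) {
          d <- bs[bs$metric == "duty_cycle", ]
          stats::setNames(as.list(d$mean), d$epoch)
        })
      if (!is.null(r$tonic_extent) && is.finite(r$tonic_extent))
        out$tonic_extent_s <- r$tonic_extent
      out
    }))
  if (!is.null(comparison))
    summary$bands <- as.list(table(comparison$table$band))
  jsonlite::write_json(summary, file.path(manifest$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(stage = "done")
  invisible(list(results = results, comparison = comparison,
                 summary = summary, out_dir = manifest$out_dir))
}

#' Render a static report for a result bundle
#'
#' Writes a multi-page PDF mirroring the standard display panels: the
#' trial-averaged percent-change frequency series (with significance bands
#' when a two-group comparison is present), per-epoch duty-cycle bars, and
#' circular phase summaries.
#'
#' @param bundle output of \code{\link{run_pipeline}}.
#' @param file output PDF path.
#' @return The file path, invisibly.
#' @export
make_report <- function(bundle, file) {
  grDevices::pdf(file, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  band_cols <- c("<0.0001" = "red", "<0.001" = "orange", "<0.01" = "gold",
                 "<0.05" = "green3", ns = "black")
  for (lb in names(bundle$results)) {
    r <- bundle$results[[lb]]
    series <- if (!is.null(r$per_experiment))
      Filter(Negate(is.null),
             lapply(r$per_experiment, `[[`, "freq_pct_series")) else NULL
    if (!is.null(series) && length(series)) {
      g <- aggregate_series(series, lb)
      gm <- grand_mean(g)
      plot(g$time, gm, type = "l", xlab = "Time (s)",
           ylab = "Frequency change (%)",
           main = paste0(lb, ": frequency change (n=", g$n, ")"))
      graphics::abline(h = 0, lty = 3)
      if (!is.null(bundle$comparison)) {
        bd <- bundle$comparison$table
        graphics::points(bd$time, rep(min(gm, na.rm = TRUE), nrow(bd)),
                         col = band_cols[as.character(bd$band)], pch = 15,
                         cex = 0.4)
      }
    }
    if (!is.null(r$burst_summary) && length(r$burst_summary)) {
      dc <- do.call(rbind, lapply(names(r$burst_summary), function(ch) {
        d <- r$burst_summary[[ch]]
        d <- d[d$metric == "duty_cycle", ]
        if (nrow(d) == 0) return(NULL)
        data.frame(channel = ch, epoch = d$epoch, duty = d$mean)
      }))
      if (is.null(dc) || nrow(dc) == 0) {
        graphics::plot.new(); graphics::title("no cycles detected")
      } else {
        m <- tapply(dc$duty, list(dc$epoch, dc$channel), mean)
        graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                          legend.text = rownames(m),
                          main = paste0(lb, ": duty cycle per epoch"),
                          ylab = "Duty cycle")
      }
    }
  }
  invisible(file)
}
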