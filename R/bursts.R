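# Burst segmentation of integrated envelopes and per-cycle pattern metrics.
#
# Burst onset/offset are defined at 40% of the trough-to-peak distance: the
# rising edge is referenced to the preceding trough, the falling edge to the
# following trough (robust to slow baseline drift), with sub-sample linear
# interpolation at the crossings.

env_channel <- function(env, channel) {
  if (is.character(channel)) channel <- match(channel, env$channels$name)
  if (is.na(channel)) stop("unknown channel")
  channel
}

# Peak prominence: height above the higher of the two basin minima reached
# before a taller sample is met on either side.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p; while (l > 1 && x[l] <= h) l <- l - 1
    r <- p; n <- length(x); while (r < n && x[r] <= h) r <- r + 1
    lmin <- min(x[l:p]); rmin <- min(x[p:r])
    h - max(lmin, rmin)
  }, numeric(1))
}

# Dominant rhythm frequency of an envelope from its raw periodogram,
# restricted to `band`; NA when nothing oscillates.
dominant_frequency <- function(x, fs, band = c(0.05, 4)) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  P <- Mod(stats::fft(x)[seq_len(floor(n / 2))])^2
  fr <- (seq_len(floor(n / 2)) - 1) * fs / n
  sel <- fr >= max(band[1], 3 / (n / fs)) & fr <= min(band[2], fs / 2.5)
  if (!any(sel)) return(NA_real_)
  fr[sel][which.max(P[sel])]
}

#' Detect locomotor cycles (troughs and peaks) in an envelope
#'
#' Extrema are located on a detection-stage smoothed copy of the envelope
#' (zero-phase low-pass at twice the dominant rhythm frequency), which
#' rejects broadband ripple riding on burst tops, and are then refined on
#' the raw envelope so peak and trough values are unsmoothed. Peaks must
#' clear a minimum prominence (a fraction of the envelope's interquartile
#' range, so no absolute threshold is hand-tuned) and a minimum separation
#' (half the dominant period by default); each peak is paired with the
#' preceding trough.
#'
#' @param env an \code{integrated_neurogram} (19 Hz typical).
#' @param channel channel name or index.
#' @param prominence_frac minimum prominence as a fraction of IQR (0.2).
#' @param min_separation minimum peak separation, seconds; NULL (default)
#'   uses half the dominant rhythm period.
#' @return data.frame(trough_time, trough_value, peak_time, peak_value);
#'   empty for constant input.
#' @export
detect_cycles <- function(env, channel = 1, prominence_frac = 0.2,
                          min_separation = NULL) {
  stopifnot(inherits(env, "integrated_neurogram"))
  ci <- env_channel(env, channel)
  x <- env$env[, ci]
  fs <- env$sampling_rate
  t <- env$t0 + (seq_along(x) - 1) / fs
  empty <- data.frame(trough_time = numeric(0), trough_value = numeric(0),
                      peak_time = numeric(0), peak_value = numeric(0))
  if (diff(range(x)) == 0) return(empty)

  f_dom <- dominant_frequency(x, fs)
  if (is.na(f_dom)) return(empty)
  if (is.null(min_separation)) min_separation <- 0.5 / f_dom
  xs <- if (2 * f_dom < 0.4 * fs) fft_lowpass(x, fs, 2 * f_dom) else x

  d <- diff(xs)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(pk)) return(empty)
  prom <- peak_prominence(xs, pk)
  # IQR of the smoothed envelope, floored for sparse (low-duty) trains
  # whose raw quartiles collapse onto the baseline
  scale_ref <- max(stats::IQR(xs), 0.25 * diff(range(xs)))
  pk <- pk[prom >= prominence_frac * scale_ref]
  if (!length(pk)) return(empty)
  # enforce separation, keeping the taller of clashing peaks
  ord <- order(xs[pk], decreasing = TRUE)
  keep <- logical(length(pk))
  taken <- numeric(0)
  for (i in ord) {
    if (!length(taken) || all(abs(t[pk[i]] - taken) >= min_separation)) {
      keep[i] <- TRUE
      taken <- c(taken, t[pk[i]])
    }
  }
  pk <- sort(pk[keep])
  # refine on the raw envelope: peaks within a quarter period of the
  # smoothed location (bounded by the flanking smoothed minima), troughs
  # within the trough-to-peak interval
  halfw <- max(1L, round(0.25 / f_dom * fs))
  n <- length(x)
  locate_troughs <- function(pk) {
    tr <- integer(length(pk))
    for (i in seq_along(pk)) {
      lo <- if (i == 1) 1L else pk[i - 1]
      seg <- lo:pk[i]
      tr[i] <- seg[which.min(xs[seg])]
    }
    for (i in seq_along(pk)) {
      lo <- max(if (i == 1) 1L else pk[i - 1], tr[i] - halfw)
      hi <- min(pk[i] - 1L, tr[i] + halfw)
      if (hi >= lo) tr[i] <- (lo:hi)[which.min(x[lo:hi])]
    }
    tr
  }
  tr <- locate_troughs(pk)
  for (i in seq_along(pk)) {
    lo <- max(tr[i] + 1L, pk[i] - halfw)
    hi <- min(if (i < length(pk)) tr[i + 1] - 1L else n, pk[i] + halfw)
    if (hi >= lo) pk[i] <- (lo:hi)[which.max(x[lo:hi])]
  }
  # reject residual ripple: a genuine cycle's raw amplitude sits near the
  # median; smoothing artifacts between bursts are far below it
  amp <- x[pk] - x[tr]
  keep2 <- amp >= 0.25 * stats::median(amp)
  if (!all(keep2)) {
    pk <- pk[keep2]
    if (!length(pk)) return(empty)
    tr <- locate_troughs(pk)
  }
  data.frame(trough_time = t[tr], trough_value = x[tr],
             peak_time = t[pk], peak_value = x[pk])
}

# Interpolated crossing of `level` between samples i and i+1 of (t, x).
cross_at <- function(t, x, i, level) {
  t[i] + (level - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
}

#' Burst onset/offset at a fractional trough-to-peak threshold
#'
#' For each detected cycle, the onset is the last upward crossing (before
#' the peak) of the level trough + threshold x (peak - trough); the offset
#' is the first downward crossing after the peak of the corresponding level
#' referenced to the \emph{following} trough. Crossing times are linearly
#' interpolated between samples. Cycles whose level is never crossed
#' (flat-top degenerate) are skipped with a warning.
#'
#' @param env an \code{integrated_neurogram}.
#' @param cycles output of \code{\link{detect_cycles}}.
#' @param threshold_fraction fraction of the trough-to-peak distance (0.40).
#' @param channel channel name or index.
#' @return data.frame(onset_time, offset_time) with NA rows for skipped
#'   cycles.
#' @export
burst_bounds <- function(env, cycles, threshold_fraction = 0.4, channel = 1) {
  stopifnot(inherits(env, "integrated_neurogram"),
            threshold_fraction > 0, threshold_fraction < 1)
  ci <- env_channel(env, channel)
  x <- env$env[, ci]
  fs <- env$sampling_rate
  t <- env$t0 + (seq_along(x) - 1) / fs
  nc <- nrow(cycles)
  onset <- offset <- rep(NA_real_, nc)
  skipped <- 0L
  for (i in seq_len(nc)) {
    if (!(cycles$trough_time[i] < cycles$peak_time[i])) { skipped <- skipped + 1L; next }
    ip <- which.min(abs(t - cycles$peak_time[i]))
    itr <- which.min(abs(t - cycles$trough_time[i]))
    lr <- cycles$trough_value[i] +
      threshold_fraction * (cycles$peak_value[i] - cycles$trough_value[i])
    # rising edge: last upward crossing before the peak
    j <- ip
    while (j > itr && x[j - 1] >= lr) j <- j - 1
    if (j == itr && x[itr] >= lr) { skipped <- skipped + 1L; next }
    onset[i] <- if (x[j - 1] < lr) cross_at(t, x, j - 1, lr) else t[j]
    # falling edge, referenced to the following trough
    tr2 <- if (i < nc) cycles$trough_value[i + 1] else cycles$trough_value[i]
    i_end <- if (i < nc) which.min(abs(t - cycles$trough_time[i + 1]))
             else length(x)
    lf <- tr2 + threshold_fraction * (cycles$peak_value[i] - tr2)
    j <- ip
    while (j < i_end && x[j + 1] > lf) j <- j + 1
    if (j >= i_end) { onset[i] <- NA; skipped <- skipped + 1L; next }
    offset[i] <- cross_at(t, x, j, lf)
  }
  if (skipped > 0)
    warning(skipped, " cycle(s) skipped: threshold level never crossed")
  data.frame(onset_time = onset, offset_time = offset)
}

#' Tabulate per-cycle burst metrics
#'
#' Duration (onset to offset), interburst interval (offset to next onset),
#' amplitude (peak minus preceding trough), period (onset to next onset) and
#' duty cycle (duration / period); each cycle is labeled by the epoch
#' containing its peak.
#'
#' @param cycles output of \code{\link{detect_cycles}}.
#' @param bounds output of \code{\link{burst_bounds}}.
#' @param epochs optional epoch table.
#' @param channel channel label for the table.
#' @param exclude optional list of c(start, end) intervals (seconds) of
#'   non-rhythmic activity (e.g. a detected tonic segment): bursts
#'   overlapping an interval are dropped, and the period/interval/duty of a
#'   cycle bridging one is set missing.
#' @return A \code{burst_table} data.frame; trailing/edge cycles have NA
#'   interval, period and duty cycle.
#' @export
burst_metrics <- function(cycles, bounds, epochs = NULL, channel = NA,
                          exclude = NULL) {
  ok <- !is.na(bounds$onset_time) & !is.na(bounds$offset_time)
  cycles <- cycles[ok, , drop = FALSE]
  bounds <- bounds[ok, , drop = FALSE]
  if (!is.null(exclude) && nrow(cycles)) {
    overl <- rep(FALSE, nrow(cycles))
    for (iv in exclude)
      overl <- overl | (bounds$onset_time < iv[2] & bounds$offset_time > iv[1])
    cycles <- cycles[!overl, , drop = FALSE]
    bounds <- bounds[!overl, , drop = FALSE]
  }
  nc <- nrow(cycles)
  if (nc == 0)
    return(structure(data.frame(), class = c("burst_table", "data.frame")))
  nxt_on <- c(bounds$onset_time[-1], NA)
  dur <- bounds$offset_time - bounds$onset_time
  ibi <- nxt_on - bounds$offset_time
  period <- nxt_on - bounds$onset_time
  if (!is.null(exclude)) {
    for (iv in exclude) {
      bridges <- !is.na(period) & bounds$onset_time < iv[1] & nxt_on > iv[2]
      ibi[bridges] <- NA
      period[bridges] <- NA
    }
  }
  out <- data.frame(
    channel = channel,
    trough_time = cycles$trough_time, peak_time = cycles$peak_time,
    onset_time = bounds$onset_time, offset_time = bounds$offset_time,
    burst_duration = dur, interburst_interval = ibi,
    amplitude = cycles$peak_value - cycles$trough_value,
    period = period, duty_cycle = dur / period)
  if (!is.null(epochs)) {
    out$epoch <- assign_epoch(out$peak_time, epochs)
    # a burst whose extent crosses an epoch boundary mixes the two regimes;
    # it is kept in the table but not attributed to either epoch
    inner <- epochs$start[-1]
    for (b in inner) {
      strad <- out$onset_time < b & out$offset_time > b
      out$epoch[strad] <- NA_character_
    }
  } else out$epoch <- NA_character_
  structure(out, class = c("burst_table", "data.frame"))
}

#' One-call burst table for an envelope channel
#'
#' @inheritParams detect_cycles
#' @inheritParams burst_bounds
#' @param exclude optional non-rhythmic intervals (see
#'   \code{\link{burst_metrics}}).
#' @return A \code{burst_table} (see \code{\link{burst_metrics}}).
#' @export
burst_table <- function(env, channel = 1, threshold_fraction = 0.4,
                        prominence_frac = 0.2, min_separation = NULL,
                        exclude = NULL) {
  cyc <- detect_cycles(env, channel, prominence_frac, min_separation)
  if (nrow(cyc) == 0)
    return(structure(data.frame(), class = c("burst_table", "data.frame")))
  b <- burst_bounds(env, cyc, threshold_fraction, channel)
  nm <- if (is.character(channel)) channel
        else env$channels$name[env_channel(env, channel)]
  burst_metrics(cyc, b, env$epochs, nm, exclude)
}

burst_metric_names <- c("burst_duration", "interburst_interval", "amplitude",
                        "period", "duty_cycle")

#' Per-epoch summary of burst metrics for one experiment
#'
#' Cycle measurements are averaged per trial and epoch, then across trials,
#' giving one value per experiment and epoch; percent change is relative to
#' the pre-light epoch mean (so the pre-light normalized mean is zero).
#'
#' @param tables a \code{burst_table} or list of them (one per trial).
#' @param baseline baseline epoch label ("pre").
#' @return data.frame with one row per epoch x metric: mean, sd (across
#'   cycles, pooled over trials), n_cycles, pct_change.
#' @export
epoch_summary <- function(tables, baseline = "pre") {
  if (inherits(tables, "burst_table")) tables <- list(tables)
  tables <- tables[vapply(tables, nrow, 0L) > 0]
  if (!length(tables)) stop("no cycles available for epoch summary")
  eplev <- unique(unlist(lapply(tables, function(tb) tb$epoch)))
  eplev <- eplev[!is.na(eplev)]
  if (!baseline %in% eplev)
    stop("no cycles in baseline epoch '", baseline, "'")
  rows <- NULL
  for (metric in burst_metric_names) {
    # trial means per epoch, then mean across trials
    tm <- sapply(tables, function(tb) {
      vapply(eplev, function(ep) {
        v <- tb[[metric]][tb$epoch == ep & !is.na(tb$epoch)]
        mean(v, na.rm = TRUE)
      }, numeric(1))
    })
    tm <- matrix(tm, nrow = length(eplev))
    em <- rowMeans(tm, na.rm = TRUE)
    base <- em[match(baseline, eplev)]
    pooled <- lapply(eplev, function(ep)
      unlist(lapply(tables, function(tb)
        tb[[metric]][tb$epoch == ep & !is.na(tb$epoch)])))
    rows <- rbind(rows, data.frame(
      epoch = eplev, metric = metric, mean = em,
      sd = vapply(pooled, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
      n_cycles = vapply(pooled, function(v) sum(!is.na(v)), numeric(1)),
      pct_change = 100 * (em / base - 1)))
  }
  rownames(rows) <- NULL
  rows
}

#' Cross-experiment aggregation of epoch summaries
#'
#' Experiment-level values (already trial-averaged) are averaged across
#' experiments, mirroring the trial -> experiment -> group averaging order.
#'
#' @param summaries list of \code{\link{epoch_summary}} outputs.
#' @return data.frame(epoch, metric, mean, sd, pct_change_mean,
#'   pct_change_sd, n_experiments).
#' @export
aggregate_epoch_summaries <- function(summaries) {
  summaries <- Filter(Negate(is.null), summaries)
  stopifnot(length(summaries) >= 1)
  key <- unique(do.call(rbind, lapply(summaries, function(s)
    s[, c("epoch", "metric")])))
  out <- NULL
  for (i in seq_len(nrow(key))) {
    vals <- vapply(summaries, function(s) {
      r <- s$epoch == key$epoch[i] & s$metric == key$metric[i]
      if (any(r)) s$mean[r][1] else NA_real_
    }, numeric(1))
    pcs <- vapply(summaries, function(s) {
      r <- s$epoch == key$epoch[i] & s$metric == key$metric[i]
      if (any(r)) s$pct_change[r][1] else NA_real_
    }, numeric(1))
    out <- rbind(out, data.frame(
      epoch = key$epoch[i], metric = key$metric[i],
      mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
      pct_change_mean = mean(pcs, na.rm = TRUE),
      pct_change_sd = stats::sd(pcs, na.rm = TRUE),
      n_experiments = sum(!is.na(vals))))
  }
  out
}
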