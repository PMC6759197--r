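# Intracellular membrane-potential analysis: spike detection, cycle-
# triggered averages of the locomotor drive, and input resistance.

#' Detect action potentials
#'
#' Upward threshold crossings confirmed by a minimum dV/dt, with refractory
#' enforcement. Zero spikes is a valid result.
#'
#' @param trace an \code{intracellular_trace} (list with \code{vm}, mV, and
#'   \code{sampling_rate}, Hz >= 5 kHz) or a numeric vector (then supply
#'   \code{sampling_rate}).
#' @param threshold absolute voltage threshold, mV (-20).
#' @param dvdt_min slope confirmation, V/s (10).
#' @param refractory minimum inter-spike interval, s (0.002).
#' @param sampling_rate Hz, when \code{trace} is a bare vector.
#' @return spike times in seconds.
#' @export
detect_spikes <- function(trace, threshold = -20, dvdt_min = 10,
                          refractory = 0.002, sampling_rate = NULL) {
  if (inherits(trace, "intracellular_trace")) {
    vm <- trace$vm; fs <- trace$sampling_rate
  } else { vm <- trace; fs <- sampling_rate }
  stopifnot(!is.null(fs))
  if (fs < 5000) stop("spike detection needs sampling >= 5 kHz")
  up <- which(vm[-1] >= threshold & vm[-length(vm)] < threshold)
  if (!length(up)) return(numeric(0))
  dv <- (vm[up + 1] - vm[up]) * fs / 1000  # V/s
  up <- up[dv >= dvdt_min]
  if (!length(up)) return(numeric(0))
  tt <- up / fs
  out <- tt[1]
  for (x in tt[-1]) if (x - out[length(out)] >= refractory) out <- c(out, x)
  out
}

#' Cycle-triggered average of the locomotor drive
#'
#' Spikes are removed with a running-median filter (15 ms), each cycle
#' (onset to next onset) is resampled onto a common phase grid, and the
#' mean and SD waveforms are duplicated to show two cycles. Drive amplitude
#' is max - min of the mean waveform; the trough potential is its minimum.
#'
#' @param trace an \code{intracellular_trace} or numeric vector (mV).
#' @param onsets cycle onset times, seconds (>= 3 complete cycles for SD).
#' @param sampling_rate Hz, when \code{trace} is a bare vector.
#' @param n_bins phase bins per cycle (200).
#' @param spike_filter_ms running-median width for spike removal, ms (15;
#'   0 disables).
#' @return A \code{cycle_triggered_average}: list(phase (two cycles, in
#'   cycle units), mean, sd, n_cycles, amplitude, trough).
#' @export
cycle_triggered_average <- function(trace, onsets, sampling_rate = NULL,
                                    n_bins = 200, spike_filter_ms = 15) {
  if (inherits(trace, "intracellular_trace")) {
    vm <- trace$vm; fs <- trace$sampling_rate
  } else { vm <- trace; fs <- sampling_rate }
  stopifnot(!is.null(fs))
  onsets <- sort(onsets)
  n_cyc <- length(onsets) - 1
  if (n_cyc < 1) stop("need at least one complete cycle")
  x <- vm
  if (spike_filter_ms > 0) {
    k <- max(3L, round(spike_filter_ms / 1000 * fs))
    if (k %% 2 == 0) k <- k + 1L
    if (k < length(x)) x <- stats::runmed(x, k, endrule = "median")
  }
  t <- (seq_along(x) - 1) / fs
  M <- matrix(NA_real_, n_cyc, n_bins)
  for (i in seq_len(n_cyc)) {
    ph <- onsets[i] + (seq_len(n_bins) - 0.5) / n_bins *
      (onsets[i + 1] - onsets[i])
    if (ph[n_bins] > t[length(t)] || ph[1] < 0) next
    M[i, ] <- stats::approx(t, x, ph)$y
  }
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 1) stop("no complete cycles overlap the trace")
  mu <- colMeans(M)
  sdv <- if (nrow(M) >= 3) apply(M, 2, stats::sd) else rep(NA_real_, n_bins)
  structure(list(phase = (seq_len(2 * n_bins) - 0.5) / n_bins,
                 mean = rep(mu, 2), sd = rep(sdv, 2), n_cycles = nrow(M),
                 amplitude = max(mu) - min(mu), trough = min(mu),
                 sd_available = nrow(M) >= 3),
            class = "cycle_triggered_average")
}

#' Input resistance from a current/voltage plot
#'
#' Ordinary least-squares slope of steady-state voltage against injected
#' current over the linear range: the largest contiguous subset (>= 3
#' steps) whose maximum absolute residual stays below
#' \code{linearity_tol} x the fitted voltage span.
#'
#' @param current injected current steps, nA.
#' @param voltage steady-state voltage responses, mV.
#' @param linearity_tol residual tolerance as a fraction of the fitted span
#'   (0.02).
#' @return list(resistance (MOhm = mV/nA), intercept, used (logical mask of
#'   points in the linear range)).
#' @export
input_resistance <- function(current, voltage, linearity_tol = 0.02) {
  stopifnot(length(current) == length(voltage))
  n <- length(current)
  if (n < 3) stop("input resistance needs >= 3 current steps")
  ord <- order(current)
  I <- current[ord]; V <- voltage[ord]
  best <- NULL
  for (len in n:3) {
    for (s in 1:(n - len + 1)) {
      idx <- s:(s + len - 1)
      fit <- stats::lm(V[idx] ~ I[idx])
      span <- diff(range(stats::fitted(fit)))
      if (span == 0) next
      if (max(abs(stats::residuals(fit))) <= linearity_tol * span) {
        best <- list(idx = idx, fit = fit)
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    stop("no contiguous linear range of >= 3 points found")
  used <- logical(n); used[best$idx] <- TRUE
  used_orig <- logical(n); used_orig[ord[best$idx]] <- TRUE
  list(resistance = unname(stats::coef(best$fit)[2]),
       intercept = unname(stats::coef(best$fit)[1]),
       used = used_orig)
}

#' Spikes per cycle
#'
#' Counts spike times within [onset, next onset) for each complete cycle.
#'
#' @param spike_times seconds.
#' @param onsets cycle onset times, seconds.
#' @return integer vector, one count per complete cycle.
#' @export
spikes_per_cycle <- function(spike_times, onsets) {
  onsets <- sort(onsets)
  n_cyc <- length(onsets) - 1
  vapply(seq_len(n_cyc), function(i)
    sum(spike_times >= onsets[i] & spike_times < onsets[i + 1]), integer(1))
}
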