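# Wavelet rhythm tracking: complex Morlet spectrograms on a log-spaced
# frequency grid, ridge frequency extraction, cross-wavelet phase, edge
# trimming, baseline normalization, and tonic-segment flagging.

#' Rhythm series container
#'
#' @param time numeric time vector (seconds, absolute).
#' @param value numeric values.
#' @param kind "frequency", "phase", "envelope-level" or "percent-change".
#' @param units unit string.
#' @param channel channel (or pair) identity.
#' @param epochs epoch table or NULL.
#' @param trim edge trim already applied, seconds.
#' @return data.frame of class \code{rhythm_series} with metadata attributes.
#' @export
rhythm_series <- function(time, value, kind, units, channel = NA,
                          epochs = NULL, trim = 0) {
  out <- data.frame(time = time, value = value)
  attr(out, "kind") <- kind
  attr(out, "units") <- units
  attr(out, "channel") <- channel
  attr(out, "epochs") <- epochs
  attr(out, "trim") <- trim
  class(out) <- c("rhythm_series", "data.frame")
  out
}

# Morlet Fourier factor: frequency = 1 / (lambda * scale).
morlet_lambda <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Complex Morlet wavelet spectrogram
#'
#' Continuous wavelet transform of one envelope channel on a log-spaced
#' frequency grid spanning the rhythm band, with the time axis resampled to
#' exactly \code{n_bins} points (3,200 by default) over the analysis window.
#'
#' @param env an \code{integrated_neurogram} at 19 Hz (or finer).
#' @param channel channel name or index (default 1).
#' @param band numeric c(fmin, fmax), Hz. Defaults to [0.05, 2] for drug
#'   episodes and [0.2, 4] for evoked episodes.
#' @param n_bins output time bins (3,200).
#' @param voices frequencies per octave on the log grid.
#' @param omega0 Morlet center-frequency parameter (6).
#' @return A \code{loco_spectrogram}: complex coefficients \code{W}
#'   (frequency x time), amplitude-normalized magnitude \code{mag},
#'   frequency grid, time grid, and the mother-wavelet parameters.
#' @export
wavelet_spectrogram <- function(env, channel = 1, band = NULL, n_bins = 3200,
                                voices = 16, omega0 = 6) {
  stopifnot(inherits(env, "integrated_neurogram"))
  if (is.character(channel)) channel <- match(channel, env$channels$name)
  if (is.na(channel)) stop("unknown channel")
  if (is.null(band)) band <- if (env$mode == "evoked") c(0.2, 4) else c(0.05, 2)
  x <- env$env[, channel]
  n <- length(x)
  fs <- env$sampling_rate
  dur <- (n - 1) / fs
  if (dur < 3 / band[1])
    stop("duration ", round(dur, 1), " s too short for lowest analyzed ",
         "frequency ", band[1], " Hz (need >= 3 periods)")
  x <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  xh <- stats::fft(c(x, numeric(npad - n)))
  wk <- 2 * pi * c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad / fs)
  lam <- morlet_lambda(omega0)
  n_oct <- log2(band[2] / band[1])
  freqs <- band[1] * 2^(seq(0, n_oct, by = 1 / voices))
  scales <- 1 / (lam * freqs)
  W <- matrix(0 + 0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- scales[i]
    psi <- sqrt(2 * pi * s * fs) * pi^-0.25 *
      exp(-0.5 * (s * wk - omega0)^2) * (wk > 0)
    W[i, ] <- stats::fft(xh * psi, inverse = TRUE)[seq_len(n)] / npad
  }
  t_in <- env$t0 + (seq_len(n) - 1) / fs
  t_out <- seq(t_in[1], t_in[n], length.out = n_bins)
  Wout <- matrix(0 + 0i, length(freqs), n_bins)
  for (i in seq_along(freqs)) {
    Wout[i, ] <- stats::approx(t_in, Re(W[i, ]), t_out)$y +
      1i * stats::approx(t_in, Im(W[i, ]), t_out)$y
  }
  mag <- abs(Wout) / sqrt(scales)  # amplitude-normalized across frequencies
  structure(list(W = Wout, mag = mag, freqs = freqs, times = t_out,
                 band = band, omega0 = omega0, voices = voices,
                 channel = env$channels$name[channel], epochs = env$epochs,
                 mode = env$mode),
            class = "loco_spectrogram")
}

#' Extract the ridge-frequency time series from a spectrogram
#'
#' Per time bin, the ridge frequency is the argmax of the
#' amplitude-normalized wavelet magnitude over the band, refined to sub-bin
#' precision by a parabolic fit through the peak and its neighbors on the
#' log-frequency grid, then median-smoothed. All-zero columns yield missing
#' values (not zeros).
#'
#' @param spec a \code{loco_spectrogram}.
#' @param smooth_bins median-filter window (odd; default 5).
#' @return A \code{\link{rhythm_series}} of kind "frequency" (Hz).
#' @export
extract_frequency <- function(spec, smooth_bins = 5) {
  stopifnot(inherits(spec, "loco_spectrogram"))
  peak <- apply(spec$mag, 2, function(col) {
    if (all(col == 0) || all(!is.finite(col))) NA_integer_ else which.max(col)
  })
  ridge <- spec$freqs[peak]
  # parabolic refinement on the log2-frequency grid; the fit uses
  # log-magnitude with the sqrt(f) amplitude-normalization tilt removed,
  # which is exactly parabolic for a Morlet responding to a single tone
  nf <- length(spec$freqs)
  dlog <- log2(spec$freqs[2] / spec$freqs[1])
  interior <- which(!is.na(peak) & peak > 1 & peak < nf)
  if (length(interior)) {
    i <- peak[interior]
    eps <- .Machine$double.xmin
    z <- function(k) log(pmax(spec$mag[cbind(k, interior)], eps)) -
      0.5 * log(spec$freqs[k])
    z0 <- z(i - 1); z1 <- z(i); z2 <- z(i + 1)
    den <- z0 - 2 * z1 + z2
    delta <- ifelse(is.finite(den) & abs(den) > .Machine$double.eps,
                    0.5 * (z0 - z2) / den, 0)
    delta <- pmax(pmin(delta, 0.5), -0.5)
    ridge[interior] <- spec$freqs[i] * 2^(delta * dlog)
  }
  if (smooth_bins > 1 && sum(!is.na(ridge)) > smooth_bins) {
    filled <- ridge
    if (anyNA(filled)) {
      ok <- which(!is.na(filled))
      filled <- stats::approx(ok, filled[ok], seq_along(filled), rule = 2)$y
    }
    sm <- stats::runmed(filled, k = smooth_bins, endrule = "median")
    sm[is.na(ridge)] <- NA
    ridge <- sm
  }
  rhythm_series(spec$times, ridge, "frequency", "Hz", spec$channel,
                spec$epochs)
}

#' Inter-channel phase time series from a spectrogram pair
#'
#' Per bin, the phase difference is the argument of the cross-wavelet
#' coefficient \eqn{W_A \bar{W}_B} evaluated at the reference (first)
#' channel's ridge frequency, wrapped to [0, 360). A positive phase means
#' the second channel lags the reference.
#'
#' @param spec_a,spec_b spectrograms of the two channels on a shared grid;
#'   \code{spec_a} is the reference.
#' @return A \code{\link{rhythm_series}} of kind "phase" (degrees).
#' @export
extract_phase <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "loco_spectrogram"),
            inherits(spec_b, "loco_spectrogram"))
  if (!isTRUE(all.equal(spec_a$times, spec_b$times)) ||
      !isTRUE(all.equal(spec_a$freqs, spec_b$freqs)))
    stop("the two spectrograms must share the time and frequency grids")
  peak <- apply(spec_a$mag, 2, function(col)
    if (all(col == 0)) NA_integer_ else which.max(col))
  nb <- ncol(spec_a$W)
  ph <- rep(NA_real_, nb)
  ok <- which(!is.na(peak))
  idx <- cbind(peak[ok], ok)
  cross <- spec_a$W[idx] * Conj(spec_b$W[idx])
  ph[ok] <- wrap360(rad2deg(Arg(cross)))
  rhythm_series(spec_a$times, ph, "phase", "degrees",
                paste0(spec_a$channel, "-", spec_b$channel), spec_a$epochs)
}

#' Trim wavelet edge artifacts from a series
#'
#' @param series a \code{\link{rhythm_series}}.
#' @param trim seconds removed from each end (default 10).
#' @return The trimmed series (epoch table untouched: absolute times).
#' @export
trim_edges <- function(series, trim = 10) {
  stopifnot(inherits(series, "rhythm_series"), trim >= 0)
  if (trim == 0) return(series)
  span <- max(series$time) - min(series$time)
  if (span <= 2 * trim)
    stop("series (", round(span, 1), " s) too short to trim ", trim,
         " s from each end")
  keep <- series$time >= min(series$time) + trim &
          series$time <= max(series$time) - trim
  out <- rhythm_series(series$time[keep], series$value[keep],
                       attr(series, "kind"), attr(series, "units"),
                       attr(series, "channel"), attr(series, "epochs"),
                       trim = attr(series, "trim") + trim)
  out
}

#' Normalize a series to percent change from baseline
#'
#' out(t) = 100 (x(t) / mean_baseline - 1), so the baseline epoch averages
#' zero. Applies to frequency series and to resampled integrated envelopes.
#'
#' @param series a \code{\link{rhythm_series}}.
#' @param baseline baseline epoch label (default "pre").
#' @return A \code{\link{rhythm_series}} of kind "percent-change" (%).
#' @export
normalize_percent_change <- function(series, baseline = "pre") {
  stopifnot(inherits(series, "rhythm_series"))
  epochs <- attr(series, "epochs")
  if (is.null(epochs) || !baseline %in% epochs$label)
    stop("baseline epoch '", baseline, "' not present")
  lab <- assign_epoch(series$time, epochs)
  base <- series$value[lab == baseline & !is.na(lab)]
  m <- mean(base, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("baseline epoch mean must be positive (got ", format(m), ")")
  rhythm_series(series$time, 100 * (series$value / m - 1), "percent-change",
                "%", attr(series, "channel"), epochs, attr(series, "trim"))
}

#' Convert a resampled envelope channel to a rhythm series
#'
#' Convenience for normalizing integrated neurograms to the control period
#' like the frequency series.
#'
#' @param env an \code{integrated_neurogram}.
#' @param channel channel name or index.
#' @return A \code{\link{rhythm_series}} of kind "envelope-level".
#' @export
envelope_series <- function(env, channel = 1) {
  stopifnot(inherits(env, "integrated_neurogram"))
  if (is.character(channel)) channel <- match(channel, env$channels$name)
  n <- nrow(env$env)
  rhythm_series(env$t0 + (seq_len(n) - 1) / env$sampling_rate,
                env$env[, channel], "envelope-level", "a.u.",
                env$channels$name[channel], env$epochs)
}

#' Flag tonic (elevated, non-oscillatory) segments
#'
#' A bin is flagged tonic when its rhythm-band oscillation amplitude falls
#' below an adaptive threshold while the envelope level exceeds its baseline
#' median. The oscillation cue is the magnitude of a single-frequency
#' complex Morlet coefficient at the light-epoch ridge frequency, computed
#' on the running-median-detrended envelope (detrending removes the slow
#' pedestal a tonic plateau would otherwise leak into the rhythm band). The
#' threshold is the midpoint between the light-epoch amplitude floor and its
#' rhythmic level, which places the tonic-to-rhythmic boundary at the
#' half-rise point of the wavelet's symmetric temporal smearing.
#'
#' @param env the (19 Hz) \code{integrated_neurogram} used for the level cue.
#' @param spec the matching \code{loco_spectrogram} (supplies the ridge
#'   frequencies and time grid).
#' @param channel envelope channel matching \code{spec}.
#' @param power_floor_frac if the light-epoch amplitude floor exceeds this
#'   fraction of the light rhythmic level, no bin is tonic (default 0.5).
#' @return A \code{tonic_mask}: list(mask = data.frame(time, tonic),
#'   params).
#' @export
flag_tonic <- function(env, spec, channel = NULL, power_floor_frac = 0.5) {
  stopifnot(inherits(env, "integrated_neurogram"),
            inherits(spec, "loco_spectrogram"))
  if (is.null(channel)) channel <- spec$channel
  if (is.character(channel)) channel <- match(channel, env$channels$name)
  nb <- length(spec$times)
  out <- data.frame(time = spec$times, tonic = rep(FALSE, nb))
  params <- list(power_floor_frac = power_floor_frac)
  epochs <- spec$epochs
  mk <- function() structure(list(mask = out, params = params),
                             class = "tonic_mask")

  lev <- stats::approx(env$t0 + (seq_len(nrow(env$env)) - 1) / env$sampling_rate,
                       env$env[, channel], spec$times, rule = 2)$y
  if (all(lev == 0) || is.null(epochs)) return(mk())
  lab <- assign_epoch(spec$times, epochs)
  pre <- lab == "pre" & !is.na(lab)
  lit <- lab == "light" & !is.na(lab)
  if (!any(pre) || !any(lit)) return(mk())

  ridge <- apply(spec$mag, 2, function(col)
    if (all(col == 0)) NA_integer_ else which.max(col))
  if (all(is.na(ridge[pre]))) return(mk())
  f_ref <- stats::median(spec$freqs[ridge[pre]], na.rm = TRUE)
  # rhythm frequency inside the light window: the late-half ridge median is
  # robust to an initial tonic stretch
  lit_idx <- which(lit)
  late <- lit_idx[lit_idx > stats::median(lit_idx)]
  f_lit <- stats::median(spec$freqs[ridge[late]], na.rm = TRUE)
  if (!is.finite(f_lit)) f_lit <- f_ref

  # single-frequency Morlet amplitude at the light rhythm frequency,
  # computed on the running-median-detrended envelope. The detection
  # wavelet uses a low center parameter (3): its temporal support is half
  # that of the analysis Morlet, so a tonic plateau of about one cycle is
  # not bridged by leakage from the flanking rhythm.
  omega_det <- 3
  dt <- stats::median(diff(spec$times))
  fs_b <- 1 / dt
  k_med <- round(1.5 / f_ref * fs_b)
  if (k_med %% 2 == 0) k_med <- k_med + 1
  k_med <- min(k_med, nb - (1 - nb %% 2))
  xd <- lev - stats::runmed(lev, k_med, endrule = "median")
  npad <- 2^ceiling(log2(nb))
  xh <- stats::fft(c(xd - mean(xd), numeric(npad - nb)))
  wk <- 2 * pi * c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * dt)
  s <- 1 / (morlet_lambda(omega_det) * f_lit)
  psi <- sqrt(2 * pi * s * fs_b) * pi^-0.25 *
    exp(-0.5 * (s * wk - omega_det)^2) * (wk > 0)
  A <- Mod(stats::fft(xh * psi, inverse = TRUE)[seq_len(nb)] / npad)

  A_low <- stats::quantile(A[lit], 0.02, names = FALSE)
  A_high <- stats::quantile(A[lit], 0.8, names = FALSE)
  if (A_high <= 0 || A_low >= power_floor_frac * A_high) return(mk())

  elevated <- lev > stats::median(lev[pre])
  close_gap <- max(1L, round(0.8 / f_lit * fs_b))
  min_run <- max(1L, round(0.8 / f_lit * fs_b))
  # tonic onsets are a light-window phenomenon: the baseline that defines
  # "rhythmic" is the pre epoch itself. Sub-cycle gaps are closed (a
  # genuine rhythm resumption keeps the amplitude up for at least a
  # cycle) and runs shorter than ~one cycle are dropped: tonic activity
  # is sustained.
  mask_at <- function(thr) {
    cand <- lit & A < thr & elevated
    r <- rle(cand)
    inner <- which(!r$values & r$lengths < close_gap &
                     seq_along(r$values) > 1 &
                     seq_along(r$values) < length(r$values))
    r$values[inner] <- TRUE
    cand <- inverse.rle(r)
    r <- rle(cand)
    r$values[r$values & r$lengths < min_run] <- FALSE
    inverse.rle(r)
  }
  thr <- 0.5 * (A_low + A_high)
  tonic <- mask_at(thr)
  if (any(tonic)) {
    # refine once: the boundary sits at the half-rise between the detected
    # plateau's own amplitude floor and the rhythmic level, which corrects
    # the undershoot a global (2nd-percentile) floor would cause
    A_floor <- stats::median(A[tonic])
    thr2 <- 0.5 * (A_floor + A_high)
    if (thr2 > thr && thr2 < A_high) {
      tonic2 <- mask_at(thr2)
      if (any(tonic2)) { tonic <- tonic2; thr <- thr2 }
    }
  }
  out$tonic <- tonic
  params$threshold <- thr
  params$f_ref <- f_ref
  params$f_light <- f_lit
  params$contrast <- A_high / max(A_low, .Machine$double.eps)
  mk()
}

#' Extent of the tonic run at light onset
#'
#' @param mask a \code{tonic_mask}.
#' @param light_on light-onset time, seconds.
#' @return Length (s) of the contiguous tonic run starting at (or spanning)
#'   light onset; 0 if none.
#' @export
tonic_extent <- function(mask, light_on) {
  m <- mask$mask
  if (!any(m$tonic)) return(0)
  r <- rle(m$tonic)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dt <- stats::median(diff(m$time))
  for (i in which(r$values)) {
    t0 <- m$time[starts[i]]; t1 <- m$time[ends[i]]
    if (t0 <= light_on + 2 && t1 >= light_on) return(t1 - max(t0, light_on) + dt)
  }
  0
}

#' Epoch means of a rhythm series
#'
#' Pairwise-complete means of the series inside each epoch. For wavelet-
#' derived frequency series, bins within one wavelet e-folding time
#' (about 1.37 / f for a Morlet with center parameter 6) of an epoch
#' boundary or of a masked-out run are temporally smeared across the
#' transition; \code{guard_efold} erodes them before averaging, the same
#' rationale as the 10 s edge trim at the record ends.
#'
#' @param series a \code{\link{rhythm_series}}.
#' @param mask optional \code{tonic_mask}; tonic bins are excluded.
#' @param guard_efold number of wavelet e-folding times to erode around
#'   epoch boundaries and masked runs (0 = no erosion). The e-folding time
#'   is estimated per epoch from the epoch's own median frequency; for
#'   non-frequency series a guard in seconds may be given via
#'   \code{guard_s}.
#' @param guard_s fixed guard in seconds (overrides \code{guard_efold}).
#' @return data.frame(epoch, mean, n).
#' @export
epoch_means <- function(series, mask = NULL, guard_efold = 0, guard_s = NULL) {
  epochs <- attr(series, "epochs")
  if (is.null(epochs)) stop("series carries no epoch table")
  lab <- assign_epoch(series$time, epochs)
  val <- series$value
  dt <- stats::median(diff(series$time))
  bad <- rep(FALSE, length(val))
  if (!is.null(mask)) {
    tn <- stats::approx(mask$mask$time, as.numeric(mask$mask$tonic),
                        series$time, method = "constant", rule = 2)$y
    bad <- tn > 0.5
    val[bad] <- NA
  }
  do.call(rbind, lapply(epochs$label, function(ep) {
    inside <- lab == ep & !is.na(lab)
    keep <- inside
    g_s <- guard_s
    if (is.null(g_s) && guard_efold > 0) {
      f_ep <- stats::median(val[inside], na.rm = TRUE)
      g_s <- if (is.finite(f_ep) && f_ep > 0 &&
                 attr(series, "kind") == "frequency")
        guard_efold * 1.37 / f_ep else 0
    }
    if (!is.null(g_s) && g_s > 0) {
      g <- round(g_s / dt)
      if (g > 0) {
        idx <- which(inside)
        # erode near the epoch's ends
        drop <- idx[idx - idx[1] < g | idx[length(idx)] - idx < g]
        # erode near masked-out runs
        if (any(bad)) {
          widen <- stats::filter(as.numeric(bad), rep(1, 2 * g + 1),
                                 sides = 2)
          widen[is.na(widen)] <- 0
          drop <- union(drop, idx[widen[idx] > 0])
        }
        keep[drop] <- FALSE
      }
    }
    v <- val[keep]
    data.frame(epoch = ep, mean = mean(v, na.rm = TRUE),
               n = sum(!is.na(v)))
  }))
}
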