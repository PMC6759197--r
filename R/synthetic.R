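# Synthetic fictive-locomotion recordings with exported ground truth.
#
# The generator emulates multi-channel lumbar ventral-root neurograms: a
# common phase oscillator drives per-channel envelopes (periodic rectangular
# pulses of programmed duty cycle and phase, smoothed by a raised-cosine
# edge), which gate a zero-mean broadband carrier on top of baseline noise.
# A light window can rescale frequency, amplitude and duty cycle, and an
# optional tonic onset (hemicord scenario) clamps the envelope high while the
# oscillator is frozen. All programmed quantities are exported as ground
# truth for parameter-recovery testing.

#' Recording/illumination protocol
#'
#' @param total_duration recording length, seconds.
#' @param light_on,light_off illumination window, seconds (NULL for none).
#' @param sampling_rate sampling rate, Hz.
#' @param stim optional stimulus-train spec: list with elements \code{start}
#'   (s), \code{rate} (Hz), \code{train_duration} (s), \code{pulse_width} (s).
#' @return An object of class \code{loco_protocol}.
#' @export
protocol <- function(total_duration = 180, light_on = 60, light_off = 120,
                     sampling_rate = 10000, stim = NULL) {
  stopifnot(total_duration > 0, sampling_rate > 0)
  if (!is.null(light_on) || !is.null(light_off)) {
    stopifnot(!is.null(light_on), !is.null(light_off))
    if (!(light_on > 0 && light_off > light_on && light_off < total_duration))
      stop("light window must lie strictly inside the recording")
  }
  if (!is.null(stim)) {
    stopifnot(all(c("start", "rate", "train_duration") %in% names(stim)))
    if (is.null(stim$pulse_width)) stim$pulse_width <- 2.5e-4
    pulses <- stim$start + seq(0, stim$train_duration - 1e-12, by = 1 / stim$rate)
    if (min(pulses) < 0 || max(pulses) + stim$pulse_width > total_duration)
      stop("stimulus train pulses must all lie inside the recording")
    stim$pulse_times <- pulses
  }
  structure(list(total_duration = total_duration, light_on = light_on,
                 light_off = light_off, sampling_rate = sampling_rate,
                 stim = stim),
            class = "loco_protocol")
}

#' Rhythm specification for the neurogram generator
#'
#' @param base_frequency locomotor frequency before the light, Hz.
#' @param channels data.frame with one row per channel and columns
#'   \code{name}, \code{role} ("flexor" or "extensor"), \code{side},
#'   \code{phase_offset} (degrees), \code{duty} (fraction in (0,1)),
#'   \code{amplitude} (a.u.), and optional per-channel light factors
#'   \code{light_amp_factor}, \code{light_duty_factor}.
#' @param light_freq_factor multiplicative frequency factor inside the light
#'   window (outside any tonic onset).
#' @param tonic_onset duration (s) of tonic, non-oscillatory activity at light
#'   onset (0 = none); the oscillator is frozen and the envelope clamped high.
#' @param edge_frac raised-cosine edge width as a fraction of the cycle period.
#' @param baseline_noise_sd additive baseline noise SD (a.u.).
#' @param amp_jitter_sd per-burst multiplicative amplitude jitter SD.
#' @param freq_wander_sd reserved for cycle-to-cycle frequency wander
#'   (default 0: the programmed profile is exact).
#' @param carrier "noise" (zero-mean Gaussian broadband) or "spikes"
#'   (rate-modulated biphasic spike train).
#' @return An object of class \code{loco_rhythm_spec}.
#' @export
rhythm_spec <- function(base_frequency, channels, light_freq_factor = 1,
                        tonic_onset = 0, edge_frac = 0.1,
                        baseline_noise_sd = 0.05, amp_jitter_sd = 0.05,
                        freq_wander_sd = 0, carrier = c("noise", "spikes")) {
  carrier <- match.arg(carrier)
  stopifnot(base_frequency > 0, light_freq_factor > 0, tonic_onset >= 0,
            edge_frac >= 0, edge_frac < 0.5)
  need <- c("name", "role", "phase_offset", "duty", "amplitude")
  if (!all(need %in% names(channels)))
    stop("channels must have columns: ", paste(need, collapse = ", "))
  if (is.null(channels$side)) channels$side <- "left"
  if (is.null(channels$light_amp_factor)) channels$light_amp_factor <- 1
  if (is.null(channels$light_duty_factor)) channels$light_duty_factor <- 1
  if (any(channels$duty <= 0 | channels$duty >= 1))
    stop("duty_cycle must lie in (0, 1)")
  if (any(channels$light_amp_factor <= 0) || any(channels$light_duty_factor <= 0))
    stop("light modulation factors must be > 0")
  channels$phase_offset <- wrap360(channels$phase_offset)
  structure(list(base_frequency = base_frequency, channels = channels,
                 light_freq_factor = light_freq_factor,
                 tonic_onset = tonic_onset, edge_frac = edge_frac,
                 baseline_noise_sd = baseline_noise_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 freq_wander_sd = freq_wander_sd, carrier = carrier),
            class = "loco_rhythm_spec")
}

#' Multi-channel raw recording container
#'
#' @param data numeric matrix, samples x channels.
#' @param sampling_rate Hz.
#' @param channels data.frame of channel metadata (name, role, side).
#' @param events list with optional \code{light_on}, \code{light_off},
#'   \code{stim_times} (seconds).
#' @param group group/genotype label.
#' @return Object of class \code{raw_recording}.
#' @export
raw_recording <- function(data, sampling_rate, channels, events = list(),
                          group = "unlabelled") {
  data <- as.matrix(data)
  stopifnot(nrow(channels) == ncol(data), sampling_rate > 0)
  dur <- nrow(data) / sampling_rate
  for (ev in c("light_on", "light_off")) {
    if (!is.null(events[[ev]]) && (events[[ev]] < 0 || events[[ev]] > dur))
      stop("event '", ev, "' lies outside the recording")
  }
  colnames(data) <- channels$name
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = channels, events = events, group = group,
                 duration = dur),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", ncol(x$data), " channel(s), ",
      format(x$duration), " s at ", x$sampling_rate, " Hz\n", sep = "")
  cat("  channels:", paste(x$channels$name, collapse = ", "), "\n")
  if (!is.null(x$events$light_on))
    cat("  light: ", x$events$light_on, "-", x$events$light_off, " s\n", sep = "")
  invisible(x)
}

# Piecewise-constant frequency profile as segments (t0, t1, f); phase is
# measured in cycles. Returns the table plus cumulative phase at segment
# starts, supporting exact (analytic) burst-boundary computation.
freq_segments <- function(proto, base, light_factor, tonic) {
  dur <- proto$total_duration
  if (is.null(proto$light_on)) {
    seg <- data.frame(t0 = 0, t1 = dur, f = base)
  } else {
    on <- proto$light_on; off <- proto$light_off
    tonic <- min(tonic, off - on)
    seg <- data.frame(
      t0 = c(0, if (tonic > 0) on else NULL, on + tonic, off),
      t1 = c(on, if (tonic > 0) on + tonic else NULL, off, dur),
      f  = c(base, if (tonic > 0) 0 else NULL, base * light_factor, base))
  }
  seg <- seg[seg$t1 > seg$t0, , drop = FALSE]
  seg$p0 <- cumsum(c(0, (seg$f * (seg$t1 - seg$t0))[-nrow(seg)]))
  seg$p1 <- seg$p0 + seg$f * (seg$t1 - seg$t0)
  seg
}

# Earliest time at which cumulative phase (cycles) reaches `p`; frozen
# (f = 0) segments are skipped, so a crossing deferred by a tonic plateau
# resolves at the plateau's end. NA if never reached.
phase_time <- function(seg, p) {
  out <- rep(NA_real_, length(p))
  for (j in seq_along(p)) {
    for (i in seq_len(nrow(seg))) {
      if (seg$f[i] > 0 && p[j] >= seg$p0[i] - 1e-12 && p[j] <= seg$p1[i] + 1e-12) {
        out[j] <- seg$t0[i] + (p[j] - seg$p0[i]) / seg$f[i]
        break
      }
    }
  }
  out
}

# Cumulative phase (cycles) at arbitrary times.
phase_at <- function(seg, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    sel <- t >= seg$t0[i] & t <= seg$t1[i]
    out[sel] <- seg$p0[i] + seg$f[i] * (t[sel] - seg$t0[i])
  }
  out
}

#' Simulate multi-channel ventral-root neurograms
#'
#' Generates a seeded synthetic recording in which every channel's envelope
#' is a smoothed periodic pulse of programmed duty cycle and phase, driven by
#' a common phase oscillator whose instantaneous frequency follows the
#' programmed profile (light factor applied inside the light window; during a
#' tonic onset the envelope is held elevated and non-oscillatory). The output
#' trace is baseline noise plus envelope times a zero-mean broadband carrier.
#'
#' @param proto a \code{\link{protocol}}.
#' @param spec a \code{\link{rhythm_spec}}.
#' @param n_channels number of channels (defaults to all rows of
#'   \code{spec$channels}).
#' @param seed integer seed; output is bit-identical for identical
#'   \code{(spec, seed)}.
#' @param group group label attached to the recording.
#' @return list with elements \code{recording} (a \code{raw_recording}) and
#'   \code{truth} (a \code{ground_truth}).
#' @export
simulate_neurograms <- function(proto, spec, n_channels = nrow(spec$channels),
                                seed = 1, group = "synthetic") {
  stopifnot(inherits(proto, "loco_protocol"), inherits(spec, "loco_rhythm_spec"),
            n_channels >= 1, n_channels <= nrow(spec$channels))
  fs <- proto$sampling_rate
  dur <- proto$total_duration
  chan <- spec$channels[seq_len(n_channels), , drop = FALSE]

  # reject specs whose shortest burst is under 2 samples
  fmax <- spec$base_frequency * max(1, spec$light_freq_factor)
  min_dur <- min(chan$duty * pmin(chan$light_duty_factor, 1)) / fmax
  if (min_dur * fs < 2)
    stop("duty x period shorter than 2 samples; rejecting rhythm spec")

  seg <- freq_segments(proto, spec$base_frequency, spec$light_freq_factor,
                       spec$tonic_onset)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  has_light <- !is.null(proto$light_on)
  tonic_iv <- if (has_light && spec$tonic_onset > 0)
    c(proto$light_on, proto$light_on + spec$tonic_onset) else NULL

  in_light <- function(tt) has_light && tt >= proto$light_on && tt < proto$light_off

  data <- matrix(0, n, n_channels)
  truth_ch <- vector("list", n_channels)
  clamped_any <- FALSE

  for (ci in seq_len(n_channels)) {
    oc <- chan$phase_offset[ci] / 360
    # candidate onsets: phase = oc + k inside oscillating segments
    onsets <- numeric(0); ks <- numeric(0)
    for (i in seq_len(nrow(seg))) {
      if (seg$f[i] <= 0) next
      kr <- seq(ceiling(seg$p0[i] - oc - 1e-9), floor(seg$p1[i] - oc + 1e-9))
      kr <- kr[kr - 1e-9 + oc >= seg$p0[i] & kr + oc < seg$p1[i] - 1e-12]
      if (length(kr)) {
        onsets <- c(onsets, seg$t0[i] + (oc + kr - seg$p0[i]) / seg$f[i])
        ks <- c(ks, kr)
      }
    }
    ord <- order(onsets); onsets <- onsets[ord]; ks <- ks[ord]

    env <- numeric(n)
    rows <- NULL
    jit <- with_seed(split_seed(seed, 1000L + ci),
                    stats::rnorm(length(onsets), 0, spec$amp_jitter_sd))
    for (bi in seq_along(onsets)) {
      on_t <- onsets[bi]
      lit <- in_light(on_t)
      duty_u <- chan$duty[ci] * if (lit) chan$light_duty_factor[ci] else 1
      if (duty_u >= 0.95) { duty_u <- 0.95; clamped_any <- TRUE }
      f_on <- seg$f[findInterval(on_t, seg$t0)]
      period <- 1 / f_on
      off_t <- phase_time(seg, oc + ks[bi] + duty_u)
      if (is.na(off_t)) next
      # bursts swallowed by the tonic clamp are represented by the clamp
      if (!is.null(tonic_iv) && on_t < tonic_iv[2] && off_t > tonic_iv[1]) next
      w <- spec$edge_frac * period
      if (on_t - w / 2 < 0 || off_t + w / 2 > dur) next
      amp <- chan$amplitude[ci] * (if (lit) chan$light_amp_factor[ci] else 1) *
        max(0.1, 1 + jit[bi])
      i0 <- max(1L, floor((on_t - w / 2) * fs) + 1L)
      i1 <- min(n, ceiling((off_t + w / 2) * fs) + 1L)
      idx <- i0:i1
      env[idx] <- env[idx] +
        amp * (hann_step((t[idx] - on_t) / w) - hann_step((t[idx] - off_t) / w))
      rows <- rbind(rows, data.frame(
        onset = on_t, offset = off_t, duration = off_t - on_t,
        period = period, duty = duty_u, amplitude = amp,
        epoch = if (!has_light) "all" else if (lit) "light"
                else if (on_t < proto$light_on) "pre" else "post"))
    }

    if (!is.null(tonic_iv)) {
      amp_t <- chan$amplitude[ci] * chan$light_amp_factor[ci]
      w2 <- spec$edge_frac / spec$base_frequency
      clamp <- amp_t * (hann_step((t - tonic_iv[1]) / w2) -
                        hann_step((t - tonic_iv[2]) / w2))
      env <- pmax(env, clamp)
    }

    noise <- with_seed(split_seed(seed, 3000L + ci),
                       stats::rnorm(n, 0, spec$baseline_noise_sd))
    if (spec$carrier == "spikes") {
      # rate-modulated biphasic spike-train carrier (config alternative)
      carrier <- with_seed(split_seed(seed, 2000L + ci), {
        p <- 400 / fs * pmax(env, 0) / max(max(env), 1e-9)
        x <- as.numeric(stats::runif(n) < p) * sample(c(-1, 1), n, replace = TRUE)
        y <- stats::filter(x, c(1, -0.6, 0.2), sides = 1)
        y[is.na(y)] <- 0
        as.numeric(y)
      })
      data[, ci] <- carrier + noise
    } else {
      carrier <- with_seed(split_seed(seed, 2000L + ci), stats::rnorm(n))
      data[, ci] <- env * carrier + noise
    }
    truth_ch[[ci]] <- rows
  }

  events <- list()
  if (has_light) events <- list(light_on = proto$light_on,
                                light_off = proto$light_off)
  if (!is.null(proto$stim)) events$stim_times <- proto$stim$pulse_times
  rec <- raw_recording(data, fs, chan[, c("name", "role", "side")],
                       events = events, group = group)
  truth <- structure(list(
    seed = seed, f_profile = seg[, c("t0", "t1", "f")],
    channels = stats::setNames(truth_ch, chan$name),
    phase_offset = stats::setNames(chan$phase_offset, chan$name),
    duty = stats::setNames(chan$duty, chan$name),
    light_duty_factor = stats::setNames(chan$light_duty_factor, chan$name),
    light_amp_factor = stats::setNames(chan$light_amp_factor, chan$name),
    light_freq_factor = spec$light_freq_factor,
    base_frequency = spec$base_frequency,
    tonic = tonic_iv, light = if (has_light) c(proto$light_on, proto$light_off),
    duty_clamped = clamped_any), class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate an intracellular motoneuron recording
#'
#' Membrane trace = baseline + rhythmic locomotor drive locked to the
#' reference envelope phase + stereotyped spikes from an inhomogeneous point
#' process whose rate rises with the drive.
#'
#' @param proto a \code{\link{protocol}}.
#' @param drive_amplitude pre-light peak-to-trough drive, mV (>= 0).
#' @param baseline_vm trough membrane potential, mV.
#' @param spike_rate_gain firing-rate gain, spikes/s per mV of drive (>= 0).
#' @param seed integer seed.
#' @param light_drive_amplitude drive amplitude inside the light window, mV.
#' @param base_frequency,light_freq_factor rhythm frequency profile, Hz.
#' @param noise_sd membrane noise SD, mV.
#' @return list(trace = intracellular_trace, truth = ground_truth-like list).
#' @export
simulate_intracellular <- function(proto, drive_amplitude, baseline_vm = -60,
                                   spike_rate_gain = 1, seed = 1,
                                   light_drive_amplitude = drive_amplitude,
                                   base_frequency = 0.3, light_freq_factor = 1,
                                   noise_sd = 0.3) {
  stopifnot(inherits(proto, "loco_protocol"))
  if (drive_amplitude < 0 || light_drive_amplitude < 0)
    stop("drive_amplitude must be >= 0")
  if (spike_rate_gain < 0) stop("spike_rate_gain must be >= 0")
  fs <- proto$sampling_rate
  n <- round(proto$total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  seg <- freq_segments(proto, base_frequency, light_freq_factor, 0)
  u <- phase_at(seg, t)
  has_light <- !is.null(proto$light_on)
  amp_t <- rep(drive_amplitude, n)
  if (has_light) amp_t[t >= proto$light_on & t < proto$light_off] <-
    light_drive_amplitude
  drive <- amp_t * 0.5 * (1 - cos(2 * pi * u))

  # inhomogeneous Poisson spikes by thinning, 20 ms refractory
  lam <- spike_rate_gain * drive
  lmax <- max(lam)
  spike_times <- numeric(0)
  if (lmax > 0) {
    spike_times <- with_seed(split_seed(seed, 11L), {
      m <- stats::rpois(1, lmax * proto$total_duration)
      cand <- sort(stats::runif(m, 0, proto$total_duration))
      keep <- stats::runif(m) < lam[pmin(n, floor(cand * fs) + 1)] / lmax
      cand <- cand[keep]
      out <- numeric(0); last <- -Inf
      for (ct in cand) if (ct - last >= 0.02) { out <- c(out, ct); last <- ct }
      out
    })
  }
  vm <- baseline_vm + drive +
    with_seed(split_seed(seed, 12L), stats::rnorm(n, 0, noise_sd))
  if (length(spike_times)) {
    # stereotyped action potential: fast rise to ~+40 mV, decay, small AHP
    tk <- seq(0, 0.01, by = 1 / fs)
    shape <- (40 - baseline_vm) * exp(-((tk - 8e-4) / 5e-4)^2) -
      4 * exp(-tk / 4e-3) * (tk > 1.6e-3)
    for (st in spike_times) {
      i0 <- floor(st * fs) + 1L
      idx <- i0:min(n, i0 + length(shape) - 1L)
      vm[idx] <- vm[idx] + shape[seq_along(idx)]
    }
  }
  onsets <- phase_time(seg, seq(0, floor(max(u)) - 1))
  trace <- structure(list(vm = vm, sampling_rate = fs, cell = "synthetic_mn",
                          events = if (has_light) list(light_on = proto$light_on,
                                                       light_off = proto$light_off)
                                   else list()),
                     class = "intracellular_trace")
  truth <- list(seed = seed, spike_times = spike_times,
                drive_amplitude = c(pre = drive_amplitude,
                                    light = light_drive_amplitude),
                baseline_vm = baseline_vm, cycle_onsets = onsets,
                f_profile = seg[, c("t0", "t1", "f")])
  list(trace = trace, truth = truth)
}

#' Simulate a calcium-imaging movie
#'
#' Each frame = static anatomy + Gaussian cell blobs modulated by the
#' programmed rhythm + a spatially uniform neuropil component sharing the
#' rhythm, all scaled by multiplicative monoexponential bleaching, plus
#' shot-like noise.
#'
#' @param proto a \code{\link{protocol}} (its sampling_rate is ignored; frames
#'   are generated at \code{frame_rate}).
#' @param cells data.frame with columns \code{x}, \code{y}, \code{radius}
#'   (pixels), \code{amplitude} (a.u.), \code{phase} (degrees vs the
#'   reference envelope).
#' @param neuropil_amplitude shared neuropil rhythm amplitude as a fraction of
#'   the baseline intensity.
#' @param bleach numeric c(amplitude, tau_seconds): intensity decays as
#'   (1 - A) + A exp(-t/tau); tau must be > 0.
#' @param frame_rate frames per second (16, 6 and 4 Hz match the acquisition
#'   rates emulated; any positive value is accepted).
#' @param seed integer seed.
#' @param field c(height, width) in pixels.
#' @param base_frequency,light_freq_factor rhythm profile, Hz.
#' @param baseline background intensity; \code{cell_baseline} static
#'   brightness added inside each cell (keeps neuropil-subtracted traces
#'   positive, as for a real indicator-filled soma); \code{noise_sd} scales
#'   shot noise.
#' @return list(stack, truth): stack has \code{data} (ny x nx x nframes),
#'   \code{frame_rate}, \code{times}; truth stores per-cell clean traces and
#'   the bleach parameters.
#' @export
simulate_calcium <- function(proto, cells, neuropil_amplitude = 0.1,
                             bleach = c(0.3, 60), frame_rate = 4, seed = 1,
                             field = c(80, 80), base_frequency = 0.3,
                             light_freq_factor = 1, baseline = 100,
                             cell_baseline = 60, noise_sd = 1) {
  stopifnot(frame_rate > 0, bleach[2] > 0, nrow(cells) >= 1)
  ny <- field[1]; nx <- field[2]
  bad <- cells$x - cells$radius < 1 | cells$x + cells$radius > nx |
         cells$y - cells$radius < 1 | cells$y + cells$radius > ny
  if (any(bad)) stop("cell ROI(s) outside the imaging field")
  nf <- floor(proto$total_duration * frame_rate)
  times <- (seq_len(nf) - 1) / frame_rate
  seg <- freq_segments(proto, base_frequency, light_freq_factor, 0)
  u <- phase_at(seg, times)

  static <- with_seed(split_seed(seed, 21L), {
    tex <- matrix(stats::rnorm(ny * nx), ny, nx)
    k <- stats::dnorm(seq(-3, 3, length.out = 9)); k <- k / sum(k)
    tex <- apply(apply(tex, 2, function(c) stats::filter(c, k, circular = TRUE)),
                 1, function(r) stats::filter(r, k, circular = TRUE))
    baseline * (1 + 0.08 * t(tex) / stats::sd(tex))
  })

  profs <- vector("list", nrow(cells))
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  for (ci in seq_len(nrow(cells))) {
    d2 <- (xg - cells$x[ci])^2 + (yg - cells$y[ci])^2
    pr <- exp(-d2 / (2 * (cells$radius[ci] / 2)^2))
    pr[d2 > cells$radius[ci]^2] <- 0
    profs[[ci]] <- pr
  }
  # a cell of phase phi peaks at cycle phase phi (phi = 0: aligned with the
  # cycle onset; phi = 180: anti-phase)
  cell_tr <- sapply(seq_len(nrow(cells)), function(ci)
    cell_baseline + cells$amplitude[ci] * 0.5 *
      (1 + cos(2 * pi * u - deg2rad(cells$phase[ci]))))
  np_tr <- neuropil_amplitude * baseline * 0.5 * (1 + cos(2 * pi * u))
  bl <- (1 - bleach[1]) + bleach[1] * exp(-times / bleach[2])

  noise <- if (noise_sd > 0)
    with_seed(split_seed(seed, 22L), array(stats::rnorm(ny * nx * nf), c(ny, nx, nf)))
  else NULL
  stack <- array(0, c(ny, nx, nf))
  for (k in seq_len(nf)) {
    fr <- static + np_tr[k]
    for (ci in seq_len(nrow(cells))) fr <- fr + profs[[ci]] * cell_tr[k, ci]
    fr <- fr * bl[k]
    if (!is.null(noise)) fr <- fr + noise_sd * sqrt(pmax(fr, 0)) * noise[, , k]
    stack[, , k] <- fr
  }
  truth <- list(seed = seed, cell_traces = cell_tr, neuropil_trace = np_tr,
                bleach_amplitude = bleach[1], bleach_tau = bleach[2],
                phase = cells$phase, cycle_phase = u,
                f_profile = seg[, c("t0", "t1", "f")])
  list(stack = structure(list(data = stack, frame_rate = frame_rate,
                              times = times, field = field),
                         class = "calcium_stack"),
       truth = truth)
}
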