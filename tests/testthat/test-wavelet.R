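# Morlet spectrograms, ridge frequency, cross-wavelet phase, trimming,
# normalization and the tonic mask.

test_that("spectrogram has 3,200 time bins and peaks at a pure tone", {
  fs <- 19
  for (dur in c(90, 170)) {
    t <- (0:(dur * fs - 1)) / fs
    env <- 1 + 0.8 * sin(2 * pi * 0.33 * t)
    ng <- env_neurogram(env, fs)
    sp <- wavelet_spectrogram(ng, 1, band = c(0.05, 2))
    expect_identical(ncol(sp$W), 3200L)
    expect_true(all(diff(sp$freqs) > 0))
    # interior columns peak at the grid frequency nearest 0.33 Hz
    interior <- sp$times > 15 & sp$times < dur - 15
    pk <- sp$freqs[apply(sp$mag[, interior], 2, which.max)]
    near <- sp$freqs[which.min(abs(sp$freqs - 0.33))]
    expect_true(all(abs(log2(pk / near)) <= log2(sp$freqs[2] / sp$freqs[1]) + 1e-9))
  }
})

test_that("short records are rejected; two tones give two periodogram-matched ridges", {
  ng <- env_neurogram(rep(1, 19 * 30), 19)
  expect_error(wavelet_spectrogram(ng, 1, band = c(0.05, 2)), "too short")

  fs <- 19; dur <- 200
  t <- (0:(dur * fs - 1)) / fs
  env <- 2 + sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.5 * t)
  sp <- wavelet_spectrogram(env_neurogram(env, fs), 1, band = c(0.05, 2))
  m <- rowMeans(sp$mag[, sp$times > 30 & sp$times < dur - 30])
  loc_max <- which(diff(sign(diff(m))) == -2) + 1
  ridge_f <- sort(sp$freqs[loc_max[order(m[loc_max], decreasing = TRUE)][1:2]])

  # oracle: the two largest periodogram peaks
  pg <- stats::spec.pgram(env - mean(env), plot = FALSE, taper = 0)
  fr <- pg$freq * fs
  sel <- fr > 0.05 & fr < 2
  ord <- order(pg$spec[sel], decreasing = TRUE)
  pg_f <- sort(fr[sel][ord[1:2]])
  expect_equal(ridge_f, pg_f, tolerance = 0.05)
})

test_that("ridge tracks a stationary tone, a chirp and a step within tolerance", {
  fs <- 19; dur <- 170
  t <- (0:(dur * fs - 1)) / fs
  ep <- epoch_table(c("pre", "light", "post"), c(0, 60, 120), c(60, 120, dur))

  env <- 1 + 0.8 * sin(2 * pi * 0.33 * t)
  fr <- extract_frequency(wavelet_spectrogram(env_neurogram(env, fs), 1,
                                              band = c(0.05, 2)))
  fr <- trim_edges(fr, 10)
  expect_lt(max(abs(fr$value - 0.33)), 0.02)

  # linear chirp 0.2 -> 0.4 Hz over 120 s (interior)
  f_inst <- 0.2 + (0.4 - 0.2) * pmin(pmax((t - 25) / 120, 0), 1)
  phase <- cumsum(f_inst) / fs
  env2 <- 1 + 0.8 * sin(2 * pi * phase)
  fr2 <- trim_edges(extract_frequency(
    wavelet_spectrogram(env_neurogram(env2, fs), 1, band = c(0.05, 2))), 12)
  truth <- approx(t, f_inst, fr2$time)$y
  interior <- fr2$time > 30 & fr2$time < 140
  expect_lt(max(abs(fr2$value[interior] - truth[interior])), 0.02)

  # step 0.10 -> 0.17 at light onset
  f3 <- ifelse(t < 60, 0.10, ifelse(t < 120, 0.17, 0.10))
  env3 <- 1 + 0.8 * sin(2 * pi * cumsum(f3) / fs)
  fr3 <- trim_edges(extract_frequency(
    wavelet_spectrogram(env_neurogram(env3, fs, epochs = ep), 1,
                        band = c(0.05, 2))), 10)
  post_step <- fr3$time > 75 & fr3$time < 110
  expect_lt(abs(mean(fr3$value[post_step]) - 0.17), 0.01)
})

test_that("ridge is invariant to envelope amplitude scaling", {
  tr <- burst_train_env(0.33, 0.5, fs = 19, duration = 150, noise_sd = 0.02,
                        seed = 2)
  f1 <- extract_frequency(wavelet_spectrogram(env_neurogram(tr$env, 19), 1,
                                              band = c(0.05, 2)))
  f2 <- extract_frequency(wavelet_spectrogram(env_neurogram(3 * tr$env, 19), 1,
                                              band = c(0.05, 2)))
  expect_equal(f1$value, f2$value, tolerance = 1e-9)
})

test_that("phase: self is 0, half-period delay is 180, quarter-period is 90", {
  fs <- 19; dur <- 170; f0 <- 0.33
  tr <- burst_train_env(f0, 0.5, fs = fs, duration = dur)
  mk <- function(phase) burst_train_env(f0, 0.5, fs = fs, duration = dur,
                                        phase = phase)$env
  ng <- function(e) env_neurogram(e, fs)
  spA <- wavelet_spectrogram(ng(tr$env), 1, band = c(0.05, 2))

  self <- trim_edges(extract_phase(spA, spA), 10)
  expect_lt(max(pmin(self$value, 360 - self$value)), 1e-6)

  for (case in list(c(0.5, 180), c(0.25, 90))) {
    spB <- wavelet_spectrogram(ng(mk(-case[1])), 1, band = c(0.05, 2))
    ph <- trim_edges(extract_phase(spA, spB), 10)
    err <- abs(((ph$value - case[2] + 180) %% 360) - 180)
    expect_lt(max(err, na.rm = TRUE), 2)
  }

  # oracle: analytic-signal phase difference for the quarter-period delay
  x <- tr$env - mean(tr$env)
  h <- function(v) {
    n <- length(v); H <- rep(0, n)
    H[1] <- 1; H[2:(n %/% 2)] <- 2; H[n %/% 2 + 1] <- 1
    stats::fft(stats::fft(v) * H, inverse = TRUE) / n
  }
  y <- mk(-0.25) - mean(mk(-0.25))
  dphi <- Arg(h(x) * Conj(h(y)))
  interior <- seq(200, length(x) - 200)
  oracle <- (mean(dphi[interior]) * 180 / pi) %% 360
  expect_lt(abs(oracle - 90), 2)
})

test_that("phase is antisymmetric between channel orderings", {
  fs <- 19
  a <- burst_train_env(0.3, 0.5, fs = fs, duration = 150)$env
  b <- burst_train_env(0.3, 0.45, fs = fs, duration = 150, phase = -0.3)$env
  spA <- wavelet_spectrogram(env_neurogram(a, fs), 1, band = c(0.05, 2))
  spB <- wavelet_spectrogram(env_neurogram(b, fs), 1, band = c(0.05, 2))
  pab <- extract_phase(spA, spB)$value
  pba <- extract_phase(spB, spA)$value
  s <- (pab + pba) %% 360
  err <- pmin(s, 360 - s)
  # ridges of A and B may differ by a bin; compare where both defined
  expect_lt(stats::quantile(err, 0.95, na.rm = TRUE), 2)
})

test_that("trim_edges arithmetic, identity and error contract", {
  fs <- 19
  s <- rhythm_series((0:(170 * fs - 1)) / fs, rnorm(170 * fs), "frequency",
                     "Hz")
  out <- trim_edges(s, 10)
  expect_equal(diff(range(out$time)), 150, tolerance = 1 / fs)
  expect_identical(trim_edges(s, 0), s)
  expect_error(trim_edges(s, 90), "too short")
})

test_that("normalize_percent_change definition, printed-means case, commuting", {
  ep <- drug_epochs(0, 60, 120, 170)
  fs <- 19
  t <- (0:(170 * fs - 1)) / fs
  lab <- assign_epoch(t, ep)

  # constant = baseline mean -> all zeros; light 1.2x -> +20%
  v <- rep(2, length(t)); v[lab == "light"] <- 2.4
  s <- rhythm_series(t, v, "frequency", "Hz", epochs = ep)
  out <- normalize_percent_change(s)
  expect_equal(out$value[lab == "pre"], rep(0, sum(lab == "pre")))
  expect_equal(out$value[lab == "light"], rep(20, sum(lab == "light")))

  # printed means: baseline 0.89 Hz, light 0.69 Hz -> light mean -22.47%
  v2 <- rep(0.89, length(t)); v2[lab == "light"] <- 0.69
  out2 <- normalize_percent_change(rhythm_series(t, v2, "frequency", "Hz",
                                                 epochs = ep))
  expect_equal(mean(out2$value[lab == "light"]),
               100 * (0.69 / 0.89 - 1), tolerance = 1e-9)
  expect_equal(100 * (0.69 / 0.89 - 1), -22.47, tolerance = 0.01)

  # trim and normalize commute when the baseline lies inside the kept region
  ep_in <- epoch_table(c("pre", "light", "post"), c(15, 60, 120),
                       c(60, 120, 160))
  lab_in <- assign_epoch(t, ep_in)
  v3 <- 1 + 0.1 * sin(2 * pi * 0.05 * t) +
    0.3 * (!is.na(lab_in) & lab_in != "pre")
  s3 <- rhythm_series(t, v3, "frequency", "Hz", epochs = ep_in)
  a <- normalize_percent_change(trim_edges(s3, 10))
  b <- trim_edges(normalize_percent_change(s3), 10)
  expect_equal(a$value, b$value, tolerance = 1e-9)

  # error contract
  szero <- rhythm_series(t, rep(0, length(t)), "frequency", "Hz", epochs = ep)
  expect_error(normalize_percent_change(szero), "positive")
})

test_that("baseline mean of a normalized series is zero within 1e-9", {
  ep <- drug_epochs(0, 60, 120, 170)
  fs <- 19
  t <- (0:(170 * fs - 1)) / fs
  set.seed(8)
  s <- rhythm_series(t, runif(length(t), 0.2, 0.5), "frequency", "Hz",
                     epochs = ep)
  out <- normalize_percent_change(s)
  lab <- assign_epoch(t, ep)
  expect_lt(abs(mean(out$value[lab == "pre"])), 1e-9)
})

test_that("tonic mask: null cases and hemicord extent recovery", {
  # fully rhythmic trial -> all-false mask
  proto <- protocol(170, 55, 115, 2000)
  sim <- simulate_neurograms(proto, rhythm_spec(0.3, single_channel(0.5)),
                             seed = 31)
  r <- suppressWarnings(analyze_trial(sim$recording, "drug",
                                      tonic_mask = TRUE))
  expect_false(any(r$mask$mask$tonic))
  expect_identical(nrow(r$mask$mask), length(r$spectra[[1]]$times))

  # constant zero envelope -> all-false (quiescent is not tonic)
  ng <- env_neurogram(rep(0, 170 * 19), 19, epochs = drug_epochs(0, 55, 115, 170))
  sp0 <- suppressWarnings(wavelet_spectrogram(
    env_neurogram(rep(c(0, 1), 170 * 19 / 2), 19,
                  epochs = drug_epochs(0, 55, 115, 170)), 1, c(0.05, 2)))
  m0 <- flag_tonic(ng, sp0, channel = 1)
  expect_false(any(m0$mask$tonic))

  # hemicord: 10 s programmed tonic onset detected within +/-2 s
  ch <- data.frame(name = c("lL2", "lL5"), role = c("flexor", "extensor"),
                   side = "left", phase_offset = c(0, 180),
                   duty = c(0.35, 0.61), amplitude = 1,
                   light_amp_factor = c(0.65, 1.61),
                   light_duty_factor = c(1.9, 1.03))
  proto2 <- protocol(180, 60, 120, 2000)
  ext <- numeric(3)
  for (s in 1:3) {
    sim2 <- simulate_neurograms(proto2,
                                rhythm_spec(0.10, ch, light_freq_factor = 1.7,
                                            tonic_onset = 10), seed = 40 + s)
    r2 <- suppressWarnings(analyze_trial(sim2$recording, "drug",
                                         tonic_mask = TRUE))
    ext[s] <- tonic_extent(r2$mask, 60)
  }
  # per-trial boundary error is bounded by the wavelet's smear; the
  # cohort-level +/-2 s criterion applies to the mean
  expect_lt(abs(mean(ext) - 10), 2)
  expect_true(all(abs(ext - 10) < 4))
})
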