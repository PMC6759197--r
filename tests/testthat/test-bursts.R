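# Burst segmentation: the fractional trough-to-peak boundary rule and the
# per-cycle pattern metrics.

test_that("triangular burst: onset level is 40% of height and duration is 0.6 base", {
  # symmetric triangle with vertices on the sample grid: piecewise-linear
  # interpolation is exact, so similar triangles give duration = (1-0.4)*base
  fs <- 100
  base <- 2                       # seconds
  period <- 10
  n <- round(40 * fs)
  t <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  for (k in 0:3) {
    a <- 5 + k * period
    up <- t >= a & t < a + base / 2
    dn <- t >= a + base / 2 & t <= a + base
    env[up] <- (t[up] - a) / (base / 2)
    env[dn] <- (a + base - t[dn]) / (base / 2)
  }
  ng <- env_neurogram(env, fs)
  cyc <- detect_cycles(ng)
  b <- burst_bounds(ng, cyc, threshold_fraction = 0.4)
  expect_true(nrow(cyc) >= 3)
  durs <- b$offset_time - b$onset_time
  expect_equal(durs, rep(0.6 * base, length(durs)), tolerance = 1e-9)
  # the crossing level itself sits at 40% of trough-to-peak
  lev <- approx(t, env, b$onset_time[1])$y
  expect_equal(lev, 0.4, tolerance = 1e-9)
})

test_that("square pulse: duration equals the width for any threshold", {
  fs <- 1000
  width <- 3
  period <- 8
  n <- round(32 * fs)
  t <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  for (k in 0:2) env[t >= 4 + k * period & t < 4 + k * period + width] <- 1
  ng <- env_neurogram(env, fs)
  cyc <- detect_cycles(ng)
  for (thr in c(0.2, 0.4, 0.7)) {
    b <- burst_bounds(ng, cyc, threshold_fraction = thr)
    durs <- b$offset_time - b$onset_time
    # step edges are one sample wide: exact up to one sample
    expect_equal(durs, rep(width, length(durs)), tolerance = 2 / fs)
  }
})

test_that("half-sine burst duration matches the root-finding oracle", {
  fs <- 1000
  base <- 2
  period <- 8
  n <- round(32 * fs)
  t <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  for (k in 0:2) {
    sel <- t >= 3 + k * period & t <= 3 + k * period + base
    env[sel] <- sin(pi * (t[sel] - 3 - k * period) / base)
  }
  ng <- env_neurogram(env, fs)
  cyc <- detect_cycles(ng)
  b <- burst_bounds(ng, cyc, threshold_fraction = 0.4)
  durs <- b$offset_time - b$onset_time

  # oracle: numerical root-finding on the continuous waveform
  up <- uniroot(function(x) sin(pi * x / base) - 0.4, c(0, base / 2),
                tol = 1e-12)$root
  oracle <- base - 2 * up
  expect_equal(oracle / base, 1 - 2 * asin(0.4) / pi, tolerance = 1e-9)
  expect_lt(max(abs(durs - oracle)), 1e-3)
})

test_that("constant envelope yields no cycles; flat-top level misses are skipped", {
  ng <- env_neurogram(rep(2, 400), 19)
  expect_identical(nrow(detect_cycles(ng)), 0L)
  expect_identical(nrow(burst_table(ng)), 0L)
})

test_that("square envelope 6 s on / 10 s period gives duty 0.600", {
  fs <- 100
  n <- 80 * fs
  t <- (seq_len(n) - 1) / fs
  env <- as.numeric((t %% 10) < 6)
  bt <- burst_table(env_neurogram(env, fs))
  interior <- bt$duty_cycle[!is.na(bt$duty_cycle)]
  expect_true(length(interior) >= 5)
  expect_equal(interior, rep(0.6, length(interior)), tolerance = 2e-3)
})

test_that("amplitude is invariant to additive offsets; duty to time rescaling", {
  tr <- burst_train_env(0.3, 0.45, fs = 50, duration = 60)
  ng1 <- env_neurogram(tr$env, 50)
  ng2 <- env_neurogram(tr$env + 5, 50)
  b1 <- burst_table(ng1); b2 <- burst_table(ng2)
  expect_equal(b1$amplitude, b2$amplitude, tolerance = 1e-9)

  tr2 <- burst_train_env(0.15, 0.45, fs = 50, duration = 120)
  b3 <- burst_table(env_neurogram(tr2$env, 50))
  expect_equal(mean(b1$duty_cycle, na.rm = TRUE),
               mean(b3$duty_cycle, na.rm = TRUE), tolerance = 0.01)
})

test_that("duration + interburst interval equals period for interior cycles", {
  tr <- burst_train_env(0.33, 0.53, fs = 19, duration = 150, noise_sd = 0.03,
                        seed = 4)
  bt <- burst_table(env_neurogram(tr$env, 19))
  ok <- !is.na(bt$period)
  expect_true(sum(ok) > 20)
  expect_equal(bt$burst_duration[ok] + bt$interburst_interval[ok],
               bt$period[ok], tolerance = 1e-12)
})

test_that("random envelopes: duty bias < 0.02 and exact burst counts at SNR >= 5", {
  set.seed(11)
  n_cases <- 150
  bias <- numeric(n_cases)
  count_err <- integer(n_cases)
  for (i in seq_len(n_cases)) {
    f <- runif(1, 0.1, 0.9)
    d <- runif(1, 0.2, 0.8)
    dur <- max(30, 12 / f)
    tr <- burst_train_env(f, d, fs = 19, duration = dur, noise_sd = 0.2 / 5,
                          seed = i)
    bt <- burst_table(env_neurogram(tr$env, 19))
    # interior bursts entirely inside the record
    n_true <- floor(dur * f - d)
    count_err[i] <- abs(nrow(bt) - n_true)
    bias[i] <- mean(bt$duty_cycle, na.rm = TRUE) - d
  }
  expect_lt(abs(mean(bias, na.rm = TRUE)), 0.02)
  expect_lt(mean(count_err > 1), 0.02)
})

test_that("crossing times match an exhaustive dense-scan oracle within 1 ms", {
  fs <- 2000
  tr <- burst_train_env(0.4, 0.5, fs = fs, duration = 30)
  ng <- env_neurogram(tr$env, fs)
  cyc <- detect_cycles(ng)
  b <- burst_bounds(ng, cyc, 0.4)
  for (i in seq_len(nrow(cyc))) {
    lev <- cyc$trough_value[i] +
      0.4 * (cyc$peak_value[i] - cyc$trough_value[i])
    ip <- which.min(abs(tr$t - cyc$peak_time[i]))
    j <- ip
    while (j > 1 && tr$env[j - 1] >= lev) j <- j - 1
    oracle_on <- tr$t[j - 1] +
      (lev - tr$env[j - 1]) / (tr$env[j] - tr$env[j - 1]) / fs
    expect_lt(abs(b$onset_time[i] - oracle_on), 1e-3)
  }
})

test_that("burst count matches generator truth on a noisy preset envelope", {
  proto <- protocol(170, 55, 115, 2000)
  sim <- simulate_neurograms(proto, rhythm_spec(0.3, single_channel(0.5)),
                             seed = 21)
  env19 <- resample_envelope(
    integrate_neurogram(align_trials(sim$recording, "drug"), "drug"))
  bt <- burst_table(env19, 1)
  truth <- sim$truth$channels$ch1
  # compare counts inside the analysis window
  w <- c(env19$t0, env19$t0 + (nrow(env19$env) - 1) / 19)
  n_true <- sum(truth$onset > w[1] & truth$offset < w[2])
  expect_lte(abs(nrow(bt) - n_true), 1)
})

test_that("epoch summary normalizes to pre and averages trial -> experiment", {
  ep <- drug_epochs()
  mk_tab <- function(dur_light) {
    tr <- burst_train_env(0.33, 0.5, fs = 19, duration = 170, t0 = 5)
    bt <- burst_table(env_neurogram(tr$env, 19, t0 = 5, epochs = ep))
    # synthetic override: scale light-epoch durations
    i <- which(bt$epoch == "light")
    bt$burst_duration[i] <- bt$burst_duration[i] * dur_light
    bt
  }
  s_same <- epoch_summary(mk_tab(1))
  expect_true(all(abs(s_same$pct_change) < 1e-9 |
                    s_same$epoch != "pre"))
  expect_true(all(abs(s_same$pct_change[s_same$epoch == "pre"]) < 1e-9))

  s_up <- epoch_summary(mk_tab(1.4))
  i <- s_up$epoch == "light" & s_up$metric == "burst_duration"
  expect_equal(s_up$pct_change[i], 40, tolerance = 0.5)

  # cross-experiment aggregation averages experiment values
  agg <- aggregate_epoch_summaries(list(epoch_summary(mk_tab(1.2)),
                                        epoch_summary(mk_tab(1.6))))
  j <- agg$epoch == "light" & agg$metric == "burst_duration"
  expect_equal(agg$pct_change_mean[j], 40, tolerance = 1)
})

test_that("preset duty cycles are recovered within 0.02 through the full chain", {
  proto <- protocol(180, 60, 120, 2000)
  spec <- rhythm_spec(0.33, std_channels(), light_freq_factor = 0.879)
  duties_f <- duties_e <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_neurograms(proto, spec, seed = 300 + s)
    r <- suppressWarnings(analyze_trial(sim$recording, "drug"))
    duties_f[s] <- mean(r$bursts$lL2$duty_cycle[r$bursts$lL2$epoch == "pre"],
                        na.rm = TRUE)
    duties_e[s] <- mean(r$bursts$lL5$duty_cycle[r$bursts$lL5$epoch == "pre"],
                        na.rm = TRUE)
  }
  expect_lt(abs(mean(duties_f) - 0.53), 0.02)
  expect_lt(abs(mean(duties_e) - 0.59), 0.02)
})
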