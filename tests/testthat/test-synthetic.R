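# The synthetic-data generator: determinism, analytic ground truth, preset
# programming, and the intracellular / calcium branches.

test_that("identical (spec, seed) gives bit-identical traces; channels are stable", {
  proto <- protocol(60, 20, 40, 1000)
  spec <- rhythm_spec(0.4, std_channels())
  a <- simulate_neurograms(proto, spec, seed = 5)
  b <- simulate_neurograms(proto, spec, seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$channels, b$truth$channels)
  # counter-based splitting: earlier channels unchanged when fewer requested
  one <- simulate_neurograms(proto, spec, n_channels = 1, seed = 5)
  expect_identical(one$recording$data[, 1], a$recording$data[, 1])
  # different seed changes the trace
  expect_false(identical(a$recording$data,
                         simulate_neurograms(proto, spec, seed = 6)$recording$data))
})

test_that("ground truth duty equals (offset - onset)/period; phase lags are exact", {
  proto <- protocol(100, 40, 70, 1000)
  spec <- rhythm_spec(0.33, std_channels(duty_factors = c(1, 1, 1)))
  sim <- simulate_neurograms(proto, spec, seed = 9)
  for (nm in names(sim$truth$channels)) {
    tb <- sim$truth$channels[[nm]]
    expect_equal(tb$duration / tb$period, tb$duty, tolerance = 1e-9)
  }
  # programmed 180 degree lag: circular mean of per-cycle onset-phase
  # differences equals the lag to < 1 degree
  on_a <- sim$truth$channels$lL2$onset
  on_b <- sim$truth$channels$rL2$onset
  f <- 0.33
  d <- vapply(on_a, function(o) {
    nb <- on_b[which.min(abs(on_b - o))]
    ((nb - o) * f * 360) %% 360
  }, numeric(1))
  expect_lt(abs(circ_mean_r(d)$mean - 180), 1)
})

test_that("truth frequency profile applies the light factor exactly", {
  proto <- protocol(100, 40, 70, 1000)
  spec <- rhythm_spec(0.3, single_channel(), light_freq_factor = 0.85,
                      tonic_onset = 5)
  sim <- simulate_neurograms(proto, spec, seed = 2)
  fp <- sim$truth$f_profile
  expect_equal(fp$f[fp$t0 == 0], 0.3)
  expect_equal(fp$f[fp$t0 == 40], 0)               # frozen during tonic
  expect_equal(fp$f[fp$t0 == 45], 0.3 * 0.85)      # light factor exact
  expect_equal(fp$f[fp$t0 == 70], 0.3)
  expect_equal(sim$truth$tonic, c(40, 45))
})

test_that("generator rejects invalid specs and normalizes phase offsets", {
  proto <- protocol(60, 20, 40, 100)
  ch <- single_channel(duty = 0.005)
  expect_error(simulate_neurograms(protocol(60, 20, 40, 50),
                                   rhythm_spec(1.8, ch), seed = 1),
               "2 samples")
  expect_error(rhythm_spec(0, single_channel()))
  expect_error(rhythm_spec(0.3, single_channel(duty = 1.2)))
  sp <- rhythm_spec(0.3, single_channel(offset = 540))
  expect_equal(sp$channels$phase_offset, 180)
  expect_error(protocol(100, 90, 120, 1000), "inside")
})

test_that("intracellular: null rhythm, determinism, programmed drive", {
  proto <- protocol(60, 20, 40, 10000)
  flat <- simulate_intracellular(proto, drive_amplitude = 0, baseline_vm = -60,
                                 spike_rate_gain = 0, seed = 3)
  expect_length(flat$truth$spike_times, 0)
  expect_lt(abs(mean(flat$trace$vm) + 60), 0.1)
  expect_lt(stats::sd(flat$trace$vm), 1)

  a <- simulate_intracellular(proto, 6.4, -60, 2, seed = 7,
                              light_drive_amplitude = 11.13,
                              base_frequency = 0.4)
  b <- simulate_intracellular(proto, 6.4, -60, 2, seed = 7,
                              light_drive_amplitude = 11.13,
                              base_frequency = 0.4)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  expect_identical(a$trace$vm, b$trace$vm)
  expect_equal(unname(a$truth$drive_amplitude), c(6.4, 11.13))
  expect_error(simulate_intracellular(proto, 5, spike_rate_gain = -1),
               ">= 0")
})

test_that("calcium: static limit, anti-phase truth, bleach fit oracle", {
  proto <- protocol(120, 40, 80, 1000)
  cells <- data.frame(x = 20, y = 20, radius = 5, amplitude = 0, phase = 0)
  still <- simulate_calcium(proto, cells, neuropil_amplitude = 0,
                            bleach = c(0, 60), frame_rate = 4, seed = 1,
                            field = c(40, 40), noise_sd = 0)
  expect_lt(diff(range(still$stack$data)), 1e-9 +
              diff(range(still$stack$data[, , 1])))
  expect_equal(still$stack$data[, , 1], still$stack$data[, , 100])

  cells2 <- data.frame(x = c(12, 28), y = c(12, 28), radius = 4,
                       amplitude = 30, phase = c(0, 180))
  mv <- simulate_calcium(proto, cells2, neuropil_amplitude = 0.05,
                         bleach = c(0.3, 50), frame_rate = 4, seed = 2,
                         field = c(40, 40), base_frequency = 0.3)
  cc <- cor(mv$truth$cell_traces[, 1], mv$truth$cell_traces[, 2])
  expect_lt(cc, -0.95)

  # mean frame intensity of a noiseless movie fits the programmed tau
  # within 2% (oracle: independent nonlinear fit)
  mv0 <- simulate_calcium(proto, cells2, neuropil_amplitude = 0,
                          bleach = c(0.4, 45), frame_rate = 4, seed = 3,
                          field = c(40, 40), noise_sd = 0)
  y <- apply(mv0$stack$data, 3, mean)
  t <- mv0$stack$times
  # nls stalls on exactly-zero residuals; a vanishing jitter regularizes it
  set.seed(1)
  y <- y + rnorm(length(y), 0, 1e-6 * diff(range(y)))
  fit <- stats::nls(y ~ a * exp(-t / tau) + c0,
                    start = list(a = y[1] - y[length(y)], tau = 30,
                                 c0 = y[length(y)]),
                    control = stats::nls.control(maxiter = 500))
  expect_lt(abs(coef(fit)[["tau"]] - 45) / 45, 0.02)

  expect_error(simulate_calcium(proto, data.frame(x = 2, y = 2, radius = 5,
                                                  amplitude = 1, phase = 0),
                                frame_rate = 4, field = c(40, 40)),
               "outside")
})

test_that("cohort presets are deterministic and program the printed values", {
  co <- simulate_cohort("wholecord-arch", n = 4, seed = 3, trials = 1,
                        sampling_rate = 500)
  co2 <- simulate_cohort("wholecord-arch", n = 4, seed = 3, trials = 1,
                         sampling_rate = 500)
  expect_identical(co$experiments[[2]]$trials[[1]]$recording$data,
                   co2$experiments[[2]]$trials[[1]]$recording$data)
  bases <- vapply(co$experiments, function(e) e$params$base, numeric(1))
  expect_true(all(abs(bases - 0.33) <= 2 * 0.06 + 1e-12))
  ffs <- vapply(co$experiments, function(e) e$params$freq_factor, numeric(1))
  expect_true(all(abs(ffs - 0.29 / 0.33) <= 2 * 0.05 * 0.29 / 0.33 + 1e-12))

  dre <- simulate_cohort("dr-evoked-arch", n = 3, seed = 2, trials = 1,
                         sampling_rate = 500)
  reds <- vapply(dre$experiments, function(e) e$params$reduction, numeric(1))
  expect_true(all(reds > 0 & abs(reds - 0.216) <= 2 * 0.1023 + 1e-12))
  expect_identical(length(dre$experiments[[1]]$control_trials), 1L)
  expect_identical(length(dre$experiments[[1]]$light_trials), 1L)

  hc <- simulate_cohort("hemicord-arch", n = 2, seed = 4, trials = 1,
                        sampling_rate = 500)
  expect_equal(unname(hc$experiments[[1]]$trials[[1]]$truth$tonic),
               c(60, 70))
})
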