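# Shared fixture builders: analytic envelopes and small synthetic scenes.

# Raised-cosine (Hann-edged) burst train sampled at `fs`: bursts of the
# given duty and frequency, edges `edge_frac` of the period wide.
burst_train_env <- function(freq, duty, fs = 19, duration = 120,
                            edge_frac = 0.1, amplitude = 1, phase = 0,
                            noise_sd = 0, t0 = 0, seed = NULL) {
  n <- round(duration * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  period <- 1 / freq
  w <- edge_frac * period
  u <- ((t - t0) * freq + phase) %% 1
  S <- function(z) locorhythm:::hann_step(z * period / w)
  env <- amplitude * ((S(u) - S(u - duty)) + (S(u - 1) - S(u - 1 - duty)))
  env <- pmax(env, 0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    env <- pmax(env + rnorm(n, 0, noise_sd), 0)
  }
  list(env = env, t = t, fs = fs)
}

# Wrap a bare envelope vector as an integrated_neurogram with drug epochs.
env_neurogram <- function(env, fs = 19, t0 = 0, epochs = NULL,
                          role = "flexor", name = "ch1") {
  as_integrated_neurogram(env, fs, t0 = t0,
                          channels = data.frame(name = name, role = role,
                                                side = "left"),
                          epochs = epochs)
}

drug_epochs <- function(w0 = 5, on = 60, off = 120, w1 = 175)
  epoch_table(c("pre", "light", "post"), c(w0, on, off), c(on, off, w1))

std_channels <- function(duties = c(0.53, 0.53, 0.59),
                         amp_factors = c(1.3, 1.3, 1.68),
                         duty_factors = c(1.23, 1.23, 1.05)) {
  data.frame(name = c("lL2", "rL2", "lL5"),
             role = c("flexor", "flexor", "extensor"),
             side = c("left", "right", "left"),
             phase_offset = c(0, 180, 180), duty = duties, amplitude = 1,
             light_amp_factor = amp_factors,
             light_duty_factor = duty_factors)
}

# dF/F with the documented remedy for non-positive minima: restore a
# baseline offset first.
safe_dff <- function(tr) {
  if (min(tr$value) <= 0) tr$value <- tr$value - min(tr$value) + 1
  dff(tr)
}

single_channel <- function(duty = 0.5, role = "flexor", offset = 0)
  data.frame(name = "ch1", role = role, side = "left", phase_offset = offset,
             duty = duty, amplitude = 1, light_amp_factor = 1,
             light_duty_factor = 1)
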