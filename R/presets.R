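# Scenario presets: seeded synthetic cohorts whose generator constants are
# the study conditions (group means +/- SD of frequency, duty cycle, light
# modulation). Per-experiment parameters are drawn from normal distributions
# truncated at +/-2 SD; all draws flow from one root seed through
# counter-based splitting.

#' Programmed constants of the scenario presets
#'
#' \itemize{
#'   \item \code{wholecord-arch}: drug-induced whole-cord rhythm, base
#'     0.33 +/- 0.06 Hz slowing to x0.879 in light; pre-light duty cycles
#'     extensor 0.59 +/- 0.04 and flexor 0.53 +/- 0.07; flexor burst
#'     duration x1.402 +/- 0.1525 in light; three channels (bilateral
#'     flexor-dominated L2 at 180 deg, ipsilateral extensor-dominated L5 at
#'     180 deg).
#'   \item \code{hemicord-arch}: hemicord rhythm, base 0.10 +/- 0.02 Hz, a
#'     10 s tonic onset at light then acceleration x1.7; duty cycles flexor
#'     0.35 +/- 0.06, extensor 0.61 +/- 0.09; extensor burst duration
#'     x0.6061 +/- 0.2236 in light; two ipsilateral channels.
#'   \item \code{dr-evoked-arch}: dorsal-root-evoked episodes, base
#'     0.89 +/- 0.10 Hz; the light scales frequency by (1 - r) with r drawn
#'     from 21.6 +/- 10.23 %; paired control/light 15.5 s episodes.
#' }
#'
#' @param preset preset name.
#' @return list of programmed constants.
#' @export
preset_params <- function(preset = c("wholecord-arch", "hemicord-arch",
                                     "dr-evoked-arch")) {
  preset <- match.arg(preset)
  switch(preset,
    "wholecord-arch" = list(
      n_default = 16, mode = "drug",
      base = c(mean = 0.33, sd = 0.06),
      freq_factor = c(mean = 0.29 / 0.33, rel_sd = 0.05),
      channels = data.frame(
        name = c("lL2", "rL2", "lL5"),
        role = c("flexor", "flexor", "extensor"),
        side = c("left", "right", "left"),
        phase_offset = c(0, 180, 180),
        duty_mean = c(0.53, 0.53, 0.59),
        duty_sd = c(0.07, 0.07, 0.04),
        dur_factor_mean = c(1.402, 1.402, 1.1963),
        dur_factor_sd = c(0.1525, 0.1525, 0.2237),
        amp_factor_mean = c(1.3003, 1.3003, 1.6777),
        amp_factor_sd = c(0.3788, 0.3788, 0.2549)),
      tonic = 0, trials_default = 3),
    "hemicord-arch" = list(
      n_default = 13, mode = "drug",
      base = c(mean = 0.10, sd = 0.02),
      freq_factor = c(mean = 1.7, rel_sd = 0.05),
      channels = data.frame(
        name = c("lL2", "lL5"),
        role = c("flexor", "extensor"),
        side = c("left", "left"),
        phase_offset = c(0, 180),
        duty_mean = c(0.35, 0.61),
        duty_sd = c(0.06, 0.09),
        dur_factor_mean = c(1.1268, 0.6061),
        dur_factor_sd = c(0.2385, 0.2236),
        amp_factor_mean = c(0.6475, 1.6114),
        amp_factor_sd = c(0.1711, 0.4554)),
      tonic = 10, trials_default = 3),
    "dr-evoked-arch" = list(
      n_default = 12, mode = "evoked",
      base = c(mean = 0.89, sd = 0.10),
      reduction = c(mean = 0.216, sd = 0.1023),
      channels = data.frame(
        name = c("lL2", "lL5"),
        role = c("flexor", "extensor"),
        side = c("left", "left"),
        phase_offset = c(0, 180),
        duty_mean = c(0.40, 0.54),
        duty_sd = c(0.05, 0.05),
        dur_factor_mean = c(1, 1),
        dur_factor_sd = c(0, 0),
        amp_factor_mean = c(1.3003, 1.6777),
        amp_factor_sd = c(0.3788, 0.2549)),
      trials_default = 3))
}

# Independent +/-2 SD draws of duty, duration factor and frequency factor
# can jointly imply a light-epoch duty cycle approaching 1 (a burst with no
# interburst gap), which no recorded rhythm shows; the implied light duty is
# capped at 0.85.
draw_channel_params <- function(ch, freq_factor, duty_cap = 0.85) {
  duty <- mapply(function(m, s) rnorm_trunc(1, m, s, lower = 0.05),
                 ch$duty_mean, ch$duty_sd)
  durf <- mapply(function(m, s) rnorm_trunc(1, m, s, lower = 0.15),
                 ch$dur_factor_mean, ch$dur_factor_sd)
  ampf <- mapply(function(m, s) rnorm_trunc(1, m, s, lower = 0.2),
                 ch$amp_factor_mean, ch$amp_factor_sd)
  data.frame(name = ch$name, role = ch$role, side = ch$side,
             phase_offset = ch$phase_offset, duty = duty, amplitude = 1,
             light_amp_factor = ampf,
             light_duty_factor = pmin(durf * freq_factor, duty_cap / duty))
}

#' Simulate a scenario cohort
#'
#' Draws per-experiment parameters from the preset's distributions
#' (truncated at +/-2 SD) and simulates \code{trials} recordings per
#' experiment; trial-to-trial frequency variability is 5\% of the
#' experiment's base frequency. Deterministic given \code{seed}.
#'
#' @param preset preset name (see \code{\link{preset_params}}).
#' @param n number of experiments (preset default when NULL).
#' @param seed root integer seed.
#' @param trials trials per experiment (preset default when NULL); the
#'   evoked preset simulates \code{trials} control and \code{trials} lit
#'   episodes.
#' @param trial_jitter_sd within-experiment trial frequency jitter,
#'   relative (0.05).
#' @param sampling_rate Hz (10,000).
#' @return A \code{loco_cohort}: list of experiments, each carrying its
#'   drawn parameters and simulated trials (recording + truth).
#' @export
simulate_cohort <- function(preset, n = NULL, seed = 1, trials = NULL,
                            trial_jitter_sd = 0.05, sampling_rate = 10000) {
  pp <- preset_params(preset)
  if (is.null(n)) n <- pp$n_default
  if (is.null(trials)) trials <- pp$trials_default
  experiments <- vector("list", n)
  for (e in seq_len(n)) {
    se <- split_seed(seed, e)
    if (pp$mode == "drug") {
      pars <- with_seed(se, {
        base <- rnorm_trunc(1, pp$base["mean"], pp$base["sd"],
                            lower = 0.02)
        ff <- rnorm_trunc(1, pp$freq_factor["mean"],
                          pp$freq_factor["mean"] * pp$freq_factor["rel_sd"],
                          lower = 0.1)
        list(base = base, freq_factor = ff,
             channels = draw_channel_params(pp$channels, ff),
             trial_base = base * (1 + rnorm_trunc(trials, 0, trial_jitter_sd)))
      })
      proto <- protocol(180, 60, 120, sampling_rate)
      tr <- lapply(seq_len(trials), function(k) {
        spec <- rhythm_spec(pars$trial_base[k], pars$channels,
                            light_freq_factor = pars$freq_factor,
                            tonic_onset = pp$tonic)
        simulate_neurograms(proto, spec, seed = split_seed(se, 100L + k),
                            group = preset)
      })
      experiments[[e]] <- list(params = pars, trials = tr, mode = "drug")
    } else {
      pars <- with_seed(se, {
        base <- rnorm_trunc(1, pp$base["mean"], pp$base["sd"], lower = 0.3)
        red <- rnorm_trunc(1, pp$reduction["mean"], pp$reduction["sd"],
                           lower = 0.001)
        list(base = base, reduction = red,
             channels = draw_channel_params(pp$channels, 1),
             trial_jit = rnorm_trunc(2 * trials, 0, trial_jitter_sd))
      })
      stim <- list(start = 10, rate = 4, train_duration = 10,
                   pulse_width = 2.5e-4)
      sim_one <- function(k, lit) {
        f <- pars$base * (1 + pars$trial_jit[k]) *
          (if (lit) 1 - pars$reduction else 1)
        proto <- protocol(30, light_on = if (lit) 5 else NULL,
                          light_off = if (lit) 29 else NULL,
                          sampling_rate = sampling_rate, stim = stim)
        spec <- rhythm_spec(f, pars$channels, light_freq_factor = 1)
        simulate_neurograms(proto, spec, seed = split_seed(se, 200L + k),
                            group = preset)
      }
      ctrl <- lapply(seq_len(trials), function(k) sim_one(k, FALSE))
      lit <- lapply(seq_len(trials), function(k) sim_one(trials + k, TRUE))
      experiments[[e]] <- list(params = pars, control_trials = ctrl,
                               light_trials = lit, mode = "evoked")
    }
  }
  structure(list(preset = preset, n = n, seed = seed,
                 experiments = experiments),
            class = "loco_cohort")
}
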