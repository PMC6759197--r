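# Internal utilities: seeded RNG streams, epoch bookkeeping, zero-phase filtering.

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global random-number generator seeded to
#' \code{seed}, restoring the previous RNG state afterwards so that seeded
#' simulations never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Deterministic counter-based seed splitting: every simulated channel,
#' trial and experiment draws from its own stream so that adding channels
#' or experiments does not perturb earlier ones. Arithmetic is done modulo
#' 2^31 - 1 in double precision (exact, all intermediates < 2^53).
#'
#' @param seed root integer seed.
#' @param index non-negative integer stream counter.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, index) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271) %% m
  x <- (x + (as.numeric(index) %% m) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 2) + 1)
}

#' Epoch table constructor
#'
#' @param labels character epoch labels.
#' @param start,end numeric vectors of epoch boundaries (seconds). Epochs are
#'   half-open \code{[start, end)} except the last, which is closed.
#' @return data.frame with columns label, start, end.
#' @export
epoch_table <- function(labels, start, end) {
  stopifnot(length(labels) == length(start), length(start) == length(end),
            all(end > start))
  data.frame(label = as.character(labels), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Assign times to epochs
#'
#' @param times numeric vector (seconds).
#' @param epochs epoch table from \code{\link{epoch_table}}.
#' @return character vector of epoch labels (NA outside all epochs).
#' @export
assign_epoch <- function(times, epochs) {
  out <- rep(NA_character_, length(times))
  n <- nrow(epochs)
  for (i in seq_len(n)) {
    inside <- if (i == n) times >= epochs$start[i] & times <= epochs$end[i]
              else times >= epochs$start[i] & times < epochs$end[i]
    out[inside] <- epochs$label[i]
  }
  out
}

# Odd-reflection padded, forward-backward (zero-phase) IIR filtering.
# Pad length is 3x an impulse-response proxy (fs / lowest corner frequency),
# which suppresses onset transients over the long pre-light window.
zerophase_filter <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad > 0) {
    front <- 2 * x[1] - x[seq(pad + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(front, x, back)
  } else xp <- x
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y <- as.numeric(y)
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

# Butterworth zero-phase stage (order 4 per pass by default).
butter_zerophase <- function(x, fs, corner, type, order = 4, pad = NULL) {
  ny <- fs / 2
  w <- corner / ny
  if (any(w >= 1))
    stop("sampling rate too low for a ", paste(corner, collapse = "-"),
         " Hz corner at fs = ", fs, " Hz")
  bf <- signal::butter(order, w, type = type)
  if (is.null(pad)) pad <- ceiling(3 * fs / min(corner))
  zerophase_filter(x, bf$b, bf$a, pad)
}

# Zero-phase low-pass via the frequency domain (8th-order Butterworth
# magnitude response), with odd-reflection padding. Numerically stable at
# arbitrarily small corner/sampling-rate ratios, unlike a time-domain IIR.
fft_lowpass <- function(x, fs, corner) {
  n <- length(x)
  pad <- min(n - 1L, ceiling(fs / corner))
  xp <- c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  np <- length(xp)
  fr <- c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) * fs / np
  # 4th-order magnitude rolloff: steep enough to kill top ripple, gentle
  # enough to avoid Gibbs ringing between bursts
  H <- 1 / sqrt(1 + (fr / corner)^8)
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / np
  y[(pad + 1):(pad + n)]
}

# Smoothed step: integral of a raised-cosine (Hann) kernel of unit width.
# S(-0.5) = 0, S(0) = 0.5, S(0.5) = 1.
hann_step <- function(xi) {
  y <- xi + 0.5 + sin(2 * pi * pmax(pmin(xi, 0.5), -0.5)) / (2 * pi)
  y[xi <= -0.5] <- 0
  y[xi >= 0.5] <- 1
  y
}

# Truncated normal draw: normal(mean, sd) rejected outside mean +/- trunc*sd,
# optionally floored at `lower`. Used for per-experiment heterogeneity.
rnorm_trunc <- function(n, mean, sd, trunc = 2, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- stats::rnorm(1, mean, sd)
      if (abs(z - mean) <= trunc * sd && z > lower) break
    }
    out[i] <- z
  }
  out
}

wrap360 <- function(x) ((x %% 360) + 360) %% 360

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
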