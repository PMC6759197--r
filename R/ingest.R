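# Trial alignment and neurogram integration.
#
# Integration follows the standard cascade for ventral-root recordings:
# low-pass 200 Hz -> high-pass 10 Hz -> full-wave rectification -> low-pass
# 5 Hz (drug-induced episodes) or 20 Hz (stimulus-evoked episodes). Every
# stage is a zero-phase 4th-order Butterworth so burst timing is preserved.

#' Align a recording to its light or stimulus events
#'
#' Drug mode windows the recording to 55 s before light onset through 55 s
#' after light offset, with pre/light/post epochs. Evoked mode windows from
#' 1 s before the first stimulus to 4.5 s after the last (15.5 s for a
#' standard 4 Hz x 10 s train), with pre/train/post epochs.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param mode "drug" or "evoked".
#' @param pre,post retained margins in seconds (drug mode defaults 55/55;
#'   evoked mode defaults 1/4.5).
#' @return An \code{aligned_trial}: windowed data plus an epoch table in the
#'   source recording's time coordinates.
#' @export
align_trials <- function(rec, mode = c("drug", "evoked"), pre = NULL,
                         post = NULL) {
  mode <- match.arg(mode)
  if (inherits(rec, "aligned_trial")) return(rec)  # idempotent
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (mode == "drug") {
    if (is.null(rec$events$light_on) || is.null(rec$events$light_off))
      stop("missing light event: drug-mode alignment needs light_on/light_off")
    pre <- if (is.null(pre)) 55 else pre
    post <- if (is.null(post)) 55 else post
    w0 <- rec$events$light_on - pre
    w1 <- rec$events$light_off + post
    if (w0 < 0 || w1 > rec$duration)
      stop("alignment window [", w0, ", ", w1, "] exceeds the recording")
    epochs <- epoch_table(c("pre", "light", "post"),
                          c(w0, rec$events$light_on, rec$events$light_off),
                          c(rec$events$light_on, rec$events$light_off, w1))
  } else {
    if (is.null(rec$events$stim_times) || !length(rec$events$stim_times))
      stop("missing stimulus event: evoked-mode alignment needs stim_times")
    st <- sort(rec$events$stim_times)
    pre <- if (is.null(pre)) 1 else pre
    post <- if (is.null(post)) 4.5 else post
    w0 <- st[1] - pre
    # post margin runs from the end of the train (last pulse plus one
    # inter-pulse interval), so a 4 Hz x 10 s train keeps 15.5 s in total
    ipi <- if (length(st) > 1) stats::median(diff(st)) else 0
    w1 <- st[length(st)] + ipi + post
    if (w0 < 0 || w1 > rec$duration)
      stop("alignment window [", w0, ", ", w1, "] exceeds the recording")
    epochs <- epoch_table(c("pre", "train", "post"),
                          c(w0, st[1], st[length(st)]),
                          c(st[1], st[length(st)], w1))
  }
  i0 <- floor(w0 * fs) + 1L
  i1 <- min(nrow(rec$data), round(w1 * fs))
  structure(list(data = rec$data[i0:i1, , drop = FALSE], sampling_rate = fs,
                 channels = rec$channels, events = rec$events, mode = mode,
                 window = c(w0, w1), t0 = (i0 - 1) / fs, epochs = epochs,
                 group = rec$group),
            class = "aligned_trial")
}

#' Integrate a neurogram
#'
#' Applies, in order: low-pass 200 Hz, high-pass 10 Hz, full-wave
#' rectification, low-pass 5 Hz (drug) or 20 Hz (evoked). All stages are
#' zero-phase 4th-order Butterworth with odd-reflection edge padding (3x the
#' longest impulse-response proxy).
#'
#' @param trial an \code{aligned_trial} (or \code{raw_recording}, aligned
#'   implicitly when events allow; otherwise integrated whole).
#' @param mode "drug" (final corner 5 Hz) or "evoked" (20 Hz).
#' @param corners optional numeric c(lp1, hp, lp2) overriding the cascade
#'   corner frequencies in Hz.
#' @return An \code{integrated_neurogram} with the filter settings recorded.
#' @export
integrate_neurogram <- function(trial, mode = c("drug", "evoked"),
                                corners = NULL) {
  mode <- match.arg(mode)
  if (inherits(trial, "raw_recording"))
    trial <- list(data = trial$data, sampling_rate = trial$sampling_rate,
                  channels = trial$channels, events = trial$events, t0 = 0,
                  epochs = NULL, group = trial$group, mode = mode)
  fs <- trial$sampling_rate
  if (is.null(corners))
    corners <- c(200, 10, if (mode == "drug") 5 else 20)
  if (fs < 2 * max(corners))
    stop("sampling rate ", fs, " Hz too low for a ", max(corners),
         " Hz corner")
  env <- apply(trial$data, 2, function(x) {
    y <- butter_zerophase(x, fs, corners[1], "low")
    y <- butter_zerophase(y, fs, corners[2], "high")
    y <- abs(y)
    butter_zerophase(y, fs, corners[3], "low")
  })
  env <- pmax(env, 0)  # clip residual filter ringing below zero
  structure(list(env = env, sampling_rate = fs, corners = corners,
                 mode = mode, channels = trial$channels, t0 = trial$t0,
                 epochs = trial$epochs, group = trial$group),
            class = "integrated_neurogram")
}

#' Resample an integrated envelope
#'
#' Anti-aliased decimation to \code{target_rate} (default 19 Hz, the
#' spectrogram time base): a zero-phase Butterworth low-pass at 0.45x the
#' target rate followed by interpolation onto the exact target grid.
#'
#' @param env an \code{integrated_neurogram}.
#' @param target_rate output rate, Hz; must be below the current rate.
#' @return The envelope on the new grid; duration preserved within one
#'   output sample.
#' @export
resample_envelope <- function(env, target_rate = 19) {
  stopifnot(inherits(env, "integrated_neurogram"))
  fs <- env$sampling_rate
  if (target_rate >= fs)
    stop("resample_envelope decimates only: target_rate must be < ", fs, " Hz")
  n <- nrow(env$env)
  t_in <- env$t0 + (seq_len(n) - 1) / fs
  t_out <- seq(env$t0, env$t0 + (n - 1) / fs, by = 1 / target_rate)
  aa <- 0.45 * target_rate
  out <- apply(env$env, 2, function(x) {
    if (aa < fs / 2) x <- butter_zerophase(x, fs, aa, "low")
    stats::approx(t_in, x, xout = t_out)$y
  })
  res <- env
  res$env <- pmax(as.matrix(out), 0)
  res$sampling_rate <- target_rate
  res
}

#' Construct an integrated neurogram from bare envelope values
#'
#' For envelopes computed elsewhere (or built analytically in tests and
#' examples); the regular route is \code{\link{integrate_neurogram}}.
#'
#' @param env numeric vector or matrix (samples x channels), non-negative.
#' @param sampling_rate Hz.
#' @param t0 time of the first sample, seconds.
#' @param channels channel metadata data.frame (names generated if NULL).
#' @param epochs optional epoch table.
#' @param mode "drug" or "evoked" (controls downstream defaults).
#' @return An \code{integrated_neurogram}.
#' @export
as_integrated_neurogram <- function(env, sampling_rate, t0 = 0,
                                    channels = NULL, epochs = NULL,
                                    mode = "drug") {
  env <- as.matrix(env)
  if (is.null(channels))
    channels <- data.frame(name = paste0("ch", seq_len(ncol(env))),
                           role = "flexor", side = "left")
  stopifnot(sampling_rate > 0, nrow(channels) == ncol(env))
  structure(list(env = env, sampling_rate = sampling_rate, corners = NA,
                 mode = mode, channels = channels, t0 = t0, epochs = epochs,
                 group = "external"),
            class = "integrated_neurogram")
}

#' @export
print.integrated_neurogram <- function(x, ...) {
  cat("<integrated_neurogram> ", ncol(x$env), " channel(s), ",
      nrow(x$env), " samples at ", x$sampling_rate,
      " Hz; cascade corners ", paste(x$corners, collapse = "/"), " Hz (",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' Write / read a recording as delimited text with a JSON sidecar
#'
#' The trace file is tab-separated with a time column and one column per
#' channel; the sidecar (same path + ".json") stores sampling rate, channel
#' roles, events and group label.
#'
#' @param rec a \code{raw_recording}.
#' @param path output file path.
#' @return \code{write_recording}: the path, invisibly.
#'   \code{read_recording}: a \code{raw_recording}.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  df <- data.frame(time = (seq_len(nrow(rec$data)) - 1) / rec$sampling_rate,
                   rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               channels = rec$channels, events = rec$events,
               group = rec$group)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  raw_recording(as.matrix(df[, -1, drop = FALSE]), meta$sampling_rate,
                as.data.frame(meta$channels), meta$events, meta$group)
}
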