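# Calcium-imaging trace extraction and conditioning: grid and cell ROIs
# with doughnut neuropil annuli, neuropil subtraction, monoexponential
# bleach correction, dF/F and band-pass filtering, plus cycle-triggered
# averages on the frame grid. The processing-order contract (neuropil ->
# bleach -> dF/F -> band-pass) is enforced through state flags.

new_ca_trace <- function(value, times, roi = NA, flags = NULL, f0 = NA,
                         fit = NULL) {
  if (is.null(flags))
    flags <- list(neuropil_subtracted = FALSE, bleach_corrected = FALSE,
                  dff = FALSE, bandpassed = FALSE)
  structure(list(value = value, times = times, roi = roi, flags = flags,
                 f0 = f0, fit = fit),
            class = "calcium_trace")
}

#' Six-rectangle grid ROI set
#'
#' Six identical, contiguous, non-overlapping rectangles tiling the field
#' dorsoventrally (along the first/row dimension). If the height is not
#' divisible by six, the last ROI absorbs the remainder.
#'
#' @param field c(height, width) in pixels (height >= 6).
#' @return list of 6 ROIs, each list(rows = c(r0, r1), cols = c(c0, c1)).
#' @export
make_grid_rois <- function(field) {
  ny <- field[1]; nx <- field[2]
  if (ny < 6) stop("field must be at least 6 pixels tall")
  h <- ny %/% 6
  lapply(seq_len(6), function(i) {
    r1 <- if (i == 6) ny else i * h
    list(rows = c((i - 1) * h + 1, r1), cols = c(1, nx), type = "rect",
         name = paste0("roi", i))
  })
}

roi_mask <- function(roi, field) {
  m <- matrix(FALSE, field[1], field[2])
  if (!is.null(roi$mask)) return(roi$mask)
  m[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]] <- TRUE
  m
}

#' Cell and doughnut (neuropil) ROI masks
#'
#' Each cell disc is paired with an annulus from the cell boundary out to
#' \code{outer} x radius, excluding the pixels of every cell ROI.
#'
#' @param cells data.frame(x, y, radius) in pixels.
#' @param field c(height, width).
#' @param outer outer annulus radius as a multiple of the cell radius (2).
#' @return list per cell: list(cell = mask, doughnut = mask).
#' @export
make_cell_rois <- function(cells, field, outer = 2) {
  ny <- field[1]; nx <- field[2]
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  discs <- lapply(seq_len(nrow(cells)), function(i)
    (xg - cells$x[i])^2 + (yg - cells$y[i])^2 <= cells$radius[i]^2)
  all_cells <- Reduce(`|`, discs)
  lapply(seq_len(nrow(cells)), function(i) {
    d2 <- (xg - cells$x[i])^2 + (yg - cells$y[i])^2
    ann <- d2 <= (outer * cells$radius[i])^2 & !all_cells
    list(cell = list(mask = discs[[i]], name = paste0("cell", i)),
         doughnut = list(mask = ann, name = paste0("doughnut", i)))
  })
}

#' Extract a mean-pixel trace from an image stack
#'
#' @param stack a \code{calcium_stack} (list with \code{data} ny x nx x
#'   nframes, \code{frame_rate}, \code{times}).
#' @param roi an ROI (rect or mask form).
#' @return A \code{calcium_trace} (per-frame mean over the ROI pixels).
#' @export
extract_trace <- function(stack, roi) {
  dims <- dim(stack$data)
  m <- roi_mask(roi, dims[1:2])
  if (!any(m)) stop("empty ROI")
  idx <- which(m)
  npx <- length(idx)
  nf <- dims[3]
  flat <- matrix(stack$data, dims[1] * dims[2], nf)
  new_ca_trace(colSums(flat[idx, , drop = FALSE]) / npx, stack$times,
               roi = if (is.null(roi$name)) NA else roi$name)
}

check_stage <- function(trace, forbid, doing) {
  bad <- forbid[unlist(trace$flags[forbid])]
  if (length(bad))
    stop("cannot apply ", doing, " after ", paste(bad, collapse = ", "),
         ": processing order is neuropil -> bleach -> dF/F -> band-pass")
}

#' Subtract the doughnut (neuropil) trace from a cell trace
#'
#' @param cell,doughnut \code{calcium_trace}s on the same frame grid.
#' @return The subtracted \code{calcium_trace}.
#' @export
doughnut_subtract <- function(cell, doughnut) {
  stopifnot(inherits(cell, "calcium_trace"), inherits(doughnut, "calcium_trace"))
  if (length(cell$times) != length(doughnut$times) ||
      max(abs(cell$times - doughnut$times)) > 1e-9)
    stop("cell and doughnut traces are not on the same frame grid")
  check_stage(cell, c("neuropil_subtracted", "bleach_corrected", "dff",
                      "bandpassed"), "neuropil subtraction")
  out <- cell
  out$value <- cell$value - doughnut$value
  out$flags$neuropil_subtracted <- TRUE
  out
}

#' Correct a trace for photobleaching
#'
#' Fits a e^{-t/tau} + c by nonlinear least squares and subtracts the
#' fitted exponential component only (the constant camera baseline is
#' retained). A non-convergent fit falls back to a linear detrend with a
#' warning.
#'
#' @param trace a \code{calcium_trace} with >= 20 frames.
#' @return The corrected \code{calcium_trace}; fit parameters recorded in
#'   \code{$fit}.
#' @export
bleach_correct <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (length(trace$value) < 20) stop("bleach correction needs >= 20 frames")
  check_stage(trace, c("bleach_corrected", "dff", "bandpassed"),
              "bleach correction")
  y <- trace$value
  t <- trace$times - trace$times[1]
  span <- max(t)
  a0 <- y[1] - y[length(y)]
  fit <- NULL
  if (abs(a0) > 1e-12 * max(abs(y), 1)) {
    # bounds keep the fit away from the degenerate a <-> c tradeoff at
    # tau >> record length (an exponential indistinguishable from a line)
    rng <- diff(range(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c,
                        start = list(a = a0, tau = span / 3,
                                     c = y[length(y)]),
                        lower = c(a = -2 * rng, tau = span / 100,
                                  c = min(y) - 2 * rng),
                        upper = c(a = 2 * rng, tau = 20 * span,
                                  c = max(y) + 2 * rng),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  out <- trace
  if (!is.null(fit) && stats::coef(fit)[["tau"]] > 0) {
    cf <- stats::coef(fit)
    out$value <- y - cf[["a"]] * exp(-t / cf[["tau"]])
    out$fit <- list(a = cf[["a"]], tau = cf[["tau"]], c = cf[["c"]],
                    method = "monoexponential")
  } else {
    if (!is.null(fit) || abs(a0) > 1e-12 * max(abs(y), 1))
      warning("monoexponential bleach fit did not converge; ",
              "falling back to linear detrend")
    lf <- stats::lm(y ~ t)
    out$value <- y - stats::coef(lf)[[2]] * t
    out$fit <- list(slope = stats::coef(lf)[[2]], method = "linear")
  }
  out$flags$bleach_corrected <- TRUE
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' \deqn{\Delta f = 100 (f - f_0)/f_0} with \eqn{f_0} the trace minimum, so
#' the output minimum is 0.
#'
#' @param trace a \code{calcium_trace}; its minimum must be positive.
#' @return The \code{calcium_trace} in percent units.
#' @export
dff <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  check_stage(trace, c("dff", "bandpassed"), "dF/F")
  f0 <- min(trace$value)
  if (f0 <= 0)
    stop("f0 = min(trace) must be > 0; restore the baseline offset before dF/F")
  out <- trace
  out$value <- 100 * (trace$value - f0) / f0
  out$f0 <- f0
  out$flags$dff <- TRUE
  out
}

#' Band-pass filter a calcium trace
#'
#' Zero-phase Butterworth band-pass in [0.05, 0.8] Hz by default.
#'
#' @param trace a \code{calcium_trace}.
#' @param band numeric c(low, high), Hz; the frame rate must exceed twice
#'   the upper corner.
#' @param order per-pass Butterworth order (2).
#' @return The filtered \code{calcium_trace}.
#' @export
bandpass_ca <- function(trace, band = c(0.05, 0.8), order = 2) {
  stopifnot(inherits(trace, "calcium_trace"))
  check_stage(trace, "bandpassed", "band-pass")
  fr <- 1 / stats::median(diff(trace$times))
  if (fr <= 2 * band[2])
    stop("frame rate ", round(fr, 2), " Hz too low for a ", band[2],
         " Hz upper corner")
  bf <- signal::butter(order, band / (fr / 2), type = "pass")
  out <- trace
  out$value <- zerophase_filter(trace$value, bf$b, bf$a,
                                pad = ceiling(3 * fr / band[1]))
  out$flags$bandpassed <- TRUE
  out
}

#' Cycle-triggered average of a calcium trace
#'
#' Same contract as the intracellular CTA, on the (slow) calcium frame
#' grid; requires at least 3 cycles overlapping the trace.
#'
#' @param trace a \code{calcium_trace}.
#' @param onsets cycle onset times from the ventral-root burst table, s.
#' @param n_bins phase bins per cycle (50: the frame grid is coarse).
#' @return A \code{cycle_triggered_average}.
#' @export
ca_cycle_triggered_average <- function(trace, onsets, n_bins = 50) {
  stopifnot(inherits(trace, "calcium_trace"))
  onsets <- sort(onsets)
  onsets <- onsets[onsets >= min(trace$times) - 1e-9]
  onsets <- onsets[onsets <= max(trace$times) + 1e-9]
  if (length(onsets) - 1 < 3)
    stop("cycle-triggered averaging needs >= 3 cycles overlapping the trace")
  fr <- 1 / stats::median(diff(trace$times))
  x <- trace$value
  n_cyc <- length(onsets) - 1
  M <- matrix(NA_real_, n_cyc, n_bins)
  for (i in seq_len(n_cyc)) {
    ph <- onsets[i] + (seq_len(n_bins) - 0.5) / n_bins *
      (onsets[i + 1] - onsets[i])
    if (ph[1] < trace$times[1] || ph[n_bins] > trace$times[length(x)]) next
    M[i, ] <- stats::approx(trace$times, x, ph)$y
  }
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 3) stop("fewer than 3 complete cycles overlap the trace")
  mu <- colMeans(M)
  structure(list(phase = (seq_len(2 * n_bins) - 0.5) / n_bins,
                 mean = rep(mu, 2), sd = rep(apply(M, 2, stats::sd), 2),
                 n_cycles = nrow(M), amplitude = max(mu) - min(mu),
                 trough = min(mu), sd_available = TRUE,
                 peak_phase = (which.max(mu) - 0.5) / n_bins),
            class = "cycle_triggered_average")
}

#' Write / read a calcium stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages; frame rate is restored
#' from a JSON sidecar.
#'
#' @param stack a \code{calcium_stack}.
#' @param path file path (.tif).
#' @return \code{write_calcium_tiff}: the path, invisibly;
#'   \code{read_calcium_tiff}: a \code{calcium_stack}.
#' @export
write_calcium_tiff <- function(stack, path) {
  # float TIFF pages live in [0, 1]; the intensity scale is restored from
  # the sidecar
  lo <- min(stack$data)
  hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k)
    (stack$data[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_rate = stack$frame_rate, offset = lo,
                            scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calcium_tiff
#' @export
read_calcium_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  off <- if (is.null(meta$offset)) 0 else meta$offset
  sc <- if (is.null(meta$scale)) 1 else meta$scale
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * sc + off
  structure(list(data = arr, frame_rate = meta$frame_rate,
                 times = (seq_along(pages) - 1) / meta$frame_rate,
                 field = dim(pages[[1]])),
            class = "calcium_stack")
}
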