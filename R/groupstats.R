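# Group-level comparison of normalized time series: experiment-wise
# aggregation and a pointwise bootstrap t test with banded significance.

#' Aggregate normalized series into a group matrix
#'
#' Trials are averaged within experiment (pairwise-complete over missing
#' bins); the per-experiment averages are stacked as the group members.
#'
#' @param experiments list of experiments; each experiment is a list of
#'   \code{\link{rhythm_series}} (its trials) or a single series.
#' @param label group label.
#' @return A \code{series_group}: list(values = experiments x time matrix,
#'   time, label, n); the grand mean is exposed via \code{grand_mean}.
#' @export
aggregate_series <- function(experiments, label = "group") {
  stopifnot(length(experiments) >= 1)
  as_list <- lapply(experiments, function(e)
    if (inherits(e, "rhythm_series")) list(e) else e)
  tref <- as_list[[1]][[1]]$time
  rows <- t(vapply(as_list, function(trials) {
    m <- vapply(trials, function(tr) {
      if (length(tr$time) != length(tref) ||
          max(abs(tr$time - tref)) > 1e-6 * max(1, diff(range(tref))))
        stop("trial series are not on a common time grid")
      tr$value
    }, numeric(length(tref)))
    rowMeans(matrix(m, nrow = length(tref)), na.rm = TRUE)
  }, numeric(length(tref))))
  structure(list(values = rows, time = tref, label = label,
                 n = length(experiments)),
            class = "series_group")
}

#' @rdname aggregate_series
#' @param group a \code{series_group}.
#' @export
grand_mean <- function(group) {
  stopifnot(inherits(group, "series_group"))
  colMeans(group$values, na.rm = TRUE)
}

# Welch t statistic per column for two value matrices (members x time).
col_moments <- function(M) {
  n <- colSums(!is.na(M))
  s1 <- colSums(M, na.rm = TRUE)
  s2 <- colSums(M * M, na.rm = TRUE)
  m <- s1 / n
  list(n = n, m = m, v = pmax(s2 - n * m^2, 0) / pmax(n - 1, 1))
}

welch_t_cols <- function(A, B) {
  a <- col_moments(A); b <- col_moments(B)
  nA <- a$n; nB <- b$n; mA <- a$m; mB <- b$m
  se2 <- a$v / nA + b$v / nB
  t <- (mA - mB) / sqrt(se2)
  d <- mA - mB
  t[se2 == 0 & d == 0] <- 0
  t[se2 == 0 & d != 0] <- Inf * sign(d[se2 == 0 & d != 0])
  t[nA < 2 | nB < 2] <- NA
  t
}

#' Pointwise bootstrap t test between two series groups
#'
#' Per timepoint, the observed statistic is the Welch t between the two
#' groups' experiment-level values. The null is built by centering each
#' group on the pooled mean and resampling experiments with replacement
#' within each group; the two-sided p-value uses the +1-corrected empirical
#' tail, so p is never 0. Deterministic given \code{seed}.
#'
#' @param a,b \code{series_group}s on a common grid, each with >= 2 members.
#' @param iterations bootstrap iterations (10,000 by default).
#' @param seed integer seed.
#' @return A \code{bootstrap_result}: data.frame(time, t, p, band) plus
#'   iteration count and seed.
#' @export
bootstrap_timeseries_test <- function(a, b, iterations = 10000, seed = 1) {
  stopifnot(inherits(a, "series_group"), inherits(b, "series_group"))
  if (length(a$time) != length(b$time) ||
      max(abs(a$time - b$time)) > 1e-6 * max(1, diff(range(a$time))))
    stop("groups are not on a common time grid")
  if (a$n < 2 || b$n < 2) stop("each group needs >= 2 experiments")
  A <- a$values; B <- b$values
  nT <- ncol(A)
  t_obs <- welch_t_cols(A, B)

  # center both groups on the pooled (combined-member) mean per timepoint
  pool <- colMeans(rbind(A, B), na.rm = TRUE)
  Ac <- sweep(A, 2, colMeans(A, na.rm = TRUE)) + rep(pool, each = nrow(A))
  Bc <- sweep(B, 2, colMeans(B, na.rm = TRUE)) + rep(pool, each = nrow(B))

  # draw resamples in sorted-label order, so exchanging the group arguments
  # reproduces the identical null distribution (two-sided symmetry)
  swap <- a$label > b$label
  G1 <- if (swap) Bc else Ac
  G2 <- if (swap) Ac else Bc
  exceed <- numeric(nT)
  with_seed(seed, {
    for (r in seq_len(iterations)) {
      R1 <- G1[sample.int(nrow(G1), replace = TRUE), , drop = FALSE]
      R2 <- G2[sample.int(nrow(G2), replace = TRUE), , drop = FALSE]
      ts <- welch_t_cols(R1, R2)
      exceed <- exceed + as.numeric(!is.na(ts) & abs(ts) >= abs(t_obs))
    }
  })
  p <- (1 + exceed) / (iterations + 1)
  p[is.na(t_obs)] <- NA
  res <- data.frame(time = a$time, t = t_obs, p = p,
                    band = significance_bands(p))
  structure(list(table = res, iterations = iterations, seed = seed,
                 groups = c(a$label, b$label)),
            class = "bootstrap_result")
}

#' Map p-values to display bands
#'
#' Bands follow the strict-inequality convention: ns for p >= 0.05, then
#' "<0.05", "<0.01", "<0.001" and "<0.0001" on half-open intervals.
#'
#' @param p numeric p-values in (0, 1] (a \code{bootstrap_result} is also
#'   accepted).
#' @return factor with levels ns, <0.05, <0.01, <0.001, <0.0001.
#' @export
significance_bands <- function(p) {
  if (inherits(p, "bootstrap_result")) p <- p$table$p
  cut(p, breaks = c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1),
      labels = c("<0.0001", "<0.001", "<0.01", "<0.05", "ns"),
      right = FALSE, include.lowest = TRUE)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$groups[1], " vs ", x$groups[2], ", ",
      x$iterations, " iterations (seed ", x$seed, ")\n", sep = "")
  print(table(x$table$band))
  invisible(x)
}
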