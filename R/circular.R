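# Circular statistics for burst-phase data: descriptive resultants, the
# Rayleigh uniformity test, the Watson-Williams equal-means test and the
# Harrison-Kanji two-way ANOVA for angles. Angles are degrees externally and
# radians internally.

circ_resultant <- function(rad, w = NULL) {
  if (is.null(w)) w <- rep(1, length(rad))
  C <- sum(w * cos(rad)); S <- sum(w * sin(rad))
  list(C = C, S = S, R = sqrt(C^2 + S^2), n = sum(w))
}

#' Circular mean and mean resultant length
#'
#' @param angles angles in degrees.
#' @param weights optional non-negative weights.
#' @return list(mean = mean angle in [0,360) degrees (NA when R = 0),
#'   R = mean resultant length in [0,1], n).
#' @export
circ_mean_r <- function(angles, weights = NULL) {
  if (!length(angles)) stop("empty circular sample")
  r <- circ_resultant(deg2rad(wrap360(angles)), weights)
  Rbar <- r$R / r$n
  mu <- if (Rbar < 1e-12) NA_real_ else wrap360(rad2deg(atan2(r$S, r$C)))
  list(mean = mu, R = Rbar, n = r$n)
}

#' Rayleigh test of circular uniformity
#'
#' Standard approximation with the finite-n correction:
#' \deqn{p = e^{-Z}[1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]}
#' with \eqn{Z = n \bar{R}^2}.
#'
#' @param angles angles in degrees (n >= 3).
#' @return list(p, R, Z, n).
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3) stop("Rayleigh test needs n >= 3")
  Rbar <- circ_mean_r(angles)$R
  Z <- n * Rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, R = Rbar, Z = Z, n = n)
}

# Inverse of A1(kappa) = I1(kappa)/I0(kappa): maximum-likelihood kappa from
# a mean resultant length (Fisher's approximation).
a1inv <- function(R) {
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

#' Watson-Williams test for equal circular means
#'
#' One-way equal-means test for k groups of angles with the standard
#' concentration correction \eqn{K = 1 + 3/(8\hat\kappa)}:
#' \deqn{F = K \frac{(N - k)(\sum_i R_i - R)}{(k - 1)(N - \sum_i R_i)}}
#' A warning is attached when the pooled mean resultant length is below the
#' test's usual validity range (R̄ < 0.45) rather than failing hard, since
#' locomotor phase samples are often small.
#'
#' @param groups list of angle vectors (degrees), each with n >= 3.
#' @return list(F, df1, df2, p, kappa, warning).
#' @export
watson_williams <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  if (any(vapply(groups, length, 0L) < 3))
    stop("each group needs n >= 3")
  rads <- lapply(groups, function(g) deg2rad(wrap360(g)))
  Ri <- vapply(rads, function(r) circ_resultant(r)$R, numeric(1))
  all_r <- unlist(rads)
  N <- length(all_r)
  R <- circ_resultant(all_r)$R
  rw <- sum(Ri) / N
  warn <- NULL
  if (rw < 0.45)
    warn <- paste0("mean resultant length ", round(rw, 3),
                   " below the Watson-Williams validity range (0.45)")
  kap <- a1inv(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  out <- list(F = Fstat, df1 = k - 1, df2 = N - k, p = p, kappa = kap,
              warning = warn)
  if (!is.null(warn)) warning(warn)
  out
}

#' Harrison-Kanji two-way ANOVA for circular data
#'
#' Two crossed factors; sums of squares are decomposed from cell, row,
#' column and total resultant lengths. At high concentration
#' (\eqn{\hat\kappa > 2}) effects are tested with F statistics carrying the
#' \eqn{1 + 3/(8\hat\kappa)} correction; at low concentration the
#' chi-squared large-sample variant with doubled degrees of freedom is used.
#'
#' @param angles angles in degrees.
#' @param factor_a,factor_b factor labels (>= 2 levels each, every cell
#'   n >= 2).
#' @return data.frame with one row per effect (A, B, interaction): df, SS,
#'   statistic, p, plus attributes kappa and variant.
#' @export
harrison_kanji <- function(angles, factor_a, factor_b) {
  stopifnot(length(angles) == length(factor_a),
            length(angles) == length(factor_b))
  fa <- factor(factor_a); fb <- factor(factor_b)
  pl <- nlevels(fa); ql <- nlevels(fb)
  stopifnot(pl >= 2, ql >= 2)
  cells <- table(fa, fb)
  if (any(cells < 2)) stop("every factor cell needs n >= 2")
  rad <- deg2rad(wrap360(angles))
  n <- length(rad)
  res_of <- function(idx) circ_resultant(rad[idx])$R
  tR <- res_of(seq_len(n))
  pR <- vapply(levels(fa), function(l) res_of(which(fa == l)), numeric(1))
  pn <- as.numeric(table(fa))
  qR <- vapply(levels(fb), function(l) res_of(which(fb == l)), numeric(1))
  qn <- as.numeric(table(fb))
  cR <- matrix(0, pl, ql); cn <- matrix(0, pl, ql)
  for (i in seq_len(pl)) for (j in seq_len(ql)) {
    idx <- which(fa == levels(fa)[i] & fb == levels(fb)[j])
    cR[i, j] <- res_of(idx); cn[i, j] <- length(idx)
  }
  kap <- a1inv(tR / n)
  df <- c(A = pl - 1, B = ql - 1, interaction = (pl - 1) * (ql - 1))
  df_r <- n - pl * ql
  if (kap > 2) {
    # high concentration: Watson-Williams-style decomposition on plain
    # resultant lengths, F tests with the 1 + 3/(8 kappa) correction
    ss_a <- sum(pR) - tR
    ss_b <- sum(qR) - tR
    ss_cells <- sum(cR) - tR
    ss <- pmax(c(A = ss_a, B = ss_b,
                 interaction = ss_cells - ss_a - ss_b), 0)
    ss_r <- n - sum(cR)
    corr <- 1 + 3 / (8 * kap)
    stat <- corr * (ss / df) / (ss_r / df_r)
    p <- stats::pf(stat, df, df_r, lower.tail = FALSE)
    variant <- "high-concentration F"
  } else {
    # low concentration: chi-squared large-sample variant on squared
    # resultants with doubled degrees of freedom
    ss_a <- sum(pR^2 / pn) - tR^2 / n
    ss_b <- sum(qR^2 / qn) - tR^2 / n
    ss_cells <- sum(cR^2 / cn) - tR^2 / n
    ss <- pmax(c(A = ss_a, B = ss_b,
                 interaction = ss_cells - ss_a - ss_b), 0)
    stat <- 2 * ss
    p <- stats::pchisq(stat, 2 * df, lower.tail = FALSE)
    variant <- "low-concentration chi-squared"
  }
  out <- data.frame(effect = names(df), df = as.numeric(df),
                    SS = as.numeric(ss), statistic = as.numeric(stat),
                    p = as.numeric(p))
  attr(out, "kappa") <- kap
  attr(out, "variant") <- variant
  attr(out, "df_resid") <- df_r
  out
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used by the synthetic phase scenarios and
#' the Monte-Carlo oracles.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0; 0 = uniform).
#' @return angles in degrees in [0, 360).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu_r + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap360(rad2deg(out))
}
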