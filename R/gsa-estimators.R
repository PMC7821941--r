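# Global sensitivity estimators.
#
# Six standard GSA algorithms, each with its usual sampling plan and
# estimator, operating on a vectorized model f: [lower, upper]^d -> R.
# All return a named score vector (one score per parameter, larger =
# more influential):
#   gsa_sobol    first-order Sobol index (Saltelli estimator)
#   gsa_morris   mu* (mean absolute elementary effect)
#   gsa_fast     first-order index by Fourier amplitude test
#   gsa_rbdfast  first-order index by random balance design FAST
#   gsa_dgsm     derivative-based measure, scaled to bound total indices
#   gsa_dmim     Borgonovo delta moment-independent measure
# Callers are responsible for seeding the RNG; each function draws from
# the current RNG state only, so a fixed seed gives identical results.

scale_unit <- function(U, lower, upper) {
  sweep(sweep(U, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Sobol first-order indices (Saltelli estimator)
#'
#' Two base Latin hypercube samples A and B of size `n` plus the d
#' radial-substitution matrices AB_i give the Saltelli (2010) first-order
#' estimator `S_i = mean(f(B) * (f(AB_i) - f(A))) / V` at a cost of
#' `n * (d + 2)` model evaluations.
#'
#' @param model Vectorized function of a parameter matrix.
#' @param lower,upper Named bound vectors.
#' @param n Base sample size.
#' @return Named vector of first-order indices.
#' @export
gsa_sobol <- function(model, lower, upper, n = 1024) {
  d <- length(lower)
  if (n < 2) stop("gsa_sobol: base sample size must be >= 2", call. = FALSE)
  A <- scale_unit(lhs::randomLHS(n, d), lower, upper)
  B <- scale_unit(lhs::randomLHS(n, d), lower, upper)
  fA <- model(A)
  fB <- model(B)
  V <- stats::var(c(fA, fB))
  s <- numeric(d)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    s[i] <- mean(fB * (model(ABi) - fA)) / V
  }
  stats::setNames(s, names(lower))
}

#' Morris elementary-effects mu*
#'
#' `r` one-at-a-time trajectories on a `levels`-level grid with step
#' `delta = levels / (2 * (levels - 1))`; the score is the mean absolute
#' elementary effect in normalized units.
#'
#' @inheritParams gsa_sobol
#' @param r Number of trajectories.
#' @param levels Grid levels (even).
#' @return Named vector of mu* scores.
#' @export
gsa_morris <- function(model, lower, upper, r = 100, levels = 4) {
  d <- length(lower)
  if (r < 2) stop("gsa_morris: need at least 2 trajectories", call. = FALSE)
  delta <- levels / (2 * (levels - 1))
  base_levels <- (seq_len(levels / 2) - 1) / (levels - 1)  # grid below 1-delta
  ee <- matrix(NA_real_, r, d)
  for (tr in seq_len(r)) {
    x <- sample(base_levels, d, replace = TRUE)
    dirs <- sample(c(-1, 1), d, replace = TRUE)
    # flip directions that would leave [0, 1]
    dirs[x + dirs * delta > 1 | x + dirs * delta < 0] <-
      -dirs[x + dirs * delta > 1 | x + dirs * delta < 0]
    ord <- sample.int(d)
    path <- matrix(x, d + 1, d, byrow = TRUE)
    for (k in seq_len(d)) {
      path[(k + 1):(d + 1), ord[k]] <- x[ord[k]] + dirs[ord[k]] * delta
    }
    y <- model(scale_unit(path, lower, upper))
    ee[tr, ord] <- (y[-1] - y[-(d + 1)]) / (dirs[ord] * delta)
  }
  stats::setNames(colMeans(abs(ee)), names(lower))
}

fast_spectrum_index <- function(y, s, omega, M) {
  # fraction of spectral variance at omega and its first M harmonics
  harmonics <- function(w) {
    a <- mean(y * cos(w * s))
    b <- mean(y * sin(w * s))
    a^2 + b^2
  }
  nhalf <- floor((length(y) - 1) / 2)
  total <- sum(vapply(seq_len(nhalf), harmonics, numeric(1)))
  part <- sum(vapply(omega * seq_len(M), harmonics, numeric(1)))
  part / total
}

#' FAST first-order indices
#'
#' Classic Fourier amplitude sensitivity test: for each parameter in turn,
#' the parameter of interest is driven at a high frequency and the
#' complementary set at low frequencies along the search curve
#' `x = 1/2 + asin(sin(omega * s + phi)) / pi`; the first-order index is
#' the spectral variance at the driving frequency and its first `M`
#' harmonics over the total. Random phase shifts make independent
#' replicates possible.
#'
#' @inheritParams gsa_sobol
#' @param n Points per search curve (odd preferred).
#' @param M Number of harmonics.
#' @return Named vector of first-order indices.
#' @export
gsa_fast <- function(model, lower, upper, n = 1025, M = 4) {
  d <- length(lower)
  if (n <= 4 * M^2) {
    stop("gsa_fast: sample size must exceed 4*M^2", call. = FALSE)
  }
  omega_max <- floor((n - 1) / (2 * M))
  omega_comp <- max(1, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(n) - n - 1) / n
  out <- numeric(d)
  for (i in seq_len(d)) {
    omega <- rep(seq_len(omega_comp), length.out = d)
    omega[i] <- omega_max
    phi <- stats::runif(d, 0, 2 * pi)
    U <- vapply(seq_len(d), function(j) {
      0.5 + asin(sin(omega[j] * s + phi[j])) / pi
    }, numeric(n))
    y <- model(scale_unit(U, lower, upper))
    out[i] <- fast_spectrum_index(y, s, omega_max, M)
  }
  stats::setNames(out, names(lower))
}

#' RBD-FAST first-order indices
#'
#' Random balance design FAST: all parameters follow the same
#' single-frequency search curve under independent random permutations;
#' re-ordering the output by each parameter's curve position concentrates
#' that parameter's variance at the base frequency. Includes the standard
#' small-sample bias correction.
#'
#' @inheritParams gsa_sobol
#' @param n Sample size.
#' @param M Number of harmonics retained.
#' @return Named vector of first-order indices.
#' @export
gsa_rbdfast <- function(model, lower, upper, n = 4096, M = 10) {
  d <- length(lower)
  if (n < 4 * M) stop("gsa_rbdfast: sample size too small", call. = FALSE)
  s0 <- seq(-pi, pi, length.out = n)
  perms <- vapply(seq_len(d), function(j) sample.int(n), integer(n))
  S <- vapply(seq_len(d), function(j) s0[perms[, j]], numeric(n))
  U <- 0.5 + asin(sin(S)) / pi
  y <- model(scale_unit(U, lower, upper))
  out <- numeric(d)
  for (i in seq_len(d)) {
    yo <- y[order(S[, i])]
    spec <- Mod(stats::fft(yo))^2 / n^2
    V <- sum(spec[2:n]) # total spectral variance, DC removed
    s1 <- 2 * sum(spec[seq_len(M) + 1]) / V
    out[i] <- s1 - (2 * M / n) * (1 - s1)  # bias correction
  }
  stats::setNames(out, names(lower))
}

#' Derivative-based global sensitivity measure
#'
#' Mean squared partial derivative over the input box, estimated by
#' forward finite differences at a Latin hypercube base sample and scaled
#' by `(upper - lower)^2 / (pi^2 * V)`, the Sobol-Kucherenko upper bound
#' on the total-effect index for uniform inputs.
#'
#' @inheritParams gsa_sobol
#' @param n Base points.
#' @param step Finite-difference step as a fraction of each range.
#' @return Named vector of scaled derivative measures (>= 0).
#' @export
gsa_dgsm <- function(model, lower, upper, n = 512, step = 1e-4) {
  d <- length(lower)
  if (n < 2) stop("gsa_dgsm: need at least 2 base points", call. = FALSE)
  U <- lhs::randomLHS(n, d) * (1 - step)  # keep x + h inside the box
  X <- scale_unit(U, lower, upper)
  f0 <- model(X)
  V <- stats::var(f0)
  out <- numeric(d)
  for (i in seq_len(d)) {
    h <- step * (upper[i] - lower[i])
    Xi <- X
    Xi[, i] <- Xi[, i] + h
    out[i] <- mean(((model(Xi) - f0) / h)^2) *
      (upper[i] - lower[i])^2 / (pi^2 * V)
  }
  stats::setNames(out, names(lower))
}

#' Delta moment-independent measure
#'
#' Borgonovo's delta: the expected shift between the unconditional output
#' density and the density conditional on each input, estimated by
#' equal-frequency binning of the input and kernel density estimates on a
#' common grid.
#'
#' @inheritParams gsa_sobol
#' @param n Sample size.
#' @param bins Number of conditioning classes per input.
#' @return Named vector of delta estimates in `[0, 1]`.
#' @export
gsa_dmim <- function(model, lower, upper, n = 4096, bins = 16) {
  d <- length(lower)
  if (n < bins * 8) stop("gsa_dmim: sample too small for bin count",
                         call. = FALSE)
  X <- scale_unit(lhs::randomLHS(n, d), lower, upper)
  y <- model(X)
  lo <- min(y); hi <- max(y)
  bw <- stats::bw.nrd0(y)
  grid_n <- 512L
  fy <- stats::density(y, bw = bw, from = lo, to = hi, n = grid_n)$y
  dx <- (hi - lo) / (grid_n - 1)
  out <- numeric(d)
  for (i in seq_len(d)) {
    qs <- stats::quantile(X[, i], probs = seq(0, 1, length.out = bins + 1))
    cls <- cut(X[, i], unique(qs), include.lowest = TRUE)
    acc <- 0
    for (lev in levels(cls)) {
      sel <- cls == lev
      m <- sum(sel)
      if (m < 2) next
      fm <- stats::density(y[sel], bw = bw, from = lo, to = hi,
                           n = grid_n)$y
      acc <- acc + (m / n) * 0.5 * sum(abs(fy - fm)) * dx
    }
    out[i] <- acc
  }
  stats::setNames(out, names(lower))
}
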