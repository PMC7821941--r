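# Independent oracles used across the suite.

# Trapezoidal quadrature of f on [0, b] with n panels.
trapezoid <- function(f, b, n = 1e4) {
  x <- seq(0, b, length.out = n + 1)
  y <- f(x)
  sum((y[-1] + y[-(n + 1)]) / 2) * (b / n)
}

# Growth-phase glucose by explicit per-period summation over the stepwise
# doubling trajectory: the population is N0 * 2^i during period i, plus a
# partial final period. Built as a loop, independent of the closed form.
stepwise_glucose_sum <- function(rate, n0, td, duration) {
  total <- 0
  t <- 0
  i <- 0
  while (t + td <= duration + 1e-12) {
    total <- total + rate * n0 * 2^i * td
    t <- t + td
    i <- i + 1
  }
  total + rate * n0 * 2^i * (duration - t)
}

# Ishigami test function and its analytic first-order Sobol indices.
ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

ishigami_s1 <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  vtot <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  c(x1 = v1 / vtot, x2 = v2 / vtot, x3 = 0)
}

ishigami_bounds <- function() {
  list(lower = stats::setNames(rep(-pi, 3), c("x1", "x2", "x3")),
       upper = stats::setNames(rep(pi, 3), c("x1", "x2", "x3")))
}
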