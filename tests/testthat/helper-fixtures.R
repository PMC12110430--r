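# Small generators shared across test files.

# random regression instance with a centered candidate matrix
rand_instance <- function(n, p, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  cc <- cptboot:::center_cols(y, Z)
  list(y = cc$y, Z = cc$Z, usable = cc$usable)
}

# noiseless piecewise series with an intercept and one random regressor
noiseless_one_change <- function(n, a, seed = 1) {
  set.seed(seed)
  x <- cbind(1, rnorm(n))
  sim_cpreg(x, beta1 = c(1, 1), deltas = list(c(3, 2)), a = a, sd = 0)
}

# brute-force two-regime SSE split: fit separate regressions before and
# after every split h and return the h minimising the total SSE
brute_force_split <- function(yw, xw, h_grid) {
  sse <- vapply(h_grid, function(h) {
    n <- length(yw)
    f1 <- stats::lm.fit(xw[1:h, , drop = FALSE], yw[1:h])
    f2 <- stats::lm.fit(xw[(h + 1):n, , drop = FALSE], yw[(h + 1):n])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, numeric(1))
  h_grid[which.min(sse)]
}
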