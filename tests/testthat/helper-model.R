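# Shared fixtures and oracles for the test-suite.

# central finite-difference Jacobian of rhs_reduced (independent oracle)
fd_jacobian <- function(state, params, rel_step = 1e-6) {
  x <- c(Sg = state[[1]], Ig = state[[2]], Ip = state[[3]])
  J <- matrix(0, 3, 3, dimnames = list(names(x), names(x)))
  for (j in 1:3) {
    h <- rel_step * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (rhs_reduced(xp, params) - rhs_reduced(xm, params)) / (2 * h)
  }
  J
}

# random state strictly inside the invariant region, away from Ng = 0
random_interior_state <- function(params) {
  c(Sg = runif(1, 1, 0.5 * params$K),
    Ig = runif(1, 1, 0.2 * params$K),
    Ip = runif(1, 0, 0.95 * params$P))
}

# sampling bounds that force a coexistence-capable regime
# (beta1 > b, beta3 > mu2)
coexistence_bounds <- function() {
  b <- default_bounds()
  b$b <- c(0.10, 0.30)
  b$beta1 <- c(0.31, 0.60)
  b$mu2 <- c(0.010, 0.019)
  b$beta3 <- c(0.02, 0.10)
  b
}

# bounds forcing the corruption-free regime beta3 < mu2
corruption_free_bounds <- function() {
  b <- default_bounds()
  b$beta3 <- c(0.001, 0.009)
  b$mu2 <- c(0.010, 0.100)
  b
}
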