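# Independent numerical oracles, deliberately built on different
# machinery than the package implementation.

# Axisymmetric annular Poiseuille flow solved by finite differences:
# mu * (u'' + u'/r) = -G on [a, b], u(a) = u(b) = 0. Returns the
# hydraulic resistance dP / Q for a channel of length L.
fd_annulus_resistance <- function(a, b, L, mu, n = 4000) {
  r <- seq(a, b, length.out = n)
  h <- r[2] - r[1]
  G <- 1 # pressure gradient, Pa/m (resistance is independent of G)
  # tridiagonal system for interior nodes
  ri <- r[2:(n - 1)]
  lower <- 1 / h^2 - 1 / (2 * h * ri)
  diag0 <- rep(-2 / h^2, n - 2)
  upper <- 1 / h^2 + 1 / (2 * h * ri)
  rhs <- rep(-G / mu, n - 2)
  # Thomas algorithm
  cp <- numeric(n - 2)
  dp <- numeric(n - 2)
  cp[1] <- upper[1] / diag0[1]
  dp[1] <- rhs[1] / diag0[1]
  for (i in 2:(n - 2)) {
    m <- diag0[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  u <- numeric(n - 2)
  u[n - 2] <- dp[n - 2]
  for (i in (n - 3):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  u_full <- c(0, u, 0)
  integrand <- u_full * r
  Q <- 2 * pi * sum((integrand[-1] + integrand[-n]) / 2) * h
  (G * L) / Q
}

# Closed-form Poiseuille resistance of an open linearly tapered tube.
cone_resistance_closed_form <- function(r1, r2, L, mu) {
  (8 * mu * L / (3 * pi)) * (r1^2 + r1 * r2 + r2^2) / (r1^3 * r2^3)
}

# Base-scenario objects shared across test files.
base_sap <- function() sapProperties()
base_tube <- function() tubeGeometry()
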