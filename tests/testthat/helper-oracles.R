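# Independent oracles and small fixtures used across the suite.

COUL <- 1389.35458
KB <- 0.008314462618

# plain LJ + analytic shift, coded independently of the package kernels
lj_sf_oracle <- function(r, sigma, epsilon, rc) {
  u <- function(x) 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6)
  du <- function(x) -24 * epsilon * (2 * (sigma / x)^12 - (sigma / x)^6) / x
  u(r) - u(rc) - (r - rc) * du(rc)
}

# energy of two finite dipoles built from +/- charge pairs (plain Coulomb)
finite_dipole_pair_oracle <- function(rvec, mi, mj, d = 0.01) {
  qi <- sqrt(sum(mi^2)) / d
  qj <- sqrt(sum(mj^2)) / d
  ui <- mi / sqrt(sum(mi^2))
  uj <- mj / sqrt(sum(mj^2))
  e <- 0
  for (si in c(1, -1)) for (sj in c(1, -1)) {
    ri <- rvec + si * d / 2 * ui
    rj <- sj * d / 2 * uj
    e <- e + COUL * (si * qi) * (sj * qj) / sqrt(sum((ri - rj)^2))
  }
  e
}

# charge q at the origin, finite dipole m centered at rvec
finite_charge_dipole_oracle <- function(rvec, q, m, d = 0.01) {
  qq <- sqrt(sum(m^2)) / d
  u <- m / sqrt(sum(m^2))
  e <- 0
  for (si in c(1, -1))
    e <- e + COUL * q * (si * qq) / sqrt(sum((rvec + si * d / 2 * u)^2))
  e
}

# shifted-force Coulomb closed form, coded independently
coulomb_sf_oracle <- function(r, qi, qj, rc) {
  COUL * qi * qj * (1 / r - 1 / rc + (r - rc) / rc^2)
}

rotate_about <- function(v, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(theta) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

# central finite-difference gradient of a pair energy in rvec
fd_gradient <- function(f, rvec, h = 1e-6) {
  vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (f(rvec + e) - f(rvec - e)) / (2 * h)
  }, 0)
}

# BEDROC from explicit exponentially weighted rank summation
# (Truchon-Bailey), written independently of the package implementation
bedroc_direct <- function(ranks, N, alpha) {
  n <- length(ranks)
  Ra <- n / N
  rie <- mean(exp(-alpha * ranks / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# small equilibrated CG water box reused by the dynamics tests
small_water_box <- function(n = 40, box = 25, seed = 101) {
  sys <- build_box("water", n, box, seed = seed)
  minimize_steepest_descent(sys, max_steps = 200)
}
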