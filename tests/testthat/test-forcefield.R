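# Pair potentials and the system evaluator.

test_that("shifted-force LJ matches the plain-LJ + analytic-shift oracle", {
  sig <- 4.1; eps <- 3.19; rc <- 12
  p <- lj_params(sig, eps)
  for (r in c(3.8, 4.6, 6.0, 10.0)) {
    res <- lj_shifted_force(c(r, 0, 0), p, p, rc)
    expect_equal(res$energy, lj_sf_oracle(r, sig, eps, rc), tolerance = 1e-12)
    g <- fd_gradient(function(rv) lj_shifted_force(rv, p, p, rc)$energy,
                     c(r, 0, 0))
    expect_lt(max(abs(res$force_i + g)), 1e-6)
    expect_equal(res$force_j, -res$force_i)
  }
})

test_that("all pair kernels vanish exactly at and beyond the cutoff", {
  p <- lj_params(3.5, 1.2)
  mu <- c(0.3, 0.2, -0.1)
  for (r in c(12, 15)) {
    expect_identical(lj_shifted_force(c(r, 0, 0), p, p, 12)$energy, 0)
    expect_identical(max(abs(lj_shifted_force(c(r, 0, 0), p, p, 12)$force_i)), 0)
    dd <- dipole_dipole_sf(c(0, r, 0), mu, -mu, 12)
    expect_identical(dd$energy, 0)
    expect_identical(max(abs(dd$force_i)), 0)
    expect_identical(max(abs(dd$torque_i)), 0)
    qd <- charge_dipole_sf(c(0, 0, r), 0.5, mu, 12)
    expect_identical(qd$energy, 0)
    expect_identical(max(abs(qd$force_i)), 0)
  }
  # continuity: just inside the cutoff both energy and force are ~0
  eps_in <- 1e-7
  near <- lj_shifted_force(c(12 - eps_in, 0, 0), p, p, 12)
  expect_lt(abs(near$energy), 1e-10)
  expect_lt(max(abs(near$force_i)), 1e-6)
})

test_that("overlapping sites raise an identifying error", {
  p <- lj_params(3.5, 1.2)
  expect_error(lj_shifted_force(c(0, 0, 0), p, p, 12), "overlap")
})

test_that("dipole-dipole interaction approaches the finite-dipole Coulomb limit", {
  set.seed(4)
  mi <- rnorm(3) * 0.3; mj <- rnorm(3) * 0.3
  rv <- c(5, 1, -2)
  big <- 1e7  # effectively unshifted
  e_pt <- dipole_dipole_sf(rv, mi, mj, big)$energy
  # O(d^2) convergence of the four-charge oracle to the point form
  err1 <- abs(finite_dipole_pair_oracle(rv, mi, mj, d = 0.02) - e_pt)
  err2 <- abs(finite_dipole_pair_oracle(rv, mi, mj, d = 0.01) - e_pt)
  expect_lt(err2, err1 / 3)  # observed order >= 2
  expect_lt(err2, 1e-4)
})

test_that("dipole-dipole symmetry, forces and torques are consistent", {
  set.seed(5)
  mi <- rnorm(3) * 0.4; mj <- rnorm(3) * 0.4
  rv <- c(4, -3, 2)
  rc <- 12
  base <- dipole_dipole_sf(rv, mi, mj, rc)
  # simultaneous inversion leaves the energy unchanged
  expect_equal(dipole_dipole_sf(rv, -mi, -mj, rc)$energy, base$energy)
  # single inversion flips the sign (kernels are linear in each dipole)
  expect_equal(dipole_dipole_sf(rv, -mi, mj, rc)$energy, -base$energy)
  # force = -gradient
  g <- fd_gradient(function(r) dipole_dipole_sf(r, mi, mj, rc)$energy, rv)
  expect_lt(max(abs(base$force_i + g)), 1e-6)
  # torque: finite rotation about any axis changes energy by -tau . dtheta
  for (axis in list(c(0, 0, 1), c(1, 1, 0) / sqrt(2))) {
    h <- 1e-6
    dU <- dipole_dipole_sf(rv, rotate_about(mi, axis, h), mj, rc)$energy -
      dipole_dipole_sf(rv, rotate_about(mi, axis, -h), mj, rc)$energy
    expect_equal(dU / (2 * h), -sum(base$torque_i * axis), tolerance = 1e-5)
  }
  expect_error(dipole_dipole_sf(rv, c(0, 0, 0), mj, rc), "zero dipole")
})

test_that("charge-dipole matches the finite-dipole oracle and finite differences", {
  set.seed(6)
  m <- rnorm(3) * 0.4
  rv <- c(6, 0.5, -1)
  big <- 1e7
  res <- charge_dipole_sf(rv, 1, m, big)
  err1 <- abs(finite_charge_dipole_oracle(rv, 1, m, d = 0.02) - res$energy)
  err2 <- abs(finite_charge_dipole_oracle(rv, 1, m, d = 0.01) - res$energy)
  expect_lt(err2, err1 / 3)
  expect_lt(err2, 1e-5)
  g <- fd_gradient(function(r) charge_dipole_sf(r, 1, m, big)$energy, rv)
  expect_lt(max(abs(res$force_i + g)), 1e-6)
  # zero charge: identically zero
  z <- charge_dipole_sf(rv, 0, m, 12)
  expect_identical(z$energy, 0)
  expect_identical(max(abs(z$force_i)), 0)
})

test_that("atom-atom pair reduces to LJ with zero charges and matches the Coulomb oracle", {
  li <- lj_params(3.4, 0.36); lj <- lj_params(2.6, 0.06)
  rv <- c(3, 1, 0.5)
  a0 <- atom_atom_pair(rv, 0, 0, li, lj, 12)
  l0 <- lj_shifted_force(rv, li, lj, 12)
  expect_identical(a0$energy, l0$energy)
  expect_identical(a0$force_i, l0$force_i)
  # +1/-1 e at 3 Å with LJ off: negative, equals the shifted-force Coulomb
  off <- lj_params(1, 0)
  q <- atom_atom_pair(c(3, 0, 0), 1, -1, off, off, 12)
  expect_lt(q$energy, 0)
  expect_equal(q$energy, coulomb_sf_oracle(3, 1, -1, 12), tolerance = 1e-12)
  expect_identical(atom_atom_pair(c(13, 0, 0), 1, -1, li, lj, 12)$energy, 0)
})

test_that("harmonic bond follows the k(r - r0)^2 convention", {
  b <- cyclohexane_bond(1, 2)
  expect_equal(b$r0, 4.05)
  expect_equal(b$k, 12.69)
  at_min <- harmonic_bond(4.05, b)
  expect_identical(at_min$energy, 0)
  expect_identical(at_min$force, 0)
  expect_equal(harmonic_bond(4.15, b)$energy, 12.69 * 0.1^2, tolerance = 1e-12)
  expect_equal(harmonic_bond(4.25, b)$energy, harmonic_bond(3.85, b)$energy)
})

test_that("cell-list evaluation equals the brute-force double loop", {
  # mixed system: charged solute in water, and a bonded cyclohexane box
  wb <- build_box("water", 120, 36, seed = 31)
  sol <- make_toy_solute("charged_site", center = c(18, 18, 18))
  sys <- solvate(sol, wb)
  eb <- total_energy_forces(sys, method = "brute")
  ec <- total_energy_forces(sys, method = "cell")
  expect_equal(ec$e_total, eb$e_total, tolerance = 1e-8)
  expect_lt(max(abs(ec$forces - eb$forces)), 1e-8)
  expect_lt(max(abs(ec$torques - eb$torques)), 1e-8)

  cb <- build_box("cyclohexane", 40, 38, seed = 32)
  eb2 <- total_energy_forces(cb, method = "brute")
  ec2 <- total_energy_forces(cb, method = "cell")
  expect_equal(ec2$e_total, eb2$e_total, tolerance = 1e-8)
  expect_lt(max(abs(ec2$forces - eb2$forces)), 1e-8)
})

test_that("system forces are the gradient of the energy and sum to zero", {
  wb <- build_box("water", 50, 25, seed = 33)
  sol <- make_toy_solute("charged_site", center = c(12.5, 12.5, 12.5))
  sys <- solvate(sol, wb)
  ev <- total_energy_forces(sys)
  expect_lt(max(abs(colSums(ev$forces))), 1e-9)
  expect_equal(ev$e_total, ev$e_ss + ev$e_sv + ev$e_solute + ev$e_bond)
  h <- 1e-5
  set.seed(34)
  for (i in sample(n_sites(sys), 4)) {
    k <- sample(3, 1)
    sp <- sys; sp$pos[i, k] <- sp$pos[i, k] + h
    sm <- sys; sm$pos[i, k] <- sm$pos[i, k] - h
    fd <- -(total_energy_forces(sp)$e_total -
              total_energy_forces(sm)$e_total) / (2 * h)
    expect_equal(ev$forces[i, k], fd, tolerance = 1e-6)
  }
})

test_that("lambda scaling decouples the solute at the endpoint", {
  wb <- build_box("water", 40, 25, seed = 35)
  sol <- make_toy_solute("charged_site", center = c(12.5, 12.5, 12.5))
  sys <- solvate(sol, wb)
  e1 <- total_energy_forces(sys, lambda = 1)
  expect_identical(e1$e_sv, 0)
  # forces on solvent at lambda = 1 equal the pure-solvent forces
  e0 <- total_energy_forces(sys, lambda = 0)
  solvent <- which(sys$sites$role == "solvent")
  sys_nosol <- sys
  sys_nosol$sites$charge[1] <- 0
  sys_nosol$sites$eps[1] <- 0
  ev_off <- total_energy_forces(sys_nosol)
  expect_equal(e1$forces[solvent, ], ev_off$forces[solvent, ],
               tolerance = 1e-12)
  # two cyclohexane molecules far apart: zero solvent-solvent energy
  far <- map_cyclohexane_to_cg(list(
    cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 1, 0, -1, -1), 0) + 2,
    cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 1, 0, -1, -1), 0) + 20), box = 60)
  expect_identical(total_energy_forces(far)$e_ss, 0)
})
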