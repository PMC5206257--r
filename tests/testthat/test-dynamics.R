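# Minimizer, integrator, thermostat/barostat plumbing, SHAKE, rotations.
# Long statistical-mechanics checks (NVE drift, 500 ps temperature hold)
# live in test-acceptance.R; these tests stay at the seconds scale.

test_that("steepest descent relaxes an LJ dimer to the analytic minimum", {
  s <- lj_params(3.5, 0.5)
  specs <- list(particle_spec("atom", s, mass = 16),
                particle_spec("atom", s, mass = 16))
  sys <- cg_system(specs, rbind(c(0, 0, 0), c(0.9 * 3.5, 0, 0)), 60,
                   molid = c(1, 2), role = "solute")
  m <- minimize_steepest_descent(sys, max_steps = 2000, tolerance = 1e-6)
  expect_equal(sqrt(sum((m$pos[1, ] - m$pos[2, ])^2)), 2^(1 / 6) * 3.5,
               tolerance = 1e-3)
  trace <- attr(m, "energy")
  expect_true(all(diff(trace) <= 0))  # descent property
  # starting at the minimum: unchanged within tolerance
  m2 <- minimize_steepest_descent(m, max_steps = 50, tolerance = 1e-6)
  expect_lt(max(abs(m2$pos - m$pos)), 1e-6)
})

test_that("minimization reduces the energy of a random water box", {
  sys <- build_box("water", 30, 25, seed = 41)
  e0 <- total_energy_forces(sys)$e_total
  m <- minimize_steepest_descent(sys, max_steps = 150)
  expect_lte(total_energy_forces(m)$e_total, e0)
})

test_that("with mts_ratio 1 the integrator is plain velocity-Verlet", {
  # two cyclohexane molecules: bonded (inner) + CG-CG LJ (outer) forces
  ring <- cbind(c(0, 1.25, 2.5, 2.5, 1.25, 0),
                c(0, 0.8, 0, -1, -1.8, -1), c(0, 0.3, 0, 0.3, 0, 0.3))
  sys <- map_cyclohexane_to_cg(list(ring + 10, ring + 14), box = 30)
  set.seed(42)
  sys <- init_velocities(sys, 100)
  pr <- md_protocol(dt_inner = 2, mts_ratio = 1)
  res <- step_mts(sys, pr, n_steps = 10, sample_every = 0)
  # independent velocity-Verlet oracle on the same total forces
  pos <- sys$pos; vel <- sys$vel
  fc <- elba_constants()$fconv
  mass <- sys$sites$mass
  st <- sys
  f <- total_energy_forces(st)$forces
  for (i in 1:10) {
    vel <- vel + 1 * f * fc / mass  # dt/2 = 1 fs
    pos <- pos + 2 * vel
    st$pos <- pos
    f <- total_energy_forces(st)$forces
    vel <- vel + 1 * f * fc / mass
  }
  expect_equal(res$system$pos, pos, tolerance = 1e-10)
  expect_equal(res$system$vel, vel, tolerance = 1e-10)
})

test_that("zero forces and velocities leave the state unchanged", {
  # two LJ sites beyond the cutoff
  s <- lj_params(3.5, 0.5)
  specs <- list(particle_spec("atom", s, mass = 16),
                particle_spec("atom", s, mass = 16))
  sys <- cg_system(specs, rbind(c(5, 5, 5), c(25, 25, 25)), 40,
                   molid = c(1, 2), role = "solute")
  res <- step_mts(sys, md_protocol(), n_steps = 5, sample_every = 0)
  expect_equal(res$system$pos, sys$pos, tolerance = 1e-14)
  expect_equal(res$system$vel, sys$vel)
})

test_that("trajectories are bitwise reproducible and restartable", {
  sys <- small_water_box(30, 25, seed = 101)
  pr <- md_protocol()
  set.seed(77)
  sys <- init_velocities(sys, 298)
  set.seed(88)
  one <- step_mts(sys, pr, n_steps = 40, thermostat = TRUE,
                  sample_every = 0)
  set.seed(88)
  half <- step_mts(sys, pr, n_steps = 20, thermostat = TRUE,
                   sample_every = 0)
  rest <- step_mts(half$system, pr, n_steps = 20, thermostat = TRUE,
                   sample_every = 0)
  expect_identical(rest$system$pos, one$system$pos)
  expect_identical(rest$system$vel, one$system$vel)
  expect_identical(rest$system$dip, one$system$dip)
})

test_that("checkpoints restore state and RNG for bit-exact continuation", {
  sys <- small_water_box(20, 25, seed = 102)
  pr <- md_protocol()
  set.seed(5)
  sys <- init_velocities(sys, 298)
  set.seed(6)
  a <- step_mts(sys, pr, n_steps = 10, thermostat = TRUE, sample_every = 0)
  ck <- file.path(tempdir(), "state.chk")
  write_checkpoint(a$system, ck)
  ref <- step_mts(a$system, pr, n_steps = 10, thermostat = TRUE,
                  sample_every = 0)
  runif(50)  # disturb the RNG stream
  restored <- read_checkpoint(ck, sys)
  cont <- step_mts(restored, pr, n_steps = 10, thermostat = TRUE,
                   sample_every = 0)
  expect_identical(cont$system$pos, ref$system$pos)
})

test_that("SHAKE restores constraints along pre-step bonds, conserving momentum", {
  sol <- make_toy_solute("constrained_diatomic", d = 1.09)
  before <- sol$pos
  # already satisfied: unchanged
  sh0 <- shake(before, before, sol$constraints, sol$sites$mass)
  expect_identical(sh0$positions, before)
  expect_equal(sh0$iterations, 0)
  # stretched 1 %: restored in < 10 iterations
  after <- before
  after[2, 1] <- after[2, 1] * 1.01
  sh <- shake(before, after, sol$constraints, sol$sites$mass)
  d <- sqrt(sum((sh$positions[1, ] - sh$positions[2, ])^2))
  expect_lt(abs(d^2 - 1.09^2), 1e-8)
  expect_lt(sh$iterations, 10)
  # constraint forces are internal: mass-weighted center unchanged
  com0 <- colSums(sol$sites$mass * after)
  com1 <- colSums(sol$sites$mass * sh$positions)
  expect_equal(com1, com0, tolerance = 1e-12)
})

test_that("SHAKE reports the worst constraint on non-convergence", {
  cons <- data.frame(i = 1, j = 2, d = 1)
  before <- rbind(c(0, 0, 0), c(1, 0, 0))
  after <- rbind(c(0, 0, 0), c(8, 0, 0))
  expect_error(shake(before, after, cons, c(1, 1), max_iter = 3),
               "constraint")
})

test_that("dipole rotation preserves norms and free-rotor invariants", {
  sys <- build_box("water", 1, 30, seed = 1)
  sys$dip[1, ] <- c(1, 0, 0)
  sys$avel[1, ] <- c(0, 0, 0.01)
  zero_t <- matrix(0, 1, 3)
  # zero torque + zero angular velocity: unchanged
  still <- sys; still$avel[1, ] <- 0
  expect_identical(rotate_dipoles(still, zero_t, 2)$dip, still$dip)
  # free precession: returns to start after one period 2*pi/|omega|
  period <- 2 * pi / 0.01
  st <- sys
  for (s in 1:500) st <- rotate_dipoles(st, zero_t, period / 500)
  expect_equal(st$dip[1, ], sys$dip[1, ], tolerance = 1e-10)
  expect_equal(sqrt(sum(st$dip[1, ]^2)), 1, tolerance = 1e-12)
  expect_equal(st$avel[1, ], sys$avel[1, ])  # rotational KE conserved
  # norm invariance over many random kicks
  set.seed(43)
  st <- sys
  for (s in 1:1000) st <- rotate_dipoles(st, matrix(rnorm(3), 1), 2)
  expect_equal(sqrt(sum(st$dip[1, ]^2)), 1, tolerance = 1e-9)
})

test_that("dipole in a uniform field oscillates at the pendulum frequency", {
  # torque tau = mu x E; small oscillations about alignment have
  # angular frequency sqrt(mu E / I) for a linear rotor
  mu_mag <- 0.5413
  E <- c(0, 0, 2)       # field such that tau = mu x E (kJ/mol per e*A)
  inertia <- 2.0
  sys <- build_box("water", 1, 30, seed = 1)
  theta0 <- 0.05
  sys$dip[1, ] <- c(sin(theta0), 0, cos(theta0))
  sys$avel[1, ] <- 0
  omega0 <- sqrt(mu_mag * sqrt(sum(E^2)) * elba_constants()$fconv / inertia)
  period <- 2 * pi / omega0
  dt <- period / 2000
  st <- sys
  angle <- function(s) atan2(s$dip[1, 1], s$dip[1, 3])
  prev <- theta0
  crossings <- numeric(0)
  for (s in 1:4200) {
    m <- mu_mag * st$dip[1, ]
    tq <- matrix(c(m[2] * E[3] - m[3] * E[2],
                   m[3] * E[1] - m[1] * E[3],
                   m[1] * E[2] - m[2] * E[1]), 1)
    st <- rotate_dipoles(st, tq, dt)
    a <- angle(st)
    if (prev > 0 && a <= 0) crossings <- c(crossings, s * dt)
    prev <- a
  }
  # successive downward zero-crossings are one period apart
  expect_gte(length(crossings), 2)
  measured <- diff(crossings)[1]
  expect_equal(measured, period, tolerance = 0.01)
})

test_that("weak-coupling barostat scaling follows the formula and geometry", {
  pr <- md_protocol()
  cb <- build_box("cyclohexane", 8, 30, seed = 44)
  # P = P0: identity
  s1 <- apply_weak_coupling_barostat(cb, pr, pressure_inst = pr$pressure)
  expect_equal(attr(s1, "mu"), 1)
  expect_identical(s1$box, cb$box)
  # P > P0 expands the box
  s2 <- apply_weak_coupling_barostat(cb, pr, pressure_inst = 1000)
  expect_gt(attr(s2, "mu"), 1)
  mu_expect <- (1 - (6 / (pr$barostat_tau * 1000)) * pr$compressibility *
                  (pr$pressure - 1000))^(1 / 3)
  expect_equal(attr(s2, "mu"), mu_expect, tolerance = 1e-12)
  # molecule-center scaling preserves intramolecular geometry
  d_before <- sqrt(sum((cb$pos[1, ] - cb$pos[2, ])^2))
  d_after <- sqrt(sum((s2$pos[1, ] - s2$pos[2, ])^2))
  expect_equal(d_after, d_before, tolerance = 1e-12)
})

test_that("the Langevin O-step with very weak coupling approaches identity", {
  sys <- small_water_box(10, 25, seed = 103)
  set.seed(3)
  sys <- init_velocities(sys, 298)
  weak <- md_protocol(thermostat_tau = 1e9)
  out <- apply_langevin(sys, weak, dt = 2)
  expect_equal(out$vel, sys$vel, tolerance = 1e-3)
  # and the thermostatted propagator with a fixed seed is reproducible
  set.seed(11)
  a <- step_mts(sys, md_protocol(), n_steps = 5, thermostat = TRUE,
                sample_every = 0)
  set.seed(11)
  b <- step_mts(sys, md_protocol(), n_steps = 5, thermostat = TRUE,
                sample_every = 0)
  expect_identical(a$system$vel, b$system$vel)
})

test_that("run_md orchestrates stages and reports observables", {
  sys <- small_water_box(20, 25, seed = 104)
  pr <- md_protocol(seed = 9)
  res <- run_md(sys, pr, minimize = FALSE, equilibrate_fs = 600,
                produce_fs = 1200, sample_every = 10)
  expect_equal(nrow(res$observables), floor(200 / 10))
  expect_true(all(diff(res$observables$time_fs) > 0))
  # zero production: state only
  res0 <- run_md(sys, pr, minimize = FALSE, equilibrate_fs = 300,
                 produce_fs = 0)
  expect_null(res0$observables)
})
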