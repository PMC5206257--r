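# Dynamics: steepest-descent minimization, impulse multiple-timestep
# integration with BAOAB Langevin steps on the inner loop, weak-coupling
# barostat and SHAKE constraints.  The propagation loop itself lives in
# C++ (md_run_cpp); these functions provide the user surface.

#' Simulation protocol
#'
#' Collects the integrator and coupling parameters.  The multiple-timestep
#' split propagates CG-CG non-bonded forces on the outer timestep
#' `dt_inner * mts_ratio` (6 fs with the defaults) and all other forces on
#' the inner timestep (2 fs).
#'
#' @param dt_inner Inner timestep in fs.
#' @param mts_ratio Integer outer/inner timestep ratio (>= 1).
#' @param temperature Thermostat target in K.
#' @param thermostat_tau Langevin coupling time in ps (friction = 1/tau),
#'   applied to solute and solvent baths alike, and to the rotational
#'   degrees of freedom of dipolar beads.
#' @param pressure Barostat target in atm.
#' @param barostat_tau Weak-coupling time in ps.
#' @param compressibility Isothermal compressibility in atm^-1
#'   (water-like default).
#' @param r_cut Non-bonded cutoff in Å.
#' @param seed RNG seed recorded with the protocol.
#' @param n_steps Default number of outer steps for [step_mts()].
#' @return An object of class `md_protocol`.
#' @export
md_protocol <- function(dt_inner = 2, mts_ratio = 3, temperature = 298,
                        thermostat_tau = 6, pressure = 1, barostat_tau = 6,
                        compressibility = 4.5e-5, r_cut = 12, seed = NULL,
                        n_steps = 1000) {
  stopifnot(dt_inner > 0, mts_ratio >= 1, thermostat_tau > 0,
            barostat_tau > 0, r_cut > 0)
  structure(list(dt_inner = dt_inner, mts_ratio = as.integer(mts_ratio),
                 temperature = temperature, thermostat_tau = thermostat_tau,
                 pressure = pressure, barostat_tau = barostat_tau,
                 compressibility = compressibility, r_cut = r_cut,
                 seed = seed, n_steps = n_steps), class = "md_protocol")
}

.check_box <- function(system, protocol) {
  if (any(system$box < 2 * protocol$r_cut))
    stop("box lengths (", paste(signif(system$box, 4), collapse = ", "),
         " Å) must be at least twice the cutoff (", protocol$r_cut, " Å)")
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent on positions and, for dipolar beads,
#' small rotations along the torque direction.  A step is accepted only if
#' the potential energy does not increase, so the energy is non-increasing
#' across accepted steps.
#'
#' @param system A [cg_system()].
#' @param max_steps Maximum iterations (default 1000).
#' @param initial_step Initial displacement scale in Å.
#' @param tolerance Stop when the maximum force component falls below this
#'   value (kJ/mol/Å).
#' @param lambda Optional decoupling parameter (see [total_energy_forces()]).
#' @param r_cut Cutoff in Å.
#' @return The minimized system, with attributes `energy` (trace of
#'   accepted energies) and `converged`.
#' @export
minimize_steepest_descent <- function(system, max_steps = 1000,
                                      initial_step = 0.1, tolerance = 10,
                                      lambda = NULL, r_cut = 12) {
  ev <- total_energy_forces(system, lambda = lambda, r_cut = r_cut)
  if (!is.finite(ev$e_total))
    stop("non-finite energy at entry to minimization")
  e <- ev$e_total
  step <- initial_step
  trace <- e
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    fmax <- max(abs(ev$forces))
    tmax <- if (any(system$sites$mu > 0)) max(abs(ev$torques)) else 0
    if (max(fmax, tmax) < tolerance) { converged <- TRUE; break }
    scale <- step / max(fmax, 1e-12)
    cand <- system
    cand$pos <- system$pos + scale * ev$forces
    if (nrow(system$constraints)) {
      p <- .pack_system(system)
      sh <- shake_cpp(system$pos, cand$pos, p$cons, 1 / p$mass, p$box,
                      1e-8, 500)
      cand$pos <- sh$positions
    }
    if (tmax > 0) {
      for (i in which(system$sites$mu > 0)) {
        tq <- ev$torques[i, ]
        tn <- sqrt(sum(tq^2))
        if (tn > 1e-12) {
          ang <- min(scale * tn, 0.3)
          cand$dip[i, ] <- rotate_unit_cpp(system$dip[i, ], tq / tn, ang)
        }
      }
    }
    ev_c <- total_energy_forces(cand, lambda = lambda, r_cut = r_cut)
    if (is.finite(ev_c$e_total) && ev_c$e_total <= e) {
      system <- cand
      e <- ev_c$e_total
      ev <- ev_c
      trace <- c(trace, e)
      step <- min(step * 1.2, 1)
    } else {
      step <- step / 2
      if (step < 1e-10) { converged <- TRUE; break }
    }
  }
  attr(system, "energy") <- trace
  attr(system, "converged") <- converged
  system
}

.run_core <- function(system, protocol, n_outer, thermostat, barostat,
                      lambda_f = 1, sample_every = 0,
                      method = c("auto", "brute")) {
  method <- match.arg(method)
  .check_box(system, protocol)
  p <- .pack_system(system)
  gamma <- 1 / (protocol$thermostat_tau * 1000)  # ps -> fs
  res <- md_run_cpp(p$pos, p$dip, p$vel, p$avel, p$box,
                    p$sigma, p$eps, p$charge, p$mu, p$mass, p$inertia,
                    p$iscg, p$molid, p$role, p$bonds, p$cons,
                    protocol$r_cut, protocol$dt_inner, protocol$mts_ratio,
                    as.integer(n_outer),
                    thermostat, protocol$temperature, gamma, gamma,
                    barostat, protocol$pressure,
                    protocol$barostat_tau * 1000,
                    protocol$compressibility, lambda_f,
                    as.integer(sample_every),
                    if (method == "brute") 0L else 1L,
                    1e-8, 500L)
  system$pos <- res$positions
  system$dip <- res$dipoles
  system$vel <- res$velocities
  system$avel <- res$angular_velocities
  system$box <- res$box
  list(system = system, observables = as.data.frame(res$observables))
}

#' Advance a system with the multiple-timestep integrator
#'
#' Impulse (r-RESPA style) splitting: CG-CG non-bonded forces kick at the
#' outer timestep, all other forces integrate with velocity-Verlet (BAOAB
#' when the thermostat is on) at the inner timestep.  With
#' `mts_ratio = 1` and the thermostat off this reduces to plain
#' velocity-Verlet.
#'
#' @param system A [cg_system()].
#' @param protocol An [md_protocol()].
#' @param n_steps Number of outer steps.
#' @param thermostat,barostat Logical switches.
#' @param lambda Optional decoupling parameter.
#' @param sample_every Record observables every this many outer steps
#'   (0 = none).
#' @return List with `system` (final state) and `observables`
#'   (data frame, one row per sample: time, energy components, kinetic
#'   temperature, pressure, volume).
#' @export
step_mts <- function(system, protocol = md_protocol(), n_steps = 1,
                     thermostat = FALSE, barostat = FALSE, lambda = NULL,
                     sample_every = 1) {
  lf <- if (is.null(lambda)) 1 else coupling(lambda)$f
  .run_core(system, protocol, n_steps, thermostat, barostat,
            lambda_f = lf, sample_every = sample_every)
}

#' One Langevin (BAOAB O-step) velocity update
#'
#' Applies the exact Ornstein-Uhlenbeck velocity map of the Langevin
#' thermostat over a time `dt` to translational velocities and, for
#' dipolar beads, angular velocities (projected perpendicular to the
#' dipole axis).  Solute and solvent form two independent baths with
#' friction 1/`thermostat_tau`.  With zero friction the state is
#' unchanged (NVE limit).
#'
#' @param system A [cg_system()].
#' @param protocol An [md_protocol()].
#' @param dt Time interval in fs.
#' @return The system with updated velocities.
#' @export
apply_langevin <- function(system, protocol = md_protocol(),
                           dt = protocol$dt_inner) {
  gamma <- 1 / (protocol$thermostat_tau * 1000)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  kT <- .const$kB * protocol$temperature
  m <- system$sites$mass
  sv <- sqrt(kT * .const$fconv / m)
  n <- n_sites(system)
  system$vel <- c1 * system$vel + c2 * sv * matrix(rnorm(3 * n), n, 3)
  dipolar <- which(system$sites$mu > 0)
  for (i in dipolar) {
    sw <- sqrt(kT * .const$fconv / system$sites$inertia[i])
    w <- c1 * system$avel[i, ] + c2 * sw * rnorm(3)
    w <- w - sum(w * system$dip[i, ]) * system$dip[i, ]
    system$avel[i, ] <- w
  }
  system
}

#' Weak-coupling (Berendsen) barostat update
#'
#' Scales the box and molecule centers by
#' mu = (1 - (dt/tau_p) kappa (P0 - P))^(1/3); internal molecular
#' geometry is preserved (molecule-center scaling).  At P = P0 the system
#' is unchanged; P > P0 expands the box.
#'
#' @param system A [cg_system()].
#' @param protocol An [md_protocol()].
#' @param pressure_inst Instantaneous pressure P in atm.
#' @param dt Coupling interval in fs (defaults to the outer timestep).
#' @return The system with scaled box and coordinates; attribute `mu`
#'   holds the scaling factor.
#' @export
apply_weak_coupling_barostat <- function(system, protocol = md_protocol(),
                                         pressure_inst,
                                         dt = protocol$dt_inner *
                                           protocol$mts_ratio) {
  kappa <- protocol$compressibility
  fac <- 1 - (dt / (protocol$barostat_tau * 1000)) * kappa *
    (protocol$pressure - pressure_inst)
  mu <- fac^(1 / 3)
  mols <- split(seq_len(n_sites(system)), system$sites$molid)
  for (sites in mols) {
    anchor <- system$pos[sites[1], ]
    rel <- sweep(system$pos[sites, , drop = FALSE], 2, anchor)
    rel <- rel - sweep(round(sweep(rel, 2, system$box, "/")), 2,
                       system$box, "*")
    center <- anchor + colMeans(rel)
    shift <- (mu - 1) * center
    system$pos[sites, ] <- sweep(system$pos[sites, , drop = FALSE], 2,
                                 shift, "+")
  }
  system$box <- system$box * mu
  attr(system, "mu") <- mu
  system
}

#' SHAKE distance-constraint solver
#'
#' Iteratively corrects `positions_after` so that every constraint
#' distance is satisfied to |d^2 - d0^2| < tol, with corrections directed
#' along the pre-step bond vectors (from `positions_before`) and weighted
#' by inverse masses, so constraint forces conserve momentum.
#'
#' @param positions_before n x 3 reference positions (pre-step), Å.
#' @param positions_after n x 3 positions to correct, Å.
#' @param constraints Data frame with columns `i`, `j`, `d`.
#' @param masses Site masses in g/mol.
#' @param box Box lengths (Å); defaults to a huge box (no wrapping).
#' @param tol Convergence tolerance on d^2 in Å².
#' @param max_iter Maximum sweeps before aborting with the worst
#'   constraint reported.
#' @return List with corrected `positions` and the `iterations` used.
#' @export
shake <- function(positions_before, positions_after, constraints, masses,
                  box = rep(1e9, 3), tol = 1e-8, max_iter = 500) {
  cons <- cbind(constraints$i - 1, constraints$j - 1, constraints$d)
  shake_cpp(as.matrix(positions_before), as.matrix(positions_after),
            cons, 1 / masses, box, tol, as.integer(max_iter))
}

#' Rotate dipole orientations under torques
#'
#' Kicks angular velocities by `dt * torque / inertia` (projected
#' perpendicular to the dipole axis, as a linear rotor has no spin about
#' it) and precesses each orientation about its angular velocity by
#' |omega| dt.  Orientations remain unit vectors; with zero torque and
#' friction, free rotation conserves rotational kinetic energy exactly.
#'
#' @param system A [cg_system()].
#' @param torques n x 3 torque matrix in kJ/mol.
#' @param dt Timestep in fs.
#' @return The system with updated orientations and angular velocities.
#' @export
rotate_dipoles <- function(system, torques, dt) {
  dipolar <- which(system$sites$mu > 0)
  for (i in dipolar) {
    w <- system$avel[i, ] +
      dt * torques[i, ] * .const$fconv / system$sites$inertia[i]
    w <- w - sum(w * system$dip[i, ]) * system$dip[i, ]
    system$dip[i, ] <- rotate_unit_cpp(system$dip[i, ], w, dt)
    system$avel[i, ] <- w
  }
  system
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns random translational velocities (and angular velocities for
#' dipolar beads, perpendicular to the dipole axis) at the protocol
#' temperature.  Used to start independent repeats with different
#' starting velocities.
#'
#' @param system A [cg_system()].
#' @param temperature Target temperature in K.
#' @param seed Optional RNG seed.
#' @return The system with fresh momenta.
#' @export
init_velocities <- function(system, temperature = 298, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kT <- .const$kB * temperature
  n <- n_sites(system)
  sv <- sqrt(kT * .const$fconv / system$sites$mass)
  system$vel <- sv * matrix(rnorm(3 * n), n, 3)
  for (i in which(system$sites$mu > 0)) {
    sw <- sqrt(kT * .const$fconv / system$sites$inertia[i])
    w <- sw * rnorm(3)
    system$avel[i, ] <- w - sum(w * system$dip[i, ]) * system$dip[i, ]
  }
  system
}

#' Run a simulation schedule
#'
#' Orchestrates minimize / NPT equilibration / production.  Observables
#' are recorded every `sample_every` outer steps during production.  The
#' trajectory is reproducible bit-for-bit under a fixed seed, and a run
#' split across [write_checkpoint()]/[read_checkpoint()] continues the
#' same random stream.
#'
#' @param system A [cg_system()].
#' @param protocol An [md_protocol()].
#' @param minimize Logical: steepest-descent minimization first.
#' @param equilibrate_fs NPT equilibration length in fs (0 = skip).
#' @param produce_fs NVT production length in fs (0 = skip).
#' @param sample_every Sampling interval in outer steps.
#' @param lambda Optional decoupling parameter held fixed for the run.
#' @return List with `system` and `observables` (production samples).
#' @export
run_md <- function(system, protocol = md_protocol(), minimize = TRUE,
                   equilibrate_fs = 0, produce_fs = 0, sample_every = 10,
                   lambda = NULL) {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  if (minimize)
    system <- minimize_steepest_descent(system, lambda = lambda,
                                        r_cut = protocol$r_cut)
  dt_outer <- protocol$dt_inner * protocol$mts_ratio
  lf <- if (is.null(lambda)) 1 else coupling(lambda)$f
  if (equilibrate_fs > 0) {
    if (all(system$vel == 0))
      system <- init_velocities(system, protocol$temperature)
    n_eq <- ceiling(equilibrate_fs / dt_outer)
    system <- .run_core(system, protocol, n_eq, thermostat = TRUE,
                        barostat = TRUE, lambda_f = lf)$system
  }
  obs <- NULL
  if (produce_fs > 0) {
    n_pr <- ceiling(produce_fs / dt_outer)
    res <- .run_core(system, protocol, n_pr, thermostat = TRUE,
                     barostat = FALSE, lambda_f = lf,
                     sample_every = sample_every)
    system <- res$system
    obs <- res$observables
  }
  list(system = system, observables = obs)
}

#' Write / read a restartable checkpoint
#'
#' Plain-text state dump (positions, orientations, velocities, box and
#' the RNG state) sufficient to continue a run bit-exactly.
#'
#' @param system A [cg_system()].
#' @param path File path.
#' @return `write_checkpoint` returns `path` invisibly;
#'   `read_checkpoint` returns the system and restores the RNG state.
#' @export
write_checkpoint <- function(system, path) {
  seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  dump <- list(pos = system$pos, dip = system$dip, vel = system$vel,
               avel = system$avel, box = system$box, rng = seed)
  writeLines(c("# elbasolv checkpoint v1",
               yaml::as.yaml(lapply(dump, function(x)
                 if (is.matrix(x)) list(dim = dim(x),
                                        data = sprintf("%.17g", x))
                 else if (is.null(x)) NULL
                 else as.character(x)))), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param template A [cg_system()] providing the topology.
#' @export
read_checkpoint <- function(path, template) {
  y <- yaml::read_yaml(path)
  getm <- function(f) matrix(as.numeric(f$data), f$dim[1], f$dim[2])
  template$pos <- getm(y$pos)
  template$dip <- getm(y$dip)
  template$vel <- getm(y$vel)
  template$avel <- getm(y$avel)
  template$box <- as.numeric(y$box)
  if (!is.null(y$rng))
    assign(".Random.seed", as.integer(y$rng), envir = globalenv())
  template
}
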