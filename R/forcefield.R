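# Force-field definitions: per-site parameters and pairwise interactions.
# All pair potentials use shifted-force truncation: each radial kernel
# 1/r^n is replaced by 1/r^n - 1/rc^n + n (r - rc)/rc^(n+1), and the LJ
# potential by U(r) - U(rc) - (r - rc) U'(rc), so that both the energy and
# the full vector force vanish identically at the cutoff.

#' Lennard-Jones parameters
#'
#' @param sigma Collision diameter in Å (> 0).
#' @param epsilon Well depth in kJ/mol (>= 0).
#' @return An object of class `lj_params`.
#' @examples
#' lj_params(4.1, 3.19)  # coarse-grained cyclohexane bead
#' @export
lj_params <- function(sigma, epsilon) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0,
            is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0)
  structure(list(sigma = sigma, epsilon = epsilon), class = "lj_params")
}

#' Per-site physical parameters
#'
#' A site is exactly one of: a Stockmayer bead (`dipole > 0`), a charged
#' atom (`charge != 0`), or a neutral Lennard-Jones site.  Dipolar sites
#' must carry a positive rotational inertia.
#'
#' @param kind One of `"cg_water"`, `"cg_cyclohexane"`, `"atom"`.
#' @param lj [lj_params()] for the site.
#' @param charge Point charge in elementary charges.
#' @param dipole Point-dipole magnitude in e·Å (0 for non-dipolar sites).
#' @param mass Mass in g/mol.
#' @param rot_inertia Rotational inertia in g/mol·Å² (dipolar sites only).
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(kind = c("atom", "cg_water", "cg_cyclohexane"),
                          lj, charge = 0, dipole = 0, mass,
                          rot_inertia = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(lj, "lj_params"), is.numeric(mass), mass > 0,
            dipole >= 0)
  if (dipole > 0 && charge != 0)
    stop("a site is either dipolar or charged, not both")
  if (dipole > 0 && rot_inertia <= 0)
    stop("dipolar sites need rot_inertia > 0")
  structure(list(kind = kind, lj = lj, charge = charge, dipole = dipole,
                 mass = mass, rot_inertia = rot_inertia),
            class = "particle_spec")
}

#' Coarse-grained Stockmayer water bead
#'
#' One CG water molecule: a point dipole embedded in a Lennard-Jones site.
#' The Lennard-Jones and dipole parameters are not restated by the study
#' this package accompanies; the defaults below are taken from the
#' published Elba water model (sigma 3.05 Å, epsilon 2.30 kJ/mol, dipole
#' 2.6 D) and the rotational inertia is a water-like configuration choice.
#' All of them are arguments so alternative parameterisations can be
#' supplied.
#'
#' @param sigma,epsilon Lennard-Jones parameters (Å, kJ/mol).
#' @param dipole_debye Dipole moment in Debye.
#' @param mass Bead mass in g/mol (one water molecule).
#' @param rot_inertia Rotational inertia in g/mol·Å².
#' @return A [particle_spec()].
#' @export
elba_water_spec <- function(sigma = 3.05, epsilon = 2.30, dipole_debye = 2.6,
                            mass = 18.015, rot_inertia = 2.0) {
  particle_spec("cg_water", lj_params(sigma, epsilon),
                dipole = dipole_debye * .const$debye,
                mass = mass, rot_inertia = rot_inertia)
}

#' Coarse-grained cyclohexane bead
#'
#' One of the three bonded, uncharged Lennard-Jones sites that make up a
#' CG cyclohexane molecule.  sigma = 4.1 Å and epsilon = 3.19 kJ/mol are
#' the lipid-tail bead parameters scaled by 0.9 (the ring-bead reduction);
#' the scaled values are stored directly.  Mass is one third of a
#' cyclohexane molecule.
#'
#' @param sigma,epsilon Lennard-Jones parameters (Å, kJ/mol).
#' @param mass Bead mass in g/mol.
#' @return A [particle_spec()].
#' @export
elba_cyclohexane_spec <- function(sigma = 4.1, epsilon = 3.19,
                                  mass = 84.16 / 3) {
  particle_spec("cg_cyclohexane", lj_params(sigma, epsilon), mass = mass)
}

#' Harmonic bond term
#'
#' Energy convention: E = k (r - r0)^2, without the 1/2 prefactor; the
#' stored cyclohexane force constant 12.69 kJ/mol/Å² follows this
#' convention.
#'
#' @param site_i,site_j 1-based site indices (i != j).
#' @param r0 Equilibrium length in Å (> 0).
#' @param k Force constant in kJ/mol/Å² (>= 0).
#' @return An object of class `bond_term`.
#' @export
bond_term <- function(site_i, site_j, r0, k) {
  stopifnot(site_i != site_j, r0 > 0, k >= 0)
  structure(list(site_i = as.integer(site_i), site_j = as.integer(site_j),
                 r0 = r0, k = k), class = "bond_term")
}

#' Bond term of the CG cyclohexane model
#'
#' r0 = 4.05 Å and k = 12.69 kJ/mol/Å² (in the E = k (r - r0)^2
#' convention).
#'
#' @inheritParams bond_term
#' @return A [bond_term()].
#' @export
cyclohexane_bond <- function(site_i, site_j) {
  bond_term(site_i, site_j, r0 = 4.05, k = 12.69)
}

.as_lj <- function(p) {
  if (inherits(p, "particle_spec")) p$lj else p
}

#' Shifted-force Lennard-Jones pair interaction
#'
#' Cross parameters follow Lorentz-Berthelot combination (arithmetic
#' sigma, geometric epsilon).  Energy and force are exactly zero at and
#' beyond `r_cut`, and the force is the analytic negative gradient of the
#' energy.
#'
#' @param r_vec Displacement vector from site j to site i, in Å.
#' @param p_i,p_j [lj_params()] (or [particle_spec()]) of the two sites.
#' @param r_cut Cutoff radius in Å.
#' @return List with `energy` (kJ/mol), `force_i` and `force_j`
#'   (kJ/mol/Å; `force_j = -force_i`).
#' @export
lj_shifted_force <- function(r_vec, p_i, p_j, r_cut = 12) {
  li <- .as_lj(p_i); lj <- .as_lj(p_j)
  res <- pair_lj_sf_cpp(as.numeric(r_vec), li$sigma, li$epsilon,
                        lj$sigma, lj$epsilon, r_cut)
  res$force_j <- -res$force_i
  res
}

#' Shifted-force dipole-dipole interaction
#'
#' Point-dipole interaction between two Stockmayer beads, with the 1/r^3
#' and 1/r^5 radial kernels individually shifted so energy and force
#' vanish at the cutoff.  For r much smaller than the cutoff the energy
#' approaches the ideal point-dipole form
#' C (mu_i·mu_j - 3 (mu_i·rhat)(mu_j·rhat)) / r^3.
#'
#' @param r_vec Displacement from j to i (Å).
#' @param mu_i,mu_j Full dipole vectors in e·Å (nonzero).
#' @param r_cut Cutoff radius in Å.
#' @return List with `energy`, `force_i`, `force_j`, `torque_i`,
#'   `torque_j` (torques in kJ/mol).
#' @export
dipole_dipole_sf <- function(r_vec, mu_i, mu_j, r_cut = 12) {
  if (sqrt(sum(mu_i^2)) == 0 || sqrt(sum(mu_j^2)) == 0)
    stop("zero dipole magnitude; use the neutral-site path instead")
  res <- pair_dd_sf_cpp(as.numeric(r_vec), as.numeric(mu_i),
                        as.numeric(mu_j), r_cut)
  res$force_j <- -res$force_i
  res
}

#' Shifted-force charge-dipole interaction
#'
#' Interaction between a point charge at site j and a point dipole at
#' site i.  `r_vec` points from the charge to the dipole.  A zero charge
#' gives an identically zero result.
#'
#' @param r_vec Displacement from the charge to the dipole (Å).
#' @param q Charge in e.
#' @param mu Dipole vector in e·Å.
#' @param r_cut Cutoff radius in Å.
#' @return List with `energy`, `force_i` (on the dipole), `force_j`,
#'   `torque_i`.
#' @export
charge_dipole_sf <- function(r_vec, q, mu, r_cut = 12) {
  res <- pair_qd_sf_cpp(as.numeric(r_vec), q, as.numeric(mu), r_cut)
  res$force_j <- -res$force_i
  res
}

#' Atom-atom pair interaction (shifted-force LJ + Coulomb)
#'
#' All-atom non-bonded pair: shifted-force Lennard-Jones plus
#' shifted-force Coulomb at the same cutoff.  With both charges zero this
#' reduces exactly to [lj_shifted_force()].
#'
#' @param r_vec Displacement from j to i (Å).
#' @param q_i,q_j Charges in e.
#' @param lj_i,lj_j [lj_params()] of the two atoms.
#' @param r_cut Cutoff radius in Å.
#' @return List with `energy`, `force_i`, `force_j`.
#' @export
atom_atom_pair <- function(r_vec, q_i, q_j, lj_i, lj_j, r_cut = 12) {
  li <- .as_lj(lj_i); lj <- .as_lj(lj_j)
  a <- pair_lj_sf_cpp(as.numeric(r_vec), li$sigma, li$epsilon,
                      lj$sigma, lj$epsilon, r_cut)
  b <- pair_qq_sf_cpp(as.numeric(r_vec), q_i, q_j, r_cut)
  res <- list(energy = a$energy + b$energy,
              force_i = a$force_i + b$force_i)
  res$force_j <- -res$force_i
  res
}

#' Harmonic bond energy and force
#'
#' E = k (r - r0)^2; the returned force magnitude is -dE/dr (positive =
#' repulsive, pushing the sites apart).
#'
#' @param r Current bond length in Å (> 0).
#' @param term A [bond_term()].
#' @return List with `energy` (kJ/mol) and `force` (kJ/mol/Å).
#' @export
harmonic_bond <- function(r, term) {
  stopifnot(r > 0, inherits(term, "bond_term"))
  list(energy = term$k * (r - term$r0)^2,
       force = -2 * term$k * (r - term$r0))
}

#' Total potential energy, forces and torques of a system
#'
#' Evaluates all non-bonded and bonded interactions of a periodic system
#' under the minimum-image convention.  Non-bonded interactions between
#' sites of the same molecule are excluded.  The solute-solvent component
#' can be scaled by the coupling function of a decoupling parameter
#' lambda; at `lambda = 1` the solute exerts no force on the solvent.
#'
#' @param system A [cg_system()].
#' @param lambda Optional decoupling parameter in `[0, 1]`; the
#'   solute-solvent energy and forces are scaled by `coupling(lambda)$f`.
#' @param r_cut Cutoff radius in Å.
#' @param split `"all"`, `"outer"` (CG-CG non-bonded only) or `"inner"`
#'   (everything else), matching the multiple-timestep force split.
#' @param method `"auto"` picks a cell list when the box accommodates at
#'   least 3 cells per dimension, otherwise an O(N^2) double loop;
#'   `"brute"` and `"cell"` force one path.
#' @return List with the energy decomposition (`e_total`, `e_ss`
#'   solvent-solvent, `e_sv` solute-solvent after scaling, `e_sv_raw`
#'   unscaled, `e_solute` intra-solute non-bonded, `e_bond`), per-site
#'   `forces` and `torques` (n x 3), and the scalar `virial`.
#' @export
total_energy_forces <- function(system, lambda = NULL, r_cut = 12,
                                split = c("all", "outer", "inner"),
                                method = c("auto", "brute", "cell")) {
  split <- match.arg(split)
  method <- match.arg(method)
  p <- .pack_system(system)
  lf <- if (is.null(lambda)) 1 else coupling(lambda)$f
  ff_eval_cpp(p$pos, p$dip, p$box, p$sigma, p$eps, p$charge, p$mu,
              p$mass, p$inertia, p$iscg, p$molid, p$role, p$bonds,
              r_cut, lf,
              match(split, c("all", "outer", "inner")) - 1L,
              switch(method, auto = 1L, cell = 1L, brute = 0L))
}
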