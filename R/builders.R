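# Builders: coarse-graining maps, solvent boxes, solvation, toy solutes.
# All stochastic choices go through R's RNG so a fixed seed reproduces a
# configuration exactly.

#' Coarse-grain all-atom water to Stockmayer beads
#'
#' Each water molecule is replaced by a single bead positioned at its
#' oxygen atom.  The initial dipole orientation is the H-O-H bisector
#' (pointing from O towards the hydrogens) when hydrogen coordinates are
#' supplied, otherwise a random unit vector.
#'
#' @param aa_waters List of molecules; each element is a list with `O`
#'   (length-3 oxygen coordinate, Å) and optionally `H` (2 x 3 matrix of
#'   hydrogen coordinates).
#' @param box Box lengths (Å).
#' @param spec Water bead [particle_spec()].
#' @param seed Optional seed for random orientations.
#' @return A [cg_system()] with one bead per input molecule.
#' @export
map_water_to_cg <- function(aa_waters, box, spec = elba_water_spec(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(aa_waters)
  if (n == 0) stop("no water molecules supplied")
  pos <- matrix(0, n, 3)
  dip <- matrix(0, n, 3)
  for (m in seq_len(n)) {
    w <- aa_waters[[m]]
    if (is.null(w$O) || length(w$O) != 3 || anyNA(w$O))
      stop("water molecule ", m, " is missing an O coordinate")
    pos[m, ] <- w$O
    if (!is.null(w$H)) {
      H <- matrix(as.numeric(w$H), ncol = 3)
      if (nrow(H) != 2) stop("water molecule ", m, ": expected 2 H atoms")
      b1 <- H[1, ] - w$O; b2 <- H[2, ] - w$O
      bis <- b1 / sqrt(sum(b1^2)) + b2 / sqrt(sum(b2^2))
      dip[m, ] <- bis / sqrt(sum(bis^2))
    } else {
      dip[m, ] <- .random_unit()
    }
  }
  cg_system(rep(list(spec), n), pos, box, molid = seq_len(n),
            role = "solvent", dip = dip)
}

#' Coarse-grain all-atom cyclohexane to a three-bead ring
#'
#' Beads are placed on the first, third and fifth ring carbon; the three
#' beads are joined into a ring by three bonds (1-2, 2-3, 3-1) carrying
#' the CG cyclohexane bond term.
#'
#' @param aa_rings List of molecules; each element a 6 x 3 matrix of ring
#'   carbon coordinates in ring order (C1..C6), Å.
#' @param box Box lengths (Å).
#' @param spec Bead [particle_spec()].
#' @return A [cg_system()] with three beads and three bonds per molecule.
#' @export
map_cyclohexane_to_cg <- function(aa_rings, box,
                                  spec = elba_cyclohexane_spec()) {
  n <- length(aa_rings)
  if (n == 0) stop("no cyclohexane molecules supplied")
  pos <- NULL
  bonds <- list()
  for (m in seq_len(n)) {
    C <- matrix(as.numeric(aa_rings[[m]]), ncol = 3)
    if (nrow(C) != 6)
      stop("cyclohexane molecule ", m, ": expected 6 ring carbons, got ",
           nrow(C))
    pos <- rbind(pos, C[c(1, 3, 5), ])
    o <- (m - 1) * 3
    bonds <- c(bonds, list(cyclohexane_bond(o + 1, o + 2),
                           cyclohexane_bond(o + 2, o + 3),
                           cyclohexane_bond(o + 3, o + 1)))
  }
  cg_system(rep(list(spec), 3 * n), pos, box,
            molid = rep(seq_len(n), each = 3), role = "solvent",
            bonds = bonds)
}

.random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Build a coarse-grained solvent box
#'
#' Places molecules on a jittered cubic lattice (molecule centers), with
#' random dipole orientations for water, and verifies that no two sites
#' of different molecules are closer than 0.8 sigma.  Momenta start at
#' zero.  Deterministic under a fixed seed.
#'
#' @param species `"water"` or `"cyclohexane"`.
#' @param n_molecules Number of molecules (>= 0).
#' @param box_length Cubic box edge in Å.
#' @param seed RNG seed.
#' @param spec Bead [particle_spec()] override.
#' @return A [cg_system()].
#' @export
build_box <- function(species = c("water", "cyclohexane"), n_molecules,
                      box_length, seed = 1, spec = NULL) {
  species <- match.arg(species)
  set.seed(seed)
  spec <- if (is.null(spec)) {
    if (species == "water") elba_water_spec() else elba_cyclohexane_spec()
  } else spec
  sites_per <- if (species == "water") 1L else 3L
  mass_mol <- spec$mass * sites_per
  dens <- n_molecules * mass_mol / 6.02214076e23 / (box_length * 1e-8)^3
  if (dens > 2) stop("requested density ", signif(dens, 3),
                     " g/cm^3 is not physically sane")
  if (n_molecules == 0) {
    # empty but valid system: a single massless-free placeholder is not
    # allowed, so return a zero-row shell the callers understand
    return(structure(list(
      sites = data.frame(kind = character(), sigma = numeric(),
                         eps = numeric(), charge = numeric(),
                         mu = numeric(), mass = numeric(),
                         inertia = numeric(), molid = integer(),
                         role = character(), stringsAsFactors = FALSE),
      bonds = data.frame(i = integer(), j = integer(), r0 = numeric(),
                         k = numeric()),
      constraints = data.frame(i = integer(), j = integer(), d = numeric()),
      pos = matrix(0, 0, 3), dip = matrix(0, 0, 3),
      vel = matrix(0, 0, 3), avel = matrix(0, 0, 3),
      box = rep(box_length, 3)), class = "cg_system"))
  }

  ncell <- ceiling(n_molecules^(1 / 3))
  a <- box_length / ncell
  min_d <- 0.8 * spec$lj$sigma
  jitter_amp <- max(0, min(a / 2 - min_d / 2, 0.15 * a))
  centers <- matrix(0, n_molecules, 3)
  idx <- 0L
  for (iz in seq_len(ncell)) for (iy in seq_len(ncell)) for (ix in seq_len(ncell)) {
    if (idx >= n_molecules) break
    idx <- idx + 1L
    centers[idx, ] <- (c(ix, iy, iz) - 0.5) * a +
      runif(3, -jitter_amp, jitter_amp)
  }

  if (species == "water") {
    dip <- t(vapply(seq_len(n_molecules), function(i) .random_unit(),
                    numeric(3)))
    sys <- cg_system(rep(list(spec), n_molecules), centers, box_length,
                     molid = seq_len(n_molecules), role = "solvent",
                     dip = dip)
  } else {
    # small equilateral triangle at the bond length around each center,
    # randomly oriented
    r0 <- 4.05
    rad <- r0 / sqrt(3)
    pos <- matrix(0, 3 * n_molecules, 3)
    bonds <- list()
    for (m in seq_len(n_molecules)) {
      u <- .random_unit()
      v0 <- .random_unit()
      v1 <- v0 - sum(v0 * u) * u
      v1 <- v1 / sqrt(sum(v1^2))
      v2 <- c(u[2] * v1[3] - u[3] * v1[2],
              u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
      for (kk in 0:2) {
        ang <- 2 * pi * kk / 3
        pos[(m - 1) * 3 + kk + 1, ] <- centers[m, ] +
          rad * (cos(ang) * v1 + sin(ang) * v2)
      }
      o <- (m - 1) * 3
      bonds <- c(bonds, list(cyclohexane_bond(o + 1, o + 2),
                             cyclohexane_bond(o + 2, o + 3),
                             cyclohexane_bond(o + 3, o + 1)))
    }
    sys <- cg_system(rep(list(spec), 3 * n_molecules), pos, box_length,
                     molid = rep(seq_len(n_molecules), each = 3),
                     role = "solvent", bonds = bonds)
  }
  .check_min_distance(sys, min_d)
  sys
}

.check_min_distance <- function(sys, min_d) {
  p <- .pack_system(sys)
  n <- nrow(p$pos)
  if (n < 2) return(invisible(TRUE))
  # brute-force minimum intermolecular distance with minimum image
  dmin <- Inf
  pos <- p$pos; box <- p$box; mol <- p$molid
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r <- sqrt(rowSums(d^2))
    r[mol[(i + 1):n] == mol[i]] <- Inf
    dmin <- min(dmin, r)
  }
  if (dmin < min_d)
    stop("could not place molecules without overlap (min distance ",
         signif(dmin, 3), " Å < ", signif(min_d, 3), " Å)")
  invisible(TRUE)
}

#' Solvate a solute in a solvent box
#'
#' Inserts the solute into the solvent box and deletes every solvent
#' molecule that has any site within `clearance` of any solute site
#' (whole-molecule deletion).  Role tags are preserved.
#'
#' @param solute A [cg_system()] tagged `"solute"`.
#' @param box A solvent [cg_system()].
#' @param clearance Deletion radius in Å.
#' @return Merged [cg_system()], solute sites first.
#' @export
solvate <- function(solute, box, clearance = 3) {
  stopifnot(all(solute$sites$role == "solute"),
            all(box$sites$role == "solvent"))
  keep_mol <- unique(box$sites$molid)
  L <- box$box
  drop <- logical(length(keep_mol))
  for (si in seq_len(nrow(solute$pos))) {
    d <- sweep(box$pos, 2, solute$pos[si, ])
    d <- d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
    close <- sqrt(rowSums(d^2)) < clearance
    drop[match(unique(box$sites$molid[close]), keep_mol)] <- TRUE
  }
  keep_sites <- !(box$sites$molid %in% keep_mol[drop])
  trimmed <- .subset_system(box, keep_sites)
  out <- .merge_systems(solute, trimmed)
  attr(out, "n_deleted") <- sum(drop)
  out
}

.subset_system <- function(sys, keep) {
  idx <- which(keep)
  if (length(idx) == 0)
    stop("solvation removed every solvent molecule; enlarge the box")
  remap <- match(seq_len(nrow(sys$sites)), idx)
  bonds <- sys$bonds[sys$bonds$i %in% idx & sys$bonds$j %in% idx, ,
                     drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  cons <- sys$constraints[sys$constraints$i %in% idx &
                            sys$constraints$j %in% idx, , drop = FALSE]
  if (nrow(cons)) { cons$i <- remap[cons$i]; cons$j <- remap[cons$j] }
  specs <- .unpack_specs(sys)[idx]
  molid <- as.integer(factor(sys$sites$molid[idx]))
  cg_system(specs, sys$pos[idx, , drop = FALSE], sys$box, molid,
            sys$sites$role[idx], bonds = .df_to_bonds(bonds),
            constraints = cons, dip = sys$dip[idx, , drop = FALSE],
            vel = sys$vel[idx, , drop = FALSE],
            avel = sys$avel[idx, , drop = FALSE])
}

#' Toy solutes for exercising every interaction path
#'
#' Three miniature solutes stand in for the challenge compounds: a single
#' neutral Lennard-Jones site, a single charged Lennard-Jones site (which
#' exercises the charge-dipole path in water), and a rigid diatomic whose
#' bond is held by one SHAKE constraint.
#'
#' @param kind `"lj_site"`, `"charged_site"` or `"constrained_diatomic"`.
#' @param sigma,epsilon LJ parameters of the solute site(s).
#' @param charge Charge in e (for `"charged_site"`).
#' @param d Constrained bond length in Å (for `"constrained_diatomic"`).
#' @param mass Site mass in g/mol.
#' @param center Placement of the solute (Å).
#' @param box Box lengths; only used until the solute is solvated.
#' @return A [cg_system()] tagged `"solute"`.
#' @export
make_toy_solute <- function(kind = c("lj_site", "charged_site",
                                     "constrained_diatomic"),
                            sigma = 3.5, epsilon = 0.5, charge = 0.5,
                            d = 1.09, mass = 16, center = c(0, 0, 0),
                            box = 50) {
  kind <- match.arg(kind)
  lj <- lj_params(sigma, epsilon)
  switch(kind,
    lj_site = cg_system(list(particle_spec("atom", lj, mass = mass)),
                        matrix(center, 1, 3), box, molid = 1,
                        role = "solute"),
    charged_site = cg_system(
      list(particle_spec("atom", lj, charge = charge, mass = mass)),
      matrix(center, 1, 3), box, molid = 1, role = "solute"),
    constrained_diatomic = cg_system(
      list(particle_spec("atom", lj, mass = mass),
           particle_spec("atom", lj, mass = 1.008)),
      rbind(center, center + c(d, 0, 0)), box, molid = c(1, 1),
      role = "solute",
      constraints = data.frame(i = 1, j = 2, d = d)))
}
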