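# System container: topology (who interacts with whom) + state (where
# everything is).  Sites live in a data.frame for vectorised access; the
# C++ layer receives plain vectors via .pack_system().

#' Construct a simulation system
#'
#' Bundles topology (per-site parameters, molecule map, role tags, bonds,
#' constraints) and state (positions, dipole orientations, velocities,
#' box) into one object.  Every site belongs to exactly one molecule and
#' is tagged either `"solute"` or `"solvent"`; the solute-solvent tag
#' boundary is what the decoupling parameter lambda acts on.
#'
#' @param specs List of [particle_spec()], one per site.
#' @param pos n x 3 matrix of positions in Å.
#' @param box Orthorhombic box lengths (length 3, or a scalar cube), Å.
#' @param molid Integer molecule id per site (consecutive from 1).
#' @param role Character `"solute"`/`"solvent"` per site (recycled).
#' @param bonds List of [bond_term()] (or NULL).
#' @param constraints Data frame with columns `i`, `j`, `d` (Å) for
#'   SHAKE distance constraints (or NULL).
#' @param dip n x 3 matrix of unit dipole orientations (rows for
#'   non-dipolar sites are zero).  Defaults to +z for dipolar sites.
#' @param vel,avel n x 3 matrices of velocities (Å/fs) and angular
#'   velocities (1/fs); default zero.
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(specs, pos, box, molid, role = "solvent",
                      bonds = NULL, constraints = NULL,
                      dip = NULL, vel = NULL, avel = NULL) {
  n <- length(specs)
  stopifnot(n > 0, all(vapply(specs, inherits, TRUE, "particle_spec")))
  pos <- matrix(as.numeric(pos), ncol = 3)
  stopifnot(nrow(pos) == n)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  molid <- as.integer(molid)
  stopifnot(length(molid) == n, all(molid >= 1))
  role <- rep_len(role, n)
  stopifnot(all(role %in% c("solute", "solvent")))
  for (m in unique(molid)) {
    r <- unique(role[molid == m])
    if (length(r) != 1)
      stop("molecule ", m, " mixes solute and solvent sites")
  }

  sigma <- vapply(specs, function(s) s$lj$sigma, 0)
  eps <- vapply(specs, function(s) s$lj$epsilon, 0)
  charge <- vapply(specs, function(s) s$charge, 0)
  mu <- vapply(specs, function(s) s$dipole, 0)
  mass <- vapply(specs, function(s) s$mass, 0)
  inertia <- vapply(specs, function(s) s$rot_inertia, 0)
  kind <- vapply(specs, function(s) s$kind, "")

  if (is.null(dip)) {
    dip <- matrix(0, n, 3)
    dip[mu > 0, 3] <- 1
  } else {
    dip <- matrix(as.numeric(dip), ncol = 3)
    nrm <- sqrt(rowSums(dip^2))
    bad <- mu > 0 & abs(nrm - 1) > 1e-10
    if (any(bad))
      stop("dipole orientations of sites ", paste(which(bad), collapse = ", "),
           " are not unit vectors")
  }
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(avel)) avel <- matrix(0, n, 3)

  bdf <- if (is.null(bonds) || length(bonds) == 0) {
    data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())
  } else {
    do.call(rbind, lapply(bonds, function(b)
      data.frame(i = b$site_i, j = b$site_j, r0 = b$r0, k = b$k)))
  }
  cdf <- if (is.null(constraints)) {
    data.frame(i = integer(), j = integer(), d = numeric())
  } else {
    constraints <- as.data.frame(constraints)
    stopifnot(all(c("i", "j", "d") %in% names(constraints)),
              all(constraints$d > 0))
    constraints[, c("i", "j", "d")]
  }

  structure(list(
    sites = data.frame(kind = kind, sigma = sigma, eps = eps,
                       charge = charge, mu = mu, mass = mass,
                       inertia = inertia, molid = molid, role = role,
                       stringsAsFactors = FALSE),
    bonds = bdf, constraints = cdf,
    pos = pos, dip = dip, vel = vel, avel = avel,
    box = as.numeric(box)), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$sites), "sites,",
      length(unique(x$sites$molid)), "molecules\n")
  cat("  box:", paste(signif(x$box, 5), collapse = " x "), "Å\n")
  cat("  roles:", sum(x$sites$role == "solute"), "solute /",
      sum(x$sites$role == "solvent"), "solvent sites\n")
  if (nrow(x$bonds)) cat("  bonds:", nrow(x$bonds), "\n")
  if (nrow(x$constraints)) cat("  constraints:", nrow(x$constraints), "\n")
  invisible(x)
}

#' Number of sites in a system
#' @param system A [cg_system()].
#' @return Integer site count.
#' @export
n_sites <- function(system) nrow(system$sites)

# flatten a cg_system into the plain arrays the C++ layer expects
.pack_system <- function(system) {
  stopifnot(inherits(system, "cg_system"))
  s <- system$sites
  list(pos = system$pos, dip = system$dip, vel = system$vel,
       avel = system$avel, box = system$box,
       sigma = s$sigma, eps = s$eps, charge = s$charge, mu = s$mu,
       mass = s$mass, inertia = s$inertia,
       iscg = as.integer(s$kind %in% c("cg_water", "cg_cyclohexane")),
       molid = s$molid,
       role = as.integer(s$role == "solvent"),
       bonds = if (nrow(system$bonds))
         cbind(system$bonds$i - 1, system$bonds$j - 1,
               system$bonds$r0, system$bonds$k)
       else matrix(0, 0, 4),
       cons = if (nrow(system$constraints))
         cbind(system$constraints$i - 1, system$constraints$j - 1,
               system$constraints$d)
       else matrix(0, 0, 3))
}

# merge two systems (solute first), renumbering molecules
.merge_systems <- function(a, b) {
  na <- n_sites(a)
  specs <- c(.unpack_specs(a), .unpack_specs(b))
  molid <- c(a$sites$molid, b$sites$molid + max(a$sites$molid))
  role <- c(a$sites$role, b$sites$role)
  bonds <- rbind(a$bonds,
                 if (nrow(b$bonds))
                   transform(b$bonds, i = i + na, j = j + na)
                 else b$bonds)
  cons <- rbind(a$constraints,
                if (nrow(b$constraints))
                  transform(b$constraints, i = i + na, j = j + na)
                else b$constraints)
  cg_system(specs, rbind(a$pos, b$pos), b$box, molid, role,
            bonds = .df_to_bonds(bonds), constraints = cons,
            dip = rbind(a$dip, b$dip), vel = rbind(a$vel, b$vel),
            avel = rbind(a$avel, b$avel))
}

.unpack_specs <- function(system) {
  s <- system$sites
  lapply(seq_len(nrow(s)), function(i)
    particle_spec(s$kind[i], lj_params(s$sigma[i], max(s$eps[i], 0)),
                  charge = s$charge[i], dipole = s$mu[i],
                  mass = s$mass[i], rot_inertia = s$inertia[i]))
}

.df_to_bonds <- function(df) {
  if (!nrow(df)) return(NULL)
  lapply(seq_len(nrow(df)), function(b)
    bond_term(df$i[b], df$j[b], df$r0[b], df$k[b]))
}
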