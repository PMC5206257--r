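# File formats: PDB/XYZ structures (XYZ extended with dipole columns),
# prediction tables (CSV), TI series (TSV) and YAML force-field files.
# Writers emit a provenance header line (version + seed) as a comment.

.provenance <- function(seed = NA) {
  ver <- as.character(utils::packageVersion("elbasolv"))
  sprintf("# elbasolv %s seed=%s", ver, seed)
}

#' Read a structure file
#'
#' PDB files are parsed with the bio3d package; XYZ files (plain or with
#' the package's extended dipole columns) with a built-in reader.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return List with `coords` (n x 3, Å), `names` (atom names) and, for
#'   extended XYZ, `dipoles` (n x 3 orientations).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path)
    xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) {
      bad <- which(apply(xyz, 1, anyNA))[1]
      stop("malformed coordinates at atom record ", bad, " of ", path)
    }
    list(coords = xyz, names = pdb$atom$elety, resid = pdb$atom$resid,
         resno = pdb$atom$resno)
  } else {
    read_xyz(path)
  }
}

#' Read an (extended) XYZ file
#'
#' Format: line 1 atom count, line 2 comment, then
#' `name x y z [ux uy uz]` per atom; the optional trailing columns are
#' unit dipole orientations.
#'
#' @param path File path.
#' @return List with `coords`, `names`, and `dipoles` when present.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ record at line 1: expected atom count")
  if (length(lines) < n + 2)
    stop("malformed XYZ: expected ", n, " atom lines, file has ",
         length(lines) - 2)
  coords <- matrix(0, n, 3)
  dip <- matrix(0, n, 3)
  nm <- character(n)
  has_dip <- FALSE
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed XYZ record at line ", i + 2)
    nm[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("malformed XYZ record at line ", i + 2)
    coords[i, ] <- v
    if (length(tok) >= 7) {
      dip[i, ] <- as.numeric(tok[5:7])
      has_dip <- TRUE
    }
  }
  out <- list(coords = coords, names = nm)
  if (has_dip) out$dipoles <- dip
  out
}

#' Write a system (or coordinates) as extended XYZ
#'
#' Dipolar sites carry three extra columns with their unit orientation.
#' The comment line records package version, seed and box lengths.
#'
#' @param system A [cg_system()] (or a bare n x 3 matrix).
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, seed = NA) {
  if (is.matrix(system))
    system <- list(pos = system, dip = matrix(0, nrow(system), 3),
                   sites = data.frame(kind = rep("atom", nrow(system)),
                                      mu = 0),
                   box = rep(NA, 3))
  n <- nrow(system$pos)
  lines <- c(as.character(n),
             paste(.provenance(seed), "box",
                   paste(signif(system$box, 8), collapse = " ")))
  for (i in seq_len(n)) {
    base <- sprintf("%-6s %14.8f %14.8f %14.8f",
                    substr(system$sites$kind[i], 1, 6),
                    system$pos[i, 1], system$pos[i, 2], system$pos[i, 3])
    if (system$sites$mu[i] > 0)
      base <- paste(base, sprintf("%12.8f %12.8f %12.8f",
                                  system$dip[i, 1], system$dip[i, 2],
                                  system$dip[i, 3]))
    lines <- c(lines, base)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a prediction table
#'
#' CSV with mandatory columns `compound_id`, `dg_water`, `se_water`,
#' `dg_chex`, `se_chex`, `logd_pred`, `se_pred`, `logd_exp`, `err_exp`
#' and optional `groups` (semicolon-separated labels).  On load each
#' record's stored log D is checked for consistency with its free-energy
#' pair through the 2.3 R T relation, within a 0.02 tolerance absorbing
#' the rounding of the published columns.
#'
#' @param path CSV file path.
#' @param check Verify the log D consistency invariant (default TRUE).
#' @return Data frame of class `prediction_table`.
#' @export
read_prediction_table <- function(path, check = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("compound_id", "dg_water", "se_water", "dg_chex",
                "se_chex", "logd_pred", "se_pred", "logd_exp", "err_exp")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("prediction table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"groups" %in% names(df)) df$groups <- NA_character_
  if (any(df$se_water < 0 | df$se_chex < 0 | df$se_pred < 0 |
            df$err_exp < 0))
    stop("negative uncertainties in prediction table")
  if (check) {
    rec <- log_d(df$dg_water, df$dg_chex)
    bad <- abs(rec - df$logd_pred) > 0.02
    if (any(bad))
      stop("stored log D inconsistent with free-energy pair for compound(s) ",
           paste(df$compound_id[bad], collapse = ", "))
  }
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' The packaged 53-compound results table
#'
#' Transcription of the submitted water/cyclohexane solvation free
#' energies, predicted log D and experimental log D for the 53 challenge
#' compounds.  Chemical-group memberships are not part of the published
#' table; the `groups` column is therefore empty (see
#' `groups_stub.csv` in the package extdata).
#'
#' @return A `prediction_table` with 53 rows.
#' @export
elba_table1 <- function() {
  read_prediction_table(system.file("extdata", "table1.csv",
                                    package = "elbasolv"))
}

#' Write / read a TI series as TSV
#'
#' Columns: lambda, sample index, dU/dlambda, U_sv.
#'
#' @param series A [ti_series()].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `path` invisibly; `read_ti_series` returns a [ti_series()].
#' @export
write_ti_series <- function(series, path, seed = NA) {
  samples <- attr(series, "samples")
  usv <- attr(series, "u_sv")
  rows <- do.call(rbind, lapply(seq_along(samples), function(k)
    data.frame(lambda = series$lambda[k],
               sample = seq_along(samples[[k]]),
               dudl = samples[[k]], u_sv = usv[[k]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ti_series
#' @export
read_ti_series <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  lam <- sort(unique(df$lambda))
  entries <- lapply(lam, function(l)
    collect_dudl(df$u_sv[df$lambda == l], l))
  ti_series(entries)
}

#' Read a force-field parameter file
#'
#' YAML schema: a `sites` map of named [particle_spec()] entries (fields
#' kind, sigma, epsilon, charge, dipole, mass, rot_inertia), optional
#' `bonds` (i, j, r0, k) and `constraints` (i, j, d) lists.  Example
#' files for water, cyclohexane and the toy solutes ship under
#' `inst/extdata/`.
#'
#' @param path YAML file path.
#' @return List with `sites` (named list of [particle_spec()]), `bonds`
#'   (list of [bond_term()]) and `constraints` (data frame).
#' @export
read_forcefield <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sites)) stop("force-field file has no 'sites' section")
  sites <- lapply(y$sites, function(s) {
    particle_spec(kind = if (is.null(s$kind)) "atom" else s$kind,
                  lj = lj_params(s$sigma, s$epsilon),
                  charge = if (is.null(s$charge)) 0 else s$charge,
                  dipole = if (is.null(s$dipole)) 0 else s$dipole,
                  mass = s$mass,
                  rot_inertia = if (is.null(s$rot_inertia)) 0
                                else s$rot_inertia)
  })
  bonds <- lapply(y$bonds, function(b) bond_term(b$i, b$j, b$r0, b$k))
  cons <- if (length(y$constraints))
    do.call(rbind, lapply(y$constraints, function(cc)
      data.frame(i = cc$i, j = cc$j, d = cc$d)))
  else data.frame(i = integer(), j = integer(), d = numeric())
  list(sites = sites, bonds = bonds, constraints = cons)
}
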