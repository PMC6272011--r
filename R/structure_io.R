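## Structure containers and PDB / charged-PDBQ I/O.
##
## Coordinates are in Angstrom, fixed-column PDB conventions, 1-based
## residue numbers as in the source file.  The "pdbq_charged" dialect is a
## standard ATOM/HETATM record extended with the partial charge
## right-justified in columns 69-76 (%8.3f) and a 1-2 character atom-type
## code in columns 78-79; MODEL blocks are allowed.  Ensemble time stamps
## are carried as `REMARK TIME_PS <number>` lines preceding each MODEL.

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SOL", "DOD")
ION_RESNAMES   <- c("MG", "ZN", "MN", "NA", "CL", "K", "CA", "FE", "CU", "LI")

COVALENT_RADII <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02,
                    P = 1.06, F = 0.71, CL = 0.99, BR = 1.14, MG = 1.30,
                    ZN = 1.25, I = 1.33)

ATOMTYPE_ELEMENT <- c(C = "C", A = "C", N = "N", "NA" = "N", O = "O",
                      OA = "O", S = "S", SA = "S", H = "H", HD = "H",
                      P = "P", Mg = "MG")

#' Construct a molecular structure
#'
#' A `Structure` is an ordered atom table plus per-atom role labels
#' (`receptor`, `ligand`, `ion`, `water`) and free-form metadata.  It is the
#' common currency of the scoring, docking, ensemble and interaction
#' modules.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `atom_type`, `resname`, `resno`, `chain`, `x`, `y`, `z`, `charge`,
#'   `occupancy`, `alt_loc`, `record`, `role`.
#' @param metadata named list of free-form annotations.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  req <- c("serial", "name", "element", "atom_type", "resname", "resno",
           "chain", "x", "y", "z", "charge", "occupancy", "alt_loc",
           "record", "role")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stopf("atoms table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(atoms) < 1L) stop("a Structure must contain at least one atom")
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a model")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (!all(is.finite(atoms$charge)))
    stop("partial charges must be finite")
  bad_role <- setdiff(unique(atoms$role),
                      c("receptor", "ligand", "ion", "water"))
  if (length(bad_role))
    stopf("unknown role label(s): %s", paste(bad_role, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat(sprintf("Structure: %d atoms (%s)\n", nrow(x$atoms),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Extract atom coordinates as an n x 3 matrix
#' @param s a `Structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param s a `Structure`.
#' @param xyz n x 3 numeric matrix matching the atom count.
#' @return the modified `Structure`.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "Structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(s$atoms) || ncol(xyz) != 3L)
    stop("replacement coordinates must be an n x 3 matrix matching the atom count")
  s$atoms$x <- xyz[, 1L]; s$atoms$y <- xyz[, 2L]; s$atoms$z <- xyz[, 3L]
  s
}

infer_element <- function(name, atom_type = NA_character_) {
  atom_type <- rep_len(atom_type, length(name))
  el <- unname(ATOMTYPE_ELEMENT[atom_type])
  fix <- is.na(el)
  if (any(fix)) {
    # first alphabetic character of the atom name, two-letter for Mg/Cl...
    nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", name[fix])))
    el2 <- substr(nm, 1L, 2L)
    el[fix] <- ifelse(el2 %in% names(COVALENT_RADII), el2, substr(nm, 1L, 1L))
  }
  toupper(el)
}

infer_roles <- function(record, resname, atom_type) {
  resname <- toupper(trimws(resname))
  role <- ifelse(record == "ATOM", "receptor", "ligand")
  role[resname %in% WATER_RESNAMES] <- "water"
  role[resname %in% ION_RESNAMES & record == "HETATM"] <- "ion"
  role[!is.na(atom_type) & atom_type == "Mg"] <- "ion"
  role
}

parse_atom_record <- function(lines, lineno, dialect) {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad))
      stopf("malformed %s field in %s record at line %d", what,
            substr(lines[bad[1L]], 1L, 6L), lineno[bad[1L]])
    v
  }
  record    <- trimws(substr(lines, 1L, 6L))
  serial    <- num(substr(lines, 7L, 11L), "serial")
  name      <- trimws(substr(lines, 13L, 16L))
  alt_loc   <- trimws(substr(lines, 17L, 17L))
  resname   <- trimws(substr(lines, 18L, 20L))
  chain     <- trimws(substr(lines, 22L, 22L))
  resno     <- num(substr(lines, 23L, 26L), "residue number")
  x         <- num(substr(lines, 31L, 38L), "x")
  y         <- num(substr(lines, 39L, 46L), "y")
  z         <- num(substr(lines, 47L, 54L), "z")
  occ_raw   <- trimws(substr(lines, 55L, 60L))
  occupancy <- suppressWarnings(as.numeric(occ_raw))
  occupancy[!nzchar(occ_raw)] <- 1
  if (anyNA(occupancy))
    stopf("malformed occupancy at line %d", lineno[which(is.na(occupancy))[1L]])

  if (dialect == "pdbq_charged") {
    charge    <- num(substr(lines, 69L, 76L), "partial charge")
    atom_type <- trimws(substr(lines, 78L, 79L))
    if (any(!nzchar(atom_type)))
      stopf("missing atom-type code at line %d",
            lineno[which(!nzchar(atom_type))[1L]])
    element <- infer_element(name, atom_type)
  } else {
    charge    <- rep(0, length(lines))
    atom_type <- NA_character_
    el_col    <- trimws(substr(lines, 77L, 78L))
    element   <- ifelse(nzchar(el_col), toupper(el_col), infer_element(name))
    atom_type <- rep(NA_character_, length(lines))
  }

  data.frame(serial = as.integer(serial), name = name, element = element,
             atom_type = atom_type, resname = resname,
             resno = as.integer(resno), chain = chain,
             x = x, y = y, z = z, charge = charge, occupancy = occupancy,
             alt_loc = alt_loc, record = record,
             role = infer_roles(record, resname, atom_type),
             stringsAsFactors = FALSE)
}

# keep one conformer per alternate-location group: highest occupancy,
# ties broken alphabetically (conformer A wins over B at equal occupancy)
collapse_alt_loc <- function(atoms) {
  has_alt <- nzchar(atoms$alt_loc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- idx[order(-atoms$occupancy[idx], atoms$alt_loc[idx])]
    keep[setdiff(idx, ord[1L])] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a single-model structure file
#'
#' Parses PDB `ATOM`/`HETATM` records, or the charged PDBQ-like dialect in
#' which each record additionally carries a partial charge (columns 69-76,
#' `%8.3f`) and an energy-table atom-type code (columns 78-79).  Alternate
#' locations are collapsed to a single conformer (highest occupancy, ties
#' alphabetical).  Role labels (`receptor`/`ligand`/`ion`/`water`) are
#' assigned from the record type and residue name.
#'
#' @param path file to read.
#' @param dialect `"pdb"` or `"pdbq_charged"`.
#' @return A [new_structure()] object with one model.
#' @export
read_structure <- function(path, dialect = c("pdb", "pdbq_charged")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  n_models <- sum(grepl("^MODEL", lines))
  if (n_models > 1L)
    stopf("%s contains %d MODEL blocks; use read_ensemble() for trajectories",
          path, n_models)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stopf("no ATOM/HETATM records found in %s", path)
  atoms <- parse_atom_record(lines[is_atom], which(is_atom), dialect)
  atoms <- collapse_alt_loc(atoms)
  new_structure(atoms, metadata = list(source = path, dialect = dialect))
}

format_atom_lines <- function(atoms, dialect) {
  name_field <- ifelse(nchar(atoms$name) >= 4L,
                       substr(atoms$name, 1L, 4L),
                       paste0(" ", sprintf("%-3s", atoms$name)))
  alt <- ifelse(nzchar(atoms$alt_loc), substr(atoms$alt_loc, 1L, 1L), " ")
  base <- sprintf("%-6s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  atoms$record, atoms$serial, name_field, alt,
                  atoms$resname, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, atoms$occupancy, 0)
  if (dialect == "pdbq_charged") {
    sprintf("%s  %8.3f %-2s", base, atoms$charge, atoms$atom_type)
  } else {
    sprintf("%s          %2s", base, toupper(substr(atoms$element, 1L, 2L)))
  }
}

#' Write a structure to disk
#'
#' Round-trip guarantee: re-reading a written file reproduces names,
#' residues, positions and charges to three decimals.
#'
#' @param s a `Structure`.
#' @param path output file.
#' @param dialect `"pdb"` or `"pdbq_charged"`.
#' @export
write_structure <- function(s, path, dialect = c("pdb", "pdbq_charged")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "Structure"))
  if (nrow(s$atoms) < 1L) stop("refusing to write an empty Structure")
  if (dialect == "pdbq_charged" && anyNA(s$atoms$atom_type))
    stop("all atoms need an atom_type to write the pdbq_charged dialect")
  lines <- c(format_atom_lines(s$atoms, dialect), "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("could not write to %s", path)
  invisible(path)
}

#' Read a multi-model PDB ensemble
#'
#' Frames are ordered by MODEL number.  Times are taken from
#' `REMARK TIME_PS <t>` lines preceding each MODEL when present; otherwise
#' frames are assigned times 0, 1, 2, ... with a warning.
#'
#' @param path multi-model PDB(Q) file.
#' @param dialect `"pdb"` or `"pdbq_charged"`.
#' @return An `EnsembleTrajectory`: list with `frames` (list of
#'   `Structure`), `times` (ps) and `topology_constant`.
#' @export
read_ensemble <- function(path, dialect = c("pdb", "pdbq_charged")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    s <- read_structure(path, dialect)
    return(new_ensemble(list(s), times = 0))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stopf("unbalanced MODEL/ENDMDL records in %s", path)
  time_lines <- grep("^REMARK +TIME_PS", lines)
  frames <- vector("list", length(model_starts))
  times <- rep(NA_real_, length(model_starts))
  for (i in seq_along(model_starts)) {
    block <- lines[model_starts[i]:model_ends[i]]
    offs  <- model_starts[i]:model_ends[i]
    is_atom <- grepl("^(ATOM  |HETATM)", block)
    if (!any(is_atom)) stopf("MODEL %d in %s has no atoms", i, path)
    atoms <- parse_atom_record(block[is_atom], offs[is_atom], dialect)
    atoms <- collapse_alt_loc(atoms)
    frames[[i]] <- new_structure(atoms, metadata = list(source = path,
                                                        model = i))
    tl <- time_lines[time_lines < model_starts[i]]
    if (length(tl)) {
      prev_end <- if (i == 1L) 0L else model_ends[i - 1L]
      tl <- tl[tl > prev_end]
      if (length(tl))
        times[i] <- as.numeric(sub("^REMARK +TIME_PS +", "", lines[tl[1L]]))
    }
  }
  if (all(is.na(times))) {
    warnf("no REMARK TIME_PS annotations in %s; assigning times 0,1,2,... ps",
          path)
    times <- seq_along(frames) - 1
  } else if (anyNA(times)) {
    stopf("REMARK TIME_PS present for only some models in %s", path)
  }
  new_ensemble(frames, times)
}

#' Construct an ensemble trajectory from structures and times
#' @param frames list of `Structure` objects sharing one topology.
#' @param times numeric vector of time stamps in ps, strictly increasing.
#' @param topology_constant are all frames the same atom list? (validated)
#' @return An `EnsembleTrajectory`.
#' @export
new_ensemble <- function(frames, times, topology_constant = TRUE) {
  if (!length(frames)) stop("an ensemble needs at least one frame")
  if (length(times) != length(frames))
    stop("times and frames lengths differ")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (topology_constant) {
    n0 <- nrow(frames[[1L]]$atoms)
    counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
    if (any(counts != n0))
      stopf("models have differing atom counts (%s); topology must be constant",
            paste(unique(counts), collapse = ", "))
  }
  structure(list(frames = frames, times = as.numeric(times),
                 topology_constant = topology_constant),
            class = "EnsembleTrajectory")
}

#' @export
print.EnsembleTrajectory <- function(x, ...) {
  cat(sprintf("EnsembleTrajectory: %d frames, %.0f-%.0f ps, %d atoms/frame\n",
              length(x$frames), min(x$times), max(x$times),
              nrow(x$frames[[1L]]$atoms)))
  invisible(x)
}

#' Write an ensemble as a multi-model PDB(Q) file with TIME_PS remarks
#' @param traj an `EnsembleTrajectory`.
#' @param path output file.
#' @param dialect `"pdb"` or `"pdbq_charged"`.
#' @export
write_ensemble <- function(traj, path, dialect = c("pdb", "pdbq_charged")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  out <- character(0)
  for (i in seq_along(traj$frames)) {
    out <- c(out,
             sprintf("REMARK TIME_PS %g", traj$times[i]),
             sprintf("MODEL %8d", i),
             format_atom_lines(traj$frames[[i]]$atoms, dialect),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

## ---- connectivity and torsion trees ----

covalent_radius <- function(element) {
  r <- COVALENT_RADII[toupper(element)]
  r[is.na(r)] <- 0.77
  unname(r)
}

# bonded iff 0.4 < d <= r_i + r_j + 0.4 (standard covalent-radius rule)
infer_connectivity <- function(s) {
  xyz <- coords(s)
  n <- nrow(xyz)
  rad <- covalent_radius(s$atoms$element)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rad, rad, `+`) + 0.4
  bonded <- d > 0.4 & d <= thr
  diag(bonded) <- FALSE
  which(bonded & upper.tri(bonded), arr.ind = TRUE)
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1L]; b <- bonds[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bfs_component <- function(adj, start, blocked_edge = NULL) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.null(blocked_edge) &&
          ((v == blocked_edge[1L] && w == blocked_edge[2L]) ||
           (v == blocked_edge[2L] && w == blocked_edge[1L]))) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

#' Build a ligand torsion tree
#'
#' Represents the ligand as a rigid root plus rotatable bonds, each moving
#' the subtree of atoms strictly beyond the bond (away from the root).
#' Connectivity is inferred from interatomic distances and covalent radii.
#'
#' @param s ligand `Structure`.
#' @param bonds list of atom-index pairs (indices into `s$atoms`) to treat
#'   as rotatable, or `NULL` to auto-select all non-ring, non-terminal
#'   heavy-atom bonds.
#' @param root_atom index anchoring the rigid root (default 1).
#' @return A `TorsionTree`: `root_atom_indices`, `rotatable_bonds`
#'   (each `list(axis, moved)`), `n_tor`, and the inferred `connectivity`.
#' @export
build_torsion_tree <- function(s, bonds = NULL, root_atom = 1L) {
  stopifnot(inherits(s, "Structure"))
  n <- nrow(s$atoms)
  conn <- infer_connectivity(s)
  adj <- adjacency_list(conn, n)
  if (length(bfs_component(adj, root_atom)) != n)
    stop("ligand connectivity graph is disconnected under the distance rule")
  if (is.null(bonds)) {
    bonds <- list()
    if (nrow(conn)) for (k in seq_len(nrow(conn))) {
      a <- conn[k, 1L]; b <- conn[k, 2L]
      if (length(adj[[a]]) < 2L || length(adj[[b]]) < 2L) next # terminal
      if (b %in% bfs_component(adj, a, blocked_edge = c(a, b))) next # ring
      if (s$atoms$element[a] == "H" || s$atoms$element[b] == "H") next
      bonds <- c(bonds, list(c(a, b)))
    }
  }
  rotatable <- vector("list", length(bonds))
  for (k in seq_along(bonds)) {
    ab <- as.integer(bonds[[k]])
    if (length(ab) != 2L || any(ab < 1L | ab > n))
      stopf("bond %d is not a valid atom-index pair", k)
    a <- ab[1L]; b <- ab[2L]
    if (!b %in% adj[[a]])
      stopf("atoms %d-%d are not bonded under the distance rule", a, b)
    if (b %in% bfs_component(adj, a, blocked_edge = c(a, b)))
      stopf("bond %d-%d lies in a ring and cannot be a torsion axis", a, b)
    comp_b <- bfs_component(adj, b, blocked_edge = c(a, b))
    # orient the axis so `a` is on the root side
    if (root_atom %in% comp_b) {
      tmp <- a; a <- b; b <- tmp
      comp_b <- bfs_component(adj, b, blocked_edge = c(a, b))
    }
    moved <- setdiff(comp_b, b)
    if (!length(moved))
      stopf("bond %d-%d is terminal; rotating it moves no atoms", a, b)
    rotatable[[k]] <- list(axis = c(a, b), moved = moved)
  }
  moved_all <- unique(unlist(lapply(rotatable, `[[`, "moved")))
  structure(list(root_atom_indices = setdiff(seq_len(n), moved_all),
                 rotatable_bonds = rotatable,
                 n_tor = length(rotatable),
                 connectivity = conn),
            class = "TorsionTree")
}

#' @export
print.TorsionTree <- function(x, ...) {
  cat(sprintf("TorsionTree: %d rotatable bond(s), root of %d atom(s)\n",
              x$n_tor, length(x$root_atom_indices)))
  invisible(x)
}

#' Rotate one torsion of a coordinate set
#'
#' @param xyz n x 3 ligand coordinates.
#' @param tree a `TorsionTree` for the same atom ordering.
#' @param k index of the rotatable bond.
#' @param angle_deg rotation in degrees about the bond axis.
#' @return rotated coordinates; only the bond's moved set changes.
#' @export
apply_torsion <- function(xyz, tree, k, angle_deg) {
  rb <- tree$rotatable_bonds[[k]]
  a <- xyz[rb$axis[1L], ]; b <- xyz[rb$axis[2L], ]
  xyz[rb$moved, ] <- rotate_about_axis(xyz[rb$moved, , drop = FALSE],
                                       origin = b, axis = b - a,
                                       angle_deg = angle_deg)
  xyz
}
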