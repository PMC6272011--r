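## Geometric interaction analysis of a bound pose (LigPlot-style):
## hydrogen bonds (donor-acceptor distance plus, when the donor hydrogen
## is present, D-H...A angle) and residue-grouped nonbonded contacts
## across the ligand/receptor boundary.  Ions and waters are excluded by
## default via their role labels.

hb_acceptor_mask <- function(atoms, tab) {
  known <- !is.na(atoms$atom_type) & atoms$atom_type %in% tab$type
  cls <- rep("none", nrow(atoms))
  cls[known] <- tab$hbond_class[match(atoms$atom_type[known], tab$type)]
  acc <- cls %in% c("acceptor", "both")
  # untyped structures: fall back to the element heuristic
  acc[!known & atoms$element %in% c("O", "N")] <- TRUE
  acc
}

attached_hydrogens <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  is_h <- atoms$element == "H"
  heavy <- which(!is_h)
  hyd <- which(is_h)
  out <- vector("list", nrow(atoms))
  if (!length(hyd)) return(out)
  for (h in hyd) {
    d <- sqrt(rowSums(sweep(xyz[heavy, , drop = FALSE], 2L, xyz[h, ])^2))
    thr <- covalent_radius(atoms$element[heavy]) + 0.37 + 0.4
    near <- heavy[d <= thr & d > 0.4]
    if (length(near)) {
      owner <- near[which.min(d[match(near, heavy)])]
      out[[owner]] <- c(out[[owner]], h)
    }
  }
  out
}

#' Detect ligand-receptor hydrogen bonds
#'
#' Donor-acceptor pairs across the ligand/receptor boundary with D-A
#' distance at most `max_da_distance` and, when the donor hydrogen is
#' present in the structure, D-H...A angle at least `min_dha_angle`.
#' Donors are N/O/S heavy atoms bearing a covalently attached hydrogen;
#' acceptors come from the parameter table's hydrogen-bond classes (with
#' an element fallback for untyped input).  Waters and ions never
#' participate.
#'
#' @param complex a `Structure` containing both ligand- and receptor-role
#'   atoms.
#' @param max_da_distance donor-acceptor cutoff, Angstrom (default 3.5).
#' @param min_dha_angle minimum D-H...A angle, degrees (default 120).
#' @param p an `EnergyParameters` object supplying the type table.
#' @return data frame: donor/acceptor serials, names, residue labels,
#'   distance (A), angle (deg, `NA` when no hydrogen present).
#' @export
detect_hbonds <- function(complex, max_da_distance = 3.5,
                          min_dha_angle = 120,
                          p = default_energy_parameters()) {
  stopifnot(inherits(complex, "Structure"))
  atoms <- complex$atoms
  active <- atoms$role %in% c("receptor", "ligand")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  hyd_of <- attached_hydrogens(atoms)
  donor <- active & atoms$element %in% c("N", "O", "S") &
    vapply(hyd_of, length, integer(1)) > 0L
  acceptor <- active & hb_acceptor_mask(atoms, p$type_table) &
    atoms$element != "H"

  res_label <- sprintf("%s%s%d", atoms$resname, atoms$chain, atoms$resno)
  out <- list()
  for (d in which(donor)) {
    for (a in which(acceptor)) {
      if (atoms$role[d] == atoms$role[a]) next  # must cross the boundary
      dist <- vnorm(xyz[a, ] - xyz[d, ])
      if (dist > max_da_distance || dist < 0.5) next
      angle <- NA_real_
      ok <- TRUE
      hs <- hyd_of[[d]]
      if (length(hs)) {
        angs <- vapply(hs, function(h) {
          v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
          acos(min(1, max(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
            180 / pi
        }, numeric(1))
        angle <- max(angs)
        ok <- angle >= min_dha_angle
      }
      if (ok)
        out[[length(out) + 1L]] <- data.frame(
          donor_serial = atoms$serial[d], donor_name = atoms$name[d],
          donor_residue = res_label[d], donor_role = atoms$role[d],
          acceptor_serial = atoms$serial[a], acceptor_name = atoms$name[a],
          acceptor_residue = res_label[a], acceptor_role = atoms$role[a],
          distance_A = dist, angle_deg = angle)
    }
  }
  if (!length(out))
    return(data.frame(donor_serial = integer(0), donor_name = character(0),
                      donor_residue = character(0), donor_role = character(0),
                      acceptor_serial = integer(0),
                      acceptor_name = character(0),
                      acceptor_residue = character(0),
                      acceptor_role = character(0),
                      distance_A = numeric(0), angle_deg = numeric(0)))
  do.call(rbind, out)
}

#' Detect ligand-receptor nonbonded contacts
#'
#' All cross-boundary heavy-atom pairs within `cutoff`, excluding pairs
#' already reported as hydrogen bonds, grouped and sorted by receptor
#' residue.  Waters and ions are excluded.
#'
#' @param complex a `Structure` with role labels.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 3.9).
#' @param hbonds optional result of [detect_hbonds()] whose donor-acceptor
#'   pairs are excluded from the contact list.
#' @return data frame: ligand atom, receptor atom, receptor residue,
#'   distance (A), sorted by residue.
#' @export
detect_contacts <- function(complex, cutoff = 3.9, hbonds = NULL) {
  stopifnot(inherits(complex, "Structure"))
  atoms <- complex$atoms
  li <- which(atoms$role == "ligand" & atoms$element != "H")
  ri <- which(atoms$role == "receptor" & atoms$element != "H")
  if (!length(li) || !length(ri))
    return(data.frame(ligand_serial = integer(0), ligand_name = character(0),
                      receptor_serial = integer(0),
                      receptor_name = character(0), residue = character(0),
                      distance_A = numeric(0)))
  lxyz <- as.matrix(atoms[li, c("x", "y", "z")])
  rxyz <- as.matrix(atoms[ri, c("x", "y", "z")])
  d2 <- outer(rowSums(lxyz^2), rowSums(rxyz^2), `+`) - 2 * lxyz %*% t(rxyz)
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!is.null(hbonds) && nrow(hbonds)) {
    hb_keys <- c(paste(hbonds$donor_serial, hbonds$acceptor_serial),
                 paste(hbonds$acceptor_serial, hbonds$donor_serial))
  } else hb_keys <- character(0)
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    i <- li[hits[k, 1L]]; j <- ri[hits[k, 2L]]
    if (paste(atoms$serial[i], atoms$serial[j]) %in% hb_keys) return(NULL)
    data.frame(ligand_serial = atoms$serial[i], ligand_name = atoms$name[i],
               receptor_serial = atoms$serial[j],
               receptor_name = atoms$name[j],
               residue = sprintf("%s%s%d", atoms$resname[j], atoms$chain[j],
                                 atoms$resno[j]),
               distance_A = sqrt(max(d2[hits[k, 1L], hits[k, 2L]], 0)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(ligand_serial = integer(0), ligand_name = character(0),
                      receptor_serial = integer(0),
                      receptor_name = character(0), residue = character(0),
                      distance_A = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$residue, out$distance_A), , drop = FALSE]
}

#' Full interaction report for a bound pose
#'
#' @inheritParams detect_hbonds
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom.
#' @return An `InteractionReport`: `hbonds`, `contacts`, `excluded_roles`
#'   and the criteria used.
#' @export
interaction_report <- function(complex, max_da_distance = 3.5,
                               min_dha_angle = 120, contact_cutoff = 3.9,
                               p = default_energy_parameters()) {
  hb <- detect_hbonds(complex, max_da_distance, min_dha_angle, p)
  ct <- detect_contacts(complex, contact_cutoff, hbonds = hb)
  structure(list(hbonds = hb, contacts = ct,
                 excluded_roles = c("ion", "water"),
                 criteria = list(max_da_distance = max_da_distance,
                                 min_dha_angle = min_dha_angle,
                                 contact_cutoff = contact_cutoff)),
            class = "InteractionReport")
}

#' @export
print.InteractionReport <- function(x, ...) {
  cat(sprintf("InteractionReport: %d hydrogen bond(s), %d contact(s) in %d residue(s)\n",
              nrow(x$hbonds), nrow(x$contacts),
              length(unique(x$contacts$residue))))
  invisible(x)
}
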