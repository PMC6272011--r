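## Affinity grid maps: per-atom-type van der Waals / hydrogen-bond fields,
## an electrostatic potential per unit charge, and the two desolvation
## fields (sum of receptor volumes and of receptor solvation parameters,
## Gaussian-weighted), tabulated on a regular lattice and evaluated by
## trilinear interpolation.  Grid scoring reproduces direct pair scoring
## exactly at grid nodes.

grid_axes <- function(box) {
  lapply(1:3, function(k) {
    box$center[k] + (seq_len(box$npts[k]) - 1 - (box$npts[k] - 1) / 2) *
      box$spacing
  })
}

#' Build affinity grid maps for a rigid receptor
#'
#' Tabulates, at every lattice node, the weighted 12-6 (and 12-10 where
#' applicable) interaction field for each requested ligand atom type, the
#' screened electrostatic potential per unit ligand charge, and the
#' Gaussian desolvation fields.  The box has `(npts - 1) * spacing` edge
#' length per axis; with the conventional 0.375 A spacing and 100 points
#' per axis this is a 37.125 A cube.
#'
#' @param receptor `Structure` with role labels; waters are excluded,
#'   ions excluded unless `include_ions`.
#' @param spacing lattice spacing, Angstrom (`> 0`).
#' @param npts integer vector of 3 points-per-axis (each `>= 2`).
#' @param ligand_types atom-type codes the maps must cover.
#' @param p an `EnergyParameters` object (stored in the box and reused by
#'   [grid_score()]).
#' @param center `"geometric"` to center on the geometric center of
#'   `selection`, or an explicit numeric xyz.
#' @param selection atom indices defining the centering selection
#'   (default: all receptor-role atoms).  The grid box of the original
#'   workflow is centered on the geometric center of the DNA; pass the
#'   DNA atom indices here to reproduce that rule.
#' @param include_ions include ion-role atoms in the receptor field?
#' @param compute_maps tabulate the field maps?  `FALSE` returns the box
#'   geometry only (cannot be scored), useful for planning grid setups.
#' @return A `GridBox`.
#' @export
make_grid_box <- function(receptor, spacing = 0.375,
                          npts = c(100L, 100L, 100L),
                          ligand_types,
                          p = default_energy_parameters(),
                          center = "geometric", selection = NULL,
                          include_ions = FALSE, compute_maps = TRUE) {
  stopifnot(inherits(receptor, "Structure"))
  if (spacing <= 0) stop("grid spacing must be positive")
  npts <- as.integer(npts)
  if (length(npts) != 3L || any(npts < 2L))
    stop("npts must be three integers, each >= 2")
  rec_idx <- select_role_atoms(receptor, c("receptor", if (include_ions) "ion"))
  if (!length(rec_idx)) stop("no receptor-role atoms for the grid field")
  if (is.character(center) && center == "geometric") {
    sel <- selection %||% rec_idx
    if (!length(sel)) stop("empty centering selection")
    center <- unname(colMeans(coords(receptor)[sel, , drop = FALSE]))
  } else {
    center <- as.numeric(center)
    if (length(center) != 3L || !all(is.finite(center)))
      stop("explicit center must be a finite xyz triple")
  }

  box <- structure(list(center = center, spacing = spacing, npts = npts,
                        ligand_types = unique(ligand_types), params = p),
                   class = "GridBox")
  if (!compute_maps) return(box)
  ax <- grid_axes(box)
  tab <- p$type_table
  t_idx <- type_index(box$ligand_types, tab)
  atoms <- receptor$atoms[rec_idx, ]
  a_idx <- type_index(atoms$atom_type, tab)

  dims <- npts
  zero <- array(0, dim = dims)
  vdw_maps <- hb_maps <- stats::setNames(
    rep(list(zero), length(box$ligand_types)), box$ligand_types)
  has_hb <- stats::setNames(logical(length(box$ligand_types)),
                            box$ligand_types)
  elec_map <- desolv_V <- desolv_S <- zero
  two_sigma2 <- 2 * p$sigma^2

  for (a in seq_len(nrow(atoms))) {
    r2 <- outer(outer((ax[[1L]] - atoms$x[a])^2,
                      (ax[[2L]] - atoms$y[a])^2, `+`),
                (ax[[3L]] - atoms$z[a])^2, `+`)
    r <- sqrt(r2)
    r[r < R_MIN] <- R_MIN
    r2c <- r * r
    r6 <- r2c^3; r10 <- r6 * r2c * r2c; r12 <- r6 * r6
    gauss <- exp(-r2c / two_sigma2)
    elec_map <- elec_map +
      pmin(p$W_elec * atoms$charge[a] * p$coulomb / (dielectric(r, p) * r),
           ENERGY_CLAMP)
    desolv_V <- desolv_V + tab$vol[a_idx[a]] * gauss
    desolv_S <- desolv_S + tab$solpar[a_idx[a]] * gauss
    for (t in seq_along(box$ligand_types)) {
      co <- pair_coefficients(t_idx[t], a_idx[a], tab)
      vdw_maps[[t]] <- vdw_maps[[t]] +
        pmin(p$W_vdw * (co$A / r12 - co$B / r6), ENERGY_CLAMP)
      if (co$is_hb) {
        has_hb[t] <- TRUE
        hb_maps[[t]] <- hb_maps[[t]] +
          pmin(p$W_hbond * (co$C / r12 - co$D / r10), ENERGY_CLAMP)
      }
    }
  }
  box$maps <- list(vdw = vdw_maps, hbond = hb_maps[has_hb],
                   elec = elec_map, desolv_V = desolv_V, desolv_S = desolv_S)
  box
}

#' @export
print.GridBox <- function(x, ...) {
  cat(sprintf("GridBox: %dx%dx%d nodes, %.3f A spacing, edge %s A, types %s\n",
              x$npts[1L], x$npts[2L], x$npts[3L], x$spacing,
              paste(sprintf("%.3f", (x$npts - 1L) * x$spacing),
                    collapse = " x "),
              paste(x$ligand_types, collapse = ", ")))
  invisible(x)
}

# trilinear interpolation of one 3-D map at positions (n x 3);
# positions must already be validated in-box
trilinear <- function(map, box, pos) {
  origin <- box$center - (box$npts - 1) / 2 * box$spacing
  u <- sweep(pos, 2L, origin) / box$spacing
  n <- box$npts
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(n - 2L, each = nrow(u)), ncol = 3L))
  f <- u - i0
  i0 <- i0 + 1L  # 1-based
  v <- numeric(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    ix <- i0[k, 1L]; iy <- i0[k, 2L]; iz <- i0[k, 3L]
    fx <- f[k, 1L]; fy <- f[k, 2L]; fz <- f[k, 3L]
    c00 <- map[ix, iy, iz]     * (1 - fx) + map[ix + 1L, iy, iz]     * fx
    c10 <- map[ix, iy + 1L, iz] * (1 - fx) + map[ix + 1L, iy + 1L, iz] * fx
    c01 <- map[ix, iy, iz + 1L] * (1 - fx) + map[ix + 1L, iy, iz + 1L] * fx
    c11 <- map[ix, iy + 1L, iz + 1L] * (1 - fx) +
      map[ix + 1L, iy + 1L, iz + 1L] * fx
    v[k] <- ((c00 * (1 - fy) + c10 * fy) * (1 - fz) +
               (c01 * (1 - fy) + c11 * fy) * fz)
  }
  v
}

check_in_box <- function(box, pos, labels) {
  origin <- box$center - (box$npts - 1) / 2 * box$spacing
  upper <- box$center + (box$npts - 1) / 2 * box$spacing
  tol <- 1e-9
  out <- which(pos[, 1L] < origin[1L] - tol | pos[, 1L] > upper[1L] + tol |
                 pos[, 2L] < origin[2L] - tol | pos[, 2L] > upper[2L] + tol |
                 pos[, 3L] < origin[3L] - tol | pos[, 3L] > upper[3L] + tol)
  if (length(out))
    stopf("ligand atom(s) outside the grid box: %s",
          paste(labels[out], collapse = ", "))
}

#' Score a ligand pose by grid interpolation
#'
#' Per-atom contributions are trilinear interpolations of the box's maps;
#' the result matches [score_pose()] exactly at grid nodes and closely
#' off-node.  Every ligand atom must lie inside the box.
#'
#' @param box a `GridBox` from [make_grid_box()].
#' @param ligand `Structure` with role `"ligand"` atoms.
#' @param tree optional `TorsionTree` for the torsional penalty.
#' @param p energy parameters; defaults to those baked into the box.
#' @return A `ScoreBreakdown`.
#' @export
grid_score <- function(box, ligand, tree = NULL, p = NULL) {
  stopifnot(inherits(box, "GridBox"), inherits(ligand, "Structure"))
  p <- p %||% box$params
  li <- select_role_atoms(ligand, "ligand")
  if (!length(li)) stop("no ligand-role atoms to score")
  la <- ligand$atoms[li, ]
  missing_types <- setdiff(la$atom_type, names(box$maps$vdw))
  if (length(missing_types))
    stopf("grid box lacks maps for ligand type(s): %s",
          paste(missing_types, collapse = ", "))
  pos <- as.matrix(la[, c("x", "y", "z")])
  check_in_box(box, pos, sprintf("%s(serial %d)", la$name, la$serial))
  tab <- p$type_table
  ti <- type_index(la$atom_type, tab)
  vdw <- hbond <- desolv <- 0
  for (t in unique(la$atom_type)) {
    sel <- which(la$atom_type == t)
    vdw <- vdw + sum(trilinear(box$maps$vdw[[t]], box,
                               pos[sel, , drop = FALSE]))
    if (t %in% names(box$maps$hbond))
      hbond <- hbond + sum(trilinear(box$maps$hbond[[t]], box,
                                     pos[sel, , drop = FALSE]))
  }
  elec <- sum(la$charge * trilinear(box$maps$elec, box, pos))
  vfield <- trilinear(box$maps$desolv_V, box, pos)
  sfield <- trilinear(box$maps$desolv_S, box, pos)
  desolv <- sum(p$W_desolv * (tab$solpar[ti] * vfield + tab$vol[ti] * sfield))
  n_tor <- if (is.null(tree)) 0L else tree$n_tor
  new_score_breakdown(vdw, hbond, elec, desolv, p$W_tor * n_tor)
}
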