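## Three evaluation tiers for a ligand in a rigid pocket:
##   rescore -- score the input coordinates as-is;
##   refine  -- stochastic accept-if-better local descent confined to a
##              small box around the input pose;
##   dock    -- multi-start search over the whole grid box (random rigid
##              placement + torsions, each locally refined on the grid),
##              pooled and clustered by pose RMSD.
## All randomness flows from a single per-call seed.

#' Construct a ligand pose
#'
#' A pose is a rigid-body transform (translation + unit quaternion about
#' the ligand centroid) plus one angle per rotatable bond, applied to the
#' reference ligand coordinates.  The identity pose reproduces the input
#' coordinates.
#'
#' @param translation xyz offset, Angstrom.
#' @param orientation unit quaternion (w, x, y, z).
#' @param torsion_angles degrees, one per rotatable bond.
#' @return A `Pose`.
#' @export
new_pose <- function(translation = c(0, 0, 0),
                     orientation = c(1, 0, 0, 0),
                     torsion_angles = numeric(0)) {
  if (abs(vnorm(orientation) - 1) > 1e-9)
    stop("orientation must be a unit quaternion")
  structure(list(translation = as.numeric(translation),
                 orientation = as.numeric(orientation),
                 torsion_angles = as.numeric(torsion_angles)),
            class = "Pose")
}

#' Realize a pose as ligand coordinates
#'
#' Torsions are applied first (about the reference geometry), then the
#' rigid rotation about the ligand centroid, then the translation.
#'
#' @param ligand reference `Structure`.
#' @param tree `TorsionTree` (may be `NULL` when the pose has no torsions).
#' @param pose a `Pose`.
#' @return `Structure` with transformed coordinates.
#' @export
realize_pose <- function(ligand, tree, pose) {
  xyz <- coords(ligand)
  if (length(pose$torsion_angles)) {
    if (is.null(tree) || tree$n_tor != length(pose$torsion_angles))
      stop("pose torsion count does not match the torsion tree")
    for (k in seq_len(tree$n_tor))
      xyz <- apply_torsion(xyz, tree, k, pose$torsion_angles[k])
  }
  ctr <- colMeans(coords(ligand))
  R <- quat_to_matrix(pose$orientation)
  xyz <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr + pose$translation, `+`)
  set_coords(ligand, xyz)
}

#' Rescore a fixed binding mode
#'
#' Tier 1 of the evaluation scheme: score the ligand exactly where it
#' stands (e.g. crystallographic coordinates).  Identical to
#' [score_pose()].
#'
#' @inheritParams score_pose
#' @return A `ScoreBreakdown`.
#' @export
rescore <- function(receptor, ligand, tree = NULL,
                    p = default_energy_parameters(), include_ions = FALSE) {
  score_pose(receptor, ligand, tree, p, include_ions = include_ions)
}

# shared accept-if-better descent kernel with adaptive step sizes.
# objective(pose) must return a finite score or +Inf.
descend <- function(objective, pose0, n_tor, n_iter,
                    step = list(t = 0.3, r = 5, tor = 5),
                    clamp = identity) {
  cur <- pose0
  cur_score <- objective(cur)
  step0 <- step
  for (it in seq_len(n_iter)) {
    cand <- cur
    cand$translation <- cand$translation + stats::rnorm(3, sd = step$t)
    axis <- stats::rnorm(3)
    cand$orientation <- quat_normalize(quat_multiply(
      quat_from_axis_angle(axis, stats::rnorm(1, sd = step$r)),
      cand$orientation))
    if (n_tor > 0L)
      cand$torsion_angles <- wrap_angle(
        cand$torsion_angles + stats::rnorm(n_tor, sd = step$tor))
    cand <- clamp(cand)
    s <- objective(cand)
    if (s < cur_score) {
      cur <- cand; cur_score <- s
      step <- Map(function(x, x0) min(x * 1.3, x0), step, step0)
    } else {
      step <- lapply(step, function(x) max(x * 0.9, 1e-4))
    }
  }
  list(pose = cur, score = cur_score)
}

#' Locally refine a ligand pose
#'
#' Tier 2: stochastic accept-if-better descent with adaptive step sizes,
#' confined to a restricted space around the input pose (translation norm,
#' net rotation angle and per-torsion deviation bounds).  The returned
#' score never exceeds the input score, and results are deterministic
#' given `seed`.
#'
#' @inheritParams score_pose
#' @param bounds list with `max_translation` (A), `max_rotation` (deg),
#'   `max_torsion` (deg); all positive.
#' @param n_iter iteration budget (`>= 1`).
#' @param seed integer RNG seed.
#' @return list with `pose` (a `Pose` relative to the input coordinates)
#'   and `score` (a `ScoreBreakdown`).
#' @export
refine <- function(receptor, ligand, tree = NULL,
                   p = default_energy_parameters(),
                   bounds = list(max_translation = 1, max_rotation = 15,
                                 max_torsion = 15),
                   n_iter = 300L, seed = 1L, include_ions = FALSE) {
  if (any(unlist(bounds) <= 0)) stop("refine bounds must be positive")
  if (!is_count(n_iter)) stop("iteration budget must be a positive integer")
  n_tor <- if (is.null(tree)) 0L else tree$n_tor
  clamp <- function(pose) {
    tn <- vnorm(pose$translation)
    if (tn > bounds$max_translation)
      pose$translation <- pose$translation * bounds$max_translation / tn
    ang <- quat_angle(pose$orientation)
    if (ang > bounds$max_rotation) {
      # pull the rotation back onto the bound along the same axis
      q <- pose$orientation
      axis <- q[2:4]
      if (vnorm(axis) > 1e-12) {
        sgn <- if (q[1L] < 0) -1 else 1
        pose$orientation <- quat_from_axis_angle(
          sgn * axis, bounds$max_rotation)
      } else pose$orientation <- quat_identity()
    }
    if (length(pose$torsion_angles)) {
      d <- pmax(pmin(pose$torsion_angles, bounds$max_torsion),
                -bounds$max_torsion)
      pose$torsion_angles <- d
    }
    pose
  }
  objective <- function(pose) {
    score_pose(receptor, realize_pose(ligand, tree, pose), tree, p,
               include_ions = include_ions)$total_dg
  }
  start <- new_pose(torsion_angles = numeric(n_tor))
  res <- with_seed(seed, {
    scale <- list(t = bounds$max_translation / 3,
                  r = bounds$max_rotation / 3,
                  tor = if (n_tor) bounds$max_torsion / 3 else 1)
    descend(objective, start, n_tor, n_iter, step = scale, clamp = clamp)
  })
  list(pose = res$pose,
       score = score_pose(receptor, realize_pose(ligand, tree, res$pose),
                          tree, p, include_ions = include_ions))
}

#' Pose RMSD in the fixed receptor frame
#'
#' Root-mean-square deviation between two conformations of the same
#' molecule with identity atom mapping and no superposition, as used when
#' comparing a docked pose to a crystallographic one in the same frame.
#' Heavy atoms only by default.
#'
#' @param a,b `Structure`s or n x 3 coordinate matrices.
#' @param mapping optional 2-column index matrix pairing atoms of `a`
#'   with atoms of `b`; default identity.
#' @param heavy_only drop hydrogens (only when structures are given).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, mapping = NULL, heavy_only = TRUE) {
  get_xyz <- function(s, keep) {
    if (inherits(s, "Structure")) {
      m <- coords(s)
      if (heavy_only) m <- m[s$atoms$element != "H", , drop = FALSE]
      m
    } else as.matrix(s)
  }
  A <- get_xyz(a); B <- get_xyz(b)
  if (!is.null(mapping)) {
    mapping <- as.matrix(mapping)
    A <- A[mapping[, 1L], , drop = FALSE]
    B <- B[mapping[, 2L], , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) stop("mapped atom counts differ")
  if (nrow(A) < 1L) stop("pose RMSD needs at least one mapped atom")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Dock a ligand into a grid box by multi-start stochastic search
#'
#' Tier 3: `n_runs` random initial placements (uniform translation inside
#' the box, uniform orientation, uniform torsions), each followed by
#' accept-if-better local descent on [grid_score()].  Results are pooled,
#' clustered greedily by pose RMSD, and cluster-best poses are ranked by
#' total dG ascending.
#'
#' @param box a `GridBox`.
#' @param ligand reference `Structure`.
#' @param tree `TorsionTree` (or `NULL` for a rigid ligand).
#' @param p energy parameters (defaults to the box's).
#' @param n_runs number of restarts.
#' @param n_iter descent iterations per restart.
#' @param seed integer RNG seed; recorded in the result.
#' @param cluster_rmsd pooling tolerance, Angstrom (default 2.0).
#' @param n_modes maximum number of ranked binding modes returned.
#' @param max_placement_attempts bounded attempts to find an in-box start.
#' @return A `DockingResult`: ranked list of `modes` (each with `pose`,
#'   `score`, realized `structure`), the `settings` echo and the `seed`.
#' @export
dock <- function(box, ligand, tree = NULL, p = NULL,
                 n_runs = 20L, n_iter = 500L, seed = 1L,
                 cluster_rmsd = 2.0, n_modes = 10L,
                 max_placement_attempts = 200L) {
  stopifnot(inherits(box, "GridBox"))
  p <- p %||% box$params
  n_tor <- if (is.null(tree)) 0L else tree$n_tor
  half <- (box$npts - 1) / 2 * box$spacing
  ctr0 <- colMeans(coords(ligand))

  objective <- function(pose) {
    s <- tryCatch(
      grid_score(box, realize_pose(ligand, tree, pose), tree, p)$total_dg,
      error = function(e) Inf)  # out-of-box proposals are rejected
    s
  }
  random_start <- function() {
    for (attempt in seq_len(max_placement_attempts)) {
      target <- box$center + stats::runif(3, -half, half)
      pose <- new_pose(translation = target - ctr0,
                       orientation = quat_random(),
                       torsion_angles = if (n_tor)
                         stats::runif(n_tor, -180, 180) else numeric(0))
      if (is.finite(objective(pose))) return(pose)
    }
    stop(paste("could not place the ligand inside the grid box after",
               max_placement_attempts, "attempts"))
  }

  runs <- with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      start <- random_start()
      descend(objective, start, n_tor, n_iter,
              step = list(t = box$spacing * 4, r = 30,
                          tor = if (n_tor) 30 else 1))
    })
  })

  ord <- order(vapply(runs, `[[`, numeric(1), "score"))
  structures <- lapply(runs, function(r) realize_pose(ligand, tree, r$pose))
  leaders <- integer(0)
  for (i in ord) {
    if (!length(leaders)) { leaders <- i; next }
    d <- vapply(leaders, function(l)
      pose_rmsd(structures[[i]], structures[[l]]), numeric(1))
    if (all(d >= cluster_rmsd)) leaders <- c(leaders, i)
    if (length(leaders) >= n_modes) break
  }
  modes <- lapply(leaders, function(i) {
    list(pose = runs[[i]]$pose,
         score = score_breakdown_from_grid(box, ligand, tree, p,
                                           runs[[i]]$pose),
         structure = structures[[i]])
  })
  structure(list(modes = modes,
                 settings = list(n_runs = n_runs, n_iter = n_iter,
                                 cluster_rmsd = cluster_rmsd,
                                 n_modes = n_modes),
                 seed = seed),
            class = "DockingResult")
}

score_breakdown_from_grid <- function(box, ligand, tree, p, pose) {
  grid_score(box, realize_pose(ligand, tree, pose), tree, p)
}

#' @export
print.DockingResult <- function(x, ...) {
  cat(sprintf("DockingResult: %d binding mode(s) from %d restarts (seed %d)\n",
              length(x$modes), x$settings$n_runs, x$seed))
  for (i in seq_along(x$modes))
    cat(sprintf("  mode %d: dG = %.3f kcal/mol\n", i,
                x$modes[[i]]$score$total_dg))
  invisible(x)
}
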