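## Side-chain rotamer analysis: chi1-chi4 dihedral extraction over an
## ensemble, circular histograms with wraparound-aware peak detection,
## agglomerative clustering under a periodic dihedral RMSD metric, and
## matching of cluster centroids to reference (e.g. crystallographic)
## conformations.  Angles are reported in (-180, 180] degrees.

#' Built-in chi-angle atom quadruples
#'
#' Currently arginine (four chi angles); extendable via the `definitions`
#' argument of [extract_chi_series()].
#' @format list keyed by residue name; each element a list of atom-name
#'   quadruples.
#' @export
CHI_DEFINITIONS <- list(
  ARG = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "NE"),
             chi4 = c("CG", "CD", "NE", "CZ"))
)

#' Signed dihedral angle of four points
#'
#' Torsion about the p2-p3 axis by the standard atan2 construction
#' (IUPAC sign convention), returned in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 xyz coordinates (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(vnorm(b1), vnorm(b2), vnorm(b3)) < 1e-8)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (min(vnorm(n1), vnorm(n2)) < 1e-8)
    stop("degenerate geometry: three consecutive points are collinear")
  ang <- atan2(sum(cross3(n1, n2) * b2 / vnorm(b2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Extract a chi-dihedral time series for one residue
#'
#' @param traj an `EnsembleTrajectory`.
#' @param residue residue selector: `list(chain =, resno =)` or a string
#'   `"B:503"` / `"B:503:ARG"`.
#' @param definitions list of atom-name quadruples (default: the built-in
#'   table for the residue's name).
#' @param keep_coords also store each frame's side-chain atom coordinates
#'   (needed for Cartesian centroid-to-reference RMSD).
#' @return A `DihedralSeries`: `residue_id`, `chi` (frames x n_chi matrix,
#'   degrees), `frame_times` (ps), `atom_quadruples`, optional `coords`.
#' @export
extract_chi_series <- function(traj, residue, definitions = NULL,
                               keep_coords = FALSE) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  if (is.character(residue)) {
    parts <- strsplit(residue, ":", fixed = TRUE)[[1L]]
    residue <- list(chain = parts[1L], resno = as.integer(parts[2L]))
  }
  first <- traj$frames[[1L]]$atoms
  in_res <- first$chain == residue$chain & first$resno == residue$resno
  if (!any(in_res))
    stopf("residue %s:%d not found", residue$chain, residue$resno)
  resname <- first$resname[in_res][1L]
  defs <- definitions %||% CHI_DEFINITIONS[[resname]]
  if (is.null(defs))
    stopf("no chi definitions for residue type %s; supply `definitions`",
          resname)
  side_atoms <- unique(unlist(defs))
  n_chi <- length(defs)
  chi <- matrix(NA_real_, nrow = length(traj$frames), ncol = n_chi,
                dimnames = list(NULL, names(defs) %||%
                                  paste0("chi", seq_len(n_chi))))
  coords_list <- if (keep_coords) vector("list", length(traj$frames))
  for (f in seq_along(traj$frames)) {
    atoms <- traj$frames[[f]]$atoms
    sel <- atoms$chain == residue$chain & atoms$resno == residue$resno
    res_atoms <- atoms[sel, , drop = FALSE]
    pos <- function(name) {
      i <- which(res_atoms$name == name)
      if (!length(i))
        stopf("atom %s missing from residue %s:%d in frame %d", name,
              residue$chain, residue$resno, f)
      c(res_atoms$x[i[1L]], res_atoms$y[i[1L]], res_atoms$z[i[1L]])
    }
    for (k in seq_len(n_chi)) {
      q <- defs[[k]]
      chi[f, k] <- dihedral(pos(q[1L]), pos(q[2L]), pos(q[3L]), pos(q[4L]))
    }
    if (keep_coords) {
      m <- t(vapply(side_atoms, pos, numeric(3)))
      coords_list[[f]] <- m
    }
  }
  structure(list(residue_id = list(chain = residue$chain,
                                   number = residue$resno, name = resname),
                 chi = chi, frame_times = traj$times,
                 atom_quadruples = defs,
                 coords = coords_list),
            class = "DihedralSeries")
}

#' @export
print.DihedralSeries <- function(x, ...) {
  cat(sprintf("DihedralSeries: %s %s%d, %d frames x %d chi angles\n",
              x$residue_id$name, x$residue_id$chain, x$residue_id$number,
              nrow(x$chi), ncol(x$chi)))
  invisible(x)
}

#' Circular histogram of an angle series with peak detection
#'
#' Bins on `(-180, 180]` with wraparound adjacency; the density integrates
#' to 1 over the full 360 degrees.  Peaks are runs of locally maximal bins
#' (strictly above both circular neighbours, plateaus merged across the
#' +-180 seam) whose density reaches `peak_frac` of the global maximum.
#'
#' @param angles degrees (any real values; wrapped internally).
#' @param bin_width degrees; must divide 360.
#' @param peak_frac minimum peak height as a fraction of the maximum
#'   density (default 0.25).
#' @return list with `bin_centers`, `densities` and `peaks` (data frame
#'   of peak centers and densities), class `AngularHistogram`.
#' @export
angular_histogram <- function(angles, bin_width = 10, peak_frac = 0.25) {
  if (!length(angles)) stop("empty angle series")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("bin width must divide 360 degrees")
  a <- wrap_angle(as.numeric(angles))
  n_bins <- as.integer(round(360 / bin_width))
  # bins (-180 + (k-1) w, -180 + k w]
  idx <- pmin(pmax(ceiling((a + 180) / bin_width - 1e-9), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  densities <- counts / (length(a) * bin_width)
  centers <- -180 + (seq_len(n_bins) - 0.5) * bin_width

  # wraparound-aware peak detection: group circular runs of equal density
  # (plateaus, so a mode straddling the +-180 seam counts once), then keep
  # runs strictly above both neighbouring runs and above the threshold
  thr <- peak_frac * max(densities)
  eps <- 1e-12
  visited <- logical(n_bins)
  peak_center <- peak_density <- numeric(0)
  for (b in seq_len(n_bins)) {
    if (visited[b]) next
    run <- b
    repeat {
      nxt <- run[length(run)] %% n_bins + 1L
      if (nxt %in% run || abs(densities[nxt] - densities[b]) >= eps) break
      run <- c(run, nxt)
    }
    repeat {
      prv <- (run[1L] - 2L) %% n_bins + 1L
      if (prv %in% run || abs(densities[prv] - densities[b]) >= eps) break
      run <- c(prv, run)
    }
    visited[run] <- TRUE
    if (length(run) == n_bins) next  # flat distribution: no peak
    left <- (run[1L] - 2L) %% n_bins + 1L
    right <- run[length(run)] %% n_bins + 1L
    if (densities[b] > densities[left] + eps &&
        densities[b] > densities[right] + eps && densities[b] >= thr) {
      th <- centers[run] * pi / 180
      peak_center <- c(peak_center,
                       wrap_angle(atan2(mean(sin(th)), mean(cos(th))) *
                                    180 / pi))
      peak_density <- c(peak_density, densities[b])
    }
  }
  peak_df <- data.frame(center = peak_center, density = peak_density)
  structure(list(bin_centers = centers, densities = densities,
                 peaks = peak_df, bin_width = bin_width),
            class = "AngularHistogram")
}

#' Plot a circular angle histogram
#' @param x an `AngularHistogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.AngularHistogram <- function(x, ...) {
  graphics::plot(x$bin_centers, x$densities, type = "h", lwd = 3,
                 xlab = "dihedral (degrees)", ylab = "density",
                 xlim = c(-180, 180), ...)
  if (nrow(x$peaks)) graphics::points(x$peaks$center, x$peaks$density,
                                      pch = 17)
  invisible(x)
}

#' Periodic dihedral RMSD between two chi tuples
#'
#' `sqrt(mean(d^2))` where each component difference `d` is the shortest
#' arc `min(|delta|, 360 - |delta|)`.  A proper metric on the torus.
#'
#' @param chi_a,chi_b equal-length angle tuples, degrees.
#' @return RMSD in degrees.
#' @export
dihedral_rmsd <- function(chi_a, chi_b) {
  if (length(chi_a) != length(chi_b))
    stop("chi tuples have different lengths")
  d <- angle_diff(chi_a, chi_b)
  sqrt(mean(d * d))
}

# full pairwise periodic dihedral RMSD matrix for an n x k chi matrix
dihedral_rmsd_matrix <- function(chi) {
  n <- nrow(chi); k <- ncol(chi)
  acc <- matrix(0, n, n)
  for (c in seq_len(k)) {
    d <- outer(chi[, c], chi[, c], angle_diff)
    acc <- acc + d * d
  }
  sqrt(acc / k)
}

#' Cluster rotamer frames from one or more dihedral series
#'
#' Frames from all input series are pooled (joint clustering across
#' simulations), then grouped by average-linkage agglomerative clustering
#' under the periodic [dihedral_rmsd()] metric, cut at `cutoff` degrees.
#' Each cluster's centroid is its medoid frame (the member minimizing the
#' summed distance to co-members); clusters are numbered by decreasing
#' population.
#'
#' @param series_list a `DihedralSeries` or list of them (all sharing the
#'   same chi arity).
#' @param cutoff linkage cut height, degrees (`> 0`, default 40).
#' @return A `RotamerClustering`: `assignments` (pooled frame -> cluster),
#'   `centroids` (per cluster: pooled frame index, source series/frame,
#'   chi tuple), `populations`, `linkage_cutoff`, `source` bookkeeping.
#' @export
cluster_rotamers <- function(series_list, cutoff = 40) {
  if (cutoff <= 0) stop("cluster cutoff must be positive")
  if (inherits(series_list, "DihedralSeries")) series_list <- list(series_list)
  arity <- unique(vapply(series_list, function(s) ncol(s$chi), integer(1)))
  if (length(arity) != 1L)
    stop("all series must share the same number of chi angles")
  chi <- do.call(rbind, lapply(series_list, `[[`, "chi"))
  src_series <- rep(seq_along(series_list),
                    vapply(series_list, function(s) nrow(s$chi), integer(1)))
  src_frame <- unlist(lapply(series_list,
                             function(s) seq_len(nrow(s$chi))))
  n <- nrow(chi)
  if (n < 1L) stop("no frames to cluster")
  if (n == 1L) {
    assignments <- 1L
  } else {
    D <- dihedral_rmsd_matrix(chi)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    assignments <- stats::cutree(hc, h = cutoff)
  }
  sizes <- table(assignments)
  # renumber by decreasing population (ties: first-seen order)
  new_id <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                            names(sizes))
  assignments <- as.integer(new_id[as.character(assignments)])
  k <- max(assignments)
  centroids <- vector("list", k)
  populations <- numeric(k)
  for (c in seq_len(k)) {
    members <- which(assignments == c)
    populations[c] <- length(members) / n
    medoid <- if (length(members) == 1L) members else {
      sub <- dihedral_rmsd_matrix(chi[members, , drop = FALSE])
      members[which.min(rowSums(sub))]
    }
    centroids[[c]] <- list(frame = medoid,
                           series = src_series[medoid],
                           series_frame = src_frame[medoid],
                           chi = chi[medoid, ])
  }
  structure(list(assignments = assignments, centroids = centroids,
                 populations = populations, linkage_cutoff = cutoff,
                 chi = chi,
                 source = data.frame(series = src_series,
                                     frame = src_frame)),
            class = "RotamerClustering")
}

#' @export
print.RotamerClustering <- function(x, ...) {
  cat(sprintf("RotamerClustering: %d cluster(s) from %d frames (cutoff %g deg)\n",
              length(x$centroids), length(x$assignments), x$linkage_cutoff))
  for (c in seq_along(x$centroids))
    cat(sprintf("  cluster %d: %.1f%%, centroid chi = (%s)\n", c,
                100 * x$populations[c],
                paste(sprintf("%.0f", x$centroids[[c]]$chi), collapse = ", ")))
  invisible(x)
}

#' Match cluster centroids to reference conformations
#'
#' Pairs each cluster centroid with its nearest reference under the
#' periodic dihedral RMSD; when both the reference and the centroid carry
#' side-chain coordinates sharing atom names, the Cartesian heavy-atom
#' RMSD is reported as well.
#'
#' @param clustering a `RotamerClustering`.
#' @param references named list; each element a list with `chi` (angle
#'   tuple) and optionally `coords` (named atom coordinate matrix).
#' @param series_list the series used for clustering, if centroid
#'   coordinates are wanted (series must have been extracted with
#'   `keep_coords = TRUE`).
#' @return data frame: cluster, population, best reference name, dihedral
#'   RMSD (deg), Cartesian RMSD (A, `NA` when not computable).
#' @export
match_to_reference <- function(clustering, references, series_list = NULL) {
  stopifnot(inherits(clustering, "RotamerClustering"))
  if (!length(references)) stop("reference list is empty")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  if (!is.null(series_list) && inherits(series_list, "DihedralSeries"))
    series_list <- list(series_list)
  rows <- lapply(seq_along(clustering$centroids), function(c) {
    cen <- clustering$centroids[[c]]
    drmsd <- vapply(references, function(r) dihedral_rmsd(cen$chi, r$chi),
                    numeric(1))
    best <- which.min(drmsd)
    cart <- NA_real_
    ref <- references[[best]]
    if (!is.null(ref$coords) && !is.null(series_list)) {
      cen_coords <- series_list[[cen$series]]$coords[[cen$series_frame]]
      if (!is.null(cen_coords)) {
        shared <- intersect(rownames(ref$coords), rownames(cen_coords))
        if (length(shared)) {
          cart <- pose_rmsd(cen_coords[shared, , drop = FALSE],
                            ref$coords[shared, , drop = FALSE])
        } else {
          warnf("cluster %d: no shared atoms with reference %s; %s", c,
                names(references)[best],
                "falling back to the dihedral metric")
        }
      }
    }
    data.frame(cluster = c, population = clustering$populations[c],
               reference = names(references)[best],
               dihedral_rmsd_deg = drmsd[best],
               cartesian_rmsd_A = cart)
  })
  do.call(rbind, rows)
}
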