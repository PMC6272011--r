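## Free-energy spectra: rescore every snapshot of a conformational
## ensemble and histogram the resulting binding free energies into a
## probability density.  The mode of that density ("most probable dG") is
## the representative binding free energy of the ensemble; its Boltzmann
## conversion gives the inhibition constant.  The minimum sampled dG
## (the left-hand tail) marks the highest-affinity conformations visited.

#' Select snapshots on a regular time lattice
#'
#' Keeps frames with `t_start < t <= t_end` that lie on the sampling
#' lattice anchored at the window end, so the final frame of a trailing
#' window (e.g. "every 100 ps over the last 9 ns") is always included.
#' The selected count is `floor((t_end - t_start) / interval_ps)` for a
#' trajectory saved at (a divisor of) the sampling interval.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param interval_ps sampling interval, ps (`> 0`).
#' @param window numeric `(t_start, t_end]` in ps, within the trajectory
#'   span.
#' @return the sub-`EnsembleTrajectory` of selected frames.
#' @export
sample_snapshots <- function(traj, interval_ps, window) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  if (interval_ps <= 0) stop("sampling interval must be positive")
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("window must be (t_start, t_end) with t_end > t_start")
  if (interval_ps > window[2L] - window[1L])
    stop("sampling interval exceeds the window span")
  t <- traj$times
  tol <- interval_ps * 1e-6
  on_lattice <- abs((window[2L] - t) / interval_ps -
                      round((window[2L] - t) / interval_ps)) * interval_ps < tol
  keep <- which(t > window[1L] + tol & t <= window[2L] + tol & on_lattice)
  if (!length(keep))
    stop("no snapshots fall in the requested window/interval lattice")
  new_ensemble(traj$frames[keep], t[keep],
               topology_constant = traj$topology_constant)
}

#' Rescore every frame of an ensemble
#'
#' Splits each frame into receptor and ligand parts by role label (or by
#' the supplied index selections, which must resolve identically in every
#' frame) and applies [score_pose()] per frame, preserving order.
#'
#' @param traj an `EnsembleTrajectory` whose frames contain both the
#'   receptor and the ligand.
#' @param p an `EnergyParameters` object.
#' @param tree optional `TorsionTree` for the torsional penalty.
#' @param receptor_idx,ligand_idx optional atom-index selections; default
#'   role labels `"receptor"` (+ ions if `include_ions`) and `"ligand"`.
#' @param include_ions include ion-role atoms on the receptor side?
#' @return list of `ScoreBreakdown`, one per frame.
#' @export
rescore_ensemble <- function(traj, p = default_energy_parameters(),
                             tree = NULL, receptor_idx = NULL,
                             ligand_idx = NULL, include_ions = FALSE) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  if (!length(traj$frames)) stop("empty frame list")
  resolve <- function(frame) {
    ri <- receptor_idx %||% select_role_atoms(frame,
                                              c("receptor",
                                                if (include_ions) "ion"))
    li <- ligand_idx %||% select_role_atoms(frame, "ligand")
    list(ri = ri, li = li)
  }
  sel0 <- resolve(traj$frames[[1L]])
  key0 <- traj$frames[[1L]]$atoms$name[c(sel0$ri, sel0$li)]
  lapply(seq_along(traj$frames), function(i) {
    frame <- traj$frames[[i]]
    sel <- resolve(frame)
    if (length(sel$ri) != length(sel0$ri) ||
        length(sel$li) != length(sel0$li) ||
        !identical(frame$atoms$name[c(sel$ri, sel$li)], key0))
      stopf("selection resolves differently in frame %d", i)
    rec <- new_structure(frame$atoms[sel$ri, , drop = FALSE])
    lig <- new_structure(frame$atoms[sel$li, , drop = FALSE])
    score_pose(rec, lig, tree, p, include_ions = include_ions)
  })
}

#' Build a free-energy spectrum from sampled binding free energies
#'
#' Histogram density over dG on a fixed lattice anchored at 0 -- bin
#' centers sit at integer multiples of `bin_width` (bin k covers
#' `(k*w - w/2, k*w + w/2]`) so spectra of different ligands share a
#' grid.  The density integrates to 1; the most probable dG is the
#' center of the maximal-density bin (ties resolved toward the more
#' negative bin) and `best_dg` is the sampled minimum.
#'
#' @param scores binding free energies, kcal/mol (non-finite values are
#'   dropped with a warning reporting the count).
#' @param bin_width histogram bin width, kcal/mol (`> 0`, default 0.5).
#' @return A `FreeEnergySpectrum` with `bin_edges`, `densities`,
#'   `sample_scores`, `most_probable_dg`, `best_dg`, `n_samples`.
#' @export
build_spectrum <- function(scores, bin_width = 0.5) {
  if (bin_width <= 0) stop("bin width must be positive")
  scores <- as.numeric(scores)
  bad <- !is.finite(scores)
  if (any(bad)) {
    warnf("dropping %d non-finite score(s)", sum(bad))
    scores <- scores[!bad]
  }
  if (!length(scores)) stop("no finite scores to histogram")
  # bin index k: right-closed bin (k*w - w/2, k*w + w/2] centered on k*w
  k <- ceiling(scores / bin_width - 0.5 - 1e-9)
  kr <- min(k):max(k)
  edges <- (c(kr, max(kr) + 1L) - 0.5) * bin_width
  counts <- tabulate(k - min(k) + 1L, nbins = length(kr))
  densities <- counts / (length(scores) * bin_width)
  mode_bin <- which.max(densities)  # first max = more negative on ties
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  structure(list(bin_edges = edges, densities = densities,
                 sample_scores = scores,
                 most_probable_dg = centers[mode_bin],
                 best_dg = min(scores),
                 n_samples = length(scores),
                 bin_width = bin_width),
            class = "FreeEnergySpectrum")
}

#' @export
print.FreeEnergySpectrum <- function(x, ...) {
  cat(sprintf(paste0("FreeEnergySpectrum: n = %d, bin width %.2f kcal/mol, ",
                     "mode %.2f, best %.2f kcal/mol\n"),
              x$n_samples, x$bin_width, x$most_probable_dg, x$best_dg))
  invisible(x)
}

#' Summarize a free-energy spectrum
#'
#' Reports the most probable dG, the best (minimum) sampled dG, the
#' inhibition constant at the mode, and a plot-ready table of bin centers
#' and densities.
#'
#' @param spectrum a `FreeEnergySpectrum`.
#' @param T temperature in K for the Ki conversion.
#' @return list with `most_probable_dg`, `best_dg`, `ki_molar`,
#'   `n_samples` and `table` (`bin_center`, `density`).
#' @export
spectrum_report <- function(spectrum, T = 298.15) {
  stopifnot(inherits(spectrum, "FreeEnergySpectrum"))
  centers <- (spectrum$bin_edges[-length(spectrum$bin_edges)] +
                spectrum$bin_edges[-1L]) / 2
  list(most_probable_dg = spectrum$most_probable_dg,
       best_dg = spectrum$best_dg,
       ki_molar = delta_g_to_ki(spectrum$most_probable_dg, T = T),
       n_samples = spectrum$n_samples,
       table = data.frame(bin_center = centers,
                          density = spectrum$densities))
}

#' Plot a free-energy spectrum
#' @param x a `FreeEnergySpectrum`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.FreeEnergySpectrum <- function(x, ...) {
  centers <- (x$bin_edges[-length(x$bin_edges)] + x$bin_edges[-1L]) / 2
  graphics::plot(centers, x$densities, type = "h", lwd = 3,
                 xlab = expression(Delta * G ~ "(kcal/mol)"),
                 ylab = "probability density", ...)
  graphics::abline(v = x$most_probable_dg, lty = 2)
  invisible(x)
}
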