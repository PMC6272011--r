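## End-to-end orchestration: dock -> pick binding modes -> build an
## ensemble -> free-energy spectrum -> rotamer report -> interaction
## analysis, from a single validated configuration, with a
## machine-readable run manifest echoing every parameter and seed.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    stages = list(dock = TRUE, ensemble = TRUE, spectrum = TRUE,
                  rotamer = TRUE, interactions = TRUE),
    complex = list(source = "synthetic", receptor = NULL, ligand = NULL,
                   dialect = "pdbq_charged", spec = NULL),
    dock = list(spacing = 0.375, npts = c(21L, 21L, 21L), n_runs = 10L,
                n_iter = 300L, n_modes = 3L, cluster_rmsd = 2.0),
    ensemble = list(n_frames = 200L, noise_sd = 0.05, dt_ps = 100,
                    two_state_prob = NULL),
    spectrum = list(bin_width = 0.5, interval_ps = NULL, window = NULL),
    rotamer = list(mixture = NULL, n_frames = 300L, cutoff = 40,
                   bin_width = 10, residue = "B:503"),
    interactions = list(max_da_distance = 3.5, min_dha_angle = 120,
                        contact_cutoff = 3.9)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stopf("unknown configuration key: %s", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys are rejected
#' with their full path, and referenced input files must exist.
#'
#' @param config YAML path or list (may be partial; defaults fill gaps).
#' @return the validated, fully populated configuration list.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is_count(abs(cfg$seed) + 1)) stop("seed must be an integer")
  if (cfg$complex$source == "files") {
    for (f in c(cfg$complex$receptor, cfg$complex$ligand))
      if (is.null(f) || !file.exists(f))
        stopf("complex input file missing or not found: %s",
              f %||% "(unset)")
  } else if (cfg$complex$source != "synthetic") {
    stop("complex.source must be 'synthetic' or 'files'")
  }
  cfg
}

#' Run the evaluation pipeline end to end
#'
#' Executes the enabled stages in dependency order: build or load the
#' receptor/ligand complex, dock into a grid box, generate (or reuse) a
#' conformational ensemble around the best mode, rescore it into a
#' free-energy spectrum, analyze side-chain rotamer populations, and
#' profile ligand-receptor interactions.  All stage parameters and the
#' seed are echoed in the returned manifest, which is also written as
#' JSON when `output_dir` is set.  A stage failure halts the run with the
#' partial manifest attached to the error.
#'
#' @param config YAML path or nested list, see [validate_run_config()].
#' @return the run manifest (list): per-stage status, parameters, output
#'   paths and headline numbers.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  p <- default_energy_parameters()
  manifest <- list(config = cfg, stages = list(), headline = list())
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  finish <- function() {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
      manifest$manifest_path <- path
    }
    manifest
  }

  ## stage: complex
  if (cfg$complex$source == "synthetic") {
    spec <- do.call(toy_complex_spec, cfg$complex$spec %||% list())
    toy <- make_toy_complex(spec, seed = cfg$seed, certify = FALSE, p = p)
    receptor <- toy$receptor; ligand <- toy$ligand; tree <- toy$tree
  } else {
    receptor <- read_structure(cfg$complex$receptor, cfg$complex$dialect)
    ligand <- read_structure(cfg$complex$ligand, cfg$complex$dialect)
    tree <- build_torsion_tree(ligand)
  }
  manifest$stages$complex <- list(status = "ok",
                                  n_receptor_atoms = nrow(receptor$atoms),
                                  n_ligand_atoms = nrow(ligand$atoms),
                                  n_tor = tree$n_tor)

  best_ligand <- ligand
  alt_ligand <- NULL

  ## stage: dock
  if (isTRUE(cfg$stages$dock)) {
    box <- make_grid_box(receptor, spacing = cfg$dock$spacing,
                         npts = cfg$dock$npts,
                         ligand_types = unique(ligand$atoms$atom_type),
                         p = p)
    res <- dock(box, ligand, tree, p, n_runs = cfg$dock$n_runs,
                n_iter = cfg$dock$n_iter, seed = cfg$seed,
                cluster_rmsd = cfg$dock$cluster_rmsd,
                n_modes = cfg$dock$n_modes)
    best_ligand <- res$modes[[1L]]$structure
    if (length(res$modes) > 1L) alt_ligand <- res$modes[[2L]]$structure
    manifest$stages$dock <- list(
      status = "ok", n_modes = length(res$modes),
      dg = vapply(res$modes, function(m) m$score$total_dg, numeric(1)))
    manifest$headline$docking_dg <- res$modes[[1L]]$score$total_dg
    if (!is.null(out_dir))
      write_ensemble(new_ensemble(lapply(res$modes, `[[`, "structure"),
                                  times = seq_along(res$modes)),
                     file.path(out_dir, "docked_modes.pdbq"),
                     dialect = "pdbq_charged")
  }

  ## stage: ensemble + spectrum
  traj <- NULL
  if (isTRUE(cfg$stages$ensemble)) {
    two_state <- NULL
    if (!is.null(cfg$ensemble$two_state_prob)) {
      alt <- alt_ligand %||%
        set_coords(best_ligand, sweep(coords(best_ligand), 2L,
                                      c(-2, 0, 0)))
      two_state <- list(ligand_b = alt, prob = cfg$ensemble$two_state_prob)
    }
    traj <- make_ensemble(receptor, best_ligand,
                          n_frames = cfg$ensemble$n_frames,
                          noise_sd = cfg$ensemble$noise_sd,
                          two_state = two_state,
                          seed = cfg$seed + 1L, dt_ps = cfg$ensemble$dt_ps)
    manifest$stages$ensemble <- list(status = "ok",
                                     n_frames = length(traj$frames))
  }
  if (isTRUE(cfg$stages$spectrum)) {
    if (is.null(traj)) stop("spectrum stage requires the ensemble stage")
    sub <- traj
    if (!is.null(cfg$spectrum$interval_ps) && !is.null(cfg$spectrum$window))
      sub <- sample_snapshots(traj, cfg$spectrum$interval_ps,
                              cfg$spectrum$window)
    scores <- vapply(rescore_ensemble(sub, p, tree), `[[`, numeric(1),
                     "total_dg")
    spec <- build_spectrum(scores, bin_width = cfg$spectrum$bin_width)
    rep <- spectrum_report(spec, T = p$T)
    manifest$stages$spectrum <- list(status = "ok",
                                     n_samples = spec$n_samples)
    manifest$headline$most_probable_dg <- rep$most_probable_dg
    manifest$headline$best_dg <- rep$best_dg
    manifest$headline$ki_molar <- rep$ki_molar
    if (!is.null(out_dir))
      utils::write.table(rep$table, file.path(out_dir, "spectrum.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  ## stage: rotamer analysis (synthetic mixture or supplied ensemble)
  if (isTRUE(cfg$stages$rotamer)) {
    mix <- cfg$rotamer$mixture %||% list(
      list(mean = c(-70, 180, 65, 90), kappa = 50, weight = 0.6),
      list(mean = c(-170, 65, -85, 180), kappa = 50, weight = 0.4))
    rot <- make_rotamer_trajectory(mix, n_frames = cfg$rotamer$n_frames,
                                   seed = cfg$seed + 2L)
    clustering <- cluster_rotamers(rot$series,
                                   cutoff = cfg$rotamer$cutoff)
    manifest$stages$rotamer <- list(
      status = "ok", n_clusters = length(clustering$centroids),
      populations = clustering$populations)
    manifest$headline$rotamer_clusters <- length(clustering$centroids)
  }

  ## stage: interactions on the representative pose
  if (isTRUE(cfg$stages$interactions)) {
    combined_atoms <- rbind(receptor$atoms, best_ligand$atoms)
    combined_atoms$serial <- seq_len(nrow(combined_atoms))
    rep_ia <- interaction_report(new_structure(combined_atoms),
                                 cfg$interactions$max_da_distance,
                                 cfg$interactions$min_dha_angle,
                                 cfg$interactions$contact_cutoff, p)
    manifest$stages$interactions <- list(status = "ok",
                                         n_hbonds = nrow(rep_ia$hbonds),
                                         n_contacts = nrow(rep_ia$contacts))
  }

  finish()
}
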