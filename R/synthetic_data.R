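## Synthetic fixtures for every pipeline stage: toy spherical pockets with
## a certified score optimum, noisy (optionally two-state) conformational
## ensembles with a controlled rescored-dG distribution, side-chain
## dihedral trajectories drawn from peaked circular (von Mises) mixtures,
## and Gaussian-mixture dG samples.  Every generator is a pure function of
## (spec, seed).  These are statistical stand-ins: they make no attempt to
## imitate real enzyme/DNA geometry or force-field realism.

#' Default toy-complex specification
#'
#' A spherical shell of receptor atoms ("pocket") with a small zig-zag
#' chain ligand at the cavity center.  The default 6 A shell leaves the
#' 4-atom chain in the attractive well of the 12-6 term.  For
#' dock-recovery checks use `n_ligand_atoms = 1, cavity_radius = 4`: with
#' the shell at the C-C pair equilibrium distance the cavity center is
#' the unique energy minimum of a single probe atom, so the certified
#' optimum is unambiguous.
#'
#' @param n_pocket_atoms atoms on the shell.
#' @param cavity_radius shell radius, Angstrom.
#' @param pocket_types,pocket_charges recycled over shell atoms.
#' @param n_ligand_atoms chain length (1 = single probe atom).
#' @param ligand_types,ligand_charges recycled over ligand atoms.
#' @param bond_length,bond_angle ligand chain geometry (A, degrees).
#' @return list spec consumed by [make_toy_complex()].
#' @export
toy_complex_spec <- function(n_pocket_atoms = 48L, cavity_radius = 6,
                             pocket_types = c("C", "OA"),
                             pocket_charges = c(0.1, -0.1),
                             n_ligand_atoms = 4L,
                             ligand_types = "C",
                             ligand_charges = 0,
                             bond_length = 1.5, bond_angle = 109.5) {
  list(n_pocket_atoms = as.integer(n_pocket_atoms),
       cavity_radius = cavity_radius,
       pocket_types = pocket_types, pocket_charges = pocket_charges,
       n_ligand_atoms = as.integer(n_ligand_atoms),
       ligand_types = ligand_types, ligand_charges = ligand_charges,
       bond_length = bond_length, bond_angle = bond_angle)
}

atom_table <- function(serial, name, element, atom_type, resname, resno,
                       chain, xyz, charge, record, role) {
  data.frame(serial = as.integer(serial), name = name, element = element,
             atom_type = atom_type, resname = resname,
             resno = as.integer(resno), chain = chain,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             charge = charge, occupancy = 1, alt_loc = "",
             record = record, role = role, stringsAsFactors = FALSE)
}

# deterministic near-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

zigzag_chain <- function(n, bond_length, bond_angle) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  half <- (180 - bond_angle) / 2 * pi / 180
  dx <- bond_length * cos(half); dy <- bond_length * sin(half)
  xyz <- cbind((seq_len(n) - 1) * dx, rep(c(0, dy), length.out = n), 0)
  sweep(xyz, 2L, colMeans(xyz))  # center on the origin
}

#' Generate a toy pocket-plus-ligand complex with a certified optimum
#'
#' Pocket atoms sit on a spherical shell around the origin; the ligand is
#' a zig-zag chain at the cavity center.  The returned "known optimum" is
#' the rigid translation (input orientation, zero torsions) certified by
#' an exhaustive translation scan on a 0.25 A lattice within +-2 A of the
#' start.
#'
#' @param spec a [toy_complex_spec()].
#' @param seed integer seed (reserved for randomized variants; geometry
#'   construction itself is deterministic).
#' @param certify run the certification scan? (skippable when only the
#'   structures are needed).
#' @param scan_step,scan_range certification lattice (A).
#' @param p energy parameters used for certification.
#' @return list with `receptor`, `ligand` (Structures), `tree`
#'   (TorsionTree), and `optimum` (list: `pose`, `coords`, `total_dg`)
#'   when certified.
#' @export
make_toy_complex <- function(spec = toy_complex_spec(), seed = 1L,
                             certify = TRUE, scan_step = 0.25,
                             scan_range = 2,
                             p = default_energy_parameters()) {
  lig_span <- (spec$n_ligand_atoms - 1) * spec$bond_length
  if (lig_span / 2 >= spec$cavity_radius)
    stop("infeasible spec: ligand is larger than the cavity")
  shell <- fibonacci_sphere(spec$n_pocket_atoms) * spec$cavity_radius
  ptypes <- rep_len(spec$pocket_types, spec$n_pocket_atoms)
  pq <- rep_len(spec$pocket_charges, spec$n_pocket_atoms)
  receptor <- new_structure(atom_table(
    seq_len(spec$n_pocket_atoms),
    name = paste0(ptypes, seq_len(spec$n_pocket_atoms)),
    element = infer_element(ptypes, ptypes),
    atom_type = ptypes, resname = "PKT", resno = seq_len(spec$n_pocket_atoms),
    chain = "A", xyz = shell, charge = pq, record = "ATOM",
    role = "receptor"), metadata = list(generator = "make_toy_complex"))

  lxyz <- zigzag_chain(spec$n_ligand_atoms, spec$bond_length,
                       spec$bond_angle)
  ltypes <- rep_len(spec$ligand_types, spec$n_ligand_atoms)
  lq <- rep_len(spec$ligand_charges, spec$n_ligand_atoms)
  ligand <- new_structure(atom_table(
    seq_len(spec$n_ligand_atoms),
    name = paste0(ltypes, seq_len(spec$n_ligand_atoms)),
    element = infer_element(ltypes, ltypes),
    atom_type = ltypes, resname = "LIG", resno = 1L, chain = "L",
    xyz = lxyz, charge = lq, record = "HETATM", role = "ligand"),
    metadata = list(generator = "make_toy_complex"))
  tree <- build_torsion_tree(ligand)

  optimum <- NULL
  if (certify) {
    offsets <- seq(-scan_range, scan_range, by = scan_step)
    best <- list(dg = Inf, t = c(0, 0, 0))
    for (ox in offsets) for (oy in offsets) for (oz in offsets) {
      t <- c(ox, oy, oz)
      s <- score_pose(receptor, set_coords(ligand, sweep(lxyz, 2L, -t)),
                      tree, p)
      if (s$total_dg < best$dg) best <- list(dg = s$total_dg, t = t)
    }
    pose <- new_pose(translation = best$t,
                     torsion_angles = numeric(tree$n_tor))
    optimum <- list(pose = pose,
                    coords = coords(realize_pose(ligand, tree, pose)),
                    total_dg = best$dg)
  }
  list(receptor = receptor, ligand = ligand, tree = tree, optimum = optimum,
       spec = spec)
}

#' Generate a noisy (optionally two-state) conformational ensemble
#'
#' Each frame is the base complex with isotropic Gaussian coordinate noise
#' per atom.  Under `two_state`, each frame independently adopts the
#' alternative ligand pose with probability `prob`, producing a bimodal
#' rescored-dG distribution whose modes sit at the two poses' noise-free
#' scores.
#'
#' @param receptor,ligand base `Structure`s.
#' @param n_frames number of frames (`>= 1`).
#' @param noise_sd per-coordinate noise, Angstrom (`>= 0`).
#' @param two_state `NULL`, or `list(ligand_b = <Structure or n x 3
#'   coords>, prob = <switch probability>)`.
#' @param seed integer seed.
#' @param dt_ps frame spacing in ps (times are `dt_ps * 1:n_frames`).
#' @return an `EnsembleTrajectory` of combined receptor+ligand frames;
#'   attribute `"states"` records each frame's pose (1 = base, 2 = alt).
#' @export
make_ensemble <- function(receptor, ligand, n_frames, noise_sd = 0.1,
                          two_state = NULL, seed = 1L, dt_ps = 100) {
  if (!is_count(n_frames)) stop("n_frames must be a positive integer")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  lig_b <- NULL
  if (!is.null(two_state)) {
    if (is.null(two_state$ligand_b) || is.null(two_state$prob))
      stop("two_state needs elements `ligand_b` and `prob`")
    lig_b <- if (inherits(two_state$ligand_b, "Structure"))
      coords(two_state$ligand_b) else as.matrix(two_state$ligand_b)
  }
  base_atoms <- rbind(receptor$atoms, ligand$atoms)
  base_atoms$serial <- seq_len(nrow(base_atoms))
  n_rec <- nrow(receptor$atoms)
  lig_rows <- n_rec + seq_len(nrow(ligand$atoms))
  base_xyz <- as.matrix(base_atoms[, c("x", "y", "z")])

  with_seed(seed, {
    states <- if (is.null(lig_b)) rep(1L, n_frames) else
      1L + stats::rbinom(n_frames, 1L, two_state$prob)
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz <- base_xyz
      if (states[f] == 2L) xyz[lig_rows, ] <- lig_b
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                          ncol = 3L)
      atoms <- base_atoms
      atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
      new_structure(atoms, metadata = list(frame = f, state = states[f]))
    })
    traj <- new_ensemble(frames, times = dt_ps * seq_len(n_frames))
    attr(traj, "states") <- states
    traj
  })
}

## von Mises sampling (Best & Fisher 1979 rejection algorithm)
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("concentration must be non-negative")
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      theta <- sign(u[3L] - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[i] <- theta * 180 / pi
      i <- i + 1L
    }
  }
  wrap_angle(mu_deg + out)
}

validate_mixture <- function(mixture, fields) {
  if (!length(mixture)) stop("mixture must have at least one component")
  w <- vapply(mixture, function(m) m$weight %||% NA_real_, numeric(1))
  if (anyNA(w) || abs(sum(w) - 1) > 1e-6)
    stop("mixture component weights must be given and sum to 1")
  for (f in fields)
    if (any(vapply(mixture, function(m) is.null(m[[f]]), logical(1))))
      stopf("every mixture component needs a `%s`", f)
  w
}

# ideal side-chain internal geometry used to realize chi tuples
place_atom <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180; dih <- dihedral_deg * pi / 180
  bc <- (C - B) / vnorm(C - B)
  n <- cross3(B - A, bc); n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  C + bc * d[1L] + m * d[2L] + n * d[3L]
}

arg_sidechain_coords <- function(chi) {
  # fixed backbone stub: N, CA, CB; chain CB-CG-CD-NE-CZ set by chi1..chi4
  atoms <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0))
  atoms$CB <- place_atom(c(0, 1, 0), atoms$N, atoms$CA, 1.52, 110, 150)
  geom <- list(c("N", "CA", "CB", "CG", 1.52, 114),
               c("CA", "CB", "CG", "CD", 1.52, 111),
               c("CB", "CG", "CD", "NE", 1.47, 112),
               c("CG", "CD", "NE", "CZ", 1.33, 124))
  for (k in seq_along(geom)) {
    g <- geom[[k]]
    atoms[[g[4L]]] <- place_atom(atoms[[g[1L]]], atoms[[g[2L]]],
                                 atoms[[g[3L]]], as.numeric(g[5L]),
                                 as.numeric(g[6L]), chi[k])
  }
  do.call(rbind, atoms)
}

#' Generate a rotamer trajectory from a circular mixture
#'
#' Per frame, a mixture component is chosen by weight and each chi angle
#' is drawn from a von Mises distribution around that component's mean.
#' The angles are realized as Cartesian coordinates of an ideal
#' arginine-like side chain (fixed bond lengths/angles; only the
#' dihedrals vary), packaged as an ensemble so the extraction code path
#' is exercised end to end.
#'
#' @param mixture list of components, each
#'   `list(mean = <4 angles deg>, kappa = <concentration>, weight = ...)`;
#'   weights sum to 1.
#' @param n_frames frames to draw (`>= 1`).
#' @param seed integer seed.
#' @param chain,resno identity of the synthetic residue (default B:503).
#' @param dt_ps frame spacing, ps.
#' @return list with `series` (the `DihedralSeries` extracted back from
#'   the realized coordinates), `trajectory` (an `EnsembleTrajectory` of
#'   the realized residue), `components` (per-frame component index) and
#'   `drawn_chi` (the ground-truth angles drawn from the mixture).
#' @export
make_rotamer_trajectory <- function(mixture, n_frames, seed = 1L,
                                    chain = "B", resno = 503L, dt_ps = 100) {
  if (!is_count(n_frames)) stop("n_frames must be a positive integer")
  w <- validate_mixture(mixture, c("mean", "kappa"))
  if (any(vapply(mixture, function(m) m$kappa <= 0, logical(1))))
    stop("mixture concentrations must be positive")
  n_chi <- unique(vapply(mixture, function(m) length(m$mean), integer(1)))
  if (length(n_chi) != 1L || n_chi != 4L)
    stop("each component mean must be a 4-tuple of chi angles")

  with_seed(seed, {
    comp <- sample.int(length(mixture), n_frames, replace = TRUE, prob = w)
    chi <- matrix(NA_real_, n_frames, 4L,
                  dimnames = list(NULL, paste0("chi", 1:4)))
    for (c in seq_along(mixture)) {
      rows <- which(comp == c)
      for (k in 1:4)
        chi[rows, k] <- rvonmises(length(rows), mixture[[c]]$mean[k],
                                  mixture[[c]]$kappa)
    }
    atom_names <- c("N", "CA", "CB", "CG", "CD", "NE", "CZ")
    elements <- c("N", "C", "C", "C", "C", "N", "C")
    types <- c("N", "C", "C", "C", "C", "N", "C")
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz <- arg_sidechain_coords(chi[f, ])
      new_structure(atom_table(seq_along(atom_names), atom_names, elements,
                               types, "ARG", resno, chain, xyz,
                               charge = 0, record = "ATOM",
                               role = "receptor"),
                    metadata = list(frame = f, component = comp[f]))
    })
    traj <- new_ensemble(frames, times = dt_ps * seq_len(n_frames))
    series <- extract_chi_series(traj, list(chain = chain, resno = resno),
                                 keep_coords = TRUE)
    list(series = series, trajectory = traj, components = comp,
         drawn_chi = chi)
  })
}

#' Draw binding free-energy samples from a Gaussian mixture
#'
#' @param mixture list of components,
#'   `list(mean = <kcal/mol>, sd = ..., weight = ...)`; weights sum to 1.
#' @param n sample count (`>= 1`).
#' @param seed integer seed.
#' @return numeric vector of dG samples (kcal/mol) with attribute
#'   `"components"`.
#' @export
make_score_samples <- function(mixture, n, seed = 1L) {
  if (!is_count(n)) stop("n must be a positive integer")
  w <- validate_mixture(mixture, c("mean", "sd"))
  if (any(vapply(mixture, function(m) m$sd <= 0, logical(1))))
    stop("mixture sds must be positive")
  with_seed(seed, {
    comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
    mu <- vapply(mixture, `[[`, numeric(1), "mean")[comp]
    sd <- vapply(mixture, `[[`, numeric(1), "sd")[comp]
    x <- stats::rnorm(n, mu, sd)
    attr(x, "components") <- comp
    x
  })
}
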