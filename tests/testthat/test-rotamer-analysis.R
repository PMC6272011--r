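test_that("dihedral angles follow the planar and rotated-oracle anchors", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  # rotation-matrix construction oracle: rotating the cis far atom by an
  # angle about the p2->p3 axis must read back as exactly that angle
  for (ang in c(60, -60, 125.5, -170, 180)) {
    p4 <- popshift:::rotate_about_axis(matrix(c(1, 1, 0), 1), c(0, 0, 0),
                                       c(0, 1, 0), ang)
    got <- dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), as.numeric(p4))
    expect_equal(got, popshift:::wrap_angle(ang), tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)),
               "collinear")
})

test_that("dihedral signs agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(2)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    ok <- tryCatch({
      mine <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
      expect_equal(mine, popshift:::wrap_angle(ref), tolerance = 1e-6)
      TRUE
    }, error = function(e) FALSE)  # skip degenerate random quadruples
  }
})

test_that("chi series extraction recovers constructed geometry", {
  rot <- make_rotamer_trajectory(
    list(list(mean = c(180, 180, 180, 180), kappa = 1e7, weight = 1)),
    n_frames = 2, seed = 3)
  expect_equal(dim(rot$series$chi), c(2, 4))
  expect_true(all(abs(popshift:::angle_diff(rot$series$chi, 180)) < 0.5))
  # missing atom: drop CG from one frame
  traj <- rot$trajectory
  broken <- traj$frames[[2]]$atoms
  traj$frames[[2]] <- new_structure(broken[broken$name != "CG", ])
  traj$topology_constant <- FALSE
  expect_error(extract_chi_series(traj, list(chain = "B", resno = 503)),
               "CG.*frame 2")
  # single-frame ensemble gives a length-1 series
  one <- new_ensemble(rot$trajectory$frames[1], times = rot$trajectory$times[1])
  s1 <- extract_chi_series(one, "B:503")
  expect_equal(nrow(s1$chi), 1)
})

test_that("angular histograms are circular, normalized and peak-aware", {
  h <- angular_histogram(rep(-70, 100), bin_width = 10)
  expect_equal(sum(h$densities) * h$bin_width, 1, tolerance = 1e-12)
  expect_equal(nrow(h$peaks), 1)
  expect_lte(abs(popshift:::angle_diff(h$peaks$center, -70)), 5)
  # wraparound: mass at 179 and -179 merges into a single seam peak
  h2 <- angular_histogram(c(rep(179, 60), rep(-179, 60)), bin_width = 10)
  expect_equal(nrow(h2$peaks), 1)
  expect_lte(min(abs(h2$peaks$center - 180), abs(h2$peaks$center + 180)), 10)
  # uniform coverage is flat: no peaks
  h3 <- angular_histogram(seq(0, 350, by = 10), bin_width = 10)
  expect_equal(nrow(h3$peaks), 0)
  # peaks are invariant under a global +360 shift
  h4 <- angular_histogram(rep(-70, 100) + 360, bin_width = 10)
  expect_equal(h4$peaks$center, h$peaks$center)
  expect_error(angular_histogram(numeric(0)), "empty")
  expect_error(angular_histogram(1:5, bin_width = 7), "divide")
})

test_that("periodic dihedral RMSD matches hand-computed anchors", {
  expect_equal(dihedral_rmsd(c(-70, 180, 65, 90), c(-70, 180, 65, 90)), 0)
  expect_equal(dihedral_rmsd(c(0, 0, 0, 0), c(10, 10, 10, 10)), 10)
  # one component wraps: |175 - (-175)| = 10 on the circle -> sqrt(100/4)
  expect_equal(dihedral_rmsd(c(175, 0, 0, 0), c(-175, 0, 0, 0)), 5)
  expect_error(dihedral_rmsd(c(1, 2), c(1, 2, 3)), "length")
})

test_that("dihedral RMSD is a metric on the 4-torus", {
  set.seed(99)
  for (i in 1:1000) {
    a <- runif(4, -180, 180); b <- runif(4, -180, 180)
    c <- runif(4, -180, 180)
    dab <- dihedral_rmsd(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, dihedral_rmsd(b, a), tolerance = 1e-12)
    expect_lte(dihedral_rmsd(a, c),
               dab + dihedral_rmsd(b, c) + 1e-9)
  }
  # identity: zero iff identical (mod 360)
  x <- c(12, -170, 91, 180)
  expect_equal(dihedral_rmsd(x, x - 360), 0, tolerance = 1e-9)
})

test_that("well-separated rotamer groups cluster cleanly", {
  chi_a <- matrix(rep(c(-70, 180, 60, 85), each = 10), 10, 4)
  chi_b <- matrix(rep(c(-170, 60, -80, 0), each = 10), 10, 4)
  fake_series <- function(chi) structure(
    list(residue_id = list(chain = "B", number = 503, name = "ARG"),
         chi = chi, frame_times = seq_len(nrow(chi)),
         atom_quadruples = CHI_DEFINITIONS$ARG, coords = NULL),
    class = "DihedralSeries")
  cl <- cluster_rotamers(list(fake_series(chi_a), fake_series(chi_b)),
                         cutoff = 30)
  expect_length(cl$centroids, 2)
  expect_equal(sort(cl$populations), c(0.5, 0.5))
  expect_equal(sum(cl$populations), 1, tolerance = 1e-9)
  # all-identical frames give one cluster whose centroid is that tuple
  cl1 <- cluster_rotamers(fake_series(chi_a), cutoff = 30)
  expect_length(cl1$centroids, 1)
  expect_equal(unname(cl1$centroids[[1]]$chi), c(-70, 180, 60, 85))
  expect_error(cluster_rotamers(fake_series(chi_a), cutoff = 0), "positive")
})

test_that("clustering recovers a 3-component circular mixture", {
  means <- list(c(-70, 180, 65, 90), c(-170, 65, -85, 180),
                c(60, -60, 180, 0))
  rts <- lapply(1:3, function(i) make_rotamer_trajectory(
    list(list(mean = means[[i]], kappa = 50, weight = 1)),
    n_frames = 150, seed = 40 + i))
  cl <- cluster_rotamers(lapply(rts, `[[`, "series"), cutoff = 40)
  expect_length(cl$centroids, 3)
  devs <- vapply(cl$centroids, function(cen)
    min(vapply(means, function(m)
      max(abs(popshift:::angle_diff(cen$chi, m))), numeric(1))),
    numeric(1))
  expect_true(all(devs < 10))
})

test_that("cluster labels are stable under frame permutation", {
  rot <- make_rotamer_trajectory(
    list(list(mean = c(-70, 180, 65, 90), kappa = 50, weight = 0.7),
         list(mean = c(60, -60, 180, 0), kappa = 50, weight = 0.3)),
    n_frames = 120, seed = 17)
  cl <- cluster_rotamers(rot$series, cutoff = 40)
  perm <- sample(nrow(rot$series$chi))
  shuffled <- rot$series
  shuffled$chi <- shuffled$chi[perm, ]
  cl2 <- cluster_rotamers(shuffled, cutoff = 40)
  expect_equal(length(cl$centroids), length(cl2$centroids))
  expect_equal(sort(cl$populations), sort(cl2$populations))
  expect_equal(cl$assignments[perm], cl2$assignments)
})

test_that("centroids match their nearest reference in both metrics", {
  rot <- make_rotamer_trajectory(
    list(list(mean = c(-70, 180, 65, 90), kappa = 200, weight = 1)),
    n_frames = 40, seed = 12)
  cl <- cluster_rotamers(rot$series, cutoff = 40)
  cen <- cl$centroids[[1]]
  refs <- list(
    near = list(chi = cen$chi),  # identical tuple -> distance 0
    far = list(chi = popshift:::wrap_angle(cen$chi + 80)))
  m <- match_to_reference(cl, refs)
  expect_equal(m$reference, "near")
  expect_equal(m$dihedral_rmsd_deg, 0, tolerance = 1e-9)
  # coordinate metric: a uniformly displaced copy reads back the shift
  cen_xyz <- rot$series$coords[[cen$series_frame]]
  refs2 <- list(shifted = list(chi = cen$chi,
                               coords = cen_xyz + 0.5 / sqrt(3)))
  m2 <- match_to_reference(cl, refs2, series_list = rot$series)
  expect_equal(m2$cartesian_rmsd_A, 0.5, tolerance = 1e-9)
  # no shared atom names -> dihedral metric with a warning
  bad <- cen_xyz
  rownames(bad) <- paste0("X", seq_len(nrow(bad)))
  expect_warning(
    m3 <- match_to_reference(cl, list(odd = list(chi = cen$chi,
                                                 coords = bad)),
                             series_list = rot$series),
    "shared atoms")
  expect_true(is.na(m3$cartesian_rmsd_A))
  expect_error(match_to_reference(cl, list()), "empty")
})
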