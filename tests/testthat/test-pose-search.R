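p_def <- default_energy_parameters()

test_that("rescore is deterministic and equals direct scoring", {
  toy <- default_toy()
  a <- rescore(toy$receptor, toy$ligand, toy$tree, p_def)
  b <- rescore(toy$receptor, toy$ligand, toy$tree, p_def)
  d <- score_pose(toy$receptor, toy$ligand, toy$tree, p_def)
  expect_identical(unclass(a)[1:6], unclass(b)[1:6])
  expect_equal(a$total_dg, d$total_dg, tolerance = 1e-12)
  # single-pair anchor: -W_vdw * eps at the pair equilibrium distance
  sys <- single_pair_system(4)
  expect_equal(rescore(sys$receptor, sys$ligand, NULL, p_def)$vdw,
               -p_def$W_vdw * 0.15, tolerance = 1e-9)
  # mislabeled roles fail loudly
  bad <- sys$ligand
  bad$atoms$role <- "receptor"
  expect_error(rescore(sys$receptor, bad, NULL, p_def), "role")
})

test_that("identity pose reproduces input coordinates exactly", {
  toy <- default_toy()
  pose0 <- new_pose(torsion_angles = numeric(toy$tree$n_tor))
  expect_equal(coords(realize_pose(toy$ligand, toy$tree, pose0)),
               coords(toy$ligand), tolerance = 1e-12)
  expect_error(new_pose(orientation = c(1, 1, 0, 0)), "unit quaternion")
})

test_that("refine starting at a single-pair minimum stays put", {
  sys <- single_pair_system(4)  # exactly at the pair r_eq
  res <- refine(sys$receptor, sys$ligand, NULL, p_def,
                bounds = list(max_translation = 0.3, max_rotation = 5,
                              max_torsion = 5),
                n_iter = 150, seed = 2)
  start <- score_pose(sys$receptor, sys$ligand, NULL, p_def)$total_dg
  expect_lte(res$score$total_dg, start)
  # the 1-D minimum is at r_eq: refinement cannot do meaningfully better
  expect_lt(start - res$score$total_dg, 1e-4)
  expect_lt(vnorm(res$pose$translation), 0.3 + 1e-9)
})

test_that("refine strictly improves a displaced start (line-search oracle)", {
  sys <- single_pair_system(4.5)  # 0.5 A off the minimum
  # oracle: the pair potential's best value along the approach line
  line <- seq(3.5, 5.5, by = 0.001)
  oracle_best <- min(vapply(line, function(r)
    sum(unlist(pair_energy("C", "C", 0, 0, r, p_def))), numeric(1)))
  start <- score_pose(sys$receptor, sys$ligand, NULL, p_def)$total_dg
  res <- refine(sys$receptor, sys$ligand, NULL, p_def,
                bounds = list(max_translation = 1, max_rotation = 15,
                              max_torsion = 15),
                n_iter = 250, seed = 4)
  expect_lt(res$score$total_dg, start)
  expect_gte(res$score$total_dg, oracle_best - 1e-6)
  expect_lt(res$score$total_dg - oracle_best, 0.005)
})

test_that("refine is bit-identical under a fixed seed and bounded", {
  toy <- default_toy()
  r1 <- refine(toy$receptor, toy$ligand, toy$tree, p_def, n_iter = 60,
               seed = 9)
  r2 <- refine(toy$receptor, toy$ligand, toy$tree, p_def, n_iter = 60,
               seed = 9)
  expect_identical(r1$pose, r2$pose)
  expect_identical(r1$score$total_dg, r2$score$total_dg)
  expect_lte(vnorm(r1$pose$translation), 1 + 1e-9)
  expect_lte(popshift:::quat_angle(r1$pose$orientation), 15 + 1e-6)
  expect_true(all(abs(r1$pose$torsion_angles) <= 15 + 1e-9))
  expect_error(refine(toy$receptor, toy$ligand, toy$tree, p_def,
                      n_iter = 0), "positive integer")
  expect_error(refine(toy$receptor, toy$ligand, toy$tree, p_def,
                      bounds = list(max_translation = -1, max_rotation = 15,
                                    max_torsion = 15)), "positive")
})

test_that("refine never increases the score over random starts", {
  toy <- default_toy()
  set.seed(123)
  for (i in 1:12) {
    lig <- set_coords(toy$ligand,
                      sweep(coords(toy$ligand), 2, runif(3, -1.5, 1.5), `+`))
    start <- score_pose(toy$receptor, lig, toy$tree, p_def)$total_dg
    res <- refine(toy$receptor, lig, toy$tree, p_def, n_iter = 40, seed = i)
    expect_lte(res$score$total_dg, start + 1e-12)
  }
})

test_that("pose RMSD is analytic and metric-like", {
  lig <- chain_ligand(4)
  xyz <- coords(lig)
  expect_equal(pose_rmsd(xyz, xyz), 0)
  expect_equal(pose_rmsd(xyz, sweep(xyz, 2, c(1, 0, 0), `+`)), 1)
  # two atoms displaced 0 and 2 A -> sqrt((0 + 4)/2) = sqrt(2)
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  b <- a; b[2, 1] <- b[2, 1] + 2
  expect_equal(pose_rmsd(a, b), sqrt(2))
  expect_error(pose_rmsd(a[0, , drop = FALSE], b[0, , drop = FALSE]),
               "at least one")
  # symmetry + triangle inequality on random triples
  set.seed(6)
  for (i in 1:25) {
    x <- matrix(rnorm(12), 4, 3); y <- matrix(rnorm(12), 4, 3)
    z <- matrix(rnorm(12), 4, 3)
    expect_equal(pose_rmsd(x, y), pose_rmsd(y, x))
    expect_lte(pose_rmsd(x, z), pose_rmsd(x, y) + pose_rmsd(y, z) + 1e-12)
  }
})

test_that("docking recovers the certified optimum of the probe pocket", {
  probe <- probe_toy()
  box <- make_grid_box(probe$receptor, spacing = 0.375, npts = c(17, 17, 17),
                       ligand_types = "C", p = p_def, center = c(0, 0, 0))
  res <- dock(box, probe$ligand, probe$tree, p_def, n_runs = 8,
              n_iter = 300, seed = 21, n_modes = 3)
  expect_lte(length(res$modes), 3)
  dgs <- vapply(res$modes, function(m) m$score$total_dg, numeric(1))
  expect_true(!is.unsorted(dgs))
  best <- res$modes[[1]]$structure
  expect_lt(pose_rmsd(coords(best), probe$optimum$coords,
                      heavy_only = FALSE), 0.5)
  # the pooled best is at least as good as the certificate's lattice value
  expect_lte(res$modes[[1]]$score$total_dg, probe$optimum$total_dg + 0.05)
})

test_that("docking is reproducible under a fixed seed", {
  probe <- probe_toy()
  box <- make_grid_box(probe$receptor, spacing = 0.375, npts = c(17, 17, 17),
                       ligand_types = "C", p = p_def, center = c(0, 0, 0))
  r1 <- dock(box, probe$ligand, probe$tree, p_def, n_runs = 3, n_iter = 80,
             seed = 33)
  r2 <- dock(box, probe$ligand, probe$tree, p_def, n_runs = 3, n_iter = 80,
             seed = 33)
  expect_identical(lapply(r1$modes, function(m) m$score$total_dg),
                   lapply(r2$modes, function(m) m$score$total_dg))
  expect_identical(coords(r1$modes[[1]]$structure),
                   coords(r2$modes[[1]]$structure))
})
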