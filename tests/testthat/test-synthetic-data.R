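p_def <- default_energy_parameters()

test_that("toy complexes echo their spec and are reproducible", {
  spec <- toy_complex_spec(n_pocket_atoms = 30, n_ligand_atoms = 3)
  a <- make_toy_complex(spec, seed = 1, certify = FALSE)
  b <- make_toy_complex(spec, seed = 1, certify = FALSE)
  expect_equal(nrow(a$receptor$atoms), 30)
  expect_equal(nrow(a$ligand$atoms), 3)
  expect_identical(coords(a$receptor), coords(b$receptor))
  expect_identical(coords(a$ligand), coords(b$ligand))
  expect_error(make_toy_complex(toy_complex_spec(n_ligand_atoms = 12,
                                                 cavity_radius = 4),
                                certify = FALSE), "infeasible")
})

test_that("the certified optimum beats random in-cavity placements", {
  probe <- probe_toy()
  set.seed(55)
  opt_dg <- probe$optimum$total_dg
  for (i in 1:200) {
    u <- rnorm(3); u <- u / vnorm(u) * runif(1, 0, 2)
    lig <- set_coords(probe$ligand, matrix(u, 1))
    # slack: the certificate is exact only on its 0.25 A scan lattice
    expect_gte(score_pose(probe$receptor, lig, probe$tree, p_def)$total_dg,
               opt_dg - 0.01)
  }
})

test_that("generated structures survive a file round trip", {
  toy <- default_toy()
  f <- withr::local_tempfile(fileext = ".pdbq")
  write_structure(toy$receptor, f, "pdbq_charged")
  got <- read_structure(f, "pdbq_charged")
  expect_equal(coords(got), round(coords(toy$receptor), 3),
               ignore_attr = TRUE)
  expect_equal(got$atoms$atom_type, toy$receptor$atoms$atom_type)
  expect_equal(got$atoms$role, toy$receptor$atoms$role)
})

test_that("ensembles are pure functions of (spec, seed)", {
  toy <- default_toy()
  t1 <- make_ensemble(toy$receptor, toy$ligand, n_frames = 5,
                      noise_sd = 0.1, seed = 7)
  t2 <- make_ensemble(toy$receptor, toy$ligand, n_frames = 5,
                      noise_sd = 0.1, seed = 7)
  expect_identical(lapply(t1$frames, coords), lapply(t2$frames, coords))
  # zero noise: all frames identical to the base complex
  t0 <- make_ensemble(toy$receptor, toy$ligand, n_frames = 5,
                      noise_sd = 0, seed = 7)
  expect_equal(coords(t0$frames[[1]]), coords(t0$frames[[5]]))
  expect_error(make_ensemble(toy$receptor, toy$ligand, n_frames = 5,
                             noise_sd = -0.1), "non-negative")
})

test_that("two-state switching matches its binomial rate", {
  toy <- default_toy()
  alt <- set_coords(toy$ligand, sweep(coords(toy$ligand), 2, 1, `+`))
  traj <- make_ensemble(toy$receptor, toy$ligand, n_frames = 1000,
                        noise_sd = 0.01,
                        two_state = list(ligand_b = alt, prob = 0.3),
                        seed = 19)
  frac <- mean(attr(traj, "states") == 2L)
  expect_gte(frac, 0.27)  # 99% binomial interval at n = 1000, p = 0.3
  expect_lte(frac, 0.33)
})

test_that("rotamer trajectories realize their drawn chi angles", {
  rot <- make_rotamer_trajectory(
    list(list(mean = c(-70, 180, 65, 90), kappa = 1e6, weight = 1)),
    n_frames = 25, seed = 4)
  # concentration limit: every frame within 0.5 degrees of the mean
  expect_true(all(abs(popshift:::angle_diff(
    rot$series$chi, matrix(rep(c(-70, 180, 65, 90), each = 25), 25))) < 0.5))
  # extraction round trip: realized coordinates return the drawn angles
  expect_true(all(abs(popshift:::angle_diff(rot$series$chi,
                                            rot$drawn_chi)) < 0.5))
  expect_error(make_rotamer_trajectory(list(), 10), "at least one")
  expect_error(make_rotamer_trajectory(
    list(list(mean = c(0, 0, 0, 0), kappa = 10, weight = 0.5)), 10),
    "sum to 1")
})

test_that("mixture component weights are respected", {
  rot <- make_rotamer_trajectory(
    list(list(mean = c(-70, 180, 65, 90), kappa = 50, weight = 0.7),
         list(mean = c(60, -60, 180, 0), kappa = 50, weight = 0.3)),
    n_frames = 1000, seed = 23)
  frac1 <- mean(rot$components == 1L)
  expect_gte(frac1, 0.66)  # 99% binomial interval at n = 1000, p = 0.7
  expect_lte(frac1, 0.74)
})

test_that("score samples follow their Gaussian mixture", {
  x <- make_score_samples(list(list(mean = -11, sd = 0.5, weight = 1)),
                          n = 1000, seed = 3)
  expect_lt(abs(mean(x) - (-11)), 0.1)  # CLT bound ~ 3 * 0.5/sqrt(1000)
  y1 <- make_score_samples(list(list(mean = -11, sd = 0.5, weight = 0.7),
                                list(mean = -6, sd = 0.5, weight = 0.3)),
                           n = 500, seed = 11)
  y2 <- make_score_samples(list(list(mean = -11, sd = 0.5, weight = 0.7),
                                list(mean = -6, sd = 0.5, weight = 0.3)),
                           n = 500, seed = 11)
  expect_identical(as.numeric(y1), as.numeric(y2))
  # the spectrum mode lands at the heavier component
  s <- build_spectrum(as.numeric(y1), 0.5)
  expect_lte(abs(s$most_probable_dg - (-11)), 0.5)
  expect_error(make_score_samples(list(list(mean = 0, sd = 1, weight = 1)),
                                  n = 0), "positive integer")
})

test_that("von Mises draws concentrate correctly", {
  x <- popshift:::with_seed(29, popshift:::rvonmises(3000, -70, 50))
  circ_mean <- atan2(mean(sin(x * pi / 180)),
                     mean(cos(x * pi / 180))) * 180 / pi
  expect_lt(abs(popshift:::angle_diff(circ_mean, -70)), 1.5)
  # circular sd ~ 1/sqrt(kappa) = 8.1 degrees
  expect_lt(abs(sd(popshift:::angle_diff(x, circ_mean)) - 8.1), 1)
})
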