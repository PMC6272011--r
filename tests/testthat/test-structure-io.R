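test_that("charged records echo through the pdbq_charged reader", {
  f <- withr::local_tempfile(fileext = ".pdbq")
  s <- new_structure(make_atoms(
    list(1L, "N1", "N", "N", "LIG", 1L, "L", 0.0, 0.0, 0.0, 0.2,
         "HETATM", "ligand"),
    list(2L, "O1", "O", "OA", "LIG", 1L, "L", 1.3, 0.0, 0.0, -0.4,
         "HETATM", "ligand"),
    list(3L, "C1", "C", "C", "LIG", 1L, "L", 2.4, 0.8, 0.0, 0.2,
         "HETATM", "ligand")))
  write_structure(s, f, "pdbq_charged")
  got <- read_structure(f, "pdbq_charged")
  expect_equal(got$atoms$charge, c(0.2, -0.4, 0.2))
  expect_equal(got$atoms$atom_type, c("N", "OA", "C"))
  expect_equal(got$atoms$name, s$atoms$name)
})

test_that("round-trip preserves names, residues, positions and charges to 3 decimals", {
  lig <- chain_ligand(4)
  lig$atoms$charge <- c(0.123456, -0.4567, 0.2, -0.05)
  f <- withr::local_tempfile(fileext = ".pdbq")
  write_structure(lig, f, "pdbq_charged")
  got <- read_structure(f, "pdbq_charged")
  expect_equal(got$atoms$name, lig$atoms$name)
  expect_equal(got$atoms$resname, lig$atoms$resname)
  expect_equal(got$atoms$resno, lig$atoms$resno)
  expect_equal(coords(got), round(coords(lig), 3), ignore_attr = TRUE)
  expect_equal(got$atoms$charge, round(lig$atoms$charge, 3))
  # a second pass must be the identity: formatting is idempotent
  f2 <- withr::local_tempfile(fileext = ".pdbq")
  write_structure(got, f2, "pdbq_charged")
  expect_identical(readLines(f), readLines(f2))
})

test_that("plain-PDB writing agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  toy <- default_toy()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$receptor, f, "pdb")
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), nrow(toy$receptor$atoms))
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE),
               round(coords(toy$receptor), 3), ignore_attr = TRUE)
  expect_equal(ref$atom$resid[1], "PKT")
})

test_that("multi-model input is rejected by the single-structure reader", {
  lig <- tiny_structure()
  f <- withr::local_tempfile(fileext = ".pdb")
  traj <- new_ensemble(list(lig, lig), times = c(0, 1))
  write_ensemble(traj, f, "pdb")
  expect_error(read_structure(f, "pdb"), "read_ensemble")
})

test_that("malformed records are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ok <- "ATOM      1  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00"
  bad <- "ATOM      2  C2  LIG L   1       x.xxx   0.000   0.000  1.00  0.00"
  writeLines(c(ok, bad, "END"), f)
  expect_error(read_structure(f, "pdb"), "line 2")
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.50  0.00",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.50  0.00",
    "ATOM      4  CB AALA A   1       2.000   1.200   0.000  0.30  0.00",
    "ATOM      5  CB BALA A   1       2.200   1.200   0.000  0.70  0.00",
    "END")
  writeLines(lines, f)
  # independent count: raw ATOM lines minus one per duplicated alt group
  raw_n <- sum(grepl("^ATOM", lines))
  alt_tags <- sub("^.{16}(.).*", "\\1", grep("^ATOM", lines, value = TRUE))
  n_dup <- sum(alt_tags == "B")
  s <- read_structure(f, "pdb")
  expect_equal(nrow(s$atoms), raw_n - n_dup)
  # equal occupancy -> conformer A; unequal -> higher occupancy wins
  ca <- s$atoms[s$atoms$name == "CA", ]
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(ca$alt_loc, "A")
  expect_equal(cb$alt_loc, "B")
})

test_that("ensembles carry REMARK time stamps and enforce constant topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  traj <- tiny_trajectory(seq(100, 500, by = 100))
  write_ensemble(traj, f, "pdb")
  got <- read_ensemble(f, "pdb")
  expect_length(got$frames, 5)
  expect_equal(got$times, c(100, 200, 300, 400, 500))

  # single-model file -> single-frame trajectory
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tiny_structure(), f1, "pdb")
  expect_length(read_ensemble(f1, "pdb")$frames, 1)

  # differing atom counts across models -> structural error
  two <- new_structure(make_atoms(
    list(1L, "C1", "C", "C", "LIG", 1L, "L", 0, 0, 0, 0, "HETATM", "ligand"),
    list(2L, "C2", "C", "C", "LIG", 1L, "L", 1.5, 0, 0, 0, "HETATM",
         "ligand")))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL        1",
             popshift:::format_atom_lines(two$atoms, "pdb"), "ENDMDL",
             "MODEL        2",
             popshift:::format_atom_lines(two$atoms[1, ], "pdb"), "ENDMDL",
             "END")
  writeLines(lines, f2)
  suppressWarnings(expect_error(read_ensemble(f2, "pdb"), "atom counts"))

  # no time stamps -> unit spacing from 0 with a warning
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               popshift:::format_atom_lines(two$atoms, "pdb"), "ENDMDL",
               "MODEL        2",
               popshift:::format_atom_lines(two$atoms, "pdb"), "ENDMDL"),
             f3)
  expect_warning(got2 <- read_ensemble(f3, "pdb"), "TIME_PS")
  expect_equal(got2$times, c(0, 1))
})

test_that("empty structures are rejected", {
  expect_error(new_structure(make_atoms(
    list(1L, "C1", "C", "C", "LIG", 1L, "L", 0, 0, 0, 0, "HETATM",
         "ligand"))[0, ]), "at least one atom")
})

test_that("torsion trees follow the strictly-beyond rule on a 4-atom path", {
  lig <- chain_ligand(4)
  # single interior bond: moved set is the far end only
  t1 <- build_torsion_tree(lig, bonds = list(c(2L, 3L)))
  expect_equal(t1$n_tor, 1L)
  expect_equal(t1$rotatable_bonds[[1]]$moved, 4L)
  # oracle: brute-force graph traversal on the path graph 1-2-3-4
  path_beyond <- function(a, b) {
    # atoms strictly beyond b, walking away from a on the path
    if (b > a) setdiff(seq(b, 4L), b) else setdiff(seq(1L, b), b)
  }
  t2 <- build_torsion_tree(lig, bonds = list(c(1L, 2L), c(2L, 3L)))
  expect_equal(t2$n_tor, 2L)
  expect_equal(sort(t2$rotatable_bonds[[1]]$moved), path_beyond(1L, 2L))
  expect_equal(sort(t2$rotatable_bonds[[2]]$moved), path_beyond(2L, 3L))
  # nested moved sets, none touching the root
  expect_true(all(t2$rotatable_bonds[[2]]$moved %in%
                    t2$rotatable_bonds[[1]]$moved))
  expect_false(any(unlist(lapply(t2$rotatable_bonds, `[[`, "moved")) %in%
                     t2$root_atom_indices))
})

test_that("ring bonds are rejected as torsion axes", {
  # square of 4 carbons, side 1.5 A: every bond is a ring bond
  ring <- new_structure(make_atoms(
    list(1L, "C1", "C", "C", "LIG", 1L, "L", 0, 0, 0, 0, "HETATM", "ligand"),
    list(2L, "C2", "C", "C", "LIG", 1L, "L", 1.5, 0, 0, 0, "HETATM", "ligand"),
    list(3L, "C3", "C", "C", "LIG", 1L, "L", 1.5, 1.5, 0, 0, "HETATM",
         "ligand"),
    list(4L, "C4", "C", "C", "LIG", 1L, "L", 0, 1.5, 0, 0, "HETATM",
         "ligand")))
  expect_error(build_torsion_tree(ring, bonds = list(c(1L, 2L))), "ring")
})

test_that("rotating a torsion 360 degrees restores coordinates", {
  lig <- chain_ligand(5)
  tree <- build_torsion_tree(lig)
  expect_gte(tree$n_tor, 2L)
  xyz <- coords(lig)
  for (k in seq_len(tree$n_tor))
    expect_lt(max(abs(apply_torsion(xyz, tree, k, 360) - xyz)), 1e-9)
  # rotating a bond changes only its moved set
  moved <- tree$rotatable_bonds[[1]]$moved
  rot <- apply_torsion(xyz, tree, 1, 35)
  expect_lt(max(abs(rot[-moved, ] - xyz[-moved, ])), 1e-12)
  expect_gt(max(abs(rot[moved, ] - xyz[moved, ])), 0.1)
})
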