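# shared in-code fixtures; everything is generated, nothing read from disk

make_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) data.frame(
    serial = r[[1]], name = r[[2]], element = r[[3]], atom_type = r[[4]],
    resname = r[[5]], resno = r[[6]], chain = r[[7]],
    x = r[[8]], y = r[[9]], z = r[[10]], charge = r[[11]], occupancy = 1,
    alt_loc = "", record = r[[12]], role = r[[13]],
    stringsAsFactors = FALSE)))
}

# minimal single-atom structure, handy for time-lattice tests
tiny_structure <- function() {
  new_structure(make_atoms(
    list(1L, "C1", "C", "C", "LIG", 1L, "L", 0, 0, 0, 0, "HETATM", "ligand")))
}

# trajectory of identical tiny frames on a regular time grid
tiny_trajectory <- function(times) {
  new_ensemble(rep(list(tiny_structure()), length(times)), times = times)
}

# one receptor atom at the origin plus one neutral ligand atom at distance r
single_pair_system <- function(r, type_rec = "C", type_lig = "C",
                               q_rec = 0, q_lig = 0) {
  receptor <- new_structure(make_atoms(
    list(1L, "C1", "C", type_rec, "PKT", 1L, "A", 0, 0, 0, q_rec,
         "ATOM", "receptor")))
  ligand <- new_structure(make_atoms(
    list(1L, "C1", "C", type_lig, "LIG", 1L, "L", r, 0, 0, q_lig,
         "HETATM", "ligand")))
  list(receptor = receptor, ligand = ligand)
}

# zig-zag n-carbon chain ligand (same geometry as the synthetic generator)
chain_ligand <- function(n, bond_length = 1.5) {
  spec <- toy_complex_spec(n_ligand_atoms = n, bond_length = bond_length)
  make_toy_complex(spec, certify = FALSE)$ligand
}

# cached toy complexes so expensive certification runs once per suite
toy_cache <- new.env(parent = emptyenv())

cached_toy <- function(key, spec, certify = FALSE) {
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- make_toy_complex(spec, certify = certify)
  toy_cache[[key]]
}

default_toy <- function() cached_toy("default", toy_complex_spec())

# single-atom probe in the tight shell: unique certified optimum at center
probe_toy <- function() {
  cached_toy("probe",
             toy_complex_spec(n_ligand_atoms = 1L, cavity_radius = 4),
             certify = TRUE)
}

# wide shell for grid-vs-direct comparisons (large clearance everywhere)
wide_toy <- function() {
  cached_toy("wide", toy_complex_spec(cavity_radius = 8))
}
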