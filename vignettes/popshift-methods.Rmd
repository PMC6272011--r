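---
title: "Methods: scoring, free-energy spectra and rotamer population shifts"
author: "popshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, free-energy spectra and rotamer population shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popshift)
```

## The problem

When a small molecule stabilizes a transient macromolecular state — the
motivating case is a topoisomerase II cleavage complex poisoned by drugs
such as etoposide — a single docking score against one crystal structure
is a fragile summary of affinity.  The receptor relaxes, side chains
repack, and the drug samples a distribution of microstates.  `popshift`
implements a workflow built around that observation:

1. **Three evaluation tiers** for a pose: `rescore()` scores fixed
   coordinates; `refine()` performs local descent in a restricted space
   around the input pose; `dock()` runs a comprehensive multi-start
   search over a grid box.
2. **Free-energy spectra**: every snapshot of a conformational ensemble
   is rescored, and the resulting binding free energies are histogrammed
   into a probability density.  The mode of that density (the *most
   probable* $\Delta G$) is the representative affinity, converted to an
   inhibition constant by $K_i = \exp(\Delta G / RT)$.
3. **Rotamer population analysis**: side-chain $\chi_1$–$\chi_4$
   dihedrals are extracted per frame, summarized as circular histograms,
   and clustered under a periodic dihedral metric, revealing
   ligand-induced shifts in rotamer populations and allowing cluster
   centroids to be matched against crystallographic conformations.

## The scoring function

The binding free energy of a pose is a semi-empirical pairwise sum of
the AutoDock4 family over all receptor–ligand atom pairs:

$$
\Delta G = W_{vdw}\sum_{ij}\Big(\frac{A_{ij}}{r^{12}}-\frac{B_{ij}}{r^6}\Big)
  + W_{hb}\sum_{ij\in DA}\Big(\frac{C_{ij}}{r^{12}}-\frac{D_{ij}}{r^{10}}\Big)
  + W_{el}\sum_{ij}\frac{332.06\,q_iq_j}{\varepsilon(r)\,r}
  + W_{ds}\sum_{ij}(S_iV_j{+}S_jV_i)\,e^{-r^2/2\sigma^2}
  + W_{tor}N_{tor}
$$

with $A = \epsilon r_{eq}^{12}$, $B = 2\epsilon r_{eq}^6$ (pair
$r_{eq}$ by arithmetic mean, $\epsilon$ by geometric mean), a 12-10
hydrogen-bond term between donor–acceptor type pairs parameterized by
the acceptor, and a sigmoidal distance-dependent dielectric

$$
\varepsilon(r) = A_\varepsilon +
  \frac{\varepsilon_0 - A_\varepsilon}
       {1 + k\,e^{-\lambda(\varepsilon_0 - A_\varepsilon) r}}
$$

rising from about 1.35 at contact to the bulk value 78.4.  Default
weights are $W_{vdw}=0.1662$, $W_{hb}=0.1209$, $W_{el}=0.1406$,
$W_{ds}=0.1322$, $W_{tor}=0.2983$, with $\sigma = 3.5$ Å and
$T = 298.15$ K; all are overridable through
`default_energy_parameters()`, and the per-type table (12 types: C, A,
N, NA, O, OA, S, SA, H, HD, P, Mg) ships as a plain-text file users can
replace.  Partial charges are *inputs* (carried in the charged PDBQ
dialect); no charge model is computed here.

Design choices worth knowing:

* **The 12-10 term is added to, not substituted for, the 12-6 term** on
  donor–acceptor pairs.  This keeps each term's contract independent;
  classic AutoDock4 substitutes instead.  With the shipped table the
  practical difference is a slightly deeper donor–acceptor well.
* **No angular attenuation on hydrogen bonds** (a pure radial 12-10):
  directional weighting complicates grid tabulation and is deliberately
  omitted; the geometric interaction profiler (below) applies an angle
  criterion where directionality matters.
* **No nonbonded cutoff** in direct rescoring — reproducibility is worth
  more than speed at this scale; the grid box bounds range in grid mode.
* **Ligand internal energy is excluded**: the total is intermolecular
  plus the torsional penalty, which is the right currency for comparing
  poses of the same ligand.
* **Clamps**: distances are floored at 0.01 Å and every pair term capped
  at $10^5$ kcal/mol, so clashed MD snapshots rescore finite (flagged in
  the breakdown's warning list) instead of producing `Inf`.
* **Waters are always excluded; ions are excluded by default** and can
  be included per call (`include_ions`), since whether structural
  Mg²⁺ should contribute to rescoring is a judgment call; both behaviors
  are one flag apart.

## Grid maps

`make_grid_box()` tabulates, on a regular lattice (default 0.375 Å
spacing; the conventional production setup of $100^3$ points spans a
37.125 Å cube), one van der Waals + hydrogen-bond field per ligand atom
type, an electrostatic potential per unit charge, and the two Gaussian
desolvation fields $\sum_j V_j g(r)$ and $\sum_j S_j g(r)$.
`grid_score()` evaluates poses by trilinear interpolation; at lattice
nodes it reproduces `score_pose()` to numerical precision *by
construction* (the same clamped per-atom contributions are accumulated),
and off-node agreement is limited only by interpolation error, which is
negligible at sensible clearances (tested below 0.05 kcal/mol at
$\geq 2$ Å clearance).

## Search

`refine()` is stochastic accept-if-better descent with adaptive step
sizes over translation, rigid rotation (quaternion) and torsions,
confined to a restricted space around the start.  The bounds of that
space are not prescribed anywhere authoritative, so the defaults —
1 Å translation, 15° rotation, 15° per torsion — are exposed as
parameters.  The returned score can never exceed the input score, and a
given seed reproduces results bit-for-bit.

`dock()` is multi-start: random in-box placements (uniform positions,
uniform quaternions, uniform torsions) each followed by descent on the
grid objective, pooled, clustered greedily by pose RMSD (2.0 Å default,
a standard docking convention) and ranked by $\Delta G$.  A
multi-start descent was chosen over a genetic algorithm deliberately:
it is simple, reproducible, and sufficient as a pose generator at this
scale; a GA could be slotted behind the same contract later.

Pose RMSD is computed in the fixed receptor frame — no superposition,
identity atom mapping, heavy atoms by default — because the use case is
comparing a docked pose to a reference pose of the same molecule in the
same frame.

## Free-energy spectra

`sample_snapshots()` selects frames on a sampling lattice anchored at
the *end* of the window, so trailing-window protocols ("every 100 ps
over the last 9 ns" → 90 frames; "every 10 ps over the last 1 ns" →
100 frames) always include the final frame.  `build_spectrum()`
histograms the rescored $\Delta G$ values with bin centers fixed at
integer multiples of the bin width (default 0.5 kcal/mol), making
spectra of different ligands directly comparable.  Ties for the maximal
bin resolve toward the more negative bin — a deliberate, stated
convention, conservative toward stronger predicted binding.  A raw
histogram (not a kernel density) is used; smoothing would blur exactly
the bimodality the spectrum is meant to reveal.  Note that because the
mode is reported as a bin *center*, the sampled minimum can exceed the
mode by up to half a bin when all mass sits right of the center.

## Rotamer analysis

Dihedrals use the standard atan2 construction with the IUPAC sign
convention, reported in $(-180, 180]$ degrees (matching the field's
"χ₁ around −70°" phrasing).  The built-in quadruple table covers
arginine (χ₁ N-CA-CB-CG through χ₄ CG-CD-NE-CZ) and is overridable.

The rotamer distance between frames is the periodic root-mean-square
deviation over χ components, a proper metric on the torus.  Frames from
*all* supplied simulations are pooled before clustering so cluster
labels are comparable across ligand systems, then grouped by
average-linkage agglomerative clustering cut at a distance threshold
(default 40°) — a cutoff, not a fixed k, because the correct number of
rotamer states is an output, not an input.  Centroids are medoid frames
rather than circular means: a medoid is an actually-sampled
conformation, and circular means of well-separated angles can land in
unpopulated regions.  `match_to_reference()` reports both the dihedral
RMSD (degrees) and, when coordinates are available, side-chain
heavy-atom RMSD (Å) of each centroid to its nearest reference — both
metrics, neither silently preferred, because reference comparisons in
the literature are quoted in Å while the clustering itself runs in
dihedral space.

Circular histograms (`angular_histogram()`) integrate to 1 over 360°,
merge plateau bins across the ±180° seam, and report local maxima above
a height fraction (default 0.25) of the global maximum, so a mode
straddling the seam is one peak, and a flat distribution has none.

## Interaction profiles

`interaction_report()` is a LigPlot-style geometric profiler of one
bound pose: hydrogen bonds are donor–acceptor pairs across the
ligand/receptor boundary within 3.5 Å (and, when the donor hydrogen is
present, D–H···A ≥ 120°); contacts are all other cross-boundary
heavy-atom pairs within 3.9 Å, grouped by receptor residue.  The
criteria follow common practice and are fully configurable; ions and
waters are excluded by default.  No 2-D depiction is attempted.

## Synthetic data: what it emulates and what it does not

All tests run on generated fixtures:

* `make_toy_complex()` builds a spherical shell of receptor atoms
  (deterministic Fibonacci lattice) around a zig-zag chain ligand, and
  certifies a "known optimum" by exhaustive translation scanning at
  0.25 Å within ±2 Å.  Two parameterizations serve different checks:
  the default 6 Å shell leaves the 4-atom ligand in the attractive well
  (refinement and rescoring tests), while a 4 Å shell with a
  single-atom probe puts the *unique* energy minimum exactly at the
  cavity center (a wide shell has a degenerate spherical shell of
  minima, and a multi-atom ligand in a spherically symmetric pocket has
  a nearly degenerate orientation, which would make a no-superposition
  RMSD check against the certificate meaningless).  Dock-recovery tests
  therefore use the probe configuration; an 8 Å shell with a small
  interior grid box (all placements ≥ ~4 Å clearance) hosts the
  grid-vs-direct comparison.
* `make_ensemble()` adds isotropic Gaussian coordinate noise
  (default 0.05 Å, a mild thermal jitter) per frame, optionally
  switching the ligand to a second pose with fixed probability — the
  minimal generative model of a two-state binding mode whose rescored
  $\Delta G$ distribution is bimodal.
* `make_rotamer_trajectory()` draws χ tuples from von Mises mixtures
  (Best–Fisher rejection sampling, implemented in-package) and realizes
  them as coordinates of an ideal arginine-like side chain with fixed
  bond lengths and angles — only the dihedrals vary, which is exactly
  what the analysis consumes.
* `make_score_samples()` draws $\Delta G$ values from Gaussian
  mixtures; the acceptance-grade check uses means −11/−6 kcal/mol,
  sd 0.5, weights 0.7/0.3, n = 500, matching the scale of real spectra.

Every generator is a pure function of its spec and seed.  What these
fixtures do **not** emulate: real enzyme/DNA geometry, force-field
realism, correlated thermal motion, or solvent.  Passing tests
demonstrate that the machinery — scoring identities, grid
interpolation, search contracts, histogram and clustering estimators —
is correct, not that the scoring function reproduces experimental
affinities for real complexes, which requires real structures and
trajectories outside this package's scope.

## Numerical choices and degenerate inputs

* Problem sizes in tests and the acceptance workload were chosen at
  "desk scale": $13^3$–$17^3$ grids, 48-atom pockets, 20 docking
  restarts, 40–300 descent iterations, 900 pooled rotamer frames.
* Covalent connectivity uses $0.4 < d \le r_i + r_j + 0.4$ Å with a
  fixed covalent-radius table — the standard rule; a multiplicative
  variant considered early on misses C–C bonds at 1.54 Å.
* Alternate locations collapse to the highest-occupancy conformer, ties
  broken alphabetically (conformer A), mirroring how practitioners pick
  one alternate side-chain conformation for docking.
* The charged PDBQ dialect puts the charge in columns 69–76 (`%8.3f`)
  and the type code in 78–79; round trips are lossless at 3 decimals.
* Degenerate dihedral geometry (coincident or collinear consecutive
  points) raises errors rather than returning NaN; torsion rotations by
  360° restore coordinates to 1e-9 Å.
* Unknown atom types fail loudly at scoring time rather than defaulting
  silently.

## Known limitations

* The term weights are adopted published defaults, not recalibrated;
  with charges supplied externally, any charge-model-specific variant
  of the scoring function reduces to charge provenance, which is out of
  scope here.
* One ligand copy per run; systems with two symmetric binding sites are
  handled by running each site separately.
* No receptor flexibility during docking, no ensemble docking, no
  snapshot reweighting (all frames weigh equally in a spectrum), no
  block-averaged error bars on spectra.
* mmCIF and binary trajectory formats are unsupported by design; the
  ensemble format is multi-model PDB(Q) with `REMARK TIME_PS` stamps.
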