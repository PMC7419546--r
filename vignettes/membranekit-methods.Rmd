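---
title: "Membrane and protein trajectory descriptors: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane and protein trajectory descriptors: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranekit)
```

## Scope

membranekit computes the standard descriptors used to characterise
coarse-grained lipid bilayer simulations — area per lipid, area
compressibility modulus, transbilayer density profile and thickness,
lateral diffusion coefficients, flip-flop events, lipid contact and
cluster statistics with a random-mixing null — together with the
protein-ensemble analyses used alongside them (superposition, RMSF and
B-factors, cross-correlation maps, PCA, and a C-alpha anisotropic
network model).  It does not run molecular dynamics.  Instead, a
synthetic-trajectory generator with known ground truth emulates the
statistical structure those analyses assume, so that every estimator in
the package is validated by parameter recovery.

The reference systems in the documentation are chloroplast-mimicking
bilayers built from four lipid species: the galactolipids MGDG and
DGDG, the anionic phospholipid PG, and the substrate lipid DAG.  Four
compositions are bundled as presets (`composition_preset("M1")` ...
`"M4"`): a PG/DAG bilayer (75/25 mol%) and three galactolipid
membranes (MGDG/DGDG/PG/DAG at 50/30/10/10, 50/30/15/5 and 40/30/25/5
mol%).  A patch of 200 lipids, 100 per leaflet, in an 8 x 8 nm periodic
box at 293 K is the canonical geometry.

## The synthetic bilayer model

`gen_bilayer_trajectory()` builds a two-leaflet system in which the
generator's parameters *are* the quantities the estimators later
recover:

* **Lateral motion.** Each lipid is an independent 2-D random walker
  with per-axis step variance `2 * D_true * dt`, wrapped into the
  periodic box.  There is no excluded volume: interactions are not
  needed to validate an MSD estimator, and lateral structure is
  injected by the layout process instead.
* **Area fluctuations.** Each frame's per-lipid area is Gaussian with
  mean `A0_true` and the equilibrium variance implied by an area
  compressibility modulus `KA_true`, `var(A) = kB*T*A0 / (N*KA)` (with
  1 J/nm^2 = 1e21 mN/m).  The box is rescaled isotropically in xy with
  z fixed, the semi-isotropic intent of an NpT membrane run without
  simulating pressure coupling.
* **Transverse structure.** Reference (GL1) beads sit at +/-
  `thickness_true/2` with Gaussian spread `leaflet_z_sigma` (default
  0.3 nm — a free fixture parameter; headgroup width is not a quantity
  the estimators recover).  One auxiliary tail bead per lipid sits
  0.3 nm toward the midplane.
* **Flip-flop.** A designated species switches leaflets as a two-state
  Markov process with per-molecule rate `flip_rate_true` (events/us);
  z relaxes to the new leaflet within one frame.  The event *count* is
  the observable being emulated, not transit kinetics.
* **Composition.** Per-leaflet species counts are apportioned by
  largest remainder, which preserves the composition exactly in
  expectation and leaflet totals exactly.

Seed handling: all randomness derives from `spec$seed`; the two leaflet
layouts use `seed + 1` and `seed + 2` and the dynamic streams use
`seed + 3`, so identical specs reproduce bit-identical trajectories.

What the generator does **not** emulate: excluded volume and lipid
packing, undulations, correlated (hydrodynamic) motion, anomalous
diffusion at short times, and asymmetric leaflets.  Passing recovery
tests therefore demonstrate estimator correctness under the stated
stochastic model, not the fidelity of any force field.

## Lateral layouts and the mixing null

`gen_lateral_layout()` places labelled lipids either uniformly (a
binomial point process) or with a designated species clustered by a
Matern process: parent points are Poisson with intensity
`parent_intensity` (at least one parent), children uniform in a disc of
`cluster_radius`.  Because analyses need exact species counts, each
clustered point is assigned to a parent uniformly at random rather than
drawing Poisson counts per parent; disc geometry and parent intensity —
the properties that make the process clustered — are unchanged.

Two contact rules follow the field's conventions: `gl1_any` (a lipid's
GL1 bead within 0.8 nm of any bead of the partner, symmetrised) for
contact percentages, and `gl1_gl1` for single-linkage clustering.  The
0.8 nm default is the first coarse-grained solvation shell.  Distances
are 3-D minimum image; the cell-list engine is required by its tests to
agree exactly with the all-pairs oracle.

`mixing_null()` formalises the comparison of observed self-contact
percentages with those "expected for a uniform distribution": the
contact graph is built once from geometry, species labels are permuted,
and the self-contact fraction is recomputed per permutation.  Under
exchangeability the expected self-contact fraction of a species with
`n_s` of `n` molecules is `(n_s - 1)/(n - 1)`, converging to the mole
fraction for large n — for a 200-lipid patch the finite-n offsets are
below half a percentage point (74.87 vs 75 for a 75% species).  The
p-value uses add-one smoothing, `(b + 1)/(n_perm + 1)`, so it can never
be exactly zero.  Whether contact fractions are averaged per frame or
pooled across frames is a reporting choice; per-frame averaging is the
default and pooled raw counts are returned alongside.

Cluster statistics exclude singletons from mean sizes by default and
report them separately; a frame of pure singletons has zero clusters,
not a mean of one.  Clustering is per leaflet (lateral structures;
inter-leaflet GL1 distances exceed the cutoff in a healthy bilayer),
with `per_leaflet = FALSE` available for flat single-layer layouts.

## Membrane descriptors

* **Area per lipid** is the lateral box area over the number of lipids
  per leaflet — the per-leaflet convention, which reproduces 0.64 nm^2
  for an 8 x 8 nm box with 100 lipids per leaflet.
* **Compressibility** inverts the fluctuation formula
  `K_A = kB*T*A0 / (N * <(A - A0)^2>)`.  Errors use a 5-block
  delete-one jackknife over contiguous blocks; with the provenance of
  literature error bars on such descriptors generally unstated, a block
  method over the single series is the defensible default.  Recovery is
  tested on the modulus grid {141, 363, 619} mN/m at 2e4 frames
  (tolerance 5%).
* **Density profiles** are time-averaged z-histograms (default bin
  0.1 nm, no smoothing), each frame centred at the *mean* z of the
  selected particles.  The mean, not the median: for a balanced
  bimodal leaflet distribution, any flip-induced count imbalance places
  both central order statistics inside one leaflet cluster, so the
  median jumps by about half a bilayer thickness while the mean moves
  by only `thickness * imbalance / n`.  The same centring backs leaflet
  assignment and flip-flop detection, where median centring produced
  spurious crossing events in testing.
* **Thickness** is the distance between the density argmax above and
  below the midplane, optionally refined by quadratic interpolation
  through the peak bins; unimodal profiles are rejected as
  non-bilayers.  Recovery is within one bin width.

## Lipid dynamics

The lateral MSD averages over all time origins and all molecules of a
species, on centre-of-geometry paths unwrapped by frame-to-frame
minimum image (assuming no molecule moves more than half a box edge per
frame).  The species-set centre of mass is removed per frame; for `m`
independent walkers this deflates the expected slope by `(1 - 1/m)`
(4% at m = 25), which sits inside the 10% recovery tolerance and is
accepted rather than corrected, matching common practice.  The
multiple-origin average is computed with the FFT autocorrelation
identity and must agree with the quadratic-time double loop to 1e-10.

`fit_diffusion()` fits `msd = 4 D t + c` by ordinary least squares over
a lag window given as fractions of the maximum lag, default 10-50% —
below 10% the intercept (origin noise) dominates, beyond 50% too few
origin pairs remain.  D is reported in nm^2/ns with a um^2/s mirror
(factor 1000); negative estimates are flagged, never suppressed.  The
coarse-grained-to-real speed-up factor (about four to five) is a
reporting decision left entirely to the user; nothing in the package
applies it silently.

Flip-flop detection uses a two-threshold hysteresis rule (default
+/- 0.5 nm about the midplane): an event requires reaching the *far*
threshold, so dwell noise around the midplane cannot inflate counts, as
it would with a single-plane crossing counter.  The implementation must
replay exactly against a brute-force state machine on random paths.
Rates are reported both per membrane and per molecule, since
"events per microsecond" is ambiguous between the two conventions.
The threshold-validity check measures the membrane's z-extent over all
reference beads, so a species whose excursions stay below threshold
legitimately yields zero events.

## Protein ensembles

Superposition uses the Kabsch algorithm with the determinant correction
(proper rotations only), iterated against the running mean structure
(at most 10 passes, 1e-8 nm tolerance).  The iteration starts from the
ensemble's stored reference, which makes superposition idempotent:
re-aligning an aligned ensemble does not re-pick an orientation.  RMSF
refuses unaligned input rather than silently absorbing rigid-body
motion; B-factors are `(8 pi^2 / 3) rmsf^2` in Angstrom^2.

The cross-correlation map normalises displacement inner products to
[-1, 1]; residues with zero variance yield flagged `NA` entries —
writing 0 would assert "uncorrelated", which is not computable.  For
map summaries, |C| >= 0.5 is the conventional threshold for calling a
pair correlated.  PCA diagonalises the 3n x 3n Cartesian covariance;
eigenvalue sum must match the trace to 1e-8 and frames are projected on
the two leading components by default.

The anisotropic network model connects C-alpha pairs within a cutoff
(default 1.5 nm, the convention of the standard ANM web service, with
uniform spring constant gamma): off-diagonal 3x3 superelements
`-(gamma/d^2) (d (x) d)`, diagonal blocks minus the row sums, hence
exact translational invariance and six zero modes for a connected
network.  Predicted B-factors are the traces of the diagonal 3x3 blocks
of the Hessian pseudo-inverse over non-rigid modes.  No mass weighting
anywhere: these are C-alpha-only analyses.

The protein-ensemble generator samples a multivariate Gaussian around a
reference structure, from either an explicit PSD covariance or the ANM
pseudo-inverse scaled by `anm_kT` (default 0.005), chosen so RMSF stays
an order of magnitude below the fold size as in a folded protein —
without the scale, unit-gamma ANM fluctuations rival the structure
dimensions and iterative superposition has no stable mean.  Optional
random rigid-body motions exercise the superposition path.

## Problem sizes and numerical choices

The validation suite runs at desk scale, with sizes chosen so each
recovery property is measured well inside its tolerance:
compressibility at 2e4 frames; diffusion at 5000 frames x ~25 molecules
per species on a four-species 100-lipid-per-leaflet patch; flip-flop at
2 us x 1 ns frames with rate 5/us; DCCM/PCA recovery at 5000 frames of
a 15-residue helical test structure; the mixing null at 200 lipids with
permutation counts of 199-1000.  Degenerate inputs error early and by
name: zero-variance area series, unimodal profiles, disconnected ANM
networks, collinear structures, cutoffs beyond half the box.  Ties in
largest-remainder rounding break by species order; `p = (b+1)/(m+1)`
keeps permutation p-values positive.

## Command-line use

`inst/scripts/membranekit` wraps the exported functions as
`generate | membrane | dynamics | clusters | report` subcommands with a
YAML config (`run_config()` documents every default), writing CSV
artifacts plus a manifest per stage.  The `report` stage assembles the
per-stage tables into one summary, one row per descriptor, mirroring
the layout in which such membrane characterisations are usually
tabulated (SA, K_A, d, per-species D, flip-flop rate, contacts).

## Known limitations

Estimator validation is against the generator's idealised stochastic
model; real coarse-grained trajectories add correlated motion,
undulations and finite-size effects the generator omits.  Orthorhombic
boxes only.  XTC/DCD binary trajectory formats are not read; convert to
GRO/PDB or the internal text container first.  The ANM energy scale is
arbitrary, so predicted B-factors are meaningful up to a profile shape,
as usual for network models.
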