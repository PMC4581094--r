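---
title: "Methods: contact-map reconstruction and foci quantification in telohic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-map reconstruction and foci quantification in telohic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telohic)
```

`telohic` studies a specific biological contrast: in cycling budding-yeast
cells the genome adopts a Rabl configuration — centromeres clustered at the
spindle-pole-body side of the nuclear envelope, telomeres tethered to the
envelope in a handful of peripheral foci — whereas long-lived quiescent
cells gather their 32 telomeres into one or two bright, centrally located
hyperclusters. This vignette documents the models and procedures the
package uses to quantify that contrast, the parameters that matter, the
design decisions taken where the design was genuinely open, and what the
synthetic-data validation does and does not establish.

## 1. Genome model and binning

Coordinates are 0-based, half-open `[start, end)` throughout (BED
convention), which makes fragment tilings unambiguous. `digest_genome()`
cuts at the first base of each recognition-site occurrence (DpnII cuts 5'
of `GATC`; any fixed offset within the site would bin identically), drops
the empty leading fragment when a site sits at position 0, and tiles each
chromosome exactly. `bin_fragments()` groups `F` consecutive fragments per
bin — 20 by default, 10 for fine maps — keeping partial terminal bins
rather than merging them, so the bin/fragment correspondence stays exact.
Bins never span chromosomes.

The default `build_toy_genome()` karyotype is a synthetic 16-chromosome
model with arm lengths rounded to the kb from the familiar budding-yeast
karyotype and an rDNA interval on chromosome XII. It is deliberately *not*
an annotation release: it exists so that simulations and tests have a
realistic chromosome-arm-length spectrum (79 kb to 1.08 Mb, 12.1 Mb
total, 605 beads of 20 kb). Only nuclear chromosomes are modeled; the
mitochondrial genome is excluded because it takes no part in telomere or
centromere organization and would only add unconnected bins.

## 2. Synthetic structures: what the generator emulates

`simulate_structure()` produces one bead chain per chromosome
(1 bead = 20 kb, coordinates in units of 10 nm) inside a spherical
nucleus, in three modes:

* **G1_rabl** — centromere beads within `tether_tolerance` (default
  0.1 µm) of a point at 0.88 R on the spindle-pole-body axis; terminal
  beads within `tether_tolerance` of the envelope, with each telomere's
  envelope anchor placed at a polar angle from the pole that grows with
  arm length. That last choice is the geometric essence of the Rabl
  configuration: short arms cannot reach far from the centromere cluster.
* **G0_hypercluster** — all 32 terminal beads within `cluster_radius` of a
  single interior point whose distance to the nuclear center is less than
  R/3. The hypercluster's physical radius is not an experimentally
  reported number, so `cluster_radius` is a free parameter defaulting to
  0.1 µm — the scale of a diffraction-limited focus.
* **uniform** — unconstrained chains, used for null comparisons and
  round-trip tests.

rDNA beads are confined to a peripheral sector opposite the pole in both
organized modes, mimicking the nucleolus.

Chains are generated as Brownian bridges between anchor points and then
repaired by alternating projections: anchor/envelope/sector projections, a
forward bond sweep pinned at the first bead, re-projection, a backward
sweep pinned at the last bead, and confinement to the nucleus (a FABRIK-
style scheme). Pure rejection sampling — the obvious alternative — is
infeasible when 32 beads must simultaneously fall inside a 0.1-µm ball;
projection reaches the same constraint set and the constraints are checked
exactly on exit (maximum bond length 300 nm per 20-kb step, all beads
inside the nucleus, anchors satisfied), with a diagnostic error otherwise.
No claim of polymer-physics realism is made: the generator reproduces the
*geometric* features the analysis measures, not chromatin mechanics.

Every stochastic operation takes an explicit seed and restores the
caller's RNG state, so pipelines are reproducible operation by operation.

## 3. The contact model and its inverse

The generator samples contacts with probability proportional to
`c0 / d(i,j)^alpha` with `alpha = 1` by default. This is deliberately the
exact inverse of the reconstruction assumption (distance = inverse contact
frequency), so that in the noiseless dense limit the
shortest-path-plus-MDS reconstruction is exact and any round-trip error is
attributable to sampling noise or normalization, not model mismatch. A
power-law exponent is exposed for users who want to break that symmetry
deliberately.

`structure_to_contact_map()` draws all contacts in one multinomial, which
is both fast and exactly reproducible; self-pairs are excluded and
coincident beads are an error (they would create infinite weight).

`simulate_read_pairs()` places each mate uniformly within a uniformly
chosen restriction fragment of its bin, appends exact PCR duplicates
(same coordinates, strands and 6-letter adapter tag) for a binomial
fraction of pairs, and downgrades a binomial fraction of mates to
MAPQ ≤ 40. The planted bin-pair counts are returned so the filtering and
matrix-building stages can be validated as a lossless round trip when
duplicates and low-quality mates are switched off.

## 4. Pair processing and SCN normalization

`preprocess_pairs()` keeps a pair only when *both* mates have MAPQ
strictly greater than 40 — the threshold is strict by design, matching the
standard unambiguous-alignment convention. Duplicates are collapsed on
(both coordinates, both strands, tag) after canonicalizing mate order, so
a ligation product sequenced in either orientation counts once. If the tag
column is absent the collapse falls back to coordinates alone, with a
warning, because coordinate-identical independent molecules are rare at
typical depth but the user should know the distinction was lost.

`filter_bins()` masks bins whose marginal is zero or below the 0.01
quantile of nonzero marginals. The threshold is this package's choice:
some low-coverage filter is required for balancing to be meaningful, and a
quantile rule adapts to sequencing depth; the parameter is exposed.

`scn_normalize()` iterates column normalization, row normalization and
symmetrization until every row and column sums to 1 within `tol`
(default 1e-6, default cap 200 rounds; non-convergence is an error that
reports the residual, never a silent pass). The symmetrized limit is not
algebraically identical to the Sinkhorn–Knopp `D M D` point, but both
balance the matrix; the tests verify double stochasticity, symmetry
preservation, zero-pattern preservation, and fixed-point behavior on
already-balanced input. On the 604-bin toy maps convergence takes ~6
rounds.

## 5. Reconstruction, rescaling, telomere distances

`contact_to_distance()` builds the graph with edge weight `1/M[i,j]` on
every nonzero off-diagonal entry and computes all-pairs shortest paths
(Dijkstra from each node, via igraph). Intra-bin (diagonal) contacts are
retained in the matrix but excluded from the graph: a self-contact carries
no inter-bin distance information. A disconnected graph is an error that
lists component sizes — completing distances across components would be
arbitrary.

`embed_3d()` is classical Torgerson scaling: double-center `-D²/2`,
eigendecompose, take the top three nonnegative eigenpairs. Negative
eigenvalues — inevitable for non-Euclidean shortest-path matrices — are
clipped; if fewer than three positive eigenvalues exist the remaining
coordinates are zero-padded with a warning. Only relative geometry is
meaningful up to rigid motion, so tests compare distance matrices, never
raw coordinates.

`rescale_structures()` first scales structure *b* isotropically so its
convex-hull volume equals structure *a*'s, then scales each so its hull
volume equals the volume of a sphere of its stated nuclear diameter
(defaults 1.5 µm and 1.7 µm for quiescent and G1 nuclei), putting both
into units of 10 nm. Volume matching, rather than a linear diameter ratio,
is used because the hull is the structure's own occupied volume and the
nuclear sphere is the physical container being equated; both
interpretations coincide up to a constant factor for similar shapes, and
the hull/diameter inputs are explicit arguments. The 3D convex hull is
computed by an incremental (beneath-beyond) algorithm implemented in the
package and validated against closed-form solids, the `s³` scaling law and
Monte Carlo integration.

`telomere_distance_matrix()` takes the first and last retained bead of
each chromosome as its telomere-proximal beads — the subtelomere extent in
beads has no canonical definition, and the terminal 20-kb bead is the
finest choice the bead model allows. Rows and columns are ordered by
increasing arm length (ties broken by chromosome name), the ordering that
reveals arm-length dependence of telomere pairing.

## 6. Contact statistics

`subtelomere_contact_profile()` averages, for each arm and each window of
`window` bp at offset 0, `window`, `2·window`, … from the telomere, the
contact between that window and the offset-0 windows of all arms of
*other* chromosomes. The sister arm of the same chromosome is excluded:
cis contacts are trivially high and would mask the trans-clustering
signal. Windows that would cross the centromere are skipped, and arms
shorter than the requested extent simply contribute fewer windows (with a
warning). The classic analysis uses 3-kb windows on fragment-resolution
maps; on 20-kb bead maps the window must be at least the bin size, and the
profile function refuses coarser-than-window matrices rather than
silently interpolating.

`random_segment_control()` samples non-telomeric segments (35 kb by
default, excluding the terminal 30 kb of every arm so the control cannot
overlap subtelomeres) and reports the mean inter-chromosomal contact
between them, with an uncertainty taken as the standard deviation of
per-segment means divided by √n. Equality of this control across
conditions is the coverage-bias null that gives the subtelomere profile
its meaning.

`centromere_contact_score()` averages normalized contact between
centromere-centered windows of different chromosomes; at least two
chromosomes are required, and masked centromere bins drop their
chromosome with a warning.

## 7. Foci quantification

The detection procedure is this package's operational definition (the
original in-house tool's internals are not published): Gaussian smoothing
(default σ 0.08 µm), background = median smoothed intensity inside the
nucleus, robust SD = 1.4826·MAD, candidate voxels above
`background + k·SD` with `k = 5`, 26-connected components of at least
`min_voxels = 4` voxels. Two refinements proved necessary and are part of
the definition:

* **Local-maxima splitting.** At realistic signal-to-noise, the threshold
  contours of two foci separated by ~4 PSF sigmas merge into one
  component even though the spots are visually distinct. Smoothed local
  maxima farther apart than `split_sep` (0.3 µm lateral-equivalent, with z
  compressed by the PSF aspect ratio 2.7) therefore seed separate foci,
  and component voxels join their nearest seed.
* **Background re-estimation.** The widefield PSF is strongly elongated in
  z (default σ_z 0.35 µm vs σ_xy 0.13 µm), so a bright focus spreads a
  diffuse tail through much of a 1-µm nucleus and inflates a naive median
  background, which in turn biases integrated intensities down by up to
  ~25 %. The background is re-estimated from mask voxels laterally
  distant from every detected focus before integration.

Integrated intensity sums background-subtracted raw voxels over a fixed
box (±0.4 µm lateral, ±1.0 µm axial) around the centroid — clipped to the
anisotropic Voronoi cell of the focus when several foci are close —
because integrating only above-threshold voxels clips the Gaussian tails
and loses ~15–20 % of the signal. Background-subtracted integrated
intensity, not peak intensity, is the focus brightness measure: it is
robust to PSF width.

`call_hypercluster()` is strict: one or two foci, and at least one focus
*strictly above* the 95th percentile of the reference (exponential-phase)
focus population. The percentile is computed over all reference foci;
computing it over per-cell brightest foci would shift the threshold up
slightly and is left to the caller's choice of reference vector.

`zone_assay()` reads "three equal concentric zones" as equal *areas* in
the focal plane — the standard yeast zoning convention — giving boundaries
at `R·√(1/3)` and `R·√(2/3)`; under uniform positioning each zone receives
exactly 1/3, which is the assay's null and is verified by Monte Carlo in
the tests. Equal radial thirds would instead give 1/9, 3/9, 5/9 and make
the null position-dependent.

`mann_whitney_u()` computes U from midranks; the p-value is exact by full
enumeration of rank assignments when the combined sample size is at most
12 with no ties, otherwise a tie-corrected, continuity-corrected normal
approximation. `two_proportion_z()` is the pooled-proportion z test. Both
are cross-checked in the tests against independent references
(`wilcox.test`'s exact distribution, `prop.test` without continuity
correction, and closed forms).

## 8. Problem sizes, numerical choices, degenerate inputs

The validation suite runs at sizes chosen to exercise every code path
while keeping a full run in minutes on one core: SCN on 50 random
matrices up to 200 bins; the noiseless round trip on a 100-bead planted
structure (exact to ~1e-12 because the sampling model inverts the
reconstruction assumption and Euclidean direct edges are always shortest);
Floyd–Warshall equivalence on 50 instances of up to 12 bins; the full
condition contrast on the 16-chromosome karyotype at 10⁶ sampled
contacts; foci recovery over 200 rendered nuclei at SNR well above 10;
hypercluster-fraction recovery on 1000 synthetic cells; and a 10⁵-point
zoning null.

Degenerate inputs fail loudly rather than silently: coincident beads in
contact sampling, disconnected contact graphs, all-zero coverage,
non-converged balancing, zero-volume hulls, empty nuclei, empty reference
populations, and foci outside the nucleus are all errors with
diagnostics.

## 9. What the synthetic validation does not show

The generator plants the *geometry* the statistics are designed to
detect; passing tests therefore demonstrate that the pipeline measures
what it claims to measure, not that real quiescent yeast behaves this
way. Real 3C libraries carry biases the simulator omits (religation and
self-circle events, fragment-length and GC biases, mappability), real
images carry camera calibration, bleed-through and cell-segmentation
uncertainty, and the population-scale figures reported for real cultures
(fractions of cells per focus-count class, fold changes of median focus
intensity, zone-3 percentages) depend on acquisition settings that a
desk-scale simulation cannot reproduce. The package's claims are
correspondingly about recovery of planted truth and internal consistency
of the estimators.
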