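# telohic

Telomere hypercluster analysis from 3C contact maps and 3D fluorescence
imaging.

In exponentially growing budding yeast, the 32 telomeres tether to the
nuclear envelope in a handful of peripheral foci, opposite a tight
centromere cluster (the Rabl configuration). When cells exhaust their
carbon source and enter quiescence, telomere-bound Rap1 foci coalesce into
one or two exceptionally bright, *central* "hyperclusters". `telohic`
provides the computational machinery to detect and quantify that
reorganization from the two assays that reveal it:

* **3C / Hi-C contact maps** — from mapped read pairs to normalized
  genome-wide contact matrices, reconstructed 3D genome models, and
  telomere/subtelomere/centromere contact statistics;
* **3D fluorescence stacks** — detection and integration of
  diffraction-limited Rap1 foci, population summaries, hypercluster
  classification, and a concentric nuclear zoning assay.

Every stage can be exercised on synthetic data with planted ground truth:
bead-chain chromosomes in a spherical nucleus (Rabl-like or
hypercluster-like), contact maps sampled from them, read pairs with PCR
duplicates and low-quality mates, and nucleus images with Poisson/Gaussian
noise.

## Methods at a glance

**Contact maps.** Mapped mates are filtered at MAPQ > 40, PCR duplicates
are collapsed on coordinates, strands and the adapter random-hexamer tag,
and each mate is assigned to its restriction fragment (DpnII `GATC` by
default). Fragments are grouped into bins of *F* = 20 fragments (10 for
fine maps), giving a symmetric count matrix *M*. Low-coverage bins are
masked and *M* is balanced by **sequential component normalization**
(SCN): iterate column normalization, row normalization and symmetrization
`(M + Mᵀ)/2` until every row and column sums to 1 within tolerance.

**3D reconstruction.** From a normalized map, the distance between bins
*i, j* is the shortest path on the weighted graph with edge weights
`1 / M[i, j]`; classical (Torgerson) multidimensional scaling of that
distance matrix gives bead coordinates (1 bead = 20 kb). To compare
conditions, two structures are scaled so their convex hulls match, then
each is scaled to the volume of its measured nuclear sphere (1.5 µm for
quiescent G0 cells, 1.7 µm for G1 daughters); coordinates are in units of
10 nm. Telomere pair distances are read directly off the structures,
ordered by chromosome arm length.

**Foci.** Images are Gaussian-smoothed; voxels above
`median + k·(robust SD)` inside the nucleus form 26-connected components,
split at well-separated local maxima; each focus reports an
intensity-weighted centroid and a background-subtracted integrated
intensity. A cell carries a *hypercluster* iff it has one or two foci and
at least one focus brighter than the 95th percentile of an
exponential-phase reference population. The zoning assay scores a focus
into three equal-area concentric zones of the focal plane (boundaries at
`R·√(1/3)` and `R·√(2/3)`; zone 3 is innermost). Population comparisons
use the Mann–Whitney U test (exact for small untied samples) and the
two-proportion Z test.

## Worked example

```r
library(telohic)
genome <- build_toy_genome()        # 16-chromosome toy karyotype
bins   <- bead_bin_table(genome)    # one 20-kb bin per bead

# planted structures: cycling (Rabl) vs quiescent (hypercluster)
s_g1 <- simulate_structure(genome, nucleus_config(mode = "G1_rabl", seed = 1))
s_g0 <- simulate_structure(genome, nucleus_config(mode = "G0_hypercluster", seed = 1))

# sample 3C contact maps and reconstruct
M_g1 <- structure_to_contact_map(s_g1, bins, n_contacts = 1e6, seed = 2)
M_g0 <- structure_to_contact_map(s_g0, bins, n_contacts = 1e6, seed = 2)
r_g1 <- reconstruct_structure(M_g1)
r_g0 <- reconstruct_structure(M_g0)
r_g0$normalized
#> ContactMatrix [normalized]: 604 x 604 bins, total 604

sc <- rescale_structures(r_g0$structure, r_g1$structure,
                         diam_a = 1.5, diam_b = 1.7)
td_g0 <- telomere_distance_matrix(sc$a, genome)
td_g1 <- telomere_distance_matrix(sc$b, genome)
median(td_g0[upper.tri(td_g0)]) / 100   # 0.26 um
median(td_g1[upper.tri(td_g1)]) / 100   # 0.92 um
```

The quiescent-mode run recovers the planted reorganization: the median
telomere–telomere distance collapses from 0.92 µm (G1) to 0.26 µm (G0),
the telomere-proximal 20-kb window's mean trans-subtelomere contact
roughly doubles (0.0039 vs 0.0019), and the centromere contact score drops
(0.0017 vs 0.0050) — centromere clustering is the cycling-cell feature.

Foci quantification on a rendered nucleus:

```r
spec <- sample_foci_spec(2, center = c(1.56, 1.56, 1.6), radius = 1, seed = 3)
img  <- render_nucleus_image(spec, center = c(1.56, 1.56, 1.6), radius = 1, seed = 4)
detect_foci(img)$foci
#>          x        y        z integrated_intensity voxel_count peak_intensity
#> 1 1.279397 1.475339 1.686768             41011.35         160       438.9483
#> 2 1.712661 1.843618 1.618015             40487.37         159       444.4202
```

Both planted 40 000-photon foci are recovered within ~2.5 % of their
integrated intensity and within a voxel of their positions.

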