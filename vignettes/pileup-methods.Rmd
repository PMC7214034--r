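---
title: "Pile-up analysis of Hi-C contact maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pile-up analysis of Hi-C contact maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A binned Hi-C map is a symmetric matrix of contact counts between genomic
bins, dominated by two nuisance structures: strong per-bin visibility
biases and a power-law decay of contact probability with genomic distance.
Individual point features — chromatin loops, domain boundaries — are rarely
distinguishable from noise at realistic depth. Pile-up analysis averages
many small 2D windows of the map centered on annotated positions; nuisance
variation averages out (or is divided out) and the mean feature enrichment
remains. `hicpileup` implements this analysis for single-resolution cooler
files, together with the simulator used to validate it.

# The pile-up model

Given windows $w$ with center bins $(i_w, j_w)$ and flank $f$, the raw
pile-up is the per-pixel mean

$$P_{a,b} = \frac{1}{N_{a,b}}\sum_w C_{\,i_w+a,\;j_w+b},$$

accumulated as a running sum plus a per-pixel count of finite
contributions. Two deliberate choices here:

- **Per-pixel denominator.** When balancing marks a bin invalid
  (non-finite weight), its pixels are *missing*, not zero — missing and
  "no contact" are different facts. The mean therefore divides by the
  per-pixel count $N_{a,b}$, not the window tally. When no bin is invalid
  the two coincide exactly (asserted by a test).
- **Edge policy.** A window that would cross a chromosome end is dropped
  entirely rather than padded with missing pixels, so all accumulated
  windows have identical shape and per-pixel counts stay comparable. All
  drops are tallied by reason and reported.

Accumulation is associative: per-chromosome accumulators are merged
field-wise, which is what makes chromosome-level parallelism exact (up to
float summation order; the contract is 1e-12 relative agreement, and tests
hold it).

# Normalization

**Balancing.** `.cool` balancing weights are consumed, never computed:
`balanced_value(i,j) = count * w_i * w_j`, with non-finite weights marking
whole rows/columns missing.

**Distance decay.** Two estimators of the expected value of a window:

1. *Chromosome-wide expected.* $d_k$ is the mean (balanced) value of
   diagonal $k$ — a mean over all pairs of valid bins, so structural zeros
   between valid bins count. Under a distance-only null the expected map is
   Toeplitz ($A_{i,j}=A_{i+1,j+1}=d_{i-j}$), so the expected window for any
   region is filled by index arithmetic alone, allocating only the window
   footprint. The normalizer is the element-wise *mean of expected windows
   over the same stream* (ratio of averages); per-window ratios are
   deliberately not offered, matching the procedure's order of operations.
2. *Randomly shifted controls.* Each source window is re-drawn `n_shifts`
   times at a shared random offset along the diagonal, preserving anchor
   separation exactly. Offsets are sampled uniformly over admissible
   positions: inside the chromosome and at least a minimum shift away from
   the source — one full window width for fixed-flank windows, a third of
   the span for rescaled windows (one feature length at the default
   padding), so a control never samples the feature it normalizes.
   Sampling directly from the admissible set replaces rejection retries
   and is uniform by construction. Controls inherit every active option
   (balancing, coverage normalization, rescaling), keeping numerator and
   denominator exchangeable.

On feature-free simulated maps both routes give central enrichments within
a few tenths of a percent of 1 and agree with each other well inside 5%;
with a small region set, the pixel variance of the control normalizer
scales as $1/(n_\mathrm{shifts}\cdot n_\mathrm{ROIs})$ — the measured
1-vs-10-shift variance ratio is 10 within sampling error.

**Coverage normalization.** For data that cannot be balanced (single-cell
maps), the pile-up is divided by the outer product of its mean flank
coverage profiles, each scaled to unit mean, where coverage is the
chromosome-wide total contact count of each bin. Simulations with planted
log-normal biases ($\sigma = 0.3$) show coverage-normalized unbalanced
pile-ups matching balanced ones within a few percent per pixel and
removing the sharp central cross that appears when regions sit on
high-visibility bins. Two caveats, both documented behavior: the method is
known to over-correct slightly and no correction factor is applied; and a
pixel where the *same* bin appears on both axes (windows closer than one
window width to the diagonal) cannot be corrected by coverage — for such
pixels $\mathbb{E}[b^2] \neq \mathbb{E}[b]^2$ — which is one reason
off-diagonal analyses use a minimum separation of at least one window
width.

# Pile-up variants

- **Pairs** (`bedpe`): one window per annotated anchor pair, canonical
  orientation, inclusive separation band in bp.
- **Combinations**: all unordered intra-chromosomal pairs of one region
  set. Self-pairs are excluded — they are on-diagonal and would contaminate
  the off-diagonal average.
- **Cross**: all intra-chromosomal pairs between two sets;
  identical-coordinate pairs excluded, unordered duplicates emitted once.
- **Local**: on-diagonal windows at region centers (insulation
  visualization).
- **Rescaled**: windows span each feature's extent plus `pad_fraction` of
  its length per side, then are resampled to a common odd `target_size`.
  Resampling is area-weighted (conservative): each output pixel is the
  overlap-weighted mean of the input pixels it covers — constants are
  preserved exactly, block structure maps to block means, same-size
  rescaling is the identity. Missing inputs are imputed with their matrix
  diagonal's mean before resampling (the natural sharing axis for
  distance-decaying data) and output pixels drawing more than half their
  weight from missing inputs are re-masked.
- **Anchored / loop-ability**: one region piled against all in-band
  partners; windows are transposed as needed so the anchor always occupies
  the row axis. The per-region score is the central pixel of the
  normalized anchored pile-up (a 3×3 option exists; the single pixel is
  the loop-ability convention, the 3×3 mean the dataset-level one — both
  are exposed with their respective defaults). Anchors without partners
  get a missing score, and anchors failing the corner-CV filter are
  flagged, never dropped.

A region's representative bin is the bin containing its midpoint
(`floor(((start+end)/2)/resolution)`) — deterministic for regions spanning
several bins. BED/BEDPE input is 0-based half-open; chromosome names are
matched exactly (no silent `chr`-prefix reconciliation — a mismatch is an
error naming both spellings, because silent renaming causes coordinate
bugs).

# Scoring and quality control

Dataset-level enrichment is the mean of the central 3×3 block; display
normalization divides by the mean of the 1-pixel top-left/bottom-right
corners; the lower-left corner mean captures intra-loop contact
enrichment. The noise filter computes the coefficient of variation (sample
SD over mean) of the 5×5 upper-left and lower-right corners and rejects a
pile-up when either CV is ≥ 0.5 — the boundary is inclusive on the failing
side, and the window must be at least 13×13 so corners cannot touch the
central 3×3. A corner with more than half its pixels missing has an
undefined CV and fails conservatively.

# The simulator

`simulate_contacts()` draws Poisson counts for the upper triangle of each
chromosome with mean

$$\lambda_{ij} = \text{depth} \cdot b_i b_j \cdot \mathrm{decay}(|i-j|)
  \cdot \mathrm{loop}(i,j) \cdot \mathrm{domain}(i,j),$$

where $\mathrm{decay}(k) = d_1 k^{-\alpha}$ for $k \ge 1$ (default
$\alpha = 1$, the canonical contact-decay exponent) and
$\mathrm{decay}(0) = 2\,\mathrm{decay}(1)$ for the self-interaction
diagonal, which is excluded from off-diagonal analyses anyway. Loops
multiply a footprint block (optionally a Gaussian focal peak normalized to
preserve the fold at its center), domains multiply a square block; features
stack multiplicatively. Biases are log-normal with median 1. Balancing
weights are either the exact inverse biases ($w_i = 1/b_i$) or iterative
correction run on the sampled counts to relative tolerance 1e-6. Poisson
(rather than negative-binomial) sampling is the simplest null consistent
with count data; overdispersion, compartment checkerboards, trans contacts
and single-cell binarization are deliberately not modeled — so passing
tests demonstrate correctness of the estimator machinery on a well-specified
null, not robustness to every structure of real maps. Sparse depth is
emulated through `depth_scale` instead.

The generator's ground-truth record (biases, planted features, weights,
and — for small genomes — dense sampled matrices) is what every recovery
test measures against, and the same seed always yields a byte-identical
pixel table.

# Numerical and design choices

- Windows, drop tallies and loop-ability output are tibbles; pile-ups are
  a small S3 class with `tidy()`/`glance()`/`autoplot()` methods. The
  contact map itself stays a sparse `Matrix` store — it is not tabular
  data.
- Cooler I/O uses `rhdf5` directly against the cooler schema. The pixel
  table of a chromosome is fetched in a single indexed read the first time
  that chromosome is touched (a fetch counter makes this testable);
  `bins/chrom` is written as an integer code column with the `chroms`
  table as lookup, a dialect noted in the file's provenance attributes.
- Division guards: a zero or missing normalizer pixel yields a missing
  output pixel (with a warning for zeros), never an infinity.
- Expected tables are long-format TSV with configurable column names,
  defaulting to the common `chrom`/`diag`/`balanced.avg` convention;
  missing diagonals stay missing and propagate.
- Validation problem sizes (chosen to make each statistical band sharp at
  desk scale): oracle checks on 2×300-bin genomes with dense ground truth;
  null calibration and shift-noise law on 2×1000-bin deep maps with 500
  and 50 ROI pairs; loop recovery with 500 planted fold-3 loops
  (3-bin footprints, so the 3×3 statistic sees the full fold) across
  4×1500 bins; coverage checks with 1000 ROIs across 4×1000 bins;
  domain recovery with 8 domains of 40–180 bins on their own 1200-bin
  chromosomes. For the domain interior/exterior ratio the expected route
  is used: interior and corner blocks of an on-diagonal rescaled window
  sample the same separations, so profile bias cancels; shifted controls
  would need chromosomes much longer than the window span to avoid
  re-sampling the domain itself (verified empirically — with 3000-bin
  chromosomes the control route recovers the same ratio).

# Known limitations

Trans (inter-chromosomal) pile-ups, strand-aware anchor flipping,
multi-resolution traversal, computing balancing weights, z-score distance
normalization and between-group significance testing of loop-ability
scores are out of scope. Coverage normalization inherits the over- and
under-correction behaviors described above. Performance is adequate for
annotation-scale inputs (10³–10⁵ windows) on a single core; the
per-chromosome `parallel` backend shortens wall time proportionally and is
exact by construction.
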