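---
title: "Methods: quantifying axonal mRNA localization with axonloc"
author: "axonloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying axonal mRNA localization with axonloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonloc)
```

## Scope and scientific setting

`axonloc` quantifies where mRNAs sit along the axons of *Drosophila*
Mushroom Body (MB) gamma neurons and how that localization relates to
binding by the Imp RNA-binding protein and to courtship memory. It covers
four analysis stages and one simulation stage:

1. **smFISH spot quantification** (`spot_quant` functions): detect
   diffraction-limited mRNA spots in 2D cell-body crops and 3D axonal
   stacks, segment the gamma lobe, and compute compartment-specific
   densities and the gamma5 enrichment ratio.
2. **Metatranscript profiling** (`metatranscript` functions): map iCLIP
   crosslink peaks from genomic to spliced transcript coordinates, rescale
   them onto a virtual 0–100 transcript, profile their density, and
   quantify 3'UTR crosslink signal per gene.
3. **Target gating** (`target_sets` functions): apply the gene-level
   filters of three assays (synaptosome RNA-seq, RIP, iCLIP), intersect
   them, and deduplicate GO terms by Jaccard distance.
4. **Behavior** (`behavior` functions): courtship indices and memory
   (courtship suppression) indices.
5. **Synthetic data** (`simulate_*` functions): generators for all inputs
   with known ground truth, so every stage is testable without any
   external download.

Upstream wet-lab and heavy-compute steps — read alignment, deduplication,
peak calling, differential-expression model fitting, microarray
normalization, video tracking — are consumed as tables, not reproduced.

## Image model and spot detection

### Coordinate conventions

Stacks are `(z, y, x)` arrays with voxel sizes 0.07 um in xy and 0.25 um
in z (high-resolution confocal acquisition). Voxel indices are 1-based in
R; physical positions are voxel centers, so voxel `i` reports
`(i - 0.5) * voxel` um, and mapping a reported position back to a voxel
(`um_to_voxel()`) recovers the source voxel exactly. Masks, spots and
axial coordinates all share this frame.

### Detection filter

Spots are detected with a scale-normalized anisotropic
Laplacian-of-Gaussian (LoG) filter. The stated spot extents — 0.4 um xy
diameter, 0.8 um z elongation — are treated as full widths at half
maximum, so the per-axis Gaussian sigma is `diameter / (2 sqrt(2 log 2))`
(about `diameter / 2.355`), converted to voxels with the voxel sizes. The
response is negated (bright blobs positive), clamped at zero, and divided
by its maximum over the image so that thresholds in (0, 1) are comparable
across images. The default threshold is 0.62, with 0.42 / 0.32 / 0.82 as
the probe-specific alternatives used in practice for cell-body crops; the
same threshold parameter is reused for 3D detection because no separate
3D quality cutoff is published.

In 2D, the thresholded response is labelled into connected components;
components smaller than 4 pixels are discarded and each survivor yields
one spot at its response-weighted centroid. In 3D, spots are
26-neighbourhood local maxima of the normalized response at or above the
threshold; plateau ties are broken toward the lowest `(z, y, x)` index so
detection is deterministic.

A consequence of max-normalization worth knowing: when two spots overlap
substantially their summed intensity sets the normalization maximum, and
isolated spots can fall below a high relative threshold. The detector is
therefore characterized (and guaranteed by tests) on fields of
*non-overlapping* spots; at planted densities where spots frequently
fuse, counts underestimate truth. This mirrors how interactive
spot-quality thresholds are tuned per experiment in commercial pipelines.

### Contrast rescaling

Cell-body crops are first contrast-rescaled so that a fixed fraction
(default 0.01%) of pixels saturates: intensities are mapped linearly from
`[min, q]` to `[0, 1]` with `q` the `1 - fraction` order-statistic
quantile, and values above `q` clip to 1. On an all-distinct-valued image
the clipped fraction equals the requested fraction to within one pixel.
Constant images are returned unchanged with a warning.

## Lobe segmentation and compartments

The reference channel is smoothed with a Gaussian at the surface-detail
scale (default 0.146 um per axis), thresholded automatically (Otsu, via
EBImage's histogram criterion), and reduced to its largest 6-connected
component with 3D cavities filled. The axial coordinate `s` of each mask
voxel is its projection onto the mask's first principal axis, min-max
normalized to `[0, 1]` and oriented so a user-supplied proximal anchor
point maps near 0. A principal axis (rather than a skeleton or medial
axis) is used because the analyzed region is tubular and only a monotone
proximal-to-distal coordinate is needed; for curved lobes a skeleton
estimator could replace it behind the same interface.

Compartment logic, with every threshold exactly as printed:

* **axonal spots**: in-region spots with `s >= 1/3` (the distal 2/3 of
  the lobe); samples with fewer than 10 axonal spots are flagged
  excluded (`included = FALSE`), the exclusion being applied after
  in-region and distal filtering;
* **gamma5 enrichment**: the lobe is split at `s = 2/3` into the distal
  gamma5 compartment and the proximal gamma2-4 remainder; spot densities
  (spots/um^3) are computed per part and reported as the gamma5 /
  gamma2-4 ratio. A zero proximal count leaves the ratio `NA` with an
  explicit reason rather than an infinity.

Counts and volumes partition exactly (`n_gamma5 + n_gamma24` equals the
in-region spot count; compartment volumes sum to the mask volume in
voxels).

Normalization of axonal spot counts across genotypes divides each
sample's count by the mean of its replicate batch's control samples. The
published figures do not state their normalization; this per-batch
control-mean convention is a deliberate, isolated choice
(`normalize_counts()`) that is scale-invariant and makes control means 1.

## Metatranscript analysis

### Reference construction

`build_reference()` retains, per gene, a single coding transcript model:
transcripts outside chromosomes X, Y, MT, 2L, 2R, 3L, 3R are removed,
then non-coding transcripts and transcripts flagged `incomplete` or
`unknown`, and finally the longest transcript per gene (summed exon
length) is kept, ties broken by the lexicographically smallest transcript
identifier so the choice is deterministic. The 5'UTR is the region
between mRNA start and CDS start, the 3'UTR between CDS end and mRNA
end, and `L5 + Lcds + L3 = L` holds exactly for every model.

### Coordinates and rescaling

Internally all coordinates are 0-based and half-open; GTF input (1-based,
closed) and BED input (0-based, half-open) are converted only at the I/O
boundary. `genomic_to_transcript()` is strand-aware (position 0 is the 5'
end on either strand) and reports intronic or flanking positions as
not-in-exon; it is the exact inverse of `transcript_to_genomic()` on
exonic positions. A position exactly at the CDS start belongs to the CDS
and one exactly at the CDS end to the 3'UTR (half-open regions; the
boundary convention is not printed anywhere and is fixed here for
consistency).

Rescaling maps 5'UTR, CDS and 3'UTR positions onto 0–19, 20–69 and
70–100 respectively: within a region of length `Lr` at region-local
offset `p`, `meta = lo + p/(Lr - 1) * (hi - lo)` (and `lo` when
`Lr = 1`). The first base of a region maps to the interval's lower bound
and the last base to its upper bound — the alternative `p / Lr`
convention is rejected because it can never attain the printed upper
endpoints (20/70/100 would be unreachable).

### Density profile

Transcripts contribute only if they carry at least 20 mapped significant
peaks. The pooled rescaled positions are profiled with a Gaussian kernel
density estimate on a fixed grid over `[0, 100]` (step 0.5), reflected at
both boundaries so the density integrates to 1 within 0.01 regardless of
how much mass sits near the edges. The bandwidth defaults to Scott's rule
(`sd * n^(-1/5)`) on the pooled positions, floored at half the grid step;
peaks are weighted equally, not by cDNA support. Neither the published
bandwidth nor any weighting is stated, so both are exposed as arguments
(`bandwidth`, `weight_by_count`) rather than silently fixed.

### 3'UTR quantification

`quantify_3utr()` counts, per gene and sample, the cDNA support of
crosslink sites whose spliced position falls in the 3'UTR — crosslinks in
the 5'UTR, CDS, introns, or on the wrong strand contribute nothing — and
normalizes samples with median-of-ratios size factors computed across all
samples jointly: for each sample, the median over all-nonzero genes of
the ratio between the sample's count and the gene's geometric mean. The
formula is implemented directly (it is the only piece of the
differential-expression machinery this pipeline needs) and is verified in
the test suite against `DESeq2::estimateSizeFactorsForMatrix` as an
independent reference.

## Target gating

Every inequality is implemented exactly as printed and pinned by boundary
tests:

| gate | rule |
|---|---|
| expression pre-filter | keep genes with CPM > 0.5 in at least 3 samples and at least one nonzero count |
| synaptic enrichment | `log2FC >= 0.85` and `padj < 0.05` (depleted: `log2FC <= -0.85`, `padj < 0.05`) |
| RIP robust list | `log2FC > 1` in **every** bound-vs-control comparison |
| iCLIP target | at least one significant peak supported by >= 5 unique cDNAs |
| overlap synaptosome arm | `log2FC > 0` |

`triple_overlap()` intersects the three gated sets. GO-term redundancy is
removed by clustering the pairwise Jaccard distance
`d(A,B) = 1 - |A∩B| / |A∪B|` with average-linkage hierarchical
clustering cut at height 0.5; each cluster reports the member with the
smallest summed distance as representative. The clustering algorithm and
cut are not published — only the distance is — so linkage and
`cut_height` are arguments with documented defaults.

## Courtship behavior

Recordings last 12.5 minutes and scoring starts at 2.5 minutes; the
courtship index (CI) is the fraction of frames with courting in the
half-open window `[2.5, 12.5)` min, frames assigned by their start time.
The full scoring window is used as the denominator (whether the published
denominator excludes inactive time is not stated). The memory index of a
trained male is `MI = 1 - CI_trained / mean(CI_naive)`: 1 for complete
suppression, 0 for naive-level courtship, negative (not clipped) when the
trained male courts more than the naive mean. Group comparisons are thin
wrappers over `t.test()` / `wilcox.test()` for reporting only.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for all tests:

* **Stacks** (`simulate_stack()`): a straight cylinder along x stands in
  for the curved medial lobe — the analysis only requires a monotone
  axial coordinate, and a straight tube is the simplest geometry
  satisfying that. Spots are anisotropic Gaussians of constant amplitude
  at Poisson positions with compartment-dependent densities (defaults
  0.5 spots/um^3, giving on the order of 100 spots in a 15 x 2 um lobe,
  the order of magnitude seen for well-localized transcripts); noise is
  additive Gaussian on a constant background (defaults: amplitude 100,
  background 20, noise 10, i.e. SNR 10; no published SNR exists, so
  these are detector-testing choices, not calibrated realism). Poisson
  shot noise is off by default behind a flag; an optional hard-core
  `min_spacing` thins overlapping positions for detector
  characterization. Not emulated: curved geometry, optics-grade PSFs,
  spectral bleed-through, intensity variation between molecules — so
  passing tests certify the algorithmic pipeline, not robustness to
  every imaging artifact.
* **Annotations** (`simulate_annotation()`): 2–6-exon coding transcripts
  on both strands of the seven reference chromosomes with 5'UTR/CDS/3'UTR
  lengths of 50–300 / 300–1500 / 100–800 nt, and peaks placed uniformly
  within a region drawn from `region_bias` (default `(0.05, 0.15, 0.80)`,
  reflecting strongly 3'UTR-skewed binding). Every peak lies in an exon
  by construction on either strand.
* **Assay tables** (`simulate_assay_tables()`): planted targets pass all
  three gates by construction; every non-target is forced to fail at
  least one randomly chosen gate, so the triple overlap recovers the
  planted set exactly — this is the oracle for the gating logic.
* **Courtship** (`simulate_courtship()`): naive indices around
  `naive_mean` (default 0.6) and trained indices around
  `naive_mean * (1 - suppression)`, Gaussian noise (default sd 0.15),
  clipped to `[0, 1]`; complete suppression yields exactly zero. Group
  sizes default to 30, typical of conditioning cohorts.

One integer seed drives everything; per-component sub-streams are derived
deterministically from it and the caller's RNG state is restored, so a
fixed configuration is reproduced byte-for-byte.

## Numerical choices and degenerate inputs

* Filters use replicate padding; kernels truncate at 4 sigma.
* Otsu thresholding refuses constant images (explicit error rather than
  an arbitrary mask).
* Local-maximum plateau ties and longest-transcript ties are broken
  deterministically (lowest index / smallest identifier).
* Undefined ratios (zero proximal count) and undefined Jaccard distances
  (two empty sets) are surfaced as `NA`-with-reason and errors
  respectively, never as infinities.
* Stacks thinner than one z filter support are rejected with the minimum
  depth named.

## Problem sizes used by the test suite

The suites run at desk scale by choice: detection is characterized on a
25 x 2 um lobe with ~100 well-separated spots; ratio recovery uses
planted gamma5:gamma2-4 ratios of 1, 2 and 3 with >= 300 in-region spots
per realization, 20 seeds each, recovered within 15% in the median;
coordinate round-trips use 1000 random positions per strand; Poisson
planting is checked over 50 seeds at expectation 100. Dataset-scale
headline numbers (hundreds of enriched genes, ~1600 iCLIP targets)
require the original deposited sequencing data and are outside what
synthetic desk-scale runs can or should reproduce.

## Known limitations

* The relative response threshold couples detection to the brightest
  object in the field; dense or fused spot fields need a lower threshold
  or spacing-aware simulation (see above).
* The principal-axis axial coordinate assumes an elongated, roughly
  straight region.
* Published normalization of axonal counts and GO clustering parameters
  are unstated; the package's conventions are documented defaults, kept
  in single, easily replaced operations.
* `min_spacing` hard-core thinning changes realized densities relative
  to the nominal Poisson intensities (stronger where spots are denser),
  so enrichment ratios should be compared against the realized ground
  truth, which the generator returns.
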