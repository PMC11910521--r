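# axonloc

Quantitative analysis of axonal mRNA localization in *Drosophila*
Mushroom Body (MB) gamma neurons.

Localized mRNAs are visible by single-molecule FISH as diffraction-limited
spots along the MB gamma lobe; their positions, binding by the Imp
RNA-binding protein (mapped at nucleotide resolution by iCLIP), and the
behavioral consequences of mislocalization (courtship memory) together
describe how axonal RNA transport supports long-term memory. `axonloc`
implements the quantitative pipeline for these analyses, plus synthetic
generators with ground truth so the whole pipeline is testable end to end
on a laptop, with no external data.

## What it computes

**smFISH spot quantification.** Spots are detected with a scale-normalized
anisotropic Laplacian-of-Gaussian filter (xy FWHM 0.4 um, z FWHM 0.8 um;
relative threshold 0.62 by default, 4-px component cutoff in 2D). The
gamma lobe is segmented from a reference channel (Gaussian smoothing at
0.146 um, Otsu threshold, largest component) and each voxel gets a
proximal-to-distal axial coordinate *s* in [0, 1] from the mask's
principal axis. Axonal spots are those with *s* ≥ 1/3 (distal 2/3 of the
lobe; samples with fewer than 10 are excluded), and compartment enrichment
is

    ratio = density(gamma5) / density(gamma2-4)
          = [n(s >= 2/3) / vol(s >= 2/3)] / [n(s < 2/3) / vol(s < 2/3)]

in spots/um^3.

**Metatranscript profiling.** One coding transcript model per gene
(chromosomes X/Y/MT/2L/2R/3L/3R, longest transcript, ambiguous and
non-coding dropped); strand-aware spliced genomic-to-transcript mapping;
positions in 5'UTR / CDS / 3'UTR rescaled onto 0–19 / 20–69 / 70–100 of a
virtual transcript; Gaussian KDE (boundary-reflected, unit integral) of
pooled peak positions from transcripts with ≥ 20 significant peaks; and
per-gene 3'UTR crosslink counts normalized by median-of-ratios size
factors.

**Target gating.** Synaptically enriched: log2FC ≥ 0.85 and adjusted
p < 0.05. RIP targets: log2FC > 1 in every comparison. iCLIP targets:
≥ 1 significant peak with ≥ 5 unique cDNAs. Candidate Imp-dependent
axonal mRNAs: triple overlap with the synaptosome arm at log2FC > 0.
GO-term redundancy is removed by average-linkage clustering of Jaccard
distances d(A,B) = 1 − |A∩B|/|A∪B|.

**Behavior.** Courtship index = fraction of the [2.5, 12.5) min window
spent courting; memory index MI = 1 − CI_trained / mean(CI_naive).

## Worked example

Simulate a lobe with a 3:1 distal:proximal planted density contrast, then
recover the enrichment with the full pipeline:

```r
library(axonloc)

cfg <- simulation_config(seed = 8L, lobe_length = 18, lobe_radius = 2,
                         density_proximal = 0.4, density_distal = 1.2,
                         min_spacing = 0.8, noise_sd = 10)
sim <- simulate_stack(cfg)
sim$stack
#> ImageStack: 21 x 75 x 275 voxels (z, y, x), 0.07 x 0.25 um
#> channels: lobe, smfish

spots <- detect_spots_3d(sim$stack)
nrow(spots)           # planted: 101
#> [1] 100

region <- segment_lobe(sim$stack,
                       proximal_anchor = c(0, sim$truth$origin["y"],
                                           sim$truth$origin["z"]))
region
#> LobeRegion: 178620 voxels, 218.8 um^3, axis (1.00, -0.00, 0.00)

inside <- filter_spots_in_region(spots, region)
count_axonal(inside, region)
#> $n_axonal [1] 72    $included [1] TRUE

compartment_ratio(inside, region)
#> CompartmentQuant: gamma5 47 spots / 73.1 um^3, gamma2-4 51 / 145.7, ratio 1.84
```

The detected enrichment (1.84) matches the realized ground truth of this
realization (1.80, from `sim$truth$spots`): the hard-core `min_spacing`
thinning attenuates the nominal 3:1 Poisson intensity contrast, and the
pipeline recovers what was actually planted to within 2%.

Metatranscript, gating and behavior stages on synthetic inputs:

```r
ann  <- simulate_annotation(n_genes = 30, region_bias = c(0.05, 0.15, 0.8),
                            seed = 2L)
prof <- metaprofile(ann$models, ann$peaks, min_peaks = 20)
prof
#> MetaProfile: 805 peaks on 30 transcripts, bandwidth 5.98
sum(prof$density[prof$grid >= 70]) / sum(prof$density)  # mass in the 3'UTR interval
#> [1] 0.748

tab <- simulate_assay_tables(n_genes = 100, n_targets = 9, seed = 3L)
triple_overlap(tab$synaptosome_stats, rip_gate(tab$rip_stats),
               gate_iclip_targets(tab$iclip_peak_support))
#> OverlapResult: synaptosome 52, RIP 12, iCLIP 55; triple overlap 9

cd <- simulate_courtship(n_naive = 30, n_trained = 30, naive_mean = 0.6,
                         suppression = 0.4, seed = 4L)
mean(memory_index(cd$trained_cis, cd$naive_cis))
#> [1] 0.458
```

The triple overlap returns exactly the 9 planted targets, and the mean
memory index of the trained group sits near the planted suppression of
0.4.

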