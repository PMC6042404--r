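---
title: "Methods: canyon calling, differential methylation, and the DNMT3A1/TET1 binding landscape"
author: "canyonscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canyon calling, differential methylation, and the DNMT3A1/TET1 binding landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`canyonscape` re-implements, as a tested pipeline, the computational
procedures used to characterize large under-methylated regions
("canyons") in mouse embryonic stem cell methylomes and the complementary
chromatin-binding landscapes of the de novo methyltransferase isoform
DNMT3A1 and the dioxygenase TET1: WGBS read-level bias filters and
per-CpG methylation ratios, two-state HMM segmentation into UMRs and
canyons, beta-posterior credible-difference DMC/DMR calling,
depth/input/spike-in occupancy normalization, genomic-window enrichment
with satellite and coverage exclusions, the signed log10-P differential
occupancy score, scaled meta-profiles, CpG-density-stratified binding
with crossing-point estimation, and k-means clustering of promoter
occupancy (G1–G5) and differential-expression patterns (C1–C7).

Read alignment, peak calling, multi-read EM allocation, and
differential-expression testing are out of scope; their outputs (read
observations, peak BEDs, FPKM tables with DE labels) are consumed as
inputs. Because full WGBS/ChIP-seq datasets are not desk-scale, all
quantitative validation runs on a seeded synthetic benchmark that
mirrors the statistical structure of such experiments; the generator is itself first-class,
tested code.

# Methylome model and read-level filters

A methylome is a table of per-CpG counts `(chrom, pos, meth, total)`
with `ratio = meth / total`; zero-coverage sites are flagged `NA`, never
imputed as 0. Three read-level filters precede the pileup:

* **M-bias trimming** (`mbias_trim()`): base calls within `n_bases`
  (default 3) of the flagged repair end of a read are dropped. The
  repair end is modeled as an explicit flag on the read record; in
  practice it is diagnosed from an M-bias plot, which we reduce to this
  parameter.
* **Clonal filtering** (`clonal_filter()`): at most `max_dup` reads are
  kept per `(chrom, start, strand)`, where `max_dup` is the smallest
  `k` with upper Poisson tail `P(X >= k+1) < 1e-5` at the genome-wide
  mean start rate. Retention is deterministic (input order). At typical
  ChIP depths this yields the familiar "keep at most two clonal reads"
  regime. The duplicate key is a documented choice; common duplicate
  definitions use start + strand.
* **Mate-overlap exclusion** (`mate_overlap_dedup()`): a CpG covered by
  both mates of a pair is counted once, taken from the mate that still
  carries the position after trimming (ties: first mate).

Pileup pools calls per CpG with strands collapsed — the plus-strand C
anchors the coordinate. Strand pooling is our convention; sites are
0-based half-open throughout.

# Segmentation into UMRs and canyons

`segment_methylome()` decodes a two-state hidden Markov model over the
per-CpG counts. Emissions are binomial with state-specific methylation
probabilities, initialized at 0.05 (low) and 0.75 (high) and
re-estimated by Baum–Welch (deterministic initialization, no random
restarts, at most 50 iterations, relative log-likelihood tolerance
1e-4); transitions are initialized sticky (0.98/0.999 self-transition)
and re-estimated. Decoding is posterior (not Viterbi) with a 0.5
threshold; ties fall to the high state, which is the conservative
direction for region calling. Runs of low-state CpGs become candidate
segments spanning first to last CpG; runs are broken at CpG gaps above
`max_cpg_gap` (default 2 kb) so CpG deserts are never bridged, and a
candidate is kept only if its coverage-weighted mean methylation is at
most `max_region_meth` (default 0.10). The 10% rule could be read per CpG or
per region; we apply it as a region-mean filter on decoded segments and
document that choice. Region extent is the CpG-to-CpG span;
we do not extend calls into flanking CpG-free sequence.

Classification follows the standard length classes: segments shorter
than 1 kb are discarded, 1–3.5 kb are UMRs, and at least 3.5 kb are
canyons. Canyon edges are the 2-kb flanks on each side, truncated at
chromosome bounds.

# Differential methylation

For two samples with counts `(m1, t1)` and `(m2, t2)` at a CpG, the
**credible difference** is the conservative bound of the equal-tailed
95% credible interval of `p2 - p1` under independent
`Beta(m + 1, t - m + 1)` posteriors: the lower bound when the interval
sits above zero, the upper bound when below, and exactly 0 when the
interval spans zero. MOABS popularized this statistic; ours is an independent definition
validated against a grid-integration oracle in the test-suite, not a
bit-compatible reproduction of that tool.

The interval is computed by Monte Carlo over posterior draws with a
fixed seed. The default of 40,000 draws per site is chosen so that the
worst-case disagreement with the grid oracle over a coverage grid
(t in {3, 10, 30, 100}) stays below 0.01 — the agreement the
test-suite asserts. Each pair of sites is
evaluated in a canonical order and sign-flipped, which makes
antisymmetry under sample swap exact rather than approximate.

DMCs require at least 3 reads in *both* samples (the "one or both"
question is unstated upstream; we require both) and
`|cdif| >= 0.2`. DMRs are maximal runs of at least 4 same-direction
DMCs (the strict reading of "more than three") with adjacent spacing within
300 bp; intervening non-DMC CpGs do not break runs, opposite-direction
DMCs do. All of these are `dm_params()` fields.

A consequence worth stating plainly: with this conservative statistic,
the exact detection power at a true difference of 0.5 and 30x coverage
is about 0.68 for a central pair (0.25 vs 0.75) and at most 0.90 over
all pairs 0.5 apart (grid-oracle enumeration). A 90% detection rate at
that effect size is therefore not achievable by any correct
implementation of the statistic as defined; the test-suite records this
as an expected failure and instead verifies that the empirical power
matches the oracle-exact value, and that the statistic's power at the
UMR-scale contrast (0.05 vs 0.75) — the contrast region calling relies
on — exceeds 99% by the same enumeration.

# Occupancy normalization and comparisons

Occupancy tracks are fixed-width binned signals (10-bp default).
`normalize_track()` scales each track to a common total tag count,
subtracts the matched input bin-wise, and floors at zero (occupancy
cannot be negative; the floor is our choice). This is a deliberate
simplification of the DANPOS-style workflow: tracks arrive already
binned and no fragment-size estimation is performed; every claim
exercised here depends only on depth/input/spike handling. Spike-in
factors are `reference_count / spike_count` from exogenous chromatin
tags and compose multiplicatively.

Genome-wide statistics use 1-kb tiling windows; windows touching
satellite repeats (by >= 1 bp — overlap rather than full
containment, a documented choice), windows with no WGBS-covered CpG, and windows with no
input signal are excluded. Feature enrichment is the mean
included-window signal of a class over the mean of all included windows
(windows are assigned by midpoint containment and classes may overlap),
reported on the log2 scale.

Differential occupancy between a knockout and its reference is scored
per bin as `sign(A - ref) * |log10 P|`, with `P` the upper-tail Poisson
probability of the larger value given the smaller as expectation. The
exact test inside DANPOS is not reproduced here; this Poisson
formulation is a documented stand-in whose sign,
antisymmetry, and monotonicity are what downstream figures rely on.
`|log10 P|` is capped at 300 to avoid infinities.

# Meta-profiles, density stratification, and peak coordinates

Scaled region profiles resample each region's body to 100 bins by
linear interpolation and attach fixed-width flank bins (5 kb for
canyons, 3 kb for gene bodies; both parameters), averaging across
regions with equal weight so long regions do not dominate. TSS matrices
are strand-oriented (minus-strand rows reversed) with off-chromosome
positions missing, excluded from means and entered as 0 only when
feeding k-means.

For density stratification, included windows are ranked by CpG density
and cut into equal-count (rank-based) bins, each
recording mean density and per-track enrichment relative to that
track's own included-window mean. The crossing point of two tracks is
located by linear interpolation between the adjacent bin centers where
the enrichment difference changes sign.

Peak-relative coordinates map a position to `u = (pos - center) /
half_width`, so the center is 0 and the edges are ±1, extended linearly
outside; DMR midpoints are assigned to the peak with the nearest center
(ties: lower coordinate) and histogrammed as a density.

Promoter CpG density counts CpGs in the strand-aware window
`[TSS - 1 kb, TSS + 0.5 kb)` per 100 bp; windows truncated at
chromosome bounds use the truncated length.

# Clustering

`kmeans_tss_groups()` concatenates row-aligned binned profiles (by
default DNMT3A1, DNMT3A2, DNMT3B1 over TSS ± 5 kb) and runs seeded
k-means (k = 5, 10 restarts, best inertia, 300-iteration cap). Genes
are sorted by id first, so input order cannot change assignments, and
groups are relabeled by descending central signal of the first track —
no canonical ordering exists for such group labels, so this is
a package convention that makes labels stable under center
permutation. If the data carry fewer distinct rows than k, the
effective k shrinks and the remaining groups are flagged empty.

`deg_clusters()` takes per-gene FPKM across the four genotypes (WT,
Dnmt3a-KO, Tet1-KO, double KO), restricts to DE-flagged genes,
log2-transforms (`+1`), standardizes per gene, and clusters into k = 7
condition patterns. Clusters are relabeled by descending double-KO
shift (ties: Dnmt3a-KO, then Tet1-KO shift), which places
"up in both knockouts" first and "down in both" last. This clustering is
sometimes described as hierarchical in figure-level summaries of such
analyses; k-means is what is implemented here. Constant-expression
genes are excluded with a warning. DE testing itself is out of scope;
the `de` flag is an input.

# The synthetic benchmark

`sim_config()` defaults describe the validation conditions: one 20-Mb
chromosome, CpGs from an inhomogeneous Bernoulli process (background 1
per 100 bp, island-like stretches at 8, shores at 3), 30 planted
canyons (4–9 kb) and 100 planted UMRs (1.2–3.2 kb) hypomethylated to a
mean of 0.03 on a 0.75 background, beta-binomial dispersion 0.02,
Poisson 30x coverage. Knockout conditions plant the directional
effects: Dnmt3a loss lowers the background by 0.12, extends planted
regions by 400 bp per side, and activates latent regions (90
canyon-like, 100 UMR-like, at 0.45 in WT) — canyon/UMR expansion;
Tet1 loss adds +0.15 methylation in the 2-kb flanks of planted regions
and doubles the height and width of DNMT3A1 peaks while removing TET1
signal. The knockout magnitudes are free parameters of the generator —
only their directions are established biology — chosen once at values
a methylome analyst would consider a strong but realistic perturbation,
and documented here rather than claimed as measured values.

Occupancy tracks are baseline plus (i) a shared saturating CpG-density
response, increasing for TET1 and decreasing for DNMT3A1, (ii) Gaussian
DNMT3A1 peaks centered 1 kb outside planted region boundaries (sd
600 bp), and (iii) promoter/gene-body peaks whose heights follow five
planted promoter archetypes (G1 bivalent DNMT3A1/TET1-bound, G2
TET1/H3K4me3-high and most expressed, G3 CpG-poor DNMT3A2-bound and
least expressed, G4 gene-body DNMT3B1, G5 background). The planted
crossing of the two normalized density-response curves at 1.5 CpG per
100 bp is enforced by calibrating the response midpoint against the
realized window-density distribution (a pure intensity offset cannot
move the normalized crossing there, because normalization is
scale-invariant); the calibration is deterministic and cached per
genome. Expression plants seven DEG archetypes with condition shifts in
units of 2 log2-fold (C1/C5 additive in the double knockout, C2/C6
Tet1-specific, C3/C4/C7 Dnmt3a-specific) on archetype-dependent
baselines.

All randomness flows from one master seed through deterministic
per-chromosome sub-streams, so identical config + seed gives
byte-identical outputs and chromosome order does not matter.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: raw reads and alignment artifacts beyond the
three modeled filters, non-CpG methylation, copy-number and mappability
structure, fragment-size effects in ChIP, batch effects, and any
biological coupling between methylation and expression beyond the
planted archetypes. Recovery rates on this benchmark measure the
correctness of the algorithms under the stated noise model, not
expected performance on arbitrary methylomes.

# Problem sizes and runtime choices

The acceptance workload uses the full 20-Mb benchmark for segmentation,
genotype comparison, crossing-point recovery, and clustering; the
differential-methylation error-control checks use 10,000 null sites and
1,000 alternative sites at 30x; the oracle-agreement grid spans
t in {3, 10, 30, 100} with five methylated-count levels each; DMR merge
combinatorics are enumerated exhaustively for up to 6 DMCs. Unit tests
run the same machinery on 0.5–5-Mb genomes. Forward–backward and the
Monte-Carlo interval sampler are implemented in C++ (via Rcpp), which
keeps a full-genome segmentation in seconds and the 10,000-site null
calibration in about two minutes on one core.

# Known limitations

* The credible difference is a re-definition, validated against its own
  oracle; it is not guaranteed to match MOABS numerically.
* The Poisson differential-occupancy test is a stand-in with the right
  sign/monotonicity behaviour; its P values should not be interpreted
  as calibrated significance on real data.
* The HMM assumes binomial emissions within state; overdispersed real
  data may need the beta-binomial dispersion built into the simulator
  but not into the decoder.
* Window/feature assignment is midpoint-based; features smaller than
  half a window can be missed.
* TSS-associated peak selection (for peak-coordinate analyses) uses a
  ±1-kb center-to-TSS rule, configurable; there is no
  canonical threshold.
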