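---
title: "Read-depth CNV calling, CNVR annotation and V_ST scans with rdcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling, CNVR annotation and V_ST scans with rdcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

`rdcnv` implements a window-based read-depth pipeline for copy number
variation (CNV) discovery in multi-sample whole-genome sequencing cohorts,
of the kind used to survey structural variation in livestock populations
(e.g. cattle breeds sequenced at ~15X), together with the population-level
summaries that usually follow such a survey: merged CNV regions (CNVRs),
genic and QTL annotation, breed-sharing sets, a V~ST~ differentiation scan,
and qPCR relative-quantification arithmetic for wet-lab validation.

The underlying model is simple and deliberately so. If reads of fixed length
$L$ start uniformly at rate proportional to the local copy number $c$, the
number of read midpoints falling in a window of width $w$ is Poisson with
mean $\lambda = \bar d \, w / L \cdot (c/2) \cdot b(\mathrm{GC}) \cdot s$,
where $\bar d$ is the diploid mean depth, $b(\cdot)$ a multiplicative GC-bias
curve and $s$ a per-sample library-size factor. Everything the pipeline does
is an attempt to invert this relationship: estimate and divide out
$b(\mathrm{GC})$ and $s$, so that the normalized depth of a window estimates
$c/2$ — 1.0 for diploid, 0.5 for a heterozygous deletion, 0 for a homozygous
deletion, 1.5 and up for duplications.

### Windowing

The genome is tiled with overlapping sliding windows of `window_size` (800 bp
by default) starting every `step` bp. The overlap step is not dictated by the
800 bp convention itself; we default to half a window (400 bp), which halves
the boundary quantization error of calls at the cost of correlated counts in
adjacent windows. Each read is assigned to every window containing its
midpoint (`start + length %/% 2`, 0-based half-open), so each read is counted
once per window *layer* and per-window counts stay Poisson. Windows truncated
at a chromosome end are masked: their counts are not comparable to full
windows and would break the exact CN/2 identity on noise-free data.

### GC correction and normalization

GC bias is corrected per sample by bin-median rescaling: windows are grouped
into equal-width GC bins, and counts in bin $b$ are multiplied by
$m^\ast / m_b$, where $m_b$ is the bin median and $m^\ast$ the *median of the
per-bin medians*. Using the median-of-medians rather than the pooled global
median as the reference is a deliberate choice: after one pass every bin
median equals $m^\ast$ exactly, so a second pass multiplies by 1 — the
correction is exactly idempotent, which makes the "already corrected" state
testable rather than approximate. Bins with fewer than `min_bin_windows`
windows (default 20) or a zero median are left uncorrected.

Sample normalization divides each sample's corrected counts by the median
over usable windows, pinning the diploid baseline at 1.0. The median (not the
mean) is used so that a sample's own CNVs cannot drag its baseline.

A window is *usable* when it is full width, its GC lies in
`[gc_min, gc_max]` (default [0.2, 0.8]), at least `usability_min_fraction`
(default 50%) of samples have a nonzero count in it, and its across-sample
median relative depth lies within `depth_rel_bounds` (default [0.05, 3]).
Two details matter here. First, the across-sample *median* is used so that a
CNV carried by a minority of samples cannot mask its own windows. Second, the
depth screen is an absolute range, not a top/bottom quantile trim: on a small
genome a rank-based trim inevitably lands on the windows of the
highest-carrier-frequency CNVs — they *are* the most extreme windows — and
silently deletes true signal. The absolute range keeps the intent (drop
collapsed-repeat-like or unmappable-like windows) without punishing
extremeness per se. The relative depths are computed against provisional
per-sample baselines, so the mask is invariant to library size.

### Calling and CNVR merging

Per unmasked window and sample, normalized depth `nd` is classified as
homozygous deletion (`nd < 0.2`), heterozygous deletion (`0.2 <= nd < 0.7`),
duplication (`nd > dup_floor`), else neutral. The deletion thresholds 0.2 and
0.7 follow the read-depth calling convention this pipeline reimplements; only
the deletion side is specified there, so the duplication floor defaults to
`2 - 0.7 = 1.3` by symmetry around the diploid level and is configurable.
The lower boundary is half-open (exactly 0.2 is het) purely for deterministic
tie-breaking. Maximal same-direction runs (het and hom deletion states may
mix; deletion and duplication never join) tolerate up to `max_gap_windows`
(default 1) neutral or masked windows, and runs of fewer than `min_windows`
(default 2) CNV windows are dropped. Deletion segments are restated from the
segment mean (`hom_del` below 0.2), so the per-window thresholds are also
enforced at segment level.

Calls are merged across samples into CNVRs by iterative agglomeration per
chromosome, left-to-right by start, repeated to a fixed point. Two candidate
regions merge iff (a) their gap is less than `merge_gap_fraction` (default
0.2) of their combined length — overlapping regions pass automatically — and
(b) the Pearson correlation between the regions' per-sample mean normalized
depth vectors is significant at `corr_alpha` (default 0.01), tested two-sided
via the t statistic with $n-2$ degrees of freedom. The correlation condition
is what prevents two *different* polymorphisms that happen to sit close
together from being fused: their carrier patterns across samples are
independent, so their depth vectors do not correlate. With fewer than 4
samples the test is undefined and merging falls back to the gap rule with a
warning. The fixed-point property (re-merging the output changes nothing) is
asserted in the test suite.

CNVRs are then filtered to carriers in at least `min_samples` samples and to
placed chromosomes when a whitelist is given. The carrier threshold defaults
to 2 ("at least two animals"); a stricter "more than two samples" reading is
available as `min_samples = 3` — surveys in this area state both, and we do
not claim either is canonical. A CNVR is a deletion if all carrier states are
deletion-type, a duplication if all are duplication-type, and mixed
otherwise.

### Annotation

Genic context uses a single-label precedence — exonic if the CNVR intersects
any exon by ≥ 1 bp, else intronic if it intersects a gene body, else
intergenic — so the three classes partition the CNVR set, matching the
mutually exclusive percentages such surveys report. UTR and ncRNA features
are folded into "exonic" unless filtered by biotype. Size bins are half-open
kb intervals (1–2, 2–5, 5–10, > 10 kb, plus an explicit < 1 kb overflow bin).
Breed sharing assigns a CNVR to every population with ≥ 1 carrier and reports
all $2^k - 1$ Venn cells. QTL overlap requires ≥ 1 bp intersection; because
one CNVR can hit QTLs of several trait categories, category percentages are
shares of QTL *hits* (they can exceed 100% of overlapping CNVRs, as in the
published tables this mirrors). Cross-study comparison reports the count and
percentage of one set's regions overlapping the other, with an optional
reciprocal-overlap fraction. Interval intersection is delegated to
`GenomicRanges`; the test suite checks it against a brute-force pairwise
scan.

### V~ST~

For each CNVR the per-sample copy number is `2 x` mean normalized depth over
the region's unmasked windows (continuous, not rounded). Between a focal
population and the pooled remainder,
$$V_{ST} = (V_T - V_S) / V_T,$$
with $V_T$ the variance of the pooled copy numbers and
$V_S = (n_1 v_1 + n_2 v_2)/(n_1+n_2)$ the population-size-weighted mean
within-group variance. Variances are population variances (ddof = 0), the
convention of the original copy-number $V_{ST}$ formulation; the
sample-variance estimator is exposed as an option since either can be argued
(the two disagree slightly, and the sign of $V_{ST}$ near zero can differ —
the documentation's worked case `{2,2,4}` vs `{2,4,4}` gives $+1/9$ with
ddof 0 and $-1/9$ with ddof 1). $V_{ST} = 1$ iff the groups are internally
constant and different; 0 means no between-group structure; slightly negative
values are real and retained. Regions with $V_T = 0$ carry no signal, are
flagged undefined, and are excluded from ranking. The top tail
(`vst_top_fraction`, default 5%) is selected with ties at the threshold
included.

### qPCR validation arithmetic

Replicate Ct values are mean-summarized; per sample
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}$, and against the
diploid calibrator ("standard") sample
$\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}$, giving copy
number $2 \times 2^{-\Delta\Delta Ct}$ under the assumption of exactly
doubling amplification per cycle. Class boundaries for the verdict — loss at
CN ≤ 1.5, gain at CN ≥ 3.0, normal between — are taken from the verbal
reading of published validation figures ("around 0 or 1" is a loss, "around
three or higher" a gain, "2 signifies normal") and are configurable. Note
that a CN = 3 duplication sits exactly on the gain boundary: with realistic
Ct noise roughly half its estimates fall below 3.0, so single-copy
duplications are intrinsically the hardest class to validate — the analysis
scripts reproduce exactly this failure mode.

## The synthetic cohort generator

Because the real data for such a survey is hundreds of gigabytes of
sequencing, every stage here is exercised on a synthetic cohort with planted
truth. The generator emulates: a multi-chromosome toy genome (default
2 × 2.5 Mb) with a smooth GC track; 3 populations × 10 samples; 15X mean
depth with Poisson counts per 400 bp bin; a unimodal multiplicative GC bias
peaking at GC = 0.5 (`gc_bias_strength`, default 0.5); log-normal per-sample
library scales (sd 0.1) so normalization has real work to do; and 45 planted
CNVs of 1.6–8 kb with carrier frequencies drawn from [0.15, 0.4], 80% of
deletion carriers heterozygous (so both the 0.2 and the 0.7 thresholds are
exercised) and 20% of duplication carriers at CN 4. Two events are planted
population-differentiated (carrier frequency 0.9 in the focal population,
0.02 elsewhere) for the V~ST~ scan to recover. Events are aligned to the
window step grid and separated by ≥ 10 kb so that distinct events can never
satisfy the merge gap rule; the per-sample depth variance across libraries is
a free parameter (real cohorts do not publish it), set to a modest 10%.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data — includes: mappability structure and repeats,
alignment artifacts, GC bias that varies between libraries, non-uniform
insert sizes, segmental-duplication CN polymorphism beyond CN 4, and
reference errors. The noise-free mode (`noise = "none"`, zero GC bias, unit
scales) makes the depth model exactly invertible and is used to assert exact
identities (normalized depth = CN/2 on all unmasked interior windows).

Recovery against planted truth counts an event as recovered when a called
CNVR of compatible type matches both boundaries within one window step. The
recall denominator is events with ≥ `min_samples` carriers: an event below
the pipeline's own carrier filter is unrecoverable by construction, which is
a property of the filter, not of the detector.

## Problem sizes and numerical choices

The bundled analyses and the heavier test suites run the full pipeline on a
5 Mb genome with 30 samples at 15X (≈ 22 million simulated reads, 12,500
windows) — large enough that Poisson noise, GC bias and library-size spread
are all material, small enough to run in seconds. At these settings a window
carries ≈ 120 reads, so the het-deletion gap (60 reads) is a ≈ 5.5σ
separation and per-window state errors are rare; single-window flukes are
additionally suppressed by the 2-window minimum, and single-sample artifacts
by the 2-carrier filter.

Other numerical choices: coordinates are 0-based half-open internally
(1-based only in human-readable output); percentages are rounded half away
from zero (2 decimals unless stated); the top-fraction threshold is the
k-th largest value with $k = \max(1, \lfloor fn \rfloor)$ and ties included;
zero-variance depth vectors in the merge test fall back to an
identical-profile check; and all generator randomness is seeded (identical
config + seed gives byte-identical outputs, asserted in the tests).

## Known limitations

* Single-evidence calling: read depth only, no split-read/paired-end or
  assembly evidence, no genotype likelihoods — by design, as in the surveys
  this mirrors.
* Boundary resolution is limited to one window step; events shorter than two
  windows are invisible.
* The duplication floor (1.3) is a symmetry convention, not an estimated
  threshold; CN 3 mosaics or contamination shift depth ratios in ways the
  pipeline does not model.
* The correlation condition of the merge rule needs ≥ 4 samples and assumes
  approximate normality of per-region mean depths across samples.
* Gene-level V~ST~ summarization for genes spanning several CNVRs is
  reported per-CNVR here; a gene-level maximum is a thin wrapper away but no
  canonical summary exists.
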