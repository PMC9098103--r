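---
title: "Calling large-scale copy number variants from methylation-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling large-scale copy number variants from methylation-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcnv)
```

## The problem

Two-channel methylation arrays (450k/EPIC-class) measure a methylated
(green) and an unmethylated (red) fluorescence intensity per CpG probe.
Although designed for methylation, the *combined* intensity of the two
channels tracks local DNA copy number, so the same library yields both an
epigenetic and a genetic readout. This matters most for large-scale
chromosomal lesions that define tumor entities: the deep 3p deletion of
clear cell renal cell carcinoma and the 1p/19q codeletion that molecularly
defines classical oligodendroglioma. `methylcnv` implements a complete,
self-contained workflow from raw two-channel intensities to segmented,
state-called CNV tables, cross-sample consensus regions, and an
overlap-based recall benchmark against gold-standard segment sets — with a
synthetic-cohort generator so the whole chain is testable without any
external data.

## The signal model

For probe $p$ in test sample $s$, the copy-number signal is the total
in-band intensity $I_T = \mathrm{meth} + \mathrm{unmeth}$, compared with a
reference intensity $I_R$:

$$\mathrm{LRR}_{p,s} = \log_2\!\frac{I_T(p,s)}{I_R(p)}.$$

At copy-neutral loci LRR ≈ 0; a hemizygous deletion sits near
$\log_2(1/2) = -1$, a single-copy gain near $\log_2(3/2) \approx 0.58$.
The methylation *fraction* is never used for copy number — it only splits
the total between the channels, which is why the generator treats it as a
nuisance parameter.

Copy states are assigned per segment either by thresholds — loss when the
segment mean LRR is $\le -0.2$, gain when $\ge 0.2$, neutral in between
(deliberately liberal cuts, appropriate for arm-scale events) — or by the
direct copy-number formula

$$\mathrm{state} = \mathrm{round}(2^{\overline{\mathrm{LRR}}} \times 2),$$

with half-up rounding (so a segment mean of $\log_2(1.25)$, i.e.
$2^{x}\cdot 2 = 2.5$, becomes copy number 3; round-half-even would give 2,
which is why the convention is documented).

## Preprocessing routes

Four stages turn raw intensities into an LRR track; they are composed into
presets by `run_pipeline()`.

* **Background correction** (`background_correct`): the out-of-band
  fluorescence of type I probes reads the opposite channel of a
  single-color assay and therefore measures pure background. The
  per-sample background level is estimated as the median of the
  out-of-band pool and subtracted from both channels, floored at zero.
  This is a deliberately simplified, median-based variant of
  out-of-band-normal background correction: it preserves in-band ordering
  and removes a constant additive background exactly, which is the
  property the downstream ratio needs.
* **Dye-bias correction** (`dye_bias_correct`): the red channel's
  empirical distribution over type II probes is quantile-matched onto the
  green channel's per sample. A global multiplicative red-channel factor is
  removed exactly, and the map is monotone so within-channel ranks are
  preserved. Below 100 usable type II probes the quantile map is too
  coarse, and a median-ratio rescaling is used instead (with a warning).
* **Detection masking** (`mask_probes`): for each probe and sample the
  detection p-value is the empirical survival function of the sample's
  out-of-band pool evaluated at the probe's total in-band intensity —
  probes indistinguishable from background get large p. Entries with
  p > 0.05 (default) are masked. Masking is monotone: no stage ever
  unmasks an entry, so masked entries never contribute to any statistic.
* **Reference construction** (`build_reference`): per-probe median over
  controls (default), mean over controls, cohort-wide median (no controls
  needed), or matched-normal pairs from the sample sheet. Where several
  reference samples must be combined into one per-probe value the median
  is used throughout — it is robust to a minority of aberrant reference
  samples and keeps the control-derived and cohort-derived modes
  consistent with each other.

The **z-score route** mirrors 450k-era pipelines that scale tumor and
control sets onto a common standardized scale before differencing:
per-sample z-transformation (sample $n-1$ SD — the conventional
statistical default, recorded in provenance), subtraction of the
z-transformed control reference, then per-sample median-centering before
segmentation. Threshold cuts on this scale are not LRR units; the route
exists for contract parity and comparison, not for calibrated copy
numbers.

## Segmentation

`cbs_segment()` implements circular binary segmentation: per sample and
chromosome, the circularized probe sequence is scanned for the arc
$(i, j]$ maximizing the two-sample contrast

$$T_{ij} = \frac{|\bar{x}_{\text{in}} - \bar{x}_{\text{out}}|}
{\sqrt{1/k + 1/(n-k)}},$$

(the residual scale cancels between observed and permuted data and is
omitted). A split is accepted when the observed maximum exceeds the
$(1-\alpha)$ quantile of `nperm` permutation maxima; the algorithm recurses
on the resulting pieces and finally merges adjacent segments whose means
differ by less than `undo_sd` times the residual SD. Defaults:
$\alpha = 0.01$, 1000 permutations, minimum segment width 2 probes,
`undo_sd` 1.0 — desk-scale permutation cost with DNAcopy-like behavior,
all exposed via `cbs_params()`.

Numerical conventions worth knowing:

* Ties in the maximum statistic break toward the smallest $i$, then
  smallest $j$, making results order-deterministic.
* Segment coordinates are the positions of the first and last member
  probes (probe-supported extents, the segment-CSV convention), so
  segments tile exactly the unmasked probes.
* The permutation stream uses R's RNG seeded from `cbs_params(seed=)`
  and restores the caller's RNG state, so identical inputs give identical
  tables on any platform.
* A constant (zero-variance) stretch is never split; chromosomes with
  fewer than `2 * min_width` usable probes emit one trivial segment.
* Per-sample mean-centering before segmentation is off in the standard
  route — baseline handling is the autocorrection stage's job — and on in
  the z-score route, which has no autocorrection.

`brute_force_segment()` is the independent oracle: exhaustive minimum-RSS
enumeration over all breakpoint placements (≤ 60 probes), preferring fewer
segments on ties. The test suite requires exact breakpoint agreement with
CBS on randomized noise-free tracks.

## Baseline autocorrection

Technical offsets (array batch, reference mismatch) shift a whole sample's
LRR track, turning copy-neutral chromosomes into wall-to-wall spurious
calls at fixed thresholds. `autocorrect_baseline()` removes the offset at
the segment level: the per-sample density of segment means, weighted by
`num_mark`, is estimated with a Gaussian kernel; the highest-density peak
is taken as the copy-neutral level and subtracted. Implementation choices,
made here because the density-mode idea itself does not pin them down:

* Bandwidth is Silverman's rule computed from mark-weighted moments with
  the effective sample size $(\sum w)^2 / \sum w^2$.
* The 2048-point evaluation grid spans $[\min - 0.5, \max + 0.5]$, so the
  grid translates exactly with the data and the correction is exactly
  shift-equivariant; idempotence holds to grid resolution (≲ 1e-3 for
  typical spans).
* Equal-height peak ties break toward the peak nearest 0.
* Mark-weighting is the default (`weighted = TRUE`) on the reasoning that
  the neutral level should be set by the bulk of the genome, not by the
  count of (possibly fragmented) segments; it is a flag because the
  opposite convention is defensible.
* A single-segment sample is centred to zero with a warning — with one
  level there is nothing else to anchor on.

The `custom` preset is exactly the standard route plus this stage before
state calling.

## Consensus regions

`consensus_regions()` summarises recurrent events across a cohort with the
population-ranges parameterisation (`density = 0.1`, `rho = 0.5`,
`est_recur = TRUE` as defaults). Gains and losses form separate pools — a
gain never supports a loss region. Within a pool and chromosome, calls are
clustered by single linkage on the reciprocal-overlap graph (two calls
link when their shared length is ≥ `rho` × each call's length);
single linkage is the simplest order-independent choice. Within each
cluster, maximal subregions where at least `density` of the cohort covers
every base are emitted, with `n_support` the number of samples covering
the entire subregion. The recurrence flag is a one-sided binomial test at
0.05 of the region's support against a genome-wide background rate (the
per-sample fraction of covered genome that is non-neutral, averaged over
samples); this test formulation is this package's own and is labelled as
such in the output attributes.

## The recall benchmark

`compute_recall()` scores a call set against a reference of normal (N) and
tumor (T) gold-standard segments:

$$R = \frac{ON + (OT - ONT)}{TR},$$

where ON is the number of N segments overlapping calls by ≥ 1 base (true
negatives), OT the same for T segments (true positives), ONT the number of
T segments overlapping N (subtracted because true negatives are
prioritized), and TR the number of intervals in the merged union of N and
T. All interval arithmetic is 1-based fully closed and strand-agnostic;
abutting closed intervals merge in the union.

Two modes are reported because the statistic's composition leaves one
choice open: whether any call may confirm a reference segment, or only a
state-concordant one. `state_matched` (the default) counts ON against
neutral-state calls and OT against non-neutral calls — the reading under
which ON is genuinely a true-negative count; `literal` applies the formula
with all calls on both sides. The open choice is resolved by reporting
both rather than guessing. Two further conventions: ONT is computed
purely between the reference sets, independent of calls; and R is clamped
to [0, 1] — TR can be smaller than ON + OT when the union merges abutting
N and T intervals, and OT − ONT can be negative, which triggers a warning.
Per-sample recall is computed sample by sample; cohort summaries report
the mean.

`classify_reference_samples()` reproduces the reference-labelling rule
used when no adjacent-normal gold standard exists: per segment, copy state
1 / 2 / 3 from the ±0.2 cuts on mean intensity; a sample is a tumor
reference when every required arm (default 1p and 19q) carries a state-1
segment with more than 10,000 marks (a large-scale event), a normal
reference when every required arm instead has such a state-2 segment and
no qualifying deletion, and unclassified otherwise. Segments belong to the
arm containing their midpoint — unambiguous for arm-scale events (a
fractional-coverage alternative would only matter for segments straddling
the centromere, which the gold-standard builder avoids by splitting
neutral segments at the arm boundary, as SNP-array references effectively
do).

## What the generator emulates — and what it does not

`simulate_cohort()` builds cohorts on a synthetic genome of three 100-Mb
chromosomes (chr1, chr3, chr19; centromere at 50 Mb). The arm boundaries
are synthetic constants, not real cytobands: only arm-level semantics
matter to the method. Scenarios: `kirc_3p` (whole-3p deletion at
`deletion_cn`, default 1 — "deep deletion" does not pin the ploidy, so
hemizygous is the default with homozygous as an option), `oligo_1p19q`
(CN = 1 over all of 1p and 19q in every tumor), and `neutral`.

The intensity model: a per-probe lognormal baseline (meanlog log 4000,
sdlog 0.4) shared across samples, multiplied by CN/2 and per-observation
log-normal noise (`noise_sd` 0.25 by default — real 450k LRR noise is not
a published constant; this value makes CBS detection nontrivial but
reliable and is config-exposed); a Uniform(0.1, 0.9) methylated fraction
splits the total into channels; `dye_bias` multiplies the red channel;
`baseline_offset` multiplies tumor totals by $2^{\text{offset}}$.
Out-of-band intensities are lognormal background draws (mean 100); by
default the in-band signal is background-free so expected intensities
follow the CN model exactly, with `background_in_band = TRUE` available to
exercise the correction stage. The matching gold standard has one row per
truth event (verbatim coordinates) plus neutral rows tiling the remainder,
with SNP-array-style marker counts (~1 marker / 1.5 kb, so arm-scale
segments exceed the 10,000-mark large-scale filter).

Not emulated: probe-type-specific chemistry beyond the dye factor,
spatially varying background, subclonal/mosaic events, focal events,
tumor purity, and real cytoband geometry. Passing tests on these cohorts
therefore demonstrate the correctness of the computational chain — exact
LRR algebra, segmentation against an exhaustive oracle, offset removal,
the recall statistic against a base-set oracle — not calling performance
on real arrays, where noise is heavier-tailed and baselines drift within
chromosomes.

## Problem sizes in the test suite

The shipped tests run cohorts of 2–10 tumors and 2–25 controls at 20–200
probes per chromosome, 100 randomized oracle tracks of 30–60 probes, 100
seeded breakpoint-recovery replicates at 200 probes, and a 50-replicate
corrected-vs-uncorrected contrast at 4 tumors × 100 probes — sizes chosen
so the full suite exercises every stage, including 1000-permutation CBS,
at desk scale. `scripts/acceptance.R` recomputes the same quantities from
scratch at the same scales.

## Known limitations

* The simplified background and dye corrections are not bit-compatible
  with noob/pOOBAH implementations; they preserve those steps' roles and
  invariants, not their exact output.
* Recall, as defined, saturates at 1 for arm-scale references and is
  insensitive to breakpoint accuracy; it is the right statistic for
  large-scale-event recovery, not for fine mapping.
* The z-score route's threshold cuts are on a standardized scale and are
  not calibrated copy-number boundaries.
* Single-core throughout; cohorts of thousands of samples would need a
  chunked segmentation loop.
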