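---
title: "Quantifying SMC-mediated chromosomal arm alignment"
author: "smcalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SMC-mediated chromosomal arm alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcalign)
```

## The problem

In *Caulobacter crescentus* (and many other bacteria) the single circular
chromosome is arranged with the replication origin (*ori*) at one cell pole,
the terminus (*ter*) near the other, and the two chromosomal arms running in
parallel between them. This arm-to-arm juxtaposition is visible in Hi-C
contact maps as a *secondary diagonal*: loci at roughly equal distances from
*ori* on opposite arms touch each other far more often than chance. The SMC
condensin complex creates this pattern: it is loaded at the centromere-like
*parS* site (about 8 kb from *ori*), tethers the two arms together, and
translocates toward *ter*, zipping the arms up progressively. Highly
transcribed genes oriented against the direction of SMC translocation
(head-on) can stall the complex on one arm, producing strikingly asymmetric
"vertical streak" contact patterns.

`smcalign` provides the analysis chain for this biology — contact-matrix
construction from classified read pairs, iterative-correction balancing,
arm-alignment score profiles and their summary statistics — together with a
generative simulator of the loading/translocation model so that every stage
of the pipeline can be exercised against known ground truth.

## From read pairs to a balanced log-scale contact map

Mapped Hi-C read pairs (one position + strand per mate, single circular
chromosome) are processed in four steps:

1. **Fragment assignment and classification.** The genome is cut in silico
   at each BglII site (`AGATCT`, cut one base after the motif start; the
   site is its own reverse complement so one strand scan suffices). Each
   mate is binary-searched into its restriction fragment. Pairs with both
   mates on one fragment pointing toward each other are unligated inserts
   (`non_ligation`); pointing away from each other, self-circularized
   fragments (`self_ligation`); mates on different fragments are `valid`
   Hi-C products. The same-fragment/equal-strand corner case fits neither
   artifact geometry and is kept as valid; the simulator never emits it.
2. **Binning.** Valid pairs are accumulated into fixed 10-kb bins (the last
   bin may be short). Off-diagonal counts are mirrored so the matrix is
   symmetric; the upper triangle plus diagonal sums to the valid-pair count.
3. **Balancing.** Iterative correction (symmetric Sinkhorn-style row/column
   scaling) equalizes bin coverage. Bins with zero coverage plus the bottom
   1% of positive coverages are masked first — sparse bins make the scaling
   diverge. Iteration stops when the coefficient of variation of unmasked
   row sums falls below `1e-6` (500 iterations maximum; non-convergence is
   flagged and warned about, never silent), and a final global rescale
   preserves total mass.
4. **Log transform.** Balanced contacts are converted to relative
   frequencies and mapped to `ln(f + pseudocount)`. The pseudocount defaults
   to half the smallest positive frequency; the paper-style maps plot
   exactly this quantity with *ori* rotated to the matrix center
   (`ori_center()`).

## Arm-alignment statistics

**Score profiles.** `secondary_diagonal()` reads the anti-diagonal through
the anchor bin: `score(d) = m[b - k, b + k]`. Offsets within 30 kb of the
anchor or of its antipode are flagged excluded — on a circle those entries
approach the intra-arm main diagonal and do not measure inter-arm contact.
`vertical_line()` extracts the anchor bin's full contact row.
`arm_profile()` scores, for each offset `d` along one arm, the *maximum*
log contact between that bin and any bin of the opposite arm. It follows
the inter-arm ridge wherever it lies, which matters as soon as the two arms
zip up at different speeds (below).

**Alignment extent.** The extent measure must work on ln-scale profiles of
arbitrary depth, so it is defined scale-freely: background = median score
over a distal window (default 1,200–1,800 kb — beyond any alignment signal
but clear of the *ter* exclusion); peak = maximum of the 3-bin
moving-median-smoothed profile; threshold = background + 0.5 × (peak −
background); extent = last offset before the smoothed profile first drops
below threshold. All three knobs (window, fraction, smoothing) are exposed.
A flat profile yields extent 0 with a `no_signal` flag. Note the artifact
floor: with no alignment signal at all, the distance-decay shoulder near the
anchor still produces an apparent "extent" of a few tens of kb; extents
below ~80 kb should not be over-interpreted (the simulator's no-tether
scenarios land there).

**Alignment rate.** Time-resolved per-arm extents are fitted by ordinary
least squares over the 10–25 min window (inclusive), giving kb/min per arm.
Per-arm extents come from `arm_profile()`: a symmetric anti-diagonal readout
cannot, by construction, yield different numbers for the two arms.

**Ridge asymmetry.** For each left-arm offset the right-arm offset with the
maximal inter-arm score is recorded; a least-absolute-deviations line
through these (dL, dR) pairs resists the off-ridge argmax outliers that
appear beyond a stall. The deviation angle `|45° − atan(slope)|` mirrors
the field's "degrees off the diagonal" phrasing. The vertical-streak flag
compares interquartile spreads of dL versus dR among near-maximal cells
(top decile): a narrow left footprint contacting a long right segment — the
stall geometry — sets the flag when IQR(dL) < IQR(dR)/4.

**Tests.** Paired Student's t on the per-offset differences of two profiles
(jointly unmasked offsets; identical grids enforced) and Pearson
correlation with the t-transform p value are delegated to `stats::t.test()`
and `stats::cor.test()`; the test suite pins both to closed-form formulas
at 1e-10. No multiple-testing correction is applied anywhere — single
planned comparisons only. To correlate a 1-kb ChIP track with a 10-kb
Hi-C profile, `track_at_offsets()` averages the track over the 10-kb
window at `anchor + d` and `anchor - d` and means the two arms, the
both-arm convention.

## ChIP-seq module

Coverage tracks use RPKPM — reads per kb per million mapped reads — with
reads assigned by 5′ position and the final partial bin normalized by its
true length. SMC enrichment is the ratio of tagged to untagged RPKPM
(pseudocount-stabilized; 1 = no enrichment). RNA polymerase abundance per
gene is the length-weighted mean RPKPM over the gene's bins × gene length
in kb; rRNA clusters can be flagged unreliable and masked (short reads do
not map uniquely there). Orientation is classified relative to SMC
translocation *away from parS*: on the right arm (+) strand genes are
co-directional, on the left arm (−) strand genes are; a gene transcribing
back toward *parS* meets SMC head-on. Inversion remapping
(`apply_inversion()`, `invert_genes()`, `invert_sequence()`) reflects the
segment `[start, end)` via `start + end − 1 − x`, an involution, flipping
contained gene strands — so head-on/co-directional classifications flip
exactly for relocated genes, the mechanism behind the inversion-strain
phenotypes.

## The generative simulator

The simulator realizes the tether model: SMC loads at *parS* and reels in
both arms, the left at `v_left` and the right at `v_right` kb/min
(defaults 19 and 16, the rates the time-resolved analysis recovers), up to
a maximum reach (`front_cap_kb`).

A tether of age τ holds the arm positions
`(min(v_left τ, cap), min(v_right τ, cap))`. Occupancy over `(dL, dR)` is

* exponential attrition `exp(−max(dL, dR)/λ)` with processivity λ
  (default 600 kb, the distance at which wild-type inter-arm signal levels
  out), times
* a Gaussian kernel (width σ = 30 kb) around that *register path* — a ray
  of slope `v_right/v_left` plus a completion segment while the lagging arm
  catches up after the leader reaches the cap,

truncated at the per-arm fronts `min(v t, cap)`. Two design choices
deserve comment:

* **Register path, not identity.** A kernel centered on `dL = dR` cannot
  express two arms aligning at different rates: the slower front caps both
  profiles and any fitted rate collapses to the slower speed. The register
  path reduces exactly to the `dL = dR` kernel when speeds are equal and
  makes the per-arm rates recoverable end-to-end otherwise.
* **`front_cap = λ`.** The model separates attrition scale from maximum
  reach but ties them by default, so the processivity parameter *is* the
  ground-truth steady-state alignment extent on both arms — the quantity
  the extent estimator is asked to recover.

**Barriers.** A barrier on an arm at offset `g` with strength β either
*unloads* (occupancy beyond `g` scaled by 1 − β) or *stalls*: a fraction β
keeps that arm pinned at `g` (Gaussian blur σ) while the other arm
continues — the added ridge at fixed `dL = g` is precisely the
vertical-streak geometry. Both modes are implemented because the mechanism
(impeding translocation versus driving dissociation) is genuinely open;
presets use stalls.

**Expected matrix and sampling.** Contact probabilities combine power-law
distance decay `(s + s₀)^(−α)` (α = 1, s₀ = 10 kb) between bin centers, a
uniform floor ε = 1e-3, and `A·O` on inter-arm bin pairs, normalized over
the upper triangle. The amplitude A = 0.08 is calibrated from the
closed-form profile: with the half-max extent rule, the ridge value just
inside the cap, `ln(A e^{-1} + background)`, must clear the threshold
midway between peak and background by a comfortable margin (~0.6 ln-units)
so that Poisson counting noise at 10⁶ sampled pairs (tens of counts per
ridge cell) cannot push the first down-crossing inside the cap, while the
inter-arm band stays visibly weaker than the primary diagonal. Valid pairs
are drawn multinomially from these cell probabilities with uniform
within-bin positions, re-drawn until the mates land on distinct restriction
fragments (a same-bin cell wholly contained in one fragment is re-drawn
altogether — this deliberately thins the matrix diagonal, and goodness-of-fit
checks therefore condition on off-diagonal cells); self-/non-ligation pairs
are placed on a single fragment, chosen proportional to length, with
outward/inward mate orientation. Class fractions default to 70/15/15
(valid/self/non), a typical 3C library composition. One seed governs
everything; per-stage substreams are derived from it, and identical
configurations are byte-identical across runs.

**ChIP simulation.** The tagged sample's expected signal is baseline +
Gaussian loading peak at *parS* + the per-arm occupancy marginals laid
along the chromosome + optional "hyper-ChIPable" artifact peaks at highly
expressed genes; the untagged control carries baseline and artifacts only
(artifacts appear in both samples and cancel in the ratio up to the
configured `artifact_ratio`, mirroring how such artifacts behave in real
tagged/untagged designs). Reads are Poisson at the configured depth.

**Scenario presets** mirror the experimental panels: `wt`; `dsmc`
(amplitude 0: no tethers, flat secondary diagonal); `flip25` (full stall at
70 kb on the left arm — a ~70-kb left region contacting a ~400-kb right
segment); `flip24` and `flip45` (partial/distal stalls); `rif`
(transcription inhibited: barriers removed *and* both arms at the mean
speed 17.5 kb/min, since the per-arm speed difference is itself attributed
to transcriptional interference); `flip15` and `ectopic_parS` (loading site
relocated; shorter reach, band re-centered on the new anchor); `timecourse`
(finite `t` per sample, 5×10⁵ pairs per time point).

## What the simulations do and do not show

The synthetic data reproduce the geometric and statistical structure the
analysis consumes: distance-decay contacts with an inter-arm band of
configurable extent/speed/asymmetry, correct read-pair classes with real
fragment geometry, and coupled ChIP tracks. They do not attempt polymer
physics, explicit RNA polymerase dynamics, replication, or the
ring-versus-handcuff question (which contact data cannot resolve anyway) —
so green tests certify the pipeline's correctness and the model's internal
consistency, not biological completeness. Real libraries additionally
contain duplicate reads (deduplication is available but off by default, as
the processing description does not mention it), mappability artifacts, and
copy-number structure that the uniform floor does not emulate.

## Numerical choices and degenerate inputs

* Coordinates are 0-based bp half-open throughout; kb appears only in
  reports and profiles. All genomic text I/O uses BED/bedGraph conventions.
* Balancing: masked bins propagate as `NA`; re-balancing a balanced matrix
  is a no-op up to the stopping tolerance (idempotence is tested).
* `log_map` refuses non-positive pseudocounts; profiles flag non-finite
  scores excluded.
* The LAD ridge fit starts from the OLS line and polishes by Nelder–Mead
  (tolerance 1e-12) — deterministic for fixed input.
* Extent on a profile whose peak does not exceed background returns 0 with
  `no_signal`; fewer than 2 time points in the rate window is an error.
* Degenerate statistics error loudly: zero-variance paired differences,
  zero-variance correlation input, mismatched profile grids.
* Problem sizes: the packaged analyses run on 405×405 matrices (10-kb bins
  on the 4,042,929-bp NA1000 chromosome) and 10⁵–10⁶ read pairs, the scale
  at which the extent/rate/ridge calibrations above are stated.

## Known limitations

* Single circular chromosome only; no multi-chromosome or liftover support
  beyond point/annotation remapping through inversions.
* The inversion endpoint "3" has no published coordinate; `flip34` is a
  deliberate `NA` placeholder.
* The secondary diagonal under unequal arm speeds dips mid-profile (the
  register ray moves off the anti-diagonal); per-arm extents should be read
  from `arm_profile()`, and the secondary diagonal kept for display and
  profile comparisons.
* Genes spanning *ori* or *ter* are rejected (ambiguous arm) rather than
  split; the preset annotation contains none.
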