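# smcalign

Quantifying SMC-mediated alignment of bacterial chromosomal arms from Hi-C
and ChIP-seq data.

In *Caulobacter crescentus* the two arms of the circular chromosome run in
parallel from the origin of replication (*ori*) toward the terminus
(*ter*). The SMC condensin complex creates this arrangement: loaded at the
centromere-like *parS* site (~8 kb from *ori*), it tethers the arms
together and translocates toward *ter*, progressively zipping the arms up —
until head-on transcription stalls it on one arm and the alignment becomes
asymmetric. In an *ori*-centered Hi-C contact map `m_ij = ln f_ij` (natural
log of balanced contact frequencies between 10-kb bins), arm alignment
appears as the *secondary diagonal*: elevated `m[b-k, b+k]` around the
*ori*/*parS* bin `b`.

`smcalign` is the analysis chain for this biology, for microbiologists and
genome-organization researchers working with single circular chromosomes:

* **genome** — circular coordinate arithmetic, in-silico restriction
  digestion (BglII `A^GATCT` by default), arm assignment, and
  inversion-strain remapping (`apply_inversion`, an involution
  `x -> start + end - 1 - x` on the inverted segment).
* **Hi-C core** — read-pair classification (valid / self-ligation /
  non-ligation from same-fragment mate orientation), 10-kb binning,
  iterative-correction balancing (row-sum CV < 1e-6, mass-preserving,
  masked sparse bins), and the log-scale map.
* **arm statistics** — secondary-diagonal / vertical-line / per-arm ridge
  score profiles; alignment **extent** (half-max over a distal background,
  first down-crossing); alignment **rate** (OLS of extent vs time over
  10–25 min, kb/min per arm); **ridge asymmetry** (LAD fit of the inter-arm
  argmax ridge, deviation in degrees off the diagonal, vertical-streak
  flag); paired t and Pearson tests against closed forms.
* **ChIP-seq** — RPKPM tracks, tagged/untagged enrichment ratios, per-gene
  RNA-polymerase occupancy (RPKPM × gene length), head-on vs co-directional
  orientation relative to SMC translocation, orientation bias.
* **simulator** — a generative model of *parS*-loaded SMC translocation
  (per-arm speeds 19/16 kb/min, processivity λ = 600 kb, stall/unload
  transcription barriers) that produces labeled read pairs, expected
  matrices, and coupled ChIP tracks with ground truth for every stage.

## Worked example

Simulate a wild-type experiment, run the full pipeline, and measure how far
the arms are zipped:

```r
library(smcalign)
g    <- caulobacter_genome()              # 4,042,929 bp, ori at 0, parS 8 kb left
frag <- synthetic_fragments(g, seed = 1)  # 700-fragment digest granularity
cfg  <- sim_preset("wt", seed = 1, n_pairs = 2e5)
pairs <- sample_pairs(cfg, frag)
table(pairs$label)
#>  non_ligation self_ligation         valid
#>         30000         30000        140000

m <- hic_matrix(pairs, g, frag = frag)    # classify -> bin -> balance -> ln
m
#> <contact_matrix> 405 x 405 bins of 10 kb, stage 'log'
#>   genome NA1000; 5 masked bin(s); rotation 0 bin(s)

alignment_extent(arm_profile(m, arm = "right", anchor = g$parS_bp))
#> <extent_estimate> 600 kb [ok]
#>   background -10.243 | threshold -9.374 | peak -8.505 (halfmax(fraction=0.5, smooth=3, bg=[1200,1800]kb))
```

The estimated 600-kb extent is the configured processivity: the right arm
is aligned out to the tether's reach, and the score then drops to the
distal background (the `background`/`threshold`/`peak` fields are ln-scale
contact frequencies). A stall barrier 70 kb out on the left arm (the
head-on transcription scenario) breaks the symmetry:

```r
stall <- sim_preset("flip25", seed = 1, n_pairs = 2e5)
ridge_asymmetry(hic_matrix(sample_pairs(stall, frag), g), anchor = g$parS_bp)
#> <ridge_fit> slope 0.65, deviation 11.8 deg from diagonal; streak ON
#>   near-maximal IQR: left 30 kb, right 170 kb
```

A ~30-kb left-arm footprint contacts a ~170-kb right-arm stretch — the
vertical-streak geometry (at the full 10⁶-pair depth the deviation
sharpens to ~30°). `plot(secondary_diagonal(m, anchor = g$parS_bp))` and
`plot(m)` draw the profile and the map.

A shell interface over the same functions ships at `inst/cli/smcalign.R`
(subcommands `simulate`, `classify`, `bin`, `balance`, `armscore`,
`extent`, `rate`, `ridge`, `chip`, `occupancy`, `digest`, `timecourse`),
writing a run manifest next to each output.

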