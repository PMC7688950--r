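---
title: "Measuring chromosomal position effects on expression mean and noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromosomal position effects on expression mean and noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripnoise)
```

## The problem and the measurement design

An identical reporter cassette (a constitutive promoter driving a
fluorescent protein, tagged with a unique 16-nt DNA barcode drawn from the
A/T/G alphabet) is integrated once per cell at a random genomic position.
Clonal lines founded from single cells then differ *only* in where the
reporter sits, so differences in their single-cell expression distributions
are position effects. Two distribution features are studied per clone: the
mean fluorescence and the squared coefficient of variation,

$$\mathrm{CV}^2 = \frac{\mathrm{Var}(X)}{\mathbb{E}[X]^2},$$

a scale-free noise measure. Three measurements connect genotype to
phenotype:

1. **Split-pool combinatorial decoding.** Each clonal line is split into a
   unique signature of exactly $k$ of $n$ pools (default 4 of 18; capacity
   $\binom{n}{k}$, e.g. $\binom{24}{4} = 10{,}626$). Sequencing the barcode
   content of each pool and asking in which pools a barcode is abundant
   recovers which clone carries which barcode without per-clone DNA
   extraction.
2. **Integration-site mapping (TRIP).** Inverse-PCR junction reads keyed by
   barcode are clustered per replicate; a barcode gets a site only when the
   top candidate of two independent replicates agrees.
3. **Flow cytometry.** ~50k events per clone and replicate; a conservative
   central FSC/SSC gate removes cell-size extrinsic noise; co-cultured
   IRFP-positive control cells, separated by IRFP gating, monitor batch
   effects; the gated Clover intensities give per-clone mean and CV².

Chromatin context is quantified per assigned site as (a) the mean
ChIP-seq fold change of each transcription factor in a window around the
site and (b) the nearest distance to each ChromHMM chromatin state.
Features are screened by Spearman correlation against the per-clone
responses and the survivors enter an ordinary least-squares model of
log10 mean and log10 CV².

## The synthetic world

Real inputs (Illumina reads, ENCODE tracks, cytometry events) are not
shipped; a seeded generator (`synthetic_config()`, `generate_truth()`,
`simulate_*()`) produces every input with ground truth retained, so each
stage is tested by recovery. What the generator states about the world:

* **Barcodes**: length 16 over \{A,T,G\}, pairwise Hamming distance > 2 by
  rejection sampling, so error collapse at radius 2 is identifiable.
  Sequencing errors substitute bases independently at the configured rate
  (default 1%) and may introduce any base, including C.
* **Expression model**: single-cell Clover intensity is lognormal per
  clone. On the log10 scale,
  $\log_{10}\text{mean} = a_0 + \sum_j \beta_j z_j + \varepsilon$ and
  $\log_{10}\mathrm{CV}^2 = b_0 - s\,\log_{10}\text{mean} + \sum_j \gamma_j z_j + \varepsilon'$,
  where $z_j$ are the clone's z-scored chromatin features. The coupling
  $s$ (default 1) builds in the observed anticorrelation between noise and
  mean, while the $\gamma$ effects and $\varepsilon'$ create
  mean-independent noise. Flow intensities are nonnegative and displayed on
  log axes, which motivates the lognormal choice; no distributional family
  is asserted by the measurement itself. Defaults $a_0 = 3$, $b_0 = 2.7$,
  residual SDs 0.25: a library spanning ~3 decades of mean and CV² mostly
  within [0.25, 85], matching the scale of real screens.
* **Planted effects**: by default 5 features per response carry
  standardized effects of ±0.4 among all TF tracks; this is the world the
  inference acceptance check (90 clones, 200 features) operates in.
* **Epigenome**: TF tracks are exponentiated AR(1) signals (bin default
  2 kb, correlation length ~100 kb — the scale of a TAD) rounded to 4
  decimals so bedGraph files round-trip exactly; the state segmentation
  tiles each chromosome with exponential segments (mean 20 kb) labelled
  uniformly from the 25-state vocabulary. Toy genome default: three 10-Mb
  chromosomes — large enough for distinct 50-kb windows, small enough for
  second-scale tests.
* **Flow model**: a latent cell-size factor drives FSC/SSC; a configurable
  fraction (`size_coupling`, default 0.3) of the Clover log-SD loads on the
  same factor. This is exactly the extrinsic noise a scatter gate removes,
  so `gate_events()` demonstrably lowers CV². Control cells share a fixed
  Clover distribution and high IRFP (two lognormal IRFP modes ~4.6 log
  units apart, crossover ≪ 0.1%). `control_fraction` defaults to 0.2 —
  enough control events after gating to estimate batch behaviour without
  sacrificing experimental cells. Per-replicate batch jitter is off by
  default and enabled only in replicate-correlation tests.
* **Noise defaults** mirror the robustness world of the acceptance checks:
  1% per-base error, 2% pool background, 2% merged-signature and 2%
  double-barcode clones, 10% off-target mapping reads, lognormal per-pool
  depth factors (log-SD 0.25; real per-pool library depths are unpublished,
  so depth imbalance is a free parameter). Noiseless runs set these to 0
  explicitly.

What a green test does **not** establish: real base-call error profiles
(quality is constant per read), PCR duplicates, doublets or spillover in
cytometry, sequence-dependent integration bias, or the actual K562
TF/state effect sizes — the generator's effects are synthetic plants.

## Numerical and design choices

* **Genuine-barcode collapse** is the greedy count-descending pass with
  ties broken lexicographically (determinism; the original description is
  silent on ties). Removal is one-shot: a mutant never absorbs others. An
  optional `min_count` floor (pipeline default 2) exists because reads with
  ≥3 substitutions fall outside every genuine barcode's radius and would
  surface as spurious singleton barcodes (~5·10⁻⁴ of reads at 1% error).
* **Positive pools** are called after dividing counts by per-pool depths
  (column sums), then thresholding at 0.2 of the barcode's maximum
  normalized value. A relative threshold is used because absolute counts
  depend on sequencing depth. Column-sum normalization presumes comparable
  clone loads per pool: the `balanced` design scheme guarantees this and is
  what the pipeline uses; the `lexicographic` scheme (deterministic
  enumeration, useful for tests) is decodable with normalization off.
  Simulated per-pool depth factors cancel exactly under normalization.
* **Merged signatures** are resolved only for pairs of still-unassigned
  clones, by exact set equality of the positive set with the signature
  union (overlapping signatures allowed, so unions of 5–8 pools match).
  Multiple matching pairs are a terminal `ambiguous` status — the decoder
  never guesses; triples are out of scope and end `unassigned`.
* **"Identical" top candidate sites** means same chromosome and strand
  within the 10-bp merge window (exact bp identity is unrealistic for
  independent inverse-PCR libraries); `merge_window = 0` restores strict
  identity. The cluster representative is the modal read position, ties to
  the smallest; a tie for the top cluster means no confident candidate.
* **Gating** defaults to per-well (clone × replicate) central quantile
  windows (0.375–0.625 per axis, ~6% joint retention: ~3k of 50k events);
  a fixed-rectangle mode reproduces any explicit gate and is idempotent.
  The automatic IRFP cutoff is a deterministic two-means split of
  log-IRFP; it refuses to act (asking for an explicit cutoff) below 4
  pooled SDs of separation, since a plain Gaussian already splits at ~2.7.
* **Statistics are computed on linear intensities** (mean, unbiased
  variance, CV² = var/mean²); log10 axes are display-only, and CV² on
  logged data would not satisfy the definition. Replicate aggregation is
  the arithmetic mean of means and of CV²s.
* **The enrichment window** is 50 kb *total* width (±25 kb). "A window of
  50 kb surrounding the site" is read as naming the window's extent; the
  trade-off argument against TAD-sized windows concerns total extent.
  `window_bp` doubles it for the ±50 kb reading. The window mean is
  bin-overlap-weighted and clipped at chromosome ends (mean over the
  clipped extent).
* **Distances** are bp gaps to the nearest contained base of a state, 0
  inside; they never cross chromosomes — a state absent from the site's
  chromosome is a masked (NA) value, the conservative choice. Coordinates
  are 0-based half-open throughout, BED-compatible. The 10-way functional
  grouping of the 25 states ships as metadata
  (`state_functional_groups()`); regression uses individual states.
* **Regression responses** are log10(mean) and log10(CV²): both span
  decades, and the transform makes the Gaussian-error OLS model sensible.
  Features are z-scored so t statistics compare across features;
  unstandardized and untransformed modes exist for sensitivity analysis.
  Screening selects on |rho| > 0.2 — moderately positive *and* negative
  correlations qualify. Raw p < 0.05 defines the significant set;
  missing-feature rows are dropped listwise. A forward–backward
  `stepwise_fit()` (AIC/BIC/p-value) is provided because a stepwise
  procedure is an equally plausible reading of the original model
  selection; the correlation filter + OLS is the default and the
  discrepancy is documented rather than resolved.
* **Type-I calibration** is asserted on unscreened all-null fits;
  screening-then-testing on the same data inflates the apparent
  false-positive rate by construction, which is why the power and
  calibration checks are separate.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_clones = 60, cells_per_clone = 5000, seed = 7)
res <- run_pipeline(cfg)
table(res$decode$barcodes$status)
table(res$sites$status)
res$model_mean$coefficients
res$orthogonality
```

The pipeline objects can also be exchanged as files (FASTQ, TSV/CSV,
bedGraph, BED4, JSON) through the `read_*`/`write_*` pairs, or driven from
a shell via `pipeline_cli()` — see `?pipeline_cli`.

## Known limitations

* Alignment itself (and genome-build liftover) is out of scope: the mapper
  consumes already-mapped read tables; strand is carried but downstream
  features are strand-agnostic.
* The decoder resolves merged signatures only as clone *pairs*; deeper
  merges and likelihood-based decoding are non-goals.
* `stepwise_fit()` with AIC is deliberately liberal (it admits terms with
  |t| slightly above √2); exact-support recovery is only guaranteed for
  orthogonal designs.
* The acceptance robustness world interprets "10% TRIP discordance" as a
  10% off-target *read* rate. Barcode-level discordance (different true
  top site per replicate) is simulated and tested separately; such
  barcodes are correct *output* of the concordance filter, not losses.
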