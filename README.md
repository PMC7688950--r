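# tripnoise

Chromosomal position effects on gene-expression **mean** and **noise**, from
barcoded-reporter screens.

When an identical reporter cassette (constitutive promoter → fluorescent
protein, tagged with a unique 16-nt barcode) integrates at different genomic
positions, the resulting isogenic clones differ only in chromatin context —
and both the average expression and its cell-to-cell variability,

&nbsp;&nbsp;&nbsp;&nbsp;CV² = Var(X) / E[X]²,

depend on that context. `tripnoise` is the analysis pipeline for such
screens, aimed at quantitative/computational biologists who want to connect
integration-site chromatin features to expression distributions:

* **barcode calling** — read QC (length, >25% of bases < Q20 fails),
  demultiplexing, and greedy collapse of sequencing-error mutants within
  Hamming distance 2 into "genuine" barcodes;
* **split-pool decoding** — k-of-n combinatorial pooling designs
  (capacity C(n,k); C(24,4) = 10,626), positive-pool calling on
  depth-normalized counts, and barcode→clone decoding including
  merged-signature pairs and double-barcode exclusions;
* **integration mapping** — clustering of inverse-PCR junction reads and
  replicate-concordant top-candidate site assignment;
* **expression statistics** — FSC/SSC quantile gating, IRFP separation of
  co-cultured internal-control cells, per-clone mean / unbiased variance /
  CV², replicate averaging and Spearman replicate concordance;
* **chromatin features** — mean TF fold-change in a 50-kb window around
  each site (bedGraph tracks) and nearest distance to each ChromHMM state
  (BED4 segmentations);
* **association** — Spearman screening (|ρ| > 0.2) followed by multivariate
  OLS of log10(mean) and log10(CV²) on z-scored features, with per-feature
  t/p statistics, optional stepwise selection, and a mean-vs-noise
  orthogonality partition;
* **synthetic data** — a fully seeded generator (`synthetic_config()`,
  `generate_truth()`, `simulate_*()`) that emulates every input with ground
  truth retained, so the whole pipeline is testable by recovery.

## Worked example

```r
library(tripnoise)
cfg <- synthetic_config(n_clones = 60, cells_per_clone = 5000, seed = 7)
res <- run_pipeline(cfg)

table(res$decode$barcodes$status)
#>    assigned merged_pair
#>          58           1
table(res$sites$status)
#> assigned
#>       60
```

Under the default (realistic) noise — 1% per-base sequencing error, 2% pool
background, per-pool depth imbalance, 2% merged-signature clones, 10%
off-target mapping reads — 58 barcodes decode directly and one is correctly
recognised as the merged readout of two sister-cell wells; all 60 barcodes
get replicate-concordant integration sites.

```r
head(res$model_mean$coefficients[order(res$model_mean$coefficients$p_value), ], 5)
#>         term estimate std_error t_value  p_value significant
#>  (Intercept)    3.000    0.0378   79.41 2.10e-47        TRUE
#>    enr_TF013    0.573    0.0506   11.34 2.33e-14        TRUE
#>    enr_TF012    0.480    0.0501    9.57 4.09e-12        TRUE
#>    enr_TF020    0.390    0.0458    8.52 1.07e-10        TRUE
#>    enr_TF005   -0.394    0.0514   -7.68 1.57e-09        TRUE

res$orthogonality
#> $mean_only
#> character(0)
#> $cv2_only
#> [1] "enr_TF001" "enr_TF009" "enr_TF015"
#> $shared
#> [1] "enr_TF003" "enr_TF005" "enr_TF012" "enr_TF013" "enr_TF020"
```

Coefficients are per SD of feature on the log10 scale: one SD more of
TF013's enrichment raises mean reporter expression ~3.7-fold. The generator
had planted mean effects on exactly TF003/TF005/TF012/TF013/TF020 — all five
are recovered (they also appear in the CV² model because noise is coupled
negatively to mean), and the three noise-only factors land in `cv2_only`.

Everything can also run over files (FASTQ / TSV / CSV / bedGraph / BED4 /
JSON) via the `read_*`/`write_*` pairs or from a shell:

```sh
Rscript inst/cli/pipeline.R simulate --config cfg.json --out sim/
Rscript inst/cli/pipeline.R call-barcodes --fastq sim/reads.fastq --out genuine.tsv
Rscript inst/cli/pipeline.R decode --counts sim/pool_counts.tsv --design sim/design.tsv --out decoded.tsv
```

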