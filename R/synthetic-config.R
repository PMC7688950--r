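#' Configuration of the synthetic reporter-screen world
#'
#' Bundles every parameter of the synthetic data generator: library geometry
#' (clones, barcodes, pools), sequencing noise, the toy genome and epigenome,
#' the expression model, and the flow-cytometry simulation. The same
#' configuration (including `seed`) always regenerates byte-identical data.
#'
#' Defaults describe a realistic small screen: 16-nt barcodes drawn from
#' \{A,T,G\}, 4-of-18 pooling signatures, 1\% per-base sequencing error, 2\%
#' pool background reads, 2\% sister-cell ("merged") and 2\% double-barcode
#' clones, 10\% off-target integration-mapping reads, a toy genome of three
#' 10-Mb chromosomes, and 50,000 flow events per clone and replicate of which
#' 20\% are IRFP-positive internal-control cells.
#'
#' @param n_clones number of founder clones (each with a unique barcode and a
#'   single integration site). Must not exceed `choose(n_pools,
#'   signature_weight)`.
#' @param barcode_length barcode length in nt (default 16).
#' @param n_pools number of split pools (default 18).
#' @param signature_weight number of pools each clone is split into
#'   (default 4).
#' @param per_base_error_rate per-base substitution probability of simulated
#'   barcode sequencing reads, in `[0, 1)`.
#' @param reads_per_barcode sequencing reads per true barcode (barcode library
#'   and pool sequencing).
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param n_tf_tracks number of simulated transcription-factor fold-change
#'   tracks.
#' @param track_bin_size bin size of the signal tracks, bp.
#' @param n_states number of chromatin-state labels in the simulated
#'   segmentation (default 25, the K562 ChromHMM vocabulary size).
#' @param cells_per_clone flow events recorded per clone and replicate
#'   (default 50000).
#' @param control_fraction fraction of events that are co-cultured
#'   IRFP-positive internal-control cells.
#' @param seed integer seed; every `simulate_*` stage derives its own stream
#'   from it (`seed`, `seed+1`, ... documented per function).
#' @param pool_background expected background read fraction per barcode
#'   spread uniformly over non-signature pools.
#' @param pool_depth_sdlog log-SD of per-pool library depth factors
#'   (lognormal, mean 1); emulates unequal sequencing depth across pool
#'   libraries, which per-pool depth normalization must undo.
#' @param merged_rate fraction of barcodes emitted with a merged (two-clone
#'   union) pooling signature; each consumes a partner clone.
#' @param double_rate fraction of clones carrying a second barcode with the
#'   same signature.
#' @param trip_reads_per_barcode integration-mapping reads per barcode and
#'   replicate.
#' @param trip_off_target fraction of mapping reads placed uniformly at
#'   random instead of at the true site.
#' @param trip_discordant fraction of barcodes whose replicate-2 reads
#'   cluster at a different (wrong) site.
#' @param trip_jitter maximal bp scatter of on-target mapping reads around
#'   the true junction.
#' @param mean_intercept,noise_intercept intercepts a0, b0 of the expression
#'   model on the log10 scale (arbitrary fluorescence units).
#' @param mean_noise_slope coupling s > 0: log10(CV2) decreases by `s` per
#'   decade of mean, reproducing the observed mean--noise anticorrelation.
#' @param resid_sd_mean,resid_sd_noise residual SDs of log10(mean) and
#'   log10(CV2) not explained by chromatin features.
#' @param effects_mean,effects_noise optional named numeric vectors of
#'   per-feature effect sizes on log10(mean) / log10(CV2) (names are feature
#'   names such as `enr_TF003`). `NULL` plants `n_planted` effects of size
#'   `planted_size` (alternating sign) on randomly chosen TF tracks.
#' @param n_planted,planted_size number and standardized size of default
#'   planted effects (per response).
#' @param size_coupling fraction (0..1) of the clover log-SD shared with the
#'   latent cell-size factor that also drives FSC/SSC; this is the extrinsic
#'   noise a scatter gate removes.
#' @param rep_effect_sd per clone-and-replicate batch jitter: SD of an
#'   additive shift of the lognormal location and of a multiplicative
#'   log-scale factor on the shape. 0 (default) disables batch effects.
#' @param state_mean_length mean chromatin-state segment length, bp.
#' @param window_bp default enrichment window (total width), bp.
#' @param fsc_meanlog,ssc_meanlog,size_sd,scatter_noise_sd scatter-channel
#'   lognormal parameters.
#' @param control_clover_meanlog,control_clover_sdlog the fixed Clover
#'   distribution shared by all internal-control cells.
#' @param irfp_control_meanlog,irfp_background_meanlog,irfp_sdlog IRFP
#'   lognormal locations for control/experimental cells and common log-SD.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_clones = 20, cells_per_clone = 2000)
#' cfg$n_pools
#' @export
synthetic_config <- function(n_clones,
                             barcode_length = 16,
                             n_pools = 18,
                             signature_weight = 4,
                             per_base_error_rate = 0.01,
                             reads_per_barcode = 500,
                             chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                             n_tf_tracks = 20,
                             track_bin_size = 2000,
                             n_states = 25,
                             cells_per_clone = 50000,
                             control_fraction = 0.2,
                             seed = 1,
                             pool_background = 0.02,
                             pool_depth_sdlog = 0.25,
                             merged_rate = 0.02,
                             double_rate = 0.02,
                             trip_reads_per_barcode = 50,
                             trip_off_target = 0.10,
                             trip_discordant = 0,
                             trip_jitter = 2,
                             mean_intercept = 3,
                             noise_intercept = 2.7,
                             mean_noise_slope = 1,
                             resid_sd_mean = 0.25,
                             resid_sd_noise = 0.25,
                             effects_mean = NULL,
                             effects_noise = NULL,
                             n_planted = 5,
                             planted_size = 0.4,
                             size_coupling = 0.3,
                             rep_effect_sd = 0,
                             state_mean_length = 20000,
                             window_bp = 50000,
                             fsc_meanlog = 10,
                             ssc_meanlog = 9.5,
                             size_sd = 0.25,
                             scatter_noise_sd = 0.1,
                             control_clover_meanlog = log(800),
                             control_clover_sdlog = 0.5,
                             irfp_control_meanlog = log(5000),
                             irfp_background_meanlog = log(50),
                             irfp_sdlog = 0.4) {
  cfg <- as.list(environment())

  for (f in c("n_clones", "barcode_length", "n_pools", "signature_weight",
              "reads_per_barcode", "n_tf_tracks", "track_bin_size", "n_states",
              "cells_per_clone", "trip_reads_per_barcode", "state_mean_length",
              "window_bp")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < ifelse(f == "signature_weight", 1, 1))
      stop2("'%s' must be a positive integer (got %s)", f, format(cfg[[f]]))
  }
  if (cfg$signature_weight >= cfg$n_pools)
    stop2("signature_weight (%d) must be smaller than n_pools (%d)",
          cfg$signature_weight, cfg$n_pools)
  cap <- design_capacity(cfg$n_pools, cfg$signature_weight)
  if (cfg$n_clones > cap)
    stop2("capacity error: n_clones (%d) exceeds choose(%d, %d) = %s",
          cfg$n_clones, cfg$n_pools, cfg$signature_weight, format(cap, big.mark = ","))
  if (!is.numeric(cfg$per_base_error_rate) ||
      cfg$per_base_error_rate < 0 || cfg$per_base_error_rate >= 1)
    stop2("per_base_error_rate must lie in [0, 1)")
  for (f in c("control_fraction", "pool_background", "merged_rate",
              "double_rate", "trip_off_target", "trip_discordant",
              "size_coupling")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop2("'%s' must lie in [0, 1]", f)
  }
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == "") ||
      anyDuplicated(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    stop2("chrom_lengths must be a named vector of positive lengths")
  if (cfg$mean_noise_slope < 0) stop2("mean_noise_slope must be >= 0")
  cfg$chrom_lengths <- round(cfg$chrom_lengths)
  cfg$seed <- as.integer(seed)

  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_config> %d clones | %d-nt barcodes | %d-of-%d pools | ",
           "genome %s | %d TF tracks, %d states | seed %d\n"),
    x$n_clones, x$barcode_length, x$signature_weight, x$n_pools,
    paste(sprintf("%s:%.1fMb", names(x$chrom_lengths), x$chrom_lengths / 1e6),
          collapse = ","),
    x$n_tf_tracks, x$n_states, x$seed))
  invisible(x)
}

#' K562-style ChromHMM state vocabulary
#'
#' Returns `n` state mnemonics. The first 25 are the familiar 25-state K562
#' labels (Tss, PromP, Gen3p, Pol2, CtcfO, H4K20, Quies, ...); beyond 25,
#' generic labels are appended.
#'
#' @param n number of states.
#' @return character vector of length `n`.
#' @export
chromhmm_states <- function(n) {
  base <- c("Tss", "TssF", "PromF", "PromP", "Enh", "EnhF", "EnhWF", "EnhW",
            "DNaseD", "DNaseU", "FaireW", "Ctcf", "CtcfO", "Gen5p", "Elon",
            "ElonW", "Gen3p", "Pol2", "H4K20", "Low", "ReprD", "Repr",
            "ReprW", "Quies", "Art")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("State%02d", seq.int(length(base) + 1L, n)))
}

#' Ten-way functional grouping of the 25-state vocabulary
#'
#' Provided as metadata only; features are computed per individual state.
#'
#' @return named character vector mapping state mnemonic to functional group.
#' @export
state_functional_groups <- function() {
  c(Tss = "active_promoter", TssF = "active_promoter",
    PromF = "promoter_flanking", PromP = "inactive_promoter",
    Enh = "strong_enhancer", EnhF = "strong_enhancer",
    EnhWF = "weak_enhancer_dnase", EnhW = "weak_enhancer_dnase",
    DNaseD = "weak_enhancer_dnase", DNaseU = "weak_enhancer_dnase",
    FaireW = "weak_enhancer_dnase",
    Ctcf = "distal_ctcf", CtcfO = "distal_ctcf",
    Gen5p = "transcription", Elon = "transcription", ElonW = "transcription",
    Gen3p = "transcription", Pol2 = "transcription", H4K20 = "transcription",
    Low = "low_activity",
    ReprD = "polycomb_repressed", Repr = "polycomb_repressed",
    ReprW = "polycomb_repressed",
    Quies = "heterochromatin", Art = "heterochromatin")
}
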