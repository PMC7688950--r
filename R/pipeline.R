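#' Run the full screen pipeline on synthetic data
#'
#' Generates a synthetic screen from `config` and pushes it through every
#' analysis stage: read filtering and barcode counting, Hamming-collapse of
#' sequencing-error mutants, split-pool decoding, replicate-concordant
#' integration-site assignment, flow-cytometry gating / control splitting /
#' per-clone summarisation, chromatin feature extraction, and the screened
#' multivariate regression against log10 mean and log10 CV2.
#'
#' @param config a [synthetic_config()].
#' @param rel_threshold positive-pool threshold for decoding.
#' @param merge_window read-cluster merge window, bp.
#' @param min_count count floor for [call_genuine()] (default 2: drops
#'   singleton sequencing artifacts).
#' @param gate a [gate_spec()].
#' @param rho_threshold Spearman screening threshold.
#' @param alpha regression significance level.
#' @return list with every intermediate: `truth`, `genuine`, `design`,
#'   `decode`, `sites`, `summaries`, `aggregated`, `fm`, `screen_mean`,
#'   `screen_cv2`, `model_mean`, `model_cv2`, `orthogonality`.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_clones = 30, cells_per_clone = 3000,
#'                         reads_per_barcode = 100, n_tf_tracks = 6,
#'                         n_states = 8, seed = 7)
#' res <- run_pipeline(cfg)
#' table(res$decode$barcodes$status)
#' }
#' @export
run_pipeline <- function(config, rel_threshold = 0.2, merge_window = 10,
                         min_count = 2, gate = gate_spec(),
                         rho_threshold = 0.2, alpha = 0.05) {
  truth <- generate_truth(config)

  reads <- simulate_barcode_reads(truth)
  kept <- filter_reads(reads, config$barcode_length)
  genuine <- call_genuine(count_barcodes(kept), radius = 2,
                          min_count = min_count)

  # balanced pool usage: depth normalization by column sums presumes that
  # every pool hosts a comparable number of clones
  design <- make_design(config$n_clones, config$n_pools,
                        config$signature_weight, scheme = "balanced")
  counts <- simulate_pool_counts(truth, design)
  counts_genuine <- counts[rownames(counts) %in% genuine$barcode, ,
                           drop = FALSE]
  decode <- decode_pools(counts_genuine, design, rel_threshold)

  trip <- simulate_trip_reads(truth)
  sites <- assign_sites(trip[trip$replicate == 1L, ],
                        trip[trip$replicate == 2L, ],
                        merge_window = merge_window,
                        barcodes = genuine$barcode)

  flow <- simulate_flow_events(truth)
  gated <- gate_events(flow, gate)
  sp <- split_control(gated)
  summaries <- summarize_expression(sp$experimental,
                                    min_cells = min(1000, config$cells_per_clone / 50))
  aggregated <- aggregate_replicates(summaries)

  bmap <- decode$barcodes
  clone_map <- stats::setNames(bmap$clone[bmap$status == "assigned"],
                               bmap$barcode[bmap$status == "assigned"])
  fm <- build_feature_matrix(sites, truth$epigenome$tracks,
                             truth$epigenome$states,
                             expression = aggregated, clone_map = clone_map,
                             window_bp = config$window_bp)

  screen_mean <- spearman_screen(fm, "log10_mean", rho_threshold)
  screen_cv2 <- spearman_screen(fm, "log10_cv2", rho_threshold)
  model_mean <- if (any(screen_mean$selected))
    fit_model(fm, "log10_mean", screen_mean, alpha = alpha) else
      intercept_only_model(fm, "log10_mean", alpha)
  model_cv2 <- if (any(screen_cv2$selected))
    fit_model(fm, "log10_cv2", screen_cv2, alpha = alpha) else
      intercept_only_model(fm, "log10_cv2", alpha)

  list(truth = truth, genuine = genuine, design = design, decode = decode,
       sites = sites, summaries = summaries, aggregated = aggregated,
       fm = fm, screen_mean = screen_mean, screen_cv2 = screen_cv2,
       model_mean = model_mean, model_cv2 = model_cv2,
       orthogonality = orthogonality_report(model_mean, model_cv2))
}
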