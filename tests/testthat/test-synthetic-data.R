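test_that("generate_truth is deterministic and validates capacity", {
  cfg <- small_config()
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_error(synthetic_config(n_clones = 11, n_pools = 5,
                                signature_weight = 2),
               "capacity")
  # different seed changes the world
  t3 <- generate_truth(small_config(seed = 999))
  expect_false(identical(t1$clones$barcode, t3$clones$barcode))
})

test_that("barcodes use the A/T/G alphabet and are pairwise Hamming > 2", {
  truth <- generate_truth(small_config(n_clones = 50, seed = 3))
  bc <- truth$clones$barcode
  expect_true(all(grepl("^[ATG]+$", bc)))
  expect_true(all(nchar(bc) == 16))
  for (i in seq_along(bc)) {
    d <- hamming(bc[i], bc[-i])
    expect_true(all(d > 2))
  }
})

test_that("null-effect world gives identical expression parameters", {
  cfg <- small_config(n_planted = 0, resid_sd_mean = 0, resid_sd_noise = 0)
  truth <- generate_truth(cfg)
  expect_equal(var(truth$clones$mu), 0)
  expect_equal(var(truth$clones$sigma), 0)
  expect_equal(truth$clones$log10_mean, rep(cfg$mean_intercept, cfg$n_clones))
})

test_that("a single planted effect drives a perfect rank correlation", {
  cfg <- small_config(effects_mean = c(enr_TF001 = 1),
                      effects_noise = c(enr_TF001 = 0),
                      resid_sd_mean = 0, resid_sd_noise = 0)
  truth <- generate_truth(cfg)
  rho <- cor(truth$features[, "enr_TF001"], truth$clones$log10_mean,
             method = "spearman")
  expect_equal(rho, 1)
  # noise response couples negatively to mean (s = 1 > 0)
  rho_cv2 <- cor(truth$clones$log10_mean, truth$clones$log10_cv2,
                 method = "spearman")
  expect_equal(rho_cv2, -1)
})

test_that("simulate_barcode_reads: noiseless copies, conservation, error rate", {
  truth <- generate_truth(small_config(n_clones = 3, seed = 5))
  r0 <- simulate_barcode_reads(truth, reads_per_barcode = 100, error_rate = 0)
  expect_equal(nrow(r0), 300)
  expect_true(all(r0$sequence %in% truth$clones$barcode))
  expect_true(all(nchar(r0$qualities) == 16))

  truth2 <- generate_truth(small_config(n_clones = 50, seed = 6))
  r1 <- simulate_barcode_reads(truth2, reads_per_barcode = 400,
                               error_rate = 0.01)
  p <- 1 - 0.99^16
  frac <- mean(!(r1$sequence %in% truth2$clones$barcode[
    match(attr(r1, "truth_clone"), truth2$clones$clone_id)]))
  tol <- 3 * sqrt(p * (1 - p) / nrow(r1))
  expect_lt(abs(frac - p), tol)
  # determinism of the stage
  r1b <- simulate_barcode_reads(truth2, reads_per_barcode = 400,
                                error_rate = 0.01)
  expect_identical(r1, r1b)
})

test_that("simulate_pool_counts concentrates reads in signature pools", {
  cfg <- noiseless_config(n_clones = 30)
  truth <- generate_truth(cfg)
  design <- make_design(30, cfg$n_pools, cfg$signature_weight, "balanced")
  counts <- simulate_pool_counts(truth, design)
  map <- attr(counts, "barcode_map")
  for (i in seq_len(nrow(counts))) {
    sig <- design$assignments[[map$clone_id[i]]]
    expect_true(all(counts[i, -sig] == 0))
    expect_equal(sum(counts[i, ]), cfg$reads_per_barcode)
  }
  # every pool hosts >= 1 clone under the balanced scheme, so depths > 0
  expect_true(all(pool_depths(counts) > 0))
})

test_that("merged and double-barcode injections carry correct ground truth", {
  cfg <- noiseless_config(n_clones = 40, merged_rate = 0.1, double_rate = 0.1)
  truth <- generate_truth(cfg)
  design <- make_design(40, cfg$n_pools, cfg$signature_weight, "balanced")
  counts <- simulate_pool_counts(truth, design)
  map <- attr(counts, "barcode_map")
  merged <- map[map$role == "merged", ]
  expect_equal(nrow(merged), 4)  # floor(0.1 * 40)
  for (i in seq_len(nrow(merged))) {
    u <- sort(union(design$assignments[[merged$clone_id[i]]],
                    design$assignments[[merged$partner[i]]]))
    expect_lte(length(u), 8)
    expect_setequal(which(counts[merged$barcode[i], ] > 0), u)
  }
  # partner clones contributed no barcode row of their own
  expect_false(any(merged$partner %in%
                     map$clone_id[map$role %in% c("single", "double_extra")]))
  doubles <- map[map$role == "double_extra", ]
  expect_gt(nrow(doubles), 0)
  expect_false(any(doubles$barcode %in% truth$clones$barcode))
})

test_that("simulate_trip_reads: schema, noiseless placement, discordance rate", {
  cfg <- noiseless_config(n_clones = 15)
  truth <- generate_truth(cfg)
  tr <- simulate_trip_reads(truth)
  expect_setequal(unique(tr$replicate), c(1L, 2L))
  hit <- merge(tr, truth$clones[, c("barcode", "chrom", "pos", "strand")],
               by = "barcode", suffixes = c("", ".true"))
  expect_true(all(hit$chrom == hit$chrom.true & hit$pos == hit$pos.true &
                    hit$strand == hit$strand.true))

  cfg2 <- noiseless_config(n_clones = 100, seed = 21)
  truth2 <- generate_truth(cfg2)
  tr2 <- simulate_trip_reads(truth2, discordant_fraction = 0.1)
  expect_equal(length(attr(tr2, "discordant_barcodes")), 10)
  sites <- assign_sites(tr2[tr2$replicate == 1, ], tr2[tr2$replicate == 2, ])
  frac_assigned <- mean(sites$status == "assigned")
  expect_lt(abs(frac_assigned - 0.9), 3 * sqrt(0.9 * 0.1 / 100) + 1e-9)
})

test_that("flow events: degenerate noise, control separation, partition", {
  # CV2 -> 0 when the lognormal shape parameter collapses
  cfg <- small_config(n_clones = 2, n_planted = 0, resid_sd_mean = 0,
                      resid_sd_noise = 0, noise_intercept = -6,
                      mean_noise_slope = 0, size_coupling = 0,
                      cells_per_clone = 5000)
  truth <- generate_truth(cfg)
  expect_lt(max(truth$clones$sigma), 2e-3)
  ev <- simulate_flow_events(truth, replicates = 1)
  s <- summarize_expression(ev[!ev$control, ], min_cells = 100)
  expect_lt(max(s$cv2), 1e-4)

  # IRFP split at control_fraction = 0.5: bimodal, near-zero crossover
  cfg2 <- small_config(n_clones = 4, control_fraction = 0.5,
                       cells_per_clone = 4000, seed = 31)
  ev2 <- simulate_flow_events(generate_truth(cfg2), replicates = 1)
  sp <- split_control(ev2)
  expect_equal(nrow(sp$experimental) + nrow(sp$control), nrow(ev2))
  mis <- mean(c(sp$experimental$control, !sp$control$control))
  expect_lt(mis, 0.001)
  expect_lt(abs(nrow(sp$control) / nrow(ev2) - 0.5), 0.02)
})

test_that("population CV2 of simulated clones matches the lognormal closed form", {
  # lognormal with log-sd s has CV2 = exp(s^2) - 1
  cfg <- small_config(n_clones = 1, n_planted = 0, resid_sd_mean = 0,
                      resid_sd_noise = 0, mean_noise_slope = 0,
                      noise_intercept = log10(exp(0.8^2) - 1),
                      control_fraction = 0, size_coupling = 0,
                      cells_per_clone = 50000, seed = 41)
  truth <- generate_truth(cfg)
  expect_equal(truth$clones$sigma, 0.8, tolerance = 1e-12)
  ev <- simulate_flow_events(truth, replicates = 1)
  s <- summarize_expression(ev, min_cells = 100)
  expect_lt(abs(s$cv2 / (exp(0.8^2) - 1) - 1), 0.05)
})

test_that("synthetic epigenome tiles chromosomes and round-trips features", {
  cfg <- small_config(seed = 51)
  truth <- generate_truth(cfg)
  seg <- truth$epigenome$states
  for (ch in names(cfg$chrom_lengths)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], unname(cfg$chrom_lengths[[ch]]))
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))  # exact partition
  }
  expect_true(all(seg$state %in% attr(seg, "vocabulary")))
  for (tr in truth$epigenome$tracks)
    expect_true(all(unlist(tr$values) >= 0))

  # cached features == rebuilding from the in-memory epigenome
  fm <- build_feature_matrix(truth$clones, truth$epigenome$tracks, seg,
                             window_bp = cfg$window_bp)
  expect_equal(fm$x, truth$features)
})

test_that("simulate_inputs writes files that round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_clones = 8, cells_per_clone = 300, seed = 61,
                      n_tf_tracks = 2, n_states = 4,
                      reads_per_barcode = 30, trip_reads_per_barcode = 10)
  sim <- simulate_inputs(cfg, dir)

  reads <- read_fastq(file.path(dir, "reads.fastq"))
  expect_equal(reads$sequence, sim$reads$sequence)
  expect_equal(reads$qualities, sim$reads$qualities)

  counts <- read_pool_counts(file.path(dir, "pool_counts.tsv"))
  expect_equal(unclass(counts), unclass(sim$pool_counts),
               ignore_attr = TRUE)

  design <- read_design(file.path(dir, "design.tsv"))
  expect_equal(design$assignments, sim$design$assignments)

  tr1 <- read_trip_reads(file.path(dir, "trip_rep1.tsv"))
  expect_equal(tr1$pos, sim$trip_reads$pos[sim$trip_reads$replicate == 1])

  flow <- read_flow_events(file.path(dir, "flow_events.csv"))
  expect_equal(nrow(flow), nrow(sim$flow_events))
  expect_equal(flow$clover, sim$flow_events$clover, tolerance = 1e-12)

  states <- read_states(file.path(dir, "states.bed"))
  expect_equal(states$start, sim$epigenome$states$start)
  expect_equal(states$state, sim$epigenome$states$state)

  tr <- read_track(file.path(dir, "tracks", "TF001.bedGraph"),
                   bin_size = cfg$track_bin_size,
                   chrom_lengths = cfg$chrom_lengths)
  expect_equal(tr$values, sim$epigenome$tracks$TF001$values,
               ignore_attr = TRUE)

  truth2 <- read_truth(file.path(dir, "truth.json"))
  expect_equal(truth2$clones$barcode, sim$truth$clones$barcode)
  expect_equal(truth2$features, sim$truth$features, tolerance = 1e-12)

  # feature values recomputed from the *files* equal the cached truth
  tracks <- lapply(list.files(file.path(dir, "tracks"), full.names = TRUE),
                   read_track, bin_size = cfg$track_bin_size,
                   chrom_lengths = cfg$chrom_lengths)
  names(tracks) <- vapply(tracks, `[[`, "", "name")
  fm <- build_feature_matrix(sim$truth$clones, tracks,
                             read_states(file.path(dir, "states.bed"),
                                         vocabulary = chromhmm_states(cfg$n_states),
                                         chrom_lengths = cfg$chrom_lengths),
                             window_bp = cfg$window_bp)
  expect_equal(fm$x, sim$truth$features)
})
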