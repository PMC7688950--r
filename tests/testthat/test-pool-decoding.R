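test_that("design_capacity is the exact binomial coefficient", {
  expect_identical(design_capacity(24, 4), 10626)
  expect_identical(design_capacity(18, 4), 3060)
  expect_identical(design_capacity(7, 0), 1)
  expect_error(design_capacity(4, 5), "domain")
})

test_that("make_design enumerates signatures deterministically", {
  d <- make_design(3, 4, 2)
  expect_equal(unname(d$assignments), list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))

  # full lexicographic enumeration equals the combn() oracle
  d2 <- make_design(design_capacity(6, 3), 6, 3)
  oracle <- lapply(seq_len(choose(6, 3)), function(i) utils::combn(6, 3)[, i])
  expect_equal(unname(d2$assignments), oracle)
  expect_equal(anyDuplicated(vapply(d2$assignments, paste, "",
                                    collapse = ",")), 0L)
  expect_error(make_design(5, 4, 2, "lexicographic"), NA)
  expect_error(make_design(7, 4, 2), "capacity")
})

test_that("balanced scheme equalises pool loads", {
  d <- make_design(6, 4, 2, scheme = "balanced")
  load <- tabulate(unlist(d$assignments), 4)
  expect_equal(load, rep(3L, 4))  # 6 clones x 2 pools / 4 pools
  expect_equal(anyDuplicated(vapply(d$assignments, paste, "",
                                    collapse = ",")), 0L)
  # larger case: loads within 1 of each other
  d2 <- make_design(100, 18, 4, scheme = "balanced")
  load2 <- tabulate(unlist(d2$assignments), 18)
  expect_lte(diff(range(load2)), 1)
})

test_that("call_positive_pools thresholds relative to the row maximum", {
  m <- rbind(a = c(100, 98, 95, 97, 2, 0, 1, 0),
             b = c(0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(call_positive_pools(m, "a", depth_normalize = FALSE),
               1:4)
  expect_equal(call_positive_pools(m, "b", depth_normalize = FALSE),
               integer(0))
  # doubling one pool's depth halves its normalized value
  m2 <- rbind(a = c(50, 50, 0, 0), depth = c(50, 150, 100, 100))
  expect_equal(call_positive_pools(m2, "a", depth_normalize = TRUE,
                                   rel_threshold = 0.6),
               1L)  # 50/100 = 0.5 vs 50/200 = 0.25 < 0.6 * 0.5
  expect_error(call_positive_pools(m, "zz"), "not in table")
})

test_that("noiseless decode round-trips the truth", {
  cfg <- noiseless_config(n_clones = 60, seed = 13)
  truth <- generate_truth(cfg)

  # balanced design + depth normalization
  des_b <- make_design(60, 18, 4, "balanced")
  counts <- simulate_pool_counts(truth, des_b)
  res <- decode_pools(counts, des_b)
  expect_true(all(res$barcodes$status == "assigned"))
  map <- attr(counts, "barcode_map")
  expect_equal(res$barcodes$clone,
               map$clone_id[match(res$barcodes$barcode, map$barcode)])
  expect_false(any(res$clones$excluded_multibarcode))

  # lexicographic design decodes with depth normalization off (pool loads
  # are too unbalanced for column-sum normalization)
  des_l <- make_design(60, 18, 4, "lexicographic")
  counts_l <- simulate_pool_counts(truth, des_l, depth_sdlog = 0)
  res_l <- decode_pools(counts_l, des_l, depth_normalize = FALSE)
  expect_true(all(res_l$barcodes$status == "assigned"))
})

test_that("per-pool depth factors cancel under depth normalization", {
  cfg <- noiseless_config(n_clones = 40, seed = 14)
  truth <- generate_truth(cfg)
  des <- make_design(40, 18, 4, "balanced")
  counts <- simulate_pool_counts(truth, des, depth_sdlog = 0.5)
  res <- decode_pools(counts, des, depth_normalize = TRUE)
  expect_true(all(res$barcodes$status == "assigned"))
})

test_that("merged pairs and double barcodes get their terminal statuses", {
  cfg <- noiseless_config(n_clones = 50, merged_rate = 0.08,
                          double_rate = 0.08, seed = 15)
  truth <- generate_truth(cfg)
  des <- make_design(50, 18, 4, "balanced")
  counts <- simulate_pool_counts(truth, des)
  res <- decode_pools(counts, des)
  map <- attr(counts, "barcode_map")

  merged <- map[map$role == "merged", ]
  for (i in seq_len(nrow(merged))) {
    row <- res$barcodes[res$barcodes$barcode == merged$barcode[i], ]
    expect_equal(row$status, "merged_pair")
    expect_setequal(c(row$clone, row$clone2),
                    c(merged$clone_id[i], merged$partner[i]))
  }
  doubled <- unique(map$clone_id[map$role == "double_extra"])
  expect_true(all(res$clones$excluded_multibarcode[
    res$clones$clone_id %in% doubled]))
  expect_false(any(res$clones$excluded_multibarcode[
    !res$clones$clone_id %in% doubled]))
  # statuses partition the barcodes
  expect_true(all(res$barcodes$status %in%
                    c("assigned", "merged_pair", "unassigned", "ambiguous")))
  expect_equal(anyDuplicated(res$barcodes$barcode), 0L)
})

test_that("merged-pair search equals brute force over all clone pairs", {
  set.seed(1613)
  for (rep in 1:10) {
    n_cl <- sample(10:40, 1)
    des <- make_design(n_cl, 12, 3, "balanced")
    # barcode readout = union of a random clone pair
    pair <- sample(names(des$assignments), 2)
    pos <- sort(union(des$assignments[[pair[1]]], des$assignments[[pair[2]]]))
    counts <- matrix(0L, 1, 12, dimnames = list("bc1", des$pool_ids))
    counts[1, pos] <- 100L
    res <- decode_pools(counts, des, depth_normalize = FALSE)
    hits <- oracle_merged_pairs(pos, des$assignments)
    if (length(hits) == 1L) {
      expect_equal(res$barcodes$status, "merged_pair")
      expect_setequal(c(res$barcodes$clone, res$barcodes$clone2), hits[[1]])
    } else {
      expect_equal(res$barcodes$status, "ambiguous")
      expect_gt(length(hits), 1)
    }
  }
})

test_that("decode stays accurate under background noise", {
  # >= 99% of 500 barcodes assigned correctly at 2% background
  cfg <- synthetic_config(n_clones = 500, reads_per_barcode = 200,
                          pool_background = 0.02, merged_rate = 0,
                          double_rate = 0, seed = 17,
                          chrom_lengths = c(chr1 = 2e6), n_tf_tracks = 2,
                          n_states = 4, cells_per_clone = 100)
  truth <- generate_truth(cfg)
  des <- make_design(500, 18, 4, "balanced")
  counts <- simulate_pool_counts(truth, des)
  res <- decode_pools(counts, des)
  map <- attr(counts, "barcode_map")
  correct <- res$barcodes$status == "assigned" &
    res$barcodes$clone == map$clone_id[match(res$barcodes$barcode,
                                             map$barcode)]
  expect_gte(mean(correct), 0.99)
})
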