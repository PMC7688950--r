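# Independent oracles and small fixture builders. These deliberately use
# different algorithms/code paths than the package implementation.

# O(n^2) all-pairs greedy collapse: full distance matrix first, then the
# sequential removal, written directly from the algorithm description.
oracle_call_genuine <- function(barcode, count, radius = 2) {
  o <- order(-count, barcode)
  barcode <- barcode[o]; count <- count[o]
  n <- length(barcode)
  chars <- strsplit(barcode, "")
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(chars[[i]] != chars[[j]])
  state <- rep("pending", n)
  for (i in seq_len(n)) {
    if (state[i] != "pending") next
    state[i] <- "genuine"
    later <- which(state == "pending")
    state[later[D[i, later] <= radius]] <- "removed"
  }
  barcode[state == "genuine"]
}

# Brute-force nearest distance: scan every interval row.
oracle_distance <- function(seg_df, chrom, pos, state) {
  best <- NA_real_
  for (r in seq_len(nrow(seg_df))) {
    if (seg_df$chrom[r] != chrom || seg_df$state[r] != state) next
    s <- seg_df$start[r]; e <- seg_df$end[r]
    d <- if (pos >= s && pos < e) 0
    else if (pos < s) s - pos
    else pos - (e - 1)
    if (is.na(best) || d < best) best <- d
  }
  best
}

# Closed-form simple linear regression: slope, intercept, SE, t, p.
oracle_simple_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  se1 <- sqrt(s2 / sxx)
  se0 <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  t1 <- b1 / se1
  t0 <- b0 / se0
  list(intercept = b0, slope = b1, se_intercept = se0, se_slope = se1,
       t_intercept = t0, t_slope = t1,
       p_intercept = 2 * pt(-abs(t0), n - 2),
       p_slope = 2 * pt(-abs(t1), n - 2),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Brute-force merged-pair search over all unordered clone pairs.
oracle_merged_pairs <- function(positive_set, assignments) {
  ids <- names(assignments)
  hits <- list()
  if (length(ids) >= 2) {
    for (a in 1:(length(ids) - 1)) for (b in (a + 1):length(ids)) {
      u <- sort(union(assignments[[ids[a]]], assignments[[ids[b]]]))
      if (length(u) == length(positive_set) && all(u == sort(positive_set)))
        hits[[length(hits) + 1L]] <- sort(c(ids[a], ids[b]))
    }
  }
  hits
}

# Clustered random barcode sets: seeds plus near-mutants, so greedy collapse
# is exercised on non-trivial inputs.
rand_barcode_set <- function(n_seeds, len = 8, mutants_per_seed = 3,
                             alphabet = c("A", "C", "G", "T")) {
  seeds <- unique(replicate(n_seeds, paste(sample(alphabet, len, TRUE),
                                           collapse = "")))
  rows <- list()
  for (s in seeds) {
    rows[[length(rows) + 1L]] <- data.frame(
      barcode = s, count = sample(50:500, 1), stringsAsFactors = FALSE)
    for (k in seq_len(sample.int(mutants_per_seed + 1, 1) - 1L)) {
      ch <- strsplit(s, "")[[1]]
      nmut <- sample.int(3, 1)  # some fall outside the radius
      at <- sample(len, nmut)
      ch[at] <- sample(alphabet, nmut, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = paste(ch, collapse = ""), count = sample(1:30, 1),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  # merge duplicates
  agg <- tapply(df$count, df$barcode, sum)
  data.frame(barcode = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE)
}

# Small fast default world used across tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_clones = 20, cells_per_clone = 2000,
                   reads_per_barcode = 100, n_tf_tracks = 4, n_states = 6,
                   chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                   track_bin_size = 1000, trip_reads_per_barcode = 20,
                   seed = 101)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# All noise channels off (explicit ... overrides still win).
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(per_base_error_rate = 0, pool_background = 0, pool_depth_sdlog = 0,
         merged_rate = 0, double_rate = 0, trip_off_target = 0,
         trip_discordant = 0, trip_jitter = 0),
    list(...))
  do.call(small_config, args)
}

make_track <- function(values_by_chrom, bin_size, chrom_lengths = NULL,
                       name = "toy") {
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(values_by_chrom, function(v)
      length(v) * bin_size, 0)
  structure(list(name = name, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, values = values_by_chrom),
            class = "signal_track")
}

make_seg <- function(df, vocabulary = NULL) {
  tripnoise:::new_segmentation(df, vocabulary %||% sort(unique(df$state)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
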