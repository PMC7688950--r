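#' Generate the ground truth of a synthetic reporter screen
#'
#' Draws, deterministically from `config$seed`: a set of pairwise
#' well-separated barcodes (Hamming distance > 2, alphabet \{A,T,G\}), one
#' integration site per clone, a synthetic epigenome (autocorrelated
#' nonnegative TF fold-change tracks plus a chromatin-state segmentation that
#' tiles each chromosome), per-clone chromatin features extracted from that
#' epigenome, and per-clone expression parameters.
#'
#' Expression parameters are deterministic functions of the clone's own
#' chromatin features:
#' \deqn{log10(mean) = a0 + sum_j beta_j z_j + eps}
#' \deqn{log10(CV2) = b0 - s * log10(mean) + sum_j gamma_j z_j + eps'}
#' where `z_j` are the z-scored features, `s > 0` couples noise negatively to
#' mean, and `eps` are clone-level residuals. The lognormal location/scale
#' `(mu, sigma)` of single-cell Clover intensity is solved from the targeted
#' mean and CV2 (`sigma^2 = log(1 + CV2)`, `mu = log(mean) - sigma^2/2`).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `trip_truth`: a list with elements `config`,
#'   `clones` (data.frame: clone_id, barcode, chrom, pos, strand, log10_mean,
#'   log10_cv2, mean, cv2, mu, sigma), `features` (clones x features matrix,
#'   columns `enr_*`/`dist_*`), `effects` (list of named effect vectors
#'   `mean`, `noise`) and `epigenome` (list `tracks`, `states`).
#' @examples
#' truth <- generate_truth(synthetic_config(n_clones = 10, n_tf_tracks = 4,
#'                                          n_states = 6))
#' head(truth$clones[, c("clone_id", "barcode", "chrom", "pos")])
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_clones
    clone_id <- sprintf("clone_%04d", seq_len(n))

    barcode <- random_barcodes(n, config$barcode_length)

    chroms <- names(config$chrom_lengths)
    chrom <- sample(chroms, n, replace = TRUE,
                    prob = config$chrom_lengths / sum(config$chrom_lengths))
    pos <- floor(stats::runif(n) * config$chrom_lengths[chrom])
    strand <- sample(c("+", "-"), n, replace = TRUE)

    tracks <- lapply(sprintf("TF%03d", seq_len(config$n_tf_tracks)),
                     simulate_signal_track,
                     chrom_lengths = config$chrom_lengths,
                     bin_size = config$track_bin_size)
    names(tracks) <- vapply(tracks, `[[`, "", "name")
    vocab <- chromhmm_states(config$n_states)
    states <- simulate_state_segmentation(config$chrom_lengths, vocab,
                                          config$state_mean_length)

    enr <- matrix(NA_real_, n, length(tracks))
    for (j in seq_along(tracks)) for (i in seq_len(n))
      enr[i, j] <- window_enrichment(tracks[[j]], chrom[i], pos[i],
                                     config$window_bp)
    dst <- matrix(NA_real_, n, length(vocab))
    for (j in seq_along(vocab)) for (i in seq_len(n))
      dst[i, j] <- distance_to_state(states, chrom[i], pos[i], vocab[j])
    features <- cbind(enr, dst)
    colnames(features) <- c(paste0("enr_", names(tracks)), paste0("dist_", vocab))
    rownames(features) <- clone_id

    eff_mean <- resolve_effects(config$effects_mean, colnames(features),
                                config$n_planted, config$planted_size)
    eff_noise <- resolve_effects(config$effects_noise, colnames(features),
                                 config$n_planted, config$planted_size)

    z <- scale_features(features)
    log10_mean <- config$mean_intercept + drop(z %*% eff_mean) +
      stats::rnorm(n, 0, config$resid_sd_mean)
    log10_cv2 <- config$noise_intercept -
      config$mean_noise_slope * log10_mean + drop(z %*% eff_noise) +
      stats::rnorm(n, 0, config$resid_sd_noise)

    mean_i <- 10^log10_mean
    cv2_i <- 10^log10_cv2
    sigma <- sqrt(log1p(cv2_i))
    mu <- log(mean_i) - sigma^2 / 2

    clones <- data.frame(clone_id = clone_id, barcode = barcode,
                         chrom = chrom, pos = as.numeric(pos), strand = strand,
                         log10_mean = log10_mean, log10_cv2 = log10_cv2,
                         mean = mean_i, cv2 = cv2_i, mu = mu, sigma = sigma,
                         stringsAsFactors = FALSE)
    structure(list(config = config, clones = clones, features = features,
                   effects = list(mean = eff_mean, noise = eff_noise),
                   epigenome = list(tracks = tracks, states = states)),
              class = "trip_truth")
  })
}

#' @export
print.trip_truth <- function(x, ...) {
  cat(sprintf("<trip_truth> %d clones | %d features (%d TF tracks, %d states) | seed %d\n",
              nrow(x$clones), ncol(x$features),
              length(x$epigenome$tracks),
              length(attr(x$epigenome$states, "vocabulary")),
              x$config$seed))
  invisible(x)
}

# Random barcodes over {A,T,G} with pairwise Hamming distance > 2 (rejection
# sampling against the accepted set).
random_barcodes <- function(n, len, min_dist = 3L) {
  alphabet <- c("A", "T", "G")
  acc <- matrix(integer(0), nrow = 0, ncol = len)
  out <- character(0)
  while (length(out) < n) {
    k <- max(16L, 2L * (n - length(out)))
    cand <- matrix(sample.int(3L, k * len, replace = TRUE), k, len)
    for (i in seq_len(k)) {
      if (length(out) >= n) break
      if (nrow(acc) > 0) {
        d <- rowSums(acc != matrix(cand[i, ], nrow(acc), len, byrow = TRUE))
        if (min(d) < min_dist) next
      }
      acc <- rbind(acc, cand[i, ])
      out <- c(out, paste(alphabet[cand[i, ]], collapse = ""))
    }
  }
  out
}

# AR(1) log-signal, exponentiated: nonnegative, spatially autocorrelated
# (correlation length ~ bin_size / (1 - phi)), unit-ish scale. Values are
# rounded to 4 decimals so bedGraph files round-trip exactly.
simulate_signal_track <- function(name, chrom_lengths, bin_size, phi = 0.98) {
  values <- lapply(chrom_lengths, function(len) {
    nb <- ceiling(len / bin_size)
    x <- as.numeric(stats::filter(stats::rnorm(nb, sd = sqrt(1 - phi^2)),
                                  phi, method = "recursive"))
    round(exp(0.6 * x), 4)
  })
  names(values) <- names(chrom_lengths)
  structure(list(name = name, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s | bin %d bp | %d chromosome(s)\n",
              x$name, x$bin_size, length(x$values)))
  invisible(x)
}

# Exponential segment lengths (floored at 200 bp), labels uniform over the
# vocabulary; every chromosome is tiled exactly once, 0-based half-open.
simulate_state_segmentation <- function(chrom_lengths, vocabulary, mean_length) {
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    w <- integer(0)
    while (sum(w) < len) {
      w <- c(w, pmax(200, round(stats::rexp(ceiling(len / mean_length) + 10,
                                            1 / mean_length))))
    }
    ends <- cumsum(w)
    k <- which(ends >= len)[1]
    ends <- ends[seq_len(k)]
    ends[k] <- len
    data.frame(chrom = ch, start = c(0, ends[-k]), end = ends,
               state = sample(vocabulary, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, rows)
  new_segmentation(seg, vocabulary, chrom_lengths)
}

new_segmentation <- function(df, vocabulary, chrom_lengths = NULL) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            vocabulary = vocabulary,
            chrom_lengths = chrom_lengths,
            class = c("state_segmentation", "data.frame"))
}

resolve_effects <- function(spec, feature_names, n_planted, planted_size) {
  beta <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (is.null(spec)) {
    pool <- grep("^enr_", feature_names, value = TRUE)
    k <- min(n_planted, length(pool))
    if (k > 0) {
      pick <- sample(pool, k)
      beta[pick] <- planted_size * rep_len(c(1, -1), k)
    }
  } else {
    if (is.null(names(spec)) && length(spec) == length(feature_names)) {
      beta[] <- spec
    } else {
      unknown <- setdiff(names(spec), feature_names)
      if (length(unknown))
        stop2("effects refer to unknown features: %s",
              paste(unknown, collapse = ", "))
      beta[names(spec)] <- spec
    }
  }
  beta
}

# z-score columns; constant or masked (NA) entries contribute 0 to effects.
scale_features <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- Inf
  z <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  z[!is.finite(z)] <- 0
  z
}
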