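#' Capacity of a k-of-n combinatorial pooling design
#'
#' The number of distinct signatures, `choose(n_pools, weight)`. With 24
#' pools and weight 4 this is 10,626 clones from 24 genomic extractions.
#'
#' @param n_pools number of pools.
#' @param weight pools per signature.
#' @return exact integer-valued count.
#' @examples
#' design_capacity(24, 4)  # 10626
#' @export
design_capacity <- function(n_pools, weight) {
  if (!is_count(n_pools) || !is_count(weight))
    stop2("n_pools and weight must be nonnegative integers")
  if (weight > n_pools)
    stop2("domain error: weight (%d) exceeds n_pools (%d)", weight, n_pools)
  round(choose(n_pools, weight))
}

#' Construct a combinatorial pooling design
#'
#' Assigns each clone a signature of exactly `weight` pools out of `n_pools`.
#' The default `"lexicographic"` scheme takes the first `n_clones`
#' weight-subsets in lexicographic order; `"balanced"` greedily equalises
#' per-pool membership (each clone takes the `weight` least-loaded pools,
#' advancing lexicographically over the load-sorted pool order when a
#' signature is already taken).
#'
#' @param n_clones number of clones; at most [design_capacity()].
#' @param n_pools,weight design geometry.
#' @param scheme `"lexicographic"` (default) or `"balanced"`.
#' @return object of class `pooling_design`: list with `n_pools`, `weight`,
#'   `pool_ids`, `scheme` and `assignments` (named list, clone id to sorted
#'   1-based pool index vector).
#' @examples
#' d <- make_design(3, 4, 2)
#' d$assignments  # {1,2}, {1,3}, {1,4}
#' @export
make_design <- function(n_clones, n_pools, weight,
                        scheme = c("lexicographic", "balanced")) {
  scheme <- match.arg(scheme)
  cap <- design_capacity(n_pools, weight)
  if (!is_count(n_clones) || n_clones < 1)
    stop2("n_clones must be a positive integer")
  if (n_clones > cap)
    stop2("capacity error: n_clones (%d) exceeds choose(%d, %d) = %s",
          n_clones, n_pools, weight, format(cap, big.mark = ","))

  assignments <- vector("list", n_clones)
  if (scheme == "lexicographic") {
    comb <- seq_len(weight)
    for (i in seq_len(n_clones)) {
      assignments[[i]] <- comb
      comb <- next_combination(comb, n_pools)
    }
  } else {
    load <- integer(n_pools)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(n_clones)) {
      ord <- order(load, seq_len(n_pools))
      comb <- seq_len(weight)  # indexes into ord
      repeat {
        sig <- sort(ord[comb])
        key <- paste(sig, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          assignments[[i]] <- sig
          load[sig] <- load[sig] + 1L
          break
        }
        comb <- next_combination(comb, n_pools)
        if (is.null(comb)) stop2("balanced scheme exhausted the design space")
      }
    }
  }
  names(assignments) <- sprintf("clone_%04d", seq_len(n_clones))
  structure(list(n_pools = as.integer(n_pools), weight = as.integer(weight),
                 pool_ids = sprintf("pool_%02d", seq_len(n_pools)),
                 scheme = scheme, assignments = assignments),
            class = "pooling_design")
}

# lexicographic successor of a k-subset of 1..n, or NULL after the last
next_combination <- function(comb, n) {
  k <- length(comb)
  i <- k
  while (i >= 1 && comb[i] == n - k + i) i <- i - 1
  if (i < 1) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < k) comb[(i + 1):k] <- comb[i] + seq_len(k - i)
  comb
}

#' @export
print.pooling_design <- function(x, ...) {
  cat(sprintf("<pooling_design> %d clones | %d-of-%d signatures | scheme %s\n",
              length(x$assignments), x$weight, x$n_pools, x$scheme))
  invisible(x)
}

#' Per-pool sequencing depths of a count table
#'
#' @param counts barcode x pool count matrix.
#' @return numeric vector of column sums.
#' @export
pool_depths <- function(counts) colSums(counts)

normalized_counts <- function(counts, depth_normalize = TRUE) {
  m <- unclass(counts)
  attr(m, "barcode_map") <- NULL
  attr(m, "design_pools") <- NULL
  if (!depth_normalize) return(m)
  d <- colSums(m)
  d[d == 0] <- 1
  sweep(m, 2, d, "/")
}

#' Call the positive pools of one barcode
#'
#' Counts are first divided by per-pool depths (column sums) when
#' `depth_normalize` is on (default), then a pool is positive iff its
#' normalized value is at least `rel_threshold` times the barcode's maximal
#' normalized value. An all-zero row yields an empty set.
#'
#' @param counts barcode x pool count matrix (rownames are barcodes).
#' @param barcode barcode (rowname) to call.
#' @param depth_normalize divide by per-pool depth first (default `TRUE`).
#' @param rel_threshold fraction of the row maximum, in (0, 1); default 0.2.
#' @return sorted integer vector of positive 1-based pool indexes.
#' @export
call_positive_pools <- function(counts, barcode, depth_normalize = TRUE,
                                rel_threshold = 0.2) {
  if (!barcode %in% rownames(counts)) stop2("barcode '%s' not in table", barcode)
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop2("rel_threshold must lie in (0, 1)")
  row <- normalized_counts(counts, depth_normalize)[barcode, ]
  positive_from_row(row, rel_threshold)
}

positive_from_row <- function(row, rel_threshold) {
  mx <- max(row)
  if (mx <= 0) return(integer(0))
  sort(which(row >= rel_threshold * mx))
}

#' Decode barcode-to-clone assignments from split-pool counts
#'
#' Implements the combinatorial decoding of a k-of-n split-pool experiment:
#' \enumerate{
#'   \item barcodes whose positive-pool set has exactly `weight` members and
#'     equals a clone's signature are `assigned`;
#'   \item barcodes with more than `weight` positive pools are matched
#'     against unions of signature pairs of still-unassigned clones: a unique
#'     matching pair gives `merged_pair`, several give `ambiguous`;
#'   \item clones matched by two or more distinct barcodes (necessarily via
#'     the identical signature) are flagged `excluded_multibarcode`;
#'   \item everything else is `unassigned`.
#' }
#' Ambiguity is terminal: the decoder never guesses.
#'
#' @param counts barcode x pool count matrix, e.g. [simulate_pool_counts()]
#'   or [read_pool_counts()].
#' @param design the [make_design()] used for pooling.
#' @param rel_threshold,depth_normalize see [call_positive_pools()].
#' @return object of class `decode_result`: list with `barcodes` (data.frame:
#'   barcode, status, clone, clone2, positive_pools) and `clones` (data.frame:
#'   clone_id, n_barcodes, excluded_multibarcode).
#' @export
decode_pools <- function(counts, design, rel_threshold = 0.2,
                         depth_normalize = TRUE) {
  stopifnot(inherits(design, "pooling_design"))
  norm <- normalized_counts(counts, depth_normalize)
  barcodes <- rownames(norm)
  pos_sets <- lapply(seq_len(nrow(norm)), function(i)
    positive_from_row(norm[i, ], rel_threshold))

  sig_of <- design$assignments
  sig_key <- vapply(sig_of, paste, "", collapse = ",")
  clone_by_key <- stats::setNames(names(sig_of), sig_key)
  w <- design$weight
  member <- matrix(FALSE, length(sig_of), design$n_pools,
                   dimnames = list(names(sig_of), NULL))
  for (cl in names(sig_of)) member[cl, sig_of[[cl]]] <- TRUE

  status <- rep("unassigned", length(barcodes))
  clone <- rep(NA_character_, length(barcodes))
  clone2 <- rep(NA_character_, length(barcodes))

  # (1) exact signature matches
  for (i in seq_along(barcodes)) {
    p <- pos_sets[[i]]
    if (length(p) == w) {
      hit <- clone_by_key[paste(p, collapse = ",")]
      if (!is.na(hit)) {
        status[i] <- "assigned"
        clone[i] <- hit
      }
    }
  }

  # (2) merged pairs among still-unassigned clones
  un_clones <- setdiff(names(sig_of), clone[status == "assigned"])
  for (i in seq_along(barcodes)) {
    p <- pos_sets[[i]]
    if (length(p) <= w || length(p) > 2 * w) next
    inP <- rep(FALSE, design$n_pools)
    inP[p] <- TRUE
    cand <- un_clones[rowSums(member[un_clones, p, drop = FALSE]) == w &
                        rowSums(member[un_clones, !inP, drop = FALSE]) == 0]
    if (length(cand) < 2) next
    hits <- list()
    for (a in seq_len(length(cand) - 1)) {
      for (b in seq.int(a + 1, length(cand))) {
        u <- union(sig_of[[cand[a]]], sig_of[[cand[b]]])
        if (length(u) == length(p) && all(sort(u) == p))
          hits[[length(hits) + 1L]] <- c(cand[a], cand[b])
      }
    }
    if (length(hits) == 1L) {
      status[i] <- "merged_pair"
      clone[i] <- hits[[1]][1]
      clone2[i] <- hits[[1]][2]
    } else if (length(hits) > 1L) {
      status[i] <- "ambiguous"
    }
  }

  bdf <- data.frame(barcode = barcodes, status = status, clone = clone,
                    clone2 = clone2,
                    positive_pools = vapply(pos_sets, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  n_bc <- table(factor(clone[status == "assigned"], levels = names(sig_of)))
  cdf <- data.frame(clone_id = names(sig_of),
                    n_barcodes = as.integer(n_bc),
                    excluded_multibarcode = as.integer(n_bc) >= 2L,
                    stringsAsFactors = FALSE)
  rownames(cdf) <- NULL
  structure(list(barcodes = bdf, clones = cdf), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  tab <- table(x$barcodes$status)
  cat("<decode_result>",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = " | "),
      sprintf("| multibarcode clones: %d\n",
              sum(x$clones$excluded_multibarcode)))
  invisible(x)
}
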