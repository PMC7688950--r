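#' Cluster mapped reads of one barcode and replicate into candidate loci
#'
#' Reads on the same chromosome and strand are merged greedily along the
#' position-sorted axis: a read joins the open cluster while it lies within
#' `merge_window` bp of the cluster representative, which is the modal read
#' position of the cluster so far (ties broken towards the smallest
#' position). Read counts are conserved.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand` (one barcode, one
#'   replicate).
#' @param merge_window merge radius in bp (default 10).
#' @return data.frame (`chrom`, `strand`, `pos`, `count`) sorted by count
#'   descending; `pos` is the cluster representative.
#' @export
cluster_reads <- function(reads, merge_window = 10) {
  stopifnot(merge_window >= 0)
  if (nrow(reads) == 0)
    return(data.frame(chrom = character(0), strand = character(0),
                      pos = numeric(0), count = integer(0)))
  key <- paste(reads$chrom, reads$strand, sep = "\r")
  out <- lapply(split(reads$pos, key), function(pos) {
    tab <- table(pos)
    upos <- as.numeric(names(tab))
    cnt <- as.integer(tab)
    o <- order(upos)
    upos <- upos[o]; cnt <- cnt[o]
    reps <- numeric(0); reps_n <- integer(0)
    mem_pos <- numeric(0); mem_cnt <- integer(0)
    rep_cur <- NA_real_
    flush <- function() {
      if (length(mem_pos)) {
        reps <<- c(reps, rep_cur)
        reps_n <<- c(reps_n, sum(mem_cnt))
      }
    }
    for (k in seq_along(upos)) {
      if (is.na(rep_cur) || upos[k] - rep_cur > merge_window) {
        flush()
        mem_pos <- upos[k]; mem_cnt <- cnt[k]
      } else {
        mem_pos <- c(mem_pos, upos[k]); mem_cnt <- c(mem_cnt, cnt[k])
      }
      # modal member, ties -> smallest position (members are position-sorted)
      rep_cur <- mem_pos[which.max(mem_cnt)]
    }
    flush()
    list(pos = reps, count = reps_n)
  })
  ck <- do.call(rbind, strsplit(names(out), "\r", fixed = TRUE))
  res <- data.frame(
    chrom = rep(ck[, 1], vapply(out, function(x) length(x$pos), 0L)),
    strand = rep(ck[, 2], vapply(out, function(x) length(x$pos), 0L)),
    pos = unlist(lapply(out, `[[`, "pos"), use.names = FALSE),
    count = unlist(lapply(out, `[[`, "count"), use.names = FALSE),
    stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top candidate locus among read clusters
#'
#' The cluster with the maximal read count; a tie for the maximum means no
#' confident top candidate.
#'
#' @param clusters data.frame from [cluster_reads()].
#' @return one-row data.frame, or `NULL` when empty or tied.
#' @export
top_candidate <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0) return(NULL)
  mx <- max(clusters$count)
  hit <- which(clusters$count == mx)
  if (length(hit) != 1L) return(NULL)
  clusters[hit, , drop = FALSE]
}

#' Assign replicate-concordant integration sites to barcodes
#'
#' Per barcode, reads of each replicate are clustered and reduced to a top
#' candidate. A site is `assigned` only when both replicates yield a top
#' candidate on the same chromosome and strand within `merge_window` bp; the
#' replicate-1 representative is reported. A barcode with reads in only one
#' replicate is `single_replicate`; mismatching (or tied, hence unconfident)
#' tops are `discordant`; a barcode without reads is `unmapped`.
#'
#' @param reads_rep1,reads_rep2 data.frames (`barcode`, `chrom`, `pos`,
#'   `strand`) of mapped reads per replicate.
#' @param merge_window bp window for clustering and for calling two top
#'   candidates identical (default 10; 0 gives strict identity).
#' @param barcodes barcodes to report (default: union of both tables); pass
#'   the genuine-barcode list to key the output on it.
#' @return data.frame of class `integration_sites`: one row per barcode with
#'   `chrom`, `pos`, `strand`, `status`, `support_rep1`, `support_rep2`.
#' @export
assign_sites <- function(reads_rep1, reads_rep2, merge_window = 10,
                         barcodes = NULL) {
  for (df in list(reads_rep1, reads_rep2))
    stopifnot(all(c("barcode", "chrom", "pos", "strand") %in% names(df)))
  if (is.null(barcodes))
    barcodes <- sort(unique(c(reads_rep1$barcode, reads_rep2$barcode)))

  f1 <- split(reads_rep1, factor(reads_rep1$barcode, levels = barcodes))
  f2 <- split(reads_rep2, factor(reads_rep2$barcode, levels = barcodes))

  one <- function(bc) {
    r1 <- f1[[bc]]; r2 <- f2[[bc]]
    has1 <- !is.null(r1) && nrow(r1) > 0
    has2 <- !is.null(r2) && nrow(r2) > 0
    t1 <- if (has1) top_candidate(cluster_reads(r1, merge_window)) else NULL
    t2 <- if (has2) top_candidate(cluster_reads(r2, merge_window)) else NULL
    row <- data.frame(barcode = bc, chrom = NA_character_, pos = NA_real_,
                      strand = NA_character_, status = "unmapped",
                      support_rep1 = if (has1) nrow(r1) else 0L,
                      support_rep2 = if (has2) nrow(r2) else 0L,
                      stringsAsFactors = FALSE)
    if (!has1 && !has2) return(row)
    if (xor(has1, has2)) {
      row$status <- "single_replicate"
      t <- if (has1) t1 else t2
      if (!is.null(t)) {
        row$chrom <- t$chrom; row$pos <- t$pos; row$strand <- t$strand
      }
      return(row)
    }
    if (is.null(t1) || is.null(t2)) {  # reads in both, but no confident top
      row$status <- "discordant"
      return(row)
    }
    match_ok <- t1$chrom == t2$chrom && t1$strand == t2$strand &&
      abs(t1$pos - t2$pos) <= merge_window
    if (match_ok) {
      row$status <- "assigned"
      row$chrom <- t1$chrom; row$pos <- t1$pos; row$strand <- t1$strand
      row$support_rep1 <- t1$count; row$support_rep2 <- t2$count
    } else {
      row$status <- "discordant"
    }
    row
  }

  out <- do.call(rbind, lapply(barcodes, one))
  rownames(out) <- NULL
  class(out) <- c("integration_sites", "data.frame")
  out
}
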