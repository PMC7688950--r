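#' Quality-filter sequencing reads
#'
#' A read passes iff its length equals `expected_length` and the fraction of
#' bases with Phred quality below `min_quality` is at most
#' `max_lowq_fraction` (defaults: more than 25\% of bases below Q20 fails).
#'
#' @param reads data.frame with `sequence` and `qualities` (Phred+33 strings)
#'   columns, e.g. from [read_fastq()] or [simulate_barcode_reads()].
#' @param expected_length required read length in nt.
#' @param max_lowq_fraction maximal tolerated fraction of low-quality bases.
#' @param min_quality Phred score below which a base counts as low quality.
#' @return the passing subset of `reads` (possibly empty).
#' @examples
#' r <- data.frame(sequence = c("ATGATGATGATGATGA", "ATG"),
#'                 qualities = c(strrep("I", 16), strrep("I", 3)))
#' nrow(filter_reads(r, 16))
#' @export
filter_reads <- function(reads, expected_length = 16,
                         max_lowq_fraction = 0.25, min_quality = 20) {
  stopifnot(is.data.frame(reads),
            all(c("sequence", "qualities") %in% names(reads)))
  if (nrow(reads) == 0) return(reads)
  len_ok <- nchar(reads$sequence) == expected_length &
    nchar(reads$qualities) == nchar(reads$sequence)
  lowq_frac <- rep(1, nrow(reads))
  if (any(len_ok)) {
    # constant-quality fast path (the common simulator output)
    qs <- reads$qualities[len_ok]
    uq <- unique(qs)
    frac <- vapply(uq, function(s) mean(utf8ToInt(s) - 33L < min_quality), 0)
    lowq_frac[len_ok] <- frac[match(qs, uq)]
  }
  reads[len_ok & lowq_frac <= max_lowq_fraction, , drop = FALSE]
}

#' Demultiplex reads by exact sample-index match
#'
#' @param reads data.frame with an `index` column (6-nt sample indexes).
#' @param index_table named character vector mapping index sequence to pool
#'   id. Indexes must be pairwise distinct.
#' @param mismatch allowed index mismatches; only the default 0 (exact match)
#'   and 1 are supported.
#' @return named list of data.frames, one per pool id plus an `"unassigned"`
#'   bin; the bins partition the input.
#' @export
demultiplex <- function(reads, index_table, mismatch = 0) {
  stopifnot(is.data.frame(reads), "index" %in% names(reads))
  idx <- names(index_table)
  if (is.null(idx) || anyDuplicated(idx))
    stop2("configuration error: index_table must have pairwise-distinct index names")
  pool <- as.character(index_table[match(reads$index, idx)])
  if (mismatch > 0) {
    todo <- which(is.na(pool))
    for (i in todo) {
      d <- vapply(idx, function(x) hamming(reads$index[i], x), 0L)
      hit <- which(d <= mismatch)
      if (length(hit) == 1L) pool[i] <- index_table[[hit]]
    }
  }
  pool[is.na(pool)] <- "unassigned"
  bins <- split(reads, factor(pool, levels = c(unique(unname(index_table)),
                                               "unassigned")))
  lapply(bins, function(df) { rownames(df) <- NULL; df })
}

#' Hamming distance between equal-length sequences
#'
#' @param a a single sequence.
#' @param b a sequence or vector of sequences of the same length as `a`.
#' @return integer vector of mismatch counts.
#' @examples
#' hamming("ATGATG", "TAGATG")
#' @export
hamming <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b))
  if (any(nchar(b) != nchar(a)))
    stop2("length error: sequences must have equal length")
  ra <- charToRaw(a)
  vapply(b, function(x) sum(charToRaw(x) != ra), 0L, USE.NAMES = FALSE)
}

#' Tabulate barcode read counts
#'
#' @param reads data.frame with a `sequence` column, or a character vector of
#'   barcode sequences.
#' @return data.frame (`barcode`, `count`) sorted by count descending then
#'   barcode ascending, with attribute `total_reads`.
#' @export
count_barcodes <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  tab <- table(seqs)
  out <- data.frame(barcode = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_reads") <- length(seqs)
  class(out) <- c("barcode_counts", "data.frame")
  out
}

#' Collapse sequencing-error mutants into genuine barcodes
#'
#' Greedy pass over barcodes sorted by count descending (ties broken by
#' lexicographically ascending sequence): each barcode not yet removed is
#' declared genuine, and all not-yet-processed barcodes within Hamming
#' distance `radius` of it are removed and logged as its mutants. Removal is
#' one-shot: a barcode removed as a mutant can never absorb others.
#'
#' `min_count` (default 1, i.e. off) drops barcodes below a count floor
#' before collapsing; with nonzero sequencing error, reads carrying three or
#' more substitutions fall outside every genuine barcode's radius and would
#' otherwise surface as spurious singleton "genuine" barcodes.
#'
#' @param counts a [count_barcodes()] data.frame or named count vector.
#' @param radius maximal Hamming distance of an absorbed mutant (default 2).
#' @param min_count minimal read count for a barcode to participate.
#' @return data.frame (`barcode`, `count`, `total_count`) of class
#'   `genuine_barcodes`, ordered by count descending; `total_count` adds the
#'   counts of absorbed mutants. Attribute `removal_log` is a data.frame
#'   (`removed`, `count`, `absorbed_by`).
#' @examples
#' cts <- count_barcodes(c("AAAA", "AAAA", "AAAT"))
#' call_genuine(cts, radius = 2)
#' @export
call_genuine <- function(counts, radius = 2, min_count = 1) {
  if (!is.data.frame(counts)) {
    stopifnot(!is.null(names(counts)))
    counts <- data.frame(barcode = names(counts), count = as.integer(counts),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("barcode", "count") %in% names(counts)))
  counts <- counts[counts$count >= min_count, , drop = FALSE]
  if (nrow(counts) == 0) stop2("no barcodes left after count filtering")
  if (length(unique(nchar(counts$barcode))) != 1L)
    stop2("length error: all barcodes must have equal length")

  o <- order(-counts$count, counts$barcode)
  bc <- counts$barcode[o]
  ct <- counts$count[o]
  n <- length(bc)
  # L x n character matrix: column j is barcode j
  M <- matrix(unlist(strsplit(bc, "", fixed = TRUE), use.names = FALSE),
              ncol = n)

  alive <- rep(TRUE, n)
  genuine <- logical(n)
  absorbed_by <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    genuine[i] <- TRUE
    if (i < n) {
      js <- which(alive[(i + 1L):n]) + i
      if (length(js)) {
        d <- colSums(M[, js, drop = FALSE] != M[, i])
        hit <- js[d <= radius]
        alive[hit] <- FALSE
        absorbed_by[hit] <- i
      }
    }
  }

  absorbed_counts <- vapply(which(genuine), function(i)
    sum(ct[which(absorbed_by == i)]), 0)
  out <- data.frame(barcode = bc[genuine], count = ct[genuine],
                    total_count = ct[genuine] + absorbed_counts,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "removal_log") <- data.frame(
    removed = bc[!genuine], count = ct[!genuine],
    absorbed_by = bc[absorbed_by[!genuine]], stringsAsFactors = FALSE)
  class(out) <- c("genuine_barcodes", "data.frame")
  out
}
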