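# File interchange. Standard formats go through Biostrings (FASTQ) and
# rtracklayer (bedGraph, BED); tables are plain TSV/CSV; ground truth is
# JSON. Coordinates are 0-based half-open on disk and in memory; GRanges
# conversion (1-based closed) happens only at the rtracklayer boundary.

#' Read a FASTQ file
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame (`read_id`, `sequence`, `qualities`).
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(s),
             sequence = as.character(s),
             qualities = as.character(S4Vectors::mcols(s)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param reads data.frame (`read_id`, `sequence`, `qualities`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  grs <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- length(v)
    start0 <- (seq_len(nb) - 1) * track$bin_size
    end0 <- pmin(track$chrom_lengths[[ch]], start0 + track$bin_size)
    GenomicRanges::GRanges(ch, IRanges::IRanges(start = start0 + 1, end = end0),
                           score = v)
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph signal track into the binned representation
#'
#' @param path bedGraph file.
#' @param name track name (default: file name without extension).
#' @param bin_size bin width in bp; default: the smallest interval width in
#'   the file (bedGraph writers merge runs of equal values, so intervals may
#'   span several bins).
#' @param chrom_lengths optional named vector; default: the maximal end per
#'   chromosome.
#' @return a `signal_track`.
#' @export
read_track <- function(path, name = NULL, bin_size = NULL, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  ch <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- GenomicRanges::end(gr)
  score <- S4Vectors::mcols(gr)$score
  bin_size <- bin_size %||% min(GenomicRanges::width(gr))
  chroms <- unique(ch)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(c) max(e0[ch == c]), 0)
  values <- lapply(chroms, function(c) {
    len <- chrom_lengths[[c]]
    v <- numeric(ceiling(len / bin_size))
    i <- which(ch == c)
    for (k in i) {
      bins <- seq.int(floor(s0[k] / bin_size), ceiling(e0[k] / bin_size) - 1)
      v[bins + 1] <- score[k]
    }
    v
  })
  names(values) <- chroms
  structure(list(name = name %||% sub("\\.[^.]*$", "", basename(path)),
                 bin_size = bin_size,
                 chrom_lengths = chrom_lengths[chroms], values = values),
            class = "signal_track")
}

#' Write a chromatin-state segmentation as BED4
#' @param seg a `state_segmentation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(seg, path) {
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(start = seg$start + 1,
                                                end = seg$end))
  gr$name <- seg$state
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED4 chromatin-state segmentation
#' @param path BED file (chrom, start, end, state; 0-based half-open).
#' @param vocabulary optional state vocabulary; default: the sorted unique
#'   labels present.
#' @param chrom_lengths optional named chromosome lengths.
#' @return a `state_segmentation`.
#' @export
read_states <- function(path, vocabulary = NULL, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   state = S4Vectors::mcols(gr)$name,
                   stringsAsFactors = FALSE)
  new_segmentation(df, vocabulary %||% sort(unique(df$state)), chrom_lengths)
}

#' @rdname design_io
#' @export
write_design <- function(design, path) {
  df <- data.frame(clone_id = names(design$assignments),
                   pools = vapply(design$assignments, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv0(df, path)
  invisible(path)
}

#' Read/write pooling designs
#'
#' TSV with columns `clone_id` and `pools` (comma-joined 1-based pool
#' indexes).
#'
#' @param design a `pooling_design`.
#' @param path file path.
#' @param n_pools total pool count; default: the largest index present.
#' @return `read_design` returns a `pooling_design`; the writer returns
#'   `path` invisibly.
#' @name design_io
#' @export
read_design <- function(path, n_pools = NULL) {
  df <- read_tsv0(path, colClasses = c("character", "character"))
  assignments <- lapply(strsplit(df$pools, ","), function(x) sort(as.integer(x)))
  names(assignments) <- df$clone_id
  w <- unique(lengths(assignments))
  if (length(w) != 1L) stop2("design has signatures of unequal weight")
  n_pools <- as.integer(n_pools %||% max(unlist(assignments)))
  structure(list(n_pools = n_pools, weight = w,
                 pool_ids = sprintf("pool_%02d", seq_len(n_pools)),
                 scheme = "file", assignments = assignments),
            class = "pooling_design")
}

#' @rdname pool_counts_io
#' @export
write_pool_counts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts),
                   as.data.frame(unclass(counts)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv0(df, path)
  invisible(path)
}

#' Read/write barcode-by-pool count tables
#'
#' TSV with a `barcode` column followed by one integer column per pool.
#'
#' @param counts matrix with barcode rownames and pool colnames.
#' @param path file path.
#' @return `read_pool_counts` returns an integer matrix of class
#'   `pool_counts`; the writer returns `path` invisibly.
#' @name pool_counts_io
#' @export
read_pool_counts <- function(path) {
  df <- read_tsv0(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  storage.mode(m) <- "integer"
  structure(m, class = c("pool_counts", class(m)))
}

#' @rdname trip_io
#' @export
write_trip_reads <- function(reads, path) {
  write_tsv0(reads[, intersect(c("barcode", "chrom", "pos", "strand",
                                 "replicate"), names(reads))], path)
  invisible(path)
}

#' Read/write mapped integration-read tables
#'
#' TSV with columns `barcode`, `chrom`, `pos` (0-based bp), `strand` and
#' optionally `replicate`.
#'
#' @param reads mapped-read data.frame.
#' @param path file path.
#' @return `read_trip_reads` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @name trip_io
#' @export
read_trip_reads <- function(path) read_tsv0(path)

#' @rdname flow_io
#' @export
write_flow_events <- function(events, path, include_truth = FALSE) {
  cols <- c("clone_id", "replicate", "fsc", "ssc", "clover", "irfp")
  if (include_truth && "control" %in% names(events)) cols <- c(cols, "control")
  utils::write.csv(events[, intersect(cols, names(events))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write flow-cytometry event tables
#'
#' CSV with per-event `fsc`, `ssc`, `clover`, `irfp` (plus `clone_id` and
#' `replicate` when events of several wells share a file).
#'
#' @param events event data.frame.
#' @param path file path.
#' @param include_truth also write the hidden ground-truth `control` label.
#' @return `read_flow_events` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @name flow_io
#' @export
read_flow_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an expression summary table
#' @param summaries a [summarize_expression()] data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression_summary <- function(summaries, path) {
  write_tsv0(summaries, path)
  invisible(path)
}

#' @rdname truth_io
#' @export
write_truth <- function(truth, path) {
  cfg <- unclass(truth$config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  obj <- list(config = cfg,
              clones = truth$clones,
              features = data.frame(clone_id = rownames(truth$features),
                                    truth$features, check.names = FALSE),
              effects = list(mean = as.list(truth$effects$mean),
                             noise = as.list(truth$effects$noise)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write synthetic ground truth as JSON
#'
#' The epigenome itself is carried by its bedGraph/BED files (see
#' [simulate_epigenome()]); `read_truth` therefore returns a `trip_truth`
#' without the `epigenome` element.
#'
#' @param truth a [generate_truth()] object.
#' @param path file path.
#' @return `read_truth` returns a `trip_truth` (no epigenome); the writer
#'   returns `path` invisibly.
#' @name truth_io
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("effects_mean", "effects_noise"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  class(cfg) <- "synthetic_config"
  feats <- as.matrix(obj$features[, -1, drop = FALSE])
  rownames(feats) <- obj$features$clone_id
  structure(list(config = cfg, clones = obj$clones, features = feats,
                 effects = list(mean = unlist(obj$effects$mean),
                                noise = unlist(obj$effects$noise)),
                 epigenome = NULL),
            class = "trip_truth")
}

#' @rdname decode_io
#' @export
write_decode_result <- function(result, path) {
  write_tsv0(result$barcodes, path)
  invisible(path)
}

#' Read/write decode results
#'
#' TSV of per-barcode decode rows (`barcode`, `status`, `clone`, `clone2`,
#' `positive_pools`).
#'
#' @param result a [decode_pools()] result.
#' @param path file path.
#' @return `read_decode_result` returns the barcode data.frame; the writer
#'   returns `path` invisibly.
#' @name decode_io
#' @export
read_decode_result <- function(path) read_tsv0(path)

#' Write integration sites
#' @param sites an [assign_sites()] data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write_tsv0(sites, path)
  invisible(path)
}

#' Read integration sites
#' @param path TSV written by [write_sites()].
#' @return data.frame of class `integration_sites`.
#' @export
read_sites <- function(path) {
  df <- read_tsv0(path)
  class(df) <- c("integration_sites", "data.frame")
  df
}

#' Write a feature matrix with a JSON metadata sidecar
#' @param fm a [build_feature_matrix()] object.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(clone_id = rownames(fm$x), fm$x, check.names = FALSE)
  if (!is.null(fm$expression))
    df <- cbind(df, fm$expression[, c("mean_avg", "cv2_avg")])
  write_tsv0(df, path)
  jsonlite::write_json(fm$meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}
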