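#' Simulate barcode sequencing reads
#'
#' Emits `reads_per_barcode` copies of each true barcode with independent
#' per-base substitution errors. A substitution always changes the base and
#' may introduce any of the other three nucleotides (sequencer noise is
#' alphabet-blind, so C appears in errors even though true barcodes use only
#' A/T/G). Quality strings are constant at the Phred score implied by the
#' error rate (Q40 when the error rate is 0). Uses RNG stream `seed + 1`.
#'
#' @param truth a [generate_truth()] object.
#' @param config configuration; defaults to `truth$config`.
#' @param reads_per_barcode,error_rate,seed overrides of the corresponding
#'   configuration fields.
#' @return data.frame (`read_id`, `sequence`, `qualities`) with attribute
#'   `truth_clone` giving the emitting clone of every read.
#' @export
simulate_barcode_reads <- function(truth, config = truth$config,
                                   reads_per_barcode = config$reads_per_barcode,
                                   error_rate = config$per_base_error_rate,
                                   seed = config$seed + 1L) {
  stopifnot(inherits(truth, "trip_truth"))
  if (error_rate < 0 || error_rate >= 1) stop2("error_rate must lie in [0, 1)")
  with_seed(seed, {
    len <- config$barcode_length
    bc <- rep(truth$clones$barcode, each = reads_per_barcode)
    clone <- rep(truth$clones$clone_id, each = reads_per_barcode)
    m <- matrix(unlist(strsplit(bc, "", fixed = TRUE), use.names = FALSE),
                ncol = len, byrow = TRUE)
    if (error_rate > 0) {
      hit <- matrix(stats::runif(length(m)) < error_rate, nrow(m), len)
      if (any(hit)) {
        others <- matrix(c("C", "G", "T",
                           "A", "G", "T",
                           "A", "C", "T",
                           "A", "C", "G"),
                         nrow = 4, byrow = TRUE,
                         dimnames = list(c("A", "C", "G", "T"), NULL))
        orig <- m[hit]
        m[hit] <- others[cbind(match(orig, rownames(others)),
                               sample.int(3L, length(orig), replace = TRUE))]
      }
    }
    q <- if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L
    reads <- data.frame(
      read_id = sprintf("read_%07d", seq_along(bc)),
      sequence = paste_rows(m),
      qualities = strrep(int_to_phred(q), len),
      stringsAsFactors = FALSE)
    attr(reads, "truth_clone") <- clone
    reads
  })
}

#' Simulate the barcode-by-pool count table of a split-pool experiment
#'
#' Each barcode's reads are multinomially distributed over its clone's
#' signature pools, plus independent Poisson background in every pool. Two
#' decoder failure modes are injected at configurable rates: \emph{merged}
#' barcodes (sister cells of one founder sorted into two wells, so one
#' barcode reads out the union of two clones' signatures and the partner
#' clone contributes no barcode of its own) and \emph{double-barcode} clones
#' (a second barcode carrying the same signature). Finally, every pool
#' column is scaled by a lognormal library-depth factor (`depth_sdlog`),
#' emulating unequal sequencing depth of the per-pool PCR libraries; per-pool
#' depth normalization in the decoder cancels these factors exactly. Uses
#' RNG stream `seed + 2`.
#'
#' @param truth a [generate_truth()] object.
#' @param design a [make_design()] covering all clones in `truth`.
#' @param config configuration; defaults to `truth$config`.
#' @param reads_per_barcode,background,merged_rate,double_rate,depth_sdlog,seed
#'   overrides.
#' @return integer matrix (barcodes x pools) of class `pool_counts` with
#'   attributes `barcode_map` (data.frame: barcode, clone_id, role, partner)
#'   and `design_pools` (pool ids).
#' @export
simulate_pool_counts <- function(truth, design, config = truth$config,
                                 reads_per_barcode = config$reads_per_barcode,
                                 background = config$pool_background,
                                 merged_rate = config$merged_rate,
                                 double_rate = config$double_rate,
                                 depth_sdlog = config$pool_depth_sdlog,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(truth, "trip_truth"), inherits(design, "pooling_design"))
  missing_cl <- setdiff(truth$clones$clone_id, names(design$assignments))
  if (length(missing_cl))
    stop2("design does not cover clones: %s",
          paste(utils::head(missing_cl, 5), collapse = ", "))
  with_seed(seed, {
    n <- nrow(truth$clones)
    np <- design$n_pools

    n_merged <- min(floor(merged_rate * n), floor(n / 2))
    avail <- sample(truth$clones$clone_id)  # random involvement order
    merged_host <- avail[seq_len(n_merged)]
    merged_partner <- avail[n_merged + seq_len(n_merged)]
    rest <- avail[-seq_len(2 * n_merged)]
    n_double <- min(floor(double_rate * n), length(rest))
    doubled <- rest[seq_len(n_double)]

    rows <- list()
    map <- list()
    emit <- function(barcode, clone, pools, role, partner = NA_character_) {
      cnt <- integer(np)
      sig <- as.integer(stats::rmultinom(1, reads_per_barcode,
                                         rep(1 / length(pools), length(pools))))
      cnt[pools] <- sig
      if (background > 0)
        cnt <- cnt + stats::rpois(np, background * reads_per_barcode / np)
      rows[[length(rows) + 1L]] <<- cnt
      map[[length(map) + 1L]] <<- data.frame(
        barcode = barcode, clone_id = clone, role = role, partner = partner,
        stringsAsFactors = FALSE)
    }

    existing <- truth$clones$barcode
    for (i in seq_len(n)) {
      cl <- truth$clones$clone_id[i]
      bc <- truth$clones$barcode[i]
      sig <- design$assignments[[cl]]
      if (cl %in% merged_partner) next  # its well holds the host's barcode
      if (cl %in% merged_host) {
        partner <- merged_partner[match(cl, merged_host)]
        emit(bc, cl, sort(union(sig, design$assignments[[partner]])),
             "merged", partner)
      } else {
        emit(bc, cl, sig, "single")
        if (cl %in% doubled) {
          extra <- random_extra_barcode(existing, config$barcode_length)
          existing <- c(existing, extra)
          emit(extra, cl, sig, "double_extra")
        }
      }
    }

    counts <- do.call(rbind, rows)
    map <- do.call(rbind, map)
    if (depth_sdlog > 0) {
      f <- stats::rlnorm(np, 0, depth_sdlog)
      counts <- round(sweep(counts, 2, f, "*"))
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(map$barcode, design$pool_ids)
    structure(counts, barcode_map = map, design_pools = design$pool_ids,
              class = c("pool_counts", class(counts)))
  })
}

random_extra_barcode <- function(existing, len, min_dist = 3L) {
  alphabet <- c("A", "T", "G")
  repeat {
    cand <- paste(alphabet[sample.int(3L, len, replace = TRUE)], collapse = "")
    d <- vapply(existing, function(b) hamming(cand, b), 0L)
    if (min(d) >= min_dist) return(cand)
  }
}

#' Simulate replicate integration-mapping read tables
#'
#' Inverse-PCR junction reads scatter within `jitter` bp of the true site; a
#' configurable fraction are off-target (uniform over the genome, random
#' strand) and a configurable fraction of barcodes are fully discordant
#' (their replicate-2 reads cluster at a different site), to exercise the
#' replicate-concordance filter. Uses RNG stream `seed + 3`.
#'
#' @param truth a [generate_truth()] object.
#' @param config configuration; defaults to `truth$config`.
#' @param reads_per_barcode,off_target,discordant_fraction,jitter,seed
#'   overrides of the corresponding `trip_*` configuration fields.
#' @return data.frame (`barcode`, `chrom`, `pos`, `strand`, `replicate`) with
#'   attribute `discordant_barcodes`.
#' @export
simulate_trip_reads <- function(truth, config = truth$config,
                                reads_per_barcode = config$trip_reads_per_barcode,
                                off_target = config$trip_off_target,
                                discordant_fraction = config$trip_discordant,
                                jitter = config$trip_jitter,
                                seed = config$seed + 3L) {
  stopifnot(inherits(truth, "trip_truth"))
  with_seed(seed, {
    cl <- truth$clones
    n <- nrow(cl)
    chroms <- names(config$chrom_lengths)
    n_disc <- round(discordant_fraction * n)
    disc <- sample(cl$barcode, n_disc)

    alt_chrom <- sample(chroms, n, replace = TRUE)
    alt_pos <- floor(stats::runif(n) * config$chrom_lengths[alt_chrom])
    alt_strand <- sample(c("+", "-"), n, replace = TRUE)

    sim_rep <- function(rep_id) {
      use_alt <- rep_id == 2L & cl$barcode %in% disc
      site_chrom <- ifelse(use_alt, alt_chrom, cl$chrom)
      site_pos <- ifelse(use_alt, alt_pos, cl$pos)
      site_strand <- ifelse(use_alt, alt_strand, cl$strand)

      m <- reads_per_barcode
      barcode <- rep(cl$barcode, each = m)
      chrom <- rep(site_chrom, each = m)
      pos <- rep(site_pos, each = m) +
        sample(seq.int(-jitter, jitter), n * m, replace = TRUE)
      strand <- rep(site_strand, each = m)
      off <- stats::runif(n * m) < off_target
      if (any(off)) {
        k <- sum(off)
        oc <- sample(chroms, k, replace = TRUE)
        chrom[off] <- oc
        pos[off] <- floor(stats::runif(k) * config$chrom_lengths[oc])
        strand[off] <- sample(c("+", "-"), k, replace = TRUE)
      }
      data.frame(barcode = barcode, chrom = chrom,
                 pos = pmax(0, pos), strand = strand,
                 replicate = rep_id, stringsAsFactors = FALSE)
    }
    out <- rbind(sim_rep(1L), sim_rep(2L))
    rownames(out) <- NULL
    attr(out, "discordant_barcodes") <- disc
    out
  })
}

#' Simulate flow-cytometry event tables
#'
#' For each clone and replicate, experimental cells draw Clover intensity
#' from the clone's lognormal `(mu, sigma)`; a fraction `control_fraction` of
#' events are internal-control cells with a fixed shared Clover distribution
#' and high IRFP. FSC/SSC come from a common lognormal size model independent
#' of clone; a fraction `size_coupling` of the Clover log-SD is carried by
#' the same latent size factor, creating the extrinsic noise a scatter gate
#' removes. Optional per clone-and-replicate batch jitter (`rep_effect_sd`)
#' perturbs `mu` additively and `sigma` multiplicatively on the log scale.
#' Uses RNG stream `seed + 4`.
#'
#' @param truth a [generate_truth()] object.
#' @param config configuration; defaults to `truth$config`.
#' @param cells_per_clone,control_fraction,replicates,size_coupling,
#'   rep_effect_sd,seed overrides.
#' @return data.frame (`clone_id`, `replicate`, `fsc`, `ssc`, `clover`,
#'   `irfp`, `control`); `control` is the hidden ground-truth label that the
#'   pipeline itself never reads.
#' @export
simulate_flow_events <- function(truth, config = truth$config,
                                 cells_per_clone = config$cells_per_clone,
                                 control_fraction = config$control_fraction,
                                 replicates = 3L,
                                 size_coupling = config$size_coupling,
                                 rep_effect_sd = config$rep_effect_sd,
                                 seed = config$seed + 4L) {
  stopifnot(inherits(truth, "trip_truth"))
  with_seed(seed, {
    w <- size_coupling
    out <- vector("list", nrow(truth$clones) * replicates)
    k <- 0L
    for (i in seq_len(nrow(truth$clones))) {
      for (r in seq_len(replicates)) {
        n_ctl <- round(cells_per_clone * control_fraction)
        n_exp <- cells_per_clone - n_ctl
        mu <- truth$clones$mu[i]
        sigma <- truth$clones$sigma[i]
        if (rep_effect_sd > 0) {
          mu <- mu + stats::rnorm(1, 0, rep_effect_sd)
          sigma <- sigma * exp(stats::rnorm(1, 0, rep_effect_sd))
        }
        u <- stats::rnorm(cells_per_clone)
        fsc <- exp(config$fsc_meanlog + config$size_sd * u +
                     config$scatter_noise_sd * stats::rnorm(cells_per_clone))
        ssc <- exp(config$ssc_meanlog + 0.8 * config$size_sd * u +
                     config$scatter_noise_sd * stats::rnorm(cells_per_clone))
        is_ctl <- c(rep(FALSE, n_exp), rep(TRUE, n_ctl))
        z <- stats::rnorm(cells_per_clone)
        loadings <- w * u + sqrt(1 - w^2) * z
        clover <- ifelse(is_ctl,
                         exp(config$control_clover_meanlog +
                               config$control_clover_sdlog * loadings),
                         exp(mu + sigma * loadings))
        irfp <- exp(ifelse(is_ctl, config$irfp_control_meanlog,
                           config$irfp_background_meanlog) +
                      config$irfp_sdlog * stats::rnorm(cells_per_clone))
        k <- k + 1L
        out[[k]] <- data.frame(
          clone_id = truth$clones$clone_id[i], replicate = r,
          fsc = fsc, ssc = ssc, clover = clover, irfp = irfp,
          control = is_ctl, stringsAsFactors = FALSE)
      }
    }
    ev <- do.call(rbind, out)
    rownames(ev) <- NULL
    ev
  })
}

#' Materialise (and optionally write) the synthetic epigenome
#'
#' The epigenome is drawn once inside [generate_truth()] so that the cached
#' per-clone features are exactly consistent with the emitted files; this
#' function returns it and, when `dir` is given, writes one bedGraph per TF
#' track, a BED4 state segmentation and a `genome.tsv` of chromosome lengths.
#'
#' @param truth a [generate_truth()] object.
#' @param config unused, kept for call symmetry with the other simulators.
#' @param dir optional output directory.
#' @return list with elements `tracks` (list of `signal_track`) and `states`
#'   (`state_segmentation`), invisibly when writing.
#' @export
simulate_epigenome <- function(truth, config = truth$config, dir = NULL) {
  stopifnot(inherits(truth, "trip_truth"))
  epi <- truth$epigenome
  if (!is.null(dir)) {
    dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
    for (tr in epi$tracks)
      write_track(tr, file.path(dir, "tracks", paste0(tr$name, ".bedGraph")))
    write_states(epi$states, file.path(dir, "states.bed"))
    write_tsv0(data.frame(chrom = names(config$chrom_lengths),
                          length = as.numeric(config$chrom_lengths)),
               file.path(dir, "genome.tsv"))
    return(invisible(epi))
  }
  epi
}

#' Simulate every pipeline input and write it to a directory
#'
#' One-stop generator: ground truth (JSON), barcode reads (FASTQ), pooling
#' design and pool counts (TSV), integration-mapping reads (TSV, two
#' replicates), flow events (CSV) and the epigenome (bedGraph/BED).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`truth`, `reads`,
#'   `design`, `pool_counts`, `trip_reads`, `flow_events`, `epigenome`).
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth(config)
  reads <- simulate_barcode_reads(truth)
  design <- make_design(config$n_clones, config$n_pools,
                        config$signature_weight, scheme = "balanced")
  counts <- simulate_pool_counts(truth, design)
  trip <- simulate_trip_reads(truth)
  flow <- simulate_flow_events(truth)

  write_truth(truth, file.path(dir, "truth.json"))
  write_fastq(reads, file.path(dir, "reads.fastq"))
  write_design(design, file.path(dir, "design.tsv"))
  write_pool_counts(counts, file.path(dir, "pool_counts.tsv"))
  write_trip_reads(trip[trip$replicate == 1L, ], file.path(dir, "trip_rep1.tsv"))
  write_trip_reads(trip[trip$replicate == 2L, ], file.path(dir, "trip_rep2.tsv"))
  write_flow_events(flow, file.path(dir, "flow_events.csv"))
  simulate_epigenome(truth, config, dir)

  invisible(list(truth = truth, reads = reads, design = design,
                 pool_counts = counts, trip_reads = trip, flow_events = flow,
                 epigenome = truth$epigenome))
}
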