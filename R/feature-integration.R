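#' Mean signal in a window around an integration site
#'
#' Bin-overlap-weighted mean of a binned signal track over
#' `[pos - window_bp/2, pos + window_bp/2)`, clipped at the chromosome ends
#' (the mean is then taken over the clipped extent only). The default window
#' is 50 kb total width, a compromise between the size of a typical TAD
#' (~100 kb, which would no longer reflect the local environment) and the
#' signal loss of very small windows.
#'
#' @param track a `signal_track` (see [read_track()]).
#' @param chrom,pos site coordinate (0-based bp).
#' @param window_bp total window width in bp (default 50000, i.e. +/-25 kb);
#'   set `window_bp = 2 * w` for a +/-`w` reading.
#' @return mean fold-change in the window, or `NA` if `chrom` is absent from
#'   the track.
#' @export
window_enrichment <- function(track, chrom, pos, window_bp = 50000) {
  stopifnot(inherits(track, "signal_track"))
  v <- track$values[[chrom]]
  if (is.null(v)) return(NA_real_)
  len <- track$chrom_lengths[[chrom]] %||% (length(v) * track$bin_size)
  half <- window_bp / 2
  s <- max(0, pos - half)
  e <- min(len, pos + half)
  if (e <= s) return(NA_real_)
  bs <- track$bin_size
  b0 <- floor(s / bs)
  b1 <- floor((e - 1) / bs)
  bins <- b0:b1
  w <- pmin(e, (bins + 1) * bs) - pmax(s, bins * bs)
  sum(v[bins + 1] * w) / sum(w)
}

#' Nearest distance from a site to a chromatin state
#'
#' 0 when the position lies inside an interval of the state; otherwise the
#' bp gap to the nearest contained base of the state on the same chromosome
#' (`start - pos` to the left edge, `pos - (end - 1)` past the right edge;
#' intervals are 0-based half-open). Distances never cross chromosomes: a
#' state absent from the site's chromosome yields `NA` (masked).
#'
#' @param seg a `state_segmentation` (see [read_states()]).
#' @param chrom,pos site coordinate (0-based bp).
#' @param state state label; must be in the segmentation's vocabulary.
#' @return distance in bp, or `NA`.
#' @export
distance_to_state <- function(seg, chrom, pos, state) {
  vocab <- attr(seg, "vocabulary") %||% unique(seg$state)
  if (!state %in% vocab) stop2("unknown state '%s'", state)
  i <- seg$chrom == chrom & seg$state == state
  if (!any(i)) return(NA_real_)
  s <- seg$start[i]
  e <- seg$end[i]
  if (any(pos >= s & pos < e)) return(0)
  d <- c(s[s > pos] - pos, pos - (e[e <= pos] - 1))
  min(d)
}

#' Assemble the clones-by-features matrix
#'
#' One row per assigned (and, when expression is supplied, expressing) clone;
#' one `enr_<TF>` column per signal track (windowed mean fold-change) and one
#' `dist_<state>` column per state in the segmentation vocabulary (nearest
#' distance in bp, `NA`-masked when the state is absent from the clone's
#' chromosome). Features are strand-agnostic.
#'
#' @param sites integration sites: a data.frame with `chrom`, `pos` and
#'   either a `clone_id` column or a `barcode` column plus `clone_map`. Rows
#'   with a `status` column are restricted to `status == "assigned"`.
#' @param tracks list of `signal_track` objects.
#' @param states a `state_segmentation`.
#' @param expression optional [aggregate_replicates()] data.frame
#'   (`clone_id`, `mean_avg`, `cv2_avg`); clones present in both are kept and
#'   clones with `mean_avg < expression_floor` (reporter silenced) are
#'   dropped.
#' @param clone_map named character vector barcode -> clone id, e.g. from a
#'   [decode_pools()] result.
#' @param window_bp enrichment window, total width in bp.
#' @param expression_floor minimal `mean_avg` for an expressing clone
#'   (default 0: keep all).
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   rownames clone ids), `expression` (data.frame with `log10_mean` and
#'   `log10_cv2` added, or `NULL`) and `meta` (per-feature data.frame).
#' @export
build_feature_matrix <- function(sites, tracks, states, expression = NULL,
                                 clone_map = NULL, window_bp = 50000,
                                 expression_floor = 0) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if ("status" %in% names(sites))
    sites <- sites[sites$status == "assigned", , drop = FALSE]
  if (!"clone_id" %in% names(sites)) {
    if (is.null(clone_map) || !"barcode" %in% names(sites))
      stop2("sites need a clone_id column, or a barcode column plus clone_map")
    sites$clone_id <- unname(clone_map[sites$barcode])
    sites <- sites[!is.na(sites$clone_id), , drop = FALSE]
  }
  sites <- sites[!duplicated(sites$clone_id), , drop = FALSE]
  excluded <- character(0)
  if (!is.null(expression)) {
    keep <- expression$clone_id[expression$mean_avg >= expression_floor]
    excluded <- setdiff(intersect(sites$clone_id, expression$clone_id), keep)
    sites <- sites[sites$clone_id %in% keep, , drop = FALSE]
  }
  if (nrow(sites) == 0) stop2("no clones overlap between sites and expression")

  n <- nrow(sites)
  vocab <- attr(states, "vocabulary") %||% unique(states$state)
  enr <- vapply(tracks, function(tr)
    vapply(seq_len(n), function(i)
      window_enrichment(tr, sites$chrom[i], sites$pos[i], window_bp),
      0), numeric(n))
  dst <- vapply(vocab, function(st)
    vapply(seq_len(n), function(i)
      distance_to_state(states, sites$chrom[i], sites$pos[i], st),
      0), numeric(n))
  x <- cbind(matrix(enr, nrow = n), matrix(dst, nrow = n))
  colnames(x) <- c(paste0("enr_", vapply(tracks, `[[`, "", "name")),
                   paste0("dist_", vocab))
  rownames(x) <- sites$clone_id

  expr <- NULL
  if (!is.null(expression)) {
    expr <- expression[match(sites$clone_id, expression$clone_id), , drop = FALSE]
    expr$log10_mean <- log10(expr$mean_avg)
    expr$log10_cv2 <- log10(expr$cv2_avg)
    rownames(expr) <- NULL
  }
  meta <- data.frame(
    feature = colnames(x),
    type = rep(c("enrichment", "distance"),
               c(length(tracks), length(vocab))),
    source = c(vapply(tracks, `[[`, "", "name"), vocab),
    window_bp = c(rep(window_bp, length(tracks)), rep(NA, length(vocab))),
    stringsAsFactors = FALSE)
  structure(list(x = x, expression = expr, meta = meta,
                 excluded_nonexpressing = excluded),
            class = "feature_matrix")
}

#' Feature matrix straight from synthetic ground truth
#'
#' Shortcut used in tests and power studies: reuses the generator's cached
#' features and true expression parameters instead of re-measuring them
#' through the flow-cytometry simulation.
#'
#' @param truth a [generate_truth()] object.
#' @return a `feature_matrix` whose `expression` carries the true
#'   `log10_mean`/`log10_cv2`.
#' @export
feature_matrix_from_truth <- function(truth) {
  stopifnot(inherits(truth, "trip_truth"))
  expr <- data.frame(clone_id = truth$clones$clone_id,
                     n_replicates = NA_integer_,
                     mean_avg = truth$clones$mean,
                     cv2_avg = truth$clones$cv2,
                     log10_mean = truth$clones$log10_mean,
                     log10_cv2 = truth$clones$log10_cv2,
                     stringsAsFactors = FALSE)
  vocab <- attr(truth$epigenome$states, "vocabulary")
  meta <- data.frame(
    feature = colnames(truth$features),
    type = rep(c("enrichment", "distance"),
               c(length(truth$epigenome$tracks), length(vocab))),
    source = c(names(truth$epigenome$tracks), vocab),
    window_bp = c(rep(truth$config$window_bp, length(truth$epigenome$tracks)),
                  rep(NA, length(vocab))),
    stringsAsFactors = FALSE)
  structure(list(x = truth$features, expression = expr, meta = meta,
                 excluded_nonexpressing = character(0)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d clones x %d features (%d enrichment, %d distance)%s\n",
              nrow(x$x), ncol(x$x), sum(x$meta$type == "enrichment"),
              sum(x$meta$type == "distance"),
              if (is.null(x$expression)) "" else " | expression attached"))
  invisible(x)
}
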