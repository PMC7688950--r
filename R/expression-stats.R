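#' Scatter-gate specification
#'
#' Default mode keeps events inside per-group empirical quantile windows on
#' FSC and SSC (defaults `(0.375, 0.625)` per axis, i.e. a central box
#' retaining about 6\% of events jointly -- roughly 3k of 50k cells).
#' Supplying `fsc_range`/`ssc_range` switches to a fixed rectangle in
#' intensity units, which reproduces any explicit gate exactly and is
#' idempotent.
#'
#' @param fsc_window,ssc_window `(low, high)` quantiles, `0 <= low < high <= 1`.
#' @param fsc_range,ssc_range optional fixed `(min, max)` intensity cuts.
#' @return object of class `gate_spec`.
#' @export
gate_spec <- function(fsc_window = c(0.375, 0.625),
                      ssc_window = c(0.375, 0.625),
                      fsc_range = NULL, ssc_range = NULL) {
  for (wname in c("fsc_window", "ssc_window")) {
    w <- get(wname)
    if (length(w) != 2 || w[1] < 0 || w[2] > 1 || w[1] >= w[2])
      stop2("%s must satisfy 0 <= low < high <= 1", wname)
  }
  structure(list(fsc_window = fsc_window, ssc_window = ssc_window,
                 fsc_range = fsc_range, ssc_range = ssc_range),
            class = "gate_spec")
}

#' Gate flow events on FSC/SSC
#'
#' Keeps events whose FSC and SSC both fall inside the gate. Quantile
#' windows are computed per group (default: per clone and replicate, i.e.
#' per well), mirroring a conservative scatter gate drawn on each sample to
#' reduce extrinsic noise from cell size and state.
#'
#' @param events data.frame with `fsc`, `ssc` columns (plus grouping
#'   columns).
#' @param gate a [gate_spec()].
#' @param by grouping columns for per-group quantiles; ignored in fixed-range
#'   mode.
#' @return the gated subset of `events`.
#' @export
gate_events <- function(events, gate = gate_spec(),
                        by = intersect(c("clone_id", "replicate"), names(events))) {
  stopifnot(inherits(gate, "gate_spec"),
            all(c("fsc", "ssc") %in% names(events)))
  if (!is.null(gate$fsc_range) || !is.null(gate$ssc_range)) {
    fr <- gate$fsc_range %||% range(events$fsc)
    sr <- gate$ssc_range %||% range(events$ssc)
    keep <- events$fsc >= fr[1] & events$fsc <= fr[2] &
      events$ssc >= sr[1] & events$ssc <= sr[2]
    return(events[keep, , drop = FALSE])
  }
  grp <- if (length(by)) interaction(events[by], drop = TRUE)
  else factor(rep(1L, nrow(events)))
  keep <- logical(nrow(events))
  for (g in levels(grp)) {
    i <- which(grp == g)
    qf <- stats::quantile(events$fsc[i], gate$fsc_window, names = FALSE)
    qs <- stats::quantile(events$ssc[i], gate$ssc_window, names = FALSE)
    keep[i] <- events$fsc[i] >= qf[1] & events$fsc[i] <= qf[2] &
      events$ssc[i] >= qs[1] & events$ssc[i] <= qs[2]
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) stop2("gate removed every event")
  empty <- setdiff(levels(grp), levels(droplevels(grp[keep])))
  if (length(empty))
    stop2("gate removed every event of group(s): %s",
          paste(empty, collapse = ", "))
  out
}

#' Separate internal-control cells by IRFP gating
#'
#' Control cells express IRFP; experimental cells show only background. With
#' `irfp_cutoff = "auto"` a deterministic two-means split of log(IRFP) is
#' used and the cutoff is the midpoint of the two component means; when the
#' two components are not clearly separated (less than 4 pooled SDs apart;
#' a unimodal Gaussian splits at about 2.7) an error asks for an explicit
#' cutoff.
#'
#' @param events data.frame with an `irfp` column.
#' @param irfp_cutoff numeric intensity cutoff, or `"auto"`.
#' @return list with `experimental` (irfp below cutoff), `control` (at or
#'   above) and `cutoff`.
#' @export
split_control <- function(events, irfp_cutoff = "auto") {
  stopifnot("irfp" %in% names(events))
  if (identical(irfp_cutoff, "auto")) {
    x <- log(pmax(events$irfp, .Machine$double.eps))
    c1 <- stats::quantile(x, 0.10, names = FALSE)
    c2 <- stats::quantile(x, 0.90, names = FALSE)
    for (i in seq_len(100)) {
      grp2 <- abs(x - c2) < abs(x - c1)
      if (!any(grp2) || all(grp2)) break
      n1 <- mean(x[!grp2]); n2 <- mean(x[grp2])
      if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) { c1 <- n1; c2 <- n2; break }
      c1 <- n1; c2 <- n2
    }
    grp2 <- abs(x - c2) < abs(x - c1)
    if (!any(grp2) || all(grp2))
      stop2("IRFP distribution looks unimodal; supply an explicit irfp_cutoff")
    sep <- abs(c2 - c1) /
      sqrt((stats::var(x[!grp2]) + stats::var(x[grp2])) / 2)
    # a 2-means split of a plain Gaussian already yields ~2.7 pooled SDs of
    # separation; require clearly more before trusting the auto cutoff
    if (!is.finite(sep) || sep < 4)
      stop2("IRFP modes are not separated (%.2f pooled SDs); supply an explicit irfp_cutoff",
            sep)
    irfp_cutoff <- exp((c1 + c2) / 2)
  }
  ctrl <- events$irfp >= irfp_cutoff
  list(experimental = events[!ctrl, , drop = FALSE],
       control = events[ctrl, , drop = FALSE],
       cutoff = irfp_cutoff)
}

#' Per-clone, per-replicate expression summaries
#'
#' Computes, over the Clover intensities of each clone-and-replicate group:
#' the arithmetic mean, the unbiased (n-1) sample variance, and the squared
#' coefficient of variation `cv2 = variance / mean^2`. Statistics are taken
#' on linear intensities; groups below `min_cells` are flagged `low_n`.
#'
#' @param events gated, control-free data.frame with `clone_id`, `replicate`,
#'   `clover`.
#' @param min_cells minimal group size for an unflagged summary
#'   (default 1000).
#' @return data.frame of class `expression_summary`: `clone_id`,
#'   `replicate`, `n_cells`, `mean`, `variance`, `cv2`, `flag`.
#' @export
summarize_expression <- function(events, min_cells = 1000) {
  stopifnot(all(c("clone_id", "replicate", "clover") %in% names(events)))
  if (nrow(events) == 0) stop2("no events to summarise")
  key <- interaction(events$clone_id, events$replicate, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(events)), key)
  rows <- lapply(idx, function(i) {
    x <- events$clover[i]
    m <- mean(x)
    v <- if (length(x) > 1) stats::var(x) else 0
    data.frame(clone_id = events$clone_id[i[1]],
               replicate = events$replicate[i[1]],
               n_cells = length(x), mean = m, variance = v,
               cv2 = v / m^2,
               flag = if (length(x) < min_cells) "low_n" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$clone_id, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("expression_summary", "data.frame")
  out
}

#' Average expression summaries across replicates
#'
#' Arithmetic mean across available replicates, separately for the mean and
#' for CV2.
#'
#' @param summaries an [summarize_expression()] data.frame.
#' @param exclude_low_n drop replicates flagged `low_n` first.
#' @return data.frame (`clone_id`, `n_replicates`, `mean_avg`, `cv2_avg`).
#' @export
aggregate_replicates <- function(summaries, exclude_low_n = FALSE) {
  s <- summaries
  if (exclude_low_n && "flag" %in% names(s)) s <- s[s$flag != "low_n", ]
  if (nrow(s) == 0) stop2("no summaries to aggregate")
  idx <- split(seq_len(nrow(s)), s$clone_id)
  out <- do.call(rbind, lapply(idx, function(i)
    data.frame(clone_id = s$clone_id[i[1]], n_replicates = length(i),
               mean_avg = mean(s$mean[i]), cv2_avg = mean(s$cv2[i]),
               stringsAsFactors = FALSE)))
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise replicate correlations of per-clone statistics
#'
#' Spearman rank correlation across clones for every replicate pair, for the
#' chosen statistic.
#'
#' @param summaries an [summarize_expression()] data.frame.
#' @param statistic `"mean"` or `"cv2"`.
#' @param method correlation method (default `"spearman"`).
#' @return replicate x replicate correlation matrix.
#' @export
replicate_correlation <- function(summaries, statistic = c("mean", "cv2"),
                                  method = "spearman") {
  statistic <- match.arg(statistic)
  reps <- sort(unique(summaries$replicate))
  clones <- sort(unique(summaries$clone_id))
  m <- matrix(NA_real_, length(clones), length(reps),
              dimnames = list(clones, paste0("rep", reps)))
  m[cbind(match(summaries$clone_id, clones),
          match(summaries$replicate, reps))] <- summaries[[statistic]]
  stats::cor(m, use = "pairwise.complete.obs", method = method)
}
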