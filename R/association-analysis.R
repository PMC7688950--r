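#' Screen features by Spearman correlation against expression
#'
#' Spearman rank correlation (average ranks for ties) between every feature
#' and the chosen response, computed on pairwise-complete rows. A feature is
#' selected when `|rho|` exceeds `threshold` (default 0.2); correlations that
#' are moderately positive or negative both pass, so the cutoff is on the
#' absolute value. Constant features have undefined rank correlation and are
#' masked, never selected.
#'
#' @param fm a [build_feature_matrix()] object with expression attached.
#' @param response `"log10_mean"` or `"log10_cv2"`.
#' @param threshold selection cutoff on `|rho|`.
#' @param min_n minimal number of complete observations per feature.
#' @return data.frame of class `screen_result`: `feature`, `response`,
#'   `rho`, `n`, `selected`.
#' @export
spearman_screen <- function(fm, response = c("log10_mean", "log10_cv2"),
                            threshold = 0.2, min_n = 3) {
  response <- match.arg(response)
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$expression))
  y <- fm$expression[[response]]
  rows <- lapply(colnames(fm$x), function(f) {
    x <- fm$x[, f]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    rho <- if (n >= min_n && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok], method = "spearman") else NA_real_
    data.frame(feature = f, response = response, rho = rho, n = n,
               selected = !is.na(rho) && abs(rho) > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Fit a multivariate linear model of expression on chromatin features
#'
#' Ordinary least squares of the (log10-scale) response on the selected
#' features plus an intercept. Features are z-scored by default so that
#' coefficients and t statistics are comparable across features. Rows with a
#' missing value in any selected feature are dropped listwise. Each
#' coefficient is reported with its standard error, `t = coef/SE`, and the
#' two-sided p-value from a Student t distribution with `n - k - 1` degrees
#' of freedom; features with `p < alpha` (default 0.05) form the significant
#' set.
#'
#' @param fm a [build_feature_matrix()] object with expression attached.
#' @param response `"log10_mean"` or `"log10_cv2"`.
#' @param features character vector of feature names, or a
#'   [spearman_screen()] result (its selected features for this response are
#'   used). `NULL` uses every feature.
#' @param standardize z-score features before fitting (default `TRUE`).
#' @param alpha significance level for the reported significant set.
#' @return object of class `expression_model`: list with `response`,
#'   `features`, `n`, `r_squared`, `alpha` and `coefficients` (data.frame:
#'   `term`, `estimate`, `std_error`, `t_value`, `p_value`, `significant`).
#' @export
fit_model <- function(fm, response = c("log10_mean", "log10_cv2"),
                      features = NULL, standardize = TRUE, alpha = 0.05) {
  response <- match.arg(response)
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$expression))
  if (inherits(features, "screen_result"))
    features <- features$feature[features$selected &
                                   features$response == response]
  if (is.null(features)) features <- colnames(fm$x)
  if (length(features) == 0) return(intercept_only_model(fm, response, alpha))
  missing_f <- setdiff(features, colnames(fm$x))
  if (length(missing_f))
    stop2("unknown features: %s", paste(missing_f, collapse = ", "))

  y <- fm$expression[[response]]
  X <- fm$x[, features, drop = FALSE]
  ok <- is.finite(y) & apply(X, 1, function(r) all(is.finite(r)))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  k <- length(features)
  if (n <= k + 1)
    stop2("need n > k + 1 observations (n = %d, k = %d)", n, k)
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop2("constant feature(s) cannot be standardized: %s",
            paste(features[sds == 0], collapse = ", "))
    X <- scale(X)
  }

  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop2("rank-deficient design; collinear feature(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- c("(Intercept)", features)
  coefs <- data.frame(term = terms,
                      estimate = ct[, 1], std_error = ct[, 2],
                      t_value = ct[, 3], p_value = ct[, 4],
                      significant = ct[, 4] < alpha,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(response = response, features = features, n = n,
                 r_squared = sm$r.squared, alpha = alpha,
                 coefficients = coefs, fit = fit),
            class = "expression_model")
}

intercept_only_model <- function(fm, response, alpha) {
  y <- fm$expression[[response]]
  y <- y[is.finite(y)]
  n <- length(y)
  se <- stats::sd(y) / sqrt(n)
  tv <- mean(y) / se
  coefs <- data.frame(term = "(Intercept)", estimate = mean(y),
                      std_error = se, t_value = tv,
                      p_value = 2 * stats::pt(-abs(tv), n - 1),
                      significant = NA, stringsAsFactors = FALSE)
  structure(list(response = response, features = character(0), n = n,
                 r_squared = 0, alpha = alpha, coefficients = coefs,
                 fit = NULL),
            class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("<expression_model> %s ~ %d feature(s) | n = %d | R2 = %.3f | %d significant at p < %g\n",
              x$response, length(x$features), x$n, x$r_squared,
              length(significant_features(x)), x$alpha))
  invisible(x)
}

#' Significant features of a fitted model
#'
#' @param model an [fit_model()] result.
#' @return character vector of feature names with `p < alpha` (intercept
#'   excluded).
#' @export
significant_features <- function(model) {
  stopifnot(inherits(model, "expression_model"))
  cf <- model$coefficients
  cf$term[cf$term != "(Intercept)" & !is.na(cf$significant) & cf$significant]
}

#' Forward-backward stepwise model selection
#'
#' Stepwise term selection from a candidate feature set, then OLS exactly as
#' in [fit_model()]. Criteria: `"aic"`/`"bic"` use [stats::step()] in both
#' directions from the intercept-only model; `"pvalue"` alternates forward
#' inclusion of the smallest-p candidate (`p < alpha_in`) with backward
#' elimination of the largest-p term (`p > alpha_out`).
#'
#' @param fm a [build_feature_matrix()] object with expression attached.
#' @param response `"log10_mean"` or `"log10_cv2"`.
#' @param candidates candidate feature names (default: all).
#' @param criterion `"aic"`, `"bic"` or `"pvalue"`.
#' @param alpha_in,alpha_out entry/exit p-value thresholds for
#'   `criterion = "pvalue"`.
#' @param standardize,alpha passed to [fit_model()].
#' @return an `expression_model` on the selected terms.
#' @export
stepwise_fit <- function(fm, response = c("log10_mean", "log10_cv2"),
                         candidates = NULL, criterion = c("aic", "bic", "pvalue"),
                         alpha_in = 0.05, alpha_out = 0.10,
                         standardize = TRUE, alpha = 0.05) {
  response <- match.arg(response)
  criterion <- match.arg(criterion)
  if (is.null(candidates)) candidates <- colnames(fm$x)
  if (length(candidates) == 0) return(intercept_only_model(fm, response, alpha))

  y <- fm$expression[[response]]
  X <- fm$x[, candidates, drop = FALSE]
  ok <- is.finite(y) & apply(X, 1, function(r) all(is.finite(r)))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 0
    X <- scale(X[, keep, drop = FALSE])
    candidates <- candidates[keep]
  }

  selected <- character(0)
  if (criterion %in% c("aic", "bic")) {
    dat <- data.frame(.y = y, X, check.names = FALSE)
    null_fit <- stats::lm(.y ~ 1, data = dat)
    scope <- stats::as.formula(paste(".y ~",
      paste(sprintf("`%s`", candidates), collapse = " + ")))
    kpen <- if (criterion == "aic") 2 else log(length(y))
    sel <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                       direction = "both", k = kpen, trace = 0)
    selected <- gsub("`", "", attr(stats::terms(sel), "term.labels"))
  } else {
    pool <- candidates
    repeat {
      changed <- FALSE
      # forward: best remaining candidate
      if (length(pool)) {
        pvals <- vapply(pool, function(f) {
          dat <- data.frame(.y = y, X[, c(selected, f), drop = FALSE],
                            check.names = FALSE)
          sm <- summary(stats::lm(.y ~ ., data = dat))$coefficients
          sm[nrow(sm), 4]
        }, 0)
        if (min(pvals) < alpha_in) {
          add <- pool[which.min(pvals)]
          selected <- c(selected, add)
          pool <- setdiff(pool, add)
          changed <- TRUE
        }
      }
      # backward: worst included term
      if (length(selected)) {
        dat <- data.frame(.y = y, X[, selected, drop = FALSE],
                          check.names = FALSE)
        sm <- summary(stats::lm(.y ~ ., data = dat))$coefficients
        p <- sm[-1, 4]
        if (max(p) > alpha_out) {
          drop_f <- selected[which.max(p)]
          selected <- setdiff(selected, drop_f)
          pool <- c(pool, drop_f)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  fit_model(fm, response, features = selected, standardize = standardize,
            alpha = alpha)
}

#' Partition significant features by the response they affect
#'
#' Compares the significant sets of a mean model and a CV2 model (the
#' Venn-diagram view of which features act on expression level, noise, or
#' both).
#'
#' @param model_mean,model_cv2 [fit_model()] results for the two responses.
#' @return list with sorted character vectors `mean_only`, `cv2_only`,
#'   `shared`.
#' @export
orthogonality_report <- function(model_mean, model_cv2) {
  a <- significant_features(model_mean)
  b <- significant_features(model_cv2)
  list(mean_only = sort(setdiff(a, b)),
       cv2_only = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}
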