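fm_from <- function(x, log10_mean, log10_cv2 = -log10_mean) {
  structure(list(
    x = x,
    expression = data.frame(clone_id = rownames(x),
                            mean_avg = 10^log10_mean, cv2_avg = 10^log10_cv2,
                            log10_mean = log10_mean, log10_cv2 = log10_cv2),
    meta = data.frame(feature = colnames(x))), class = "feature_matrix")
}

test_that("spearman_screen ranks, masks and selects on |rho|", {
  set.seed(81)
  n <- 40
  x <- cbind(f_pos = rnorm(n), f_const = rep(1, n), f_null = rnorm(n))
  rownames(x) <- sprintf("c%02d", 1:n)
  y <- rank(x[, "f_pos"]) / n
  fm <- fm_from(x, log10_mean = y)
  sc <- spearman_screen(fm, "log10_mean")
  expect_equal(sc$rho[sc$feature == "f_pos"], 1)
  expect_true(is.na(sc$rho[sc$feature == "f_const"]))
  expect_false(sc$selected[sc$feature == "f_const"])

  # rank reversal flips the sign; |rho| selection keeps both directions
  fm_rev <- fm_from(x, log10_mean = -y)
  sc_rev <- spearman_screen(fm_rev, "log10_mean")
  expect_equal(sc_rev$rho[sc_rev$feature == "f_pos"], -1)
  expect_true(sc_rev$selected[sc_rev$feature == "f_pos"])

  # invariance under strictly monotone transforms of the feature
  x2 <- x
  x2[, "f_pos"] <- exp(x2[, "f_pos"])
  expect_equal(spearman_screen(fm_from(x2, y), "log10_mean")$rho,
               sc$rho)
})

test_that("fit_model recovers a noiseless linear truth", {
  set.seed(82)
  n <- 50
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("c%02d", 1:n), paste0("f", 1:4)))
  z <- scale(x)
  y <- drop(1.5 + 2 * z[, 1] - 1 * z[, 3])
  # lm warns about the essentially perfect fit; that is the point here
  m <- suppressWarnings(fit_model(fm_from(x, y), "log10_mean"))
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_equal(unname(est[c("f1", "f2", "f3", "f4")]), c(2, 0, -1, 0),
               tolerance = 1e-8)
  expect_equal(unname(est["(Intercept)"]), 1.5, tolerance = 1e-8)
  # in the exact-fit limit the true-nonzero terms are significant (the null
  # terms' t ratios are 0/0 numerics and are not asserted)
  expect_true(all(c("f1", "f3") %in% significant_features(m)))
  expect_gt(m$r_squared, 0.999)
})

test_that("OLS t and p equal the closed-form simple-regression formulas", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 5, 4, 5)
  xm <- matrix(x, 5, 1, dimnames = list(paste0("c", 1:5), "f"))
  m <- fit_model(fm_from(xm, y), "log10_mean", features = "f",
                 standardize = FALSE)
  o <- oracle_simple_ols(x, y)
  cf <- m$coefficients
  expect_equal(cf$estimate, c(o$intercept, o$slope), tolerance = 1e-12)
  expect_equal(cf$std_error, c(o$se_intercept, o$se_slope), tolerance = 1e-12)
  expect_equal(cf$t_value, c(o$t_intercept, o$t_slope), tolerance = 1e-12)
  expect_equal(cf$p_value, c(o$p_intercept, o$p_slope), tolerance = 1e-12)
  expect_equal(m$r_squared, o$r_squared, tolerance = 1e-12)
})

test_that("fit_model errors on rank deficiency and tiny n", {
  set.seed(83)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  x <- cbind(x, b_copy = x[, "b"])
  rownames(x) <- paste0("c", 1:10)
  fm <- fm_from(x, rnorm(10))
  expect_error(fit_model(fm, "log10_mean"), "collinear|rank")
  expect_error(fit_model(fm_from(x[1:3, ], rnorm(3)), "log10_mean",
                         features = c("a", "b")),
               "n > k")
})

test_that("type-I error of the OLS p-values is calibrated", {
  set.seed(84)
  pvals <- unlist(lapply(1:60, function(i) {
    n <- 60
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("c", 1:n), paste0("f", 1:8)))
    m <- fit_model(fm_from(x, rnorm(n)), "log10_mean")
    cf <- m$coefficients
    cf$p_value[cf$term != "(Intercept)"]
  }))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(pvals)))
})

test_that("stepwise_fit finds the true support and handles empty candidates", {
  # orthogonalised design with noise orthogonal to every candidate: null
  # terms have exactly zero partial t, so exact-support recovery is
  # deterministic under every criterion
  set.seed(85)
  n <- 80
  x0 <- matrix(rnorm(n * 8), n, 8)
  q <- qr.Q(qr(cbind(1, x0)))[, -1]        # centered, mutually orthogonal
  x <- scale(q)
  dimnames(x) <- list(paste0("c", 1:n), paste0("f", 1:8))
  e <- residuals(lm(rnorm(n) ~ x))
  y <- drop(x[, 2] * 1.2 - x[, 5] * 0.9) + 0.05 * e / sd(e)
  for (crit in c("aic", "bic", "pvalue")) {
    m <- stepwise_fit(fm_from(x, y), "log10_mean", criterion = crit)
    expect_setequal(m$features, c("f2", "f5"))
  }
  m0 <- stepwise_fit(fm_from(x, y), "log10_mean", candidates = character(0))
  expect_equal(length(m0$features), 0)
  expect_equal(m0$coefficients$term, "(Intercept)")
})

test_that("orthogonality_report partitions significant features", {
  set.seed(86)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("c", 1:n), c("fm", "fs", "fc", "fn")))
  z <- scale(x)
  y_mean <- drop(2 * z[, "fm"] + 1.5 * z[, "fs"]) + rnorm(n, 0, 0.1)
  y_cv2 <- drop(-2 * z[, "fc"] + 1.5 * z[, "fs"]) + rnorm(n, 0, 0.1)
  fm <- fm_from(x, y_mean, y_cv2)
  part <- orthogonality_report(fit_model(fm, "log10_mean"),
                               fit_model(fm, "log10_cv2"))
  expect_equal(part$mean_only, "fm")
  expect_equal(part$cv2_only, "fc")
  expect_equal(part$shared, "fs")

  # degenerate cases
  m1 <- fit_model(fm, "log10_mean", features = c("fm", "fs"))
  expect_equal(orthogonality_report(m1, m1)$mean_only, character(0))
})

test_that("screen + fit is invariant to clone order", {
  truth <- generate_truth(small_config(n_clones = 40, seed = 87))
  fm <- feature_matrix_from_truth(truth)
  set.seed(87)
  perm <- sample(nrow(fm$x))
  fm_p <- fm
  fm_p$x <- fm$x[perm, ]
  fm_p$expression <- fm$expression[perm, ]
  sc <- spearman_screen(fm, "log10_mean")
  sc_p <- spearman_screen(fm_p, "log10_mean")
  expect_equal(sc_p$rho, sc$rho)
  feats <- sc$feature[sc$selected]
  if (length(feats) >= 1) {
    m <- fit_model(fm, "log10_mean", feats)
    m_p <- fit_model(fm_p, "log10_mean", feats)
    expect_equal(m_p$coefficients$estimate, m$coefficients$estimate)
  }
})

test_that("screen + OLS recovers planted effects (scaled-down power check)", {
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg <- synthetic_config(
      n_clones = 90, n_tf_tracks = 60, n_states = 5,
      chrom_lengths = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6),
      track_bin_size = 2000, n_planted = 5, planted_size = 0.4,
      cells_per_clone = 100, seed = 500 + seed)
    truth <- generate_truth(cfg)
    fm <- feature_matrix_from_truth(truth)
    sc <- spearman_screen(fm, "log10_mean", threshold = 0.2)
    m <- fit_model(fm, "log10_mean", sc)
    planted <- names(which(truth$effects$mean != 0))
    hits <- hits + sum(planted %in% significant_features(m))
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.8)
})
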