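make_ft <- function(X, cond) {
  # wrap a metabolite x sample intensity matrix plus a manifest of
  # biological injections only is not allowed by the QC filters, so tests
  # here build normalized_table objects directly where possible
  feature_table(data.frame(feature_id = rownames(X),
                           mz = seq_len(nrow(X)), rt = seq_len(nrow(X))), X)
}

bio_manifest <- function(cond) {
  ids <- sprintf("%s_%02d", cond, stats::ave(seq_along(cond), cond, FUN = seq_along))
  data.frame(injection_id = ids, role = "biological", condition = cond,
             matrix = "serum", injection_order = seq_along(cond),
             dilution_factor = NA_real_, stringsAsFactors = FALSE)
}

test_that("median centering equalizes sample medians within conditions", {
  set.seed(1)
  cond <- rep(c("Control", "IV"), each = 6)
  m <- bio_manifest(cond)
  X <- matrix(2^(rnorm(40 * 12, 15, 1)), 40, 12,
              dimnames = list(sprintf("M%02d", 1:40), m$injection_id))
  # inject per-sample loading offsets that centering must remove
  X <- sweep(X, 2, 2^runif(12, -1, 1), "*")
  nt <- log2_median_center(make_ft(X, cond), m)
  for (cc in c("Control", "IV")) {
    med <- apply(nt$log2[, nt$condition == cc], 2, median)
    expect_lt(diff(range(med)), 1e-12)
  }
  # centering is per-sample shifts only: within-sample differences preserved
  d_raw <- log2(X[1, ]) - log2(X[2, ])
  d_cen <- nt$log2[1, ] - nt$log2[2, ]
  expect_equal(unname(d_cen), unname(d_raw), tolerance = 1e-12)
})

test_that("non-positive intensities are rejected with a named error", {
  cond <- rep(c("Control", "IV"), each = 2)
  m <- bio_manifest(cond)
  X <- matrix(1000, 3, 4, dimnames = list(c("Ma", "Mb", "Mc"), m$injection_id))
  X[2, 3] <- 0
  expect_error(log2_median_center(make_ft(X, cond), m),
               "non-positive intensity for feature 'Mb' in sample 'IV_01'")
})

test_that("imputation changes nothing when nothing is missing", {
  set.seed(2)
  lx <- matrix(rnorm(30, 15), 5, 6,
               dimnames = list(sprintf("M%d", 1:5), sprintf("s%d", 1:6)))
  nt <- normalized_table(lx, rep(c("Control", "IV"), each = 3))
  out <- impute_missing(nt, seed = 7)
  expect_identical(out$log2, lx)
  expect_false(any(out$imputed))
})

test_that("imputation is deterministic, leaves observed values untouched", {
  set.seed(3)
  lx <- matrix(rnorm(200, 15), 20, 10,
               dimnames = list(sprintf("M%02d", 1:20), sprintf("s%d", 1:10)))
  lx[sample(length(lx), 30)] <- NA
  nt <- normalized_table(lx, rep(c("Control", "IV"), each = 5))
  a <- impute_missing(nt, seed = 11)
  b <- impute_missing(nt, seed = 11)
  c <- impute_missing(nt, seed = 12)
  expect_identical(a$log2, b$log2)
  expect_false(identical(a$log2, c$log2))
  obs <- !is.na(lx)
  expect_identical(a$log2[obs], lx[obs])
  expect_identical(a$imputed, is.na(lx))
  expect_false(anyNA(a$log2))
})

test_that("with lambda = 0 the imputation follows the conditional regression", {
  # M2 is an exact linear function of M1 (plus one tight residual), so the
  # conditional distribution of a missing M2 value is nearly degenerate at
  # the regression prediction
  set.seed(4)
  x <- rnorm(30, 15, 1)
  y <- 2 * x + 1 + rnorm(30, sd = 1e-4)
  lx <- rbind(M1 = x, M2 = y)
  colnames(lx) <- sprintf("s%d", 1:30)
  lx["M2", 5] <- NA
  nt <- normalized_table(lx, rep("Control", 30))
  out <- impute_missing(nt, seed = 5, lambda = 0)
  expect_equal(out$log2["M2", 5], 2 * x[5] + 1, tolerance = 1e-2)
})

test_that("all-missing metabolites are dropped, near-empty ones rejected", {
  lx <- matrix(rnorm(24, 15), 4, 6,
               dimnames = list(sprintf("M%d", 1:4), sprintf("s%d", 1:6)))
  lx[3, ] <- NA
  nt <- normalized_table(lx, rep(c("Control", "IV"), each = 3))
  expect_warning(out <- impute_missing(nt, seed = 1), "M3")
  expect_equal(rownames(out$log2), c("M1", "M2", "M4"))
  lx2 <- lx[1:2, , drop = FALSE]
  lx2[2, 2:6] <- NA
  nt2 <- normalized_table(lx2, rep(c("Control", "IV"), each = 3))
  expect_error(impute_missing(nt2, seed = 1), "fewer than 2 observed")
})

test_that("trigamma_inverse round-trips over many magnitudes", {
  for (y in c(1e-5, 0.01, 0.5, 2, 10, 1e4))
    expect_equal(trigamma(metabnet:::trigamma_inverse(y)), y,
                 tolerance = 1e-8)
})

test_that("moderated t matches the established empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(6)
  G <- 60; nA <- 4; nB <- 5
  A <- matrix(rnorm(G * nA, 0, sqrt(rchisq(G, 4) / 4)), G, nA)
  B <- matrix(rnorm(G * nB), G, nB)
  A[1:10, ] <- A[1:10, ] + 2          # some real effects
  rownames(A) <- rownames(B) <- sprintf("M%02d", 1:G)
  ours <- moderated_t_test(A, B)

  design <- cbind(Intercept = 1, A_vs_B = c(rep(1, nA), rep(0, nB)))
  fit <- limma::eBayes(limma::lmFit(cbind(A, B), design))
  expect_equal(ours$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(ours$df_prior[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(ours$s2_prior[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(ours$s2_post, unname(fit$s2.post), tolerance = 1e-8)
  expect_equal(ours$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("prior_df = 0 reduces to the ordinary pooled t-test", {
  set.seed(7)
  A <- matrix(rnorm(40, 1), 10, 4); B <- matrix(rnorm(40), 10, 4)
  rownames(A) <- rownames(B) <- sprintf("M%02d", 1:10)
  ours <- moderated_t_test(A, B, prior_df = 0)
  for (g in 1:10) {
    tt <- t.test(A[g, ], B[g, ], var.equal = TRUE)
    expect_equal(ours$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value[g], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(unique(ours$df_resid), 6)
})

test_that("prior_df = Inf gives a normal-reference statistic", {
  set.seed(8)
  A <- matrix(rnorm(60, 0.5), 15, 4); B <- matrix(rnorm(60), 15, 4)
  rownames(A) <- rownames(B) <- sprintf("M%02d", 1:15)
  ours <- moderated_t_test(A, B, prior_df = Inf)
  expect_true(all(ours$s2_post == ours$s2_post[1]))   # fully pooled
  expect_equal(ours$p_value, 2 * pnorm(-abs(ours$t)), tolerance = 1e-12)
})

test_that("zero-variance metabolites get flagged, degenerate p-values", {
  A <- matrix(c(rep(5, 4), rep(2, 4)), 2, 4, byrow = TRUE)
  B <- matrix(c(rep(3, 4), rep(2, 4)), 2, 4, byrow = TRUE)
  rownames(A) <- rownames(B) <- c("up", "flat")
  ours <- moderated_t_test(A, B, prior_df = 0)
  expect_true(all(ours$zero_variance))
  expect_identical(ours$t, c(Inf, 0))
  expect_identical(ours$p_value, c(0, 1))
})

test_that("pi0 estimator matches hand values and validates input", {
  expect_equal(estimate_pi0_robust(c(0.1, 0.2, 0.3, 0.4)), 0.5)
  expect_equal(estimate_pi0_robust(c(0.9, 0.8)), 1)    # capped
  set.seed(9)
  expect_equal(estimate_pi0_robust(runif(20000)), 1, tolerance = 0.02)
  expect_error(estimate_pi0_robust(numeric(0)), "non-empty")
  expect_error(estimate_pi0_robust(c(0.5, 1.2)), "0, 1")
})

test_that("adaptive BH scales classical BH by pi0 and stays monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_adaptive_bh(p, pi0 = 1), p.adjust(p, "BH"))
  expect_equal(adjust_adaptive_bh(p, pi0 = 0.5), rep(0.02, 4))
  set.seed(10)
  pr <- runif(100)^2
  adj <- adjust_adaptive_bh(pr, pi0 = 0.7)
  expect_true(all(diff(adj[order(pr)]) >= 0))
  expect_true(all(adj <= 1 & adj >= 0))
  expect_error(adjust_adaptive_bh(p, pi0 = 0), "pi0")
})

test_that("signed fold change follows the reporting convention", {
  expect_equal(signed_fold_change(c(1, 0, -1)), c(2, 1, -2))
  expect_equal(signed_fold_change(-0.613), -2^0.613)
  expect_equal(signed_fold_change(-0.613), -1.52944, tolerance = 1e-4)
  lfc <- seq(-3, 3, by = 0.25)
  expect_true(all(abs(signed_fold_change(lfc)) >= 1))
})

test_that("significance gates: fold-change boundary in, FDR boundary in", {
  res <- data.frame(log2FC = c(1, 0.999, -1, 0.5, 2),
                    adj_p = c(0.01, 0.001, 0.0100000, 0.001, 0.011))
  out <- call_differential(res, fc_min = 2, fdr = 0.01)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$signedFC, c(2, 2^0.999, -2, 2^0.5, 4))
})

test_that("test_contrast recovers a planted effect end to end", {
  set.seed(11)
  nA <- nB <- 15; G <- 80
  lx <- matrix(rnorm(G * (nA + nB), 15, 0.3), G, nA + nB,
               dimnames = list(sprintf("M%02d", 1:G),
                               sprintf("s%d", 1:(nA + nB))))
  lx[1:5, 1:nA] <- lx[1:5, 1:nA] + 1.5    # planted up in stage IV
  nt <- normalized_table(lx, rep(c("IV", "Control"), c(nA, nB)))
  res <- test_contrast(nt, "IV")
  expect_true(all(res$significant[1:5]))
  expect_false(any(res$significant[6:G]))
  expect_gt(attr(res, "pi0"), 0.7)
  expect_error(test_contrast(nt, "III"), ">= 2 samples")
})

test_that("group_compare reports exact Mann-Whitney p for small groups", {
  g <- group_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(g$median_a, 2)
  expect_equal(g$median_b, 11)
  expect_equal(g$p_value, 0.1)   # 2 / choose(6, 3) hand value
  expect_equal(g$p_value,
               wilcox.test(c(1, 2, 3), c(10, 11, 12), exact = TRUE)$p.value)
  # ties or large groups fall back to the corrected normal approximation
  gt <- group_compare(c(1, 1, 2), c(2, 3, 4))
  expect_true(gt$p_value > 0 && gt$p_value < 1)
  big <- group_compare(1:20, 5:24)
  expect_equal(big$p_value,
               suppressWarnings(wilcox.test(1:20, 5:24, exact = FALSE,
                                            correct = TRUE)$p.value))
})
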