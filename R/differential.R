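#' Inverse of the trigamma function
#'
#' Newton iteration on a monotone transform, used when matching moments of
#' log sample variances to a scaled-F model.
#' @param y positive value.
#' @return x with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:100) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

# empirical-Bayes prior (d0, s0^2) for residual variances: the marginal
# distribution of s^2 is s0^2 * F(d, d0); moments of log s^2 identify
# (d0, s0^2) through digamma/trigamma identities.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    return(list(df_prior = 0, s2_prior = NA_real_))
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(df_prior = d0, s2_prior = s0)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each metabolite, the pooled residual variance is shrunk toward a prior
#' variance estimated across all metabolites by matching the moments of the
#' log sample variances to a scaled-F model (the standard empirical-Bayes
#' moderation of microarray-style tests). The moderated statistic
#' `t = log2FC / (s_tilde * sqrt(1/nA + 1/nB))` with
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` is referred to a Student t
#' distribution on `d0 + d` degrees of freedom (normal when `d0` is
#' infinite).
#'
#' @param groupA,groupB log2 matrices with identical metabolite rows and at
#'   least two sample columns each; no missing values (impute first).
#'   `log2FC` is `mean(A) - mean(B)`, so pass the stage as `groupA` and the
#'   control as `groupB`.
#' @param prior_df override of the prior degrees of freedom `d0`: `0` gives
#'   the ordinary pooled-variance t-test, `Inf` a z-like statistic with fully
#'   pooled variance, `NULL` (default) estimates `d0` from the data.
#' @return data.frame with one row per metabolite: `metabolite`, `log2FC`,
#'   `t`, `df_resid`, `df_prior`, `s2_prior`, `s2_post`, `p_value`, and
#'   `zero_variance` flag.
#' @export
moderated_t_test <- function(groupA, groupB, prior_df = NULL) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            nrow(groupA) == nrow(groupB))
  if (!is.null(rownames(groupA)) && !is.null(rownames(groupB)) &&
      !identical(rownames(groupA), rownames(groupB)))
    stop("groupA and groupB must have identical metabolite rows")
  if (anyNA(groupA) || anyNA(groupB))
    stop("missing values present; impute before testing")
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2 || nB < 2) stop("need at least 2 samples per group")

  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  fc <- mA - mB
  d <- nA + nB - 2
  s2 <- (rowSums((groupA - mA)^2) + rowSums((groupB - mB)^2)) / d

  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2, rep(d, length(s2)))
  } else if (prior_df == 0) {
    pr <- list(df_prior = 0, s2_prior = NA_real_)
  } else {
    pr0 <- fit_variance_prior(s2, rep(d, length(s2)))
    pr <- list(df_prior = prior_df,
               s2_prior = if (is.finite(pr0$s2_prior)) pr0$s2_prior else mean(s2))
  }
  d0 <- pr$df_prior; s0 <- pr$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else if (d0 == 0) s2
             else (d0 * s0 + d * s2) / (d0 + d)

  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = df_total)
  p[is.infinite(t)] <- 0
  p[t == 0 & se == 0] <- 1

  data.frame(metabolite = rownames(groupA) %||% sprintf("m%d", seq_along(fc)),
             log2FC = unname(fc), t = unname(t), df_resid = d, df_prior = d0,
             s2_prior = s0, s2_post = unname(s2_post), p_value = unname(p),
             zero_variance = unname(s2 == 0), stringsAsFactors = FALSE)
}

#' Robust estimate of the proportion of true null hypotheses
#'
#' The Pounds-Cheng robust estimator: `pi0 = min(1, 2 * mean(p))`. Under the
#' null, p-values are uniform with mean 1/2, so twice the mean p estimates
#' the null proportion; truncation at 1 keeps it a proportion.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return the estimated pi0 in `(0, 1]`.
#' @export
estimate_pi0_robust <- function(pvalues) {
  if (length(pvalues) == 0) stop("'pvalues' must be non-empty")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("'pvalues' must lie in [0, 1]")
  min(1, 2 * mean(pvalues))
}

#' Adaptive Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p-values scaled by the estimated null
#' proportion `pi0` and capped at 1. With `pi0 = 1` this is exactly classical
#' BH; smaller `pi0` makes the procedure less conservative while controlling
#' the FDR at `pi0 * alpha`.
#'
#' @param pvalues raw p-values.
#' @param pi0 proportion of true nulls in `(0, 1]` (see
#'   [estimate_pi0_robust()]).
#' @return adjusted p-values, monotone in the raw p-values.
#' @export
adjust_adaptive_bh <- function(pvalues, pi0) {
  stopifnot(length(pi0) == 1, is.finite(pi0), pi0 > 0, pi0 <= 1)
  pmin(1, pi0 * stats::p.adjust(pvalues, method = "BH"))
}

#' Signed fold change
#'
#' Converts a log2 fold change to the reporting convention where
#' down-regulation by a factor k is written as -k: `2^log2FC` when
#' `log2FC >= 0`, else `-2^(-log2FC)`. Magnitudes are always >= 1.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return signed fold changes.
#' @export
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Call differentially abundant metabolites
#'
#' A metabolite is significant iff `|log2FC| >= log2(fc_min)` (a minimal fold
#' change of `fc_min`, boundary included) and its adjusted p-value is at most
#' `fdr`.
#'
#' @param results data.frame with columns `log2FC` and `adj_p` (e.g. the
#'   output of [moderated_t_test()] augmented by [adjust_adaptive_bh()]).
#' @param fc_min minimal fold change (default 2).
#' @param fdr FDR threshold on the adjusted p-value (default 0.01).
#' @return `results` with columns `signedFC` and `significant` added.
#' @export
call_differential <- function(results, fc_min = 2, fdr = 0.01) {
  stopifnot(all(c("log2FC", "adj_p") %in% names(results)))
  results$signedFC <- signed_fold_change(results$log2FC)
  results$significant <- abs(results$log2FC) >= log2(fc_min) &
    results$adj_p <= fdr
  results
}

#' Test one stage-vs-control contrast end to end
#'
#' Runs the moderated t-test for `stage` against `control`, estimates pi0 on
#' the contrast's p-values, applies the adaptive BH adjustment and the fold
#' change / FDR gates. Each contrast is its own adjustment family.
#'
#' @param table an imputed [normalized_table()].
#' @param stage,control condition labels.
#' @param fc_min,fdr significance gates (see [call_differential()]).
#' @param prior_df optional `d0` override (see [moderated_t_test()]).
#' @return a `DifferentialResult` data.frame with attribute `pi0`.
#' @export
test_contrast <- function(table, stage, control = "Control",
                          fc_min = 2, fdr = 0.01, prior_df = NULL) {
  stopifnot(inherits(table, "normalized_table"))
  jA <- which(table$condition == stage)
  jB <- which(table$condition == control)
  if (length(jA) < 2 || length(jB) < 2)
    stop(sprintf("need >= 2 samples in '%s' and '%s'", stage, control))
  res <- moderated_t_test(table$log2[, jA, drop = FALSE],
                          table$log2[, jB, drop = FALSE],
                          prior_df = prior_df)
  pi0 <- estimate_pi0_robust(res$p_value)
  res$adj_p <- adjust_adaptive_bh(res$p_value, pi0)
  res <- call_differential(res, fc_min = fc_min, fdr = fdr)
  attr(res, "pi0") <- pi0
  res
}

#' Compare two groups with the Mann-Whitney test
#'
#' Convenience comparison used for scalar biomarkers (e.g. inflammatory
#' markers): reports group medians and the two-sided Mann-Whitney p-value,
#' exact for small groups (both n <= 8, no ties) and a tie-corrected normal
#' approximation otherwise.
#'
#' @param values_a,values_b numeric vectors (at least one value each).
#' @return `list(median_a, median_b, p_value)`.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  p <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, exact = exact, correct = !exact)$p.value)
  list(median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       p_value = p)
}
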