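#' Dilution-series correlation of a feature
#'
#' Pearson correlation between chromatographic peak areas and the relative
#' concentration of the QC dilution series (the undiluted pool counts as
#' factor 1). A genuine metabolite dilutes proportionally, giving r close
#' to 1; noise features do not. Areas missing at a dilution level are treated
#' as 0: a metabolite diluted below its detection limit still supports
#' proportionality, and zeros preserve the monotone decline.
#'
#' @param areas peak areas over the qc_pool + qc_diluted injections
#'   (`NA` = not detected).
#' @param factors matching relative concentrations in (0, 1].
#' @return the correlation, or `NA` when undefined (fewer than 3 distinct
#'   concentration levels with a detected area, or zero variance), with
#'   attribute `flag` naming the reason.
#' @export
dilution_correlation <- function(areas, factors) {
  stopifnot(length(areas) == length(factors))
  lv <- unique(factors[!is.na(areas)])
  if (length(lv) < 3)
    return(structure(NA_real_, flag = "insufficient dilution data"))
  a <- ifelse(is.na(areas), 0, areas)
  if (stats::sd(a) == 0 || stats::sd(factors) == 0)
    return(structure(NA_real_, flag = "zero variance"))
  stats::cor(a, factors)
}

#' Repeatability (CV) of a feature over QC-pool injections
#'
#' @param areas peak areas over the qc_pool injections.
#' @return the coefficient of variation in percent
#'   (100 x sample sd / mean), or `NA` with a `flag` attribute when fewer
#'   than 2 areas are detected or the mean is not positive.
#' @export
qc_cv <- function(areas) {
  a <- areas[!is.na(areas)]
  if (length(a) < 2)
    return(structure(NA_real_, flag = "fewer than 2 QC areas"))
  m <- mean(a)
  if (m <= 0) return(structure(NA_real_, flag = "non-positive QC mean"))
  100 * stats::sd(a) / m
}

#' Biological-to-blank peak-area ratio of a feature
#'
#' @param bio_areas areas over biological injections (`NA` excluded from the
#'   mean).
#' @param blank_areas areas over blank injections (`NA` treated as 0: an
#'   undetected blank is no background).
#' @return mean(biological) / mean(blank); `Inf` when the blank mean is 0
#'   (passes the filter), `NA` with a `flag` when no biological area is
#'   detected.
#' @export
blank_ratio <- function(bio_areas, blank_areas) {
  b <- bio_areas[!is.na(bio_areas)]
  if (length(b) == 0)
    return(structure(NA_real_, flag = "no detected biological area"))
  blk <- mean(ifelse(is.na(blank_areas), 0, blank_areas))
  if (blk <= 0) return(Inf)
  mean(b) / blk
}

#' Apply the three QC feature filters
#'
#' A feature is retained iff all of:
#' (i) dilution-series correlation `> r_dil_min` (default 0.7),
#' (ii) QC-pool CV `< cv_max` percent (default 30), and
#' (iii) biological/blank area ratio `> blank_min` (default 3).
#' All comparisons are strict, so boundary values fail; an undefined
#' statistic fails its criterion. Filtering is idempotent: reapplying it to
#' its own output retains every feature it already kept.
#'
#' @param table a [feature_table()].
#' @param manifest injection manifest covering every column of `table`.
#' @param r_dil_min,cv_max,blank_min filter thresholds.
#' @return `list(table = filtered feature_table, report = data.frame)`; the
#'   report has one row per input feature with the three statistics, the
#'   per-criterion pass flags, the overall `retained` flag and any flags
#'   explaining undefined statistics.
#' @export
apply_feature_filters <- function(table, manifest,
                                  r_dil_min = 0.7, cv_max = 30, blank_min = 3) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(colnames(table$intensity), manifest$injection_id)
  if (anyNA(idx)) stop("manifest does not cover all feature-table columns")
  role <- manifest$role[idx]
  for (need in c("qc_diluted", "blank", "qc_pool"))
    if (!any(role == need))
      stop("manifest has no injections with role '", need, "'")

  dil_cols <- role %in% c("qc_pool", "qc_diluted")
  dil_fac <- manifest$dilution_factor[idx][dil_cols]
  qc_cols <- role == "qc_pool"
  bio_cols <- role == "biological"
  blank_cols <- role == "blank"

  G <- nrow(table$intensity)
  r_dil <- cv <- ratio <- rep(NA_real_, G)
  flags <- character(G)
  for (g in seq_len(G)) {
    x <- table$intensity[g, ]
    r <- dilution_correlation(x[dil_cols], dil_fac)
    v <- qc_cv(x[qc_cols])
    b <- blank_ratio(x[bio_cols], x[blank_cols])
    r_dil[g] <- as.numeric(r); cv[g] <- as.numeric(v); ratio[g] <- as.numeric(b)
    fl <- c(attr(r, "flag"), attr(v, "flag"), attr(b, "flag"))
    flags[g] <- paste(fl, collapse = "; ")
  }
  pass_dil <- !is.na(r_dil) & r_dil > r_dil_min
  pass_cv <- !is.na(cv) & cv < cv_max
  pass_blank <- !is.na(ratio) & ratio > blank_min
  retained <- pass_dil & pass_cv & pass_blank
  report <- data.frame(feature_id = table$features$feature_id,
                       r_dil = r_dil, qc_cv = cv, blank_ratio = ratio,
                       pass_dilution = pass_dil, pass_cv = pass_cv,
                       pass_blank = pass_blank, retained = retained,
                       flags = flags, stringsAsFactors = FALSE)
  list(table = feature_table(table$features[retained, , drop = FALSE],
                             table$intensity[retained, , drop = FALSE]),
       report = report)
}

# local linear regression of QC areas on injection order, evaluated at all
# injection orders; linear extrapolation beyond the QC range
loess_fit_eval <- function(qc_order, qc_area, eval_order, span) {
  # the direct-surface solver emits benign rank warnings (pseudoinverse,
  # zero reciprocal condition number) when a local window is close to
  # collinear; the fitted values remain well defined
  fit <- suppressWarnings(
    stats::loess(qc_area ~ qc_order, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  lo <- min(qc_order); hi <- max(qc_order)
  inside <- pmin(pmax(eval_order, lo), hi)
  # near-duplicate prediction points can trigger benign rank warnings in the
  # local solver; the predictions themselves are well defined
  pr <- function(v) suppressWarnings(
    as.numeric(stats::predict(fit, data.frame(qc_order = v))))
  yhat <- pr(inside)
  # linear extrapolation from the slope of the fit at the run ends
  h <- max((hi - lo) * 1e-3, 1e-6)
  sl_lo <- (pr(lo + h) - pr(lo)) / h
  sl_hi <- (pr(hi) - pr(hi - h)) / h
  left <- eval_order < lo
  right <- eval_order > hi
  yhat[left] <- yhat[left] + as.numeric(sl_lo) * (eval_order[left] - lo)
  yhat[right] <- yhat[right] + as.numeric(sl_hi) * (eval_order[right] - hi)
  yhat
}

#' LOESS correction of injection-order signal drift
#'
#' For each feature and each biological matrix, a locally weighted linear
#' regression (tricube weights, degree 1) of QC-pool intensity on injection
#' order is fitted and evaluated at every injection order (linear
#' extrapolation beyond the first/last QC). Each intensity is divided by
#' `fit / fit(midpoint)`, flattening the QC trace while keeping intensities
#' on their original scale; missing values stay missing. Features whose QC
#' trace has fewer than `min_qc` detected points, or whose fit dips to a
#' non-positive value, are left uncorrected and flagged.
#'
#' @param table a [feature_table()].
#' @param manifest injection manifest covering every column.
#' @param span LOESS span (fraction of QC points in each local window).
#' @param min_qc minimum number of QC-pool injections required; with fewer in
#'   the manifest the whole table is returned uncorrected with a warning.
#' @return a corrected [feature_table()] with attribute `uncorrected_features`
#'   listing features left untouched.
#' @export
loess_drift_correct <- function(table, manifest, span = 0.75, min_qc = 5) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(colnames(table$intensity), manifest$injection_id)
  if (anyNA(idx)) stop("manifest does not cover all feature-table columns")
  out <- table$intensity
  skipped <- character(0)
  for (mx in unique(manifest$matrix[idx])) {
    in_mx <- which(manifest$matrix[idx] == mx)
    role <- manifest$role[idx][in_mx]
    ord <- manifest$injection_order[idx][in_mx]
    dfac <- manifest$dilution_factor[idx][in_mx]
    # only full-strength pools anchor the fit, not the dilution series
    is_qc <- role == "qc_pool" & (is.na(dfac) | dfac == 1)
    if (sum(is_qc) < min_qc) {
      warning(sprintf(
        "matrix '%s': only %d QC-pool injections (< %d); drift correction skipped",
        mx, sum(is_qc), min_qc))
      next
    }
    qc_ord <- ord[is_qc]
    mid <- stats::median(range(ord))
    for (g in seq_len(nrow(out))) {
      y <- table$intensity[g, in_mx][is_qc]
      ok <- !is.na(y)
      if (sum(ok) < min_qc) {
        skipped <- c(skipped, table$features$feature_id[g])
        next
      }
      fit <- loess_fit_eval(qc_ord[ok], y[ok], c(ord, mid), span)
      fmid <- fit[length(fit)]
      fit <- fit[-length(fit)]
      if (any(fit <= 0) || fmid <= 0) {
        skipped <- c(skipped, table$features$feature_id[g])
        next
      }
      out[g, in_mx] <- table$intensity[g, in_mx] / (fit / fmid)
    }
  }
  res <- feature_table(table$features, out)
  attr(res, "uncorrected_features") <- unique(skipped)
  res
}
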