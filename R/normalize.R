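#' Construct a normalized metabolite table
#'
#' @param log2 metabolite x sample matrix of log2 intensities (`NA` allowed
#'   before imputation).
#' @param condition named vector of condition labels, one per sample column.
#' @param detected logical matrix of the same shape: `TRUE` where the raw
#'   intensity was observed (the pre-imputation detection mask used by the
#'   prevalence filters).
#' @return an object of class `normalized_table`.
#' @export
normalized_table <- function(log2, condition, detected = !is.na(log2)) {
  stopifnot(is.matrix(log2), length(condition) == ncol(log2),
            is.matrix(detected), all(dim(detected) == dim(log2)))
  structure(list(log2 = log2,
                 condition = stats::setNames(as.character(condition), colnames(log2)),
                 detected = detected,
                 imputed = is.na(log2) & matrix(FALSE, nrow(log2), ncol(log2))),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("normalized_table:", nrow(x$log2), "metabolites x", ncol(x$log2),
      "samples;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$log2))))
  invisible(x)
}

#' Log2 transform and median-center within conditions
#'
#' Intensities of the biological samples are log2-transformed; within each
#' condition, every sample column is shifted so its median equals the
#' condition's common target (the median of the condition's sample medians).
#' This removes per-sample loading differences while preserving
#' between-condition structure. Missing values stay missing.
#'
#' @param table a [feature_table()] (drift-corrected, filtered).
#' @param manifest injection manifest; only `role == "biological"` columns
#'   are kept.
#' @return a [normalized_table()].
#' @export
log2_median_center <- function(table, manifest) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(colnames(table$intensity), manifest$injection_id)
  if (anyNA(idx)) stop("manifest does not cover all feature-table columns")
  bio <- which(manifest$role[idx] == "biological")
  x <- table$intensity[, bio, drop = FALSE]
  cond <- manifest$condition[idx][bio]

  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive intensity for feature '%s' in sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  lx <- log2(x)
  for (cc in unique(cond)) {
    j <- which(cond == cc)
    med <- apply(lx[, j, drop = FALSE], 2, stats::median, na.rm = TRUE)
    target <- stats::median(med)
    lx[, j] <- sweep(lx[, j, drop = FALSE], 2, med - target, "-")
  }
  normalized_table(lx, stats::setNames(cond, colnames(lx)),
                   detected = !is.na(lx))
}

# EM fit of a multivariate normal with missing data; covariance shrunk
# toward its diagonal at every M step so it stays well conditioned when
# metabolites outnumber samples.
em_mvn <- function(X, lambda, max_iter = 100, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- stats::median(v[is.finite(v) & v > 0], na.rm = TRUE)
  if (!is.finite(stats::median(v))) v[] <- 1
  mu[is.na(mu)] <- mean(mu, na.rm = TRUE)
  sigma <- diag(v, p)
  miss <- is.na(X)
  if (!any(miss)) return(list(mu = mu, sigma = sigma, X = X))

  Xc <- X
  for (it in seq_len(max_iter)) {
    Csum <- matrix(0, p, p)
    for (i in seq_len(n)) {
      m <- which(miss[i, ])
      if (length(m) == 0) next
      o <- which(!miss[i, ])
      if (length(o) == 0) {
        Xc[i, ] <- mu
        Csum <- Csum + sigma
        next
      }
      Soo <- sigma[o, o, drop = FALSE]
      Smo <- sigma[m, o, drop = FALSE]
      W <- Smo %*% solve(Soo)
      Xc[i, m] <- mu[m] + as.vector(W %*% (X[i, o] - mu[o]))
      Cm <- sigma[m, m, drop = FALSE] - W %*% t(Smo)
      Csum[m, m] <- Csum[m, m] + Cm
    }
    mu_new <- colMeans(Xc)
    S <- (crossprod(sweep(Xc, 2, mu_new)) + Csum) / n
    S <- (1 - lambda) * S + lambda * diag(diag(S), p)
    delta <- max(abs(mu_new - mu), abs(S - sigma) / (1 + max(abs(sigma))))
    mu <- mu_new; sigma <- S
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma, X = Xc, miss = miss)
}

#' Impute missing log2 intensities from a multivariate-normal model
#'
#' Per condition, a multivariate normal is fitted to the metabolite x sample
#' block by EM, with the covariance shrunk toward its diagonal (intensity
#' `lambda`, default `p / (p + n)` so the matrix stays well-conditioned when
#' metabolites far outnumber samples). Missing entries are then filled with a
#' single stochastic draw from the conditional normal given the sample's
#' observed values. Observed values are never changed; the draw is
#' deterministic given `seed`.
#'
#' @param table a [normalized_table()].
#' @param seed integer seed for the imputation draw.
#' @param lambda diagonal shrinkage intensity in `[0, 1]`, or `NULL` for the
#'   per-condition default `p / (p + n)`.
#' @return a [normalized_table()] with no missing values; `$imputed` marks
#'   the filled cells. Metabolites missing in every sample of every condition
#'   are dropped with a warning.
#' @export
impute_missing <- function(table, seed = 1L, lambda = NULL) {
  stopifnot(inherits(table, "normalized_table"))
  all_missing <- rowSums(!is.na(table$log2)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " metabolite(s) with no observed value in any condition: ",
            paste(utils::head(rownames(table$log2)[all_missing], 5), collapse = ", "))
    table$log2 <- table$log2[!all_missing, , drop = FALSE]
    table$detected <- table$detected[!all_missing, , drop = FALSE]
  }
  few <- rowSums(!is.na(table$log2)) < 2
  if (any(few))
    stop("metabolite(s) with fewer than 2 observed values: ",
         paste(rownames(table$log2)[few], collapse = ", "))

  lx <- table$log2
  imputed <- is.na(lx)
  if (!any(imputed)) {
    table$imputed <- imputed
    return(table)
  }
  set.seed(as.integer(seed))
  for (cc in unique(table$condition)) {
    j <- which(table$condition == cc)
    X <- t(lx[, j, drop = FALSE])          # samples x metabolites
    lam <- lambda %||% (ncol(X) / (ncol(X) + nrow(X)))
    fit <- em_mvn(X, lambda = lam)
    for (i in seq_len(nrow(X))) {
      m <- which(is.na(X[i, ]))
      if (length(m) == 0) next
      o <- which(!is.na(X[i, ]))
      if (length(o) == 0) {
        cm <- fit$mu[m]
        Cm <- fit$sigma[m, m, drop = FALSE]
      } else {
        Soo <- fit$sigma[o, o, drop = FALSE]
        Smo <- fit$sigma[m, o, drop = FALSE]
        W <- Smo %*% solve(Soo)
        cm <- fit$mu[m] + as.vector(W %*% (X[i, o] - fit$mu[o]))
        Cm <- fit$sigma[m, m, drop = FALSE] - W %*% t(Smo)
      }
      # draw from the conditional normal (chol with a tiny ridge: the
      # conditional covariance can be numerically semi-definite)
      L <- chol(Cm + diag(1e-10, length(m)))
      X[i, m] <- cm + as.vector(t(L) %*% stats::rnorm(length(m)))
    }
    lx[, j] <- t(X)
  }
  out <- table
  out$log2 <- lx
  out$imputed <- imputed
  out
}
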