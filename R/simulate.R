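#' Generate the injection manifest for a simulated run
#'
#' Lays out the acquisition sequence the way QC-aware untargeted runs are
#' acquired: blanks at the start and end, the QC-pool dilution series injected
#' in replicate at the beginning of the sequence (the undiluted pool rows
#' carry role `qc_pool`, diluted rows `qc_diluted`), and the biological block
#' with QC-pool injections interleaved at a fixed cadence (the block also
#' opens and closes with a QC pool). Biological samples are randomized across
#' conditions under the config seed. Injection order is a strict total order.
#'
#' @param cfg a [sim_config()].
#' @return a `data.frame` with columns `injection_id`, `role`, `condition`,
#'   `matrix`, `injection_order`, `dilution_factor`.
#' @export
generate_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  blank_row <- function(i) data.frame(
    injection_id = sprintf("Blank_%02d", i), role = "blank",
    condition = NA_character_, matrix = cfg$matrix_name,
    dilution_factor = NA_real_, stringsAsFactors = FALSE)

  nb_start <- ceiling(cfg$n_blanks / 2)
  nb_end <- cfg$n_blanks - nb_start
  if (nb_start > 0) rows <- c(rows, lapply(seq_len(nb_start), blank_row))

  # dilution series: each level in replicate, undiluted pool rows are qc_pool
  k <- 0L
  for (li in seq_along(cfg$dilution_levels)) {
    lev <- cfg$dilution_levels[li]
    for (r in seq_len(cfg$dilution_replicates)) {
      k <- k + 1L
      rows <- c(rows, list(data.frame(
        injection_id = sprintf("dQC_l%d_r%d", li, r),
        role = if (lev < 1) "qc_diluted" else "qc_pool",
        condition = NA_character_, matrix = cfg$matrix_name,
        dilution_factor = lev, stringsAsFactors = FALSE)))
    }
  }

  # biological block, randomized, with interleaved QC pools
  bio_ids <- unlist(lapply(CONDITIONS, function(cc)
    if (cfg$n_per_condition[[cc]] > 0)
      sprintf("%s_%02d", cc, seq_len(cfg$n_per_condition[[cc]])) else character(0)))
  bio_cond <- sub("_[0-9]+$", "", bio_ids)
  n_bio <- length(bio_ids)
  if (n_bio > 0) {
    set.seed(derive_seed(cfg$seed, 1L))
    ord <- sample.int(n_bio)
    bio_ids <- bio_ids[ord]; bio_cond <- bio_cond[ord]
  }

  qc_i <- 0L
  qc_row <- function() {
    qc_i <<- qc_i + 1L
    data.frame(injection_id = sprintf("QC_%02d", qc_i), role = "qc_pool",
               condition = NA_character_, matrix = cfg$matrix_name,
               dilution_factor = 1, stringsAsFactors = FALSE)
  }
  if (n_bio > 0) {
    if (!is.null(cfg$n_qc_injections) && cfg$n_qc_injections > 0) {
      # spread the requested number of pools evenly through the block
      after <- unique(round(seq(0, n_bio, length.out = cfg$n_qc_injections)))
    } else {
      after <- unique(c(seq(0, n_bio, by = cfg$qc_cadence), n_bio))
    }
    for (j in seq_len(n_bio)) {
      if ((j - 1L) %in% after) rows <- c(rows, list(qc_row()))
      rows <- c(rows, list(data.frame(
        injection_id = bio_ids[j], role = "biological",
        condition = bio_cond[j], matrix = cfg$matrix_name,
        dilution_factor = NA_real_, stringsAsFactors = FALSE)))
    }
    if (n_bio %in% after) rows <- c(rows, list(qc_row()))
  }

  if (nb_end > 0)
    rows <- c(rows, lapply(nb_start + seq_len(nb_end), blank_row))

  manifest <- do.call(rbind, rows)
  manifest$injection_order <- seq_len(nrow(manifest))
  rownames(manifest) <- NULL
  manifest[, c("injection_id", "role", "condition", "matrix",
               "injection_order", "dilution_factor")]
}

# shared latent Gaussian factors carrying the planted species-metabolite
# correlations; one factor per planted edge, one value per biological sample
# (in manifest order). Regenerated identically by the feature and taxa
# generators from the same seed.
latent_factors <- function(cfg, manifest) {
  bio <- manifest[manifest$role == "biological", , drop = FALSE]
  n_edges <- if (is.null(cfg$planted_edges)) 0L else nrow(cfg$planted_edges)
  if (n_edges == 0L || nrow(bio) == 0L)
    return(matrix(0, nrow(bio), n_edges,
                  dimnames = list(bio$injection_id, NULL)))
  set.seed(derive_seed(cfg$seed, 3L))
  matrix(stats::rnorm(nrow(bio) * n_edges), nrow(bio), n_edges,
         dimnames = list(bio$injection_id, NULL))
}

drift_curve <- function(t, amplitude, wiggle) {
  (1 - amplitude * t) * (1 + amplitude * wiggle * sin(2 * pi * t))
}

#' Construct a feature table
#'
#' @param features `data.frame` with columns `feature_id`, `mz`, `rt`.
#' @param intensity numeric matrix, one row per feature and one column per
#'   injection; `NA` marks a missing (undetected) value.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(features, intensity) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "rt") %in% names(features)),
            is.matrix(intensity), nrow(intensity) == nrow(features))
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0 where present")
  rownames(intensity) <- features$feature_id
  structure(list(features = features, intensity = intensity),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensity), "features x",
      ncol(x$intensity), "injections;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Simulate an LC-MS feature intensity table
#'
#' Per-feature mean log2 intensities are uniform over
#' `cfg$feature_log2_mean_range`; biological samples add Gaussian
#' between-subject variation (and any planted condition effects) on the log2
#' scale; QC-pool injections sit at the cohort-average pool level;
#' dilution-series injections scale linearly with relative concentration;
#' blanks sit at `blank_fraction` of the pool level (contaminant features at
#' 50%). All intensities are multiplied by a smooth injection-order drift
#' curve and by log-normal analytical noise with CV `noise_cv`, then censored
#' missing-not-at-random: the probability that a value goes missing is a
#' decreasing logistic in its log2 intensity.
#'
#' @param cfg a [sim_config()].
#' @param manifest the manifest from [generate_manifest()] for `cfg`.
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(manifest))
  G <- cfg$n_features
  N <- nrow(manifest)

  set.seed(derive_seed(cfg$seed, 2L))
  mu <- stats::runif(G, cfg$feature_log2_mean_range[1], cfg$feature_log2_mean_range[2])
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(G)),
    mz = round(stats::runif(G, 85, 1000), 4),
    rt = round(stats::runif(G, 0.5, 17), 3))

  # planted condition effects, features x conditions
  delta <- matrix(0, G, length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  if (!is.null(cfg$planted_diff))
    for (i in seq_len(nrow(cfg$planted_diff)))
      delta[cfg$planted_diff$feature[i], cfg$planted_diff$condition[i]] <-
        delta[cfg$planted_diff$feature[i], cfg$planted_diff$condition[i]] +
        cfg$planted_diff$log2fc[i]

  # the QC pool averages the cohort on the raw scale
  n_bio <- sum(cfg$n_per_condition)
  pool_lvl <- if (n_bio > 0) {
    mu + log2(as.vector(2^delta %*% cfg$n_per_condition) / n_bio)
  } else mu

  z <- latent_factors(cfg, manifest)
  edge_of_feature <- rep(NA_integer_, G)
  if (!is.null(cfg$planted_edges))
    edge_of_feature[cfg$planted_edges$feature] <- seq_len(nrow(cfg$planted_edges))

  set.seed(derive_seed(cfg$seed, 5L))
  log2true <- matrix(NA_real_, G, N)
  bio_seen <- 0L
  for (j in seq_len(N)) {
    role <- manifest$role[j]
    if (role == "biological") {
      bio_seen <- bio_seen + 1L
      eps <- stats::rnorm(G)
      e <- eps
      pe <- which(!is.na(edge_of_feature))
      if (length(pe)) {
        rho <- cfg$planted_edges$rho[edge_of_feature[pe]]
        w <- sign(rho) * sqrt(abs(rho))
        e[pe] <- w * z[bio_seen, edge_of_feature[pe]] +
          sqrt(1 - w^2) * eps[pe]
      }
      log2true[, j] <- mu + delta[, manifest$condition[j]] + cfg$bio_sd_log2 * e
    } else if (role %in% c("qc_pool", "qc_diluted")) {
      log2true[, j] <- pool_lvl + log2(manifest$dilution_factor[j])
    } else { # blank
      bf <- rep(cfg$blank_fraction, G)
      bf[cfg$contaminant_features] <- 0.5
      log2true[, j] <- pool_lvl + log2(bf)
    }
  }

  # analytical noise: multiplicative log-normal with mean 1 and CV noise_cv
  if (cfg$noise_cv > 0) {
    s_ln <- sqrt(log(1 + cfg$noise_cv^2))
    log2true <- log2true +
      (matrix(stats::rnorm(G * N, 0, s_ln), G, N) - s_ln^2 / 2) / log(2)
  }

  tt <- if (N > 1) (manifest$injection_order - 1) / (N - 1) else rep(0, N)
  dc <- drift_curve(tt, cfg$drift_amplitude, cfg$drift_wiggle)
  intensity <- 2^log2true * rep(dc, each = G)

  mrp <- cfg$missing_rate_params
  if (mrp[["scale"]] > 0) {
    pmiss <- stats::plogis((mrp[["mid"]] - log2(intensity)) / mrp[["scale"]])
    intensity[matrix(stats::runif(G * N), G, N) < pmiss] <- NA_real_
  }
  colnames(intensity) <- manifest$injection_id
  feature_table(features, intensity)
}

#' Construct a species relative-abundance table
#'
#' @param abundance numeric matrix of relative abundances in percent, one row
#'   per species, one column per sample; columns sum to 100.
#' @param group named character vector (or factor) of group labels, one per
#'   sample column.
#' @return an object of class `taxa_table`.
#' @export
taxa_table <- function(abundance, group) {
  stopifnot(is.matrix(abundance), length(group) == ncol(abundance))
  if (any(abundance < 0)) stop("relative abundances must be >= 0")
  structure(list(abundance = abundance,
                 group = stats::setNames(as.character(group), colnames(abundance))),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("taxa_table:", nrow(x$abundance), "species x", ncol(x$abundance),
      "samples; groups:", paste(names(table(x$group)), table(x$group),
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a species relative-abundance table
#'
#' Non-planted species are drawn from a log-normal compositional model
#' (species mean log abundances spread with sd `species_log_mean_sd`,
#' within-species sd `species_log_sd`), zeroed per cell with probability
#' `1 - species_prevalence`, and closed so every sample column sums to 100.
#' A species carrying a planted edge gets its relative abundance built
#' directly on the shared latent factor of that edge — a low-variance
#' log-normal (sigma 0.2) around a 1.5% mean — so the target correlation with
#' the partner metabolite's log10 intensity is controlled analytically; the
#' remaining species are closed to the residual mass.
#'
#' @param cfg a [sim_config()].
#' @param manifest the manifest from [generate_manifest()] for `cfg`.
#' @return a [taxa_table()] over the biological samples.
#' @export
generate_taxa_table <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(manifest))
  bio <- manifest[manifest$role == "biological", , drop = FALSE]
  if (nrow(bio) == 0) stop("manifest has no biological samples")
  S <- cfg$n_species
  n <- nrow(bio)
  z <- latent_factors(cfg, manifest)

  set.seed(derive_seed(cfg$seed, 4L))
  m_s <- stats::rnorm(S, 0, cfg$species_log_mean_sd)
  eps <- matrix(stats::rnorm(S * n), S, n)
  present <- matrix(stats::runif(S * n), S, n) <
    matrix(cfg$species_prevalence, S, n)

  raw <- exp(m_s + cfg$species_log_sd * eps) * present

  planted_pct <- matrix(0, 0, n)
  planted_idx <- integer(0)
  if (!is.null(cfg$planted_edges) && nrow(cfg$planted_edges) > 0) {
    pe <- cfg$planted_edges
    planted_idx <- pe$species
    sig <- 0.2                      # low sigma keeps exp() nearly linear
    mean_pct <- 1.5                 # percent, per planted species
    planted_pct <- t(vapply(seq_len(nrow(pe)), function(e) {
      x <- sqrt(abs(pe$rho[e])) * z[, e] +
        sqrt(1 - abs(pe$rho[e])) * stats::rnorm(n)
      mean_pct * exp(sig * x - sig^2 / 2)
    }, numeric(n)))
    tot <- colSums(planted_pct)
    if (any(tot >= 100))
      stop("planted species exceed the compositional budget; reduce edges")
  }

  abundance <- matrix(0, S, n,
                      dimnames = list(sprintf("sp%03d", seq_len(S)), bio$injection_id))
  others <- setdiff(seq_len(S), planted_idx)
  budget <- 100 - (if (length(planted_idx)) colSums(planted_pct) else 0)
  raw_o <- raw[others, , drop = FALSE]
  cs <- colSums(raw_o)
  scl <- ifelse(cs > 0, budget / cs, 0)
  abundance[others, ] <- sweep(raw_o, 2, scl, "*")
  if (length(planted_idx)) abundance[planted_idx, ] <- planted_pct
  taxa_table(abundance, stats::setNames(bio$condition, bio$injection_id))
}
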