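CONDITIONS <- c("Control", "I", "II", "III", "IV")
ROLES <- c("biological", "qc_pool", "qc_diluted", "blank")
MATRICES <- c("serum", "urine", "fecal_water")

#' Configuration for the synthetic study generator
#'
#' Describes a simulated LC-MS run of one biological matrix: a cohort of
#' Control and stage I-IV samples, a QC pool injected throughout the run, a
#' dilution series of that pool injected in triplicate at the start of the
#' sequence, blank injections, a smooth multiplicative injection-order drift,
#' intensity-dependent (MNAR) missingness, planted between-condition fold
#' changes, and planted species-metabolite correlations carried by shared
#' latent Gaussian factors.
#'
#' @param n_per_condition samples per condition; either a single count or a
#'   named vector over `Control, I, II, III, IV`.
#' @param n_features number of LC-MS features (metabolites).
#' @param n_species number of microbial species in the taxa table.
#' @param qc_cadence a QC-pool injection is inserted after every
#'   `qc_cadence` biological injections (the run also starts and ends the
#'   biological block with a QC pool).
#' @param n_qc_injections optional override: exact number of interleaved
#'   QC-pool injections, spread evenly through the biological block. `NULL`
#'   (default) derives the count from `qc_cadence`.
#' @param dilution_levels relative concentrations of the dilution series,
#'   each in (0, 1]. Level 1 is the undiluted pool itself.
#' @param dilution_replicates injections per dilution level (default 3).
#' @param n_blanks number of blank injections, split between the start and
#'   end of the sequence.
#' @param matrix_name biological matrix label (`serum`, `urine`,
#'   `fecal_water`).
#' @param drift_amplitude total fractional signal loss across the run: the
#'   multiplicative drift curve decays from 1 at the first injection to
#'   `1 - drift_amplitude` at the last.
#' @param drift_wiggle relative amplitude of a superimposed single-period
#'   sinusoid (0 gives a purely monotone drift).
#' @param noise_cv analytical (injection-to-injection) coefficient of
#'   variation; noise is multiplicative log-normal with exactly this CV.
#' @param bio_sd_log2 between-subject biological standard deviation of each
#'   feature on the log2 scale.
#' @param feature_log2_mean_range range of per-feature mean log2 intensities
#'   (arbitrary area units), drawn uniformly.
#' @param blank_fraction blank intensity as a fraction of the feature's pool
#'   intensity for non-contaminant features.
#' @param contaminant_features indices of features that appear in blanks at
#'   half their pool intensity (so they fail the blank-ratio filter).
#' @param missing_rate_params named vector `c(mid =, scale =)` of the MNAR
#'   logistic: an intensity with log2 value `x` is missing with probability
#'   `plogis((mid - x) / scale)`, i.e. missingness decreases with intensity.
#'   Set `scale = 0` for no missingness.
#' @param species_log_mean_sd spread (sd) of species mean log abundances.
#' @param species_log_sd within-species between-sample sd of log abundance.
#' @param species_prevalence per-cell detection probability for non-planted
#'   species; a vector of length `n_species` gives per-species values
#'   (0 forces an all-zero row).
#' @param planted_diff `data.frame(feature, condition, log2fc)`: additive
#'   log2 effects applied to the named condition's biological samples.
#' @param planted_edges `data.frame(species, feature, rho)`: target Pearson
#'   correlations between a species' relative abundance and the log10
#'   intensity of a feature, induced by a shared latent factor.
#' @param seed master seed; identical seeds give bit-identical tables.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_condition = 20,
                       n_features = 200,
                       n_species = 60,
                       qc_cadence = 10,
                       n_qc_injections = NULL,
                       dilution_levels = c(1, 0.5, 0.25, 0.125),
                       dilution_replicates = 3,
                       n_blanks = 4,
                       matrix_name = "serum",
                       drift_amplitude = 0.3,
                       drift_wiggle = 0.05,
                       noise_cv = 0.10,
                       bio_sd_log2 = 0.8,
                       feature_log2_mean_range = c(10, 20),
                       blank_fraction = 0.01,
                       contaminant_features = integer(0),
                       missing_rate_params = c(mid = 9, scale = 1),
                       species_log_mean_sd = 1.5,
                       species_log_sd = 1.0,
                       species_prevalence = 0.95,
                       planted_diff = NULL,
                       planted_edges = NULL,
                       seed = 1L) {
  if (is.list(n_per_condition)) n_per_condition <- unlist(n_per_condition)
  if (is.list(missing_rate_params)) missing_rate_params <- unlist(missing_rate_params)
  if (length(n_per_condition) == 1L)
    n_per_condition <- stats::setNames(rep(n_per_condition, 5L), CONDITIONS)
  if (is.null(names(n_per_condition)) ||
      !setequal(names(n_per_condition), CONDITIONS))
    stop("'n_per_condition' must be a scalar or named over: ",
         paste(CONDITIONS, collapse = ", "))
  n_per_condition <- n_per_condition[CONDITIONS]
  if (any(n_per_condition < 0)) stop("counts in 'n_per_condition' must be >= 0")

  assert_scalar_num(n_features, "n_features", lo = 0)
  assert_scalar_num(n_species, "n_species", lo = 0)
  assert_scalar_num(qc_cadence, "qc_cadence", lo = 1)
  assert_scalar_num(n_blanks, "n_blanks", lo = 0)
  assert_scalar_num(dilution_replicates, "dilution_replicates", lo = 0)
  assert_scalar_num(drift_amplitude, "drift_amplitude", lo = 0, hi = 0.95)
  assert_scalar_num(drift_wiggle, "drift_wiggle", lo = 0, hi = 1)
  assert_scalar_num(noise_cv, "noise_cv", lo = 0)
  assert_scalar_num(bio_sd_log2, "bio_sd_log2", lo = 0)
  assert_scalar_num(blank_fraction, "blank_fraction", lo = 0)
  if (any(dilution_levels <= 0) || any(dilution_levels > 1))
    stop("'dilution_levels' must lie in (0, 1]")
  matrix_name <- match.arg(matrix_name, MATRICES)
  if (!all(c("mid", "scale") %in% names(missing_rate_params)))
    stop("'missing_rate_params' needs named entries 'mid' and 'scale'")
  if (missing_rate_params[["scale"]] < 0) stop("MNAR 'scale' must be >= 0")
  if (length(species_prevalence) == 1L)
    species_prevalence <- rep(species_prevalence, n_species)
  if (length(species_prevalence) != n_species ||
      any(species_prevalence < 0 | species_prevalence > 1))
    stop("'species_prevalence' must be length 1 or n_species, in [0, 1]")

  if (!is.null(planted_diff)) {
    planted_diff <- as.data.frame(planted_diff)
    if (!all(c("feature", "condition", "log2fc") %in% names(planted_diff)))
      stop("'planted_diff' needs columns feature, condition, log2fc")
    bad <- planted_diff$feature < 1 | planted_diff$feature > n_features
    if (any(bad))
      stop("planted_diff feature index out of range: ",
           paste(planted_diff$feature[bad], collapse = ", "))
    if (!all(planted_diff$condition %in% CONDITIONS))
      stop("planted_diff conditions must be among: ",
           paste(CONDITIONS, collapse = ", "))
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    if (!all(c("species", "feature", "rho") %in% names(planted_edges)))
      stop("'planted_edges' needs columns species, feature, rho")
    bad_f <- planted_edges$feature < 1 | planted_edges$feature > n_features
    if (any(bad_f))
      stop("planted_edges feature index out of range: ",
           paste(planted_edges$feature[bad_f], collapse = ", "))
    bad_s <- planted_edges$species < 1 | planted_edges$species > n_species
    if (any(bad_s))
      stop("planted_edges species index out of range: ",
           paste(planted_edges$species[bad_s], collapse = ", "))
    if (any(abs(planted_edges$rho) >= 1))
      stop("planted rho must lie in (-1, 1)")
    if (anyDuplicated(planted_edges$feature) || anyDuplicated(planted_edges$species))
      stop("each species and feature may carry at most one planted edge")
  }
  assert_scalar_num(seed, "seed")

  structure(list(
    n_per_condition = n_per_condition, n_features = as.integer(n_features),
    n_species = as.integer(n_species), qc_cadence = as.integer(qc_cadence),
    n_qc_injections = if (is.null(n_qc_injections)) NULL else as.integer(n_qc_injections),
    dilution_levels = dilution_levels,
    dilution_replicates = as.integer(dilution_replicates),
    n_blanks = as.integer(n_blanks), matrix_name = matrix_name,
    drift_amplitude = drift_amplitude, drift_wiggle = drift_wiggle,
    noise_cv = noise_cv, bio_sd_log2 = bio_sd_log2,
    feature_log2_mean_range = feature_log2_mean_range,
    blank_fraction = blank_fraction,
    contaminant_features = as.integer(contaminant_features),
    missing_rate_params = missing_rate_params,
    species_log_mean_sd = species_log_mean_sd,
    species_log_sd = species_log_sd,
    species_prevalence = species_prevalence,
    planted_diff = planted_diff, planted_edges = planted_edges,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", sum(x$n_per_condition), " biological samples (",
      paste(sprintf("%s=%d", CONDITIONS, x$n_per_condition), collapse = ", "),
      ")\n", sep = "")
  cat("  features:", x$n_features, " species:", x$n_species,
      " matrix:", x$matrix_name, "\n")
  cat("  dilution series:", paste(x$dilution_levels, collapse = "/"),
      "x", x$dilution_replicates, "replicates;",
      x$n_blanks, "blanks; QC cadence", x$qc_cadence, "\n")
  cat("  drift amplitude:", x$drift_amplitude, " noise CV:", x$noise_cv,
      " seed:", x$seed, "\n")
  invisible(x)
}
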