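#' Read and write pipeline tables as TSV
#'
#' All tables travel as plain tab-separated text: feature tables with the
#' feature identifier, m/z and retention time in the first three columns and
#' one intensity column per injection (`NA` = missing); manifests with one
#' row per injection; taxa tables with the species identifier in the first
#' column. `write_simulation()` materializes a full simulated study plus a
#' run-metadata YAML echoing every generator parameter and seed.
#'
#' @param x object to write.
#' @param path file path.
#' @return the input (writers, invisibly) or the parsed object (readers).
#' @name metabnet-io
NULL

#' @rdname metabnet-io
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- cbind(x$features, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname metabnet-io
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(df)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  feature_table(df[need],
                as.matrix(df[setdiff(names(df), need)]))
}

#' @rdname metabnet-io
#' @export
write_manifest <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname metabnet-io
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("injection_id", "role", "condition", "matrix",
            "injection_order", "dilution_factor")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$injection_order))
    stop("injection_order values must be unique")
  m
}

#' @rdname metabnet-io
#' @export
write_taxa_table <- function(x, path) {
  stopifnot(inherits(x, "taxa_table"))
  df <- data.frame(species_id = rownames(x$abundance),
                   as.data.frame(x$abundance, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  # group labels ride along in a sidecar
  utils::write.table(
    data.frame(sample_id = colnames(x$abundance), group = unname(x$group)),
    paste0(path, ".groups"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname metabnet-io
#' @export
read_taxa_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ab <- as.matrix(df[-1])
  rownames(ab) <- df[[1]]
  gf <- paste0(path, ".groups")
  grp <- if (file.exists(gf)) {
    g <- utils::read.delim(gf, stringsAsFactors = FALSE)
    stats::setNames(g$group, g$sample_id)[colnames(ab)]
  } else rep(NA_character_, ncol(ab))
  taxa_table(ab, grp)
}

#' Simulate a study and write it to disk
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @return named list of file paths, invisibly.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- generate_manifest(cfg)
  ft <- generate_feature_table(cfg, manifest)
  paths <- list(manifest = file.path(dir, "manifest.tsv"),
                features = file.path(dir, "features.tsv"),
                metadata = file.path(dir, "run_metadata.yaml"))
  write_manifest(manifest, paths$manifest)
  write_feature_table(ft, paths$features)
  if (cfg$n_species > 0 && sum(cfg$n_per_condition) > 0) {
    tx <- generate_taxa_table(cfg, manifest)
    paths$taxa <- file.path(dir, "taxa.tsv")
    write_taxa_table(tx, paths$taxa)
  }
  meta <- unclass(cfg)
  meta$n_per_condition <- as.list(meta$n_per_condition)
  meta$missing_rate_params <- as.list(meta$missing_rate_params)
  for (nm in c("planted_diff", "planted_edges"))
    if (!is.null(meta[[nm]])) meta[[nm]] <- as.list(as.data.frame(meta[[nm]]))
  yaml::write_yaml(meta, paths$metadata)
  invisible(paths)
}
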