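#' Abundance and prevalence filter for species
#'
#' Within one sample group, keeps species whose mean relative abundance
#' strictly exceeds `min_abundance` percent and whose prevalence (fraction of
#' group samples where the species is present, abundance > 0) is at least
#' `min_prevalence` percent. The returned table is restricted to the group's
#' samples.
#'
#' @param taxa a [taxa_table()].
#' @param group group label to analyze.
#' @param min_abundance mean relative-abundance threshold, percent
#'   (default 0.01; strictly greater-than).
#' @param min_prevalence prevalence threshold, percent (default 40; species
#'   below it are excluded, at it retained).
#' @return a filtered [taxa_table()] over the group's samples.
#' @export
filter_species <- function(taxa, group, min_abundance = 0.01,
                           min_prevalence = 40) {
  stopifnot(inherits(taxa, "taxa_table"))
  j <- which(taxa$group == group)
  if (length(j) == 0) stop("no samples in group '", group, "'")
  ab <- taxa$abundance[, j, drop = FALSE]
  keep <- rowMeans(ab) > min_abundance &
    100 * rowMeans(ab > 0) >= min_prevalence
  taxa_table(ab[keep, , drop = FALSE], taxa$group[j])
}

#' Prevalence filter for metabolites
#'
#' Keeps metabolites detected (pre-imputation) in at least `min_prevalence`
#' percent of the group's samples; metabolites below the threshold are
#' excluded.
#'
#' @param detected logical metabolite x sample matrix over the group's
#'   samples (`TRUE` = detected before imputation).
#' @param min_prevalence prevalence threshold, percent (default 40).
#' @return named logical vector: `TRUE` for retained metabolites.
#' @export
filter_metabolite_prevalence <- function(detected, min_prevalence = 40) {
  stopifnot(is.matrix(detected) || length(detected) == 0)
  if (length(detected) == 0) return(logical(0))
  stats::setNames(100 * rowMeans(detected) >= min_prevalence,
                  rownames(detected))
}

#' Correlation between a species and a metabolite
#'
#' @param x species relative abundances.
#' @param y log10 metabolite intensities (same samples).
#' @param method `"pearson"` or `"spearman"` (mid-ranks for ties).
#' @return the coefficient, or `NA` with attribute `flag` when either vector
#'   has zero variance.
#' @export
correlate_pair <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite; drop incomplete pairs first")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, flag = "zero variance"))
  stats::cor(x, y, method = method)
}

#' Permutation p-value for a correlation
#'
#' Permutes `y` uniformly `B` times under `seed` and reports the two-sided
#' add-one p-value `(1 + #{|r_perm| >= |r_obs|}) / (B + 1)`. Deterministic
#' given the seed; a perfectly correlated pair attains the minimum `1/(B+1)`.
#'
#' @inheritParams correlate_pair
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @return the p-value, or `NA` (flagged) when the correlation is undefined.
#' @export
permutation_pvalue <- function(x, y, method = c("pearson", "spearman"),
                               B = 1000, seed = 1L) {
  method <- match.arg(method)
  r_obs <- correlate_pair(x, y, method)
  if (is.na(r_obs)) return(r_obs)
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)   # permuting y == permuting its ranks
  }
  set.seed(as.integer(seed))
  idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  Yp <- matrix(y[idx], n, B)
  r_perm <- as.vector(stats::cor(x, Yp))
  (1 + sum(abs(r_perm) >= abs(r_obs))) / (B + 1)
}

#' Build a group-specific species-metabolite co-occurrence network
#'
#' Every species x metabolite pair is evaluated on the group's samples:
#' Pearson and Spearman coefficients on pairwise-complete values, and a
#' permutation p-value of the retention statistic (Pearson by default). An
#' edge is retained iff `p < p_threshold` and `|r| > r_threshold`, both
#' strict. The result is bipartite by construction. Node fold changes
#' (group vs control) are attached when control tables are supplied.
#'
#' @param taxa a group-filtered [taxa_table()] (see [filter_species()]).
#' @param metab metabolite x sample matrix of log10 intensities for the same
#'   group (`NA` allowed: incomplete samples are dropped pairwise).
#' @param group group label carried on the network.
#' @param control optional `list(taxa =, metab =)` with the control group's
#'   matrices (same row sets), used for node fold changes.
#' @param b_perms permutations per pair (default 1000).
#' @param r_threshold retention threshold on `|r|` (default 0.3, strict).
#' @param p_threshold retention threshold on the permutation p (default
#'   0.05, strict).
#' @param method statistic the retention rule keys on (default Pearson;
#'   Spearman is always reported as an edge attribute).
#' @param seed master seed; each pair permutes under a child seed derived
#'   from it and the pair index, so evaluation order cannot change results.
#' @param keep_isolates keep nodes without any edge (default `FALSE`).
#' @param min_n minimum pairwise-complete samples per pair (default 3;
#'   sparser pairs are skipped and flagged).
#' @return an object of class `cooc_network`: `list(nodes, edges, group,
#'   params, skipped)`.
#' @export
build_network <- function(taxa, metab, group, control = NULL,
                          b_perms = 1000, r_threshold = 0.3,
                          p_threshold = 0.05,
                          method = c("pearson", "spearman"),
                          seed = 1L, keep_isolates = FALSE, min_n = 3) {
  method <- match.arg(method)
  stopifnot(inherits(taxa, "taxa_table"), is.matrix(metab))
  samples <- intersect(colnames(taxa$abundance), colnames(metab))
  if (length(samples) < 3)
    stop("fewer than 3 aligned samples between taxa and metabolite tables")
  ab <- taxa$abundance[, samples, drop = FALSE]
  mt <- metab[, samples, drop = FALSE]

  species <- rownames(ab); metabs <- rownames(mt)
  edges <- list()
  skipped <- list()
  pair_i <- 0L
  for (s in seq_along(species)) {
    x_full <- ab[s, ]
    for (m in seq_along(metabs)) {
      pair_i <- pair_i + 1L
      y_full <- mt[m, ]
      ok <- !is.na(x_full) & !is.na(y_full)
      if (sum(ok) < min_n) {
        skipped <- c(skipped, list(data.frame(
          species = species[s], metabolite = metabs[m],
          reason = "fewer complete samples than min_n")))
        next
      }
      x <- x_full[ok]; y <- y_full[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        skipped <- c(skipped, list(data.frame(
          species = species[s], metabolite = metabs[m],
          reason = "zero variance")))
        next
      }
      r_p <- stats::cor(x, y, method = "pearson")
      r_s <- stats::cor(x, y, method = "spearman")
      r_stat <- if (method == "pearson") r_p else r_s
      # a pair failing the |r| gate can never be retained, so its
      # permutation test is not run (per-pair seeds keep this exact)
      p <- if (abs(r_stat) > r_threshold)
        permutation_pvalue(x, y, method = method, B = b_perms,
                           seed = derive_seed(seed, pair_i)) else NA_real_
      if (!is.na(p) && p < p_threshold && abs(r_stat) > r_threshold) {
        edges <- c(edges, list(data.frame(
          species = species[s], metabolite = metabs[m],
          pearson_r = r_p, spearman_rho = r_s, perm_p = p,
          sign = if (r_p >= 0) "positive" else "negative",
          stringsAsFactors = FALSE)))
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(species = character(0), metabolite = character(0),
               pearson_r = numeric(0), spearman_rho = numeric(0),
               perm_p = numeric(0), sign = character(0),
               stringsAsFactors = FALSE)

  node_ids_s <- if (keep_isolates) species else unique(edges$species)
  node_ids_m <- if (keep_isolates) metabs else unique(edges$metabolite)
  fc_s <- fc_m <- NULL
  if (!is.null(control)) {
    cs <- rowMeans(control$taxa$abundance)[species]
    gs <- rowMeans(ab)
    fc_s <- stats::setNames(
      ifelse(cs > 0 & gs > 0, signed_fold_change(log2(gs / cs)), NA_real_),
      species)
    cm <- rowMeans(control$metab, na.rm = TRUE)[metabs]
    gm <- rowMeans(mt, na.rm = TRUE)
    # log10 difference back to a signed fold change on the raw scale
    fc_m <- stats::setNames(signed_fold_change((gm - cm) * log2(10)), metabs)
  }
  nodes <- rbind(
    data.frame(id = node_ids_s, class = rep("species", length(node_ids_s)),
               mean_abundance = unname(rowMeans(ab)[node_ids_s]),
               fold_change = if (is.null(fc_s))
                 rep(NA_real_, length(node_ids_s)) else unname(fc_s[node_ids_s]),
               stringsAsFactors = FALSE),
    data.frame(id = node_ids_m, class = rep("metabolite", length(node_ids_m)),
               mean_abundance = unname(rowMeans(mt, na.rm = TRUE)[node_ids_m]),
               fold_change = if (is.null(fc_m))
                 rep(NA_real_, length(node_ids_m)) else unname(fc_m[node_ids_m]),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, group = group,
                 params = list(b_perms = b_perms, r_threshold = r_threshold,
                               p_threshold = p_threshold, method = method,
                               seed = seed),
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("cooc_network (group ", x$group, "): ",
      sum(x$nodes$class == "species"), " species, ",
      sum(x$nodes$class == "metabolite"), " metabolites, ",
      nrow(x$edges), " edges (",
      sum(x$edges$sign == "positive"), " co-occurrence / ",
      sum(x$edges$sign == "negative"), " co-exclusion)\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(net$nodes) > 0)
    g <- igraph::add_vertices(g, nrow(net$nodes),
                              name = net$nodes$id, class = net$nodes$class,
                              mean_abundance = net$nodes$mean_abundance,
                              fold_change = net$nodes$fold_change)
  if (nrow(net$edges) > 0)
    g <- igraph::add_edges(
      g, rbind(match(net$edges$species, net$nodes$id),
               match(net$edges$metabolite, net$nodes$id)),
      pearson_r = net$edges$pearson_r, spearman_rho = net$edges$spearman_rho,
      perm_p = net$edges$perm_p, sign = net$edges$sign)
  g <- igraph::set_graph_attr(g, "group", net$group %||% "")
  g
}

#' Export a co-occurrence network
#'
#' `graphml` carries all node attributes (class, mean abundance, fold change)
#' and edge attributes (Pearson r, Spearman rho, permutation p, sign) and
#' round-trips exactly through [import_network_graphml()]; `sif` is the
#' Cytoscape simple-interaction format with interaction labels
#' `co_occurrence` / `co_exclusion`; `edge_tsv` is a flat edge list.
#'
#' @param net a `cooc_network` (see [build_network()]).
#' @param path output file.
#' @param format one of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = "graphml") {
  stopifnot(inherits(net, "cooc_network"))
  supported <- c("graphml", "sif", "edge_tsv")
  if (!format %in% supported)
    stop("unknown format '", format, "'; supported: ",
         paste(supported, collapse = ", "))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges) > 0)
      paste(net$edges$species,
            ifelse(net$edges$sign == "positive", "co_occurrence", "co_exclusion"),
            net$edges$metabolite, sep = "\t") else character(0)
    writeLines(lines, path)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network back from GraphML
#'
#' @param path a GraphML file written by [export_network()].
#' @return a `cooc_network`.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  nodes <- data.frame(
    id = if (n) igraph::vertex_attr(g, "name") else character(0),
    class = if (n) igraph::vertex_attr(g, "class") else character(0),
    mean_abundance = if (n) igraph::vertex_attr(g, "mean_abundance") else numeric(0),
    fold_change = if (n) igraph::vertex_attr(g, "fold_change") else numeric(0),
    stringsAsFactors = FALSE)
  ne <- igraph::ecount(g)
  if (ne > 0) {
    ends <- igraph::as_edgelist(g)
    cls <- stats::setNames(nodes$class, nodes$id)
    sp <- ifelse(cls[ends[, 1]] == "species", ends[, 1], ends[, 2])
    mb <- ifelse(cls[ends[, 1]] == "species", ends[, 2], ends[, 1])
    edges <- data.frame(species = unname(sp), metabolite = unname(mb),
                        pearson_r = igraph::edge_attr(g, "pearson_r"),
                        spearman_rho = igraph::edge_attr(g, "spearman_rho"),
                        perm_p = igraph::edge_attr(g, "perm_p"),
                        sign = igraph::edge_attr(g, "sign"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(species = character(0), metabolite = character(0),
                        pearson_r = numeric(0), spearman_rho = numeric(0),
                        perm_p = numeric(0), sign = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 group = igraph::graph_attr(g, "group"),
                 params = NULL, skipped = NULL),
            class = "cooc_network")
}
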