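RUN_CONFIG_KEYS <- list(
  top = c("seed", "outdir", "simulate", "qc", "differential", "network"),
  qc = c("span", "min_qc", "r_dil_min", "cv_max", "blank_min"),
  differential = c("fc_min", "fdr", "contrasts", "prior_df"),
  network = c("b_perms", "r_threshold", "p_threshold", "min_abundance",
              "min_prevalence", "groups", "control_group", "method",
              "keep_isolates")
)

#' Read and validate a pipeline run configuration
#'
#' Configurations are plain YAML with sections `simulate`, `qc`,
#' `differential`, `network` plus top-level `seed` and `outdir`. Every key is
#' checked against the known schema; unknown keys are rejected before any
#' computation so typos cannot silently fall back to defaults.
#'
#' @param path YAML file, or a list with the same structure.
#' @return the validated config list.
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim_keys <- setdiff(names(formals(sim_config)), "")
  for (sec in c("simulate", "qc", "differential", "network")) {
    allowed <- if (sec == "simulate") sim_keys else RUN_CONFIG_KEYS[[sec]]
    unknown <- setdiff(names(config[[sec]]), allowed)
    if (length(unknown))
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  config
}

#' Run the full pipeline: simulate, QC, test, network
#'
#' Orchestrates the whole analysis into one run directory: synthetic-data
#' generation, LOESS drift correction and the three QC feature filters,
#' log2 median-centering + EM imputation + moderated testing per contrast
#' with adaptive BH, and group-specific co-occurrence networks exported as
#' GraphML/SIF/TSV. Every threshold and seed is echoed into the run log and
#' config snapshot; identical config and seed give identical numeric outputs.
#'
#' @param config a YAML path or list (see [read_run_config()]).
#' @param seed optional master-seed override.
#' @param outdir optional run-directory override.
#' @return invisibly, `list(outdir =, summary =)`; the summary counts are
#'   also written to `summary.json` in the run directory.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  config <- read_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% tempfile("metabnet_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  snapshot <- config
  snapshot$seed <- seed
  yaml::write_yaml(snapshot, file.path(outdir, "config_snapshot.yaml"))

  stage <- function(name, expr) {
    msg(sprintf("[%s] start", name), logfile = logfile)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  qc_cfg <- config$qc %||% list()
  dcfg <- config$differential %||% list()
  ncfg <- config$network %||% list()

  # ---- simulate -----------------------------------------------------------
  sim <- stage("simulate", {
    cfg <- do.call(sim_config, c(config$simulate %||% list(), list(seed = seed)))
    simdir <- file.path(outdir, "sim")
    write_simulation(cfg, simdir)
    manifest <- generate_manifest(cfg)
    list(cfg = cfg, manifest = manifest,
         ft = generate_feature_table(cfg, manifest),
         taxa = if (cfg$n_species > 0) generate_taxa_table(cfg, manifest) else NULL)
  })
  msg(sprintf("[simulate] %d injections, %d features, %d species",
              nrow(sim$manifest), sim$cfg$n_features, sim$cfg$n_species),
      logfile = logfile)

  # ---- qc -----------------------------------------------------------------
  qc <- stage("qc", {
    corrected <- loess_drift_correct(sim$ft, sim$manifest,
                                     span = qc_cfg$span %||% 0.75,
                                     min_qc = qc_cfg$min_qc %||% 5)
    filt <- apply_feature_filters(corrected, sim$manifest,
                                  r_dil_min = qc_cfg$r_dil_min %||% 0.7,
                                  cv_max = qc_cfg$cv_max %||% 30,
                                  blank_min = qc_cfg$blank_min %||% 3)
    utils::write.table(filt$report, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_table(filt$table, file.path(outdir, "features_filtered.tsv"))
    filt
  })
  msg(sprintf("[qc] retained %d / %d features",
              nrow(qc$table$intensity), sim$cfg$n_features), logfile = logfile)

  # ---- differential -------------------------------------------------------
  diff <- stage("differential", {
    nt <- log2_median_center(qc$table, sim$manifest)
    imp <- impute_missing(nt, seed = derive_seed(seed, 101L))
    contrasts <- dcfg$contrasts %||% c("I", "II", "III", "IV")
    res <- list()
    for (st in contrasts) {
      r <- test_contrast(imp, stage = st, control = "Control",
                         fc_min = dcfg$fc_min %||% 2,
                         fdr = dcfg$fdr %||% 0.01,
                         prior_df = dcfg$prior_df)
      out <- r[, c("metabolite", "log2FC", "signedFC", "t", "df_resid",
                   "p_value", "adj_p", "significant")]
      utils::write.table(out,
                         file.path(outdir, sprintf("differential_%s_vs_Control.tsv", st)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res[[st]] <- r
      msg(sprintf("[differential] %s vs Control: %d significant (pi0 = %.3f)",
                  st, sum(r$significant), attr(r, "pi0")), logfile = logfile)
    }
    list(normalized = nt, imputed = imp, results = res)
  })

  # ---- network ------------------------------------------------------------
  nets <- list()
  if (!is.null(sim$taxa)) {
    nets <- stage("network", {
      groups <- ncfg$groups %||%
        list(Control = "Control", Cancer = c("I", "II", "III", "IV"))
      control_group <- ncfg$control_group %||% "Control"
      # regroup taxa samples by network group
      glab <- rep(NA_character_, ncol(sim$taxa$abundance))
      for (g in names(groups))
        glab[sim$taxa$group %in% groups[[g]]] <- g
      gtaxa <- taxa_table(sim$taxa$abundance, glab)
      # pre-imputation log10 intensities of the filtered features
      bio_cols <- intersect(colnames(qc$table$intensity),
                            colnames(sim$taxa$abundance))
      lmat <- log10(qc$table$intensity[, bio_cols, drop = FALSE])
      detected <- !is.na(lmat)
      out <- list()
      gi <- 0L
      for (g in names(groups)) {
        gi <- gi + 1L
        gsam <- bio_cols[glab[match(bio_cols, colnames(sim$taxa$abundance))] == g]
        tg <- filter_species(gtaxa, g,
                             min_abundance = ncfg$min_abundance %||% 0.01,
                             min_prevalence = ncfg$min_prevalence %||% 40)
        keepm <- filter_metabolite_prevalence(
          detected[, gsam, drop = FALSE],
          min_prevalence = ncfg$min_prevalence %||% 40)
        csam <- bio_cols[glab[match(bio_cols, colnames(sim$taxa$abundance))] == control_group]
        ctrl <- if (length(csam) && g != control_group)
          list(taxa = taxa_table(sim$taxa$abundance[, csam, drop = FALSE],
                                 rep(control_group, length(csam))),
               metab = lmat[, csam, drop = FALSE]) else NULL
        net <- build_network(tg, lmat[keepm, gsam, drop = FALSE], group = g,
                             control = ctrl,
                             b_perms = ncfg$b_perms %||% 1000,
                             r_threshold = ncfg$r_threshold %||% 0.3,
                             p_threshold = ncfg$p_threshold %||% 0.05,
                             method = ncfg$method %||% "pearson",
                             seed = derive_seed(seed, 200L + gi),
                             keep_isolates = isTRUE(ncfg$keep_isolates))
        export_network(net, file.path(outdir, sprintf("network_%s.graphml", g)), "graphml")
        export_network(net, file.path(outdir, sprintf("network_%s.sif", g)), "sif")
        export_network(net, file.path(outdir, sprintf("network_%s_edges.tsv", g)), "edge_tsv")
        msg(sprintf("[network] group %s: %d species x %d metabolites -> %d edges",
                    g, nrow(tg$abundance), sum(keepm), nrow(net$edges)),
            logfile = logfile)
        out[[g]] <- net
      }
      out
    })
  }

  summary <- list(
    seed = seed,
    n_injections = nrow(sim$manifest),
    n_features_input = sim$cfg$n_features,
    n_features_retained = nrow(qc$table$intensity),
    n_significant = lapply(diff$results, function(r) sum(r$significant)),
    pi0 = lapply(diff$results, function(r) attr(r, "pi0")),
    n_edges = lapply(nets, function(n) nrow(n$edges)),
    n_network_species = lapply(nets, function(n) sum(n$nodes$class == "species")),
    n_network_metabolites = lapply(nets, function(n) sum(n$nodes$class == "metabolite"))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg("[done] run directory: ", outdir, logfile = logfile)
  invisible(list(outdir = outdir, summary = summary, networks = nets,
                 differential = diff$results, qc_report = qc$report))
}
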