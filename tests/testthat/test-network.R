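test_that("species filter: abundance strictly >, prevalence >= boundaries", {
  sam <- sprintf("s%d", 1:5)
  ab <- rbind(
    at_abund  = rep(0.01, 5),                 # mean exactly 0.01 -> excluded
    ok_abund  = rep(0.0100001, 5),            # just above -> retained
    at_prev   = c(2, 2, 0, 0, 0),             # prevalence 40% -> retained
    low_prev  = c(5, 0, 0, 0, 0),             # prevalence 20% -> excluded
    absent    = rep(0, 5))
  colnames(ab) <- sam
  tx <- taxa_table(ab, rep("Control", 5))
  out <- filter_species(tx, "Control")
  expect_identical(rownames(out$abundance),
                   c("ok_abund", "at_prev"))
  expect_error(filter_species(tx, "Cancer"), "no samples in group 'Cancer'")
})

test_that("metabolite prevalence filter keeps the 40% boundary", {
  det <- rbind(M1 = c(TRUE, TRUE, FALSE, FALSE, FALSE),   # 40% -> keep
               M2 = c(TRUE, FALSE, FALSE, FALSE, FALSE),  # 20% -> drop
               M3 = rep(TRUE, 5))
  keep <- filter_metabolite_prevalence(det)
  expect_identical(keep, c(M1 = TRUE, M2 = FALSE, M3 = TRUE))
})

test_that("correlate_pair: exact values, rank invariance, degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(correlate_pair(x, 2 * x + 1)), 1)
  expect_equal(as.numeric(correlate_pair(x, -x)), -1)
  # spearman sees only ranks: a convex monotone transform changes pearson
  y <- exp(x)
  expect_equal(as.numeric(correlate_pair(x, y, "spearman")), 1)
  expect_lt(as.numeric(correlate_pair(x, y, "pearson")), 1)
  r <- correlate_pair(x, rep(3, 5))
  expect_true(is.na(r))
  expect_match(attr(r, "flag"), "zero variance")
  expect_error(correlate_pair(c(1, 2), c(3, 4)), "at least 3")
  expect_error(correlate_pair(x, c(1, NA, 3, 4, 5)), "finite")
})

test_that("permutation p-value: exact floor, determinism, add-one formula", {
  x <- as.numeric(1:10)
  # a perfect pair beats every permutation: p = 1/(B+1) exactly
  expect_identical(permutation_pvalue(x, 3 * x, B = 1000, seed = 4), 1 / 1001)
  expect_identical(permutation_pvalue(x, -x, B = 500, seed = 4), 1 / 501)
  # deterministic under a fixed seed
  set.seed(123); y <- rnorm(10)
  p1 <- permutation_pvalue(x, y, B = 200, seed = 9)
  p2 <- permutation_pvalue(x, y, B = 200, seed = 9)
  expect_identical(p1, p2)
  # p is an achievable add-one fraction
  expect_true((p1 * 201) %% 1 == 0)
  # uncorrelated data should not look significant
  expect_gt(permutation_pvalue(x, rep(c(1, 2), 5), B = 1000, seed = 2), 0.5)
})

test_that("spearman permutation p is invariant to monotone transforms", {
  set.seed(14)
  x <- rnorm(15); y <- x + rnorm(15, sd = 2)
  p_raw <- permutation_pvalue(x, y, method = "spearman", B = 300, seed = 77)
  p_tr  <- permutation_pvalue(exp(x), y^3 + 10 * y, method = "spearman",
                              B = 300, seed = 77)
  expect_identical(p_raw, p_tr)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(15)
  n <- 12
  x <- rnorm(n)
  p <- vapply(1:400, function(i) {
    permutation_pvalue(x, rnorm(n), B = 99, seed = i)
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
  expect_gt(mean(p), 0.45); expect_lt(mean(p), 0.55)
})

# deterministic network fixture: one perfect edge, one null metabolite,
# one zero-variance species
net_fixture <- function() {
  sam <- sprintf("s%02d", 1:20)
  ab <- rbind(S1 = seq(1, 20) / 10, S2 = rep(5, 20))
  colnames(ab) <- sam
  mt <- rbind(M1 = 2 * seq(1, 20) / 10 + 3,       # perfectly tracks S1
              M2 = rep(c(4, 5), 10))              # near-zero correlation
  colnames(mt) <- sam
  list(taxa = taxa_table(ab, rep("Cancer", 20)), metab = mt)
}

test_that("build_network keeps true edges, skips degenerate pairs", {
  fx <- net_fixture()
  net <- build_network(fx$taxa, fx$metab, group = "Cancer", b_perms = 500,
                       seed = 3)
  expect_s3_class(net, "cooc_network")
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$species, "S1")
  expect_identical(net$edges$metabolite, "M1")
  expect_equal(net$edges$pearson_r, 1, tolerance = 1e-12)
  expect_identical(net$edges$perm_p, 1 / 501)
  expect_identical(net$edges$sign, "positive")
  # the constant species is skipped with a reason, for both metabolites
  expect_identical(unique(net$skipped$species), "S2")
  expect_identical(unique(net$skipped$reason), "zero variance")
  # bipartite: every edge joins one species and one metabolite node
  cls <- setNames(net$nodes$class, net$nodes$id)
  expect_true(all(cls[net$edges$species] == "species"))
  expect_true(all(cls[net$edges$metabolite] == "metabolite"))
  # isolates dropped by default, kept on request
  expect_identical(sort(net$nodes$id), c("M1", "S1"))
  net_iso <- build_network(fx$taxa, fx$metab, group = "Cancer", b_perms = 500,
                           seed = 3, keep_isolates = TRUE)
  expect_identical(sort(net_iso$nodes$id), c("M1", "M2", "S1", "S2"))
})

test_that("network edges are reproducible under the master seed", {
  set.seed(16)
  sam <- sprintf("s%02d", 1:15)
  ab <- matrix(rexp(4 * 15), 4, 15, dimnames = list(sprintf("S%d", 1:4), sam))
  mt <- matrix(rnorm(6 * 15, 5), 6, 15,
               dimnames = list(sprintf("M%d", 1:6), sam))
  mt[1, ] <- mt[1, ] + 2 * scale(ab[2, ])[, 1]
  tx <- taxa_table(ab, rep("Control", 15))
  n1 <- build_network(tx, mt, "Control", b_perms = 300, seed = 42)
  n2 <- build_network(tx, mt, "Control", b_perms = 300, seed = 42)
  expect_identical(n1$edges, n2$edges)
  expect_true(any(n1$edges$species == "S2" & n1$edges$metabolite == "M1"))
})

test_that("co-exclusion edges carry a negative sign", {
  sam <- sprintf("s%02d", 1:12)
  ab <- rbind(S1 = seq(12, 1))
  colnames(ab) <- sam
  mt <- rbind(M1 = as.numeric(1:12))
  colnames(mt) <- sam
  net <- build_network(taxa_table(ab, rep("g", 12)), mt, "g", b_perms = 200,
                       seed = 5)
  expect_identical(net$edges$sign, "negative")
  expect_equal(net$edges$pearson_r, -1, tolerance = 1e-12)
})

test_that("pairs with too few complete samples are skipped", {
  fx <- net_fixture()
  mt <- fx$metab
  mt["M2", 1:18] <- NA
  net <- build_network(fx$taxa, mt, "Cancer", b_perms = 100, seed = 6)
  expect_true(any(net$skipped$metabolite == "M2" &
                    net$skipped$reason == "fewer complete samples than min_n"))
})

test_that("node fold changes reflect the control group", {
  fx <- net_fixture()
  ctrl <- list(
    taxa = taxa_table(fx$taxa$abundance / 2,
                      rep("Control", 20)),          # group doubles the species
    metab = fx$metab - 1)                            # group is 10x (log10 + 1)
  net <- build_network(fx$taxa, fx$metab, "Cancer", control = ctrl,
                       b_perms = 200, seed = 7)
  nodes <- setNames(net$nodes$fold_change, net$nodes$id)
  expect_equal(unname(nodes["S1"]), 2, tolerance = 1e-12)
  expect_equal(unname(nodes["M1"]), 10, tolerance = 1e-12)
})

test_that("graphml export round-trips nodes, edges and attributes", {
  fx <- net_fixture()
  net <- build_network(fx$taxa, fx$metab, "Cancer", b_perms = 500, seed = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  back <- import_network_graphml(path)
  expect_identical(back$group, "Cancer")
  expect_identical(back$nodes$id, net$nodes$id)
  expect_identical(back$nodes$class, net$nodes$class)
  # igraph serializes reals with 15 significant digits
  expect_equal(back$nodes$mean_abundance, net$nodes$mean_abundance,
               tolerance = 1e-12)
  expect_identical(back$edges$species, net$edges$species)
  expect_identical(back$edges$metabolite, net$edges$metabolite)
  expect_equal(back$edges$pearson_r, net$edges$pearson_r, tolerance = 1e-12)
  expect_equal(back$edges$spearman_rho, net$edges$spearman_rho,
               tolerance = 1e-12)
  expect_equal(back$edges$perm_p, net$edges$perm_p, tolerance = 1e-12)
  expect_identical(back$edges$sign, net$edges$sign)
})

test_that("sif and edge_tsv exports have the documented shapes", {
  fx <- net_fixture()
  net <- build_network(fx$taxa, fx$metab, "Cancer", b_perms = 500, seed = 3)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_identical(readLines(sif), "S1\tco_occurrence\tM1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  tab <- read.delim(tsv)
  expect_identical(names(tab),
                   c("species", "metabolite", "pearson_r", "spearman_rho",
                     "perm_p", "sign"))
  expect_equal(tab$pearson_r, net$edges$pearson_r, tolerance = 1e-12)
  expect_error(export_network(net, tsv, "gexf"),
               "unknown format 'gexf'; supported: graphml, sif, edge_tsv")
})

test_that("an empty network still exports and re-imports", {
  sam <- sprintf("s%d", 1:6)
  ab <- rbind(S1 = c(1, 2, 1, 2, 1, 2)); colnames(ab) <- sam
  mt <- rbind(M1 = c(5, 5.1, 5, 5.1, 5.05, 5)); colnames(mt) <- sam
  net <- build_network(taxa_table(ab, rep("g", 6)), mt, "g", b_perms = 50,
                       seed = 8, r_threshold = 0.999)
  expect_equal(nrow(net$edges), 0)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  back <- import_network_graphml(path)
  expect_equal(nrow(back$edges), 0)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_identical(readLines(sif), character(0))
})
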