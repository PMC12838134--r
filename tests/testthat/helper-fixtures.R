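# Fixtures are built in code, no files needed.

# Manifest for the hand-built QC-filter fixture: 2 blanks, the dilution
# series (3 x level 1 pools + 3 x 3 diluted), 4 interleaved QC pools and 6
# biological samples. 16 injections enter the dilution correlation (7 at
# factor 1), 7 the QC CV, 6 vs 2 the blank ratio.
qc_fixture_manifest <- function() {
  data.frame(
    injection_id = c("Blank_01", "Blank_02",
                     "dQC_l1_r1", "dQC_l1_r2", "dQC_l1_r3",
                     "dQC_l2_r1", "dQC_l2_r2", "dQC_l2_r3",
                     "dQC_l3_r1", "dQC_l3_r2", "dQC_l3_r3",
                     "dQC_l4_r1", "dQC_l4_r2", "dQC_l4_r3",
                     "QC_01", "Control_01", "Control_02", "QC_02",
                     "IV_01", "IV_02", "QC_03", "Control_03", "IV_03", "QC_04"),
    role = c("blank", "blank",
             rep("qc_pool", 3), rep("qc_diluted", 9),
             "qc_pool", "biological", "biological", "qc_pool",
             "biological", "biological", "qc_pool", "biological",
             "biological", "qc_pool"),
    condition = c(rep(NA, 15), "Control", "Control", NA, "IV", "IV", NA,
                  "Control", "IV", NA),
    matrix = "serum",
    injection_order = 1:24,
    dilution_factor = c(NA, NA, rep(1, 3), rep(0.5, 3), rep(0.25, 3),
                        rep(0.125, 3), 1, NA, NA, 1, NA, NA, 1, NA, NA, 1),
    stringsAsFactors = FALSE)
}

# Six features: F1/F2 clean; F3 dilution correlation exactly 0.7 (integer
# construction: areas = 6000 + 7*W + g with W the centered integer dilution
# scores and g a level-internal contrast with Sgg = 51*SWW, making
# cor(areas, factors) land exactly on the double 0.7); F4 QC CV exactly 30%
# (pool deviations (50,-50,10,-10,10,-10,0) around 100); F5 blank ratio
# exactly 3 (bio mean 300, blank mean 100); F6 anti-proportional dilution.
qc_fixture_table <- function() {
  m <- qc_fixture_manifest()
  G <- 6
  X <- matrix(NA_real_, G, nrow(m), dimnames = list(NULL, m$injection_id))
  series <- sprintf("dQC_l%d_r%d", rep(1:4, each = 3), rep(1:3, 4))
  pools_extra <- c("QC_01", "QC_02", "QC_03", "QC_04")
  bio <- c("Control_01", "Control_02", "IV_01", "IV_02", "Control_03", "IV_03")
  blanks <- c("Blank_01", "Blank_02")
  lev <- c(rep(1, 3), rep(0.5, 3), rep(0.25, 3), rep(0.125, 3))

  set_feature <- function(g, series_vals, pool_vals, bio_vals, blank_vals) {
    X[g, series] <<- series_vals
    X[g, pools_extra] <<- pool_vals
    X[g, bio] <<- bio_vals
    X[g, blanks] <<- blank_vals
  }
  # F1 clean: exact proportionality, flat pools, clean blanks
  set_feature(1, 1000 * lev, rep(1000, 4), rep(800, 6), c(10, 10))
  # F2 clean: mild pool noise, blanks undetected
  set_feature(2, c(2000, 1900, 2100, 1000, 980, 1020, 500, 505, 495,
                   250, 248, 252),
              c(2000, 1950, 2050, 2000), rep(1500, 6), c(NA, NA))
  # F3: r_dil exactly 0.7 (boundary, must fail the strict > 0.7)
  a <- c(7628, 7228, 7508, 7348, 7428, 7428, 7428,       # 7 pools
         8636, 2636, 5636, 7044, 2436, 4740, 4852, 3732, 4292)
  set_feature(3, c(a[1:3], a[8:16]), a[4:7], rep(5000, 6), c(10, 10))
  # F4: QC CV exactly 30% (boundary, must fail the strict < 30)
  set_feature(4, c(150, 50, 110, 50, 50, 50, 25, 25, 25, 12, 13, 12),
              c(90, 110, 90, 100), rep(300, 6), c(3, 3))
  # F5: blank ratio exactly 3 (boundary, must fail the strict > 3)
  set_feature(5, 1000 * lev, rep(1000, 4),
              c(200, 300, 400, 250, 350, 300), c(80, 120))
  # F6: anti-proportional dilution profile
  set_feature(6, c(rep(125, 3), rep(250, 3), rep(500, 3), rep(1000, 3)),
              rep(125, 4), rep(800, 6), c(10, 10))

  feature_table(data.frame(feature_id = sprintf("FX%d", 1:G),
                           mz = 100 + 1:G, rt = 1 + 1:G / 10),
                X)
}

# independent brute-force tricube local linear regression, for checking the
# drift-correction fit against a from-scratch implementation
tricube_local_reg <- function(x, y, x0, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0, function(p) {
    d <- abs(x - p)
    dq <- sort(d)[q]
    w <- if (dq > 0) pmax(1 - (d / dq)^3, 0)^3 else as.numeric(d == 0)
    stats::lm.wfit(cbind(1, x - p), y, w)$coefficients[[1]]
  }, numeric(1))
}

# small simulated run shared by drift tests
drift_cfg <- function(amplitude, noise_cv, seed, n = 8, wiggle = 0) {
  sim_config(n_per_condition = n, n_features = 25, n_species = 0,
             drift_amplitude = amplitude, drift_wiggle = wiggle,
             noise_cv = noise_cv,
             missing_rate_params = c(mid = 0, scale = 0), seed = seed)
}

qc_pool_cols <- function(manifest) {
  manifest$injection_id[manifest$role == "qc_pool" &
                          manifest$dilution_factor %in% 1]
}

cv_pct <- function(x) {
  x <- x[!is.na(x)]
  100 * stats::sd(x) / mean(x)
}
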