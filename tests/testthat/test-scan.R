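test_that("marker-regression LOD matches the normal-equations oracle", {
  set.seed(41)
  for (rep in 1:5) {
    g <- manual_geno(list(mkA = sample(0:2, 12, TRUE, prob = c(.25, .5, .25)),
                          mkB = sample(0:2, 12, TRUE),
                          mkC = rep(1L, 12)))          # monomorphic
    y <- trait_vector(rnorm(12), rownames(g$codes))
    curve <- scan_trait(g, y, min_n = 5)
    for (mk in c("mkA", "mkB")) {
      expect_equal(curve$lod[curve$marker_id == mk],
                   oracle_lod(as.numeric(y), g$codes[, mk]),
                   tolerance = 1e-8)
    }
    expect_identical(curve$lod[curve$marker_id == "mkC"], 0)
  }
})

test_that("LOD is invariant under affine transformation of the trait", {
  geno <- simulate_cross(small_config(seed = 14))
  set.seed(15)
  y <- trait_vector(rnorm(nrow(geno$codes)), rownames(geno$codes))
  y2 <- trait_vector(3.7 * as.numeric(y) - 11, names(y))
  expect_equal(scan_trait(geno, y)$lod, scan_trait(geno, y2)$lod,
               tolerance = 1e-9)
  expect_error(scan_trait(geno, trait_vector(rep(1, nrow(geno$codes)),
                                             rownames(geno$codes))),
               "zero-variance trait")
})

test_that("missing genotypes are handled by per-marker complete cases", {
  geno <- simulate_cross(small_config(n_mice = 60, seed = 16))
  codes <- geno$codes
  set.seed(17)
  codes[sample(length(codes), length(codes) * 0.1)] <- NA
  geno2 <- genotype_matrix(codes, geno$map, max_missing = 1)
  y <- trait_vector(rnorm(60), rownames(codes))
  curve <- scan_trait(geno2, y)
  j <- match("c2_m010", curve$marker_id)
  expect_equal(curve$lod[j], oracle_lod(as.numeric(y), codes[, "c2_m010"]),
               tolerance = 1e-8)
})

test_that("an unrelated covariate barely moves a null scan", {
  geno <- simulate_cross(small_config(n_mice = 200, seed = 18))
  set.seed(19)
  y <- trait_vector(rnorm(200), rownames(geno$codes))
  cv <- setNames(rnorm(200), rownames(geno$codes))
  plain <- scan_trait(geno, y)
  cond <- scan_trait(geno, y, covariate = cv)
  expect_lt(max(abs(plain$lod - cond$lod)), 0.5)
  expect_error(scan_trait(geno, y, covariate = setNames(rep(2, 200), names(cv))),
               "collinear")
})

test_that("permutation thresholds are reproducible and alpha=1 hits the minimum", {
  geno <- simulate_cross(small_config(n_mice = 100, seed = 20))
  set.seed(21)
  y <- trait_vector(rnorm(100), rownames(geno$codes))
  t1 <- genomewide_threshold(geno, y, n_perm = 120, alpha = 0.05, seed = 3)
  t2 <- genomewide_threshold(geno, y, n_perm = 120, alpha = 0.05, seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))
  tmin <- genomewide_threshold(geno, y, n_perm = 120, alpha = 1, seed = 3)
  expect_equal(as.numeric(tmin), min(attr(tmin, "perm_maxima")))
  expect_warning(genomewide_threshold(geno, y, n_perm = 50, seed = 3),
                 "unstable")
})

test_that("interval calling finds the planted two-locus architecture", {
  # below threshold -> nothing; single spike -> degenerate interval
  curve <- data.frame(marker_id = c("a", "b", "c"), chromosome = "1",
                      position_cM = c(0, 10, 20), lod = c(0.2, 2.8, 0.1))
  expect_equal(nrow(call_intervals(curve, threshold = 3)), 0)
  iv <- call_intervals(curve, threshold = 2.5, drop = 1.5)
  expect_equal(iv$start_cM, 10)
  expect_equal(iv$end_cM, 10)
  expect_equal(iv$peak_marker_id, "b")

  # recovery: strong direct two-locus trait, no hub mediation
  hits <- sapply(1:20, function(s) {
    cfg <- small_config(beta1 = 0.45, beta2 = 0.4, gamma_hub = 0, seed = 400 + s)
    geno <- simulate_cross(cfg)
    et <- simulate_expression_and_trait(geno, cfg)
    thr <- genomewide_threshold(geno, et$trait, n_perm = 150, alpha = 0.05,
                                seed = 400 + s)
    iv <- call_intervals(scan_trait(geno, et$trait), thr)
    # the true loci live at the markers nearest 70 / 30 cM
    pos <- geno$map$position_cM[match(et$truth$locus_markers,
                                      geno$map$marker_id)]
    nrow(iv) == 2 &&
      setequal(iv$chromosome, c("2", "19")) &&
      iv$start_cM[iv$chromosome == "2"] <= pos[1] &&
      iv$end_cM[iv$chromosome == "2"] >= pos[1] &&
      iv$start_cM[iv$chromosome == "19"] <= pos[2] &&
      iv$end_cM[iv$chromosome == "19"] >= pos[2]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("variance explained behaves at the R-squared extremes", {
  geno <- simulate_cross(small_config(n_mice = 250, seed = 23))
  mk <- c("c2_m028", "c19_m014")
  y_perfect <- trait_vector(as.numeric(geno$codes[, mk[1]]),
                            rownames(geno$codes))
  ve_perfect <- suppressWarnings(variance_explained(geno, y_perfect, mk[1]))
  expect_equal(unname(ve_perfect$per_marker), 1.0, tolerance = 1e-12)
  set.seed(24)
  nulls <- replicate(20, {
    y <- trait_vector(rnorm(250), rownames(geno$codes))
    unname(variance_explained(geno, y, mk[1])$per_marker)
  })
  expect_gte(mean(nulls < 0.05), 0.95)
  y <- trait_vector(rnorm(250), rownames(geno$codes))
  ve <- variance_explained(geno, y, mk)
  expect_gte(ve$joint, max(ve$per_marker))
})
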