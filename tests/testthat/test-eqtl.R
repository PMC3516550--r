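test_that("cis classification applies the 10 Mb window inclusively", {
  map <- genetic_map(c("mk1", "mk2", "mk3"), c("7", "7", "8"),
                     c(10, 30, 5), c(55e6, 60e6, 5e6))
  annot <- gene_annotation(c("gA", "gB", "gC"), c("7", "7", "7"),
                           c(50e6, 50e6, 50e6))
  calls <- data.frame(gene_id = c("gA", "gB", "gC"), tissue = "islet",
                      peak_marker_id = c("mk1", "mk3", "mk2"),
                      chromosome = c("7", "8", "7"),
                      position_cM = c(10, 5, 30), lod = 6,
                      stringsAsFactors = FALSE)
  out <- classify_cis(calls, annot, map)
  expect_identical(out$is_cis, c(TRUE, FALSE, TRUE))  # 5 Mb; other chr; 10 Mb boundary
})

test_that("trait-QTL overlap uses inclusive interval bounds and flags both-linked genes", {
  iv <- data.frame(chromosome = c("2", "19"), start_cM = c(59.5, 25),
                   end_cM = c(82.5, 35.38), peak_marker_id = c("p2", "p19"),
                   peak_lod = c(6.5, 5.4), threshold = 3.9,
                   stringsAsFactors = FALSE)
  calls <- data.frame(
    gene_id = c("in2", "out2", "edge2", "dual", "dual"),
    tissue = "islet",
    peak_marker_id = paste0("m", 1:5),
    chromosome = c("2", "2", "2", "2", "19"),
    position_cM = c(70, 50, 59.5, 65, 30), lod = 6,
    stringsAsFactors = FALSE)
  out <- overlap_with_trait_qtl(calls, iv)
  expect_identical(out$overlapped_locus,
                   c("locus1", "none", "locus1", "both", "both"))
  expect_identical(out$peak_in, c("locus1", "none", "locus1", "locus1", "locus2"))
})

test_that("planted cis-eQTLs are recovered at their own location", {
  hits <- unlist(lapply(1:5, function(s) {
    cfg <- small_config(eqtl_effect = 1, seed = 500 + s)
    st <- simulate_f2_study(cfg)
    calls <- suppressWarnings(
      scan_all_genes(st$genotypes, st$expression, lod_min = 5))
    calls <- classify_cis(calls, st$annotation, st$map)
    cis_genes <- st$truth$roles$gene_id[st$truth$roles$kind == "cis"]
    sapply(cis_genes, function(gn) {
      sub <- calls[calls$gene_id == gn, ]
      if (!nrow(sub)) return(FALSE)
      top <- sub[which.max(sub$lod), ]
      gi <- match(gn, st$annotation$gene_id)
      top$chromosome == st$annotation$chromosome[gi] && top$is_cis
    })
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("noise genes rarely clear the genome-wide threshold", {
  cfg <- small_config(seed = 510)
  st <- simulate_f2_study(cfg)
  thr <- genomewide_threshold(st$genotypes, st$trait, n_perm = 200,
                              alpha = 0.05, seed = 510)
  calls <- suppressWarnings(
    scan_all_genes(st$genotypes, st$expression, lod_min = as.numeric(thr)))
  noise <- st$truth$roles$gene_id[st$truth$roles$kind == "noise"]
  fp <- mean(noise %in% calls$gene_id)
  expect_lte(fp, 0.05)
})

test_that("genes driven by both loci yield two recorded peaks", {
  cfg <- small_config(eqtl_effect = 0.9, seed = 520)
  st <- simulate_f2_study(cfg)
  calls <- suppressWarnings(
    scan_all_genes(st$genotypes, st$expression, lod_min = 4))
  both <- st$truth$roles$gene_id[st$truth$roles$kind == "both"]
  two_peaks <- sapply(both, function(gn) {
    chr <- calls$chromosome[calls$gene_id == gn]
    all(c("2", "19") %in% chr)
  })
  expect_true(all(two_peaks))
})

test_that("joint-permutation FDR is calibrated on null and planted panels", {
  # null panel: observed counts should match the permutation expectation
  cfg <- small_config(eqtl_effect = 0, gamma_hub = 0, hub_effect1 = 0,
                      hub_effect2 = 0, reactive_effect = 0, seed = 530)
  st <- simulate_f2_study(cfg)
  iv <- data.frame(chromosome = c("2", "19"), start_cM = c(55, 20),
                   end_cM = c(85, 40), peak_marker_id = c("x", "y"),
                   peak_lod = c(9, 9), threshold = 1.5,
                   stringsAsFactors = FALSE)
  fdr0 <- count_fdr(st$genotypes, st$expression, iv, lod_min = 1.5,
                    n_perm = 8, seed = 531)
  expect_true(all(fdr0$observed > 0))
  ratio <- sum(fdr0$mean_null) / sum(fdr0$observed)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)

  # planted trans band: far fewer null than observed overlaps
  cfg1 <- small_config(eqtl_effect = 0.9, n_trans1_genes = 30, seed = 540)
  st1 <- simulate_f2_study(cfg1)
  fdr1 <- count_fdr(st1$genotypes, st1$expression, iv, lod_min = 4,
                    n_perm = 8, seed = 541)
  expect_lt(fdr1$fdr[fdr1$locus == "locus1"], 0.2)

  expect_error(count_fdr(st$genotypes, st$expression, iv, lod_min = 2,
                         n_perm = 0), "n_perm")
})
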