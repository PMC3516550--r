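test_that("min-max normalization hits its endpoints and closed form", {
  E <- expression_matrix(matrix(c(0, 1, 3,
                                  5, 5, 5,
                                  2, -1, 4), nrow = 3, byrow = TRUE,
                                dimnames = list(c("g1", "g2", "g3"),
                                                c("m1", "m2", "m3"))))
  N <- normalize_expression(E)
  expect_equal(unname(N["g1", ]), c(0, 1 / 3, 1))
  expect_identical(attr(N, "excluded_genes"), "g2")
  expect_true(all(is.na(N["g2", ])))
  expect_equal(unname(N["g3", ]), c(0.6, 0, 1))
})

test_that("interaction potential is the product of normalized levels", {
  N <- matrix(c(0, 1 / 3, 2 / 3, 1,
                0, 1 / 3, 2 / 3, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("gi", "gj"), paste0("m", 1:4)))
  ip <- interaction_potential(N, c("gi", "gj"))
  expect_equal(unname(ip), c(0, 1 / 9, 4 / 9, 1))
  # either partner at the panel minimum kills the interaction
  expect_equal(unname(ip)[1], 0)
  expect_equal(unname(ip)[4], 1)
  expect_equal(unname(interaction_potential(N, c("gi", "gj"), ip_form = "min")),
               c(0, 1 / 3, 2 / 3, 1))
})

test_that("TIPC matches a hand-computed Pearson oracle", {
  ip <- c(0.1, 0.4, 0.2, 0.9, 0.55, 0.3)
  tv <- c(2.5, 4.0, 1.0, 8.2, 5.1, 3.3)
  expect_equal(tipc(ip, tv), oracle_pearson(ip, tv), tolerance = 1e-12)
  expect_equal(tipc(ip, ip), 1.0)
  expect_equal(tipc(ip, -ip), -1.0)
  flat <- tipc(rep(0.5, 6), tv)
  expect_identical(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
})

test_that("the degree rule zeroes genes below five interactions", {
  ppi <- ppi_network(rep("h", 6), paste0("n", 1:6))
  x4 <- build_cross_network(ppi[1:4, ], "h", paste0("n", 1:4))
  expect_identical(tie_gene("h", x4, rep(0.95, 4)), 0)
  x5 <- build_cross_network(ppi[1:5, ], "h", paste0("n", 1:5))
  expect_equal(tie_gene("h", x5, c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)
})

test_that("TIE and p-values match a brute-force recomputation", {
  set.seed(91)
  genes <- sprintf("G%02d", 1:30)
  E <- random_expression(30, 40, seed = 91, prefix = "G")
  rownames(E) <- genes
  ppi <- suppressMessages(suppressWarnings(
    ppi_network(sample(genes, 120, TRUE), sample(genes, 120, TRUE))))
  g1 <- genes[1:18]
  g2 <- genes[13:30]
  nw <- build_cross_network(ppi, g1, g2)
  tv <- trait_vector(rnorm(40), colnames(E))
  fit <- tie_score(nw, E, tv, n_perm = 5, seed = 1)
  ref <- oracle_tie_scores(nw$edges, unclass(E)[names(nw$degree)[
    names(nw$degree) %in% rownames(E)], , drop = FALSE], as.numeric(tv))
  expect_equal(fit$edges$tipc, ref$tipcs, tolerance = 1e-10)
  ord <- fit$records$gene_id
  expect_equal(fit$records$tie, unname(ref$tie[ord]), tolerance = 1e-10)
  expect_equal(fit$records$n_interactions, unname(ref$degree[ord]))
})

test_that("TIE is invariant under affine expression and trait changes", {
  st <- simulate_f2_study(small_config(seed = 93))
  roles <- st$truth$roles
  nw <- build_cross_network(st$ppi,
                            roles$gene_id[roles$regulator %in% c("locus1", "both")],
                            roles$gene_id[roles$regulator %in% c("locus2", "both")])
  f1 <- tie_score(nw, st$expression, st$trait, n_perm = 3, seed = 5)
  E2 <- expression_matrix(2.5 * unclass(st$expression) + 7, tissue = "islet")
  t2 <- trait_vector(-3 * as.numeric(st$trait) + 1, names(st$trait))
  f2 <- tie_score(nw, E2, t2, n_perm = 3, seed = 5)
  expect_equal(f1$records$tie, f2$records$tie, tolerance = 1e-10)
  expect_identical(f1$records$gene_id, f2$records$gene_id)
})

test_that("permutation p-values honour the add-one convention and degree rule", {
  # strong planted signal: observed TIE should beat every permutation
  cfg <- small_config(seed = 95)
  st <- simulate_f2_study(cfg)
  roles <- st$truth$roles
  nw <- build_cross_network(st$ppi,
                            roles$gene_id[roles$regulator %in% c("locus1", "both")],
                            roles$gene_id[roles$regulator %in% c("locus2", "both")])
  fit <- tie_score(nw, st$expression, st$trait, n_perm = 50, seed = 6)
  hub <- st$truth$hub_gene_id
  rec <- fit$records[fit$records$gene_id == hub, ]
  expect_equal(rec$p_value, 1 / 51, tolerance = 1e-12)
  low <- fit$records[fit$records$n_interactions < 5, ]
  expect_true(all(low$tie == 0))
  expect_true(all(low$p_value == 1))
  expect_error(tie_score(nw, st$expression, st$trait, n_perm = 0), "n_perm")
})

test_that("ranking breaks ties by degree then gene id", {
  # all-zero TIE scores: order must fall back to degree, then lexicographic
  ppi <- ppi_network(c("b", "b", "a", "c"), c("x", "y", "x", "x"))
  nw <- build_cross_network(ppi, c("a", "b", "c"), c("x", "y"))
  E <- random_expression(5, 30, seed = 97)
  rownames(E) <- c("a", "b", "c", "x", "y")
  tv <- trait_vector(rnorm(30), colnames(E))
  rt <- rank_table(tie_score(nw, E, tv, n_perm = 2, seed = 1))
  expect_true(all(rt$tie == 0))          # every degree < 5
  expect_identical(rt$gene_id[1], "x")   # degree 3
  expect_identical(rt$gene_id[2], "b")   # degree 2
  expect_identical(rt$gene_id[3:5], c("a", "c", "y"))
})
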