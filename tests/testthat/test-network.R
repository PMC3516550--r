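test_that("only cross-group edges survive, with both-group membership honoured", {
  net <- suppressMessages(ppi_network(c("a", "a"), c("c", "b")))
  x <- build_cross_network(net, group1 = c("a", "b"), group2 = "c")
  expect_equal(nrow(x$edges), 1)
  expect_identical(paste(x$edges$from, x$edges$to), "a c")

  # y belongs to both groups; its edge to a plain group-1 gene qualifies
  net2 <- ppi_network(c("y", "a"), c("a", "b"))
  x2 <- build_cross_network(net2, group1 = c("a", "b", "y"), group2 = "y")
  expect_identical(paste(x2$edges$from, x2$edges$to), "a y")
  expect_identical(x2$both, "y")

  expect_warning(build_cross_network(net, "zz", "c"), "empty")
})

test_that("cross-network construction agrees with a brute-force filter", {
  skip_if_not_installed("igraph")
  set.seed(81)
  for (rep in 1:3) {
    genes <- sprintf("n%03d", 1:200)
    ppi <- suppressMessages(suppressWarnings(
      ppi_network(sample(genes, 600, TRUE), sample(genes, 600, TRUE))))
    g1 <- sample(genes, 60)
    g2 <- sample(genes, 50)
    x <- build_cross_network(ppi, g1, g2)
    ref <- oracle_cross_edges(ppi, intersect(g1, network_genes <- unique(c(ppi$from, ppi$to))),
                              intersect(g2, network_genes))
    expect_setequal(paste(x$edges$from, x$edges$to),
                    paste(ref$from, ref$to))
    expect_lte(nrow(x$edges), nrow(ppi))
    # degree cross-check through igraph
    if (nrow(x$edges)) {
      ig <- igraph::graph_from_data_frame(x$edges, directed = FALSE)
      d <- igraph::degree(ig)
      expect_identical(unname(x$degree[names(d)]), as.integer(d))
    }
  }
})

test_that("cross-group frequency reproduces the published count arithmetic", {
  fr <- cross_frequency(823, 225, 1349)
  expect_equal(round(fr$frequency_pct, 2), 0.73)
  fr2 <- cross_frequency(201, 42, 119)
  expect_equal(round(fr2$frequency_pct, 1), 1.4)
  expect_equal(cross_frequency(10, 10, 0)$frequency_pct, 0)
  expect_warning(fr3 <- cross_frequency(0, 10, 0), "undefined")
  expect_true(is.na(fr3$frequency_pct))
  fr4 <- cross_frequency(823, 225, 1349)
  expect_true(fr4$frequency_pct >= 0 && fr4$frequency_pct <= 100)
})

test_that("the planted hub's cross-degree equals its planted neighbor count", {
  cfg <- small_config(seed = 83)
  st <- simulate_f2_study(cfg)
  roles <- st$truth$roles
  g1 <- roles$gene_id[roles$regulator %in% c("locus1", "both")]
  g2 <- roles$gene_id[roles$regulator %in% c("locus2", "both")]
  x <- build_cross_network(st$ppi, g1, g2)
  planted <- nrow(st$truth$planted_edges)
  expect_gte(unname(x$degree[st$truth$hub_gene_id]), planted)
  # planted star edges alone: degree is exactly the planted count
  cfg0 <- small_config(background_edges = 0, seed = 83)
  st0 <- simulate_f2_study(cfg0)
  x0 <- build_cross_network(st0$ppi,
                            roles$gene_id[roles$regulator %in% c("locus1", "both")],
                            roles$gene_id[roles$regulator %in% c("locus2", "both")])
  expect_equal(unname(x0$degree[st0$truth$hub_gene_id]),
               nrow(st0$truth$planted_edges))
})

test_that("cytoscape export writes SIF plus coloured node attributes", {
  net <- ppi_network(c("a", "a", "y"), c("c", "y", "c"))
  x <- build_cross_network(net, group1 = c("a", "y"), group2 = c("c", "y"))
  sif <- withr::local_tempfile()
  att <- withr::local_tempfile()
  write_cross_network(x, sif, att)
  expect_true(any(grepl(" pp ", readLines(sif))))
  nodes <- utils::read.delim(att, comment.char = "#")
  expect_identical(nodes$color[nodes$gene_id == "y"], "yellow")
  expect_setequal(nodes$gene_id, c("a", "c", "y"))
})
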