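test_that("Haldane map function matches its closed form and bounds", {
  expect_identical(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  d <- seq(0, 500, by = 2.5)
  r <- haldane_r(d)
  expect_true(all(r < 0.5))
  expect_true(all(diff(r) > 0))
  expect_error(haldane_r(-1), ">= 0")
})

test_that("gamete simulation reproduces single and double recombination rates", {
  r <- haldane_r(1)
  g <- simulate_gametes(5000, c(0, 1, 2), seed = 21)
  rec1 <- mean(g[, 1] != g[, 2])
  rec2 <- mean(g[, 2] != g[, 3])
  band <- 3 * sqrt(r * (1 - r) / 5000)
  expect_lt(abs(rec1 - r), band)
  expect_lt(abs(rec2 - r), band)
  # double recombinants occur at ~ r^2: expected 0.49 of 5000, so a handful
  doubles <- sum(g[, 1] != g[, 2] & g[, 2] != g[, 3])
  expect_lte(doubles, 5)
  expect_identical(g, simulate_gametes(5000, c(0, 1, 2), seed = 21))
})

test_that("F2 genotype frequencies follow the 1:2:1 law", {
  set.seed(5)
  g <- simulate_gametes(2 * 2000, 25)[, 1]
  codes <- g[1:2000] + g[2001:4000]
  obs <- table(factor(codes, levels = 0:2))
  chisq <- sum((obs - 2000 * c(.25, .5, .25))^2 / (2000 * c(.25, .5, .25)))
  expect_lt(chisq, qchisq(0.99, df = 2))

  # marginal frequencies across a multi-chromosome panel
  geno2 <- simulate_cross(small_config(n_mice = 2000, seed = 6))
  for (j in seq(1, ncol(geno2$codes), by = 10)) {
    fr <- mean(geno2$codes[, j] == 1)
    expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 2000))
  }
})

test_that("the whole generation is a pure function of config and seed", {
  cfg <- small_config(seed = 33)
  s1 <- simulate_f2_study(cfg)
  s2 <- simulate_f2_study(cfg)
  expect_identical(s1$genotypes$codes, s2$genotypes$codes)
  expect_identical(unclass(s1$expression), unclass(s2$expression))
  expect_identical(as.numeric(s1$trait), as.numeric(s2$trait))
  expect_identical(as.data.frame(s1$ppi), as.data.frame(s2$ppi))
})

test_that("hub expression correlates with the trait in the designed band", {
  rs <- sapply(1:20, function(sd) {
    st <- simulate_expression_and_trait(
      simulate_cross(small_config(seed = 100 + sd)),
      small_config(seed = 100 + sd))
    cor(unclass(st$expression)[st$truth$hub_gene_id, ],
        as.numeric(st$trait))
  })
  expect_gte(mean(rs > -0.75 & rs < -0.45), 0.9)
  expect_gt(mean(rs), -0.66)
  expect_lt(mean(rs), -0.54)
})

test_that("a null configuration produces no expression-trait correlation", {
  cfg <- small_config(gamma_hub = 0, hub_effect1 = 0, hub_effect2 = 0,
                      eqtl_effect = 0, reactive_effect = 0, seed = 77)
  st <- simulate_expression_and_trait(simulate_cross(cfg), cfg)
  rs <- apply(unclass(st$expression), 1, cor, y = as.numeric(st$trait))
  expect_lt(max(abs(rs)), 4 / sqrt(cfg$n_mice))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("realized variance fractions track the requested architecture", {
  fr <- sapply(1:10, function(s) {
    cfg <- small_config(n_mice = 2000, seed = 300 + s)
    simulate_expression_and_trait(simulate_cross(cfg), cfg)$truth$variance_fractions
  })
  m <- rowMeans(fr)
  expect_lt(abs(m["locus1"] - 0.10), 0.05)
  expect_lt(abs(m["locus2"] - 0.08), 0.05)
  expect_true(all(colSums(fr[1:3, ]) <= 1))
})

test_that("planted networks honour the hub-degree and background contracts", {
  cfg <- small_config(seed = 9)
  st <- simulate_f2_study(cfg)
  deg_hub <- sum(st$ppi$from == st$truth$hub_gene_id |
                   st$ppi$to == st$truth$hub_gene_id)
  expect_gte(deg_hub, 2 * cfg$hub_neighbors_per_group)
  expect_false(any(st$ppi$from == st$ppi$to))
  expect_false(anyDuplicated(paste(st$ppi$from, st$ppi$to)) > 0)

  cfg0 <- small_config(background_edges = 0, seed = 9)
  st0 <- simulate_f2_study(cfg0)
  expect_equal(nrow(st0$ppi), 2 * cfg0$hub_neighbors_per_group)
  expect_true(all(st0$ppi$from == st0$truth$hub_gene_id |
                    st0$ppi$to == st0$truth$hub_gene_id))

  expect_error(plant_network(st$truth, small_config(background_edges = 1e9)),
               "exceeds")
})
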