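triplet <- function(n, model, seed, eqtl = 1, med = 0.7) {
  set.seed(seed)
  x <- sample(0:2, n, TRUE, prob = c(.25, .5, .25))
  z <- (x - 1) / sqrt(0.5)
  if (model == "causal") {
    G <- eqtl * z + rnorm(n); T_ <- med * G + rnorm(n)
  } else if (model == "reactive") {
    T_ <- eqtl * z + rnorm(n); G <- med * T_ + rnorm(n)
  } else {
    G <- eqtl * z + rnorm(n); T_ <- eqtl * z + rnorm(n)
  }
  list(x = x, G = G, T_ = T_)
}

test_that("each generating topology is recovered by the BIC test", {
  acc <- experiment_causality_accuracy(n_reps = 40, n = 250, seed = 51)
  expect_gte(acc[["causal"]], 0.85)
  expect_gte(acc[["reactive"]], 0.85)
  expect_gte(acc[["independent"]], 0.80)
})

test_that("labels are invariant under affine rescaling of gene and trait", {
  for (model in c("causal", "reactive", "independent")) {
    tr <- triplet(200, model, seed = 52)
    a <- classify_triplet(tr$x, tr$G, tr$T_)
    b <- classify_triplet(tr$x, 4.2 * tr$G - 3, -0.5 * tr$T_ + 8)
    expect_identical(a$label, b$label)
    expect_equal(a$margin, b$margin, tolerance = 1e-6)
  }
})

test_that("swapping gene and trait maps causal calls to reactive ones", {
  map_swap <- c(causal = "reactive", reactive = "causal",
                independent = "independent")
  for (s in 1:10) {
    tr <- triplet(250, sample(c("causal", "reactive", "independent"), 1),
                  seed = 60 + s)
    a <- classify_triplet(tr$x, tr$G, tr$T_)
    b <- classify_triplet(tr$x, tr$T_, tr$G)
    expect_identical(b$label, unname(map_swap[a$label]))
  }
})

test_that("classification sharpens with sample size", {
  accs <- sapply(c(100, 500), function(n) {
    mean(experiment_causality_accuracy(n_reps = 60, n = n, seed = 9,
                                       eqtl_effect = 0.5, mediation = 0.4))
  })
  expect_gte(accs[2], accs[1])
  expect_gte(accs[2], 0.9)
})

test_that("degenerate triplets are rejected with clear errors", {
  tr <- triplet(100, "causal", seed = 70)
  expect_error(classify_triplet(rep(1L, 100), tr$G, tr$T_), "monomorphic")
  expect_error(classify_triplet(tr$x, rep(0, 100), tr$T_), "zero-variance gene")
  expect_error(classify_triplet(tr$x, tr$G, rep(2, 100)), "zero-variance trait")
  expect_error(classify_triplet(tr$x[1:10], tr$G[1:10], tr$T_[1:10]),
               "complete triplet")
})

test_that("the causal/reactive filter keeps mediators and drops independents", {
  # trivial label fixtures
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      locus = c("locus1", "locus1", "locus1", "locus2"),
                      label = c("causal", "reactive", "independent", "causal"),
                      stringsAsFactors = FALSE)
  sets <- filter_causal_reactive(calls)
  expect_identical(sets$locus1, c("a", "b"))
  expect_identical(sets$locus2, "d")
  all_ind <- within(calls, label <- "independent")
  expect_identical(unname(lengths(filter_causal_reactive(all_ind))), c(0L, 0L))

  # recovery: 50 mediators (half causal, half reactive) + 50 independents
  for (s in 1:3) {
    labs <- data.frame(gene_id = sprintf("g%03d", 1:100), locus = "locus1",
                       label = NA_character_, stringsAsFactors = FALSE)
    truth_med <- rep(c(TRUE, FALSE), each = 50)
    for (i in 1:100) {
      model <- if (truth_med[i]) c("causal", "reactive")[1 + i %% 2] else "independent"
      tr <- triplet(250, model, seed = 7000 + 100 * s + i)
      labs$label[i] <- classify_triplet(tr$x, tr$G, tr$T_)$label
    }
    kept <- filter_causal_reactive(labs)$locus1
    recall <- mean(labs$gene_id[truth_med] %in% kept)
    precision <- mean(kept %in% labs$gene_id[truth_med])
    expect_gte(recall, 0.8)
    expect_gte(precision, 0.8)
  }
})
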