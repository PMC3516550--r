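# Synthetic F2 intercross generator. Emulates the study design the package
# targets: a two-locus architecture for a clinical trait (plasma-insulin
# analogue), cis/trans eQTL structure including genes linked to both trait
# loci, a planted hub gene that negatively regulates the trait through both
# loci, reactive (trait-driven) genes, and a planted PPI graph. A truth
# record accompanies every simulated panel so recovery can be measured.

#' Default chromosome layout for the simulated cross
#'
#' Nineteen autosomes with mouse-like genetic lengths and roughly 1.4
#' markers per cM, giving ~2,000 informative markers genome-wide.
#'
#' @return data.frame with columns `name`, `length_cM`, `n_markers`.
#' @export
default_chromosomes <- function() {
  len <- c(98, 103, 82, 88, 90, 79, 89, 76, 75, 77,
           80, 73, 67, 66, 59, 57, 61, 59, 55)
  data.frame(name = as.character(seq_along(len)), length_cM = len,
             n_markers = pmax(20L, round(len * 1.4)),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cross
#'
#' Defaults emulate the study conditions: 250 F2 mice, ~2,000 markers over
#' 19 autosomes, trait loci on chromosomes 2 (70 cM) and 19 (30 cM), a hub
#' gene regulated by both loci whose standardized effect on the trait is
#' `gamma_hub = -0.6`, and no direct locus-to-trait effects (the loci act
#' on the trait entirely through the hub). The hub's locus effects default
#' to `sqrt(0.10)/|gamma_hub|` and `sqrt(0.08)/|gamma_hub|` so the two
#' mediated trait QTLs explain ~10% and ~8% of trait variance.
#'
#' All effect sizes are standardized (genotypes are coded 0/1/2 and scaled
#' to unit variance; every simulated variable has variance ~1), so an
#' effect of e contributes ~e^2 of the downstream variable's variance.
#' Noise standard deviations are derived so each gene and the trait are
#' standardized; `trait_noise_sd = NULL` means "whatever brings the trait
#' variance to 1" and is an error if the systematic part already exceeds 1.
#'
#' @param n_mice number of F2 animals.
#' @param chromosomes data.frame as [default_chromosomes()].
#' @param locus1,locus2 trait-QTL positions, `list(chromosome=, position_cM=)`;
#'   must lie on distinct chromosomes.
#' @param n_cis_genes,n_trans1_genes,n_trans2_genes,n_both_genes gene counts
#'   per regulatory class (cis anywhere; trans driven by locus 1, locus 2,
#'   or both).
#' @param n_reactive_genes genes driven by the trait (downstream).
#' @param n_noise_genes unregulated genes.
#' @param hub_neighbors_per_group planted PPI neighbors of the hub inside
#'   each locus group.
#' @param beta1,beta2 direct locus-to-trait standardized effects.
#' @param gamma_hub hub-expression-to-trait standardized effect (negative
#'   by default: the hub suppresses the trait).
#' @param hub_effect1,hub_effect2 locus-to-hub-expression standardized
#'   effects (positive: BTBR alleles raise hub expression).
#' @param eqtl_effect locus-to-expression standardized effect for non-hub
#'   regulated genes.
#' @param reactive_effect trait-to-expression effect for reactive genes.
#' @param trait_noise_sd trait residual SD, or NULL to standardize.
#' @param background_edges random PPI edges among non-hub gene pairs.
#' @param reactive_hub if TRUE the hub is generated downstream of the trait
#'   instead of upstream (for testing causal/reactive discrimination).
#' @param seed master seed; the whole generation is a pure function of the
#'   configuration including this seed.
#' @return A `cross_config` list.
#' @export
cross_config <- function(n_mice = 250,
                         chromosomes = default_chromosomes(),
                         locus1 = list(chromosome = "2", position_cM = 70),
                         locus2 = list(chromosome = "19", position_cM = 30),
                         n_cis_genes = 60, n_trans1_genes = 60,
                         n_trans2_genes = 40, n_both_genes = 20,
                         n_reactive_genes = 30, n_noise_genes = 100,
                         hub_neighbors_per_group = 10,
                         beta1 = 0, beta2 = 0, gamma_hub = -0.6,
                         hub_effect1 = sqrt(0.10) / 0.6,
                         hub_effect2 = sqrt(0.08) / 0.6,
                         eqtl_effect = 0.5, reactive_effect = 0.5,
                         trait_noise_sd = NULL,
                         background_edges = 400,
                         reactive_hub = FALSE,
                         seed = 1) {
  cfg <- list(n_mice = n_mice, chromosomes = chromosomes,
              locus1 = locus1, locus2 = locus2,
              n_cis_genes = n_cis_genes, n_trans1_genes = n_trans1_genes,
              n_trans2_genes = n_trans2_genes, n_both_genes = n_both_genes,
              n_reactive_genes = n_reactive_genes, n_noise_genes = n_noise_genes,
              hub_neighbors_per_group = hub_neighbors_per_group,
              beta1 = beta1, beta2 = beta2, gamma_hub = gamma_hub,
              hub_effect1 = hub_effect1, hub_effect2 = hub_effect2,
              eqtl_effect = eqtl_effect, reactive_effect = reactive_effect,
              trait_noise_sd = trait_noise_sd,
              background_edges = background_edges,
              reactive_hub = reactive_hub, seed = seed)
  class(cfg) <- "cross_config"
  validate_cross_config(cfg)
}

validate_cross_config <- function(cfg) {
  ch <- cfg$chromosomes
  if (!all(c("name", "length_cM", "n_markers") %in% names(ch))) {
    stop2("chromosomes need columns name, length_cM, n_markers")
  }
  if (any(ch$length_cM <= 0) || any(ch$n_markers < 1)) {
    stop2("chromosome lengths must be > 0 and marker counts >= 1")
  }
  for (loc in list(cfg$locus1, cfg$locus2)) {
    i <- match(as.character(loc$chromosome), ch$name)
    if (is.na(i)) stop2("trait locus on unknown chromosome ", loc$chromosome)
    if (loc$position_cM < 0 || loc$position_cM > ch$length_cM[i]) {
      stop2("trait locus outside its chromosome")
    }
  }
  if (identical(as.character(cfg$locus1$chromosome),
                as.character(cfg$locus2$chromosome))) {
    stop2("the two trait loci must lie on distinct chromosomes")
  }
  counts <- c(cfg$n_cis_genes, cfg$n_trans1_genes, cfg$n_trans2_genes,
              cfg$n_both_genes, cfg$n_reactive_genes, cfg$n_noise_genes,
              cfg$hub_neighbors_per_group, cfg$background_edges)
  if (any(counts < 0)) stop2("all counts must be >= 0")
  if (cfg$n_mice < 2) stop2("need at least 2 mice")
  if (abs(cfg$eqtl_effect) > 1 || abs(cfg$reactive_effect) > 1) {
    stop2("standardized expression effects must lie in [-1, 1]")
  }
  if (cfg$hub_effect1^2 + cfg$hub_effect2^2 > 1) {
    stop2("hub locus effects imply hub expression variance > 1")
  }
  cfg
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under no interference: r = (1 - exp(-2d))/2 with d in Morgans.
#'
#' @param distance_cM nonnegative genetic distance(s) in cM.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(distance_cM) {
  if (any(distance_cM < 0)) stop2("distance must be >= 0")
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Simulate gametes along one chromosome
#'
#' Each gamete is a Markov chain over markers: the first allele is drawn
#' fair, and the allele switches between adjacent markers with the Haldane
#' recombination fraction of their cM distance.
#'
#' @param n_gametes number of gametes.
#' @param positions_cM marker positions (nondecreasing).
#' @param seed optional seed.
#' @return 0/1 allele matrix, gametes x markers.
#' @export
simulate_gametes <- function(n_gametes, positions_cM, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(positions_cM)
  r <- haldane_r(diff(positions_cM))
  out <- matrix(0L, nrow = n_gametes, ncol = m)
  out[, 1] <- stats::rbinom(n_gametes, 1, 0.5)
  if (m > 1) {
    for (j in 2:m) {
      flip <- stats::rbinom(n_gametes, 1, r[j - 1])
      out[, j] <- (out[, j - 1] + flip) %% 2L
    }
  }
  out
}

#' Simulate the F2 genotype panel
#'
#' Each mouse is the union of two independently simulated gametes per
#' chromosome; genotype = sum of the two gamete alleles (0/1/2 with 2 =
#' BTBR/BTBR). Markers are spaced evenly in cM; physical positions assume
#' ~2 Mb per cM.
#'
#' @param config a [cross_config()].
#' @return a [genotype_matrix()] (its `$map` element is the genetic map).
#' @export
simulate_cross <- function(config) {
  config <- validate_cross_config(config)
  set.seed(config$seed)
  ch <- config$chromosomes
  n <- config$n_mice
  mice <- sprintf("M%04d", seq_len(n))
  maps <- list()
  blocks <- list()
  for (i in seq_len(nrow(ch))) {
    m <- ch$n_markers[i]
    pos <- if (m == 1) ch$length_cM[i] / 2 else seq(0, ch$length_cM[i], length.out = m)
    ids <- sprintf("c%s_m%03d", ch$name[i], seq_len(m))
    maps[[i]] <- data.frame(marker_id = ids, chromosome = ch$name[i],
                            position_cM = pos,
                            position_bp = round(pos * 2e6) + 1,
                            stringsAsFactors = FALSE)
    g <- simulate_gametes(2L * n, pos)
    codes <- g[seq_len(n), , drop = FALSE] + g[n + seq_len(n), , drop = FALSE]
    colnames(codes) <- ids
    blocks[[i]] <- codes
  }
  codes <- do.call(cbind, blocks)
  rownames(codes) <- mice
  genotype_matrix(codes, do.call(rbind, maps))
}

locus_marker_index <- function(map, locus) {
  on_chr <- which(map$chromosome == as.character(locus$chromosome))
  if (!length(on_chr)) stop2("no markers on locus chromosome ", locus$chromosome)
  on_chr[which.min(abs(map$position_cM[on_chr] - locus$position_cM))]
}

std_geno <- function(x) (x - 1) / sqrt(0.5)

#' Simulate expression traits and the clinical trait
#'
#' Builds a genes x mice expression panel on top of a simulated genotype
#' panel: cis genes sit at their own marker and respond to it; trans genes
#' respond to trait locus 1, locus 2, or both; one hub gene responds to
#' both loci (BTBR alleles raise its expression) and drives the trait with
#' standardized effect `gamma_hub`; reactive genes respond to the realized
#' trait; noise genes are pure noise. The trait is
#' `T = beta1 z1 + beta2 z2 + gamma_hub E_hub + noise`, standardized.
#' Non-cis genes are placed on chromosomes other than the two trait-locus
#' chromosomes so their linkage is genuinely trans.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_cross()].
#' @param config the same [cross_config()].
#' @return list with elements `expression` ([expression_matrix()]),
#'   `annotation` ([gene_annotation()]), `trait` ([trait_vector()]) and
#'   `truth` (a `synth_truth` list: `hub_gene_id`, per-gene `roles`,
#'   realized `variance_fractions`, locus marker ids).
#' @export
simulate_expression_and_trait <- function(genotypes, config) {
  config <- validate_cross_config(config)
  set.seed(config$seed + 1L)
  map <- genotypes$map
  codes <- genotypes$codes
  n <- nrow(codes)
  i1 <- locus_marker_index(map, config$locus1)
  i2 <- locus_marker_index(map, config$locus2)
  z1 <- std_geno(codes[, i1])
  z2 <- std_geno(codes[, i2])

  n_hub <- 1L
  counts <- c(hub = n_hub, trans1 = config$n_trans1_genes,
              trans2 = config$n_trans2_genes, both = config$n_both_genes,
              cis = config$n_cis_genes, reactive = config$n_reactive_genes,
              noise = config$n_noise_genes)
  total <- sum(counts)
  gene_id <- sprintf("g%04d", seq_len(total))
  regulator <- rep(c("both", "locus1", "locus2", "both", "cis", "none", "none"),
                   counts)
  causal_role <- rep(c("causal", "independent", "independent", "independent",
                       "independent", "reactive", "independent"), counts)
  kind <- rep(names(counts), counts)
  hub_id <- gene_id[kind == "hub"]

  qtl_chrs <- c(as.character(config$locus1$chromosome),
                as.character(config$locus2$chromosome))
  away <- which(!(map$chromosome %in% qtl_chrs))
  if (!length(away)) stop2("no chromosomes available to place trans genes")
  n_cis <- config$n_cis_genes
  if (n_cis > nrow(map)) stop2("more cis genes requested than placeable markers")
  placement <- integer(total)
  placement[kind == "cis"] <- sample(nrow(map), n_cis)
  placement[kind != "cis"] <- sample(away, total - n_cis, replace = TRUE)

  ef <- config$eqtl_effect
  sd_e <- sqrt(max(0, 1 - ef^2))
  h1 <- config$hub_effect1
  h2 <- config$hub_effect2
  E <- matrix(NA_real_, nrow = total, ncol = n,
              dimnames = list(gene_id, rownames(codes)))
  for (i in which(kind == "trans1")) E[i, ] <- ef * z1 + sd_e * stats::rnorm(n)
  for (i in which(kind == "trans2")) E[i, ] <- ef * z2 + sd_e * stats::rnorm(n)
  for (i in which(kind == "both")) {
    E[i, ] <- ef / sqrt(2) * (z1 + z2) + sd_e * stats::rnorm(n)
  }
  for (i in which(kind == "cis")) {
    zl <- std_geno(codes[, placement[i]])
    E[i, ] <- ef * zl + sd_e * stats::rnorm(n)
  }
  hub_idx <- which(kind == "hub")
  sd_hub <- sqrt(max(0, 1 - h1^2 - h2^2))
  e_hub <- h1 * z1 + h2 * z2 + sd_hub * stats::rnorm(n)

  gamma <- config$gamma_hub
  if (config$reactive_hub) {
    # trait first (direct locus effects only), hub downstream of the trait
    var_sys <- config$beta1^2 + config$beta2^2
    sd_t <- config$trait_noise_sd %||% sqrt(max(0, 1 - var_sys))
    tr <- config$beta1 * z1 + config$beta2 * z2 + sd_t * stats::rnorm(n)
    E[hub_idx, ] <- gamma * tr + sqrt(max(0, 1 - gamma^2)) * stats::rnorm(n)
    causal_role[hub_idx] <- "reactive"
  } else {
    E[hub_idx, ] <- e_hub
    var_sys <- config$beta1^2 + config$beta2^2 + gamma^2 +
      2 * gamma * (config$beta1 * h1 + config$beta2 * h2)
    if (is.null(config$trait_noise_sd) && var_sys > 1) {
      stop2("systematic trait variance exceeds 1; give an explicit trait_noise_sd")
    }
    sd_t <- config$trait_noise_sd %||% sqrt(max(0, 1 - var_sys))
    tr <- config$beta1 * z1 + config$beta2 * z2 + gamma * e_hub +
      sd_t * stats::rnorm(n)
  }
  re <- config$reactive_effect
  for (i in which(kind == "reactive")) {
    E[i, ] <- re * tr + sqrt(max(0, 1 - re^2)) * stats::rnorm(n)
  }
  for (i in which(kind == "noise")) E[i, ] <- stats::rnorm(n)

  # realized variance decomposition (sequential, so fractions sum to <= 1)
  an <- stats::anova(stats::lm(tr ~ z1 + z2 + E[hub_idx, ]))
  fr <- an[["Sum Sq"]] / sum(an[["Sum Sq"]])
  variance_fractions <- c(locus1 = fr[1], locus2 = fr[2],
                          hub = fr[3], residual = fr[4])

  annotation <- gene_annotation(gene_id, map$chromosome[placement],
                                map$position_bp[placement])
  truth <- structure(list(
    hub_gene_id = hub_id,
    roles = data.frame(gene_id = gene_id, kind = kind, regulator = regulator,
                       causal_role = causal_role, stringsAsFactors = FALSE),
    variance_fractions = variance_fractions,
    locus_markers = c(map$marker_id[i1], map$marker_id[i2]),
    planted_edges = NULL
  ), class = "synth_truth")

  list(expression = expression_matrix(E, tissue = "islet"),
       annotation = annotation,
       trait = trait_vector(tr, mouse_id = rownames(codes),
                            trait_name = "plasma_insulin"),
       truth = truth)
}

#' Plant the PPI network around the hub
#'
#' Connects the hub to `hub_neighbors_per_group` genes in each locus group
#' (so its degree is at least twice that), then adds `background_edges`
#' edges sampled uniformly over non-hub gene pairs without duplicates or
#' self-loops.
#'
#' @param truth the `synth_truth` record from
#'   [simulate_expression_and_trait()].
#' @param config the same [cross_config()].
#' @return a [ppi_network()] with a `source` tag per edge
#'   (`planted_hub` / `background`).
#' @export
plant_network <- function(truth, config) {
  config <- validate_cross_config(config)
  set.seed(config$seed + 2L)
  roles <- truth$roles
  hub <- truth$hub_gene_id
  g1 <- setdiff(roles$gene_id[roles$regulator %in% c("locus1", "both")], hub)
  g2 <- setdiff(roles$gene_id[roles$regulator %in% c("locus2", "both")], hub)
  k <- config$hub_neighbors_per_group
  if (length(g1) < k || length(g2) < k) {
    stop2("not enough group genes to give the hub ", k, " neighbors per group")
  }
  # prefer single-locus genes so both-linked genes stay available for group 2
  g1_only <- setdiff(g1, g2)
  nb1 <- if (length(g1_only) >= k) sample(g1_only, k) else {
    c(g1_only, sample(setdiff(g1, g1_only), k - length(g1_only)))
  }
  pool2 <- setdiff(g2, nb1)
  if (length(pool2) < k) stop2("not enough distinct group-2 genes for hub neighbors")
  nb2 <- sample(pool2, k)
  hub_from <- rep(hub, length(nb1) + length(nb2))
  hub_to <- c(nb1, nb2)

  others <- setdiff(roles$gene_id, hub)
  m <- length(others)
  n_pairs <- m * (m - 1) / 2
  if (config$background_edges > n_pairs) {
    stop2("background_edges exceeds the number of available non-hub pairs")
  }
  if (n_pairs <= 2e6) {
    pairs <- utils::combn(m, 2)
    picked <- sample(ncol(pairs), config$background_edges)
    i <- pairs[1, picked]
    j <- pairs[2, picked]
  } else {
    # rejection sampling for very large gene sets
    i <- integer(0)
    j <- integer(0)
    while (length(i) < config$background_edges) {
      a <- sample.int(m, config$background_edges)
      b <- sample.int(m, config$background_edges)
      ok <- a < b
      key <- paste0(a[ok], "_", b[ok])
      keep <- !duplicated(c(paste0(i, "_", j), key))[-seq_along(i)]
      i <- c(i, a[ok][keep])
      j <- c(j, b[ok][keep])
    }
    i <- i[seq_len(config$background_edges)]
    j <- j[seq_len(config$background_edges)]
  }
  net <- ppi_network(c(hub_from, others[i]), c(hub_to, others[j]),
                     source = c(rep("planted_hub", length(hub_from)),
                                rep("background", length(picked))))
  attr(net, "planted_hub_edges") <- data.frame(from = hub_from, to = hub_to,
                                               stringsAsFactors = FALSE)
  net
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_cross()], [simulate_expression_and_trait()] and
#' [plant_network()] under one master seed and bundles the results.
#'
#' @param config a [cross_config()].
#' @return list of class `f2_study` with elements `genotypes`, `map`,
#'   `expression`, `annotation`, `trait`, `ppi`, `truth`, `config`.
#' @export
simulate_f2_study <- function(config = cross_config()) {
  genotypes <- simulate_cross(config)
  et <- simulate_expression_and_trait(genotypes, config)
  ppi <- plant_network(et$truth, config)
  truth <- et$truth
  truth$planted_edges <- attr(ppi, "planted_hub_edges")
  structure(list(genotypes = genotypes, map = genotypes$map,
                 expression = et$expression, annotation = et$annotation,
                 trait = et$trait, ppi = ppi, truth = truth, config = config),
            class = "f2_study")
}

#' @export
print.f2_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic F2 study: %d mice, %d markers, %d genes, ",
                     "%d PPI edges (hub: %s)\n"),
              nrow(x$genotypes$codes), ncol(x$genotypes$codes),
              nrow(x$expression), nrow(x$ppi), x$truth$hub_gene_id))
  invisible(x)
}
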