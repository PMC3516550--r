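# Shared fixture builders. Everything is generated in code at test time;
# the small map keeps module tests fast while the acceptance suite uses
# the full default configuration.

small_chromosomes <- function() {
  data.frame(name = c("2", "19", "5"), length_cM = c(100, 55, 80),
             n_markers = c(40L, 25L, 30L), stringsAsFactors = FALSE)
}

small_config <- function(...) {
  defaults <- list(chromosomes = small_chromosomes(), n_cis_genes = 10,
                   n_trans1_genes = 12, n_trans2_genes = 8, n_both_genes = 4,
                   n_reactive_genes = 6, n_noise_genes = 10,
                   background_edges = 40)
  do.call(cross_config, utils::modifyList(defaults, list(...)))
}

# hand-built genotype panel: n mice x given marker codes (list of columns)
manual_geno <- function(cols, chromosome = "1") {
  codes <- do.call(cbind, cols)
  colnames(codes) <- names(cols)
  rownames(codes) <- sprintf("m%02d", seq_len(nrow(codes)))
  map <- genetic_map(names(cols), rep(chromosome, length(cols)),
                     seq(0, by = 10, length.out = length(cols)),
                     seq(1e6, by = 1e7, length.out = length(cols)))
  genotype_matrix(codes, map, max_missing = 1)
}

random_expression <- function(n_genes, n_mice, seed = 1, prefix = "g") {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_genes * n_mice), nrow = n_genes,
           dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                           sprintf("m%03d", seq_len(n_mice)))),
    tissue = "islet")
}
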