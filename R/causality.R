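# Causal / reactive / independent classification of (locus, gene, trait)
# triplets. Because the clinical trait sits in a physiological feedback
# loop, genes whose expression overlaps a trait locus can relate to the
# trait in three ways:
#   causal      L -> G -> T    (gene mediates the locus effect)
#   reactive    L -> T -> G    (gene responds to the trait)
#   independent L -> G, L -> T (shared locus, no mediation; a residual
#                               correlation parameter absorbs pleiotropy)
# Each topology is fitted as a Gaussian graphical model by maximum
# likelihood and scored by BIC; the minimum-BIC model wins. Only causal and
# reactive genes survive the filter into network construction.

gauss_ll <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

rss_group <- function(y, g) sum((y - stats::ave(y, g))^2)

rss_linear <- function(y, x) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  sum(yc^2) - if (sxx > 0) sum(xc * yc)^2 / sxx else 0
}

#' Classify one locus-gene-trait triplet
#'
#' Fits the causal (`L->G->T`), reactive (`L->T->G`) and independent
#' (`L->G`, `L->T` plus residual correlation) models by maximum likelihood,
#' with the locus as a 3-level genotype factor, and returns the
#' minimum-BIC label. A BIC tie (margin below 1e-9) is resolved
#' conservatively to "independent". Labels are invariant under affine
#' rescaling of gene expression and trait.
#'
#' @param locus_genotypes per-mouse genotype codes (0/1/2) at the locus
#'   peak marker.
#' @param gene_expr per-mouse expression of the candidate gene.
#' @param trait per-mouse clinical trait values.
#' @param min_n minimum complete triplet observations.
#' @param gene_id,locus optional labels carried into the result.
#' @return A `causal_call`: list with `gene_id`, `locus`, `scores` (BIC per
#'   model), `label`, `margin` (runner-up BIC minus best, >= 0).
#' @export
classify_triplet <- function(locus_genotypes, gene_expr, trait, min_n = 30,
                             gene_id = NA_character_, locus = NA_character_) {
  if (!is.null(names(locus_genotypes)) && !is.null(names(gene_expr)) &&
      !is.null(names(trait))) {
    mice <- Reduce(intersect, list(names(locus_genotypes), names(gene_expr),
                                   names(trait)))
    locus_genotypes <- locus_genotypes[mice]
    gene_expr <- gene_expr[mice]
    trait <- trait[mice]
  }
  g <- as.integer(locus_genotypes)
  G <- as.numeric(gene_expr)
  T_ <- as.numeric(trait)
  ok <- !is.na(g) & is.finite(G) & is.finite(T_)
  n <- sum(ok)
  if (n < min_n) stop2("fewer than ", min_n, " complete triplet observations")
  g <- factor(g[ok])
  G <- G[ok]
  T_ <- T_[ok]
  if (nlevels(g) <= 1) stop2("monomorphic locus")
  if (stats::sd(G) == 0) stop2("zero-variance gene expression")
  if (stats::sd(T_) == 0) stop2("zero-variance trait")

  k_grp <- nlevels(g) + 1   # class means + residual variance
  ll_G_L <- gauss_ll(rss_group(G, g), n)
  ll_T_L <- gauss_ll(rss_group(T_, g), n)
  ll_T_G <- gauss_ll(rss_linear(T_, G), n)
  ll_G_T <- gauss_ll(rss_linear(G, T_), n)
  res_G <- G - stats::ave(G, g)
  res_T <- T_ - stats::ave(T_, g)
  r <- if (stats::sd(res_G) > 0 && stats::sd(res_T) > 0) {
    stats::cor(res_G, res_T)
  } else 0
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)

  ll <- c(causal = ll_G_L + ll_T_G,
          reactive = ll_T_L + ll_G_T,
          independent = ll_G_L + ll_T_L - n / 2 * log(1 - r^2))
  k <- c(causal = k_grp + 3, reactive = k_grp + 3,
         independent = 2 * k_grp + 1)
  scores <- -2 * ll + k * log(n)
  ord <- order(scores)
  margin <- scores[ord[2]] - scores[ord[1]]
  label <- if (margin < 1e-9) "independent" else names(scores)[ord[1]]
  structure(list(gene_id = gene_id, locus = locus, scores = scores,
                 label = label, margin = as.numeric(margin)),
            class = "causal_call")
}

#' @export
print.causal_call <- function(x, ...) {
  cat(sprintf("causal_call: %s (margin %.2f)\n", x$label, x$margin))
  print(round(x$scores, 2))
  invisible(x)
}

#' Classify all overlapping eQTL genes
#'
#' Runs [classify_triplet()] for every eQTL call whose peak lies inside a
#' trait QTL interval (column `peak_in` from [overlap_with_trait_qtl()]),
#' using that call's peak marker as the locus.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()].
#' @param trait a [trait_vector()].
#' @param calls `eqtl_calls` with the `peak_in` column.
#' @param min_n minimum complete triplets; genes with fewer are skipped
#'   with a warning.
#' @return data.frame: `gene_id`, `locus`, `label`, `margin`.
#' @export
classify_eqtl_genes <- function(genotypes, expression, trait, calls,
                                min_n = 30) {
  if (!"peak_in" %in% names(calls)) {
    stop2("calls need the 'peak_in' column from overlap_with_trait_qtl()")
  }
  sel <- calls[calls$peak_in != "none", , drop = FALSE]
  mice <- Reduce(intersect, list(rownames(genotypes$codes),
                                 colnames(expression), names(trait)))
  rows <- vector("list", nrow(sel))
  skipped <- 0L
  for (i in seq_len(nrow(sel))) {
    gmk <- genotypes$codes[mice, sel$peak_marker_id[i]]
    ex <- unclass(expression)[sel$gene_id[i], mice]
    res <- tryCatch(
      classify_triplet(gmk, ex, as.numeric(trait[mice]), min_n = min_n,
                       gene_id = sel$gene_id[i], locus = sel$peak_in[i]),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(gene_id = res$gene_id, locus = res$locus,
                            label = res$label, margin = res$margin,
                            stringsAsFactors = FALSE)
  }
  if (skipped) warn2(skipped, " triplet(s) skipped (degenerate or too few mice)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), locus = character(),
                      label = character(), margin = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter gene lists to causal-or-reactive genes
#'
#' Genes classified "independent" are removed; the survivors are returned
#' as one gene-id set per locus, ready for cross-network construction.
#'
#' @param calls data.frame with columns `gene_id`, `locus`, `label`
#'   (from [classify_eqtl_genes()] or assembled by hand).
#' @return named list of sorted gene-id vectors, one per locus present.
#' @export
filter_causal_reactive <- function(calls) {
  keep <- calls$label %in% c("causal", "reactive")
  loci <- sort(unique(calls$locus))
  out <- lapply(loci, function(lc) {
    sort(unique(calls$gene_id[keep & calls$locus == lc]))
  })
  names(out) <- loci
  out
}
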