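# Trait-Interaction-Expression (TIE) scoring.
#
# For two interacting genes i, j and mouse m, the Interaction Potential is
#   IP_{ij,m} = E~_{i,m} * E~_{j,m}
# where E~ is the gene's expression min-max normalized across the panel,
# so IP is in [0, 1] and proportional to the relative abundance of both
# partners (mass-action view of association rates: if either partner is at
# its panel minimum the interaction cannot form, IP = 0). The
# Trait-Interaction-Potential Correlation (TIPC) of an edge is the Pearson
# correlation across mice between its IP profile and the clinical trait.
# A gene's TIE score is the mean |TIPC| over its edges in the cross-group
# network, zeroed below 5 interactions; significance comes from permuting
# every gene's expression across mice independently and recomputing all
# TIE scores. The product form of IP and the mean-|TIPC| form of TIE are
# declared modelling choices (see the package vignette); `ip_form` and
# `tipc_exponent` expose the alternatives.

#' Min-max normalize an expression panel
#'
#' Per gene, `(E - min) / (max - min)` across the mice of the panel, so
#' every gene spans `[0, 1]` with 1 at its panel maximum. Genes constant
#' across the panel (or entirely missing) cannot be normalized; they are
#' returned as all-NA rows and listed in the `excluded_genes` attribute.
#'
#' @param expression an [expression_matrix()] or plain genes x mice matrix.
#' @return numeric matrix of the same shape with values in `[0, 1]` (NA
#'   preserved) and attribute `excluded_genes`.
#' @export
normalize_expression <- function(expression) {
  E <- unclass(expression)
  lo <- suppressWarnings(apply(E, 1, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(E, 1, max, na.rm = TRUE))
  span <- hi - lo
  bad <- !is.finite(span) | span == 0
  N <- (E - lo) / ifelse(bad, 1, span)
  N[bad, ] <- NA_real_
  attr(N, "excluded_genes") <- rownames(E)[bad]
  attr(N, "tissue") <- NULL
  class(N) <- "matrix"
  N
}

#' Interaction potential of one edge
#'
#' @param normalized output of [normalize_expression()].
#' @param edge character vector of two gene ids.
#' @param ip_form combination rule: `"product"` (default, mass-action),
#'   `"min"` (limiting partner), or `"geomean"`.
#' @return per-mouse IP vector in `[0, 1]` (NA where either gene is
#'   missing).
#' @export
interaction_potential <- function(normalized, edge,
                                  ip_form = c("product", "min", "geomean")) {
  ip_form <- match.arg(ip_form)
  if (length(edge) != 2) stop2("an edge is a pair of gene ids")
  idx <- match(edge, rownames(normalized))
  if (anyNA(idx)) stop2("edge gene(s) missing from the normalized panel: ",
                        paste(edge[is.na(idx)], collapse = ", "))
  ip_combine(normalized[idx[1], ], normalized[idx[2], ], ip_form)
}

ip_combine <- function(a, b, ip_form) {
  switch(ip_form,
         product = a * b,
         min = pmin(a, b),
         geomean = sqrt(a * b))
}

# IP profiles for all edges at once: edges x mice matrix. Edges whose
# endpoint is absent from the normalized panel get an all-NA profile.
ip_matrix <- function(normalized, from, to, ip_form) {
  ii <- match(from, rownames(normalized))
  jj <- match(to, rownames(normalized))
  n <- ncol(normalized)
  A <- matrix(NA_real_, nrow = length(from), ncol = n)
  ok <- !is.na(ii) & !is.na(jj)
  if (any(ok)) {
    A[ok, ] <- ip_combine(normalized[ii[ok], , drop = FALSE],
                          normalized[jj[ok], , drop = FALSE], ip_form)
  }
  colnames(A) <- colnames(normalized)
  A
}

#' Trait-Interaction-Potential Correlation of one edge
#'
#' Pearson correlation across mice between an edge's IP profile and the
#' trait, over pairwise-complete observations. Degenerate profiles (fewer
#' than 3 complete pairs, or constant IP or trait on the complete set)
#' yield 0 with attribute `degenerate = TRUE` rather than dropping the
#' edge, so node degrees stay stable.
#'
#' @param edge_ip per-mouse IP vector (see [interaction_potential()]).
#' @param trait a [trait_vector()] or named numeric aligned to the same
#'   mice.
#' @return TIPC in `[-1, 1]`.
#' @export
tipc <- function(edge_ip, trait) {
  if (!is.null(names(edge_ip)) && !is.null(names(trait))) {
    mice <- intersect(names(edge_ip), names(trait))
    edge_ip <- edge_ip[mice]
    trait <- trait[mice]
  }
  r <- pearson_or_na(as.numeric(edge_ip), as.numeric(trait))
  if (is.na(r)) structure(0, degenerate = TRUE) else r
}

# Vectorised row-wise Pearson correlation of an edges x mice matrix with a
# trait vector; degenerate rows give 0.
row_pearson <- function(IP, tv) {
  ok_t <- is.finite(tv)
  M <- is.finite(IP)
  M[, !ok_t] <- FALSE
  IP0 <- ifelse(M, IP, 0)
  tvm <- ifelse(ok_t, tv, 0)
  n <- rowSums(M)
  Sx <- rowSums(IP0)
  Sy <- as.vector(M %*% tvm)
  Sxx <- rowSums(IP0^2)
  Syy <- as.vector(M %*% tvm^2)
  Sxy <- as.vector(IP0 %*% tvm)
  vx <- n * Sxx - Sx^2
  vy <- n * Syy - Sy^2
  r <- (n * Sxy - Sx * Sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  r[!is.finite(r) | n < 3 | vx <= 0 | vy <= 0] <- 0
  pmin(pmax(r, -1), 1)
}

# Per-gene TIE from per-edge TIPCs: mean |TIPC|^exponent over incident
# edges, zero below min_degree. `degree` is the full cross-network degree.
tie_from_tipc <- function(tipcs, from, to, degree, min_degree, exponent) {
  w <- abs(tipcs)^exponent
  tie <- stats::setNames(numeric(length(degree)), names(degree))
  if (length(w)) {
    s <- rowsum(c(w, w), group = c(from, to))
    tie[rownames(s)] <- s[, 1] / degree[rownames(s)]
  }
  tie[degree < min_degree] <- 0
  tie
}

#' TIE score of one gene
#'
#' Convenience scorer for a single node: mean `|TIPC|^exponent` over the
#' gene's edges in the cross network, or exactly 0 when its degree is
#' below `min_degree`.
#'
#' @param gene gene id.
#' @param network a `cross_network` from [build_cross_network()].
#' @param edge_tipcs numeric vector of TIPCs aligned to `network$edges`
#'   rows.
#' @param min_degree interaction threshold below which TIE is zeroed.
#' @param exponent power applied to |TIPC|.
#' @return TIE score (>= 0).
#' @export
tie_gene <- function(gene, network, edge_tipcs, min_degree = 5, exponent = 1) {
  deg <- network$degree[gene]
  if (is.na(deg)) stop2("gene '", gene, "' is not in the cross network")
  if (deg < min_degree) return(0)
  inc <- network$edges$from == gene | network$edges$to == gene
  mean(abs(edge_tipcs[inc])^exponent)
}

#' Fit TIE scores with permutation significance
#'
#' The central scorer: computes per-edge Interaction Potential profiles
#' and TIPCs on the cross-group network, aggregates them into per-gene TIE
#' scores (zero below `min_degree` interactions), and attaches empirical
#' p-values from `n_perm` permutations in which every gene's expression is
#' shuffled across mice independently (destroying gene-gene and gene-trait
#' structure while preserving each gene's marginal distribution):
#'   p(gene) = (1 + #\{perm TIE >= observed TIE\}) / (n_perm + 1).
#' Genes below the degree threshold receive p = 1.
#'
#' @param network a `cross_network` from [build_cross_network()].
#' @param expression an [expression_matrix()] covering the network genes.
#' @param trait a [trait_vector()].
#' @param min_degree minimum interactions for a non-zero TIE (default 5).
#' @param n_perm number of expression permutations.
#' @param ip_form,tipc_exponent see [interaction_potential()] and
#'   [tie_gene()].
#' @param seed optional seed for the permutation stream.
#' @return A `tie_score` object: list with `records` (ranked data.frame:
#'   `gene_id`, `n_interactions`, `tie`, `p_value`, `expr_trait_corr`),
#'   `edges` (with per-edge `tipc` and `n_complete`), `params`, `n_mice`,
#'   `excluded_genes`.
#' @seealso [rank_table()], [plot.tie_score()]
#' @export
tie_score <- function(network, expression, trait, min_degree = 5,
                      n_perm = 1000, ip_form = c("product", "min", "geomean"),
                      tipc_exponent = 1, seed = NULL) {
  stopifnot(inherits(network, "cross_network"))
  ip_form <- match.arg(ip_form)
  if (n_perm < 1) stop2("n_perm must be >= 1")
  mice <- intersect(colnames(expression), names(trait))
  if (length(mice) < 3) stop2("fewer than 3 mice shared between expression and trait")
  genes <- names(network$degree)
  E <- unclass(expression)[intersect(rownames(expression), genes), mice,
                           drop = FALSE]
  N <- normalize_expression(E)
  tv <- as.numeric(trait[mice])
  from <- network$edges$from
  to <- network$edges$to
  deg <- network$degree

  IP <- ip_matrix(N, from, to, ip_form)
  tipc_obs <- row_pearson(IP, tv)
  n_complete <- rowSums(is.finite(IP) & rep(is.finite(tv), each = nrow(IP)))
  tie_obs <- tie_from_tipc(tipc_obs, from, to, deg, min_degree, tipc_exponent)

  if (!is.null(seed)) set.seed(seed)
  exceed <- stats::setNames(numeric(length(deg)), names(deg))
  for (b in seq_len(if (nrow(N) && nrow(network$edges)) n_perm else 0)) {
    Np <- t(apply(N, 1, sample))
    rownames(Np) <- rownames(N)
    tie_p <- tie_from_tipc(row_pearson(ip_matrix(Np, from, to, ip_form), tv),
                           from, to, deg, min_degree, tipc_exponent)
    exceed <- exceed + (tie_p >= tie_obs - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[deg < min_degree] <- 1

  corr <- rep(NA_real_, length(genes))
  names(corr) <- genes
  have <- intersect(genes, rownames(E))
  corr[have] <- vapply(have, function(gn) pearson_or_na(E[gn, ], tv),
                       numeric(1))
  records <- data.frame(gene_id = genes,
                        n_interactions = as.integer(deg[genes]),
                        tie = as.numeric(tie_obs[genes]),
                        p_value = as.numeric(p[genes]),
                        expr_trait_corr = as.numeric(corr[genes]),
                        stringsAsFactors = FALSE)
  records <- records[order(-records$tie, -records$n_interactions,
                           records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  edges <- data.frame(from = from, to = to, tipc = tipc_obs,
                      n_complete = as.integer(n_complete),
                      stringsAsFactors = FALSE)
  structure(list(records = records, edges = edges,
                 params = list(min_degree = min_degree, n_perm = n_perm,
                               ip_form = ip_form,
                               tipc_exponent = tipc_exponent),
                 n_mice = length(mice),
                 excluded_genes = attr(N, "excluded_genes")),
            class = "tie_score")
}

#' Ranked TIE table
#'
#' Genes sorted by TIE descending, ties broken by interaction count
#' descending then gene id; the five columns mirror the standard report:
#' gene, number of interactions, TIE score, permutation p-value, and the
#' gene's expression-trait correlation.
#'
#' @param fit a `tie_score` object.
#' @return data.frame of the ranked records.
#' @export
rank_table <- function(fit) {
  stopifnot(inherits(fit, "tie_score"))
  fit$records
}

#' @export
print.tie_score <- function(x, ...) {
  cat(sprintf(paste0("TIE scoring: %d genes, %d cross edges, %d mice ",
                     "(min degree %d, %d permutations, IP = %s)\n"),
              nrow(x$records), nrow(x$edges), x$n_mice,
              x$params$min_degree, x$params$n_perm, x$params$ip_form))
  scored <- sum(x$records$tie > 0)
  cat(sprintf("genes with non-zero TIE: %d\n", scored))
  print(utils::head(x$records, 5), row.names = TRUE)
  invisible(x)
}

#' @export
summary.tie_score <- function(object, alpha = 0.05, ...) {
  r <- object$records
  cat("TIE score summary\n")
  cat(sprintf("  genes: %d   cross edges: %d   mice: %d\n",
              nrow(r), nrow(object$edges), object$n_mice))
  cat(sprintf("  scored (degree >= %d): %d   significant (p <= %.2g): %d\n",
              object$params$min_degree, sum(r$n_interactions >=
                                              object$params$min_degree),
              alpha, sum(r$p_value <= alpha)))
  if (length(object$excluded_genes)) {
    cat(sprintf("  constant genes excluded from scoring: %d\n",
                length(object$excluded_genes)))
  }
  cat("  top genes:\n")
  print(utils::head(r, 10), row.names = TRUE)
  invisible(object)
}

#' Plot TIE scores against degree
#'
#' Scatter of each gene's TIE score against its number of cross-network
#' interactions; genes significant at `alpha` are filled.
#'
#' @param x a `tie_score` object.
#' @param alpha significance highlight level.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tie_score <- function(x, alpha = 0.05, ...) {
  r <- x$records
  sig <- r$p_value <= alpha
  graphics::plot(r$n_interactions, r$tie,
                 pch = ifelse(sig, 19, 1),
                 col = ifelse(sig, "firebrick", "grey40"),
                 xlab = "# interactions (cross network)",
                 ylab = "TIE score", ...)
  graphics::abline(v = x$params$min_degree - 0.5, lty = 3)
  if (any(sig)) {
    graphics::text(r$n_interactions[sig], r$tie[sig], r$gene_id[sig],
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}
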