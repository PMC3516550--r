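# Cross-group PPI network: the subgraph of the interactome keeping only
# edges that join a gene linked to trait locus 1 with a gene linked to
# trait locus 2. Genes linked to both loci belong to both groups, so an
# edge between two such genes also qualifies as a cross-group edge.

#' Build the cross-group interaction network
#'
#' Restricts the two locus gene groups to genes present in the PPI, then
#' keeps an edge (i, j) iff one endpoint is in group 1 and the other in
#' group 2 (membership in both groups satisfies either side). Within-group
#' edges are discarded.
#'
#' @param ppi a [ppi_network()].
#' @param group1,group2 character vectors of gene ids linked to locus 1
#'   resp. locus 2 (genes linked to both loci should appear in both).
#' @return A `cross_network`: list with `group1`, `group2`, `both`
#'   (PPI-present members; `both` is the intersection), `edges`
#'   (data.frame `from`/`to`), and `degree` (named, over all group
#'   members, zero included).
#' @export
build_cross_network <- function(ppi, group1, group2) {
  stopifnot(inherits(ppi, "ppi_network"))
  present <- network_genes(ppi)
  g1 <- intersect(unique(as.character(group1)), present)
  g2 <- intersect(unique(as.character(group2)), present)
  if (!length(g1) || !length(g2)) {
    warn2("a restricted group is empty; cross network has no edges")
  }
  f1 <- ppi$from %in% g1
  f2 <- ppi$from %in% g2
  t1 <- ppi$to %in% g1
  t2 <- ppi$to %in% g2
  keep <- (f1 & t2) | (f2 & t1)
  edges <- data.frame(from = ppi$from[keep], to = ppi$to[keep],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  members <- sort(union(g1, g2))
  deg <- integer(length(members))
  names(deg) <- members
  tab <- table(c(edges$from, edges$to))
  deg[names(tab)] <- as.integer(tab)
  structure(list(group1 = sort(g1), group2 = sort(g2),
                 both = sort(intersect(g1, g2)),
                 edges = edges, degree = deg),
            class = "cross_network")
}

#' @export
print.cross_network <- function(x, ...) {
  fr <- cross_frequency(x)
  cat(sprintf(paste0("cross-group network: %d x %d genes (%d in both), ",
                     "%d cross edges (%.2f%%)\n"),
              fr$n_group1, fr$n_group2, length(x$both), fr$n_edges,
              fr$frequency_pct))
  invisible(x)
}

#' Cross-group interaction frequency
#'
#' The number of observed cross-group edges as a percentage of all possible
#' cross-group pairs, `100 * n_edges / (|group1| * |group2|)`. The
#' denominator deliberately counts genes linked to both loci in both
#' groups. Undefined (NA, with a warning) when either group is empty.
#'
#' @param x a `cross_network`, or the group-1 size when calling with raw
#'   counts.
#' @param n_group2,n_edges group-2 size and edge count (raw-count form).
#' @return list: `n_edges`, `n_group1`, `n_group2`, `frequency_pct`.
#' @examples
#' cross_frequency(823, 225, 1349)$frequency_pct  # 0.728...
#' @export
cross_frequency <- function(x, n_group2 = NULL, n_edges = NULL) {
  if (inherits(x, "cross_network")) {
    n1 <- length(x$group1)
    n2 <- length(x$group2)
    ne <- nrow(x$edges)
  } else {
    n1 <- as.numeric(x)
    n2 <- as.numeric(n_group2)
    ne <- as.numeric(n_edges)
  }
  freq <- if (n1 == 0 || n2 == 0) {
    warn2("empty group: cross-group frequency undefined")
    NA_real_
  } else {
    100 * ne / (n1 * n2)
  }
  list(n_edges = ne, n_group1 = n1, n_group2 = n2, frequency_pct = freq)
}

#' Export a cross network for Cytoscape
#'
#' Writes the subgraph as SIF (`gene1 pp gene2`) plus a node-attribute TSV
#' with each gene's group and display colour (group 1 green, group 2 red,
#' both yellow).
#'
#' @param network a `cross_network`.
#' @param sif_path,attr_path output paths.
#' @return the SIF path, invisibly.
#' @export
write_cross_network <- function(network, sif_path, attr_path) {
  stopifnot(inherits(network, "cross_network"))
  writeLines(c(FORMAT_TAG,
               sprintf("%s pp %s", network$edges$from, network$edges$to)),
             sif_path)
  members <- names(network$degree)
  grp <- ifelse(members %in% network$both, "both",
                ifelse(members %in% network$group1, "group1", "group2"))
  col <- c(group1 = "green", group2 = "red", both = "yellow")[grp]
  write_body(data.frame(gene_id = members, group = grp, color = unname(col),
                        degree = as.integer(network$degree),
                        stringsAsFactors = FALSE),
             attr_path)
  invisible(sif_path)
}
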