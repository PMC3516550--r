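# Domain containers. Deliberately light S3 wrappers around base structures
# (data.frames, matrices, named vectors) so downstream code can use ordinary
# subsetting; constructors do all validation up front and never coerce
# silently.

#' Genetic map
#'
#' One row per marker with its chromosome, genetic position (centimorgans)
#' and physical position (base pairs, 1-based point coordinates). Rows are
#' stored sorted by chromosome (order of first appearance) and cM position;
#' the bp order must agree with the cM order within each chromosome.
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome chromosome label per marker.
#' @param position_cM genetic position in centimorgans (>= 0).
#' @param position_bp physical position in base pairs (>= 0).
#' @return A `genetic_map` data.frame.
#' @export
genetic_map <- function(marker_id, chromosome, position_cM, position_bp) {
  df <- data.frame(
    marker_id = as.character(marker_id),
    chromosome = as.character(chromosome),
    position_cM = as.numeric(position_cM),
    position_bp = as.numeric(position_bp),
    stringsAsFactors = FALSE
  )
  validate_genetic_map(df)
}

validate_genetic_map <- function(df) {
  need <- c("marker_id", "chromosome", "position_cM", "position_bp")
  if (!all(need %in% names(df))) {
    stop2("genetic map needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$marker_id <- as.character(df$marker_id)
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$marker_id)) {
    stop2("duplicate marker ids in map: ",
          paste(utils::head(unique(df$marker_id[duplicated(df$marker_id)]), 3),
                collapse = ", "))
  }
  if (any(!is.finite(df$position_cM)) || any(df$position_cM < 0)) {
    stop2("cM positions must be finite and >= 0")
  }
  if (any(!is.finite(df$position_bp)) || any(df$position_bp < 0)) {
    stop2("bp positions must be finite and >= 0")
  }
  chr_order <- unique(df$chromosome)
  df <- df[order(match(df$chromosome, chr_order), df$position_cM), , drop = FALSE]
  for (chr in chr_order) {
    bp <- df$position_bp[df$chromosome == chr]
    if (is.unsorted(bp)) stop2("bp and cM orders disagree on chromosome ", chr)
  }
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' F2 genotype matrix
#'
#' Genotype codes for an F2 panel: mice in rows, markers in columns, values
#' in \{0, 1, 2, NA\} with 0 = B6/B6 homozygote, 1 = heterozygote,
#' 2 = BTBR/BTBR homozygote. Columns are reordered to match the map.
#'
#' @param codes integer matrix (mice x markers) with mouse ids as rownames
#'   and marker ids as colnames.
#' @param map a [genetic_map()] covering exactly the markers in `codes`.
#' @param max_missing maximum tolerated per-marker missingness fraction.
#' @return A `genotype_matrix` object (list with elements `codes`, `map`).
#' @export
genotype_matrix <- function(codes, map, max_missing = 0.2) {
  map <- validate_genetic_map(map)
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) stop2("genotype matrix needs mouse ids as rownames")
  if (is.null(colnames(codes))) stop2("genotype matrix needs marker ids as colnames")
  missing_from_map <- setdiff(colnames(codes), map$marker_id)
  if (length(missing_from_map)) {
    stop2("marker(s) absent from map: ",
          paste(utils::head(missing_from_map, 3), collapse = ", "))
  }
  if (!setequal(colnames(codes), map$marker_id)) {
    stop2("dimension mismatch: map has markers not present in the genotype matrix")
  }
  codes <- codes[, map$marker_id, drop = FALSE]
  suppressWarnings(storage.mode(codes) <- "integer")
  bad <- !is.na(codes) & !(codes %in% c(0L, 1L, 2L))
  if (any(bad)) stop2("invalid genotype code: ", first_bad_cell(bad, codes))
  miss <- colMeans(is.na(codes))
  if (any(miss > max_missing)) {
    worst <- which.max(miss)
    stop2(sprintf("marker '%s' exceeds missingness cap (%.2f > %.2f)",
                  colnames(codes)[worst], miss[worst], max_missing))
  }
  structure(list(codes = codes, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("F2 genotype matrix: %d mice x %d markers on %d chromosomes\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chromosome))))
  invisible(x)
}

#' Expression matrix
#'
#' Genes x mice matrix of expression values on a log-ratio scale, tagged
#' with the tissue of origin. Values must be finite or NA.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), mice
#'   in columns (colnames = mouse ids).
#' @param tissue tissue label.
#' @return An `expression_matrix` (a matrix with a `tissue` attribute).
#' @export
expression_matrix <- function(values, tissue = "unspecified") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop2("expression matrix needs gene ids as rownames")
  if (is.null(colnames(values))) stop2("expression matrix needs mouse ids as colnames")
  if (!is.numeric(values)) stop2("expression values must be numeric")
  if (any(!is.finite(values) & !is.na(values))) {
    stop2("expression values must be finite or NA")
  }
  if (anyDuplicated(rownames(values))) stop2("duplicate gene ids in expression matrix")
  attr(values, "tissue") <- as.character(tissue)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix [%s]: %d genes x %d mice\n",
              attr(x, "tissue"), nrow(x), ncol(x)))
  invisible(x)
}

#' Clinical trait vector
#'
#' @param values numeric trait values (e.g. plasma insulin in ng/ml), one
#'   per mouse; at least 3 non-missing values are required.
#' @param mouse_id mouse ids (defaults to `names(values)`).
#' @param trait_name trait label.
#' @return A named numeric vector of class `trait_vector`.
#' @export
trait_vector <- function(values, mouse_id = names(values), trait_name = "trait") {
  force(mouse_id)
  values <- as.numeric(values)
  if (is.null(mouse_id)) stop2("trait vector needs mouse ids")
  if (length(mouse_id) != length(values)) stop2("trait length does not match mouse id list")
  if (anyDuplicated(mouse_id)) stop2("duplicate mouse ids in trait vector")
  if (sum(is.finite(values)) < 3) stop2("trait needs >= 3 non-missing values")
  names(values) <- as.character(mouse_id)
  attr(values, "trait_name") <- as.character(trait_name)
  class(values) <- "trait_vector"
  values
}

#' @export
print.trait_vector <- function(x, ...) {
  cat(sprintf("trait '%s': %d mice (%d missing)\n", attr(x, "trait_name"),
              length(x), sum(!is.finite(unclass(x)))))
  invisible(x)
}

#' Protein-protein interaction network
#'
#' Undirected edge list over gene ids. Self-loops are dropped with a
#' warning; duplicate unordered pairs are collapsed (a message reports the
#' count). Edges are stored in canonical order (`from` < `to`).
#'
#' @param from,to character vectors of gene ids (edge endpoints).
#' @param source optional per-edge source tag.
#' @return A `ppi_network` data.frame with columns `from`, `to` (and
#'   optionally `source`).
#' @export
ppi_network <- function(from, to, source = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop2("edge endpoint vectors differ in length")
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(source)) df$source <- as.character(source)
  loops <- df$from == df$to
  if (any(loops)) {
    warn2(sum(loops), " self-loop edge(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  a <- pmin(df$from, df$to)
  b <- pmax(df$from, df$to)
  df$from <- a
  df$to <- b
  dup <- duplicated(paste0(df$from, "\r", df$to))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ppi_network", "data.frame")
  df
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d edges over %d genes\n",
              nrow(x), length(unique(c(x$from, x$to)))))
  invisible(x)
}

network_genes <- function(net) unique(c(net$from, net$to))

#' Gene annotation table
#'
#' @param gene_id unique gene ids.
#' @param chromosome chromosome label per gene.
#' @param position_bp genomic position in base pairs (>= 0).
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, chromosome, position_bp) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    position_bp = as.numeric(position_bp),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) stop2("duplicate gene ids in annotation")
  if (any(!is.finite(df$position_bp)) || any(df$position_bp < 0)) {
    stop2("gene bp positions must be finite and >= 0")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}
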