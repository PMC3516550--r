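# Readers and writers for the tab-delimited text formats the pipeline
# touches. All writers emit a "#fileformat=tiescore-v1" header line plus
# optional "#key=value" metadata lines; readers skip any leading "#" lines.
# Missing values are encoded by the literal token "NA" everywhere.

FORMAT_TAG <- "#fileformat=tiescore-v1"

write_body <- function(df, path, meta = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(FORMAT_TAG, con)
  if (length(meta)) writeLines(paste0("#", names(meta), "=", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_body <- function(path, as_character = FALSE) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  first_body <- which(!is_meta)[1]
  if (is.na(first_body)) stop2("no data rows in ", path)
  meta_lines <- lines[is_meta & seq_along(lines) < first_body]
  body <- lines[!is_meta]
  meta <- list()
  kv <- regmatches(meta_lines, regexec("^#([A-Za-z_][A-Za-z0-9_]*)=(.*)$", meta_lines))
  for (m in kv) if (length(m) == 3) meta[[m[2]]] <- m[3]
  if (!length(body)) stop2("no data rows in ", path)
  df <- utils::read.delim(
    text = paste(body, collapse = "\n"), sep = "\t",
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = if (as_character) "character" else NA,
    na.strings = if (as_character) character() else "NA"
  )
  attr(df, "meta") <- meta
  df
}

#' Write / read a genetic map
#'
#' @param map a [genetic_map()].
#' @param path file path (tab-delimited text).
#' @return `read_map()` returns a `genetic_map`; writers return the path
#'   invisibly.
#' @export
write_map <- function(map, path) {
  write_body(as.data.frame(unclass(map)), path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  validate_genetic_map(read_body(path))
}

#' Write / read F2 genotypes
#'
#' The genotype file holds mice as rows and markers as columns (first column
#' `mouse_id`); the map file holds the four [genetic_map()] columns. Codes
#' other than those named in `code_map` (or the missing-value token "NA")
#' are a hard error that names the offending cell.
#'
#' @param geno a [genotype_matrix()].
#' @param path genotype file path.
#' @param map_path map file path.
#' @param code_map named integer vector mapping file tokens to the internal
#'   codes 0 (B6/B6), 1 (het), 2 (BTBR/BTBR); override to relabel on read.
#' @param max_missing per-marker missingness cap, passed to
#'   [genotype_matrix()].
#' @return `read_genotypes()` returns a `genotype_matrix`.
#' @export
write_genotypes <- function(geno, path, map_path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(mouse_id = rownames(geno$codes), geno$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_body(df, path)
  write_map(geno$map, map_path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map_path,
                           code_map = c("0" = 0L, "1" = 1L, "2" = 2L),
                           max_missing = 0.2) {
  map <- read_map(map_path)
  df <- read_body(path, as_character = TRUE)
  if (names(df)[1] != "mouse_id") stop2("genotype file must start with a 'mouse_id' column")
  mice <- df$mouse_id
  raw <- as.matrix(df[, -1, drop = FALSE])
  rownames(raw) <- mice
  known <- raw %in% c(names(code_map), "NA") | is.na(raw)
  if (!all(known)) {
    bad <- matrix(!known, nrow = nrow(raw), dimnames = dimnames(raw))
    stop2("unknown genotype code: ", first_bad_cell(bad, raw))
  }
  codes <- matrix(code_map[raw], nrow = nrow(raw), dimnames = dimnames(raw))
  genotype_matrix(codes, map, max_missing = max_missing)
}

#' Write / read an expression matrix
#'
#' Genes as rows (first column `gene_id`), mice as columns. A non-numeric
#' cell that is not the "NA" token is an error naming its location.
#'
#' @param expr an [expression_matrix()].
#' @param path file path.
#' @return `read_expression()` returns an `expression_matrix`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_body(df, path, meta = c(tissue = attr(expr, "tissue")))
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_body(path, as_character = TRUE)
  if (names(df)[1] != "gene_id") stop2("expression file must start with a 'gene_id' column")
  genes <- df$gene_id
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(vals) & !(raw == "NA" | is.na(raw))
  if (any(bad)) {
    dimnames(bad) <- list(genes, colnames(raw))
    rownames(raw) <- genes
    stop2("non-numeric expression cell: ", first_bad_cell(bad, raw))
  }
  dimnames(vals) <- list(genes, colnames(raw))
  tissue <- attr(df, "meta")$tissue %||% "unspecified"
  expression_matrix(vals, tissue = tissue)
}

#' Write / read a clinical trait vector
#'
#' Two-column file (`mouse_id`, `value`); the trait name travels in a
#' `#trait_name=` metadata line.
#'
#' @param trait a [trait_vector()].
#' @param path file path.
#' @return `read_trait()` returns a `trait_vector`.
#' @export
write_trait <- function(trait, path) {
  stopifnot(inherits(trait, "trait_vector"))
  df <- data.frame(mouse_id = names(trait), value = as.numeric(trait),
                   stringsAsFactors = FALSE)
  write_body(df, path, meta = c(trait_name = attr(trait, "trait_name")))
}

#' @rdname write_trait
#' @export
read_trait <- function(path) {
  df <- read_body(path)
  if (!all(c("mouse_id", "value") %in% names(df))) {
    stop2("trait file needs columns 'mouse_id' and 'value'")
  }
  trait_vector(df$value, mouse_id = df$mouse_id,
               trait_name = attr(df, "meta")$trait_name %||% "trait")
}

#' Write / read a protein-protein interaction edge list
#'
#' `read_edges()` accepts either the package's two/three-column TSV
#' (`from`, `to`, optional `source`) or the SIF dialect, where each line is
#' `A <relation> B [C D ...]` and expands to edges A-B, A-C, ... Duplicate
#' unordered pairs are collapsed and self-loops dropped (see
#' [ppi_network()]).
#'
#' @param net a [ppi_network()].
#' @param path file path.
#' @return `read_edges()` returns a `ppi_network`.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  write_body(as.data.frame(unclass(net)), path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop2("no edges in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  has_header <- identical(toks[[1]][1:2], c("from", "to"))
  if (has_header) {
    header <- toks[[1]]
    toks <- toks[-1]
    from <- vapply(toks, `[`, "", 1)
    to <- vapply(toks, `[`, "", 2)
    src <- if (length(header) >= 3 && header[3] == "source") {
      vapply(toks, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    }
    return(ppi_network(from, to, source = src))
  }
  from <- character()
  to <- character()
  for (tk in toks) {
    if (length(tk) == 2) {
      from <- c(from, tk[1]); to <- c(to, tk[2])
    } else if (length(tk) >= 3) {
      # SIF: source, relation, one or more targets
      from <- c(from, rep(tk[1], length(tk) - 2))
      to <- c(to, tk[-(1:2)])
    } else {
      stop2("malformed edge line: '", paste(tk, collapse = " "), "'")
    }
  }
  ppi_network(from, to)
}

#' Write / read a gene annotation table
#'
#' @param annot a [gene_annotation()].
#' @param path file path.
#' @return `read_annotation()` returns a `gene_annotation`.
#' @export
write_annotation <- function(annot, path) {
  stopifnot(inherits(annot, "gene_annotation"))
  write_body(as.data.frame(unclass(annot)), path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read_body(path)
  gene_annotation(df$gene_id, df$chromosome, df$position_bp)
}
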