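# Transcriptome-wide eQTL mapping: every gene's expression is scanned as a
# quantitative trait, chromosome-wise peaks are recorded (a gene may link
# to several loci), peaks are classified cis/trans by physical distance to
# the gene, and overlap with the clinical-trait QTL intervals is annotated.

#' eQTL scan of an expression panel
#'
#' Runs the marker-regression scan of [scan_trait()] for every gene and
#' records, per gene and chromosome, the peak marker wherever the peak LOD
#' reaches `lod_min`. Constant expression rows are skipped with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()] (genes x mice).
#' @param lod_min minimum peak LOD to record (typically the clinical
#'   trait's genome-wide threshold).
#' @param chunk genes scanned per matrix block.
#' @param min_n minimum complete mice per marker.
#' @return An `eqtl_calls` data.frame: `gene_id`, `tissue`,
#'   `peak_marker_id`, `chromosome`, `position_cM`, `lod` — one row per
#'   qualifying (gene, chromosome) peak.
#' @export
scan_all_genes <- function(genotypes, expression, lod_min, chunk = 200,
                           min_n = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  mice <- intersect(rownames(genotypes$codes), colnames(expression))
  if (length(mice) < min_n) stop2("too few mice shared between genotypes and expression")
  codes <- genotypes$codes[mice, , drop = FALSE]
  map <- genotypes$map
  E <- unclass(expression)[, mice, drop = FALSE]
  sds <- apply(E, 1, function(v) stats::sd(v[is.finite(v)]))
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warn2(sum(constant), " constant expression row(s) skipped")
    E <- E[!constant, , drop = FALSE]
  }
  chr_idx <- split(seq_len(nrow(map)), map$chromosome)
  chr_idx <- chr_idx[unique(map$chromosome)]
  out <- list()
  done <- 0L
  while (done < nrow(E)) {
    rows <- seq(done + 1L, min(done + chunk, nrow(E)))
    lod <- scan_matrix(E[rows, , drop = FALSE], codes, min_n = min_n)
    for (chr in names(chr_idx)) {
      cols <- chr_idx[[chr]]
      sub <- lod[, cols, drop = FALSE]
      sub[is.na(sub)] <- -Inf
      pk <- max.col(sub, ties.method = "first")
      pl <- sub[cbind(seq_along(pk), pk)]
      hit <- which(pl >= lod_min)
      if (length(hit)) {
        mi <- cols[pk[hit]]
        out[[length(out) + 1]] <- data.frame(
          gene_id = rownames(E)[rows[hit]],
          tissue = attr(expression, "tissue") %||% "unspecified",
          peak_marker_id = map$marker_id[mi],
          chromosome = map$chromosome[mi],
          position_cM = map$position_cM[mi],
          lod = pl[hit], stringsAsFactors = FALSE
        )
      }
    }
    done <- done + length(rows)
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    gene_id = character(), tissue = character(), peak_marker_id = character(),
    chromosome = character(), position_cM = numeric(), lod = numeric(),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$gene_id, -calls$lod), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("eqtl_calls", "data.frame")
  calls
}

#' Classify eQTL peaks as cis or trans
#'
#' A peak is cis when it lies on the gene's own chromosome within
#' `cis_window_bp` of the gene's position (boundary inclusive; 10 Mb by
#' default), trans otherwise. The cis/trans partition is exhaustive and
#' exclusive for every call.
#'
#' @param calls an `eqtl_calls` data.frame from [scan_all_genes()].
#' @param annotation a [gene_annotation()].
#' @param map the [genetic_map()] the scan used.
#' @param cis_window_bp cis distance window in base pairs.
#' @return `calls` with a logical `is_cis` column (NA for genes missing
#'   from the annotation, reported with a warning).
#' @export
classify_cis <- function(calls, annotation, map, cis_window_bp = 10000000) {
  gi <- match(calls$gene_id, annotation$gene_id)
  if (anyNA(gi) && nrow(calls)) {
    warn2(sum(is.na(gi)), " gene(s) missing from annotation; is_cis set to NA")
  }
  mi <- match(calls$peak_marker_id, map$marker_id)
  if (anyNA(mi) && nrow(calls)) stop2("peak marker(s) absent from map")
  same_chr <- annotation$chromosome[gi] == map$chromosome[mi]
  dist_bp <- abs(annotation$position_bp[gi] - map$position_bp[mi])
  calls$is_cis <- same_chr & dist_bp <= cis_window_bp
  calls
}

#' Overlap eQTL peaks with trait QTL intervals
#'
#' A peak overlaps a trait locus when it sits on the interval's chromosome
#' with cM position inside `[start_cM, end_cM]` (bounds inclusive).
#' Interval rows are labelled `locus1`, `locus2`, ... in the order given.
#' Two columns are added: `peak_in` (the interval containing this row's
#' peak, or "none") and the gene-level `overlapped_locus`, which becomes
#' "both" for genes with qualifying peaks in two intervals.
#'
#' @param calls an `eqtl_calls` data.frame.
#' @param trait_intervals a `qtl_intervals` data.frame from
#'   [call_intervals()].
#' @return `calls` with `peak_in` and `overlapped_locus` columns.
#' @export
overlap_with_trait_qtl <- function(calls, trait_intervals) {
  labels <- paste0("locus", seq_len(nrow(trait_intervals)))
  peak_in <- rep("none", nrow(calls))
  for (i in seq_len(nrow(trait_intervals))) {
    iv <- trait_intervals[i, ]
    hit <- calls$chromosome == iv$chromosome &
      calls$position_cM >= iv$start_cM & calls$position_cM <= iv$end_cM
    peak_in[hit & peak_in == "none"] <- labels[i]
  }
  calls$peak_in <- peak_in
  agg <- tapply(peak_in, calls$gene_id, function(x) {
    hits <- unique(x[x != "none"])
    if (length(hits) >= 2) "both" else if (length(hits) == 1) hits else "none"
  })
  gene_label <- as.character(agg[calls$gene_id])
  calls$overlapped_locus <- ifelse(peak_in == "none", "none", gene_label)
  calls
}

#' Permutation FDR for per-locus eQTL counts
#'
#' The observed statistic per trait locus is the number of distinct genes
#' whose eQTL peak overlaps the locus interval. Mouse labels of the whole
#' expression matrix are then shuffled jointly (preserving gene-gene
#' correlation while breaking all genotype linkage) `n_perm` times and
#'   FDR(locus) = mean(permuted count) / observed count.
#' Undefined (NA) when the observed count is zero.
#'
#' @inheritParams scan_all_genes
#' @param trait_intervals a `qtl_intervals` data.frame.
#' @param n_perm number of joint label permutations (>= 1).
#' @param seed optional seed.
#' @return data.frame with one row per locus: `locus`, `observed`,
#'   `mean_null`, `fdr`.
#' @export
count_fdr <- function(genotypes, expression, trait_intervals, lod_min,
                      n_perm, seed = NULL, chunk = 200) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  labels <- paste0("locus", seq_len(nrow(trait_intervals)))
  count_once <- function(expr) {
    calls <- suppressWarnings(scan_all_genes(genotypes, expr, lod_min, chunk = chunk))
    calls <- overlap_with_trait_qtl(calls, trait_intervals)
    vapply(labels, function(lb) {
      length(unique(calls$gene_id[calls$overlapped_locus %in% c(lb, "both")]))
    }, numeric(1))
  }
  observed <- count_once(expression)
  if (!is.null(seed)) set.seed(seed)
  null_counts <- matrix(0, nrow = n_perm, ncol = length(labels))
  for (b in seq_len(n_perm)) {
    perm <- unclass(expression)[, sample.int(ncol(expression)), drop = FALSE]
    colnames(perm) <- colnames(expression)
    null_counts[b, ] <- count_once(
      expression_matrix(perm, tissue = attr(expression, "tissue"))
    )
  }
  mean_null <- colMeans(null_counts)
  data.frame(locus = labels, observed = observed, mean_null = mean_null,
             fdr = ifelse(observed > 0, mean_null / observed, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
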