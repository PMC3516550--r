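# Single-trait QTL mapping by marker regression. At each marker the trait
# is regressed on genotype as a 3-level factor (2 df) over the mice with
# complete (genotype, trait) data, and
#   LOD = (n/2) * log10(RSS_null / RSS_full).
# This is classical marker regression rather than HMM interval mapping; the
# marker set is dense enough that peak markers and support intervals are
# what downstream stages consume. Missing genotypes are handled per marker
# by complete-case analysis, never imputed.

# Vectorised scan of many traits at once. Y is traits x mice (NA allowed),
# codes is mice x markers in {0,1,2,NA}. Returns the LOD matrix (traits x
# markers) with NA where fewer than min_n complete observations remain and
# 0 at monomorphic markers.
scan_matrix <- function(Y, codes, min_n = 10) {
  Ik <- lapply(0:2, function(k) {
    m <- codes == k
    m[is.na(m)] <- FALSE
    m + 0
  })
  W <- is.finite(Y) + 0
  Y0 <- ifelse(is.finite(Y), Y, 0)
  Y2 <- Y0^2
  S <- lapply(Ik, function(I) Y0 %*% I)
  N <- lapply(Ik, function(I) W %*% I)
  Q <- lapply(Ik, function(I) Y2 %*% I)
  Ntot <- N[[1]] + N[[2]] + N[[3]]
  Stot <- S[[1]] + S[[2]] + S[[3]]
  Qtot <- Q[[1]] + Q[[2]] + Q[[3]]
  rss0 <- Qtot - Stot^2 / pmax(Ntot, 1)
  between <- S[[1]]^2 / pmax(N[[1]], 1) + S[[2]]^2 / pmax(N[[2]], 1) +
    S[[3]]^2 / pmax(N[[3]], 1)
  rss1 <- Qtot - between
  n_classes <- (N[[1]] > 0) + (N[[2]] > 0) + (N[[3]] > 0)
  lod <- (Ntot / 2) * log10(pmax(rss0, 1e-300) / pmax(rss1, rss0 * 1e-12))
  lod[n_classes <= 1] <- 0                       # monomorphic marker
  lod[rss0 <= .Machine$double.eps^0.75 * pmax(Qtot, 1)] <- 0
  lod <- pmax(lod, 0)
  lod[Ntot < min_n] <- NA_real_
  lod
}

align_mice <- function(genotypes, trait, covariate = NULL) {
  mice <- intersect(rownames(genotypes$codes), names(trait))
  if (!is.null(covariate)) {
    if (is.null(names(covariate))) stop2("covariate needs mouse ids as names")
    mice <- intersect(mice, names(covariate))
  }
  if (length(mice) < 3) stop2("fewer than 3 mice shared between genotypes and trait")
  mice
}

#' Genome scan of a single trait
#'
#' Marker-regression LOD scan: at each marker the null model
#' `trait ~ 1 (+ covariate)` and full model `trait ~ genotype factor
#' (+ covariate)` are fitted on the mice complete for that marker, and
#' `LOD = (n/2) log10(RSS_null/RSS_full)`. Monomorphic markers score 0;
#' markers with fewer than `min_n` complete mice are dropped with a
#' warning. The conditional mode (a non-NULL `covariate`) is how mediation
#' is probed: if the covariate carries the locus effect, the LOD collapses.
#'
#' @param genotypes a [genotype_matrix()].
#' @param trait a [trait_vector()] (or named numeric).
#' @param covariate optional named numeric (another trait, or one gene's
#'   expression) to condition both models on.
#' @param min_n minimum complete observations per marker.
#' @return A `lod_curve` data.frame: `marker_id`, `chromosome`,
#'   `position_cM`, `lod`.
#' @export
scan_trait <- function(genotypes, trait, covariate = NULL, min_n = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  mice <- align_mice(genotypes, trait, covariate)
  y <- as.numeric(trait[mice])
  if (stats::sd(y[is.finite(y)]) == 0) stop2("zero-variance trait")
  codes <- genotypes$codes[mice, , drop = FALSE]
  if (is.null(covariate)) {
    lod <- scan_matrix(matrix(y, nrow = 1), codes, min_n = min_n)[1, ]
  } else {
    cv <- as.numeric(covariate[mice])
    if (stats::sd(cv[is.finite(cv)]) == 0) {
      stop2("covariate is collinear with the intercept")
    }
    lod <- vapply(seq_len(ncol(codes)), function(j) {
      g <- codes[, j]
      ok <- is.finite(y) & is.finite(cv) & !is.na(g)
      n <- sum(ok)
      if (n < min_n) return(NA_real_)
      if (length(unique(g[ok])) <= 1) return(0)
      X0 <- cbind(1, cv[ok])
      X1 <- cbind(X0, g[ok] == 1, g[ok] == 2)
      rss0 <- sum(.lm.fit(X0, y[ok])$residuals^2)
      rss1 <- sum(.lm.fit(X1, y[ok])$residuals^2)
      if (rss0 <= .Machine$double.eps^0.75 * sum(y[ok]^2)) return(0)
      max((n / 2) * log10(rss0 / max(rss1, rss0 * 1e-12)), 0)
    }, numeric(1))
  }
  map <- genotypes$map
  keep <- !is.na(lod)
  if (any(!keep)) {
    warn2(sum(!keep), " marker(s) dropped: fewer than ", min_n, " complete mice")
  }
  out <- data.frame(marker_id = map$marker_id[keep],
                    chromosome = map$chromosome[keep],
                    position_cM = map$position_cM[keep],
                    lod = lod[keep], stringsAsFactors = FALSE)
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Permutation genome-wide LOD threshold
#'
#' Permutes the trait across mice `n_perm` times, rescans the genome for
#' each permutation, and returns the empirical `1 - alpha` quantile of the
#' per-permutation maximum LOD. Controls the family-wise error rate of the
#' scan at level `alpha` under the null of no linkage.
#'
#' @inheritParams scan_trait
#' @param n_perm number of permutations (a warning is issued below 100:
#'   the tail quantile is unstable).
#' @param alpha genome-wide significance level.
#' @param seed optional seed for the permutation stream.
#' @param chunk permutations processed per matrix block (memory control).
#' @return The threshold (numeric scalar) with the vector of permutation
#'   maxima attached as attribute `perm_maxima`.
#' @export
genomewide_threshold <- function(genotypes, trait, n_perm = 1000, alpha = 0.05,
                                 seed = NULL, chunk = 250, min_n = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (n_perm < 1) stop2("n_perm must be >= 1")
  if (n_perm < 100) warn2("n_perm < 100 gives an unstable threshold quantile")
  mice <- align_mice(genotypes, trait)
  y <- as.numeric(trait[mice])
  if (stats::sd(y[is.finite(y)]) == 0) stop2("zero-variance trait")
  codes <- genotypes$codes[mice, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  maxima <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- t(vapply(seq_len(b), function(i) y[sample.int(n)], numeric(n)))
    lod <- scan_matrix(P, codes, min_n = min_n)
    maxima[done + seq_len(b)] <- apply(lod, 1, max, na.rm = TRUE)
    done <- done + b
  }
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 1, names = FALSE)
  attr(thr, "perm_maxima") <- maxima
  thr
}

#' Call QTL support intervals from a LOD curve
#'
#' One interval per chromosome whose maximum LOD reaches the threshold.
#' Interval bounds are the outermost markers on that chromosome whose LOD
#' lies within `drop` units of the peak (the classical LOD-support
#' interval; `drop = 1.5` by default).
#'
#' @param curve a `lod_curve` from [scan_trait()].
#' @param threshold genome-wide LOD threshold.
#' @param drop LOD fall-off defining the support interval.
#' @return A `qtl_intervals` data.frame: `chromosome`, `start_cM`,
#'   `end_cM`, `peak_marker_id`, `peak_lod`, `threshold`; zero rows when
#'   nothing reaches the threshold.
#' @export
call_intervals <- function(curve, threshold, drop = 1.5) {
  threshold <- as.numeric(threshold)
  rows <- list()
  for (chr in unique(curve$chromosome)) {
    sub <- curve[curve$chromosome == chr, , drop = FALSE]
    peak <- which.max(sub$lod)
    if (sub$lod[peak] < threshold) next
    near <- sub$lod >= sub$lod[peak] - drop
    rows[[length(rows) + 1]] <- data.frame(
      chromosome = chr,
      start_cM = min(sub$position_cM[near]),
      end_cM = max(sub$position_cM[near]),
      peak_marker_id = sub$marker_id[peak],
      peak_lod = sub$lod[peak],
      threshold = threshold,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chromosome = character(), start_cM = numeric(), end_cM = numeric(),
    peak_marker_id = character(), peak_lod = numeric(), threshold = numeric(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Trait variance explained at peak markers
#'
#' R-squared of the trait on each peak-marker genotype factor, and (for two
#' markers) the joint additive two-factor model.
#'
#' @inheritParams scan_trait
#' @param markers character vector of one or two marker ids.
#' @return list with `per_marker` (named R-squared per marker) and `joint`
#'   (joint additive R-squared; NA for a single marker).
#' @export
variance_explained <- function(genotypes, trait, markers) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!all(markers %in% colnames(genotypes$codes))) {
    stop2("unknown marker id(s): ",
          paste(setdiff(markers, colnames(genotypes$codes)), collapse = ", "))
  }
  if (!length(markers) %in% 1:2) stop2("give one or two peak markers")
  mice <- align_mice(genotypes, trait)
  y <- as.numeric(trait[mice])
  gs <- lapply(markers, function(mk) genotypes$codes[mice, mk])
  per <- vapply(gs, function(g) {
    ok <- is.finite(y) & !is.na(g)
    summary(stats::lm(y[ok] ~ factor(g[ok])))$r.squared
  }, numeric(1))
  names(per) <- markers
  joint <- NA_real_
  if (length(markers) == 2) {
    ok <- is.finite(y) & !is.na(gs[[1]]) & !is.na(gs[[2]])
    joint <- summary(stats::lm(y[ok] ~ factor(gs[[1]][ok]) +
                                 factor(gs[[2]][ok])))$r.squared
  }
  list(per_marker = per, joint = joint)
}
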