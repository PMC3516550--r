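# Independent brute-force reference implementations used to verify the
# optimized paths. Deliberately written with explicit loops and textbook
# formulas, sharing no code with the package internals.

oracle_lod <- function(y, g) {
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]
  g <- g[ok]
  n <- length(y)
  if (length(unique(g)) <= 1) return(0)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- 0
  for (k in unique(g)) {
    yk <- y[g == k]
    rss1 <- rss1 + sum((yk - mean(yk))^2)
  }
  (n / 2) * log10(rss0 / rss1)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# full TIE recomputation by explicit loops on a complete-data panel
oracle_tie_scores <- function(edges, E, tv, min_degree = 5) {
  genes <- rownames(E)
  N <- E
  for (g in seq_len(nrow(E))) {
    lo <- min(E[g, ]); hi <- max(E[g, ])
    for (m in seq_len(ncol(E))) {
      N[g, m] <- if (hi > lo) (E[g, m] - lo) / (hi - lo) else NA_real_
    }
  }
  tipcs <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ip <- numeric(ncol(N))
    for (m in seq_len(ncol(N))) {
      ip[m] <- N[edges$from[e], m] * N[edges$to[e], m]
    }
    tipcs[e] <- if (anyNA(ip) || length(unique(ip)) == 1 ||
                    length(unique(tv)) == 1) 0 else oracle_pearson(ip, tv)
  }
  deg <- setNames(integer(length(genes)), genes)
  acc <- setNames(numeric(length(genes)), genes)
  for (e in seq_len(nrow(edges))) {
    for (gn in c(edges$from[e], edges$to[e])) {
      deg[gn] <- deg[gn] + 1L
      acc[gn] <- acc[gn] + abs(tipcs[e])
    }
  }
  tie <- ifelse(deg >= min_degree, acc / pmax(deg, 1), 0)
  list(tipcs = tipcs, tie = tie, degree = deg)
}

oracle_cross_edges <- function(ppi, g1, g2) {
  keep <- logical(nrow(ppi))
  for (e in seq_len(nrow(ppi))) {
    a <- ppi$from[e]; b <- ppi$to[e]
    keep[e] <- (a %in% g1 && b %in% g2) || (a %in% g2 && b %in% g1)
  }
  ppi[keep, c("from", "to")]
}
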