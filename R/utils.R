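# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

# Pearson correlation over pairwise-complete observations; NA when fewer than
# min_n complete pairs remain or either side is constant on the complete set.
pearson_or_na <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# derive k reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(2147483646L, k)
}

first_bad_cell <- function(bad, codes) {
  idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
  sprintf("value '%s' for mouse '%s' at marker '%s'",
          as.character(codes[idx[1], idx[2]]),
          rownames(codes)[idx[1]], colnames(codes)[idx[2]])
}
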