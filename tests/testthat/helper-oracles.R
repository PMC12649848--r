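# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# Expressed-gene filter: explicit loops, no vectorized shortcuts.
oracle_filter_expressed <- function(values) {
  global_med <- median(as.vector(values))
  keep <- character()
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    n_nonzero <- 0
    for (v in row) if (v != 0) n_nonzero <- n_nonzero + 1
    if (median(row) > global_med && n_nonzero / length(row) > 0.5)
      keep <- c(keep, rownames(values)[i])
  }
  keep
}

# GSEA enrichment score: full running sum over every rank position.
oracle_es <- function(metric, is_hit, p) {
  N <- length(metric)
  k <- sum(is_hit)
  w <- abs(metric)^p
  denom <- sum(w[is_hit])
  ph <- cumsum(ifelse(is_hit, if (denom > 0) w / denom else 1 / k, 0))
  pm <- cumsum(!is_hit) / (N - k)
  dev <- ph - pm
  dev[which.max(abs(dev))]
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(x, K, N, n) {
  total <- choose(N, n)
  sum(vapply(x:min(K, n), function(j) choose(K, j) * choose(N - K, n - j), 0)) / total
}

# Small labelled expression matrix builder.
make_expr <- function(values, genes = NULL, samples = NULL, groups = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  endotalk::expression_matrix(m, group_labels = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
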