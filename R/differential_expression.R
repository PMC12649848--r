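# Two-group differential expression with fold-change and FDR call gates.

#' Benjamini-Hochberg false discovery rates
#'
#' Validating wrapper around the standard step-up adjustment
#' (`stats::p.adjust(method = "BH")`): output in input order, clipped to
#' `[0, 1]`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    abort_val("p-values must lie in [0, 1]")
  pmin(1, stats::p.adjust(p_values, method = "BH"))
}

#' Two-group differential expression
#'
#' Fold change is the ratio of pseudocounted linear group means,
#' `(mean(test) + c) / (mean(ref) + c)`; the p-value comes from a two-sided
#' Welch t-test on `log2(x + c)` (or, with `test = "permutation"`, from a
#' seeded group-label permutation of the same t statistic); FDR by
#' Benjamini-Hochberg over all tested genes. A gene is called significant
#' when its fold change exceeds `fc_threshold` in either direction
#' (`fc > 2` or `fc < 0.5` at the default) and its FDR is below
#' `fdr_threshold`.
#'
#' @param matrix an [expression_matrix()] carrying exactly two group labels.
#' @param groups optional length-2 character vector giving (reference, test)
#'   order; defaults to the labels' order of first appearance.
#' @param pseudocount linear-scale pseudocount `c` guarding zero means.
#' @param fc_threshold linear fold-change gate (applied symmetrically).
#' @param fdr_threshold FDR gate.
#' @param test `"welch"` or `"permutation"`.
#' @param n_permutations label permutations when `test = "permutation"`.
#' @param seed seed for the permutation test.
#' @return a `data.frame` of class `DegTable`: per gene `fold_change`,
#'   `log2_fc`, `p_value`, `fdr`, `direction` (`up`/`down`/`none`) and
#'   `is_significant`.
#' @export
differential_expression <- function(matrix, groups = NULL, pseudocount = 1,
                                    fc_threshold = 2, fdr_threshold = 0.01,
                                    test = c("welch", "permutation"),
                                    n_permutations = 1000, seed = 1L) {
  test <- match.arg(test)
  labels <- group_labels(matrix)
  if (is.null(labels)) abort_val("matrix carries no group labels")
  groups <- groups %||% unique(labels)
  if (length(groups) != 2) abort_val("exactly two groups required; got ",
                                     paste(groups, collapse = ", "))
  unknown <- setdiff(labels, groups)
  if (length(unknown)) abort_val("unknown group label(s): ",
                                 paste(unique(unknown), collapse = ", "))
  i1 <- which(labels == groups[1]); i2 <- which(labels == groups[2])
  if (length(i1) < 2 || length(i2) < 2)
    abort_val("each group needs >= 2 samples (", groups[1], ": ", length(i1),
              ", ", groups[2], ": ", length(i2), ")")
  vals <- unclass(matrix)
  m1 <- rowMeans(vals[, i1, drop = FALSE]); m2 <- rowMeans(vals[, i2, drop = FALSE])
  fold_change <- (m2 + pseudocount) / (m1 + pseudocount)
  logm <- log2(vals + pseudocount)
  tstat <- welch_t(logm[, i1, drop = FALSE], logm[, i2, drop = FALSE])
  p <- if (test == "welch") {
    tstat$p
  } else {
    permutation_p(logm, i1, i2, abs(tstat$t), n_permutations, seed)
  }
  fdr <- bh_fdr(p)
  direction <- ifelse(fold_change > 1, "up", ifelse(fold_change < 1, "down", "none"))
  sig <- (fold_change > fc_threshold | fold_change < 1 / fc_threshold) &
    fdr < fdr_threshold
  out <- data.frame(gene_id = rownames(vals), fold_change = unname(fold_change),
                    log2_fc = unname(log2(fold_change)), p_value = unname(p),
                    fdr = unname(fdr), direction = unname(direction),
                    is_significant = unname(sig), stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  class(out) <- c("DegTable", "data.frame")
  out
}

# Row-wise Welch t statistic and two-sided p for two log-scale submatrices.
welch_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # zero-variance genes (constant in both groups): no evidence either way
  degenerate <- !is.finite(t) | !is.finite(df)
  t[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = pmin(1, p))
}

# Permutation p-values: proportion of label permutations whose |t| meets or
# exceeds the observed |t|, with the +1 correction keeping p > 0.
permutation_p <- function(logm, i1, i2, observed_abs_t, n_permutations, seed) {
  set.seed(seed)
  idx <- c(i1, i2)
  n1 <- length(i1)
  exceed <- integer(nrow(logm))
  for (b in seq_len(n_permutations)) {
    perm <- sample(idx)
    tb <- welch_t(logm[, perm[seq_len(n1)], drop = FALSE],
                  logm[, perm[-seq_len(n1)], drop = FALSE])$t
    exceed <- exceed + (abs(tb) >= observed_abs_t)
  }
  (exceed + 1) / (n_permutations + 1)
}
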