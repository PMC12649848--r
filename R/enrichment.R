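# Gene-set enrichment: a running-sum GSEA engine with gene-set permutation
# nulls, hypergeometric over-representation with a log10 observed/expected
# strength statistic, and pathway-to-category grouping.

#' Rank genes for GSEA between two groups
#'
#' The signal-to-noise metric is `(mu2 - mu1) / (sd2 + sd1)` computed on
#' `log2(x + 1)`, with each group standard deviation floored at
#' `max(0.2 * |mu|, 0.2)` so low-variance genes cannot dominate;
#' `log2fc` ranks by the difference of log2 group means. Ties are broken
#' by lexicographic gene id, making the order fully deterministic.
#'
#' @param matrix an [expression_matrix()] with two group labels.
#' @param metric `"signal_to_noise"` or `"log2fc"`.
#' @param groups optional (reference, test) label order.
#' @return a `data.frame` of class `RankedList`, genes ordered by metric
#'   descending, columns `gene_id` and `metric`.
#' @export
rank_genes <- function(matrix, metric = c("signal_to_noise", "log2fc"),
                       groups = NULL) {
  metric <- match.arg(metric)
  labels <- group_labels(matrix)
  if (is.null(labels)) abort_val("matrix carries no group labels")
  groups <- groups %||% unique(labels)
  if (length(groups) != 2) abort_val("exactly two groups required")
  i1 <- which(labels == groups[1]); i2 <- which(labels == groups[2])
  if (metric == "signal_to_noise" && (length(i1) < 2 || length(i2) < 2))
    abort_val("signal_to_noise needs >= 2 samples per group")
  logm <- log2(unclass(matrix) + 1)
  m1 <- rowMeans(logm[, i1, drop = FALSE]); m2 <- rowMeans(logm[, i2, drop = FALSE])
  if (metric == "signal_to_noise") {
    s1 <- apply(logm[, i1, drop = FALSE], 1, stats::sd)
    s2 <- apply(logm[, i2, drop = FALSE], 1, stats::sd)
    s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
    s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
    val <- (m2 - m1) / (s2 + s1)
  } else {
    val <- m2 - m1
  }
  o <- order(-val, rownames(logm))
  out <- data.frame(gene_id = rownames(logm)[o], metric = unname(val[o]),
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}

#' GSEA enrichment score for one gene set
#'
#' The signed maximal deviation of the weighted running sum: walking down
#' the ranked list, hits advance by `|metric|^p` (normalized over hits) and
#' misses advance by `1 / (N - k)`; the ES is the deviation of largest
#' absolute value, keeping its sign. `weight_p = 0` gives the classical
#' Kolmogorov-Smirnov-style statistic.
#'
#' @param ranked a [rank_genes()] result (or data.frame with `gene_id`,
#'   `metric`).
#' @param gene_set character vector of member gene ids.
#' @param weight_p metric weighting exponent, >= 0.
#' @return the enrichment score, a real in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  if (weight_p < 0) abort_val("weight_p must be >= 0")
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) abort_val("set not represented in ranked list")
  es_from_hits(which(hit), abs(ranked$metric)^weight_p, nrow(ranked))
}

# Core running-sum evaluation from hit positions. The running deviation is
# piecewise linear with its extrema at hit positions (upper) and at the
# position just before each hit (lower), so only those 2k candidates are
# examined.
es_from_hits <- function(idx, wp, N) {
  k <- length(idx)
  if (N - k == 0) abort_val("gene set covers the whole ranked list (N - k = 0)")
  idx <- sort(idx)
  w <- wp[idx]
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / k, k) else w <- w / tot  # all-zero metric: unweighted
  cumhit <- cumsum(w)
  miss_rate <- 1 / (N - k)
  at_hit <- cumhit - (idx - seq_len(k)) * miss_rate
  # deviation immediately before hit j (position idx_j - 1):
  before_hit <- c(0, cumhit[-k]) - (idx - seq_len(k)) * miss_rate
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Gene-set enrichment analysis with a gene-set permutation null
#'
#' For every set, the observed ES is compared with `n_permutations` random
#' same-size sets drawn from the ranked universe. NES is the ES divided by
#' the mean |null ES| of matching sign; the nominal p-value is the fraction
#' of same-sign null ES at least as extreme; the FDR follows the
#' NES-distribution ratio construction (fraction of pooled null NES beyond
#' the observed NES over the fraction of observed NES beyond it), with
#' `fdr_method = "bh"` offering Benjamini-Hochberg on nominal p-values as
#' an alternative. Sets larger than `N - 1` are skipped with a warning.
#'
#' @param ranked a [rank_genes()] result.
#' @param collection a `GeneSetCollection` (named list of gene id vectors).
#' @param n_permutations number of null sets per gene set (>= 100).
#' @param weight_p metric weighting exponent.
#' @param seed integer seed; the null stream is reproducible.
#' @param fdr_method `"nes_ratio"` or `"bh"`.
#' @param fdr_threshold,nes_threshold the call gates; a set passes when
#'   `fdr < fdr_threshold` and `|NES| > nes_threshold`.
#' @return a `data.frame` of class `GseaResult`: per set `size`, `es`,
#'   `nes`, `nominal_p`, `fdr`, `passes`.
#' @export
gsea <- function(ranked, collection, n_permutations = 1000, weight_p = 1,
                 seed = 1L, fdr_method = c("nes_ratio", "bh"),
                 fdr_threshold = 0.25, nes_threshold = 1.5) {
  fdr_method <- match.arg(fdr_method)
  if (n_permutations < 100) abort_val("n_permutations must be >= 100")
  N <- nrow(ranked)
  wp <- abs(ranked$metric)^weight_p
  universe <- ranked$gene_id
  sizes <- vapply(collection, function(s) length(intersect(s, universe)), 0L)
  usable <- sizes >= 1 & sizes <= N - 1
  if (any(!usable))
    warning("skipping ", sum(!usable),
            " set(s) with no overlap or covering the whole list", call. = FALSE)
  keep <- names(collection)[usable]
  es <- vapply(keep, function(nm) gsea_es(ranked, collection[[nm]], weight_p),
               numeric(1))
  set.seed(seed)
  null_by_size <- list()  # one shared null per distinct set size
  for (k in sort(unique(sizes[keep]))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_permutations),
      function(b) es_from_hits(sample.int(N, k), wp, N), numeric(1))
  }
  nes <- nominal_p <- rep(NA_real_, length(keep))
  null_nes <- list()
  for (j in seq_along(keep)) {
    nul <- null_by_size[[as.character(sizes[[keep[j]]])]]
    same <- nul[sign(nul) == sign(es[j]) | es[j] == 0]
    if (length(same) == 0) { nes[j] <- NA; nominal_p[j] <- 1 / n_permutations; next }
    denom <- mean(abs(same))
    nes[j] <- es[j] / denom
    nominal_p[j] <- mean(abs(same) >= abs(es[j]))
    pos <- nul[nul >= 0]; neg <- nul[nul < 0]
    null_nes[[j]] <- c(if (length(pos)) pos / mean(pos),
                       if (length(neg)) neg / mean(-neg))
  }
  pooled_null <- unlist(null_nes)
  fdr <- if (fdr_method == "bh") {
    bh_fdr(nominal_p)
  } else {
    vapply(seq_along(keep), function(j) {
      if (!is.finite(nes[j])) return(1)
      if (nes[j] >= 0) {
        num_pool <- pooled_null[pooled_null >= 0]
        num <- if (length(num_pool)) mean(num_pool >= nes[j]) else 0
        obs <- nes[is.finite(nes) & nes >= 0]
        den <- mean(obs >= nes[j])
      } else {
        num_pool <- pooled_null[pooled_null < 0]
        num <- if (length(num_pool)) mean(num_pool <= nes[j]) else 0
        obs <- nes[is.finite(nes) & nes < 0]
        den <- mean(obs <= nes[j])
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
  }
  passes <- is.finite(nes) & fdr < fdr_threshold & abs(nes) > nes_threshold
  out <- data.frame(set_name = keep, size = unname(sizes[keep]),
                    es = unname(es), nes = nes, nominal_p = nominal_p,
                    fdr = fdr, passes = passes, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("GseaResult", "data.frame")
  out
}

#' Hypergeometric over-representation with STRING-style strength
#'
#' For each set, the overlap of the network's genes with the set (inside
#' the background universe) is tested with the upper-tail hypergeometric
#' distribution; `strength = log10(observed / expected)` where
#' `expected = n * K / N`. FDR by Benjamini-Hochberg across sets. A set
#' passes when `strength > strength_threshold` and
#' `fdr < fdr_threshold`. Empty overlaps report `p = 1`, an undefined
#' (`NA`) strength, and never pass.
#'
#' @param network_genes genes in the network (must lie inside `background`).
#' @param collection a `GeneSetCollection`.
#' @param background the background gene universe.
#' @param strength_threshold,fdr_threshold the call gates.
#' @return a `data.frame` of class `OraResult`: per set `overlap`,
#'   `set_size`, `expected`, `strength`, `p_value`, `fdr`, `passes`.
#' @export
ora <- function(network_genes, collection, background,
                strength_threshold = 0.7, fdr_threshold = 0.001) {
  network_genes <- unique(network_genes)
  background <- unique(background)
  out_of_bg <- setdiff(network_genes, background)
  if (length(out_of_bg))
    abort_val("network genes outside the background: ",
              paste(utils::head(out_of_bg, 5), collapse = ", "))
  N <- length(background); n <- length(network_genes)
  res <- lapply(names(collection), function(nm) {
    K <- length(intersect(collection[[nm]], background))
    x <- length(intersect(intersect(network_genes, collection[[nm]]), background))
    expected <- n * K / N
    if (x == 0) {
      data.frame(set_name = nm, overlap = 0L, set_size = K, expected = expected,
                 strength = NA_real_, p_value = 1, stringsAsFactors = FALSE)
    } else {
      p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      data.frame(set_name = nm, overlap = x, set_size = K, expected = expected,
                 strength = log10((x / n) / (K / N)), p_value = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out$passes <- !is.na(out$strength) & out$strength > strength_threshold &
    out$fdr < fdr_threshold
  class(out) <- c("OraResult", "data.frame")
  out
}

#' Group enriched pathways into higher-order biological categories
#'
#' Applies a pathway-to-category map (e.g. cytokine signalling, leukocyte
#' activation and chemotaxis grouped under inflammation); pathways absent
#' from the map are collected under `"unassigned"`.
#'
#' @param pathway_names character vector (e.g. the `set_name` column of a
#'   `GseaResult` or `OraResult`).
#' @param map a data.frame with columns `pathway` and `category`, or a
#'   named character vector `pathway -> category`.
#' @return named list: category -> character vector of pathways.
#' @export
group_pathways <- function(pathway_names, map = default_category_map()) {
  if (is.data.frame(map)) map <- stats::setNames(map$category, map$pathway)
  dup <- unique(names(map)[duplicated(names(map))])
  if (length(dup)) abort_val("duplicate pathway key(s) in category map: ",
                             paste(dup, collapse = ", "))
  cat <- ifelse(pathway_names %in% names(map), map[pathway_names], "unassigned")
  split(pathway_names, factor(cat, levels = unique(c(setdiff(unique(cat), "unassigned"),
                                                     "unassigned"))))
}

#' Default pathway-to-category map
#'
#' The shipped skeleton covering the three higher-order categories the
#' pipeline reports on — inflammation, stress response and cell death —
#' with representative pathway names. Users supply their own TSV for real
#' collections.
#'
#' @return data.frame with columns `pathway` and `category`.
#' @export
default_category_map <- function() {
  data.frame(
    pathway = c("cytokine signalling", "leukocyte activation", "chemotaxis",
                "interferon signalling",
                "response to oxidative stress", "heat shock response",
                "unfolded protein response",
                "apoptosis", "programmed cell death", "pyroptosis"),
    category = c(rep("inflammation", 4), rep("stress response", 3),
                 rep("cell death", 3)),
    stringsAsFactors = FALSE)
}

#' Read a pathway-to-category map TSV
#' @param path TSV with columns `pathway` and `category`.
#' @return data.frame with those columns.
#' @export
read_category_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  miss <- setdiff(c("pathway", "category"), names(df))
  if (length(miss)) abort_val("category map missing column(s): ",
                              paste(miss, collapse = ", "))
  dup <- unique(df$pathway[duplicated(df$pathway)])
  if (length(dup)) abort_val("duplicate pathway key(s) in category map: ",
                             paste(dup, collapse = ", "))
  df[, c("pathway", "category")]
}
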