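# Single-cell arm: depth normalization, two-stage reference-correlation
# cell typing, per-sample proportions, pseudobulk aggregation, and the
# immune secretome differential analysis that feeds the network overlay.

#' Depth-normalize single-cell counts
#'
#' Each cell's counts are scaled to the median total count across cells,
#' then transformed with `log2(x + 1)`. Cells with zero total count are
#' dropped with a warning. This is a deliberately simple variance
#' stabilization; the downstream typing and averaging logic is the point,
#' not the normalization.
#'
#' @param dataset a [single_cell_dataset()].
#' @return list of class `NormalizedCells`: `matrix` (genes x cells, dense
#'   log2 scale), `sample_id`, `sample_groups`.
#' @export
sc_normalize <- function(dataset) {
  totals <- Matrix::colSums(dataset$counts)
  if (all(totals == 0)) abort_val("all cells have zero total count")
  drop <- totals == 0
  if (any(drop))
    warning(sum(drop), " cell(s) with zero total count dropped", call. = FALSE)
  counts <- dataset$counts[, !drop, drop = FALSE]
  totals <- totals[!drop]
  target <- stats::median(totals)
  scaled <- counts %*% Matrix::Diagonal(x = target / totals)
  m <- log2(as.matrix(scaled) + 1)
  dimnames(m) <- list(dataset$gene_ids, dataset$cell_ids[!drop])
  structure(list(matrix = m,
                 sample_id = dataset$sample_id[!drop],
                 sample_groups = dataset$sample_groups),
            class = "NormalizedCells")
}

#' Two-stage reference-correlation cell typing
#'
#' Stage one correlates every cell (Spearman by default) against each
#' broad reference profile over the top variable genes of the broad tier;
#' the best-correlated label wins, ties broken lexicographically. Cells
#' landing on the `immune` broad label are re-scored against the immune
#' tier for a subtype. The margin to the runner-up is recorded per cell.
#'
#' @param normalized a [sc_normalize()] result.
#' @param reference a `ReferenceProfiles` object (matrices genes x types).
#' @param n_variable_genes number of top-variance reference genes used
#'   per tier.
#' @param method correlation method, `"spearman"` (rank-based, robust to
#'   monotone distortions) or `"pearson"`.
#' @param min_shared_genes minimum genes shared between dataset and
#'   reference.
#' @param immune_label broad-tier label that triggers subtype refinement.
#' @return a `data.frame` of class `CellTypeAssignment`: per cell
#'   `broad_label`, `immune_sublabel` (`NA` for non-immune), `label`
#'   (sublabel where present, else broad), `score`, `delta`.
#' @export
assign_cell_types <- function(normalized, reference, n_variable_genes = 500,
                              method = c("spearman", "pearson"),
                              min_shared_genes = 50, immune_label = "immune") {
  method <- match.arg(method)
  m <- normalized$matrix
  tier_scores <- function(profiles) {
    shared <- intersect(rownames(m), rownames(profiles))
    if (length(shared) < min_shared_genes)
      abort_val("only ", length(shared), " genes shared with the reference (need >= ",
                min_shared_genes, ")")
    lp <- log2(profiles[shared, , drop = FALSE] + 1)
    v <- apply(lp, 1, stats::var)
    top <- shared[order(-v)][seq_len(min(n_variable_genes, length(shared)))]
    stats::cor(m[top, , drop = FALSE], lp[top, , drop = FALSE], method = method)
  }
  pick <- function(scores) {
    # argmax per row with lexicographic tie-break (columns pre-sorted)
    ord <- order(colnames(scores))
    s <- scores[, ord, drop = FALSE]
    best <- apply(s, 1, which.max)
    score <- s[cbind(seq_len(nrow(s)), best)]
    runner <- apply(s, 1, function(r) if (length(r) > 1) max(r[-which.max(r)]) else NA_real_)
    list(label = colnames(s)[best], score = score, delta = score - runner)
  }
  broad <- pick(tier_scores(reference$broad))
  sublabel <- rep(NA_character_, ncol(m))
  score <- broad$score; delta <- broad$delta
  imm <- broad$label == immune_label
  if (any(imm)) {
    imm_scores <- tier_scores(reference$immune)[imm, , drop = FALSE]
    sub <- pick(imm_scores)
    sublabel[imm] <- sub$label
    score[imm] <- sub$score
    delta[imm] <- sub$delta
  }
  out <- data.frame(cell_id = colnames(m), broad_label = broad$label,
                    immune_sublabel = sublabel,
                    label = ifelse(is.na(sublabel), broad$label, sublabel),
                    score = score, delta = delta, stringsAsFactors = FALSE)
  class(out) <- c("CellTypeAssignment", "data.frame")
  out
}

#' Per-sample cell-type counts, proportions, and immune fraction
#'
#' Proportions use each sample's total cell count as the denominator, so
#' they sum to one exactly; the immune fraction is the summed proportion
#' of cells with an immune sublabel.
#'
#' @param assignments a [assign_cell_types()] result.
#' @param normalized the matching [sc_normalize()] result (provides sample
#'   ids and group labels).
#' @return a `data.frame` of class `ProportionTable`: per (sample, label)
#'   `n_cells`, `proportion`, plus per-sample `immune_fraction` and
#'   `group`.
#' @export
sc_proportions <- function(assignments, normalized) {
  sample_id <- normalized$sample_id[assignments$cell_id]
  if (any(is.na(sample_id))) abort_val("assignments contain unknown cell ids")
  tab <- table(sample_id, assignments$label)
  totals <- rowSums(tab)
  rows <- expand.grid(sample_id = rownames(tab), label = colnames(tab),
                      stringsAsFactors = FALSE)
  rows$n_cells <- as.vector(tab)
  rows$proportion <- rows$n_cells / totals[rows$sample_id]
  imm_by_sample <- tapply(!is.na(assignments$immune_sublabel), sample_id, sum)
  rows$immune_fraction <- as.vector(imm_by_sample[rows$sample_id] /
                                      totals[rows$sample_id])
  if (!is.null(normalized$sample_groups))
    rows$group <- normalized$sample_groups[rows$sample_id]
  rows <- rows[rows$n_cells > 0 | TRUE, , drop = FALSE]
  rows <- rows[order(rows$sample_id, rows$label), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("ProportionTable", "data.frame")
  rows
}

#' Pseudobulk aggregation per (sample, cell type)
#'
#' The arithmetic mean of normalized expression across all cells of one
#' type within one sample; pairs below `min_cells` are dropped. The result
#' is a valid [expression_matrix()] whose columns are `sample|type` pairs,
#' directly consumable by [filter_expressed()] and
#' [differential_expression()].
#'
#' @param normalized a [sc_normalize()] result.
#' @param assignments the matching [assign_cell_types()] result.
#' @param min_cells minimum cells per (sample, type) pair.
#' @return list of class `PseudobulkMatrix`: `matrix` (an
#'   `ExpressionMatrix`, linear scale is NOT restored — values stay log2),
#'   `meta` (data.frame of `column`, `sample_id`, `label`, `group`,
#'   `n_cells`).
#' @export
sc_pseudobulk <- function(normalized, assignments, min_cells = 10) {
  sample_id <- normalized$sample_id[assignments$cell_id]
  key <- paste(sample_id, assignments$label, sep = "|")
  counts <- table(key)
  keep_keys <- names(counts)[counts >= min_cells]
  if (!length(keep_keys)) abort_val("no (sample, type) pair reaches min_cells = ", min_cells)
  cols <- lapply(keep_keys, function(k) {
    rowMeans(normalized$matrix[, key == k, drop = FALSE])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- keep_keys
  parts <- do.call(rbind, strsplit(keep_keys, "|", fixed = TRUE))
  meta <- data.frame(column = keep_keys, sample_id = parts[, 1],
                     label = parts[, 2],
                     n_cells = as.vector(counts[keep_keys]),
                     stringsAsFactors = FALSE)
  if (!is.null(normalized$sample_groups))
    meta$group <- normalized$sample_groups[meta$sample_id]
  structure(list(matrix = expression_matrix(m, group_labels = meta$group),
                 meta = meta),
            class = "PseudobulkMatrix")
}

#' Immune-cell secretome differential expression
#'
#' For each requested immune cell type: take its pseudobulk columns as
#' samples, apply the dual-criterion expressed-gene filter, restrict to
#' genes annotated `secreted`, and run the two-group differential test.
#' The result is keyed by cell type for
#' [overlay_ligand_perturbation()]. Types present in fewer than 2 samples
#' per group are skipped with a warning. Pseudobulk values are log2-scale,
#' so the matrices are put back on linear scale (`2^x - 1`) before the
#' filter and fold-change computation.
#'
#' @param pseudobulk a [sc_pseudobulk()] result with group labels.
#' @param annotation a [gene_annotation()] table.
#' @param types immune cell types to analyse.
#' @param groups (reference, test) group labels.
#' @param ... passed to [differential_expression()] (thresholds, test).
#' @return named list of `DegTable`s (secreted expressed genes only),
#'   one per analysed type.
#' @export
immune_secretome <- function(pseudobulk, annotation,
                             types = c("NK", "CD4_T", "CD8_T"),
                             groups = NULL, ...) {
  meta <- pseudobulk$meta
  if (is.null(meta$group)) abort_val("pseudobulk carries no group labels")
  groups <- groups %||% unique(meta$group)
  secreted <- genes_with_tag(annotation, "secreted")
  out <- list()
  for (ty in types) {
    sel <- meta$label == ty
    per_group <- table(factor(meta$group[sel], levels = groups))
    if (any(per_group < 2)) {
      warning("skipping type '", ty, "': fewer than 2 samples in some group",
              call. = FALSE)
      next
    }
    m <- unclass(pseudobulk$matrix)[, sel, drop = FALSE]
    linear <- expression_matrix(pmax(2^m - 1, 0), group_labels = meta$group[sel])
    expressed <- filter_expressed(linear, dataset_id = ty)
    keep <- intersect(expressed$gene_ids, secreted)
    if (!length(keep)) {
      warning("type '", ty, "': no secreted expressed genes", call. = FALSE)
      out[[ty]] <- differential_expression(
        expression_matrix(unclass(linear)[0, , drop = FALSE],
                          group_labels = meta$group[sel]), groups = groups, ...)
      next
    }
    sub <- expression_matrix(unclass(linear)[keep, , drop = FALSE],
                             group_labels = meta$group[sel])
    out[[ty]] <- differential_expression(sub, groups = groups, ...)
  }
  out
}
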