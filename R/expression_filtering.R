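# Dual-criterion expressed-gene filter and compartment partitioning into
# endometrial receptors, embryo-secreted ligands, and decoy soluble factors.

#' Filter a matrix to its expressed genes
#'
#' A gene counts as expressed when it meets two criteria simultaneously:
#' (1) its median expression across all samples strictly exceeds the global
#' median over every entry of the matrix, and (2) it is non-zero in strictly
#' more than half of the samples. Both inequalities are strict, so a gene
#' tied with the global median, or non-zero in exactly 50% of samples, is
#' excluded — the conservative reading.
#'
#' @param matrix an [expression_matrix()] with at least 2 samples.
#' @param dataset_id tag recorded on the result.
#' @return list of class `ExpressedGeneSet` with `dataset_id`, `gene_ids`
#'   (the members), and `criteria` — a per-gene data.frame of `gene_median`,
#'   `global_median`, `nonzero_fraction` and `expressed` for every gene in
#'   the input, members and non-members alike.
#' @export
filter_expressed <- function(matrix, dataset_id = "dataset") {
  if (ncol(matrix) < 2)
    abort_val("expressed-gene filter needs >= 2 samples; got ", ncol(matrix))
  vals <- unclass(matrix)
  global_median <- stats::median(vals)
  gene_median <- apply(vals, 1, stats::median)
  nonzero_fraction <- rowMeans(vals != 0)
  expressed <- gene_median > global_median & nonzero_fraction > 0.5
  criteria <- data.frame(gene_id = rownames(vals),
                         gene_median = unname(gene_median),
                         global_median = global_median,
                         nonzero_fraction = unname(nonzero_fraction),
                         expressed = unname(expressed),
                         stringsAsFactors = FALSE)
  structure(list(dataset_id = dataset_id,
                 gene_ids = rownames(vals)[expressed],
                 criteria = criteria),
            class = "ExpressedGeneSet")
}

#' @export
print.ExpressedGeneSet <- function(x, ...) {
  cat(sprintf("ExpressedGeneSet '%s': %d of %d genes expressed\n",
              x$dataset_id, length(x$gene_ids), nrow(x$criteria)))
  invisible(x)
}

#' Partition expressed genes into receptors, ligands and decoys
#'
#' The endometrial side keeps only genes annotated `plasma_membrane`
#' (candidate receptors); the embryo side keeps only genes annotated
#' `secreted`, split into true ligands and decoy soluble factors. Decoys
#' are excluded from network nodes but retained in the enrichment
#' background. Expressed genes absent from the annotation are dropped
#' (with a message), mirroring the loss inherent to any annotation join.
#'
#' @param expressed_endometrium,expressed_embryo [filter_expressed()] results.
#' @param annotation a [gene_annotation()] table.
#' @return list of class `CompartmentSets` with `receptors`, `ligands`,
#'   `decoys`, `background` (all annotated expressed genes, decoys
#'   included) and `n_unannotated`.
#' @export
partition_compartments <- function(expressed_endometrium, expressed_embryo,
                                   annotation) {
  if (nrow(annotation) == 0) abort_val("annotation table is empty")
  endo <- expressed_endometrium$gene_ids
  embr <- expressed_embryo$gene_ids
  covered <- annotation$gene_id
  dropped <- length(setdiff(endo, covered)) + length(setdiff(embr, covered))
  if (dropped > 0)
    message(dropped, " expressed gene(s) absent from the annotation were dropped")
  pm <- genes_with_tag(annotation, "plasma_membrane")
  sec <- genes_with_tag(annotation, "secreted")
  decoy_ids <- annotation$gene_id[annotation$is_decoy]
  receptors <- intersect(endo, pm)
  secreted_embryo <- intersect(embr, sec)
  decoys <- intersect(secreted_embryo, decoy_ids)
  ligands <- setdiff(secreted_embryo, decoys)
  structure(list(receptors = receptors, ligands = ligands, decoys = decoys,
                 background = union(intersect(endo, covered),
                                    intersect(embr, covered)),
                 n_unannotated = dropped),
            class = "CompartmentSets")
}

#' @export
print.CompartmentSets <- function(x, ...) {
  cat(sprintf("CompartmentSets: %d receptors, %d ligands, %d decoys (%d unannotated dropped)\n",
              length(x$receptors), length(x$ligands), length(x$decoys),
              x$n_unannotated))
  invisible(x)
}
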