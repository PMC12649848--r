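# Bipartite receptor-ligand network assembly, perturbation overlays, and
# modulated-receptor summaries.

#' Assemble the bipartite receptor-ligand network
#'
#' An interaction becomes an edge when one endpoint is an expressed
#' endometrial receptor, the other an expressed secreted ligand (decoys are
#' never nodes), and it passes all three gates: combined score at or above
#' the threshold, physical interaction, and curated receptor-ligand
#' evidence. Node sets contain only connected nodes.
#'
#' @param compartments a [partition_compartments()] result, or any list
#'   with `receptors` and `ligands` character vectors.
#' @param interactions an [interaction_table()].
#' @param score_threshold minimum combined confidence score (high
#'   confidence at the 0.7 default).
#' @param ligand_source tag recorded on every edge (e.g. `"embryo"`, or an
#'   immune cell type for secretome networks).
#' @return list of class `BipartiteNetwork` with `receptors`, `ligands`
#'   (connected nodes only) and `edges` (data.frame `receptor`, `ligand`,
#'   `combined_score`, `source`).
#' @export
build_network <- function(compartments, interactions, score_threshold = 0.7,
                          ligand_source = "embryo") {
  rec <- compartments$receptors; lig <- compartments$ligands
  if (length(rec) == 0 && length(lig) == 0)
    abort_val("compartments are empty")
  tab <- as.data.frame(interactions)
  if (nrow(tab) == 0) {
    edges <- data.frame(receptor = character(), ligand = character(),
                        combined_score = numeric(), source = character())
  } else {
    a_rec <- tab$protein_a %in% rec & tab$protein_b %in% lig
    b_rec <- tab$protein_b %in% rec & tab$protein_a %in% lig
    gates <- tab$combined_score >= score_threshold & tab$is_physical &
      tab$receptor_ligand_evidence
    keep <- (a_rec | b_rec) & gates
    edges <- data.frame(
      receptor = ifelse(a_rec[keep], tab$protein_a[keep], tab$protein_b[keep]),
      ligand = ifelse(a_rec[keep], tab$protein_b[keep], tab$protein_a[keep]),
      combined_score = tab$combined_score[keep],
      source = rep(ligand_source, sum(keep)), stringsAsFactors = FALSE)
    edges <- edges[order(edges$receptor, edges$ligand), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(receptors = sort(unique(edges$receptor)),
                 ligands = sort(unique(edges$ligand)),
                 edges = edges),
            class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork: %d receptors, %d ligands, %d edges\n",
              length(x$receptors), length(x$ligands), nrow(x$edges)))
  invisible(x)
}

#' Merge bipartite networks over ligand sources
#'
#' Used to pool per-cell-type secretome networks: edge lists are
#' concatenated (the source tag keeps them distinct) and node sets unioned.
#'
#' @param ... `BipartiteNetwork` objects.
#' @return a `BipartiteNetwork`.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  edges <- edges[order(edges$receptor, edges$ligand, edges$source), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(receptors = sort(unique(edges$receptor)),
                 ligands = sort(unique(edges$ligand)),
                 edges = edges),
            class = "BipartiteNetwork")
}

#' Overlay receptor-side differential expression on a network
#'
#' Counts how many endometrial receptors in the network (optionally
#' restricted to a functional subnetwork) are significantly modulated in
#' the DEG table. Receptors absent from the DEG universe count as
#' non-modulated, with a warning. The percentage is rounded half-up to one
#' decimal place.
#'
#' @param network a [build_network()] result.
#' @param degs a `DegTable`.
#' @param subnetwork_genes optional gene set restricting the receptors
#'   considered (e.g. receptors annotated for tissue remodelling).
#' @param name label for the summary.
#' @return list of class `OverlaySummary`: `name`, `n_receptors_total`,
#'   `n_receptors_modulated`, `percent_modulated`, `receptor_direction`
#'   (named vector `up`/`down`/`none`).
#' @export
overlay_deg <- function(network, degs, subnetwork_genes = NULL,
                        name = "network") {
  rec <- network$receptors
  if (!is.null(subnetwork_genes)) rec <- intersect(rec, subnetwork_genes)
  if (length(rec) == 0)
    abort_val("no receptors left after subnetwork restriction")
  missing <- setdiff(rec, degs$gene_id)
  if (length(missing))
    warning(length(missing), " receptor(s) absent from the DEG table ",
            "counted as non-modulated", call. = FALSE)
  idx <- match(rec, degs$gene_id)
  modulated <- !is.na(idx) & degs$is_significant[idx]
  direction <- rep("none", length(rec))
  direction[modulated] <- degs$direction[idx[modulated]]
  names(direction) <- rec
  overlay_summary(name, length(rec), sum(modulated), direction)
}

#' Overlay ligand-side (secretome) perturbations on a network
#'
#' An endometrial receptor counts as affected when at least one incident
#' edge carries a ligand that is significantly modulated in the DEG table
#' of that edge's source (immune cell type). Edges are annotated with the
#' ligand's direction.
#'
#' @param network a [build_network()] or [merge_networks()] result whose
#'   edges carry source tags.
#' @param ligand_degs named list of `DegTable`s keyed by source tag.
#' @param name label for the summary.
#' @return an `OverlaySummary`; also carries `edge_annotations` (per-edge
#'   `up`/`down`/`none` for the ligand side).
#' @export
overlay_ligand_perturbation <- function(network, ligand_degs,
                                        name = "secretome") {
  edges <- network$edges
  unknown <- setdiff(unique(edges$source), names(ligand_degs))
  if (length(unknown))
    abort_val("no ligand DEG table for source tag(s): ",
              paste(unknown, collapse = ", "))
  edge_dir <- rep("none", nrow(edges))
  for (src in unique(edges$source)) {
    deg <- ligand_degs[[src]]
    sel <- edges$source == src
    idx <- match(edges$ligand[sel], deg$gene_id)
    sig <- !is.na(idx) & deg$is_significant[idx]
    edge_dir[sel][sig] <- deg$direction[idx[sig]]
  }
  affected <- unique(edges$receptor[edge_dir != "none"])
  direction <- rep("none", length(network$receptors))
  names(direction) <- network$receptors
  direction[affected] <- "affected"
  out <- overlay_summary(name, length(network$receptors), length(affected),
                         direction)
  out$edge_annotations <- data.frame(edges[, c("receptor", "ligand", "source")],
                                     ligand_direction = edge_dir,
                                     stringsAsFactors = FALSE)
  out
}

overlay_summary <- function(name, n_total, n_modulated, direction) {
  structure(list(name = name,
                 n_receptors_total = n_total,
                 n_receptors_modulated = n_modulated,
                 percent_modulated = round_half_up(100 * n_modulated / n_total, 1),
                 receptor_direction = direction),
            class = "OverlaySummary")
}

#' @export
print.OverlaySummary <- function(x, ...) {
  cat(sprintf("OverlaySummary '%s': %d of %d receptors modulated (%.1f%%)\n",
              x$name, x$n_receptors_modulated, x$n_receptors_total,
              x$percent_modulated))
  invisible(x)
}

#' Export a network as edge-list TSV and GraphML
#'
#' Edges are written in deterministic (receptor, ligand) lexicographic
#' order; overlay directions, when given, become node attributes.
#'
#' @param network a `BipartiteNetwork`.
#' @param tsv_path,graphml_path output paths (either may be `NULL` to skip).
#' @param overlay optional `OverlaySummary` whose `receptor_direction`
#'   annotates receptor nodes.
#' @return invisibly, the igraph object written.
#' @export
export_network <- function(network, tsv_path = NULL, graphml_path = NULL,
                           overlay = NULL) {
  edges <- network$edges[order(network$edges$receptor, network$edges$ligand), ,
                         drop = FALSE]
  if (!is.null(tsv_path))
    utils::write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  nodes <- data.frame(name = c(network$receptors, network$ligands),
                      side = c(rep("receptor", length(network$receptors)),
                               rep("ligand", length(network$ligands))),
                      stringsAsFactors = FALSE)
  nodes$direction <- "none"
  if (!is.null(overlay)) {
    hit <- match(names(overlay$receptor_direction), nodes$name)
    nodes$direction[hit[!is.na(hit)]] <-
      overlay$receptor_direction[!is.na(hit)]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("receptor", "ligand", "combined_score", "source")],
    directed = FALSE, vertices = nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}
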