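# Orchestration: one validated config drives simulate -> filter -> DE ->
# enrichment -> network -> single-cell -> overlays, with a machine-readable
# run report.

default_run_config <- function() {
  list(
    simulate = TRUE,
    inputs = list(endometrium = NULL, embryo = NULL, groups = NULL,
                  annotation = NULL, interactions = NULL, gene_sets = NULL,
                  category_map = NULL, sc_dir = NULL,
                  reference_broad = NULL, reference_immune = NULL),
    thresholds = list(fc = 2, fdr_de = 0.01, score = 0.7,
                      gsea_fdr = 0.25, nes = 1.5,
                      strength = 0.7, ora_fdr = 0.001),
    de_test = "welch",
    gsea_metric = "signal_to_noise",
    gsea_permutations = 1000,
    gsea_weight_p = 1,
    secretome_types = c("NK", "CD4_T", "CD8_T"),
    min_cells = 10,
    seed = 1L,
    out_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' Loads a YAML file (or takes a list), injects defaults, and rejects
#' unknown keys and non-positive thresholds. An empty file yields the full
#' default configuration, whose thresholds are the analysis gates the
#' pipeline was designed around (FC > 2, FDR < 0.01; score >= 0.7;
#' GSEA FDR < 0.25 with |NES| > 1.5; strength > 0.7 with FDR < 0.001).
#'
#' @param path YAML file path, or `NULL`.
#' @param config list overriding `path` (for programmatic use).
#' @return a validated `RunConfig` list.
#' @export
validate_config <- function(path = NULL, config = NULL) {
  user <- config %||% (if (!is.null(path)) yaml::read_yaml(path) else list())
  user <- user %||% list()
  def <- default_run_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    abort_val("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nested in c("inputs", "thresholds")) {
    if (!is.null(user[[nested]])) {
      bad <- setdiff(names(user[[nested]]), names(def[[nested]]))
      if (length(bad))
        abort_val("unknown config key(s) under ", nested, ": ",
                  paste(bad, collapse = ", "))
      def[[nested]][names(user[[nested]])] <- user[[nested]]
    }
  }
  for (k in setdiff(names(user), c("inputs", "thresholds")))
    def[[k]] <- user[[k]]
  th <- unlist(def$thresholds)
  if (any(!is.finite(th) | th <= 0))
    abort_val("thresholds must be positive: ",
              paste(names(th)[!is.finite(th) | th <= 0], collapse = ", "))
  def$seed <- as.integer(def$seed)
  structure(def, class = "RunConfig")
}

#' Run the full embryo-endometrium interactome pipeline
#'
#' Executes, in dependency order: input simulation (or loading), the
#' dual-criterion expressed-gene filter on both tissues, compartment
#' partitioning, receptor-ligand network assembly, endometrial
#' differential expression with GSEA and network ORA, the single-cell arm
#' (normalization, two-stage typing, proportions, pseudobulk, immune
#' secretome), and both network overlays. Identical config and seed give
#' an identical report (wall-times aside).
#'
#' @param config a [validate_config()] result (or `NULL` for defaults).
#' @param out_dir output directory; overrides the config entry.
#' @return a `RunReport` list: per-stage counts, thresholds, seed, overlay
#'   summaries and wall-times; also written to `out_dir/run_report.json`
#'   along with DEG/network/proportion TSVs.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  config <- config %||% validate_config()
  out_dir <- out_dir %||% config$out_dir %||% tempfile("endotalk_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, thresholds = config$thresholds,
                 stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      abort_val("stage '", name, "' failed: ", conditionMessage(e)))
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  inp <- config$inputs
  if (isTRUE(config$simulate)) {
    bundle <- t_stage("simulate",
                      generate_bundle(file.path(out_dir, "inputs"),
                                      seed = config$seed))
    inp <- bundle[setdiff(names(bundle), "truth_data")]
  } else {
    missing <- names(inp)[vapply(inp, is.null, TRUE)]
    missing <- setdiff(missing, "groups")
    if (length(missing))
      abort_val("missing input path(s): ", paste(missing, collapse = ", "))
    absent <- unlist(inp[!vapply(inp, is.null, TRUE)])
    absent <- absent[!file.exists(absent)]
    if (length(absent))
      abort_val("input file(s) not found: ", paste(absent, collapse = ", "))
  }

  groups_df <- utils::read.delim(inp$groups, colClasses = "character")
  endo <- t_stage("load", {
    m <- read_expression_tsv(inp$endometrium)
    expression_matrix(unclass(m),
                      group_labels = groups_df$group[match(colnames(m),
                                                           groups_df$sample_id)])
  })
  embryo <- read_expression_tsv(inp$embryo)
  ann <- read_annotation_tsv(inp$annotation)
  inter <- read_interaction_tsv(inp$interactions)
  sets <- read_gmt(inp$gene_sets)
  cmap <- read_category_map(inp$category_map)

  expressed_endo <- t_stage("filter_endometrium",
                            filter_expressed(endo, "endometrium"))
  expressed_embryo <- t_stage("filter_embryo",
                              filter_expressed(embryo, "embryo"))
  comp <- t_stage("compartments",
                  partition_compartments(expressed_endo, expressed_embryo, ann))
  net <- t_stage("network",
                 build_network(comp, inter,
                               score_threshold = config$thresholds$score))
  degs <- t_stage("differential_expression",
                  differential_expression(endo,
                                          fc_threshold = config$thresholds$fc,
                                          fdr_threshold = config$thresholds$fdr_de,
                                          test = config$de_test,
                                          seed = child_seed(config$seed, 11)))
  ranked <- rank_genes(endo, metric = config$gsea_metric)
  gsea_res <- t_stage("gsea",
                      gsea(ranked, sets,
                           n_permutations = config$gsea_permutations,
                           weight_p = config$gsea_weight_p,
                           seed = child_seed(config$seed, 12),
                           fdr_threshold = config$thresholds$gsea_fdr,
                           nes_threshold = config$thresholds$nes))
  network_genes <- union(net$receptors, net$ligands)
  ora_res <- t_stage("ora", {
    bg <- union(comp$background, network_genes)
    ora(network_genes, sets, bg,
        strength_threshold = config$thresholds$strength,
        fdr_threshold = config$thresholds$ora_fdr)
  })
  categories <- group_pathways(gsea_res$set_name[gsea_res$passes], cmap)
  overlay_embryo <- t_stage("overlay_deg",
                            overlay_deg(net, degs, name = "embryo_interactome"))

  # single-cell arm
  sc <- t_stage("sc_load",
                read_single_cell(file.path(inp$sc_dir, "matrix.mtx"),
                                 file.path(inp$sc_dir, "cells.tsv"),
                                 file.path(inp$sc_dir, "genes.tsv")))
  ref <- list(broad = unclass(read_expression_tsv(inp$reference_broad)),
              immune = unclass(read_expression_tsv(inp$reference_immune)))
  norm <- t_stage("sc_normalize", sc_normalize(sc))
  assign <- t_stage("sc_annotate", assign_cell_types(norm, ref))
  props <- t_stage("sc_proportions", sc_proportions(assign, norm))
  pb <- t_stage("sc_pseudobulk",
                sc_pseudobulk(norm, assign, min_cells = config$min_cells))
  secretome <- t_stage("sc_secretome",
                       immune_secretome(pb, ann,
                                        types = config$secretome_types,
                                        fc_threshold = config$thresholds$fc,
                                        fdr_threshold = config$thresholds$fdr_de))
  sec_nets <- lapply(names(secretome), function(ty) {
    build_network(list(receptors = comp$receptors,
                       ligands = secretome[[ty]]$gene_id),
                  inter, score_threshold = config$thresholds$score,
                  ligand_source = ty)
  })
  overlay_secretome <- NULL
  if (length(sec_nets)) {
    sec_net <- do.call(merge_networks, sec_nets)
    if (nrow(sec_net$edges) > 0)
      overlay_secretome <- t_stage("overlay_secretome",
                                   overlay_ligand_perturbation(sec_net, secretome))
  }

  # outputs
  write_deg <- function(d, p) utils::write.table(as.data.frame(d), p, sep = "\t",
                                                 quote = FALSE, row.names = FALSE)
  write_deg(degs, file.path(out_dir, "deg_endometrium.tsv"))
  write_deg(gsea_res, file.path(out_dir, "gsea.tsv"))
  write_deg(ora_res, file.path(out_dir, "ora.tsv"))
  write_deg(props, file.path(out_dir, "sc_proportions.tsv"))
  export_network(net, tsv_path = file.path(out_dir, "network_edges.tsv"),
                 graphml_path = file.path(out_dir, "network.graphml"),
                 overlay = overlay_embryo)

  report$counts <- list(
    genes_endometrium = nrow(endo), genes_embryo = nrow(embryo),
    expressed_endometrium = length(expressed_endo$gene_ids),
    expressed_embryo = length(expressed_embryo$gene_ids),
    receptors = length(comp$receptors), ligands = length(comp$ligands),
    decoys = length(comp$decoys),
    network_edges = nrow(net$edges),
    degs_significant = sum(degs$is_significant),
    gsea_sets_passing = sum(gsea_res$passes),
    ora_sets_passing = sum(ora_res$passes),
    cells = length(sc$cell_ids),
    pseudobulk_columns = nrow(pb$meta))
  report$categories <- lapply(categories, as.character)
  strip <- function(ov) if (is.null(ov)) NULL else
    ov[c("name", "n_receptors_total", "n_receptors_modulated", "percent_modulated")]
  report$overlays <- list(embryo = strip(overlay_embryo),
                          secretome = strip(overlay_secretome))
  report$immune_fraction_by_group <- {
    one <- props[!duplicated(props$sample_id), ]
    if (!is.null(one$group))
      as.list(tapply(one$immune_fraction, one$group, mean))
    else NULL
  }
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-24s ok  %7.2fs\n", nm, x$stages[[nm]]$seconds))
  ov <- x$overlays$embryo
  if (!is.null(ov))
    cat(sprintf("  embryo overlay: %d/%d receptors modulated (%.1f%%)\n",
                ov$n_receptors_modulated, ov$n_receptors_total,
                ov$percent_modulated))
  ov <- x$overlays$secretome
  if (!is.null(ov))
    cat(sprintf("  secretome overlay: %d/%d receptors affected (%.1f%%)\n",
                ov$n_receptors_modulated, ov$n_receptors_total,
                ov$percent_modulated))
  invisible(x)
}
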