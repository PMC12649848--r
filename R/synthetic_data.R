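# Seeded generators for every pipeline input, each with a ground-truth
# record so planted effects can be recovered by recomputation from the
# emitted objects alone.

#' Configuration for the bulk expression simulator
#'
#' Defaults emulate the secretory-phase endometrial cohort the pipeline is
#' aimed at: two groups of 12 samples, log-normal noise around a per-gene
#' baseline, and a subset of genes carrying a planted two-fold-squared
#' (|log2 FC| = 2) group effect with directions split evenly.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per condition.
#' @param n_de_genes number of genes carrying the planted effect.
#' @param log2_effect planted |log2 fold change|.
#' @param noise_sd log2-scale standard deviation of the noise.
#' @param baseline_log2_mean_range interval the per-gene log2 baselines are
#'   drawn from uniformly.
#' @param seed integer seed.
#' @return a `BulkSimConfig` list.
#' @export
bulk_sim_config <- function(n_genes = 2000, n_samples_per_group = 12,
                            n_de_genes = 200, log2_effect = 2,
                            noise_sd = 0.5,
                            baseline_log2_mean_range = c(3, 10),
                            seed = 1L) {
  if (n_de_genes > n_genes) abort_val("n_de_genes must be <= n_genes")
  if (noise_sd <= 0) abort_val("noise_sd must be > 0")
  if (log2_effect < 0) abort_val("log2_effect must be >= 0")
  if (length(baseline_log2_mean_range) != 2 ||
      diff(baseline_log2_mean_range) < 0)
    abort_val("baseline_log2_mean_range must be an increasing interval")
  structure(list(n_genes = n_genes, n_samples_per_group = n_samples_per_group,
                 n_de_genes = n_de_genes, log2_effect = log2_effect,
                 noise_sd = noise_sd,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 seed = as.integer(seed)),
            class = "BulkSimConfig")
}

#' Simulate a two-group bulk expression matrix with planted DE genes
#'
#' Linear-scale values are `2^(baseline + group * effect * direction +
#' N(0, noise_sd))`. Exactly `n_de_genes` genes carry the effect, with up /
#' down directions split as evenly as possible. Same seed, same output.
#'
#' @param config a [bulk_sim_config()].
#' @param gene_prefix prefix for generated gene ids.
#' @param groups the two condition labels, in (reference, test) order.
#' @return list with `matrix` (an [expression_matrix()] with group labels)
#'   and `truth` (data.frame of planted gene ids and directions).
#' @export
generate_bulk <- function(config = bulk_sim_config(), gene_prefix = "G",
                          groups = c("control", "endometriosis")) {
  stopifnot(inherits(config, "BulkSimConfig"))
  set.seed(config$seed)
  ng <- config$n_genes; np <- config$n_samples_per_group
  gid <- sprintf("%s%04d", gene_prefix, seq_len(ng))
  sid <- c(sprintf("%s_%02d", groups[1], seq_len(np)),
           sprintf("%s_%02d", groups[2], seq_len(np)))
  grp <- rep(groups, each = np)
  baseline <- stats::runif(ng, config$baseline_log2_mean_range[1],
                           config$baseline_log2_mean_range[2])
  de_idx <- sort(sample.int(ng, config$n_de_genes))
  dir <- integer(ng)
  if (config$n_de_genes > 0) {
    half <- ceiling(config$n_de_genes / 2)
    signs <- sample(c(rep(1L, half), rep(-1L, config$n_de_genes - half)))
    dir[de_idx] <- signs
  }
  log2mu <- outer(baseline, rep(0, 2 * np), `+`)
  log2mu[, grp == groups[2]] <- log2mu[, grp == groups[2]] +
    dir * config$log2_effect
  noise <- matrix(stats::rnorm(ng * 2 * np, 0, config$noise_sd), nrow = ng)
  values <- 2^(log2mu + noise)
  dimnames(values) <- list(gid, sid)
  truth <- data.frame(gene_id = gid[de_idx],
                      direction = c("down", "up")[(dir[de_idx] > 0) + 1L],
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, group_labels = grp), truth = truth)
}

#' Generate a synthetic localization / decoy / evidence annotation
#'
#' Assigns exactly `round(fraction * n)` genes per class: receptors get the
#' `plasma_membrane` tag, secreted genes the `secreted` tag (with an
#' optional overlap carrying both), decoys are drawn from the secreted
#' class only, and everything else is tagged `other`.
#'
#' @param gene_ids gene universe.
#' @param receptor_fraction,secreted_fraction,decoy_fraction class fractions;
#'   `receptor + secreted` must be <= 1 and `decoy <= secreted`.
#' @param overlap_fraction fraction of genes tagged both `plasma_membrane`
#'   and `secreted` (drawn from the receptor class).
#' @param protein_evidence_rate probability a gene has protein-level evidence.
#' @param seed integer seed.
#' @return a [gene_annotation()] table.
#' @export
generate_annotation <- function(gene_ids, receptor_fraction = 0.10,
                                secreted_fraction = 0.20,
                                decoy_fraction = 0.02,
                                overlap_fraction = 0,
                                protein_evidence_rate = 0.9,
                                seed = 1L) {
  fr <- c(receptor_fraction, secreted_fraction, decoy_fraction, overlap_fraction)
  if (any(fr < 0 | fr > 1)) abort_val("fractions must lie in [0, 1]")
  if (receptor_fraction + secreted_fraction > 1)
    abort_val("receptor_fraction + secreted_fraction must be <= 1")
  if (decoy_fraction > secreted_fraction)
    abort_val("decoy_fraction must be <= secreted_fraction")
  set.seed(seed)
  n <- length(gene_ids)
  n_rec <- round(receptor_fraction * n)
  n_sec <- round(secreted_fraction * n)
  n_dec <- round(decoy_fraction * n)
  n_ovl <- min(round(overlap_fraction * n), n_rec)
  perm <- sample(gene_ids)
  receptors <- perm[seq_len(n_rec)]
  secreted <- perm[n_rec + seq_len(n_sec)]
  overlap <- if (n_ovl > 0) receptors[seq_len(n_ovl)] else character()
  decoys <- if (n_dec > 0) secreted[seq_len(n_dec)] else character()
  loc <- lapply(gene_ids, function(g) {
    tags <- character()
    if (g %in% receptors) tags <- c(tags, "plasma_membrane")
    if (g %in% secreted || g %in% overlap) tags <- c(tags, "secreted")
    if (!length(tags)) tags <- "other"
    tags
  })
  gene_annotation(gene_ids, loc,
                  is_decoy = gene_ids %in% decoys,
                  protein_evidence = stats::runif(n) < protein_evidence_rate)
}

#' Generate a synthetic scored interaction table with planted true pairs
#'
#' True receptor-ligand pairs pass all three network gates (score >= 0.7,
#' physical, curated evidence); each noise pair fails at least one gate,
#' chosen uniformly among the three failure modes.
#'
#' @param receptor_ids,ligand_ids node pools.
#' @param n_true_pairs,n_noise_pairs pair counts.
#' @param seed integer seed.
#' @return list with `interactions` (an [interaction_table()]) and `truth`
#'   (data.frame of the planted true pairs).
#' @export
generate_interactions <- function(receptor_ids, ligand_ids,
                                  n_true_pairs = 10, n_noise_pairs = 30,
                                  seed = 1L) {
  capacity <- length(receptor_ids) * length(ligand_ids)
  n_total <- n_true_pairs + n_noise_pairs
  if (n_total > capacity)
    abort_val("requested ", n_total, " pairs but only ", capacity, " distinct pairs exist")
  set.seed(seed)
  pick <- sample.int(capacity, n_total)
  r <- receptor_ids[((pick - 1L) %% length(receptor_ids)) + 1L]
  l <- ligand_ids[((pick - 1L) %/% length(receptor_ids)) + 1L]
  is_true <- c(rep(TRUE, n_true_pairs), rep(FALSE, n_noise_pairs))
  score <- stats::runif(n_total, 0.7, 1)
  physical <- rep(TRUE, n_total)
  evidence <- rep(TRUE, n_total)
  if (n_noise_pairs > 0) {
    mode <- sample.int(3, n_noise_pairs, replace = TRUE)
    ni <- which(!is_true)
    score[ni[mode == 1]] <- stats::runif(sum(mode == 1), 0, 0.699)
    physical[ni[mode == 2]] <- FALSE
    evidence[ni[mode == 3]] <- FALSE
  }
  tab <- interaction_table(r, l, score, physical, evidence)
  truth <- data.frame(receptor = r[is_true], ligand = l[is_true],
                      stringsAsFactors = FALSE)
  list(interactions = tab, truth = truth)
}

#' Generate two-tier synthetic reference expression profiles
#'
#' A stand-in for atlas references used in correlation-based cell typing:
#' a broad tier (non-immune tissue types plus one aggregate `immune`
#' profile) and an immune tier with the five canonical subtypes. Each
#' subtype profile is an independent log-normal vector, so profiles are
#' mutually near-orthogonal and typing consistency is provable under
#' Poisson sampling.
#'
#' @param gene_ids gene universe.
#' @param broad_types non-immune broad type names.
#' @param immune_types immune subtype names.
#' @param seed integer seed.
#' @return list of class `ReferenceProfiles` with matrices `broad` and
#'   `immune` (genes x types); the broad tier contains an `immune` column
#'   equal to the mean of the immune-tier profiles.
#' @export
generate_reference_profiles <- function(gene_ids,
                                        broad_types = c("epithelial", "stromal", "endothelial"),
                                        immune_types = c("B", "CD4_T", "CD8_T",
                                                         "NK", "monocyte_macrophage"),
                                        seed = 1L) {
  set.seed(seed)
  ng <- length(gene_ids)
  draw <- function() 2^stats::rnorm(ng, mean = 4, sd = 2)
  broad <- vapply(broad_types, function(t) draw(), numeric(ng))
  immune <- vapply(immune_types, function(t) draw(), numeric(ng))
  rownames(broad) <- rownames(immune) <- gene_ids
  broad <- cbind(broad, immune = rowMeans(immune))
  structure(list(broad = broad, immune = immune), class = "ReferenceProfiles")
}

#' Configuration for the single-cell simulator
#'
#' Defaults emulate multi-sample secretory-phase endometrial single-cell
#' cohorts with a planted between-group shift in the immune fraction.
#'
#' @param cell_types names of the types cells are drawn from; immune
#'   subtypes must exist in the reference immune tier.
#' @param cells_per_sample cells simulated per sample.
#' @param n_samples_per_group samples per condition.
#' @param immune_fraction_by_group named per-group probability that a cell
#'   is immune.
#' @param depth_mean mean library size (Poisson totals around this depth).
#' @param seed integer seed.
#' @return a `ScSimConfig` list.
#' @export
sc_sim_config <- function(cell_types = c("epithelial", "stromal", "B", "CD4_T",
                                         "CD8_T", "NK", "monocyte_macrophage"),
                          cells_per_sample = 1000,
                          n_samples_per_group = 3,
                          immune_fraction_by_group = c(control = 0.15,
                                                       endometriosis = 0.30),
                          depth_mean = 2000,
                          seed = 1L) {
  if (any(immune_fraction_by_group < 0 | immune_fraction_by_group > 1))
    abort_val("immune fractions must lie in [0, 1]")
  if (cells_per_sample <= 0) abort_val("cells_per_sample must be > 0")
  structure(list(cell_types = cell_types, cells_per_sample = cells_per_sample,
                 n_samples_per_group = n_samples_per_group,
                 immune_fraction_by_group = immune_fraction_by_group,
                 depth_mean = depth_mean, noise_model = "poisson_on_reference",
                 seed = as.integer(seed)),
            class = "ScSimConfig")
}

#' Simulate a multi-sample single-cell dataset from reference profiles
#'
#' Each cell draws a true type (immune with its group's configured
#' probability, the subtype then uniform over the configured immune types;
#' otherwise uniform over non-immune types) and counts from
#' `Poisson(depth * profile / sum(profile))` where `depth` is the
#' configured mean library size. An optional `shift` plants a secretome
#' perturbation: for group-2 cells of the named types, the named genes'
#' profile entries are multiplied by `2^log2_effect`.
#'
#' @param config an [sc_sim_config()].
#' @param reference a [generate_reference_profiles()] object covering all
#'   configured cell types.
#' @param shift optional list with `types`, `gene_ids`, `log2_effect`.
#' @return list with `dataset` (a [single_cell_dataset()]) and `truth`
#'   (data.frame of per-cell true labels plus the shift spec).
#' @export
generate_single_cell <- function(config = sc_sim_config(),
                                 reference, shift = NULL) {
  stopifnot(inherits(config, "ScSimConfig"))
  profiles <- cbind(reference$broad[, setdiff(colnames(reference$broad), "immune"),
                                    drop = FALSE],
                    reference$immune)
  missing <- setdiff(config$cell_types, colnames(profiles))
  if (length(missing))
    abort_val("reference does not cover cell type(s): ", paste(missing, collapse = ", "))
  if (config$depth_mean == 0)
    warning("depth_mean is 0; all counts will be zero", call. = FALSE)
  immune_types <- intersect(config$cell_types, colnames(reference$immune))
  other_types <- setdiff(config$cell_types, immune_types)
  groups <- names(config$immune_fraction_by_group)
  set.seed(config$seed)
  ncell <- config$cells_per_sample
  all_counts <- list(); cell_sample <- character(); true_type <- character()
  sample_groups <- character()
  for (g in groups) {
    for (s in seq_len(config$n_samples_per_group)) {
      sid <- sprintf("%s_s%d", g, s)
      sample_groups[sid] <- g
      imm <- stats::runif(ncell) < config$immune_fraction_by_group[[g]]
      type <- character(ncell)
      type[imm] <- sample(immune_types, sum(imm), replace = TRUE)
      type[!imm] <- sample(other_types, sum(!imm), replace = TRUE)
      prof <- profiles[, type, drop = FALSE]
      if (!is.null(shift) && g == groups[length(groups)]) {
        hit <- type %in% shift$types
        if (any(hit)) {
          rows <- match(shift$gene_ids, rownames(prof))
          prof[rows, hit] <- prof[rows, hit] * 2^shift$log2_effect
        }
      }
      rate <- sweep(prof, 2, colSums(prof), `/`) * config$depth_mean
      cnt <- matrix(stats::rpois(length(rate), rate), nrow = nrow(rate))
      all_counts[[sid]] <- cnt
      cell_sample <- c(cell_sample, rep(sid, ncell))
      true_type <- c(true_type, type)
    }
  }
  counts <- do.call(cbind, all_counts)
  rownames(counts) <- rownames(profiles)
  colnames(counts) <- sprintf("cell_%05d", seq_len(ncol(counts)))
  ds <- single_cell_dataset(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "CsparseMatrix"),
                            cell_sample, sample_groups = sample_groups)
  truth <- data.frame(cell_id = ds$cell_ids, sample_id = cell_sample,
                      true_type = true_type,
                      is_immune = true_type %in% immune_types,
                      stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth, shift = shift)
}

#' Generate a synthetic gene-set collection with planted enriched sets
#'
#' Random sets from the universe plus optional sets concentrated in a
#' designated gene pool (e.g. the top of a ranked list) so enrichment
#' recovery can be tested.
#'
#' @param universe gene universe.
#' @param n_sets number of random background sets.
#' @param set_size genes per set.
#' @param planted optional named list of character vectors appended as-is.
#' @param seed integer seed.
#' @return a `GeneSetCollection`.
#' @export
generate_gene_sets <- function(universe, n_sets = 20, set_size = 50,
                               planted = NULL, seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
  sets <- c(sets, planted)
  attr(sets, "source") <- stats::setNames(rep("synthetic", length(sets)), names(sets))
  class(sets) <- "GeneSetCollection"
  sets
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes every file the pipeline consumes — endometrial and embryo bulk
#' TSVs, annotation and interaction TSVs, gene sets and category map, and a
#' single-cell MTX bundle — into `dir`, together with a ground-truth JSON.
#' One run seed fans out to per-generator child streams.
#'
#' @param dir output directory.
#' @param seed run seed.
#' @param bulk_config,sc_config optional overriding configs.
#' @return named list of paths plus the in-memory truth records, invisibly.
#' @export
generate_bundle <- function(dir, seed = 1L,
                            bulk_config = NULL, sc_config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bulk_config <- bulk_config %||% bulk_sim_config(seed = child_seed(seed, 1))
  endo <- generate_bulk(bulk_config, gene_prefix = "G")
  embryo_cfg <- bulk_sim_config(n_genes = bulk_config$n_genes,
                                n_samples_per_group = 3, n_de_genes = 0,
                                noise_sd = bulk_config$noise_sd,
                                seed = child_seed(seed, 2))
  # day-5 embryo set: one 3-sample condition, no planted effect
  embryo_full <- generate_bulk(embryo_cfg, gene_prefix = "G",
                               groups = c("day5", "day5b"))
  embryo_mat <- expression_matrix(
    unclass(embryo_full$matrix)[, 1:3, drop = FALSE])
  gid <- rownames(endo$matrix)
  ann <- generate_annotation(gid, seed = child_seed(seed, 3))
  receptors <- genes_with_tag(ann, "plasma_membrane")
  secreted <- setdiff(genes_with_tag(ann, "secreted"), ann$gene_id[ann$is_decoy])
  inter <- generate_interactions(receptors, secreted,
                                 n_true_pairs = 40, n_noise_pairs = 120,
                                 seed = child_seed(seed, 4))
  sets <- generate_gene_sets(gid, n_sets = 15, set_size = 50,
                             seed = child_seed(seed, 5))
  ref <- generate_reference_profiles(gid, seed = child_seed(seed, 6))
  sc_config <- sc_config %||% sc_sim_config(seed = child_seed(seed, 7))
  shift_genes <- sample(secreted, min(30, length(secreted)))
  shift <- list(types = c("NK", "CD4_T", "CD8_T"), gene_ids = shift_genes,
                log2_effect = 2)
  sc <- generate_single_cell(sc_config, ref, shift = shift)

  paths <- list(
    endometrium = file.path(dir, "endometrium.tsv"),
    embryo = file.path(dir, "embryo.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    category_map = file.path(dir, "category_map.tsv"),
    groups = file.path(dir, "groups.tsv"),
    sc_dir = file.path(dir, "single_cell"),
    reference_broad = file.path(dir, "reference_broad.tsv"),
    reference_immune = file.path(dir, "reference_immune.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_expression_tsv(endo$matrix, paths$endometrium)
  utils::write.table(data.frame(sample_id = colnames(endo$matrix),
                                group = unname(group_labels(endo$matrix))),
                     paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(embryo_mat, paths$embryo)
  write_annotation_tsv(ann, paths$annotation)
  write_interaction_tsv(inter$interactions, paths$interactions)
  write_gmt(sets, paths$gene_sets)
  utils::write.table(default_category_map(), paths$category_map,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_single_cell(sc$dataset, paths$sc_dir)
  write_expression_tsv(expression_matrix(ref$broad), paths$reference_broad)
  write_expression_tsv(expression_matrix(ref$immune), paths$reference_immune)
  truth <- list(bulk_de = endo$truth, interactions = inter$truth,
                cells = sc$truth, secretome_shift = shift)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth_data = truth)))
}
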