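make_sc <- function(counts, samples, groups = NULL) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(m) <- list(sprintf("G%03d", seq_len(nrow(m))),
                      sprintf("c%03d", seq_len(ncol(m))))
  single_cell_dataset(m, samples, sample_groups = groups)
}

test_that("normalization is depth-invariant and scales to the median total", {
  base <- matrix(rpois(40, 5), nrow = 10)
  counts <- cbind(base[, 1], base[, 1], 2 * base[, 2], base[, 2])
  ds <- make_sc(counts, rep("s1", 4))
  norm <- sc_normalize(ds)
  # identical cells normalize identically; doubled depth washes out
  expect_equal(norm$matrix[, 1], norm$matrix[, 2])
  expect_equal(norm$matrix[, 3], norm$matrix[, 4])
  # per-cell totals after rescaling all equal the median total
  set.seed(5)
  ds2 <- make_sc(matrix(rpois(200, 4), nrow = 20), rep(c("s1", "s2"), each = 5))
  n2 <- sc_normalize(ds2)
  totals <- colSums(2^n2$matrix - 1)
  expect_equal(unname(totals), rep(median(Matrix::colSums(ds2$counts)), 10),
               tolerance = 1e-8)
  # zero-total cells are dropped with a warning; all-zero data errors
  ds3 <- make_sc(cbind(c(1, 2, 0), 0), c("s1", "s1"))
  expect_warning(n3 <- sc_normalize(ds3), "zero total")
  expect_equal(ncol(n3$matrix), 1L)
  expect_error(suppressWarnings(sc_normalize(make_sc(matrix(0, 3, 2), rep("s1", 2)))),
               "zero total")
})

test_that("cells matching a reference profile get that label with high score", {
  gid <- sprintf("G%03d", 1:300)
  ref <- generate_reference_profiles(gid, seed = 2)
  # noiseless cells: counts proportional to the profile itself
  types <- c("epithelial", "stromal", "NK")
  profiles <- cbind(ref$broad[, c("epithelial", "stromal")], ref$immune[, "NK", drop = FALSE])
  counts <- round(sweep(profiles, 2, colSums(profiles), `/`) * 50000)
  ds <- make_sc(counts, rep("s1", 3))
  asg <- assign_cell_types(sc_normalize(ds), ref, n_variable_genes = 300)
  expect_equal(asg$label, types)
  expect_true(all(asg$score > 0.9))
  expect_true(all(is.na(asg$immune_sublabel[1:2])))
  expect_equal(asg$immune_sublabel[3], "NK")
  # shared-gene guard
  expect_error(assign_cell_types(sc_normalize(ds), ref, min_shared_genes = 1000),
               "shared with the reference")
})

test_that("tie between two profiles resolves to the lexicographically first label", {
  gid <- sprintf("G%03d", 1:100)
  set.seed(8)
  p <- 2^rnorm(100, 4, 2)
  ref <- list(broad = cbind(alpha = p, beta = p, zeta = 2^rnorm(100, 4, 2)),
              immune = cbind(B = p, NK = p))
  rownames(ref$broad) <- rownames(ref$immune) <- gid
  class(ref) <- "ReferenceProfiles"
  counts <- matrix(round(p / sum(p) * 20000), ncol = 1)
  ds <- make_sc(counts, "s1")
  asg <- assign_cell_types(sc_normalize(ds), ref, n_variable_genes = 100,
                           immune_label = "zeta")
  expect_equal(asg$broad_label, "alpha")
  expect_equal(asg$delta, 0)
})

test_that("Poisson cells from 5 types are recovered at >= 95% accuracy", {
  gid <- sprintf("G%04d", 1:800)
  ref <- generate_reference_profiles(gid, seed = 12)
  cfg <- sc_sim_config(cell_types = c("epithelial", "stromal", "NK", "CD4_T",
                                      "CD8_T"),
                       cells_per_sample = 500, n_samples_per_group = 1,
                       immune_fraction_by_group = c(a = 0.6, b = 0.6),
                       depth_mean = 2000, seed = 13)
  sim <- generate_single_cell(cfg, ref)
  asg <- assign_cell_types(sc_normalize(sim$dataset), ref)
  expect_gte(mean(asg$label == sim$truth$true_type), 0.95)
})

test_that("proportions sum to one per sample and recover the immune fraction", {
  asg <- data.frame(cell_id = sprintf("c%03d", 1:200),
                    broad_label = rep(c("epithelial", "immune"), c(160, 40)),
                    immune_sublabel = c(rep(NA, 160), rep("NK", 40)),
                    label = rep(c("epithelial", "NK"), c(160, 40)),
                    score = 0.9, delta = 0.5)
  class(asg) <- c("CellTypeAssignment", "data.frame")
  norm <- list(sample_id = setNames(rep("s1", 200), asg$cell_id),
               sample_groups = c(s1 = "ctl"))
  props <- sc_proportions(asg, norm)
  expect_equal(sum(props$proportion), 1)
  expect_equal(unique(props$immune_fraction), 0.2)
  # planted immune fraction recovered within the binomial bound
  gid <- sprintf("G%04d", 1:500)
  ref <- generate_reference_profiles(gid, seed = 22)
  cfg <- sc_sim_config(cells_per_sample = 1000, n_samples_per_group = 1,
                       immune_fraction_by_group = c(ctl = 0.3, dis = 0.3),
                       depth_mean = 1500, seed = 23)
  sim <- generate_single_cell(cfg, ref)
  norm2 <- sc_normalize(sim$dataset)
  asg2 <- assign_cell_types(norm2, ref)
  props2 <- sc_proportions(asg2, norm2)
  per_sample <- props2$immune_fraction[!duplicated(props2$sample_id)]
  expect_true(all(abs(per_sample - 0.3) < 0.05))
})

test_that("pseudobulk equals a brute-force group-by mean and is idempotent", {
  set.seed(33)
  counts <- matrix(rpois(30 * 60, 6), nrow = 30)
  ds <- make_sc(counts, rep(c("s1", "s2"), each = 30),
                groups = c(s1 = "ctl", s2 = "dis"))
  norm <- sc_normalize(ds)
  labels <- rep(rep(c("NK", "CD4_T"), each = 15), 2)
  asg <- data.frame(cell_id = colnames(norm$matrix), broad_label = "immune",
                    immune_sublabel = labels, label = labels,
                    score = 0.9, delta = 0.4)
  class(asg) <- c("CellTypeAssignment", "data.frame")
  pb <- sc_pseudobulk(norm, asg, min_cells = 2)
  for (col in colnames(pb$matrix)) {
    parts <- strsplit(col, "|", fixed = TRUE)[[1]]
    sel <- norm$sample_id[asg$cell_id] == parts[1] & asg$label == parts[2]
    expect_equal(unclass(pb$matrix)[, col],
                 rowMeans(norm$matrix[, sel, drop = FALSE]))
  }
  # identical cells of one type collapse to that cell's vector
  ds_id <- make_sc(cbind(c(3, 1, 4), c(3, 1, 4)), rep("s1", 2))
  norm_id <- sc_normalize(ds_id)
  asg_id <- data.frame(cell_id = colnames(norm_id$matrix),
                       broad_label = "immune", immune_sublabel = "NK",
                       label = "NK", score = 1, delta = 1)
  class(asg_id) <- c("CellTypeAssignment", "data.frame")
  pb_id <- sc_pseudobulk(norm_id, asg_id, min_cells = 1)
  expect_equal(unname(unclass(pb_id$matrix)[, 1]), unname(norm_id$matrix[, 1]))
  # min_cells excludes sparse pairs
  expect_error(sc_pseudobulk(norm_id, asg_id, min_cells = 5), "min_cells")
})

test_that("planted secretome shifts are recovered through the immune secretome", {
  gid <- sprintf("G%04d", 1:600)
  ann <- generate_annotation(gid, receptor_fraction = 0.1,
                             secreted_fraction = 0.3, decoy_fraction = 0,
                             seed = 41)
  secreted <- genes_with_tag(ann, "secreted")
  ref <- generate_reference_profiles(gid, seed = 42)
  shift_genes <- secreted[1:20]
  cfg <- sc_sim_config(cell_types = c("epithelial", "NK", "CD4_T", "CD8_T"),
                       cells_per_sample = 400, n_samples_per_group = 3,
                       immune_fraction_by_group = c(control = 0.5,
                                                    endometriosis = 0.5),
                       depth_mean = 1500, seed = 43)
  sim <- generate_single_cell(cfg, ref,
                              shift = list(types = "NK", gene_ids = shift_genes,
                                           log2_effect = 3))
  norm <- sc_normalize(sim$dataset)
  asg <- assign_cell_types(norm, ref)
  pb <- sc_pseudobulk(norm, asg, min_cells = 10)
  sec <- immune_secretome(pb, ann, types = c("NK", "CD4_T"),
                          groups = c("control", "endometriosis"))
  nk <- sec$NK
  called_up <- nk$gene_id[nk$is_significant & nk$direction == "up"]
  # most planted genes that survive the expressed filter are called up
  planted_tested <- intersect(shift_genes, nk$gene_id)
  expect_gte(length(planted_tested), 5)
  expect_gte(mean(planted_tested %in% called_up), 0.6)
  # unshifted CD4 cells yield no calls
  expect_equal(sum(sec$CD4_T$is_significant), 0)
  # secretome tables contain only secreted genes
  expect_true(all(nk$gene_id %in% secreted))
})
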