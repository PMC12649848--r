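comp_fix <- list(receptors = c("R1", "R2"), ligands = c("L1", "L2"))

tab_fix <- interaction_table(
  c("R1", "R1", "R2", "R2"), c("L1", "L2", "L1", "L2"),
  c(0.9, 0.9, 0.8, 0.65),
  is_physical = c(TRUE, TRUE, FALSE, TRUE),
  receptor_ligand_evidence = c(TRUE, FALSE, TRUE, TRUE))

test_that("the three network gates admit exactly the qualifying pairs", {
  net <- build_network(comp_fix, tab_fix)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$receptor, "R1")
  expect_equal(net$edges$ligand, "L1")
  # only connected nodes remain
  expect_equal(net$receptors, "R1")
  expect_equal(net$ligands, "L1")
  # empty interaction table, empty network
  empty <- build_network(comp_fix, interaction_table(character(), character(),
                                                     numeric(), logical(),
                                                     logical()))
  expect_equal(nrow(empty$edges), 0L)
})

test_that("edge count is monotone non-increasing in the score threshold and gates commute", {
  set.seed(67)
  rec <- sprintf("R%02d", 1:15); lig <- sprintf("L%02d", 1:15)
  tab <- interaction_table(sample(rec, 60, TRUE), sample(lig, 60, TRUE),
                           runif(60), runif(60) > 0.3, runif(60) > 0.3)
  comp <- list(receptors = rec, ligands = lig)
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(build_network(comp, tab, score_threshold = th)$edges), 0)
  expect_true(all(diff(counts) <= 0))
  # score-then-evidence equals evidence-then-score: filter the table first by
  # evidence+physical, then apply only the score gate via build_network
  pre <- tab[tab$is_physical & tab$receptor_ligand_evidence, ]
  class(pre) <- class(tab)
  a <- build_network(comp, tab, score_threshold = 0.5)$edges
  b <- build_network(comp, pre, score_threshold = 0.5)$edges
  expect_equal(a, b)
})

test_that("network on a synthetic table equals the planted true pairs exactly", {
  rec <- sprintf("R%02d", 1:25); lig <- sprintf("L%02d", 1:25)
  out <- generate_interactions(rec, lig, n_true_pairs = 10, n_noise_pairs = 30,
                               seed = 3)
  net <- build_network(list(receptors = rec, ligands = lig), out$interactions)
  got <- paste(net$edges$receptor, net$edges$ligand)
  want <- paste(out$truth$receptor, out$truth$ligand)
  expect_setequal(got, want)
})

test_that("DEG overlay reproduces the printed modulated percentages", {
  make_case <- function(n_mod, n_total) {
    rec <- sprintf("R%03d", seq_len(n_total))
    net <- list(receptors = rec, ligands = "L1",
                edges = data.frame(receptor = rec, ligand = "L1",
                                   combined_score = 0.9, source = "embryo"))
    class(net) <- "BipartiteNetwork"
    degs <- data.frame(gene_id = rec, fold_change = 1, log2_fc = 0,
                       p_value = 1, fdr = 1, direction = "none",
                       is_significant = seq_len(n_total) <= n_mod)
    degs$direction[degs$is_significant] <- "up"
    class(degs) <- c("DegTable", "data.frame")
    overlay_deg(net, degs)
  }
  expect_equal(make_case(13, 43)$percent_modulated, 30.2)
  expect_equal(make_case(18, 44)$percent_modulated, 40.9)
  expect_equal(make_case(29, 44)$percent_modulated, 65.9)
  expect_equal(make_case(0, 10)$percent_modulated, 0.0)
  # receptors missing from the DEG universe count as non-modulated
  case <- make_case(5, 10)
  degs_small <- data.frame(gene_id = sprintf("R%03d", 1:5), fold_change = 3,
                           log2_fc = log2(3), p_value = 0, fdr = 0,
                           direction = "up", is_significant = TRUE)
  net10 <- list(receptors = sprintf("R%03d", 1:10), ligands = "L1",
                edges = data.frame(receptor = sprintf("R%03d", 1:10),
                                   ligand = "L1", combined_score = 0.9,
                                   source = "embryo"))
  class(net10) <- "BipartiteNetwork"
  expect_warning(ov <- overlay_deg(net10, degs_small), "absent")
  expect_equal(ov$n_receptors_modulated, 5L)
  expect_error(overlay_deg(net10, degs_small, subnetwork_genes = "ZZZ"),
               "no receptors")
})

test_that("ligand-side perturbation overlay counts receptors once and keeps edge notes", {
  net <- list(receptors = c("R1", "R2"), ligands = c("L1", "L2"),
              edges = data.frame(receptor = c("R1", "R1", "R2"),
                                 ligand = c("L1", "L2", "L2"),
                                 combined_score = 0.9,
                                 source = c("NK", "NK", "CD4_T")))
  class(net) <- "BipartiteNetwork"
  deg_nk <- data.frame(gene_id = c("L1", "L2"), fold_change = c(4, 0.2),
                       log2_fc = c(2, log2(0.2)), p_value = 0, fdr = 0,
                       direction = c("up", "down"),
                       is_significant = c(TRUE, TRUE))
  deg_cd4 <- data.frame(gene_id = "L2", fold_change = 1, log2_fc = 0,
                        p_value = 1, fdr = 1, direction = "none",
                        is_significant = FALSE)
  ov <- overlay_ligand_perturbation(net, list(NK = deg_nk, CD4_T = deg_cd4))
  # R1 has one up and one down incident ligand: counted once
  expect_equal(ov$n_receptors_modulated, 1L)
  expect_equal(ov$percent_modulated, 50.0)
  ann <- ov$edge_annotations
  expect_equal(ann$ligand_direction[ann$receptor == "R1"], c("up", "down"))
  expect_equal(ann$ligand_direction[ann$receptor == "R2"], "none")
  # unknown source tag errors; no significant ligands -> zero affected
  expect_error(overlay_ligand_perturbation(net, list(NK = deg_nk)), "CD4_T")
  none <- overlay_ligand_perturbation(net, list(NK = deg_cd4, CD4_T = deg_cd4))
  expect_equal(none$n_receptors_modulated, 0L)
})

test_that("half-up one-decimal rounding behaves at the .x5 boundary", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.04999, 1), 2.0)
})

test_that("network exports round-trip through TSV and GraphML", {
  net <- build_network(comp_fix, tab_fix)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  degs <- data.frame(gene_id = "R1", fold_change = 4, log2_fc = 2,
                     p_value = 0, fdr = 0, direction = "up",
                     is_significant = TRUE)
  class(degs) <- c("DegTable", "data.frame")
  ov <- overlay_deg(net, degs)
  export_network(net, tsv_path = tsv, graphml_path = gml, overlay = ov)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$receptor, net$edges$receptor)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(igraph::vertex_attr(g, "direction",
                                   igraph::V(g)[igraph::V(g)$name == "R1"]),
               "up")
})
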