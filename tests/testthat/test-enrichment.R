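test_that("signal-to-noise ranking floors sigma and breaks ties lexicographically", {
  # identical groups: all metrics zero, order is lexicographic
  m <- make_expr(matrix(rep(c(1, 3, 2), 4), nrow = 3),
                 genes = c("gB", "gC", "gA"),
                 groups = rep(c("x", "y"), each = 2))
  r <- rank_genes(m)
  expect_equal(r$metric, rep(0, 3))
  expect_equal(r$gene_id, c("gA", "gB", "gC"))

  # hand computation of the floored formula: log2 means 0 and 2 with zero
  # within-group sd -> floors max(0.2*0, 0.2) = 0.2 and max(0.2*2, 0.2) = 0.4,
  # metric = 2 / 0.6
  m2 <- make_expr(matrix(c(0, 0, 3, 3), nrow = 1), genes = "g1",
                  groups = c("x", "x", "y", "y"))
  expect_equal(rank_genes(m2)$metric, 2 / 0.6, tolerance = 1e-12)

  # planted DE genes occupy extreme ranks
  sim <- generate_bulk(bulk_sim_config(n_genes = 1000, n_de_genes = 100,
                                       seed = 19))
  rk <- rank_genes(sim$matrix)
  up <- sim$truth$gene_id[sim$truth$direction == "up"]
  expect_lte(median(match(up, rk$gene_id)), 100)  # top decile
})

test_that("enrichment score matches worked examples and degenerate cases", {
  r10 <- data.frame(gene_id = paste0("g", 1:10), metric = 10:1)
  expect_equal(gsea_es(r10, "g1", weight_p = 0), 1.0)
  r6 <- data.frame(gene_id = paste0("g", 1:6), metric = 6:1)
  expect_equal(gsea_es(r6, c("g1", "g3"), weight_p = 0), 0.75)
  expect_error(gsea_es(r6, paste0("g", 1:6), 0), "N - k")
  expect_error(gsea_es(r6, "absent", 0), "not represented")
})

test_that("enrichment score agrees with the brute-force running sum", {
  set.seed(91)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:N), metric = metric)
    k <- sample(2:min(30, N - 1), 1)
    hits <- sort(sample.int(N, k))
    set_ids <- ranked$gene_id[hits]
    p <- sample(c(0, 1), 1)
    is_hit <- seq_len(N) %in% hits
    expect_equal(gsea_es(ranked, set_ids, p), oracle_es(metric, is_hit, p),
                 tolerance = 1e-12)
  }
})

test_that("weight_p = 0 score is invariant to monotone metric transforms", {
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       metric = sort(rexp(40), decreasing = TRUE))
  set_ids <- c("g03", "g11", "g25")
  es1 <- gsea_es(ranked, set_ids, weight_p = 0)
  ranked2 <- ranked; ranked2$metric <- ranked$metric^3 + 5
  expect_equal(gsea_es(ranked2, set_ids, weight_p = 0), es1)
})

test_that("gsea recovers a planted set, is calibrated under the null, and is seeded", {
  set.seed(23)
  universe <- sprintf("G%04d", 1:2000)
  metric <- sort(rnorm(2000), decreasing = TRUE)
  ranked <- data.frame(gene_id = universe, metric = metric)
  planted <- list(PLANTED = sample(universe[1:200], 50))
  sets <- c(generate_gene_sets(universe, n_sets = 20, set_size = 50, seed = 6),
            planted, recursive = FALSE)
  class(sets) <- "GeneSetCollection"
  g1 <- gsea(ranked, sets, n_permutations = 500, seed = 10)
  g2 <- gsea(ranked, sets, n_permutations = 500, seed = 10)
  expect_identical(g1$nes, g2$nes)
  expect_true(g1$passes[g1$set_name == "PLANTED"])
  # null calibration: random sets on an unrelated ranked list
  null_rate <- mean(g1$passes[g1$set_name != "PLANTED"])
  expect_lte(null_rate, 0.05)
})

test_that("gsea cross-checks against fgsea on shared score definitions", {
  skip_if_not_installed("fgsea")
  set.seed(37)
  universe <- sprintf("G%03d", 1:300)
  metric <- sort(rnorm(300, sd = 2), decreasing = TRUE)
  ranked <- data.frame(gene_id = universe, metric = metric)
  sets <- list(A = sample(universe, 25), B = sample(universe[1:60], 15))
  ours <- vapply(sets, function(s) gsea_es(ranked, s, weight_p = 1), 0)
  stats <- setNames(metric, universe)
  theirs <- suppressWarnings(
    fgsea::fgsea(sets, stats, minSize = 1, maxSize = 500, nperm = 100))
  expect_equal(unname(ours[theirs$pathway]), theirs$ES, tolerance = 1e-6)
})

test_that("ora matches exhaustive hypergeometric enumeration for N <= 12", {
  for (N in c(8, 10, 12)) {
    bg <- sprintf("g%02d", 1:N)
    for (K in c(2, 4, N %/% 2)) {
      for (n in c(2, 5)) {
        set <- bg[1:K]
        net <- bg[seq(N - n + 1, N)]
        x <- length(intersect(net, set))
        res <- ora(net, list(S = set), bg)
        if (x == 0) {
          expect_equal(res$p_value, 1)
          expect_true(is.na(res$strength))
          expect_false(res$passes)
        } else {
          expect_equal(res$p_value, oracle_hyper_upper(x, K, N, n),
                       tolerance = 1e-12)
          expect_equal(res$strength, log10((x / n) / (K / N)), tolerance = 1e-12)
        }
      }
    }
  }
  # worked example: N=10, K=5, n=5, x=5
  res <- ora(sprintf("g%02d", 1:5), list(S = sprintf("g%02d", 1:5)),
             sprintf("g%02d", 1:10))
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$strength, log10(2), tolerance = 1e-4)
  # network = background: strength 0 everywhere
  bg <- sprintf("g%02d", 1:10)
  res0 <- ora(bg, list(S = bg[1:4]), bg)
  expect_equal(res0$strength, 0)
  expect_error(ora(c(bg, "zz"), list(S = bg), bg), "outside the background")
})

test_that("pathway grouping applies the category map deterministically", {
  map <- data.frame(pathway = c("P1", "P2"),
                    category = c("inflammation", "cell death"))
  out <- group_pathways(c("P1", "P2", "P3"), map)
  expect_equal(out$inflammation, "P1")
  expect_equal(out$`cell death`, "P2")
  expect_equal(out$unassigned, "P3")
  out_empty <- group_pathways(c("P1", "P2"), map[0, ])
  expect_equal(out_empty$unassigned, c("P1", "P2"))
  dup <- data.frame(pathway = c("P1", "P1"), category = c("a", "b"))
  expect_error(group_pathways("P1", dup), "duplicate pathway")
  # shipped map covers the three reported higher-order categories
  expect_setequal(unique(default_category_map()$category),
                  c("inflammation", "stress response", "cell death"))
})
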