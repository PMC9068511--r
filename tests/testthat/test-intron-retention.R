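test_that("retention estimators reproduce the worked arithmetic", {
  expect_equal(retention_rate(10, 100, 200, 1000), 0.5)
  expect_equal(retention_rate(0, 100, 200, 1000), 0)
  expect_equal(retention_rate(c(5, 15), c(50, 150), 100, 500), 0.5)
  expect_equal(junction_rate(20, 30, 50, 200, 1000), 2.5)
  expect_equal(junction_rate(0, 0, 50, 200, 1000), 0)
  expect_error(retention_rate(10, 100, 0, 1000), "C = 0")
  expect_error(junction_rate(5, 5, 50, 0, 1000), "C = 0")
  expect_error(junction_rate(5, 5, 1, 10, 1000), "read_length")
})

test_that("the density estimator is scale-invariant in the counts", {
  r1 <- retention_rate(12, 300, 150, 900)
  r2 <- retention_rate(12 * 7, 300, 150 * 7, 900)
  expect_equal(r1, r2)
})

test_that("undefined rates are flagged, not imputed", {
  models <- gen_gene_models(3, frac_utr_intron = 1, seed = 2)
  truth <- sim_truth(models, 0.5, 0.5)
  reads <- sim_reads(models, truth, depth = 100, seed = 1)
  # drop every read of the first gene so its CDS count is zero
  reads <- reads[reads$gene_id != models[[1]]$gene_id, ]
  rt <- retention_table(count_features(reads, models))
  expect_true(rt$undefined[rt$gene_id == models[[1]]$gene_id])
  expect_true(is.na(rt$r[rt$gene_id == models[[1]]$gene_id]))
  folds <- normalize_to_control(rt, rt)
  expect_false(models[[1]]$gene_id %in% rank_by_fold(folds))
})

test_that("control normalization follows the pseudocount formula", {
  rec <- function(r) data.frame(gene_id = "g1", intron_class = "cds",
                                intron = NA_integer_, method = "density",
                                r = r, undefined = FALSE)
  out <- normalize_to_control(rec(0.4), rec(0.2), pseudocount = 1e-9)
  expect_equal(out$fold, 2, tolerance = 1e-6)
  expect_equal(normalize_to_control(rec(0.37), rec(0.37), pseudocount = 0.05)$fold, 1)
  expect_equal(normalize_to_control(rec(0.1), rec(0), pseudocount = 0.01)$fold, 11)
  ctrl <- rec(0.2); ctrl$gene_id <- "g2"
  expect_error(normalize_to_control(rec(0.4), ctrl, 0.01), "pairing")
})

test_that("gene ranking orders by fold with deterministic tie-breaks", {
  recs <- data.frame(gene_id = c("a", "b", "c"), fold = c(3, 1, 2))
  expect_equal(as.character(rank_by_fold(recs)), c("a", "c", "b"))
  ties <- data.frame(gene_id = c("zz", "aa", "mm"), fold = c(1, 1, 1))
  expect_equal(as.character(rank_by_fold(ties)), c("aa", "mm", "zz"))
  # genes with several records contribute their maximum fold
  multi <- data.frame(gene_id = c("a", "a", "b"), fold = c(1, 5, 3))
  expect_equal(as.character(rank_by_fold(multi)), c("a", "b"))

  set.seed(42)
  folds <- data.frame(gene_id = sprintf("g%03d", 1:100), fold = runif(100))
  got <- as.character(rank_by_fold(folds))
  # selection-sort oracle: repeatedly extract the largest remaining fold
  remaining <- folds
  oracle <- character(0)
  while (nrow(remaining)) {
    top <- remaining[remaining$fold == max(remaining$fold), "gene_id"]
    pick <- sort(top)[1]
    oracle <- c(oracle, pick)
    remaining <- remaining[remaining$gene_id != pick, ]
  }
  expect_equal(got, oracle)
  expect_equal(rank_by_fold(folds[0, ]), character(0))
})

test_that("hypergeometric enrichment matches exact enumeration and Monte Carlo", {
  universe <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrichment(universe, universe[1:5], top_n = 4)
  # all four top genes in a 5-member set: C(5,4)*C(5,0)/C(10,4)
  expect_equal(res$p, choose(5, 4) / choose(10, 4))
  expect_equal(res$k, 4)

  expect_equal(hypergeom_enrichment(universe, character(0), 4)$p, 1)
  expect_error(hypergeom_enrichment(universe, universe[1:2], 11), "top_n")

  # tail probability vs Monte-Carlo draw frequency (N=20, K=8, n=6)
  universe <- sprintf("g%02d", 1:20)
  res <- hypergeom_enrichment(universe, universe[1:8], top_n = 6)
  k_obs <- res$k
  set.seed(9)
  draws <- replicate(1e5, sum(sample(20, 6) <= 8))
  p_mc <- mean(draws >= k_obs)
  se <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(res$p - p_mc), 3 * se + 1e-12)
})

test_that("BH adjustment matches the independent step-up", {
  expect_equal(bh_adjust(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(5)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("junction and density estimators agree on fully retained genes", {
  # long introns keep the block-overlap edge inflation of the density path
  # small, so both estimators target the same coverage ratio
  models <- gen_gene_models(12, frac_utr_intron = 1, seed = 31,
                            intron_len = c(500L, 900L), cds_len = c(500L, 900L))
  truth <- sim_truth(models, 1, 1, abundance = 2)
  reads <- sim_reads(models, truth, depth = 800, seed = 13)
  counts <- count_features(reads, models, read_length = 50)
  ends <- count_intron_end_overlaps(reads, models)
  rd <- retention_table(counts, "density")
  rj <- retention_table(counts, "junction", end_counts = ends)
  expect_lt(abs(mean(rj$r) / mean(rd$r) - 1), 0.15)
  expect_true(all(rj$r / rd$r > 0.6 & rj$r / rd$r < 1.4))
})

test_that("junction and density estimators rank genes concordantly", {
  models <- gen_gene_models(15, frac_utr_intron = 1, seed = 17)
  set.seed(3)
  rho <- seq(0.05, 0.95, length.out = 15)[sample.int(15)]
  truth <- sim_truth(models, rho, rho, abundance = 3)
  reads <- sim_reads(models, truth, depth = 1000, seed = 23)
  counts <- count_features(reads, models, read_length = 50)
  ends <- count_intron_end_overlaps(reads, models)
  rd <- retention_table(counts, "density")
  rj <- retention_table(counts, "junction", end_counts = ends)
  expect_gt(cor(rd$r, rj$r, method = "spearman"), 0.9)
})
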