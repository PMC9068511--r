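test_that("gene model generation honours forced fractions and rejects bad input", {
  m <- gen_gene_models(1, frac_rp = 0, frac_utr_intron = 1, seed = 7)
  expect_length(m, 1)
  expect_equal(nrow(m[[1]]$introns), 1)
  expect_equal(m[[1]]$introns$class, "five_prime_utr")

  expect_error(gen_gene_models(0), "positive")
  expect_error(gen_gene_models(5, frac_rp = 1.2), "frac_rp")
})

test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_gene_models(20, seed = 11), gen_gene_models(20, seed = 11))
  models <- gen_gene_models(5, frac_utr_intron = 1, seed = 1)
  truth <- sim_truth(models, 0.5, 0.5)
  expect_identical(sim_reads(models, truth, depth = 100, seed = 3),
                   sim_reads(models, truth, depth = 100, seed = 3))
  expect_identical(sim_survival(0.1, 0.2, seed = 4), sim_survival(0.1, 0.2, seed = 4))
  g <- gradient_grid(c(0, 1), c(0, 1))
  p <- flow_sim_params(n_cells = 50)
  expect_identical(sim_flow_grid(g, p, seed = 5), sim_flow_grid(g, p, seed = 5))
  expect_identical(sim_growth_curve(0.3, seed = 6), sim_growth_curve(0.3, seed = 6))
})

test_that("generated genes and their intervals never overlap", {
  models <- gen_gene_models(50, frac_both = 0.3, frac_second_cds = 0.5, seed = 1)
  by_chrom <- split(models, vapply(models, `[[`, "", "chrom"))
  for (ms in by_chrom) {
    spans <- t(vapply(ms, `[[`, c(0, 0), "span"))
    if (nrow(spans) > 1) {
      for (i in 1:(nrow(spans) - 1))
        for (j in (i + 1):nrow(spans))
          expect_true(spans[i, 2] <= spans[j, 1] || spans[j, 2] <= spans[i, 1])
    }
  }
  for (m in models) {
    ints <- m$introns
    if (nrow(ints) > 1)
      for (i in 1:(nrow(ints) - 1))
        for (j in (i + 1):nrow(ints))
          expect_true(ints$end[i] <= ints$start[j] || ints$end[j] <= ints$start[i])
    expect_true(all(ints$start >= m$span[1] & ints$end <= m$span[2]))
    expect_true(m$cds[2] > m$cds[1])
  }
})

test_that("read simulation respects the retention truth at the extremes", {
  models <- gen_gene_models(6, frac_utr_intron = 0.5, seed = 2)
  spliced <- sim_reads(models, sim_truth(models, 0, 0), depth = 400, seed = 1)
  fc0 <- count_features(spliced, models)
  expect_true(all(fc0$introns$count == 0))  # no block ever lands in an intron

  retained <- sim_reads(models, sim_truth(models, 1, 1), depth = 400, seed = 1)
  expect_true(all(retained$n_blocks == 1))  # no spliced isoform, no junction gaps
})

test_that("read density over intron vs CDS recovers the simulated retention", {
  rho <- 0.3
  models <- gen_gene_models(1, frac_utr_intron = 1, seed = 5)
  truth <- sim_truth(models, rho, rho, abundance = 2)
  depth <- 1000
  reads <- sim_reads(models, truth, depth = depth, seed = 3)
  counts <- count_features(reads, models)
  rt <- retention_table(counts)
  # closed-form expectations for block-overlap counts, Poisson error bars
  li <- counts$introns$length[1]; lc <- counts$genes$cds_length[1]
  lam_i <- rho * depth * 2 * (li + 49) / 1000
  lam_c <- depth * 2 * (lc + 49) / 1000
  r_expect <- (lam_i / li) / (lam_c / lc)
  tol <- 3 * r_expect * sqrt(1 / lam_i + 1 / lam_c)
  expect_gt(lam_i, 200)
  expect_lt(abs(rt$r[1] - r_expect), tol)
})

test_that("reads are conserved within their source genes", {
  models <- gen_gene_models(10, frac_both = 0.2, seed = 3)
  truth <- sim_truth(models, 0.4, 0.4)
  reads <- sim_reads(models, truth, depth = 150, seed = 9)
  spans <- do.call(rbind, lapply(models, function(m)
    data.frame(gene_id = m$gene_id, chrom = m$chrom, lo = m$span[1],
               hi = m$span[2])))
  merged <- merge(reads, spans, by = "gene_id")
  expect_true(all(merged$chrom.x == merged$chrom.y))
  expect_true(all(merged$start >= merged$lo & merged$end <= merged$hi))
  expect_equal(sum(table(reads$gene_id)), nrow(reads))
})

test_that("flow simulator hits the logistic limits and the analytic median", {
  params <- flow_sim_params(n_cells = 10000)
  g3 <- data.frame(well = c("w1", "w2", "w3"), conc_a = c(0, 0.5, 1),
                   conc_b = c(0, 0.5, 1))
  sim <- sim_flow_grid(g3, params, seed = 2)
  expect_gt(sim$truth$p[1], 0.95)           # median above m_star
  expect_equal(sim$truth$p[2], 0.5)         # median at m_star
  expect_lt(sim$truth$p[3], 0.05)
  # a median far above m_star saturates the high mode
  far <- flow_sim_params(n_cells = 10,
                         dose_response = function(a, b) rep(1000, length(a)))
  expect_gt(sim_flow_grid(g3[1, ], far, seed = 1)$truth$p, 0.99)
  # sample median of the balanced-mixture well vs analytic mixture median,
  # 3 standard errors via the asymptotic density-at-median formula
  vals <- with(sim$cells[sim$cells$well == "w2", ], fitc_h / fsc_h)
  med_an <- sim$truth$m_analytic[2]
  x <- log10(med_an)
  f <- 0.5 * dnorm(x, params$mu_low, params$sigma) +
    0.5 * dnorm(x, params$mu_high, params$sigma)
  se <- 1 / (2 * f * sqrt(length(vals)))
  expect_lt(abs(log10(median(vals)) - x), 3 * se)
  expect_identical(nrow(sim_flow_grid(gradient_grid(numeric(0), numeric(0)),
                                      params)$cells), 0L)
})

test_that("survival simulator matches its Poisson construction", {
  tab <- sim_survival(0.1, 0.1, cfu0 = 100, timepoints = 10,
                      replicates = 1000, seed = 8)
  mu <- 100 * exp(-1)
  expect_lt(abs(mean(tab$colonies[tab$population == "low"]) - mu),
            3 * sqrt(mu / 1000))
  expect_true(all(sim_survival(0.2, 0.3, cfu0 = 0, seed = 1)$colonies == 0))
  expect_error(sim_survival(-0.1, 0.2), "rate_low")
  expect_error(sim_survival(0.1, 0.2, timepoints = numeric(0)), "timepoints")
})

test_that("growth-curve simulator is exactly log-linear without noise", {
  cv <- sim_growth_curve(0.4, od0 = 0.005, capacity = Inf, background = 0,
                         noise_sd = 0, times = seq(0, 10, 0.5))
  slopes <- diff(log(cv$od)) / diff(cv$times)
  expect_equal(slopes, rep(0.4, length(slopes)), tolerance = 1e-10)
  flat <- sim_growth_curve(0, od0 = 0.01, capacity = 1, background = 0.08,
                           noise_sd = 0, times = 0:5)
  expect_equal(flat$od, rep(0.09, 6), tolerance = 1e-12)
  expect_error(sim_growth_curve(0.3, times = c(0, 1, 1)), "increasing")
})
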