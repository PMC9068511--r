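# Seeded end-to-end validation experiments. Each one simulates data with
# known ground truth, runs the corresponding analysis stage, and summarizes
# how well the truth is recovered. The testthat suite asserts on these
# summaries and scripts/acceptance.R reports them.

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Retention-rate recovery across a grid of true retention fractions
#'
#' For every true retention fraction in `rho_grid` and every replicate seed,
#' simulates reads from toy genes carrying a single 5' UTR intron at a depth
#' giving at least ~200 expected intron-overlapping reads per intron at full
#' retention, runs the feature counter and the density estimator, and
#' compares recovery to the truth. The per-simulation estimate is the mean
#' retention over the genes of that simulation (each an independent replicate
#' of the same true fraction); bias and root-mean-square error are taken
#' over the replicate simulations of each grid point.
#'
#' 5' UTR introns are used because their host CDS is uninterrupted: CDS
#' features split by a CDS intron collect junction-edge reads on both chunk
#' boundaries, which deflates the density ratio by roughly
#' `2 (read_length - 1) / L_C` on short toy genes (see the methods
#' vignette).
#'
#' @param rho_grid true retention fractions.
#' @param n_seeds replicate simulations per grid point.
#' @param n_genes genes per simulation (each with exactly one 5' UTR intron).
#' @param depth reads per kb of transcript (see [sim_reads()]).
#' @param read_length read length (bp).
#' @param seed master seed.
#' @return list with `estimates` (data.frame `rho`, `r`; one row per
#'   simulation), `per_rho` (data.frame `rho`, `bias`, `rmse`, `n`), and
#'   `slope`, `intercept` of the estimated-versus-true regression.
#' @export
retention_recovery_experiment <- function(rho_grid = seq(0, 1, by = 0.1),
                                          n_seeds = 20L, n_genes = 20L,
                                          depth = 500, read_length = 50L,
                                          seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 2L * length(rho_grid) * n_seeds),
                  ncol = 2L)
  est <- vector("list", length(rho_grid) * n_seeds)
  cell <- 0L
  for (ri in seq_along(rho_grid)) {
    rho <- rho_grid[ri]
    for (s in seq_len(n_seeds)) {
      cell <- cell + 1L
      models <- gen_gene_models(n_genes, frac_rp = 0, frac_utr_intron = 1,
                                seed = seeds[cell, 1])
      truth <- sim_truth(models, rho_utr = rho, rho_cds = rho, abundance = 1)
      reads <- sim_reads(models, truth, depth = depth,
                         read_length = read_length, seed = seeds[cell, 2])
      counts <- count_features(reads, models, read_length = read_length)
      rt <- retention_table(counts, method = "density")
      est[[cell]] <- data.frame(rho = rho, r = mean(rt$r[!rt$undefined]))
    }
  }
  estimates <- do.call(rbind, est)
  per_rho <- do.call(rbind, lapply(split(estimates, estimates$rho), function(g)
    data.frame(rho = g$rho[1], bias = mean(g$r) - g$rho[1],
               rmse = sqrt(mean((g$r - g$rho[1])^2)), n = nrow(g))))
  rownames(per_rho) <- NULL
  fit <- stats::lm(r ~ rho, data = estimates)
  list(estimates = estimates, per_rho = per_rho,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Fast-versus-naive counting agreement on random instances
#'
#' Generates random gene models and random reads (including multi-block and
#' off-annotation reads), counts them with the interval-index counters and
#' the brute-force reference counters, and reports the fraction of instances
#' in exact agreement for both feature counts and junction-end counts.
#'
#' @param n_instances number of random instances.
#' @param max_reads,max_genes upper bounds on instance size (sizes are drawn
#'   log-uniformly up to these).
#' @param seed master seed.
#' @return list with `agreement` (fraction of instances where both counters
#'   match exactly), `n_instances`, and `sizes` (data.frame of instance
#'   sizes).
#' @export
counting_oracle_experiment <- function(n_instances = 100L, max_reads = 10000L,
                                       max_genes = 40L, seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 2L * n_instances), ncol = 2L)
  ok <- logical(n_instances)
  sizes <- data.frame(n_reads = integer(n_instances),
                      n_features = integer(n_instances))
  for (i in seq_len(n_instances)) {
    n_genes <- with_seed(seeds[i, 1], sample(2:max_genes, 1))
    models <- gen_gene_models(n_genes, frac_rp = 0, frac_utr_intron = 0.5,
                              frac_both = 0.2, seed = seeds[i, 1])
    reads <- random_reads(models, max_reads = max_reads, seed = seeds[i, 2])
    fast <- count_features(reads, models)
    naive <- count_features_naive(reads, models)
    fast_ends <- count_intron_end_overlaps(reads, models)
    naive_ends <- count_intron_end_overlaps_naive(reads, models)
    ok[i] <- identical(fast$genes$cds_count, naive$genes$cds_count) &&
      identical(fast$introns$count, naive$introns$count) &&
      all(fast_ends$n5 == naive_ends$n5) && all(fast_ends$n3 == naive_ends$n3) &&
      fast$n_ignored == naive$n_ignored
    sizes$n_reads[i] <- nrow(reads)
    sizes$n_features[i] <- nrow(fast$introns) + nrow(fast$genes)
  }
  list(agreement = mean(ok), n_instances = n_instances, sizes = sizes)
}

# random reads over (and beyond) a set of gene models: mixture of
# single-block and gapped two-block reads plus some on an unknown chromosome
random_reads <- function(models, max_reads = 10000L, seed = NULL) {
  with_seed(seed, {
    n <- sample(50:max_reads, 1)
    chroms <- unique(vapply(models, `[[`, "", "chrom"))
    extent <- max(vapply(models, function(m) m$span[2], 0)) + 500L
    chrom <- sample(c(chroms, "chrUn"), n, replace = TRUE,
                    prob = c(rep(0.95 / length(chroms), length(chroms)), 0.05))
    start <- sample.int(extent, n, replace = TRUE) - 1L
    len1 <- sample(20:60, n, replace = TRUE)
    two_block <- stats::runif(n) < 0.3
    gap <- sample(50:400, n, replace = TRUE)
    len2 <- sample(20:60, n, replace = TRUE)
    end <- ifelse(two_block, start + len1 + gap + len2, start + len1)
    data.frame(chrom = chrom, start = start, end = as.integer(end),
               name = sprintf("rr%06d", seq_len(n)),
               n_blocks = ifelse(two_block, 2L, 1L),
               block_sizes = ifelse(two_block, paste(len1, len2, sep = ","),
                                    as.character(len1)),
               block_starts = ifelse(two_block, paste(0L, len1 + gap, sep = ","),
                                     "0"),
               stringsAsFactors = FALSE)
  })
}

#' Recovery of the bimodality peak on simulated drug gradients
#'
#' Simulates the full two-drug grid with the bistable-like generator, maps
#' per-well median and trough depth, and checks how close the median of
#' maximal pooled bimodality (`m_peak`) lands to the median at which the
#' generating high-mode fraction crosses 1/2 (`m_star`). Success means
#' landing within one inter-well spacing of the generating median levels.
#'
#' @param n_seeds replicate grids.
#' @param grid_n grid side (default 24, a 24 x 24 gradient).
#' @param n_cells cells per well.
#' @param params [flow_sim_params()] generating parameters (cell count is
#'   overridden by `n_cells`).
#' @param smooth_window,window analysis parameters (histogram smoothing bins;
#'   running-average window).
#' @param seed master seed.
#' @return list with `per_seed` (data.frame `seed`, `m_peak`,
#'   `log10_error`, `success`), `n_success`, `spacing_log10` (inter-well
#'   spacing of the generating analytic medians around the p = 1/2 level,
#'   log10 units).
#' @export
bimodality_recovery_experiment <- function(n_seeds = 20L, grid_n = 24L,
                                           n_cells = 2000L,
                                           params = flow_sim_params(),
                                           smooth_window = 5L, window = 30L,
                                           seed = 1L) {
  params$n_cells <- as.integer(n_cells)
  grid <- gradient_grid(seq(0, 1, length.out = grid_n),
                        seq(0, 1, length.out = grid_n))
  seeds <- derive_seeds(seed, n_seeds)
  # the m axis of the pooled curve is the per-well median expression, so the
  # inter-well spacing is measured on the generating analytic medians: near
  # the p = 1/2 crossing one dose step moves the mixture median across the
  # trough region, i.e. much further than the dose-grid spacing itself
  m_targets <- sort(unique(round(
    params$dose_response(grid$conc_a, grid$conc_b), 9)))
  p_levels <- stats::plogis((log10(m_targets) - log10(params$m_star)) /
                              params$slope)
  lv <- log10(vapply(p_levels, mixture_quantile, 0, params = params))
  target <- log10(mixture_quantile(0.5, params))
  below <- max(lv[lv <= target]); above <- min(lv[lv >= target])
  spacing <- if (above > below) above - below else {
    i <- which.min(abs(lv - target))
    mean(diff(lv[max(1, i - 1):min(length(lv), i + 1)]))
  }
  rows <- lapply(seq_len(n_seeds), function(s) {
    sim <- sim_flow_grid(grid, params, seed = seeds[s])
    map <- grid_bimodality_map(sim$cells, smooth_window = smooth_window,
                               window = window)
    err <- abs(log10(map$m_peak) - target)
    data.frame(seed = seeds[s], m_peak = map$m_peak, log10_error = err,
               success = is.finite(err) && err <= spacing)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, n_success = sum(per_seed$success),
       spacing_log10 = spacing)
}

#' Type-I error calibration of the Poisson-surrogate bootstrap
#'
#' Draws null survival datasets (both populations share the same decay
#' truth), runs the bootstrap test on each, and reports the rejection rate at
#' the requested level.
#'
#' @param n_null number of null datasets.
#' @param n_surrogates surrogates per test.
#' @param alpha nominal level.
#' @param rate shared death rate (per hour).
#' @param cfu0 expected colonies at t = 0.
#' @param seed master seed.
#' @return list with `rejection_rate`, `pvals`, `alpha`, `n_null`.
#' @export
bootstrap_calibration_experiment <- function(n_null = 500L,
                                             n_surrogates = 2000L,
                                             alpha = 0.05, rate = 0.1,
                                             cfu0 = 200, seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 2L * n_null), ncol = 2L)
  pvals <- vapply(seq_len(n_null), function(i) {
    tab <- sim_survival(rate, rate, cfu0 = cfu0, seed = seeds[i, 1])
    poisson_bootstrap_p(tab, n_surrogates = n_surrogates,
                        seed = seeds[i, 2])$p_two_sided
  }, 0)
  list(rejection_rate = mean(pvals <= alpha), pvals = pvals, alpha = alpha,
       n_null = n_null)
}

#' Power of the Poisson-surrogate bootstrap under a strong survival effect
#'
#' The effect simulation: low-expression cells die at 0.05 per hour,
#' high-expression cells at 0.5 per hour, 200 expected colonies at t = 0,
#' four timepoints with two plating replicates.
#'
#' @param n_runs number of simulated experiments.
#' @param n_surrogates surrogates per test.
#' @param p_threshold two-sided significance threshold counted as a
#'   detection.
#' @param seed master seed.
#' @return list with `power`, `pvals`, `n_runs`.
#' @export
bootstrap_power_experiment <- function(n_runs = 100L, n_surrogates = 10000L,
                                       p_threshold = 0.01, seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 2L * n_runs), ncol = 2L)
  pvals <- vapply(seq_len(n_runs), function(i) {
    tab <- sim_survival(0.05, 0.5, cfu0 = 200, timepoints = c(0, 2, 4, 8),
                        replicates = 2L, seed = seeds[i, 1])
    poisson_bootstrap_p(tab, n_surrogates = n_surrogates,
                        seed = seeds[i, 2])$p_two_sided
  }, 0)
  list(power = mean(pvals < p_threshold), pvals = pvals, n_runs = n_runs)
}

#' Growth-rate recovery on noisy logistic curves
#'
#' Simulates plate-reader curves with realistic background, noise and
#' carrying capacity, fits the log-linear window, and reports the error
#' against the generating rate.
#'
#' @param n_seeds replicate curves.
#' @param rate_true generating rate (per hour).
#' @param noise_sd OD measurement noise.
#' @param od_lo,od_hi fitting window on background-corrected OD.
#' @param seed master seed.
#' @return list with `errors` (signed, per curve), `mean_abs_error`,
#'   `rate_true`.
#' @export
growth_recovery_experiment <- function(n_seeds = 20L, rate_true = 0.35,
                                       noise_sd = 0.002, od_lo = 0.02,
                                       od_hi = 0.2, seed = 1L) {
  seeds <- derive_seeds(seed, n_seeds)
  rates <- vapply(seq_len(n_seeds), function(i) {
    cv <- sim_growth_curve(rate_true, noise_sd = noise_sd, seed = seeds[i],
                           well_id = sprintf("w%02d", i))
    fit_growth_rate(cv, od_lo = od_lo, od_hi = od_hi)$rate
  }, 0)
  list(errors = rates - rate_true, mean_abs_error = mean(abs(rates - rate_true)),
       rate_true = rate_true)
}

#' End-to-end enrichment benchmark under a salt-stress-like scenario
#'
#' Ribosomal-protein-labeled genes receive strongly elevated true retention
#' under treatment while background genes shift mildly; the pipeline
#' (simulate, count, estimate, normalize to control, rank, test) must rank
#' the RP set with the smallest adjusted p value among decoy sets of the same
#' size.
#'
#' @param n_runs seeded pipeline runs.
#' @param n_genes genes per run.
#' @param frac_rp fraction of genes labeled RP.
#' @param depth sequencing depth (reads per kb per unit abundance).
#' @param rho_control true retention in the no-drug control (all genes).
#' @param rho_rp,rho_bg treated retention of RP and background genes.
#' @param n_decoys decoy gene sets per run; each is a random set of
#'   background (non-RP) genes of the same size as the RP set, emulating an
#'   unrelated gene category.
#' @param top_frac top-list fraction for the hypergeometric test.
#' @param seed master seed.
#' @return list with `success_rate` (fraction of runs where the RP set has
#'   the strictly smallest adjusted p), `n_runs`, and `per_run` details.
#' @export
enrichment_benchmark <- function(n_runs = 100L, n_genes = 60L, frac_rp = 0.25,
                                 depth = 80, rho_control = 0.02, rho_rp = 0.35,
                                 rho_bg = 0.06, n_decoys = 5L, top_frac = 0.1,
                                 seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 4L * n_runs), ncol = 4L)
  rows <- lapply(seq_len(n_runs), function(i) {
    models <- gen_gene_models(n_genes, frac_rp = frac_rp,
                              frac_utr_intron = 0.5, frac_both = 0.15,
                              seed = seeds[i, 1])
    rp <- vapply(models, function(m) "RP" %in% m$labels, TRUE)
    ids <- vapply(models, `[[`, "", "gene_id")
    rho_trt <- ifelse(rp, rho_rp, rho_bg)
    truth_c <- sim_truth(models, rho_utr = rho_control, rho_cds = rho_control)
    truth_t <- sim_truth(models, rho_utr = rho_trt, rho_cds = rho_trt)
    reads_c <- sim_reads(models, truth_c, depth = depth, seed = seeds[i, 2])
    reads_t <- sim_reads(models, truth_t, depth = depth, seed = seeds[i, 3])
    rt_c <- retention_table(count_features(reads_c, models), "density")
    rt_t <- retention_table(count_features(reads_t, models), "density")
    folds <- normalize_to_control(rt_t, rt_c)
    ranked <- rank_by_fold(folds)
    rp_set <- ids[rp]
    decoys <- with_seed(seeds[i, 4], replicate(n_decoys,
      sample(ids[!rp], length(rp_set)), simplify = FALSE))
    names(decoys) <- sprintf("decoy%d", seq_len(n_decoys))
    sets <- c(list(RP = rp_set), decoys)
    et <- enrichment_table(ranked, sets,
                           top_n = ceiling(length(ranked) * top_frac))
    rp_p <- et$p_adj[et$set_name == "RP"]
    data.frame(run = i, rp_p_adj = rp_p,
               best_decoy_p_adj = min(et$p_adj[et$set_name != "RP"]),
               success = rp_p < min(et$p_adj[et$set_name != "RP"]))
  })
  per_run <- do.call(rbind, rows)
  list(success_rate = mean(per_run$success), n_runs = n_runs,
       per_run = per_run)
}
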