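test_that("fluorescence normalization is a guarded elementwise ratio", {
  expect_equal(as.numeric(normalize_fluorescence(c(2, 4), c(1, 2))), c(2, 2))
  v <- normalize_fluorescence(c(2, 4, 6), c(1, 0, 2))
  expect_equal(as.numeric(v), c(2, 3))
  expect_equal(attr(v, "n_dropped"), 1L)
  expect_equal(as.numeric(normalize_fluorescence(c(2, 4) * 7, c(1, 2) * 7)),
               c(2, 2))
  expect_error(normalize_fluorescence(c(1, 2), c(0, -1)), "empty")
  expect_error(normalize_fluorescence(1:3, 1:2), "equal length")
})

test_that("log-binned histograms follow the fixed layout", {
  h <- histogram_log(rep(1, 500))
  expect_length(h$bin_edges, 101)
  expect_equal(sum(h$rel_counts), 1, tolerance = 1e-12)
  expect_equal(sum(h$rel_counts > 0), 1)  # all mass in one bin

  # values at the midpoints of two adjacent bins split 50/50
  h2 <- histogram_log(rep(c(h$mids[40], h$mids[41]), each = 50))
  expect_equal(h2$rel_counts[40], 0.5)
  expect_equal(h2$rel_counts[41], 0.5)

  h3 <- histogram_log(c(1e-5, 0.5, 2, 1e6, -3))
  expect_equal(h3$n_out_low, 2)  # 1e-5 and the non-positive value
  expect_equal(h3$n_out_high, 1)
  expect_equal(h3$n_in, 2)
  expect_error(histogram_log(c(1e-9, 1e9)), "empty distribution")
})

test_that("histogram frequencies match analytic mixture bin probabilities", {
  params <- flow_sim_params()
  p <- 0.4
  set.seed(11)
  n <- 1e5
  mu <- ifelse(runif(n) < p, params$mu_high, params$mu_low)
  vals <- 10^rnorm(n, mu, params$sigma)
  h <- histogram_log(vals)
  le <- log10(h$bin_edges)
  prob <- (1 - p) * diff(pnorm(le, params$mu_low, params$sigma)) +
    p * diff(pnorm(le, params$mu_high, params$sigma))
  se <- sqrt(prob * (1 - prob) / n)
  # 2/n slack absorbs single stray counts in essentially-zero-probability
  # tail bins, where the binomial band collapses below one count
  expect_true(all(abs(h$rel_counts - prob) <= 3 * se + 2 / n))
})

test_that("trough depth reproduces the definitional arithmetic", {
  expect_equal(trough_depth(c(0.02, 0.10, 0.03, 0.08, 0.01))$d, 0.05)
  expect_equal(trough_depth(c(0.10, 0.06, 0.10))$d, 0.04)
  expect_equal(trough_depth(c(0.01, 0.05, 0.10, 0.05, 0.01))$d, 0)  # unimodal
  expect_equal(trough_depth(sort(runif(30)))$d, 0)                  # monotone
  # degenerate guard: fewer than 3 nonzero bins scores 0 by definition
  expect_equal(trough_depth(c(0, 0.5, 0, 0.5, 0))$d, 0)
  expect_equal(trough_depth(c(0, 0.1, 0))$d, 0)
  sc <- trough_depth(c(0.02, 0.10, 0.03, 0.08, 0.01))
  expect_equal(sc$trough_bin, 3L)
  expect_equal(sc$peak_bins, c(2L, 4L))
})

test_that("trough depth equals the exhaustive triple-scan oracle", {
  set.seed(7)
  for (i in 1:120) {
    n <- sample(5:40, 1)
    f <- runif(n)^sample(1:3, 1)
    f <- f / sum(f)
    expect_equal(trough_depth(f)$d, trough_depth_oracle(f),
                 info = sprintf("case %d", i))
  }
})

test_that("trough depth is zero on random unimodal histograms", {
  set.seed(8)
  for (i in 1:200) {
    f <- random_unimodal(sample(5:60, 1))
    expect_equal(trough_depth(f)$d, 0, info = sprintf("case %d", i))
  }
})

test_that("depth is invariant under raw-count scaling", {
  set.seed(3)
  vals <- 10^c(rnorm(400, -0.5, 0.2), rnorm(600, 0.6, 0.2))
  d1 <- trough_depth(histogram_log(vals))$d
  d3 <- trough_depth(histogram_log(rep(vals, 3)))$d  # tripled counts
  expect_equal(d1, d3)
})

test_that("median and running average behave as defined", {
  expect_equal(median_expression(c(1, 2, 3)), 2)
  expect_equal(median_expression(c(1, 2, 3, 4)), 2.5)
  expect_error(median_expression(numeric(0)), "non-empty")

  expect_equal(running_average(c(5, 1, 9), window = 1), c(5, 1, 9))
  expect_equal(running_average(rep(2.5, 40), window = 30), rep(2.5, 40))
  expect_equal(running_average(1:10, window = 50), rep(5.5, 10))

  # interior of a linear ramp vs direct summation with the same clipping
  d <- seq_len(100)
  got <- running_average(d, window = 30)
  for (i in c(40, 55, 70)) {
    lo <- i - ceiling(29 / 2); hi <- i + floor(29 / 2)
    expect_equal(got[i], mean(d[lo:hi]))
  }
})

test_that("the grid map pools wells order-independently and flags unimodal grids", {
  grid <- gradient_grid(seq(0, 1, length.out = 4), seq(0, 1, length.out = 4))
  sim <- sim_flow_grid(grid, flow_sim_params(n_cells = 400), seed = 5)
  map1 <- grid_bimodality_map(sim$cells)
  perm <- rev(seq_len(nrow(sim$cells)))
  map2 <- grid_bimodality_map(sim$cells[perm, ])
  expect_equal(map1$curve$d_smooth, map2$curve$d_smooth)
  expect_equal(map1$m_peak, map2$m_peak)

  # all wells far above m_star: unimodal high expression everywhere
  uni <- flow_sim_params(n_cells = 400,
                         dose_response = function(a, b) rep(100, length(a)))
  sim_u <- sim_flow_grid(grid, uni, seed = 6)
  map_u <- grid_bimodality_map(sim_u$cells)
  expect_true(all(map_u$per_well$d == 0))
  expect_true(is.na(map_u$m_peak))
})

test_that("depth peaks near a balanced mixture and vanishes at the extremes", {
  params <- flow_sim_params(n_cells = 4000)
  p_grid <- c(0.001, 0.1, 0.3, 0.5, 0.7, 0.9, 0.999)
  set.seed(12)
  d_mean <- vapply(p_grid, function(p) {
    mean(vapply(1:5, function(s) {
      mu <- ifelse(runif(params$n_cells) < p, params$mu_high, params$mu_low)
      vals <- 10^rnorm(params$n_cells, mu, params$sigma)
      trough_depth(histogram_log(vals), smooth_window = 5)$d
    }, 0))
  }, 0)
  expect_equal(which.max(d_mean), which(p_grid == 0.5))
  expect_lt(d_mean[1], 0.1 * d_mean[4])
  expect_lt(d_mean[7], 0.1 * d_mean[4])
})

test_that("the fraction above the analytic trough recovers the mixture weight", {
  params <- flow_sim_params()
  for (p in c(0.2, 0.5, 0.8)) {
    set.seed(round(100 * p))
    n <- 20000
    mu <- ifelse(runif(n) < p, params$mu_high, params$mu_low)
    vals <- 10^rnorm(n, mu, params$sigma)
    thr <- 10^mixture_trough_log10(p, params)
    frac_hi <- mean(vals > thr)
    expect_lt(abs(frac_hi - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
  }
})
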