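make_table <- function(low, high, timepoints = seq_along(low)) {
  do.call(rbind, lapply(seq_along(timepoints), function(i)
    data.frame(population = c("low", "high"), timepoint_h = timepoints[i],
               replicate = 1L, colonies = c(low[i], high[i]))))
}

test_that("the Delta statistic is a plain total difference", {
  tab <- make_table(c(10, 8, 6), c(9, 5, 4))
  expect_equal(delta_statistic(tab), 6)
  expect_equal(delta_statistic(make_table(c(5, 5), c(5, 5))), 0)

  set.seed(2)
  tab2 <- expand.grid(population = c("low", "high"), timepoint_h = c(0, 5, 9),
                      replicate = 1:2, stringsAsFactors = FALSE)
  tab2$colonies <- rpois(nrow(tab2), 40)
  manual <- 0
  for (i in seq_len(nrow(tab2)))
    manual <- manual + ifelse(tab2$population[i] == "low", 1, -1) * tab2$colonies[i]
  expect_equal(delta_statistic(tab2), manual)
  expect_error(delta_statistic(tab2[tab2$population == "low", ]), "both populations")
})

test_that("the Poisson bootstrap pools per-timepoint rates and guards p values", {
  tab <- make_table(c(12, 6), c(8, 2))
  bt <- poisson_bootstrap_p(tab, n_surrogates = 500, seed = 1)
  expect_equal(unname(bt$lambdas), c(10, 4))  # pooled means per timepoint
  expect_gte(bt$p_one_sided, 1 / 501)
  expect_gte(bt$p_two_sided, 1 / 501)

  sym <- make_table(c(5, 5), c(5, 5))
  expect_equal(poisson_bootstrap_p(sym, 200, seed = 2)$p_two_sided, 1)
})

test_that("the bootstrap is label-antisymmetric and bit-reproducible", {
  tab <- sim_survival(0.05, 0.4, cfu0 = 150, seed = 3)
  b1 <- poisson_bootstrap_p(tab, 2000, seed = 11)
  b2 <- poisson_bootstrap_p(tab, 2000, seed = 11)
  expect_identical(b1$p.value, b2$p.value)

  swapped <- tab
  swapped$population <- ifelse(tab$population == "low", "high", "low")
  b3 <- poisson_bootstrap_p(swapped, 2000, seed = 11)
  expect_equal(unname(b3$statistic), -unname(b1$statistic))
  expect_equal(b3$p_two_sided, b1$p_two_sided)
})

test_that("bootstrap type-I error is calibrated and power is high", {
  cal <- bootstrap_calibration_experiment(n_null = 150, n_surrogates = 1000,
                                          seed = 5)
  expect_gt(cal$rejection_rate, 0.02)
  expect_lt(cal$rejection_rate, 0.09)
  pw <- bootstrap_power_experiment(n_runs = 30, n_surrogates = 2000, seed = 6)
  expect_gt(pw$power, 0.9)
})

test_that("the permutation test matches exhaustive enumeration", {
  set.seed(4)
  a <- rbinom(6, 1, 0.3); b <- rbinom(6, 1, 0.7)
  got <- permutation_fraction_test(a, b, n_perm = 20000, seed = 1)$p.value
  pool <- c(a, b)
  splits <- combn(12, 6)
  stat_obs <- mean(b) - mean(a)
  stats_all <- apply(splits, 2, function(idx)
    mean(pool[idx]) - mean(pool[-idx]))
  p_exact <- mean(stats_all >= stat_obs - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(got - p_exact), 3 * se + 1e-4)

  # complete separation attains the add-one lower bound
  sep <- permutation_fraction_test(rep(0, 20), rep(1, 20), n_perm = 999,
                                   seed = 2)
  expect_equal(sep$p.value, 1 / 1000)

  same <- permutation_fraction_test(rep(c(0, 1), 10), rep(c(0, 1), 10),
                                    n_perm = 2000, seed = 3)
  expect_gt(same$p.value, 0.4)
  expect_error(permutation_fraction_test(numeric(0), c(0, 1)), "non-empty")
})

test_that("Mann-Whitney exact enumeration reproduces textbook cases", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), sided = "one")
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 1 / choose(6, 3))
  expect_true(mw$exact)

  same <- mann_whitney_u(c(2, 4, 7), c(2, 4, 7))
  expect_equal(same$p.value, 1)

  # agreement with the standard implementation on tie-free data
  set.seed(8)
  x <- rnorm(7); y <- rnorm(7, 0.8)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("the normal approximation converges to the exact Mann-Whitney p", {
  set.seed(9)
  for (n in c(5, 8, 10)) {
    x <- rnorm(n); y <- rnorm(n, 0.5)
    exact <- mann_whitney_u(x, y)
    expect_true(exact$exact)
    approx_p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact$p.value - approx_p), if (n >= 8) 0.02 else 0.06)
  }
  # above the exact-enumeration guard the approximation takes over and
  # matches the standard implementation
  x <- rnorm(25); y <- rnorm(25, 0.3)
  got <- mann_whitney_u(x, y)
  expect_false(got$exact)
  expect_equal(got$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("the pooled-variance t test handles degenerate inputs", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  deg <- two_sample_t(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)

  set.seed(10)
  x <- rnorm(12); y <- rnorm(12, 0.3)
  got <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(got$statistic), unname(ref$statistic), tolerance = 1e-12)
})

test_that("survival curves summarize replicates with standard errors", {
  tab <- data.frame(population = rep(c("low", "high"), each = 2),
                    timepoint_h = 0, replicate = c(1, 2, 1, 2),
                    colonies = c(10, 14, 7, 7))
  sc <- survival_curve(tab)
  expect_equal(sc$mean_colonies[sc$population == "low"], 12)
  expect_equal(sc$se[sc$population == "low"], 2)

  one <- data.frame(population = c("low", "high"), timepoint_h = 0,
                    replicate = 1, colonies = c(5, 4))
  expect_true(all(is.na(survival_curve(one)$se)))
})

test_that("survival-curve slopes track the simulated death rates", {
  tab <- sim_survival(0.08, 0.5, cfu0 = 5000, timepoints = c(0, 2, 4, 6, 8),
                      replicates = 6, seed = 12)
  sc <- survival_curve(tab)
  for (pop in c("low", "high")) {
    g <- sc[sc$population == pop, ]
    slope <- coef(lm(log(mean_colonies) ~ timepoint_h, data = g))[2]
    truth <- if (pop == "low") -0.08 else -0.5
    expect_lt(abs(slope - truth), 0.03)
  }
})
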