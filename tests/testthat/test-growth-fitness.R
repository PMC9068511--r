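test_that("noiseless exponentials are fitted exactly", {
  cv <- sim_growth_curve(0.4, od0 = 0.005, capacity = Inf, background = 0,
                         noise_sd = 0, times = seq(0, 14, 0.25))
  fit <- fit_growth_rate(cv, od_lo = 0.01, od_hi = 1, background = 0)
  expect_lt(abs(fit$rate - 0.4), 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)

  flat <- growth_curve(0:9, rep(0.08, 10), well_id = "flat")
  expect_error(fit_growth_rate(flat, 0.02, 0.2), "insufficient data.*flat")
})

test_that("the fitted slope is invariant to scaling the corrected OD", {
  cv <- sim_growth_curve(0.3, od0 = 1e-3, capacity = Inf, background = 0,
                         noise_sd = 0, times = seq(0, 18, 0.5))
  f1 <- fit_growth_rate(cv, 0.02, 0.2, background = 0)
  cv5 <- growth_curve(cv$times, cv$od * 5, well_id = "scaled")
  f2 <- fit_growth_rate(cv5, 0.02 * 5, 0.2 * 5, background = 0)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-9)
})

test_that("noisy logistic curves are recovered within 0.02 per hour", {
  res <- growth_recovery_experiment(n_seeds = 20, rate_true = 0.35, seed = 4)
  expect_lt(res$mean_abs_error, 0.02)
})

test_that("the contamination filter discards strictly above threshold", {
  mk <- function(rate, id) structure(list(well_id = id, rate = rate,
                                          window = c(0.02, 0.2),
                                          n_points_used = 10, r_squared = 0.99,
                                          background = 0.08, flagged = FALSE),
                                     class = "rate_fit")
  res <- filter_rates(list(mk(0.3, "a"), mk(0.9, "b"), mk(0.85, "c")))
  expect_equal(vapply(res$kept, `[[`, "", "well_id"), c("a", "c"))
  expect_equal(vapply(res$flagged, `[[`, "", "well_id"), "b")
  expect_equal(res$flagged[[1]]$flag_reason, "contamination")
  empty <- filter_rates(list())
  expect_length(empty$kept, 0)
  expect_length(empty$flagged, 0)
})

test_that("relative growth is a clipped ratio with a guarded reference", {
  expect_equal(relative_growth(0.2, 0.4), 0.5)
  expect_equal(relative_growth(0.4, 0.4), 1)
  expect_equal(relative_growth(-0.05, 0.4), 0)
  expect_error(relative_growth(0.2, 0), "reference")
})

test_that("inhibitory concentrations interpolate linearly", {
  dr <- dose_response(c(0, 10, 20), c(1, 0.5, 0))
  expect_equal(ic_interpolate(dr, 0.5), 10)
  expect_equal(ic_interpolate(dr, 0.75), 5)
  expect_error(ic_interpolate(dr, -0.1), "extrapolate")
})

test_that("noisy Hill curves yield IC50 within 10 percent", {
  hill <- function(c, ic50, h) 1 / (1 + (c / ic50)^h)
  conc <- c(0, 1, 2, 4, 6, 8, 10, 14, 20, 30)
  set.seed(6)
  errs <- vapply(1:10, function(i) {
    rg <- pmax(hill(conc, 8, 2) + rnorm(length(conc), 0, 0.02), 0)
    rg[1] <- 1
    ic_interpolate(dose_response(conc, rg), 0.5)
  }, 0)
  expect_true(all(abs(errs - 8) / 8 < 0.1))
})

test_that("antiparallel gradients mix iso-effective doses linearly", {
  dr_a <- dose_response(c(0, 5, 10, 20), c(1, 0.75, 0.5, 0))
  dr_b <- dose_response(c(0, 1, 2, 4), c(1, 0.75, 0.5, 0))
  des <- design_antiparallel_gradient(dr_a, dr_b, level = 0.5, n_points = 3)
  expect_equal(des$conc_a, c(10, 5, 0))
  expect_equal(des$conc_b, c(0, 1, 2))
  des2 <- design_antiparallel_gradient(dr_a, dr_b, level = 0.5, n_points = 2)
  expect_equal(des2$conc_a, c(10, 0))
  expect_equal(des2$conc_b, c(0, 2))
  # endpoints reproduce the interpolated iso-effective doses exactly
  expect_equal(des$conc_a[1], ic_interpolate(dr_a, 0.5))
  expect_equal(des$conc_b[3], ic_interpolate(dr_b, 0.5))
})

test_that("designed points hold the target inhibition under Loewe additivity", {
  # additive surface: rel growth depends on a/IC50_A + b/IC50_B only
  surface <- function(a, b) 1 / (1 + (a / 12 + b / 3)^2)
  conc_a <- seq(0, 40, length.out = 15)
  conc_b <- seq(0, 10, length.out = 15)
  dr_a <- dose_response(conc_a, surface(conc_a, 0))
  dr_b <- dose_response(conc_b, surface(0, conc_b))
  des <- design_antiparallel_gradient(dr_a, dr_b, level = 0.5, n_points = 24)
  achieved <- surface(des$conc_a, des$conc_b)
  expect_true(all(abs(achieved - 0.5) < 0.05))
})
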