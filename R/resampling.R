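check_survival_table <- function(table) {
  need <- c("population", "timepoint_h", "replicate", "colonies")
  if (!all(need %in% names(table)))
    stop_invalid("invalid table: need columns %s", paste(need, collapse = ", "))
  pops <- unique(table$population)
  if (!setequal(pops, c("low", "high")))
    stop_invalid("invalid table: need both populations \"low\" and \"high\" (got %s)",
                 paste(pops, collapse = ", "))
  if (any(table$colonies < 0) || any(table$colonies != round(table$colonies)))
    stop_invalid("invalid table: colony counts must be non-negative integers")
  tl <- unique(table$timepoint_h[table$population == "low"])
  th <- unique(table$timepoint_h[table$population == "high"])
  if (!setequal(tl, th))
    stop_invalid("invalid table: populations must share the same timepoints")
  invisible(table)
}

#' Total colony-count difference between sorted populations
#'
#' The survival statistic: `Delta` is the difference between the total
#' low-expression and high-expression colony counts summed over all
#' timepoints and replicates.
#'
#' @param table survival table (columns `population` in `{low, high}`,
#'   `timepoint_h`, `replicate`, `colonies`); see [sim_survival()] /
#'   [read_survival_csv()].
#' @return `Delta` (integer-valued).
#' @export
delta_statistic <- function(table) {
  check_survival_table(table)
  sum(table$colonies[table$population == "low"]) -
    sum(table$colonies[table$population == "high"])
}

#' Poisson-surrogate bootstrap test for survival differences
#'
#' Tests the observed `Delta` (see [delta_statistic()]) against the null
#' hypothesis of no difference between the populations. For each timepoint,
#' the null plating rate `lambda_t` is the mean colony count pooled over both
#' populations' replicates (the maximum-likelihood rate under the null). Each
#' of the `n_surrogates` artificial datasets redraws every (population,
#' timepoint, replicate) cell from `Poisson(lambda_t)` and recomputes
#' `Delta*`. P values use the add-one guard:
#' `p_one = (#{Delta* >= Delta_obs} + 1) / (n_surrogates + 1)` and
#' `p_two` analogously with `|Delta*| >= |Delta_obs|`.
#'
#' @param table survival table.
#' @param n_surrogates number of null surrogates (default 10000).
#' @param seed integer seed; results are bit-reproducible given (inputs,
#'   seed, n_surrogates).
#' @param sided `"two"` (default) or `"one"` — which p value `p.value`
#'   reports; both are always returned.
#' @return object of classes `poisson_bootstrap` and `htest`; fields include
#'   `statistic` (`Delta`), `lambdas`, `p.value`, `p_one_sided`,
#'   `p_two_sided`, `n_surrogates`, `seed`.
#' @export
poisson_bootstrap_p <- function(table, n_surrogates = 10000L, seed = NULL,
                                sided = c("two", "one")) {
  sided <- match.arg(sided)
  check_survival_table(table)
  if (n_surrogates < 1) stop_invalid("`n_surrogates` must be >= 1")
  if (!nrow(table)) stop_invalid("invalid table: empty")
  lam_tab <- tapply(table$colonies, table$timepoint_h, mean)
  lambdas <- stats::setNames(as.numeric(lam_tab), names(lam_tab))
  lam_row <- lambdas[as.character(table$timepoint_h)]
  sgn <- ifelse(table$population == "low", 1, -1)
  delta_obs <- sum(sgn * table$colonies)
  nr <- nrow(table)
  delta_star <- with_seed(seed, {
    draws <- matrix(stats::rpois(nr * n_surrogates, lam_row), nrow = nr)
    as.vector(crossprod(sgn, draws))
  })
  p_one <- (sum(delta_star >= delta_obs) + 1) / (n_surrogates + 1)
  p_two <- (sum(abs(delta_star) >= abs(delta_obs)) + 1) / (n_surrogates + 1)
  structure(list(
    statistic = c(Delta = delta_obs),
    p.value = if (sided == "two") p_two else p_one,
    p_one_sided = p_one, p_two_sided = p_two,
    lambdas = lambdas, n_surrogates = as.integer(n_surrogates), seed = seed,
    alternative = if (sided == "two") "two.sided" else "greater",
    method = sprintf("Poisson-surrogate bootstrap (%d surrogates, pooled per-timepoint rates)",
                     as.integer(n_surrogates)),
    data.name = "colony counts by population, timepoint and replicate"),
    class = c("poisson_bootstrap", "htest"))
}

#' One-sided permutation test for a difference in fractions
#'
#' Statistic: `fraction(b) - fraction(a)` of binary outcomes (e.g. the
#' fraction of cells dead after starvation in two strains). Group labels are
#' permuted across the pooled cells; since outcomes are binary, the
#' permutation distribution is sampled exactly via hypergeometric draws of
#' the number of successes landing in group b.
#' `p = (#{stat* >= stat_obs} + 1) / (n_perm + 1)`.
#'
#' @param flags_a,flags_b binary (0/1 or logical) outcome vectors, non-empty.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return object of class `htest` with the observed statistic and one-sided
#'   p value.
#' @export
permutation_fraction_test <- function(flags_a, flags_b, n_perm = 10000L,
                                      seed = NULL) {
  flags_a <- as.numeric(flags_a); flags_b <- as.numeric(flags_b)
  if (!length(flags_a) || !length(flags_b))
    stop_invalid("both groups must be non-empty")
  if (!all(flags_a %in% c(0, 1)) || !all(flags_b %in% c(0, 1)))
    stop_invalid("outcomes must be binary (0/1)")
  na <- length(flags_a); nb <- length(flags_b)
  S <- sum(flags_a) + sum(flags_b)
  stat_obs <- mean(flags_b) - mean(flags_a)
  stat_star <- with_seed(seed, {
    s_b <- stats::rhyper(n_perm, S, na + nb - S, nb)
    s_b / nb - (S - s_b) / na
  })
  p <- (sum(stat_star >= stat_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(
    statistic = c(`fraction(b) - fraction(a)` = stat_obs), p.value = p,
    alternative = "greater", n_perm = as.integer(n_perm), seed = seed,
    method = sprintf("one-sided permutation test (%d label permutations)",
                     as.integer(n_perm)),
    data.name = sprintf("%d vs %d binary outcomes", na, nb)),
    class = "htest")
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `x` value exceeds a `y` value, with half credit
#' for ties. Small samples (`n * m <= 400` and a feasible number of splits)
#' are tested by exact enumeration of all rank assignments, which handles
#' ties correctly; larger samples use the normal approximation with
#' tie-corrected variance and continuity correction. The one-sided
#' alternative is that `x` is stochastically smaller than `y` (small `U`).
#'
#' @param x,y non-empty numeric samples.
#' @param sided `"two"` (default) or `"one"`.
#' @return object of class `htest` with fields `statistic` (`U`), `p.value`,
#'   and `exact` (whether enumeration was used).
#' @export
mann_whitney_u <- function(x, y, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!length(x) || !length(y)) stop_invalid("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_of <- function(rank_sum_x) rank_sum_x - n * (n + 1) / 2
  U <- u_of(sum(r[seq_len(n)]))
  exact <- n * m <= 400 && choose(N, n) <= 2e5
  if (exact) {
    splits <- utils::combn(N, n)
    u_all <- u_of(colSums(matrix(r[splits], nrow = n)))
    p <- if (sided == "one") mean(u_all <= U + 1e-9)
    else mean(abs(u_all - n * m / 2) >= abs(U - n * m / 2) - 1e-9)
  } else {
    ties <- table(r)
    mu <- n * m / 2
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p <- if (sided == "one") stats::pnorm((U - mu + 0.5) / sigma)
    else min(1, 2 * stats::pnorm(-(abs(U - mu) - 0.5) / sigma))
  }
  structure(list(
    statistic = c(U = U), p.value = p, exact = exact,
    alternative = if (sided == "two") "two.sided" else "x stochastically smaller than y",
    method = paste0("Mann-Whitney U test (",
                    if (exact) "exact enumeration" else "tie-corrected normal approximation",
                    ")"),
    data.name = sprintf("x (n = %d) vs y (m = %d)", n, m)),
    class = "htest")
}

#' Pooled-variance two-sample t test
#'
#' Classic two-sample t statistic with pooled variance and
#' `n + m - 2` degrees of freedom, two-sided. Degenerate inputs (zero pooled
#' variance) are handled explicitly: equal means give `p = 1`, unequal means
#' give the `p = 0` limit with a `degenerate` flag instead of an error.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param var_equal if `FALSE`, delegates to the Welch unequal-variance test.
#' @return object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value` and a `degenerate` flag.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop_invalid("both samples must have >= 2 values")
  if (!var_equal) {
    ht <- stats::t.test(x, y)
    ht$degenerate <- FALSE
    return(ht)
  }
  n <- length(x); m <- length(y)
  sp2 <- ((n - 1) * stats::var(x) + (m - 1) * stats::var(y)) / (n + m - 2)
  df <- n + m - 2
  if (sp2 <= 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    t <- if (same) 0 else sign(mean(x) - mean(y)) * Inf
    p <- if (same) 1 else 0
    out <- list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                degenerate = TRUE,
                method = "pooled-variance two-sample t test (degenerate: zero variance)",
                alternative = "two.sided",
                data.name = sprintf("x (n = %d) vs y (m = %d)", n, m))
    return(structure(out, class = "htest"))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n + 1 / m))
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(t), df), degenerate = FALSE,
                 method = "pooled-variance two-sample t test",
                 alternative = "two.sided",
                 data.name = sprintf("x (n = %d) vs y (m = %d)", n, m)),
            class = "htest")
}

#' Survival curves from a colony-count table
#'
#' Replicate means and standard errors per population and timepoint,
#' optionally normalized to the t = 0 mean of each population. Single
#' replicates report a missing standard error.
#'
#' @param table survival table.
#' @param normalize divide each population's means by its t = 0 mean.
#' @return data.frame with columns `population`, `timepoint_h`,
#'   `n_replicates`, `mean_colonies`, `se`.
#' @export
survival_curve <- function(table, normalize = FALSE) {
  check_survival_table(table)
  agg <- do.call(rbind, lapply(split(table, table[c("timepoint_h", "population")],
                                     drop = TRUE), function(g) {
    data.frame(population = g$population[1], timepoint_h = g$timepoint_h[1],
               n_replicates = nrow(g), mean_colonies = mean(g$colonies),
               se = if (nrow(g) > 1) stats::sd(g$colonies) / sqrt(nrow(g)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$population, agg$timepoint_h), ]
  rownames(agg) <- NULL
  if (normalize) {
    for (pop in unique(agg$population)) {
      sel <- agg$population == pop
      t0 <- agg$mean_colonies[sel & agg$timepoint_h == min(agg$timepoint_h[sel])]
      agg$mean_colonies[sel] <- agg$mean_colonies[sel] / t0
      agg$se[sel] <- agg$se[sel] / t0
    }
  }
  agg
}
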