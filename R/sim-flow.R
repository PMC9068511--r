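#' Two-drug gradient grid
#'
#' Builds the well layout of a discretized two-drug gradient: every
#' combination of the supplied concentrations, one well per combination.
#'
#' @param conc_a,conc_b ascending concentration vectors (>= 0) of the two
#'   drugs; the default emulates a 24 x 24 gradient in normalized dose units.
#' @return data.frame with columns `well`, `conc_a`, `conc_b`.
#' @export
gradient_grid <- function(conc_a = seq(0, 1, length.out = 24),
                          conc_b = seq(0, 1, length.out = 24)) {
  if (any(conc_a < 0) || any(conc_b < 0))
    stop_invalid("concentrations must be >= 0")
  g <- expand.grid(col = seq_along(conc_b), row = seq_along(conc_a))
  data.frame(well = sprintf("r%02dc%02d", g$row, g$col),
             conc_a = conc_a[g$row], conc_b = conc_b[g$col],
             stringsAsFactors = FALSE)
}

#' Parameters of the bistable-like flow-cytometry simulator
#'
#' The generator emulates a protein whose single-cell expression is a
#' two-component log-normal mixture. The drug doses set a target median
#' expression `m` through `dose_response`; the fraction of cells in the high
#' mode is a logistic function of `log10(m)` centred at the unstable level
#' `m_star`, so bimodality (both modes populated) peaks exactly where the
#' median crosses `m_star` - the signature of an unstable fixed point between
#' two stable expression states.
#'
#' @param mu_low,mu_high log10 means of the low and high expression modes
#'   (FITC/FSC ratio scale); `mu_low < mu_high`.
#' @param sigma common log10 standard deviation of the modes (> 0).
#' @param m_star median expression of maximal bimodality (ratio scale).
#' @param slope logistic steepness (log10 units) of the high-mode fraction
#'   versus median.
#' @param n_cells cells measured per well (default 10000, one flow-cytometry
#'   acquisition).
#' @param dose_response function `(conc_a, conc_b) -> target median m`;
#'   the default declines log-linearly with mean normalized dose, spanning
#'   `10^0.6` down to `10^-0.6` so that the default grid crosses `m_star = 1`
#'   mid-gradient.
#' @param fsc_meanlog10,fsc_sdlog10 log10 parameters of the independent
#'   forward-scatter (cell size) distribution.
#' @return object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(mu_low = -0.6, mu_high = 0.6, sigma = 0.2,
                            m_star = 1, slope = 0.15, n_cells = 10000L,
                            dose_response = NULL,
                            fsc_meanlog10 = 2, fsc_sdlog10 = 0.08) {
  if (mu_low >= mu_high) stop_invalid("`mu_low` must be < `mu_high`")
  assert_scalar_num(sigma, "sigma", lo = 1e-12)
  assert_scalar_num(m_star, "m_star", lo = 1e-12)
  assert_scalar_num(slope, "slope", lo = 1e-12)
  if (n_cells < 1) stop_invalid("`n_cells` must be >= 1")
  if (is.null(dose_response))
    dose_response <- function(conc_a, conc_b) 10^(0.6 - 1.2 * (conc_a + conc_b) / 2)
  structure(list(mu_low = mu_low, mu_high = mu_high, sigma = sigma,
                 m_star = m_star, slope = slope, n_cells = as.integer(n_cells),
                 dose_response = dose_response,
                 fsc_meanlog10 = fsc_meanlog10, fsc_sdlog10 = fsc_sdlog10),
            class = "flow_sim_params")
}

#' Simulate single-cell fluorescence across a two-drug gradient
#'
#' Per well, the target median `m` comes from `params$dose_response`; the
#' high-mode fraction is `p = plogis((log10(m) - log10(m_star)) / slope)`;
#' cells draw their normalized expression from the two-component log10-normal
#' mixture, an independent log-normal forward scatter (FSC-H) is attached and
#' the recorded FITC-H is expression times FSC-H, so downstream code must
#' redo the FITC/FSC normalization.
#'
#' @param grid well layout from [gradient_grid()] (may be empty).
#' @param params [flow_sim_params()] object.
#' @param seed integer seed.
#' @return list with `cells` (long data.frame: `well`, `conc_a`, `conc_b`,
#'   `fitc_h`, `fsc_h`, one row per cell) and `truth` (per well: target
#'   median `m_target`, high-mode fraction `p`, and the analytic mixture
#'   median `m_analytic` on the normalized scale).
#' @export
sim_flow_grid <- function(grid, params = flow_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "flow_sim_params"))
  if (!nrow(grid))
    return(list(cells = data.frame(well = character(), conc_a = numeric(),
                                   conc_b = numeric(), fitc_h = numeric(),
                                   fsc_h = numeric()),
                truth = data.frame(well = character(), conc_a = numeric(),
                                   conc_b = numeric(), m_target = numeric(),
                                   p = numeric(), m_analytic = numeric())))
  with_seed(seed, {
    m_target <- params$dose_response(grid$conc_a, grid$conc_b)
    p <- stats::plogis((log10(m_target) - log10(params$m_star)) / params$slope)
    n <- params$n_cells
    nw <- nrow(grid)
    high <- stats::rbinom(nw * n, 1L, rep(p, each = n))
    mu <- ifelse(high == 1L, params$mu_high, params$mu_low)
    expr <- 10^stats::rnorm(nw * n, mean = mu, sd = params$sigma)
    fsc <- 10^stats::rnorm(nw * n, mean = params$fsc_meanlog10,
                           sd = params$fsc_sdlog10)
    cells <- data.frame(well = rep(grid$well, each = n),
                        conc_a = rep(grid$conc_a, each = n),
                        conc_b = rep(grid$conc_b, each = n),
                        fitc_h = expr * fsc, fsc_h = fsc,
                        stringsAsFactors = FALSE)
    truth <- data.frame(well = grid$well, conc_a = grid$conc_a,
                        conc_b = grid$conc_b, m_target = m_target, p = p,
                        m_analytic = vapply(p, mixture_quantile, 0,
                                            params = params, q = 0.5),
                        stringsAsFactors = FALSE)
    list(cells = cells, truth = truth)
  })
}

#' Analytic quantile of the generating expression mixture
#'
#' Quantile (on the normalized-expression scale) of the two-component
#' log10-normal mixture with high-mode weight `p`; used as the oracle for
#' median-recovery checks.
#'
#' @param p high-mode fraction in \[0, 1\].
#' @param params [flow_sim_params()] object.
#' @param q quantile level (default 0.5, the median).
#' @return quantile on the ratio scale.
#' @export
mixture_quantile <- function(p, params, q = 0.5) {
  cdf <- function(x) (1 - p) * stats::pnorm(x, params$mu_low, params$sigma) +
    p * stats::pnorm(x, params$mu_high, params$sigma)
  lo <- params$mu_low - 6 * params$sigma
  hi <- params$mu_high + 6 * params$sigma
  10^stats::uniroot(function(x) cdf(x) - q, c(lo, hi), tol = 1e-10)$root
}

#' Analytic trough of the generating expression mixture
#'
#' Location (log10 scale) where the two weighted component densities cross
#' between the modes; the population fraction above this point approximates
#' the high-mode weight `p`.
#'
#' @inheritParams mixture_quantile
#' @return log10 expression at the inter-mode density crossing.
#' @export
mixture_trough_log10 <- function(p, params) {
  if (p <= 0 || p >= 1) stop_invalid("`p` must be strictly inside (0, 1)")
  mid <- (params$mu_low + params$mu_high) / 2
  mid + params$sigma^2 / (params$mu_high - params$mu_low) * log((1 - p) / p)
}
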