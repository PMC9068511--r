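#' Fit an exponential growth rate from an OD curve
#'
#' Ordinary least squares of `log(od - background)` against time, restricted
#' to the log-linear window `od_lo <= od - background <= od_hi`. The slope is
#' the exponential growth rate per hour. The default window (0.02, 0.2)
#' matches corrected plate-reader measurements of dilute cultures; (0.01, 1)
#' is the wider raw-OD window. When `background` is not supplied it is
#' estimated as the mean of the first three readings (the inoculum
#' contributes negligibly next to medium and plate at typical dilutions, and
#' averaging keeps measurement noise out of the estimate).
#'
#' @param curve a `growth_curve` object (see [growth_curve()]).
#' @param od_lo,od_hi background-corrected OD window bounds (`od_lo < od_hi`).
#' @param background scalar background OD; `NULL` to estimate.
#' @return object of class `rate_fit`: list with `well_id`, `rate` (per
#'   hour), `window`, `n_points_used`, `r_squared`, `background`, `flagged`
#'   (contamination flag, set by [filter_rates()]).
#' @export
fit_growth_rate <- function(curve, od_lo = 0.02, od_hi = 0.2,
                            background = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!(od_lo < od_hi)) stop_invalid("`od_lo` must be < `od_hi`")
  if (is.null(background)) background <- mean(curve$od[1:3])
  odc <- curve$od - background
  use <- is.finite(odc) & odc >= od_lo & odc <= od_hi & odc > 0
  if (sum(use) < 2)
    stop_invalid("insufficient data in well %s: %d point(s) inside the (%g, %g) window",
                 curve$well_id, sum(use), od_lo, od_hi)
  fit <- stats::lm.fit(cbind(1, curve$times[use]), log(odc[use]))
  y <- log(odc[use])
  r2 <- if (stats::var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else NA_real_
  structure(list(well_id = curve$well_id, rate = unname(fit$coefficients[2]),
                 window = c(od_lo, od_hi), n_points_used = sum(use),
                 r_squared = r2, background = background, flagged = FALSE),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> well %s: rate %.4g /h (window %g-%g, %d points, R^2 %.3f)%s\n",
              x$well_id, x$rate, x$window[1], x$window[2], x$n_points_used,
              x$r_squared, if (isTRUE(x$flagged)) "  [flagged: contamination]" else ""))
  invisible(x)
}

#' Filter out contaminated wells by growth rate
#'
#' Yeast cannot grow faster than about 0.85 per hour; wells fitting a higher
#' rate are bacterial contaminations and are flagged and discarded. The
#' threshold is strict: a rate exactly equal to `max_rate` is kept.
#'
#' @param fits list of `rate_fit` objects.
#' @param max_rate contamination threshold (per hour).
#' @return list with `kept` and `flagged` (each a list of `rate_fit`; flagged
#'   fits carry `flagged = TRUE` and `flag_reason = "contamination"`).
#' @export
filter_rates <- function(fits, max_rate = 0.85) {
  if (inherits(fits, "rate_fit")) fits <- list(fits)
  rates <- vapply(fits, `[[`, 0, "rate")
  bad <- rates > max_rate
  flagged <- lapply(fits[bad], function(f) {
    f$flagged <- TRUE
    f$flag_reason <- "contamination"
    f
  })
  list(kept = fits[!bad], flagged = flagged)
}

#' Growth rate relative to an unperturbed reference
#'
#' @param fit a `rate_fit` (or bare rate).
#' @param reference reference `rate_fit` (or bare rate); must be positive.
#' @return `fit.rate / reference.rate`, clipped below at 0.
#' @export
relative_growth <- function(fit, reference) {
  r <- if (inherits(fit, "rate_fit")) fit$rate else fit
  r0 <- if (inherits(reference, "rate_fit")) reference$rate else reference
  if (!is.finite(r0) || r0 <= 0)
    stop_invalid("invalid reference: rate must be positive (got %g)", r0)
  max(r / r0, 0)
}

#' Dose-response curve container
#'
#' Relative growth (fraction of the drug-free rate) over an ascending
#' concentration series. Values are renormalized to the zero-concentration
#' entry so that `relative_growth(0) = 1` by construction.
#'
#' @param concentrations ascending, first entry 0 (the drug-free reference).
#' @param rel_growth growth rates relative to drug-free, same length.
#' @param drug_id label.
#' @return object of class `dose_response`.
#' @export
dose_response <- function(concentrations, rel_growth, drug_id = "drug") {
  if (length(concentrations) != length(rel_growth) || length(concentrations) < 2)
    stop_invalid("need >= 2 matching (concentration, relative growth) points")
  if (any(diff(concentrations) <= 0) || concentrations[1] != 0)
    stop_invalid("`concentrations` must be strictly ascending starting at 0")
  if (rel_growth[1] <= 0)
    stop_invalid("drug-free relative growth must be positive")
  structure(list(drug_id = drug_id, concentrations = as.numeric(concentrations),
                 rel_growth = as.numeric(rel_growth / rel_growth[1])),
            class = "dose_response")
}

#' Interpolate an inhibitory concentration from a dose-response curve
#'
#' Finds the concentration at which relative growth equals `level` (e.g.
#' `level = 0.5` gives the IC50, the half-maximal inhibitory concentration).
#' The curve is first made monotone non-increasing by pool-adjacent-violators
#' (measurement noise can break monotonicity), then linearly interpolated.
#'
#' @param dr a `dose_response` object.
#' @param level target relative growth, inside the observed range.
#' @return interpolated concentration.
#' @export
ic_interpolate <- function(dr, level) {
  stopifnot(inherits(dr, "dose_response"))
  rg <- -stats::isoreg(dr$concentrations, -dr$rel_growth)$yf  # non-increasing
  if (level > max(rg) || level < min(rg))
    stop_invalid("level %g outside the observed relative-growth range [%g, %g]: cannot extrapolate",
                 level, min(rg), max(rg))
  i <- which(rg <= level)[1]  # first point at or below the target level
  if (rg[i] == level) return(dr$concentrations[i])
  # bracket [i-1, i] with rg[i-1] > level > rg[i]
  x0 <- dr$concentrations[i - 1L]; x1 <- dr$concentrations[i]
  y0 <- rg[i - 1L]; y1 <- rg[i]
  x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
}

#' Design an antiparallel two-drug isogrowth gradient
#'
#' Builds `n_points` drug combinations running from the single-drug
#' iso-effective dose of drug A to that of drug B while nominally keeping the
#' overall inhibition constant: point `i` mixes
#' `conc_a = ICA * (1 - i/(n-1))` with `conc_b = ICB * i/(n-1)`, where `ICA`
#' and `ICB` are interpolated at the target `level`. Under Loewe additivity
#' every designed point sits on the iso-effect line of the two drugs.
#'
#' @param dr_a,dr_b `dose_response` curves of the two drugs.
#' @param level target relative growth held constant along the gradient
#'   (default 0.5, a 50%-inhibition isobole).
#' @param n_points number of gradient points (>= 2).
#' @return data.frame with columns `point`, `conc_a`, `conc_b`.
#' @export
design_antiparallel_gradient <- function(dr_a, dr_b, level = 0.5, n_points = 24L) {
  if (n_points < 2) stop_invalid("`n_points` must be >= 2")
  ica <- ic_interpolate(dr_a, level)
  icb <- ic_interpolate(dr_b, level)
  frac <- (seq_len(n_points) - 1) / (n_points - 1)
  data.frame(point = seq_len(n_points), conc_a = ica * (1 - frac),
             conc_b = icb * frac)
}
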