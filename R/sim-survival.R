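#' Simulate a colony-count survival assay
#'
#' Two sorted populations ("low" and "high" reporter expression) starve and
#' die exponentially; at each sampling timepoint an aliquot is plated and the
#' colony-forming units are counted. Plating noise is Poisson:
#' `colonies ~ Poisson(cfu0 * exp(-rate_pop * t))` independently per
#' population, timepoint and replicate.
#'
#' @param rate_low,rate_high exponential death rates (per hour, >= 0) of the
#'   two populations.
#' @param cfu0 expected colony count at t = 0 (>= 0).
#' @param timepoints sampling times in hours (non-empty).
#' @param replicates plated replicates per timepoint (>= 1; default 2 plates).
#' @param seed integer seed.
#' @return `survival_table`: data.frame with columns `population`
#'   (`"low"`/`"high"`), `timepoint_h`, `replicate`, `colonies`.
#' @export
sim_survival <- function(rate_low, rate_high, cfu0 = 200,
                         timepoints = c(0, 4, 8, 24), replicates = 2L,
                         seed = NULL) {
  assert_scalar_num(rate_low, "rate_low", lo = 0)
  assert_scalar_num(rate_high, "rate_high", lo = 0)
  assert_scalar_num(cfu0, "cfu0", lo = 0)
  if (!length(timepoints)) stop_invalid("`timepoints` must be non-empty")
  if (replicates < 1) stop_invalid("`replicates` must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates), timepoint_h = timepoints,
                      population = c("low", "high"), stringsAsFactors = FALSE)
  rate <- ifelse(grid$population == "low", rate_low, rate_high)
  lambda <- cfu0 * exp(-rate * grid$timepoint_h)
  out <- with_seed(seed, {
    grid$colonies <- stats::rpois(nrow(grid), lambda)
    grid
  })
  structure(out[, c("population", "timepoint_h", "replicate", "colonies")],
            class = c("survival_table", "data.frame"))
}

#' Simulate an optical-density growth curve
#'
#' Logistic growth trajectory plus a constant background offset and i.i.d.
#' Gaussian measurement noise:
#' `od(t) = background + K * od0 * exp(r t) / (K + od0 * (exp(r t) - 1)) + noise`.
#' With `capacity = Inf` the trajectory is a pure exponential. The generating
#' rate is recorded on the returned object.
#'
#' @param rate_true true exponential rate (per hour).
#' @param od0 inoculum optical density (must be < `capacity`).
#' @param capacity carrying capacity (OD units; may be `Inf`).
#' @param background constant OD offset (medium + plate).
#' @param noise_sd standard deviation of additive measurement noise.
#' @param times measurement times in hours, strictly increasing (default a
#'   24 h run read every 20 min).
#' @param seed integer seed.
#' @param well_id well label.
#' @return `growth_curve` object: list with `well_id`, `times`, `od`, and
#'   recorded truth `rate_true`, `background_true`.
#' @export
sim_growth_curve <- function(rate_true, od0 = 5e-4, capacity = 1.8,
                             background = 0.08, noise_sd = 0.002,
                             times = seq(0, 24, by = 1 / 3), seed = NULL,
                             well_id = "w1") {
  if (any(diff(times) <= 0) || length(times) < 3)
    stop_invalid("`times` must be strictly increasing with >= 3 points")
  if (!(od0 < capacity)) stop_invalid("`od0` must be < `capacity`")
  growth <- if (is.infinite(capacity)) od0 * exp(rate_true * times)
  else capacity * od0 * exp(rate_true * times) /
    (capacity + od0 * (exp(rate_true * times) - 1))
  od <- with_seed(seed,
    growth + background + stats::rnorm(length(times), 0, noise_sd))
  growth_curve(times, od, well_id = well_id, rate_true = rate_true,
               background_true = background)
}

#' Construct a growth curve object
#'
#' @param times hours, strictly increasing, at least 3 points.
#' @param od raw optical density readings (same length as `times`).
#' @param well_id well label.
#' @param rate_true,background_true optional recorded simulation truth.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, well_id = "w1", rate_true = NA_real_,
                         background_true = NA_real_) {
  if (length(times) != length(od) || length(times) < 3)
    stop_invalid("`times` and `od` must have equal length >= 3")
  if (any(diff(times) <= 0)) stop_invalid("`times` must be strictly increasing")
  structure(list(well_id = well_id, times = as.numeric(times),
                 od = as.numeric(od), rate_true = rate_true,
                 background_true = background_true),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s: %d readings over %.1f h, OD %.3g-%.3g\n",
              x$well_id, length(x$times), diff(range(x$times)), min(x$od),
              max(x$od)))
  if (!is.na(x$rate_true))
    cat(sprintf("  simulated truth: rate %.3g /h\n", x$rate_true))
  invisible(x)
}
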