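#' Normalize fluorescence by forward scatter
#'
#' Cell-wise ratio of green fluorescence (FITC-H) to forward scatter (FSC-H),
#' removing cell-size variation. Cells with non-positive forward scatter are
#' dropped and tallied in the `"n_dropped"` attribute.
#'
#' @param fitc,fsc per-cell channel values of equal length.
#' @return numeric vector of normalized expression values with attribute
#'   `n_dropped`.
#' @export
normalize_fluorescence <- function(fitc, fsc) {
  if (length(fitc) != length(fsc))
    stop_invalid("`fitc` and `fsc` must have equal length")
  keep <- is.finite(fsc) & fsc > 0 & is.finite(fitc)
  if (!any(keep))
    stop_invalid("empty distribution: all cells dropped (non-positive FSC)")
  structure(fitc[keep] / fsc[keep], n_dropped = sum(!keep))
}

#' Log-binned relative-frequency expression histogram
#'
#' Relative counts in `n_bins` bins spaced logarithmically between `lo` and
#' `hi` (default 100 bins from 1e-3 to 1e5). Bins are left-closed,
#' right-open, except the last which is closed. Non-positive or out-of-range
#' values are excluded from the frequencies but tallied, so tail peaks are
#' never silently clipped into the range. Frequencies are normalized by the
#' in-range total.
#'
#' @param values positive expression values (e.g. from
#'   [normalize_fluorescence()]).
#' @param n_bins number of bins.
#' @param lo,hi histogram range.
#' @return object of class `expr_histogram`: list with `bin_edges`
#'   (`n_bins + 1` values), `mids` (geometric bin midpoints), `rel_counts`,
#'   `n_in`, `n_out_low`, `n_out_high`.
#' @export
histogram_log <- function(values, n_bins = 100L, lo = 1e-3, hi = 1e5) {
  stopifnot(n_bins >= 1, lo > 0, hi > lo)
  llo <- log10(lo); lhi <- log10(hi)
  w <- (lhi - llo) / n_bins
  pos <- is.finite(values) & values > 0
  lv <- log10(values[pos])
  out_low <- sum(!pos) + sum(lv < llo)
  out_high <- sum(lv > lhi)
  lv <- lv[lv >= llo & lv <= lhi]
  if (!length(lv))
    stop_invalid("empty distribution: no values inside [%g, %g]", lo, hi)
  idx <- pmin(floor((lv - llo) / w) + 1L, n_bins)  # right edge closes last bin
  counts <- tabulate(idx, nbins = n_bins)
  edges <- 10^seq(llo, lhi, length.out = n_bins + 1L)
  structure(list(bin_edges = edges,
                 mids = 10^(llo + (seq_len(n_bins) - 0.5) * w),
                 rel_counts = counts / length(lv),
                 n_in = length(lv), n_out_low = out_low, n_out_high = out_high),
            class = "expr_histogram")
}

#' @export
print.expr_histogram <- function(x, ...) {
  cat(sprintf("<expr_histogram> %d bins over [%g, %g]; %d cells in range (%d below, %d above)\n",
              length(x$rel_counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n_in, x$n_out_low,
              x$n_out_high))
  invisible(x)
}

#' Bimodality as histogram trough depth
#'
#' Quantifies bimodality as the depth of the trough separating two histogram
#' peaks: the y-axis distance between the trough and the lower of its two
#' flanking peaks. Operationally this is the prominence of the peak obtained
#' by inverting the (optionally smoothed) histogram: for every interior local
#' maximum of the inverted series,
#' `depth = min(highest peak left, highest peak right) - trough height`,
#' and the score is the maximum depth over candidate troughs. Unimodal or
#' monotone histograms score exactly zero.
#'
#' Smoothing (centered moving average over `smooth_window` bins) suppresses
#' single-bin noise troughs; `smooth_window = 1` is the raw definitional
#' path, and all reported heights refer to the series the troughs were found
#' on.
#'
#' @param hist an `expr_histogram`, or a bare numeric vector of relative
#'   frequencies.
#' @param smooth_window moving-average width in bins (>= 1; 1 = no
#'   smoothing).
#' @return object of class `bimodality_score`: list with `d` (depth, relative
#'   frequency units), `trough_bin`, `peak_bins` (length-2), all index fields
#'   `NA` when `d = 0`.
#' @export
#' @examples
#' trough_depth(c(0.02, 0.10, 0.03, 0.08, 0.01))$d  # 0.05
trough_depth <- function(hist, smooth_window = 1L) {
  f <- if (inherits(hist, "expr_histogram")) hist$rel_counts else as.numeric(hist)
  if (smooth_window < 1) stop_invalid("`smooth_window` must be >= 1")
  if (sum(f > 0) < 3)
    return(structure(list(d = 0, trough_bin = NA_integer_,
                          peak_bins = c(NA_integer_, NA_integer_)),
                     class = "bimodality_score"))
  fs <- moving_average(f, smooth_window)
  n <- length(fs)
  # prefix/suffix maxima give, for every interior bin, the highest peak on
  # each side; depth at j = min(left, right) - fs[j]
  left_max <- cummax(fs)
  right_max <- rev(cummax(rev(fs)))
  j <- 2:(n - 1L)
  depth <- pmin(left_max[j - 1L], right_max[j + 1L]) - fs[j]
  d <- max(depth, 0)
  if (d <= 0)
    return(structure(list(d = 0, trough_bin = NA_integer_,
                          peak_bins = c(NA_integer_, NA_integer_)),
                     class = "bimodality_score"))
  tb <- j[which.max(depth)]
  pk_left <- which.max(fs[1:(tb - 1L)])
  pk_right <- tb + which.max(fs[(tb + 1L):n])
  structure(list(d = d, trough_bin = tb, peak_bins = c(pk_left, pk_right)),
            class = "bimodality_score")
}

#' @export
print.bimodality_score <- function(x, ...) {
  if (x$d > 0)
    cat(sprintf("<bimodality_score> depth %.4g (trough bin %d between peaks %d and %d)\n",
                x$d, x$trough_bin, x$peak_bins[1], x$peak_bins[2]))
  else cat("<bimodality_score> unimodal (depth 0)\n")
  invisible(x)
}

#' Median expression of a distribution
#'
#' Sample median (mean of the central two values for even counts).
#'
#' @param values non-empty numeric vector.
#' @return the median.
#' @export
median_expression <- function(values) {
  if (!length(values)) stop_invalid("`values` must be non-empty")
  stats::median(values)
}

#' Running average of depth against median
#'
#' Centered moving average of the second coordinate over a sequence sorted by
#' the first, with windows clipped at the edges; output length equals input
#' length. A window wider than the series collapses to the global mean.
#'
#' @param d numeric vector (e.g. trough depths sorted by median expression).
#' @param window window size in data points (default 30).
#' @return smoothed vector, same length.
#' @export
running_average <- function(d, window = 30L) {
  if (window < 1) stop_invalid("`window` must be >= 1")
  moving_average(as.numeric(d), as.integer(window))
}

#' Bimodality map over a two-drug gradient grid
#'
#' Per well: normalizes FITC-H by FSC-H, computes the median expression `m`
#' and the trough depth `d` of the log-binned histogram. All wells are then
#' pooled, sorted by `m` (ties by well id, for determinism), and the running
#' average of `d` versus `m` locates `m_peak`, the median expression at which
#' bimodality is maximal.
#'
#' @param cells long data.frame with columns `well`, `conc_a`, `conc_b`,
#'   `fitc_h`, `fsc_h` (one row per cell; see [sim_flow_grid()] or
#'   [read_cells_csv()]).
#' @param smooth_window histogram smoothing for [trough_depth()] (bins).
#' @param window running-average window (data points).
#' @param n_bins,lo,hi histogram layout passed to [histogram_log()].
#' @return list with `per_well` (data.frame `well`, `conc_a`, `conc_b`,
#'   `n_cells`, `m`, `d`, `trough_bin`), `curve` (data.frame `well`, `m`,
#'   `d`, `d_smooth` sorted by `m`) and `m_peak` (`NA` when every well is
#'   unimodal).
#' @export
grid_bimodality_map <- function(cells, smooth_window = 5L, window = 30L,
                                n_bins = 100L, lo = 1e-3, hi = 1e5) {
  wells <- unique(cells[, c("well", "conc_a", "conc_b")])
  if (anyDuplicated(wells$well))
    stop_invalid("well ids must map to unique grid positions")
  split_idx <- split(seq_len(nrow(cells)), cells$well)
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells$well[i]
    ci <- split_idx[[w]]
    vals <- tryCatch(
      normalize_fluorescence(cells$fitc_h[ci], cells$fsc_h[ci]),
      error = function(e) stop_invalid("well %s (conc_a=%g, conc_b=%g): %s",
                                       w, wells$conc_a[i], wells$conc_b[i],
                                       conditionMessage(e)))
    h <- tryCatch(histogram_log(vals, n_bins = n_bins, lo = lo, hi = hi),
                  error = function(e) stop_invalid("well %s (conc_a=%g, conc_b=%g): %s",
                                                   w, wells$conc_a[i],
                                                   wells$conc_b[i],
                                                   conditionMessage(e)))
    sc <- trough_depth(h, smooth_window = smooth_window)
    data.frame(well = w, conc_a = wells$conc_a[i], conc_b = wells$conc_b[i],
               n_cells = length(vals), m = median_expression(vals), d = sc$d,
               trough_bin = sc$trough_bin, stringsAsFactors = FALSE)
  })
  per_well <- do.call(rbind, rows)
  ord <- order(per_well$m, per_well$well, method = "radix")
  curve <- per_well[ord, c("well", "m", "d")]
  curve$d_smooth <- running_average(curve$d, window = window)
  rownames(curve) <- NULL
  m_peak <- if (all(per_well$d == 0)) NA_real_
  else curve$m[which.max(curve$d_smooth)]
  list(per_well = per_well, curve = curve, m_peak = m_peak)
}
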