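#' Analysis configuration
#'
#' One validated source of truth for every tunable constant of the pipeline.
#' Defaults are the assay constants the analyses were designed around:
#' 50 bp single-end reads; 100 histogram bins spaced logarithmically over
#' \[1e-3, 1e5\]; a running-average window of 30 data points and histogram
#' smoothing over 5 bins; 10^4 bootstrap surrogates; OD fitting windows
#' (0.01, 1) on raw and (0.02, 0.2) on background-corrected measurements; a
#' contamination cutoff of 0.85 per hour; and a top-decile enrichment list.
#'
#' @param seed master seed for all simulation stages.
#' @param read_length library read length (bp).
#' @param histogram list with `n_bins`, `lo`, `hi`.
#' @param running_window running-average window (data points).
#' @param smooth_window histogram smoothing window (bins).
#' @param n_surrogates bootstrap surrogates.
#' @param growth_window raw-OD log-linear fitting window.
#' @param corrected_growth_window background-corrected OD fitting window.
#' @param max_rate contamination threshold (per hour).
#' @param top_frac enrichment top-list fraction of the ranked universe.
#' @param retention,bimodality,survival per-scenario simulation sizes; lists
#'   with the fields shown in the defaults.
#' @return validated object of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L,
                            read_length = 50L,
                            histogram = list(n_bins = 100L, lo = 1e-3, hi = 1e5),
                            running_window = 30L,
                            smooth_window = 5L,
                            n_surrogates = 10000L,
                            growth_window = c(0.01, 1),
                            corrected_growth_window = c(0.02, 0.2),
                            max_rate = 0.85,
                            top_frac = 0.1,
                            retention = list(n_genes = 60L, frac_rp = 0.25,
                                             depth = 80, rho_control = 0.02,
                                             rho_rp = 0.35, rho_bg = 0.06,
                                             n_decoys = 5L),
                            bimodality = list(grid_n = 24L, n_cells = 10000L),
                            survival = list(rate_low = 0.05, rate_high = 0.5,
                                            cfu0 = 200,
                                            timepoints = c(0, 4, 8, 24),
                                            replicates = 2L)) {
  cfg <- structure(list(seed = as.integer(seed), read_length = read_length,
                        histogram = histogram, running_window = running_window,
                        smooth_window = smooth_window,
                        n_surrogates = n_surrogates,
                        growth_window = growth_window,
                        corrected_growth_window = corrected_growth_window,
                        max_rate = max_rate, top_frac = top_frac,
                        retention = retention, bimodality = bimodality,
                        survival = survival),
                   class = "analysis_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  chk(is.numeric(cfg$read_length) && cfg$read_length >= 1, "read_length")
  chk(is.list(cfg$histogram) &&
        all(c("n_bins", "lo", "hi") %in% names(cfg$histogram)) &&
        cfg$histogram$n_bins >= 1 && cfg$histogram$lo > 0 &&
        cfg$histogram$hi > cfg$histogram$lo, "histogram")
  chk(is.numeric(cfg$running_window) && cfg$running_window >= 1, "running_window")
  chk(is.numeric(cfg$smooth_window) && cfg$smooth_window >= 1, "smooth_window")
  chk(is.numeric(cfg$n_surrogates) && cfg$n_surrogates >= 1, "n_surrogates")
  chk(is.numeric(cfg$growth_window) && length(cfg$growth_window) == 2 &&
        cfg$growth_window[1] < cfg$growth_window[2], "growth_window")
  chk(is.numeric(cfg$corrected_growth_window) &&
        length(cfg$corrected_growth_window) == 2 &&
        cfg$corrected_growth_window[1] < cfg$corrected_growth_window[2],
      "corrected_growth_window")
  chk(is.numeric(cfg$max_rate) && cfg$max_rate > 0, "max_rate")
  chk(is.numeric(cfg$top_frac) && cfg$top_frac > 0 && cfg$top_frac <= 1,
      "top_frac")
  chk(is.list(cfg$retention), "retention")
  chk(is.list(cfg$bimodality), "bimodality")
  chk(is.list(cfg$survival), "survival")
  if (length(bad))
    stop_invalid("invalid configuration key(s): %s", paste(bad, collapse = ", "))
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  seed %d | read length %d bp | %d histogram bins [%g, %g]\n",
              x$seed, x$read_length, x$histogram$n_bins, x$histogram$lo,
              x$histogram$hi))
  cat(sprintf("  running window %d | smoothing %d bins | %d surrogates | contamination cutoff %g /h\n",
              x$running_window, x$smooth_window, x$n_surrogates, x$max_rate))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly (up to numeric representation).
#'
#' @param cfg `analysis_config` object.
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("invalid configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Run an end-to-end analysis scenario
#'
#' Orchestrates simulate-then-analyze runs from a single configuration:
#' \describe{
#'   \item{retention}{simulate control and treated reads, count features,
#'     estimate retention (density and junction), normalize to control, rank
#'     genes and test RP enrichment against decoy sets.}
#'   \item{bimodality}{simulate a two-drug gradient, map per-well median and
#'     trough depth, locate the bimodality peak.}
#'   \item{survival}{simulate sorted-population colony counts, compute
#'     survival curves and the Poisson-surrogate bootstrap p value.}
#' }
#' Every stage writes its tables into `out_dir` together with the
#' configuration and a machine-readable `summary.json`; a run log records
#' the seeds. Re-running with an identical configuration reproduces every
#' output byte except the log timestamps.
#'
#' @param config `analysis_config` object.
#' @param scenario one of `"retention"`, `"bimodality"`, `"survival"`,
#'   `"all"`.
#' @param out_dir output directory (created; must not exist or be empty).
#' @return invisibly, the summary list.
#' @export
run_scenario <- function(config = analysis_config(),
                         scenario = c("retention", "bimodality", "survival", "all"),
                         out_dir = tempfile("intromodal_run")) {
  scenario <- match.arg(scenario)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                       sprintf(...)),
                               file = log_path, append = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  logline("scenario %s, master seed %d", scenario, config$seed)
  summary <- list(scenario = scenario, seed = config$seed)

  if (scenario %in% c("retention", "all")) {
    rc <- config$retention
    seeds <- derive_seeds(config$seed + 101L, 4L)
    models <- gen_gene_models(rc$n_genes, frac_rp = rc$frac_rp,
                              frac_utr_intron = 0.5, frac_both = 0.15,
                              seed = seeds[1])
    ids <- vapply(models, `[[`, "", "gene_id")
    rp <- ids[vapply(models, function(m) "RP" %in% m$labels, TRUE)]
    truth_c <- sim_truth(models, rc$rho_control, rc$rho_control)
    rho_t <- ifelse(ids %in% rp, rc$rho_rp, rc$rho_bg)
    truth_t <- sim_truth(models, rho_t, rho_t)
    reads_c <- sim_reads(models, truth_c, depth = rc$depth,
                         read_length = config$read_length, seed = seeds[2])
    reads_t <- sim_reads(models, truth_t, depth = rc$depth,
                         read_length = config$read_length, seed = seeds[3])
    write_saf(models, file.path(out_dir, "annotation.saf"))
    counts_c <- count_features(reads_c, models, config$read_length)
    counts_t <- count_features(reads_t, models, config$read_length)
    ends_t <- count_intron_end_overlaps(reads_t, models)
    write_counts_tsv(counts_t, file.path(out_dir, "counts_treated.tsv"), ends_t)
    write_counts_tsv(counts_c, file.path(out_dir, "counts_control.tsv"))
    rt_c <- retention_table(counts_c, "density")
    rt_t <- retention_table(counts_t, "density")
    folds <- normalize_to_control(rt_t, rt_c)
    utils::write.table(folds, file.path(out_dir, "retention.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ranked <- rank_by_fold(folds)
    decoys <- with_seed(seeds[4], replicate(rc$n_decoys,
      sample(setdiff(ids, rp), length(rp)), simplify = FALSE))
    names(decoys) <- sprintf("decoy%d", seq_along(decoys))
    sets <- c(list(RP = rp), decoys)
    write_gene_sets(sets, file.path(out_dir, "gene_sets.tsv"))
    et <- enrichment_table(ranked, sets,
                           top_n = ceiling(length(ranked) * config$top_frac))
    utils::write.table(et, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$retention <- list(
      n_genes = rc$n_genes, n_ranked = length(ranked),
      rp_p_adj = et$p_adj[et$set_name == "RP"],
      best_decoy_p_adj = min(et$p_adj[et$set_name != "RP"]),
      top_gene = ranked[1])
    logline("retention: %d genes ranked, RP p_adj %.3g", length(ranked),
            summary$retention$rp_p_adj)
  }

  if (scenario %in% c("bimodality", "all")) {
    bc <- config$bimodality
    seeds <- derive_seeds(config$seed + 202L, 1L)
    grid <- gradient_grid(seq(0, 1, length.out = bc$grid_n),
                          seq(0, 1, length.out = bc$grid_n))
    params <- flow_sim_params(n_cells = bc$n_cells)
    sim <- sim_flow_grid(grid, params, seed = seeds[1])
    map <- grid_bimodality_map(sim$cells, smooth_window = config$smooth_window,
                               window = config$running_window,
                               n_bins = config$histogram$n_bins,
                               lo = config$histogram$lo,
                               hi = config$histogram$hi)
    utils::write.table(map$per_well, file.path(out_dir, "bimodality_wells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(map$curve, file.path(out_dir, "bimodality_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$bimodality <- list(n_wells = nrow(map$per_well),
                               m_peak = map$m_peak,
                               max_depth = max(map$per_well$d),
                               m_star_true = params$m_star)
    logline("bimodality: %d wells, m_peak %.3g", nrow(map$per_well), map$m_peak)
  }

  if (scenario %in% c("survival", "all")) {
    sc <- config$survival
    seeds <- derive_seeds(config$seed + 303L, 2L)
    tab <- sim_survival(sc$rate_low, sc$rate_high, cfu0 = sc$cfu0,
                        timepoints = sc$timepoints,
                        replicates = sc$replicates, seed = seeds[1])
    write_survival_csv(tab, file.path(out_dir, "cfu.csv"))
    curves <- survival_curve(tab)
    utils::write.table(curves, file.path(out_dir, "survival_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bt <- poisson_bootstrap_p(tab, n_surrogates = config$n_surrogates,
                              seed = seeds[2])
    summary$survival <- list(delta = unname(bt$statistic),
                             p_two_sided = bt$p_two_sided,
                             p_one_sided = bt$p_one_sided,
                             n_surrogates = bt$n_surrogates)
    logline("survival: Delta %d, two-sided p %.4g", summary$survival$delta,
            bt$p_two_sided)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(summary)
}
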