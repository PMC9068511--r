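#' Toy gene models for simulation
#'
#' Generates a set of non-overlapping toy gene annotations on synthetic
#' chromosomes. Each gene carries a CDS span and up to two introns, each
#' classified as a 5' UTR intron (upstream of the CDS) or a CDS intron
#' (splitting the CDS into exonic chunks). A random subset of genes is
#' tagged with the label `"RP"` so that gene-set enrichment can be exercised
#' against a known truth.
#'
#' Coordinates are 0-based half-open throughout the package; the SAF
#' reader/writer converts to and from the 1-based inclusive interchange
#' convention (see [write_saf()]).
#'
#' Geometry note: intron and CDS lengths are drawn from the same range by
#' default (ribosomal-protein-like genes, whose introns are unusually long and
#' comparable to their short CDS). Flanking untranslated exons at least one
#' read length wide surround every intron and the CDS, so that block-overlap
#' counting sees the same edge inflation on both feature classes.
#'
#' @param n_genes number of genes (>= 1).
#' @param frac_rp fraction of genes labeled `"RP"`.
#' @param frac_utr_intron fraction of intron-bearing genes whose intron is a
#'   5' UTR intron (the rest carry CDS introns).
#' @param seed integer seed; the output is a pure function of the arguments.
#' @param frac_both fraction of genes carrying both a 5' UTR intron and a CDS
#'   intron.
#' @param frac_second_cds among CDS-intron genes, fraction carrying a second
#'   CDS intron.
#' @param frac_intronless fraction of genes with no intron at all.
#' @param cds_len,intron_len length-2 ranges (bp) from which CDS and intron
#'   lengths are drawn uniformly.
#' @param pad width (bp) of the flanking untranslated exons.
#' @param genes_per_chrom genes placed per synthetic chromosome.
#' @return list of `gene_model` objects; each has fields `gene_id`, `chrom`,
#'   `strand`, `cds` (length-2 integer, 0-based half-open span),
#'   `introns` (data.frame `start`, `end`, `class`) and `labels`.
#' @export
#' @examples
#' models <- gen_gene_models(5, frac_rp = 0.4, frac_utr_intron = 0.5, seed = 1)
#' models[[1]]
gen_gene_models <- function(n_genes, frac_rp = 0.2, frac_utr_intron = 0.5,
                            seed = NULL, frac_both = 0, frac_second_cds = 0.3,
                            frac_intronless = 0,
                            cds_len = c(300L, 600L), intron_len = c(300L, 600L),
                            pad = 60L, genes_per_chrom = 25L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_invalid("`n_genes` must be a positive integer (got %s)",
                 deparse(substitute(n_genes)))
  n_genes <- as.integer(n_genes)
  assert_fraction(frac_rp, "frac_rp")
  assert_fraction(frac_utr_intron, "frac_utr_intron")
  assert_fraction(frac_both, "frac_both")
  assert_fraction(frac_second_cds, "frac_second_cds")
  assert_fraction(frac_intronless, "frac_intronless")

  with_seed(seed, {
    rp <- rep(FALSE, n_genes)
    rp[sample.int(n_genes, round(frac_rp * n_genes))] <- TRUE
    u_type <- stats::runif(n_genes)
    u_class <- stats::runif(n_genes)
    u_second <- stats::runif(n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    models <- vector("list", n_genes)
    pos <- 0L
    gap <- 200L
    for (i in seq_len(n_genes)) {
      chrom <- sprintf("chrS%d", (i - 1L) %/% genes_per_chrom + 1L)
      if ((i - 1L) %% genes_per_chrom == 0L) pos <- 0L
      lc <- sample(cds_len[1]:cds_len[2], 1L)
      has_intron <- u_type[i] >= frac_intronless
      both <- has_intron && u_type[i] >= 1 - frac_both
      utr <- has_intron && !both && u_class[i] < frac_utr_intron
      cdsint <- has_intron && (both || !utr)
      n_cds_introns <- if (!cdsint) 0L else if (!both && u_second[i] < frac_second_cds) 2L else 1L
      has_utr_intron <- has_intron && (utr || both)

      introns <- data.frame(start = integer(), end = integer(),
                            class = character(), stringsAsFactors = FALSE)
      cur <- pos + pad  # 5' untranslated exon
      if (has_utr_intron) {
        li <- sample(intron_len[1]:intron_len[2], 1L)
        introns <- rbind(introns, data.frame(start = cur, end = cur + li,
                                             class = "five_prime_utr"))
        cur <- cur + li + pad  # exon between UTR intron and CDS
      }
      cds_start <- cur
      if (n_cds_introns == 0L) {
        cur <- cur + lc
      } else {
        cuts <- round(lc * seq_len(n_cds_introns) / (n_cds_introns + 1L))
        prev <- 0L
        for (k in seq_len(n_cds_introns)) {
          cur <- cur + (cuts[k] - prev)
          li <- sample(intron_len[1]:intron_len[2], 1L)
          introns <- rbind(introns, data.frame(start = cur, end = cur + li,
                                               class = "cds"))
          cur <- cur + li
          prev <- cuts[k]
        }
        cur <- cur + (lc - prev)
      }
      cds_end <- cur
      gene_end <- cur + pad  # 3' untranslated exon
      models[[i]] <- structure(list(
        gene_id = sprintf("g%03d", i),
        chrom = chrom,
        strand = strand[i],
        span = c(pos, gene_end),
        cds = c(cds_start, cds_end),
        introns = introns,
        labels = if (rp[i]) "RP" else character(0)
      ), class = "gene_model")
      pos <- gene_end + gap
    }
    models
  })
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)%s\n", x$gene_id, x$chrom,
              x$span[1], x$span[2], x$strand,
              if (length(x$labels)) paste0("  [", paste(x$labels, collapse = ","), "]") else ""))
  cat(sprintf("  CDS span [%d, %d), exonic CDS %d bp\n", x$cds[1], x$cds[2],
              sum(cds_parts(x)$end - cds_parts(x)$start)))
  if (nrow(x$introns)) {
    for (k in seq_len(nrow(x$introns)))
      cat(sprintf("  intron %d: [%d, %d) %s (%d bp)\n", k, x$introns$start[k],
                  x$introns$end[k], x$introns$class[k],
                  x$introns$end[k] - x$introns$start[k]))
  } else cat("  no introns\n")
  invisible(x)
}

# exonic CDS chunks: CDS span minus any introns inside it
cds_parts <- function(model) {
  s <- model$cds[1]; e <- model$cds[2]
  ints <- model$introns
  ints <- ints[ints$start >= s & ints$end <= e, , drop = FALSE]
  if (!nrow(ints)) return(data.frame(start = s, end = e))
  ints <- ints[order(ints$start), , drop = FALSE]
  starts <- c(s, ints$end)
  ends <- c(ints$start, e)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# flat feature table used by the counters:
# one row per exonic-CDS chunk and per intron
models_to_features <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    cp <- cds_parts(m)
    rbind(
      data.frame(gene_id = m$gene_id, chrom = m$chrom, start = cp$start,
                 end = cp$end, kind = "cds", class = "cds", intron = NA_integer_,
                 stringsAsFactors = FALSE),
      if (nrow(m$introns))
        data.frame(gene_id = m$gene_id, chrom = m$chrom,
                   start = m$introns$start, end = m$introns$end,
                   kind = "intron", class = m$introns$class,
                   intron = seq_len(nrow(m$introns)), stringsAsFactors = FALSE)
    )
  }))
}

#' Latent simulation truth for intron retention
#'
#' Builds the per-gene ground-truth table consumed by [sim_reads()]: the true
#' retention fraction of the 5' UTR intron and of the CDS intron(s), and the
#' expected transcript abundance.
#'
#' @param models list of `gene_model` objects.
#' @param rho_utr,rho_cds true retention fractions in \[0, 1\], recycled over
#'   genes.
#' @param abundance expected transcripts per gene (> 0), recycled.
#' @return data.frame with columns `gene_id`, `rho_utr`, `rho_cds`,
#'   `abundance`.
#' @export
sim_truth <- function(models, rho_utr = 0.1, rho_cds = 0.1, abundance = 1) {
  ids <- vapply(models, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop_invalid("duplicated gene ids in `models`")
  n <- length(ids)
  out <- data.frame(gene_id = ids,
                    rho_utr = rep_len(rho_utr, n),
                    rho_cds = rep_len(rho_cds, n),
                    abundance = rep_len(abundance, n),
                    stringsAsFactors = FALSE)
  if (any(out$rho_utr < 0 | out$rho_utr > 1 | out$rho_cds < 0 | out$rho_cds > 1))
    stop_invalid("retention fractions must lie in [0, 1]")
  if (any(out$abundance <= 0)) stop_invalid("`abundance` must be positive")
  out
}
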