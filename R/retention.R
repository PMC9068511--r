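#' Intron retention rate from read densities
#'
#' The retention rate is the ratio of intron read density to CDS read
#' density: `r = (I / L_I) / (C / L_C)`, where `I` and `C` are intron and CDS
#' read counts and `L_I`, `L_C` the feature lengths. Multiple introns passed
#' together are treated jointly (`I = sum of counts`, `L_I = sum of lengths`),
#' which is the convention for CDS introns; 5' UTR introns are scored one at
#' a time.
#'
#' @param intron_counts intron read count(s), non-negative.
#' @param intron_lengths matching intron length(s) in bp (> 0).
#' @param cds_count CDS read count (> 0; a gene without CDS reads has no
#'   defined rate).
#' @param cds_length exonic CDS length in bp (> 0).
#' @return retention rate `r` (dimensionless, >= 0).
#' @export
#' @examples
#' retention_rate(10, 100, 200, 1000)            # 0.5
#' retention_rate(c(5, 15), c(50, 150), 100, 500) # joint CDS introns: 0.5
retention_rate <- function(intron_counts, intron_lengths, cds_count, cds_length) {
  if (length(intron_counts) != length(intron_lengths))
    stop_invalid("intron counts and lengths must have equal length")
  if (any(intron_counts < 0) || any(intron_lengths <= 0) || cds_length <= 0)
    stop_invalid("counts must be >= 0 and lengths > 0")
  if (cds_count <= 0)
    stop_invalid("undefined retention rate: CDS has no reads (C = 0)")
  (sum(intron_counts) / sum(intron_lengths)) / (cds_count / cds_length)
}

#' Intron retention rate from junction-end read counts
#'
#' Variant estimator using only contiguous reads that cross the intron
#' boundaries: the boundary counts are averaged between the 5' and 3' intron
#' ends and divided by the read length, then normalized by CDS read density:
#' `r = (((n5 + n3) / 2) / read_length) / (C / L_C)`. Vectors `n5`, `n3`
#' (several introns scored jointly) are averaged across introns.
#'
#' @param n5,n3 contiguous-read counts overlapping the 5' and 3' intron ends.
#' @param read_length library read length in bp (>= 2).
#' @param cds_count,cds_length CDS read count (> 0) and exonic CDS length.
#' @return retention rate `r`.
#' @export
#' @examples
#' junction_rate(20, 30, 50, 200, 1000)  # 2.5
junction_rate <- function(n5, n3, read_length, cds_count, cds_length) {
  if (read_length < 2) stop_invalid("`read_length` must be >= 2")
  if (any(n5 < 0) || any(n3 < 0)) stop_invalid("end counts must be >= 0")
  if (cds_count <= 0)
    stop_invalid("undefined retention rate: CDS has no reads (C = 0)")
  (mean((n5 + n3) / 2) / read_length) / (cds_count / cds_length)
}

#' Per-gene retention records from a feature-counts table
#'
#' Applies the multi-intron convention of the density estimator: all CDS
#' introns of a gene are treated jointly (one record), every 5' UTR intron
#' separately (one record each). Genes with zero CDS reads yield flagged
#' records (`undefined = TRUE`, `r = NA`) rather than silent zeros, and are
#' excluded from downstream ranking.
#'
#' @param counts `feature_counts` object from [count_features()].
#' @param method `"density"` (block-overlap counts) or `"junction"`
#'   (intron-end counts; requires `end_counts`).
#' @param end_counts for `method = "junction"`, the table from
#'   [count_intron_end_overlaps()].
#' @param read_length read length for the junction estimator; defaults to the
#'   one recorded in `counts`.
#' @return data.frame with columns `gene_id`, `intron_class`, `intron`
#'   (index, `NA` for the joint CDS record), `method`, `r`, `undefined`.
#' @export
retention_table <- function(counts, method = c("density", "junction"),
                            end_counts = NULL, read_length = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "feature_counts"))
  if (method == "junction") {
    if (is.null(end_counts))
      stop_invalid("`end_counts` is required for the junction estimator")
    read_length <- read_length %||% counts$read_length
    if (is.null(read_length) || is.na(read_length))
      stop_invalid("junction estimator needs a read length")
    key <- paste(end_counts$gene_id, end_counts$intron)
  }
  genes <- counts$genes
  rownames(genes) <- genes$gene_id
  intr <- counts$introns

  rec <- function(gene_id, class, intron_idx, I, L, n5, n3) {
    g <- genes[gene_id, ]
    undef <- g$cds_count <= 0
    r <- if (undef) NA_real_
    else if (method == "density")
      retention_rate(I, L, g$cds_count, g$cds_length)
    else junction_rate(n5, n3, read_length, g$cds_count, g$cds_length)
    data.frame(gene_id = gene_id, intron_class = class, intron = intron_idx,
               method = method, r = r, undefined = undef,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (gid in unique(intr$gene_id)) {
    gi <- intr[intr$gene_id == gid, , drop = FALSE]
    cds_i <- gi[gi$class == "cds", , drop = FALSE]
    utr_i <- gi[gi$class == "five_prime_utr", , drop = FALSE]
    if (nrow(cds_i)) {
      if (method == "junction") {
        m <- match(paste(gid, cds_i$intron), key)
        out[[length(out) + 1L]] <- rec(gid, "cds", NA_integer_, NA, NA,
                                       end_counts$n5[m], end_counts$n3[m])
      } else {
        out[[length(out) + 1L]] <- rec(gid, "cds", NA_integer_,
                                       cds_i$count, cds_i$length, NA, NA)
      }
    }
    for (k in seq_len(nrow(utr_i))) {
      if (method == "junction") {
        m <- match(paste(gid, utr_i$intron[k]), key)
        out[[length(out) + 1L]] <- rec(gid, "five_prime_utr", utr_i$intron[k],
                                       NA, NA, end_counts$n5[m], end_counts$n3[m])
      } else {
        out[[length(out) + 1L]] <- rec(gid, "five_prime_utr", utr_i$intron[k],
                                       utr_i$count[k], utr_i$length[k], NA, NA)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), intron_class = character(),
                      intron = integer(), method = character(), r = numeric(),
                      undefined = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold change of retention relative to a no-drug control
#'
#' Matches treated and control retention records by gene, intron class,
#' intron index and method, and computes
#' `fold = (r_treated + eps) / (r_control + eps)` with a small pseudocount
#' `eps` guarding against zero-count control introns. The default pseudocount
#' is `1e-3` times the median nonzero rate pooled over both tables.
#'
#' @param treated,control retention tables from [retention_table()] (or
#'   single records with the same columns).
#' @param pseudocount small positive `eps`; `NULL` for the data-driven
#'   default.
#' @return the treated table with extra columns `r_control` and `fold`;
#'   records undefined in either condition get `fold = NA`.
#' @export
normalize_to_control <- function(treated, control, pseudocount = NULL) {
  need <- c("gene_id", "intron_class", "intron", "method", "r")
  if (!all(need %in% names(treated)) || !all(need %in% names(control)))
    stop_invalid("retention tables must carry columns %s",
                 paste(need, collapse = ", "))
  kt <- paste(treated$gene_id, treated$intron_class, treated$intron, treated$method)
  kc <- paste(control$gene_id, control$intron_class, control$intron, control$method)
  if (anyDuplicated(kt) || anyDuplicated(kc))
    stop_invalid("invalid pairing: duplicated records")
  m <- match(kt, kc)
  if (anyNA(m) || length(kt) != length(kc))
    stop_invalid("invalid pairing: treated and control records do not match one-to-one")
  if (is.null(pseudocount)) {
    pool <- c(treated$r, control$r)
    pool <- pool[!is.na(pool) & pool > 0]
    pseudocount <- if (length(pool)) 1e-3 * stats::median(pool) else 1e-6
  }
  assert_scalar_num(pseudocount, "pseudocount", lo = 1e-300)
  out <- treated
  out$r_control <- control$r[m]
  out$fold <- (out$r + pseudocount) / (out$r_control + pseudocount)
  out
}

#' Rank genes by retention fold change
#'
#' Genes with several records (e.g. one 5' UTR and one joint CDS record)
#' contribute their maximum fold change. Undefined folds are dropped. Order
#' is descending fold, ties broken lexicographically by gene id so that the
#' ranking is deterministic.
#'
#' @param records data.frame with columns `gene_id` and `fold` (e.g. from
#'   [normalize_to_control()]).
#' @return character vector of gene ids, most elevated retention first, with
#'   the per-gene folds attached as the `"fold"` attribute.
#' @export
rank_by_fold <- function(records) {
  if (!nrow(records)) return(character(0))
  ok <- !is.na(records$fold)
  records <- records[ok, , drop = FALSE]
  if (!nrow(records)) return(character(0))
  fold <- tapply(records$fold, records$gene_id, max)
  ord <- order(-unname(fold), names(fold), method = "radix")
  structure(names(fold)[ord], fold = unname(fold)[ord])
}

#' Hypergeometric enrichment of a gene set in the top of a ranked list
#'
#' Tests whether the first `top_n` genes of a ranked list are enriched for a
#' gene set: with `N` ranked genes, `K` of them in the set and `k` set genes
#' among the top `n = top_n`, the p value is the exact upper tail
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' Set members absent from the ranked universe are dropped (with a message)
#' before testing.
#'
#' @param ranked character vector of ranked gene ids (no duplicates).
#' @param gene_set character vector of set members.
#' @param top_n size of the top list (1 <= top_n <= length(ranked)).
#' @param set_name label for the output row.
#' @return one-row data.frame: `set_name`, `k`, `K`, `n`, `N`, `p`.
#' @export
hypergeom_enrichment <- function(ranked, gene_set, top_n, set_name = "set") {
  if (anyDuplicated(ranked)) stop_invalid("`ranked` must not contain duplicates")
  N <- length(ranked)
  if (top_n < 1 || top_n > N)
    stop_invalid("`top_n` must lie in [1, %d] (got %s)", N, as.character(top_n))
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, ranked)
  if (length(missing)) {
    message(sprintf("%d gene-set member(s) outside the ranked universe dropped",
                    length(missing)))
    gene_set <- setdiff(gene_set, missing)
  }
  K <- length(gene_set)
  k <- length(intersect(ranked[seq_len(top_n)], gene_set))
  p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, top_n, lower.tail = FALSE)
  data.frame(set_name = set_name, k = k, K = K, n = as.integer(top_n), N = N,
             p = p, stringsAsFactors = FALSE)
}

#' Enrichment of several gene sets with multiple-testing correction
#'
#' @param ranked ranked gene ids (see [rank_by_fold()]).
#' @param gene_sets named list of character vectors.
#' @param top_n top-list size; default one tenth of the universe.
#' @return data.frame with one row per set and columns of
#'   [hypergeom_enrichment()] plus `p_adj` (Benjamini-Hochberg).
#' @export
enrichment_table <- function(ranked, gene_sets, top_n = ceiling(length(ranked) / 10)) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm)
    hypergeom_enrichment(ranked, gene_sets[[nm]], top_n, set_name = nm))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, mapped back to the input order.
#'
#' @param pvals numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_invalid("p values must be numbers in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
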