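#' Simulate aligned reads from a mixture of spliced and intron-retained
#' isoforms
#'
#' For every gene, transcripts either retain each intron (with that intron's
#' true retention fraction) or splice it out; single-end reads of fixed length
#' start uniformly along the chosen isoform. Reads from a spliced isoform that
#' cross an exon-intron junction become multi-block records with the gap over
#' the spliced intron; all other reads are single-block ("contiguous").
#' Expected single-block coverage per intron bp is proportional to
#' `rho * abundance * depth`, and per exonic-CDS bp to `abundance * depth`,
#' which is exactly the signal the retention estimators consume.
#'
#' The per-isoform read count is Poisson with mean
#' `depth * abundance * P(isoform) * (L_isoform - read_length + 1) / 1000`,
#' i.e. `depth` is the expected number of read start positions per kilobase of
#' transcript at unit abundance.
#'
#' @param models list of `gene_model` objects (see [gen_gene_models()]).
#' @param truth ground-truth table from [sim_truth()].
#' @param depth expected reads per kb of transcript per unit abundance (> 0).
#' @param read_length read length in bp (default 50, single-end).
#' @param seed integer seed.
#' @return data.frame of read records with columns `chrom`, `start`, `end`
#'   (0-based half-open outer span), `name`, `n_blocks`, `block_sizes`,
#'   `block_starts` (comma-separated, BED12 convention: starts relative to
#'   `start`), and `gene_id` (simulation provenance).
#' @export
sim_reads <- function(models, truth, depth, read_length = 50L, seed = NULL) {
  assert_scalar_num(depth, "depth", lo = 1e-12)
  if (!is.numeric(read_length) || read_length < 1)
    stop_invalid("`read_length` must be >= 1")
  rl <- as.integer(read_length)
  rownames(truth) <- truth$gene_id

  with_seed(seed, {
    per_gene <- lapply(models, function(m) {
      tr <- truth[m$gene_id, ]
      if (is.na(tr$gene_id))
        stop_invalid("no truth row for gene %s", m$gene_id)
      span_len <- m$span[2] - m$span[1]
      if (span_len < rl) {
        warning(sprintf("gene %s shorter than read_length; skipped", m$gene_id),
                call. = FALSE)
        return(NULL)
      }
      ints <- m$introns
      k <- nrow(ints)
      rho <- if (k) ifelse(ints$class == "five_prime_utr", tr$rho_utr, tr$rho_cds) else numeric(0)
      configs <- if (k) expand.grid(rep(list(c(TRUE, FALSE)), k)) else data.frame(row.names = 1)
      chunks <- lapply(seq_len(nrow(configs)), function(ci) {
        retained <- if (k) unlist(configs[ci, ], use.names = FALSE) else logical(0)
        prob <- prod(ifelse(retained, rho, 1 - rho))
        if (prob <= 0) return(NULL)
        spliced <- ints[!retained, , drop = FALSE]
        spliced <- spliced[order(spliced$start), , drop = FALSE]
        # genomic blocks of this isoform = gene span minus spliced introns
        bs <- c(m$span[1], spliced$end)
        be <- c(spliced$start, m$span[2])
        keep <- be > bs
        bs <- bs[keep]; be <- be[keep]
        bl <- be - bs
        l_iso <- sum(bl)
        if (l_iso < rl) return(NULL)
        lambda <- depth * tr$abundance * prob * (l_iso - rl + 1) / 1000
        n <- stats::rpois(1L, lambda)
        if (n == 0L) return(NULL)
        t0 <- sample.int(l_iso - rl + 1L, n, replace = TRUE) - 1L
        off <- cumsum(c(0L, bl))[seq_along(bl)]  # transcript start of block
        i <- findInterval(t0, off)
        j <- findInterval(t0 + rl - 1L, off)
        g_start <- bs[i] + (t0 - off[i])
        g_end <- bs[j] + (t0 + rl - off[j])
        nb <- j - i + 1L
        sizes <- as.character(rep(rl, n))
        starts <- rep("0", n)
        multi <- which(nb > 1L)
        for (r in multi) {
          bb <- i[r]:j[r]
          ps <- bs[bb] + pmax(0L, t0[r] - off[bb])
          pe <- bs[bb] + pmin(bl[bb], t0[r] + rl - off[bb])
          sizes[r] <- paste(pe - ps, collapse = ",")
          starts[r] <- paste(ps - g_start[r], collapse = ",")
        }
        data.frame(chrom = m$chrom, start = g_start, end = g_end,
                   n_blocks = nb, block_sizes = sizes, block_starts = starts,
                   gene_id = m$gene_id, stringsAsFactors = FALSE)
      })
      do.call(rbind, chunks)
    })
    out <- do.call(rbind, per_gene)
    if (is.null(out))
      out <- data.frame(chrom = character(), start = integer(), end = integer(),
                        n_blocks = integer(), block_sizes = character(),
                        block_starts = character(), gene_id = character(),
                        stringsAsFactors = FALSE)
    out$name <- if (nrow(out)) sprintf("read%07d", seq_len(nrow(out))) else character(0)
    rownames(out) <- NULL
    out[, c("chrom", "start", "end", "name", "n_blocks", "block_sizes",
            "block_starts", "gene_id")]
  })
}

# expand read records into one row per block (read_idx, chrom, start, end)
read_blocks <- function(reads) {
  if (!nrow(reads))
    return(data.frame(read = integer(), chrom = character(),
                      start = integer(), end = integer()))
  single <- reads$n_blocks == 1L
  out1 <- data.frame(read = which(single), chrom = reads$chrom[single],
                     start = reads$start[single], end = reads$end[single],
                     stringsAsFactors = FALSE)
  if (all(single)) return(out1)
  idx <- which(!single)
  sz <- strsplit(reads$block_sizes[idx], ",", fixed = TRUE)
  st <- strsplit(reads$block_starts[idx], ",", fixed = TRUE)
  nb <- lengths(sz)
  rd <- rep(idx, nb)
  bstart <- reads$start[rd] + as.integer(unlist(st))
  bend <- bstart + as.integer(unlist(sz))
  out2 <- data.frame(read = rd, chrom = reads$chrom[rd], start = bstart,
                     end = bend, stringsAsFactors = FALSE)
  rbind(out1, out2)
}
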