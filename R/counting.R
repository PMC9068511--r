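#' Count reads into intron and CDS features
#'
#' A read increments a feature's count iff any of its aligned blocks overlaps
#' the feature by at least one bp. Intron and CDS counters are independent:
#' one read may increment both, but never a feature twice. A multi-block read
#' whose gap spans an intron does not increment that intron (the gap has no
#' block overlap). The CDS feature of a gene is its exonic CDS (CDS span
#' minus any CDS introns), mirroring a multi-row feature annotation as
#' consumed by standard feature counters.
#'
#' Reads on chromosomes absent from the annotation are ignored and tallied in
#' the `n_ignored` field.
#'
#' @param reads read records (see [sim_reads()] / [read_reads_bed()]).
#' @param models list of `gene_model` objects.
#' @param read_length library read length in bp, stored for the junction
#'   estimator; defaults to the most common single-block span in `reads`.
#' @return object of class `feature_counts`: list with `genes` (data.frame
#'   `gene_id`, `cds_count`, `cds_length`), `introns` (data.frame `gene_id`,
#'   `intron`, `class`, `start`, `end`, `length`, `count`), `read_length`,
#'   `n_ignored`.
#' @export
count_features <- function(reads, models, read_length = NULL) {
  feats <- models_to_features(models)
  blocks <- read_blocks(reads)
  known <- unique(feats$chrom)
  n_ignored <- length(unique(blocks$read[!blocks$chrom %in% known]))
  if (n_ignored > 0)
    message(sprintf("%d read(s) on unknown chromosomes ignored", n_ignored))
  feats$key <- ifelse(feats$kind == "cds", paste0(feats$gene_id, "::cds"),
                      paste0(feats$gene_id, "::intron", feats$intron))

  hit_keys <- character(0); hit_reads <- integer(0)
  for (ch in known) {
    fb <- feats[feats$chrom == ch, , drop = FALSE]
    bb <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (!nrow(fb) || !nrow(bb)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(bb$start + 1L, bb$end),
      IRanges::IRanges(fb$start + 1L, fb$end))
    if (!length(ov)) next
    hit_keys <- c(hit_keys, fb$key[S4Vectors::subjectHits(ov)])
    hit_reads <- c(hit_reads, bb$read[S4Vectors::queryHits(ov)])
  }
  pair_key <- unique(paste(hit_reads, hit_keys, sep = "\r"))
  counts <- table(sub("^[^\r]*\r", "", pair_key))

  ids <- vapply(models, `[[`, "", "gene_id")
  cds_len <- vapply(models, function(m) {
    cp <- cds_parts(m); sum(cp$end - cp$start)
  }, 0)
  genes <- data.frame(gene_id = ids, cds_count = 0L, cds_length = as.integer(cds_len),
                      stringsAsFactors = FALSE)
  ck <- paste0(ids, "::cds")
  hit <- ck %in% names(counts)
  genes$cds_count[hit] <- as.integer(counts[ck[hit]])

  intr <- feats[feats$kind == "intron", c("gene_id", "intron", "class", "start", "end", "key")]
  intr$length <- intr$end - intr$start
  intr$count <- 0L
  hit <- intr$key %in% names(counts)
  intr$count[hit] <- as.integer(counts[intr$key[hit]])
  intr$key <- NULL
  rownames(intr) <- NULL

  if (is.null(read_length)) {
    single <- reads$n_blocks == 1L
    read_length <- if (any(single))
      as.integer(names(sort(table(reads$end[single] - reads$start[single]),
                            decreasing = TRUE))[1])
    else NA_integer_
  }
  structure(list(genes = genes, introns = intr,
                 read_length = read_length, n_ignored = n_ignored),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("<feature_counts> %d genes, %d introns (%d five_prime_utr, %d cds)\n",
              nrow(x$genes), nrow(x$introns),
              sum(x$introns$class == "five_prime_utr"),
              sum(x$introns$class == "cds")))
  cat(sprintf("  CDS reads: %d total; intron reads: %d total; read length %s bp; %d read(s) ignored\n",
              sum(x$genes$cds_count), sum(x$introns$count),
              as.character(x$read_length), x$n_ignored))
  invisible(x)
}

#' Count contiguous reads overlapping intron ends
#'
#' For every intron boundary, counts the single-block ("contiguous") reads
#' whose interval strictly contains the boundary coordinate, i.e. covers at
#' least one bp on each side of the exon-intron junction. Only such reads are
#' informative about retention: a read merely touching the boundary is not
#' counted. Counts at the genomic left/right boundary are relabeled to the
#' 5'/3' intron end according to gene strand.
#'
#' @inheritParams count_features
#' @return data.frame with columns `gene_id`, `intron`, `class`, `n5`, `n3`.
#' @export
count_intron_end_overlaps <- function(reads, models) {
  feats <- models_to_features(models)
  intr <- feats[feats$kind == "intron", , drop = FALSE]
  strand <- vapply(models, `[[`, "", "strand")
  names(strand) <- vapply(models, `[[`, "", "gene_id")
  single <- reads[reads$n_blocks == 1L, , drop = FALSE]

  n_left <- integer(nrow(intr)); n_right <- integer(nrow(intr))
  for (ch in unique(intr$chrom)) {
    ii <- which(intr$chrom == ch)
    rr <- single[single$chrom == ch, , drop = FALSE]
    if (!nrow(rr)) next
    subj <- IRanges::IRanges(rr$start + 1L, rr$end)
    # two-base window around boundary b: 1-based positions b and b+1
    n_left[ii] <- IRanges::countOverlaps(
      IRanges::IRanges(intr$start[ii], width = 2L), subj, type = "within")
    n_right[ii] <- IRanges::countOverlaps(
      IRanges::IRanges(intr$end[ii], width = 2L), subj, type = "within")
  }
  minus <- strand[intr$gene_id] == "-"
  data.frame(gene_id = intr$gene_id, intron = intr$intron, class = intr$class,
             n5 = ifelse(minus, n_right, n_left),
             n3 = ifelse(minus, n_left, n_right),
             row.names = NULL, stringsAsFactors = FALSE)
}
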