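# Naive quadratic reference counters. These deliberately share no code with
# the interval-index path in counting.R: every feature is compared against
# every read block by direct coordinate comparison; used to validate the
# fast counters on random instances.

#' Brute-force reference read counter
#'
#' All-pairs (read block x feature) overlap counting by direct coordinate
#' comparison, quadratic in the input. Produces the same structure as
#' [count_features()] and exists purely as an independent validation path for
#' it; use the fast counter for real work.
#'
#' @inheritParams count_features
#' @return `feature_counts` object.
#' @export
count_features_naive <- function(reads, models, read_length = NULL) {
  feats <- models_to_features(models)
  blocks <- read_blocks(reads)
  ids <- vapply(models, `[[`, "", "gene_id")
  cds_len <- vapply(models, function(m) {
    cp <- cds_parts(m); sum(cp$end - cp$start)
  }, 0)

  overlapping_reads <- function(chrom, start, end)
    blocks$read[blocks$chrom == chrom & blocks$start < end & blocks$end > start]

  genes <- data.frame(gene_id = ids, cds_count = 0L,
                      cds_length = as.integer(cds_len), stringsAsFactors = FALSE)
  for (gi in seq_along(models)) {
    m <- models[[gi]]
    cp <- cds_parts(m)
    hits <- unlist(lapply(seq_len(nrow(cp)), function(ci)
      overlapping_reads(m$chrom, cp$start[ci], cp$end[ci])))
    genes$cds_count[gi] <- length(unique(hits))
  }

  intr <- feats[feats$kind == "intron", c("gene_id", "chrom", "intron", "class",
                                          "start", "end")]
  intr$length <- intr$end - intr$start
  intr$count <- vapply(seq_len(nrow(intr)), function(ii)
    length(unique(overlapping_reads(intr$chrom[ii], intr$start[ii],
                                    intr$end[ii]))), 0L)
  intr$chrom <- NULL
  rownames(intr) <- NULL

  known <- unique(feats$chrom)
  n_ignored <- length(unique(blocks$read[!blocks$chrom %in% known]))
  structure(list(genes = genes,
                 introns = intr[, c("gene_id", "intron", "class", "start",
                                    "end", "length", "count")],
                 read_length = read_length, n_ignored = n_ignored),
            class = "feature_counts")
}

#' Brute-force reference junction-end counter
#'
#' Direct per-boundary comparison against every contiguous read, validating
#' [count_intron_end_overlaps()].
#'
#' @inheritParams count_features
#' @return data.frame with columns `gene_id`, `intron`, `class`, `n5`, `n3`.
#' @export
count_intron_end_overlaps_naive <- function(reads, models) {
  feats <- models_to_features(models)
  intr <- feats[feats$kind == "intron", , drop = FALSE]
  strand <- vapply(models, `[[`, "", "strand")
  names(strand) <- vapply(models, `[[`, "", "gene_id")
  single <- reads[reads$n_blocks == 1L, , drop = FALSE]
  contains <- function(chrom, b)
    sum(single$chrom == chrom & single$start < b & single$end > b)
  n_left <- vapply(seq_len(nrow(intr)), function(ii)
    contains(intr$chrom[ii], intr$start[ii]), 0)
  n_right <- vapply(seq_len(nrow(intr)), function(ii)
    contains(intr$chrom[ii], intr$end[ii]), 0)
  minus <- strand[intr$gene_id] == "-"
  data.frame(gene_id = intr$gene_id, intron = intr$intron, class = intr$class,
             n5 = ifelse(minus, n_right, n_left),
             n3 = ifelse(minus, n_left, n_right),
             row.names = NULL, stringsAsFactors = FALSE)
}
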