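# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive triple-scan trough depth: maximum over all (left peak, trough,
# right peak) bin triples of min(peaks) - trough
trough_depth_oracle <- function(f) {
  n <- length(f)
  if (n < 3) return(0)
  best <- 0
  for (j in 2:(n - 1))
    for (i in 1:(j - 1))
      for (k in (j + 1):n)
        best <- max(best, min(f[i], f[k]) - f[j])
  best
}

# independent Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# random unimodal (single-peak) histogram: rises then falls
random_unimodal <- function(n) {
  peak <- sample.int(n, 1)
  up <- sort(runif(peak))
  down <- sort(runif(n - peak), decreasing = TRUE)
  f <- c(up, down * up[peak])
  f / sum(f)
}

# two hand-built toy genes on one chromosome used by counting tests:
#  gA (+): 5'UTR intron [100, 200), CDS [230, 430)
#  gB (-): CDS [600, 1000) split by a CDS intron [700, 800)
toy_models <- function() {
  list(
    structure(list(gene_id = "gA", chrom = "chrT", strand = "+",
                   span = c(40, 490), cds = c(230, 430),
                   introns = data.frame(start = 100L, end = 200L,
                                        class = "five_prime_utr"),
                   labels = character(0)), class = "gene_model"),
    structure(list(gene_id = "gB", chrom = "chrT", strand = "-",
                   span = c(540, 1060), cds = c(600, 1000),
                   introns = data.frame(start = 700L, end = 800L,
                                        class = "cds"),
                   labels = character(0)), class = "gene_model"))
}

make_read <- function(chrom, start, end, blocks = NULL, name = "r1") {
  if (is.null(blocks)) {
    data.frame(chrom = chrom, start = start, end = end, name = name,
               n_blocks = 1L, block_sizes = as.character(end - start),
               block_starts = "0", stringsAsFactors = FALSE)
  } else {
    sizes <- vapply(blocks, function(b) b[2] - b[1], 0)
    starts <- vapply(blocks, function(b) b[1] - start, 0)
    data.frame(chrom = chrom, start = start, end = end, name = name,
               n_blocks = length(blocks),
               block_sizes = paste(sizes, collapse = ","),
               block_starts = paste(starts, collapse = ","),
               stringsAsFactors = FALSE)
  }
}
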