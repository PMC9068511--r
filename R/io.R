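#' Write gene models as a SAF annotation file
#'
#' Simplified annotation format as consumed by standard feature counters:
#' tab-separated columns `GeneID`, `Chr`, `Start`, `End`, `Strand`,
#' 1-based inclusive coordinates (internal coordinates are 0-based half-open;
#' the conversion happens here). Feature class is encoded in a `GeneID`
#' suffix: `<gene>::cds` rows are the exonic CDS chunks of a gene (several
#' rows form one feature), and each `<gene>::intron_utr` / `<gene>::intron_cds`
#' row is one intron. Gene-set labels and the padded gene span are not part
#' of SAF; labels travel in a gene-set file (see [write_gene_sets()]) and the
#' span is reconstructed as the feature hull on read.
#'
#' @param models list of `gene_model` objects.
#' @param path output file.
#' @export
write_saf <- function(models, path) {
  rows <- lapply(models, function(m) {
    cp <- cds_parts(m)
    r <- data.frame(GeneID = paste0(m$gene_id, "::cds"), Chr = m$chrom,
                    Start = cp$start + 1L, End = cp$end, Strand = m$strand,
                    stringsAsFactors = FALSE)
    if (nrow(m$introns)) {
      suffix <- ifelse(m$introns$class == "five_prime_utr", "intron_utr",
                       "intron_cds")
      r <- rbind(r, data.frame(GeneID = paste0(m$gene_id, "::", suffix),
                               Chr = m$chrom, Start = m$introns$start + 1L,
                               End = m$introns$end, Strand = m$strand,
                               stringsAsFactors = FALSE))
    }
    r
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from a SAF annotation file
#'
#' Inverse of [write_saf()]; see there for the format note. Coordinates are
#' converted from 1-based inclusive to the internal 0-based half-open
#' convention.
#'
#' @param path SAF file.
#' @return list of `gene_model` objects (with empty `labels`; the gene span
#'   is the hull of the gene's features).
#' @export
read_saf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("GeneID", "Chr", "Start", "End", "Strand")
  if (!all(need %in% names(df)))
    stop_invalid("malformed SAF: need columns %s", paste(need, collapse = ", "))
  if (!nrow(df)) return(list())
  allowed <- c("cds", "intron_utr", "intron_cds")
  df$GeneID <- as.character(df$GeneID)
  bad <- which(!grepl("::", df$GeneID, fixed = TRUE) |
                 is.na(suppressWarnings(as.integer(df$Start))) |
                 is.na(suppressWarnings(as.integer(df$End))) |
                 df$End < df$Start |
                 !df$Strand %in% c("+", "-"))
  if (length(bad))
    stop_invalid("malformed SAF row at line %d", bad[1] + 1L)  # +1 for header
  parts <- strsplit(df$GeneID, "::", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  suffix <- vapply(parts, function(p) paste(p[-1], collapse = "::"), "")
  unknown <- which(!suffix %in% allowed)
  if (length(unknown))
    stop_invalid("unknown feature suffix \"%s\" at line %d (allowed: %s)",
                 suffix[unknown[1]], unknown[1] + 1L,
                 paste0("::", allowed, collapse = ", "))
  df$Start <- as.integer(df$Start) - 1L  # to 0-based half-open
  df$End <- as.integer(df$End)
  lapply(split(seq_len(nrow(df)), factor(gene, levels = unique(gene))),
         function(i) {
           g <- df[i, ]; sfx <- suffix[i]
           if (length(unique(g$Chr)) != 1L || length(unique(g$Strand)) != 1L)
             stop_invalid("gene %s spans several chromosomes or strands",
                          gene[i[1]])
           cds_rows <- g[sfx == "cds", , drop = FALSE]
           if (!nrow(cds_rows))
             stop_invalid("gene %s has no ::cds rows", gene[i[1]])
           int_idx <- which(sfx != "cds")
           int_idx <- int_idx[order(g$Start[int_idx])]
           introns <- data.frame(
             start = g$Start[int_idx], end = g$End[int_idx],
             class = ifelse(sfx[int_idx] == "intron_utr", "five_prime_utr",
                            "cds"),
             stringsAsFactors = FALSE)
           structure(list(gene_id = gene[i[1]], chrom = g$Chr[1],
                          strand = g$Strand[1],
                          span = c(min(g$Start), max(g$End)),
                          cds = c(min(cds_rows$Start), max(cds_rows$End)),
                          introns = introns, labels = character(0)),
                     class = "gene_model")
         })
}

#' Write read records as a BED12-style TSV
#'
#' Columns `chrom`, `start`, `end`, `name`, `score`, `strand`, `blockCount`,
#' `blockSizes`, `blockStarts` (0-based half-open, BED conventions; reads are
#' strand-ignored, written as `.`).
#'
#' @param reads read records (see [sim_reads()]).
#' @param path output file.
#' @export
write_reads_bed <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom, start = reads$start, end = reads$end,
                    name = reads$name, score = 0L, strand = ".",
                    blockCount = reads$n_blocks, blockSizes = reads$block_sizes,
                    blockStarts = reads$block_starts, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read read records from a BED12-style TSV
#'
#' @param path file written by [write_reads_bed()] (or any TSV with the same
#'   header).
#' @return read-records data.frame (columns `chrom`, `start`, `end`, `name`,
#'   `n_blocks`, `block_sizes`, `block_starts`).
#' @export
read_reads_bed <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(blockSizes = "character",
                                         blockStarts = "character"))
  need <- c("chrom", "start", "end", "name", "blockCount", "blockSizes",
            "blockStarts")
  if (!all(need %in% names(df)))
    stop_invalid("malformed reads file: need columns %s",
                 paste(need, collapse = ", "))
  data.frame(chrom = df$chrom, start = as.integer(df$start),
             end = as.integer(df$end), name = df$name,
             n_blocks = as.integer(df$blockCount),
             block_sizes = df$blockSizes, block_starts = df$blockStarts,
             stringsAsFactors = FALSE)
}

#' Write / read per-cell fluorescence tables
#'
#' Long CSV with one row per cell: `well`, `conc_a`, `conc_b`, `fitc_h`,
#' `fsc_h`.
#'
#' @param cells cells data.frame (see [sim_flow_grid()]).
#' @param path file path.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells[, c("well", "conc_a", "conc_b", "fitc_h", "fsc_h")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "conc_a", "conc_b", "fitc_h", "fsc_h")
  if (!all(need %in% names(df)))
    stop_invalid("malformed cells file: need columns %s",
                 paste(need, collapse = ", "))
  df
}

#' Write / read colony-count survival tables
#'
#' CSV with columns `population`, `timepoint_h`, `replicate`, `colonies`.
#'
#' @param table survival table (see [sim_survival()]).
#' @param path file path.
#' @export
write_survival_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_survival_table(df)
  structure(df, class = c("survival_table", "data.frame"))
}

#' Write / read OD growth curves as long CSV
#'
#' Columns `well`, `time_h`, `od`, one row per reading.
#'
#' @param curves list of `growth_curve` objects (or a single one).
#' @param path file path.
#' @export
write_growth_csv <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  long <- do.call(rbind, lapply(curves, function(cv)
    data.frame(well = cv$well_id, time_h = cv$times, od = cv$od,
               stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "od")
  if (!all(need %in% names(df)))
    stop_invalid("malformed growth file: need columns %s",
                 paste(need, collapse = ", "))
  lapply(split(df, factor(df$well, levels = unique(df$well))), function(g) {
    g <- g[order(g$time_h), ]
    growth_curve(g$time_h, g$od, well_id = g$well[1])
  })
}

#' Write / read feature-count tables as TSV
#'
#' One row per feature: `gene_id`, `feature` (`cds` or `intron<k>`), `class`,
#' `length`, `count`, and for introns the junction-end counts `n5`, `n3`
#' (`NA` unless supplied).
#'
#' @param counts `feature_counts` object.
#' @param path file path.
#' @param end_counts optional table from [count_intron_end_overlaps()].
#' @export
write_counts_tsv <- function(counts, path, end_counts = NULL) {
  g <- counts$genes
  rows <- data.frame(gene_id = g$gene_id, feature = "cds", class = "cds",
                     length = g$cds_length, count = g$cds_count,
                     n5 = NA_integer_, n3 = NA_integer_,
                     stringsAsFactors = FALSE)
  if (nrow(counts$introns)) {
    it <- counts$introns
    n5 <- n3 <- rep(NA_integer_, nrow(it))
    if (!is.null(end_counts)) {
      m <- match(paste(it$gene_id, it$intron),
                 paste(end_counts$gene_id, end_counts$intron))
      n5 <- end_counts$n5[m]; n3 <- end_counts$n3[m]
    }
    rows <- rbind(rows, data.frame(gene_id = it$gene_id,
                                   feature = paste0("intron", it$intron),
                                   class = it$class, length = it$length,
                                   count = it$count, n5 = n5, n3 = n3,
                                   stringsAsFactors = FALSE))
  }
  attr_line <- sprintf("# read_length=%s", as.character(counts$read_length))
  writeLines(attr_line, path)
  suppressWarnings(utils::write.table(rows, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  rl <- if (grepl("^# read_length=", first))
    suppressWarnings(as.integer(sub("^# read_length=", "", first)))
  else NA_integer_
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "feature", "class", "length", "count")
  if (!all(need %in% names(df)))
    stop_invalid("malformed counts file: need columns %s",
                 paste(need, collapse = ", "))
  cds <- df[df$feature == "cds", ]
  genes <- data.frame(gene_id = cds$gene_id, cds_count = cds$count,
                      cds_length = cds$length, stringsAsFactors = FALSE)
  it <- df[df$feature != "cds", ]
  introns <- data.frame(gene_id = it$gene_id,
                        intron = as.integer(sub("^intron", "", it$feature)),
                        class = it$class, start = NA_integer_,
                        end = NA_integer_, length = it$length,
                        count = it$count, stringsAsFactors = FALSE)
  end_counts <- if ("n5" %in% names(it) && any(!is.na(it$n5)))
    data.frame(gene_id = introns$gene_id, intron = introns$intron,
               class = introns$class, n5 = it$n5, n3 = it$n3,
               stringsAsFactors = FALSE)
  else NULL
  structure(list(genes = genes, introns = introns, read_length = rl,
                 n_ignored = 0L, end_counts = end_counts),
            class = "feature_counts")
}

#' Write / read gene sets as two-column TSV
#'
#' Columns `set_name`, `gene_id`; one row per membership.
#'
#' @param gene_sets named list of character vectors.
#' @param path file path.
#' @export
write_gene_sets <- function(gene_sets, path) {
  df <- data.frame(set_name = rep(names(gene_sets), lengths(gene_sets)),
                   gene_id = unlist(gene_sets, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene_id") %in% names(df)))
    stop_invalid("malformed gene-set file: need columns set_name, gene_id")
  lapply(split(df$gene_id, factor(df$set_name, levels = unique(df$set_name))),
         unique)
}
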