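#' Write reads as BED6
#'
#' Reads are stored internally as 5' positions; BED intervals are emitted with
#' a nominal read length (the 5' end is `start` for `+` reads and `end - 1`
#' for `-` reads).
#'
#' @param reads Read data.frame (`chrom`, `pos`, `strand`).
#' @param path Output path.
#' @param read_length Nominal read length in bp.
#' @param genome Optional `genome_spec` (or named length vector) used to clip
#'   intervals at chromosome ends.
#' @export
write_reads_bed <- function(reads, path, read_length = 50L, genome = NULL) {
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$pos, pmax(0L, reads$pos + 1L - read_length))
  end <- ifelse(plus, reads$pos + read_length, reads$pos + 1L)
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    end <- pmin(end, lens[reads$chrom])
  }
  df <- data.frame(reads$chrom, as.integer(start), as.integer(end),
                   sprintf("read%d", seq_len(nrow(reads))), 0L, reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 reads back to 5' positions
#'
#' @param path BED6 file.
#' @return Read data.frame (`chrom`, `pos`, `strand`).
#' @export
read_reads_bed <- function(path) {
  bed <- read_bed_intervals(path)
  if (is.null(bed$strand)) stop("BED6 with a strand column is required")
  data.frame(chrom = bed$chrom,
             pos = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Parse a BED interval file
#'
#' Accepts BED3+ with optional name/score/strand columns; `track`, `browser`
#' and `#` comment lines are skipped. Malformed lines raise an error naming
#' the offending line number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", idx[which(nf < 3)[1]], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | end < start
  if (any(bad)) {
    stop("malformed BED line ", idx[which(bad)[1]],
         ": invalid start/end coordinates")
  }
  out <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[`, "", 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  if (all(nf >= 6)) out$strand <- vapply(fields, `[`, "", 6)
  out
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, start, end, name (peak id), score
#' (`round(100 * log2(fold))`), strand (`.`), then summit, support and strand
#' balance.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   round(100 * log2(peaks$enrichment)), ".",
                   peaks$summit, peaks$support, signif(peaks$balance, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from the BED6+3 layout written by [write_peaks_bed()]
#'
#' @param path BED6+3 file.
#' @param stage Optional stage label to stamp on the peaks.
#' @return Peak data.frame in the [call_peaks()] layout.
#' @export
read_peaks_bed <- function(path, stage = NA_character_) {
  f <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(f) < 9) stop("expected BED6+3 with summit, support and balance columns")
  data.frame(peak_id = f[[4]], chrom = f[[1]], start = as.integer(f[[2]]),
             end = as.integer(f[[3]]), summit = as.integer(f[[7]]),
             enrichment = 2^(f[[5]] / 100), support = as.integer(f[[8]]),
             balance = as.numeric(f[[9]]), stage = stage,
             stringsAsFactors = FALSE)
}

#' Write a count matrix and its sample metadata as TSV
#'
#' @param counts Gene x sample matrix.
#' @param meta Sample sheet data.frame.
#' @param counts_path,meta_path Output paths.
#' @export
write_counts_tsv <- function(counts, meta, counts_path, meta_path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix (genes x samples) from TSV
#'
#' @param counts_path TSV with a `gene_id` first column.
#' @param meta_path Optional sample-sheet TSV.
#' @return List with `counts` matrix and `meta` (NULL when not given).
#' @export
read_counts_tsv <- function(counts_path, meta_path = NULL) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  meta <- if (!is.null(meta_path)) {
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  list(counts = counts, meta = meta)
}

#' Import an externally computed differential-expression table
#'
#' Accepts tables in the layout (gene, comparison, likelihood, FDR, direction)
#' produced by posterior-likelihood DE engines. Genes whose posterior
#' likelihood does not exceed `likelihood_min` are treated as not
#' differentially expressed for downstream scoring.
#'
#' @param x A TSV path or a data.frame.
#' @param likelihood_min Posterior-likelihood threshold (strict).
#' @return Standardized data.frame: `gene_id`, `comparison`, `fdr`,
#'   `direction`, `likelihood`, `significant`.
#' @export
import_de_results <- function(x, likelihood_min = 0.9) {
  de <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else x
  names(de) <- tolower(names(de))
  need <- c("gene_id", "fdr", "direction")
  alias <- c(gene = "gene_id", ddb_g = "gene_id", lik = "likelihood")
  for (a in names(alias)) {
    if (a %in% names(de) && !(alias[[a]] %in% names(de))) {
      names(de)[names(de) == a] <- alias[[a]]
    }
  }
  if (!all(need %in% names(de))) {
    stop("external DE table must provide columns: ",
         paste(need, collapse = ", "))
  }
  if (is.null(de$comparison)) de$comparison <- NA_character_
  if (is.null(de$likelihood)) de$likelihood <- NA_real_
  de$significant <- de$fdr < 0.05 &
    (is.na(de$likelihood) | de$likelihood > likelihood_min)
  de[, c("gene_id", "comparison", "fdr", "direction", "likelihood",
         "significant")]
}
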