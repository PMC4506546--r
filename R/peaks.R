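#' Cap duplicate reads at identical coordinates
#'
#' Retains at most `cap` reads per (chromosome, 5' position, strand) triple,
#' keeping the first-seen reads in input order. PCR duplicates beyond the cap
#' inflate local coverage without adding evidence, so the caller works on the
#' capped set.
#'
#' @param reads Read data.frame (`chrom`, `pos`, `strand`).
#' @param cap Maximum reads per coordinate triple (default 5).
#' @return The filtered read data.frame, in the original row order.
#' @export
deduplicate_reads <- function(reads, cap = 5L) {
  stopifnot(cap >= 1)
  n <- nrow(reads)
  if (n == 0) return(reads)
  chrom_i <- match(reads$chrom, unique(reads$chrom))
  strand_i <- as.integer(reads$strand == "+")
  key <- (chrom_i * 2 + strand_i) * (max(reads$pos) + 1) + reads$pos
  ord <- order(key, method = "radix")  # stable: ties keep input order
  occ <- sequence(rle(key[ord])$lengths)
  keep <- sort(ord[occ <= cap])
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window scaled log ratios of sample vs control coverage
#'
#' Tiles every chromosome with 200-bp windows overlapping by 50% and computes,
#' per window, the log2 ratio of library-size-scaled read counts between the
#' sample and control libraries, with a pseudocount to keep ratios finite:
#' `log2((c_s/N_s + p/N_s) / (c_c/N_c + p/N_c))` where `c` is the window read
#' count (by 5' position, half-open membership), `N` the library size and `p`
#' the pseudocount. 5-kb regions are a processing partition only: window
#' coordinates tile each chromosome identically regardless of `region`.
#'
#' @param sample,control Read data.frames (`chrom`, `pos`, `strand`), already
#'   deduplicated.
#' @param genome A `genome_spec` or named chromosome-length vector.
#' @param window Window size in bp (even).
#' @param step Step between window starts; must equal `window / 2`.
#' @param region Processing-partition size (bp); has no effect on results.
#' @param pseudocount Pseudocount in reads.
#' @return data.frame with `chrom`, `start`, `end`, `sample_count`,
#'   `control_count`, `log_ratio`, and `pvalue`/`qvalue` columns left `NA`
#'   until [estimate_window_fdr()] fills them.
#' @export
compute_window_stats <- function(sample, control, genome, window = 200L,
                                 step = window %/% 2L, region = 5000L,
                                 pseudocount = 1) {
  stopifnot(window %% 2L == 0L, step == window %/% 2L, pseudocount >= 0)
  lens <- chrom_lengths(genome)
  ns <- nrow(sample); nc <- nrow(control)
  if (nc == 0) stop("empty control library: cannot scale coverage")
  if (ns == 0) stop("empty sample library: cannot scale coverage")
  res <- lapply(names(lens), function(chr) {
    L <- lens[[chr]]
    nstart <- floor((L - window) / step) + 1L
    if (nstart < 1) return(NULL)
    nb <- nstart + 1L
    bin_counts <- function(reads) {
      p <- reads$pos[reads$chrom == chr]
      p <- p[p < nb * step]
      tabulate(p %/% step + 1L, nbins = nb)
    }
    bs <- bin_counts(sample)
    bc <- bin_counts(control)
    i <- seq_len(nstart)
    cs <- bs[i] + bs[i + 1L]
    cc <- bc[i] + bc[i + 1L]
    data.frame(chrom = chr,
               start = as.integer((i - 1L) * step),
               end = as.integer((i - 1L) * step + window),
               sample_count = cs, control_count = cc,
               log_ratio = log2(((cs + pseudocount) / ns) /
                                ((cc + pseudocount) / nc)),
               pvalue = NA_real_, qvalue = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Empirical window-level FDR from a label-swap null
#'
#' Fills per-window p-values as the add-one empirical exceedance probability of
#' each window's log ratio under a null set of window statistics (canonically
#' produced by swapping the sample and control labels on the same libraries),
#' then converts to q-values by Benjamini-Hochberg across all windows.
#'
#' @param stats Window statistics from [compute_window_stats()].
#' @param null_stats Window statistics of the label-swapped (or otherwise null)
#'   configuration.
#' @return `stats` with `pvalue` and `qvalue` filled.
#' @export
estimate_window_fdr <- function(stats, null_stats) {
  b <- nrow(null_stats)
  if (b == 0) stop("empty null window set: cannot calibrate FDR")
  snull <- sort(null_stats$log_ratio)
  n_ge <- b - findInterval(stats$log_ratio, snull, left.open = TRUE)
  stats$pvalue <- (n_ge + 1) / (b + 1)
  stats$qvalue <- stats::p.adjust(stats$pvalue, method = "BH")
  stats
}

#' Call peaks from thresholded windows
#'
#' Windows passing the enrichment, FDR and (after merging) read-support
#' thresholds become peaks. Overlapping or book-ended significant windows are
#' merged. For each candidate peak the strand shift is estimated by scanning
#' integer offsets up to `shift_max` for the one maximizing the Pearson
#' correlation of 10-bp-binned plus- and minus-strand 5' profiles; reads are
#' shifted toward each other by half that offset and the summit is the
#' leftmost maximum of the combined, 51-bp-smoothed shifted profile. Read
#' support and strand balance are evaluated on the shift-corrected reads
#' falling inside the merged peak, so that a peak whose significant windows
#' cover only one strand's pile is still judged on both piles. Candidates
#' with dissimilar read support on the two strands
#' (`|log2(plus/minus)| >= balance_max`) are discarded as artifacts. All
#' threshold comparisons are strict: fold `>` `fold_min`, q `<` `fdr_max`,
#' support `>` `support_min`, balance `<` `balance_max`.
#'
#' @param stats Window statistics with q-values (see [estimate_window_fdr()]).
#' @param sample Deduplicated sample reads used for summits and support.
#' @param fold_min Linear fold-enrichment threshold (exclusive).
#' @param fdr_max q-value threshold (exclusive).
#' @param support_min Sample-read support threshold on the merged peak
#'   (exclusive).
#' @param shift_max Maximum strand shift considered (bp).
#' @param balance_max Strand-balance threshold (exclusive upper bound on the
#'   absolute log2 plus/minus support ratio).
#' @param stage Optional stage label stored on the peaks.
#' @return Peak data.frame: `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `enrichment` (linear fold, `2^max window log ratio`), `support`,
#'   `balance`, `stage`. Zero rows when nothing passes.
#' @export
call_peaks <- function(stats, sample, fold_min = 4, fdr_max = 0.01,
                       support_min = 50, shift_max = 200L, balance_max = 0.5,
                       stage = NA_character_) {
  if (anyNA(stats$qvalue)) {
    stop("window stats carry no q-values; run estimate_window_fdr() first")
  }
  empty <- data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), enrichment = numeric(0),
                      support = integer(0), balance = numeric(0),
                      stage = character(0), stringsAsFactors = FALSE)
  sig <- 2^stats$log_ratio > fold_min & stats$qvalue < fdr_max
  s <- stats[sig, , drop = FALSE]
  if (nrow(s) == 0) return(empty)
  bin <- 10L
  out <- list()
  for (chr in unique(s$chrom)) {
    sc <- s[s$chrom == chr, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(sc$start + 1L, sc$end))
    pos <- sample$pos[sample$chrom == chr]
    strand <- sample$strand[sample$chrom == chr]
    for (j in seq_along(merged)) {
      p_start <- BiocGenerics::start(merged)[j] - 1L
      p_end <- BiocGenerics::end(merged)[j]
      ps <- p_start - shift_max
      pe <- p_end + shift_max
      in_pad <- pos >= ps & pos < pe
      plus <- pos[in_pad & strand == "+"]
      minus <- pos[in_pad & strand == "-"]
      shift <- estimate_strand_shift(plus, minus, ps, pe, shift_max, bin)
      half <- shift %/% 2L
      plus_s <- plus + half
      minus_s <- minus - (shift - half)
      in_plus <- plus_s >= p_start & plus_s < p_end
      in_minus <- minus_s >= p_start & minus_s < p_end
      shifted <- c(plus_s[in_plus], minus_s[in_minus])
      width <- p_end - p_start
      summit <- if (length(shifted)) {
        prof <- tabulate(shifted - p_start + 1L, nbins = width)
        # smooth with a centred 51-bp moving sum before taking the mode
        cs <- cumsum(c(0, prof))
        idx <- seq_len(width)
        sm <- cs[pmin(width, idx + 25L) + 1L] - cs[pmax(1L, idx - 25L) - 1L + 1L]
        p_start + which.max(sm) - 1L  # leftmost maximum
      } else p_start
      n_plus <- sum(in_plus)
      n_minus <- sum(in_minus)
      support <- n_plus + n_minus
      balance <- strand_balance(n_plus, n_minus)
      wsel <- sc$start < p_end & sc$end > p_start
      enrichment <- 2^max(sc$log_ratio[wsel])
      if (support > support_min && balance < balance_max) {
        out[[length(out) + 1L]] <- data.frame(
          peak_id = NA_character_, chrom = chr, start = p_start, end = p_end,
          summit = as.integer(summit), enrichment = enrichment,
          support = as.integer(support), balance = balance, stage = stage,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  peaks <- do.call(rbind, out)
  tag <- if (is.na(stage)) "pk" else paste0(stage, "_pk")
  peaks$peak_id <- sprintf("%s%04d", tag, seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks
}

# Offset (bp, multiple of `bin`, in [0, shift_max]) maximizing the Pearson
# correlation between the plus-strand profile and the minus-strand profile
# shifted left; ties break toward the smallest offset.
estimate_strand_shift <- function(plus, minus, ps, pe, shift_max, bin = 10L) {
  nb <- as.integer((pe - ps) %/% bin)
  if (nb < 4 || length(plus) == 0 || length(minus) == 0) return(0L)
  pp <- tabulate(pmin((plus - ps) %/% bin + 1L, nb), nbins = nb)
  mm <- tabulate(pmin((minus - ps) %/% bin + 1L, nb), nbins = nb)
  best <- 0L
  best_cor <- -Inf
  for (k in 0:(shift_max %/% bin)) {
    if (nb - k < 3) break
    a <- pp[seq_len(nb - k)]
    b <- mm[seq_len(nb - k) + k]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (!is.na(r) && r > best_cor + 1e-12) {
      best_cor <- r
      best <- k
    }
  }
  as.integer(best * bin)
}

#' Strand balance of a candidate peak
#'
#' Absolute log2 ratio of plus- to minus-strand read support; `Inf` when one
#' strand has no reads. Peaks are kept only when this is strictly below the
#' balance threshold.
#'
#' @param n_plus,n_minus Strand-specific read counts.
#' @return Non-negative numeric (possibly `Inf`).
#' @export
strand_balance <- function(n_plus, n_minus) {
  b <- abs(log2(n_plus / n_minus))
  b[is.nan(b)] <- Inf
  b
}

#' Intersect called peaks with an external interval list
#'
#' Retains internal peaks overlapping (by at least 1 bp) any interval of an
#' externally produced list, e.g. a peak set from an independent caller. With
#' `external = NULL` the peak list is returned unchanged.
#'
#' @param internal Peak data.frame from [call_peaks()].
#' @param external A BED file path, or a data.frame with `chrom`, `start`,
#'   `end` (0-based half-open), or `NULL`.
#' @return The filtered peak data.frame.
#' @export
intersect_peaks <- function(internal, external = NULL) {
  if (is.null(external)) return(internal)
  if (is.character(external)) external <- read_bed_intervals(external)
  if (nrow(internal) == 0) return(internal)
  if (nrow(external) == 0) return(internal[0, , drop = FALSE])
  gi <- GenomicRanges::GRanges(internal$chrom,
                               IRanges::IRanges(internal$start + 1L,
                                                internal$end))
  ge <- GenomicRanges::GRanges(external$chrom,
                               IRanges::IRanges(external$start + 1L,
                                                external$end))
  hit <- GenomicRanges::countOverlaps(gi, ge) > 0
  out <- internal[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
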