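#' Define promoter regions
#'
#' The promoter of a gene is the intergenic region 5' of its ORF, running from
#' the transcription start to the nearest annotated boundary of any other gene
#' (regardless of that gene's strand), or to the chromosome end when no such
#' boundary exists. For `+` genes the promoter ends at the gene start; for `-`
#' genes it begins at the gene end. Optionally truncated to `max_len` bp
#' closest to the transcription start.
#'
#' @param genome A `genome_spec`.
#' @param max_len Optional maximum promoter length in bp (default: none).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (0-based half-open;
#'   possibly zero-length when genes abut), `strand`.
#' @export
define_promoters <- function(genome, max_len = NULL) {
  lens <- chrom_lengths(genome)
  g <- genome$genes
  out <- lapply(split(g, g$chrom), function(gc) {
    L <- lens[[gc$chrom[1]]]
    bnd <- sort(c(gc$start, gc$end))
    p_start <- integer(nrow(gc)); p_end <- integer(nrow(gc))
    for (i in seq_len(nrow(gc))) {
      if (gc$strand[i] == "+") {
        s <- gc$start[i]
        idx <- findInterval(s, bnd)              # boundaries <= s
        n_eq <- idx - findInterval(s - 1L, bnd)  # boundaries == s (incl. own start)
        lower <- if (n_eq >= 2) s else if (idx - 1L >= 1L) bnd[idx - 1L] else 0L
        p_start[i] <- lower; p_end[i] <- s
      } else {
        e <- gc$end[i]
        idx <- findInterval(e, bnd)              # boundaries <= e
        n_eq <- idx - findInterval(e - 1L, bnd)  # boundaries == e (incl. own end)
        upper <- if (n_eq >= 2) e else if (idx + 1L <= length(bnd)) bnd[idx + 1L] else L
        p_start[i] <- e; p_end[i] <- upper
      }
    }
    data.frame(gene_id = gc$gene_id, chrom = gc$chrom,
               start = as.integer(p_start), end = as.integer(p_end),
               strand = gc$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(max_len)) {
    plus <- out$strand == "+"
    out$start[plus] <- pmax(out$start[plus], out$end[plus] - as.integer(max_len))
    out$end[!plus] <- pmin(out$end[!plus], out$start[!plus] + as.integer(max_len))
  }
  out[match(genome$genes$gene_id, out$gene_id), , drop = FALSE]
}

#' Assign peaks to genes through their promoters
#'
#' A peak is assigned to a gene when its summit lies within that gene's
#' promoter (half-open membership). A single peak can serve two genes whose
#' divergent promoters share the intergenic region. Peaks whose summit falls
#' inside any gene body are dropped: only intergenic peaks are considered.
#'
#' @param peaks Peak data.frame (needs `peak_id`, `chrom`, `summit`,
#'   `enrichment`, `stage`).
#' @param promoters Promoter table from [define_promoters()].
#' @param genome A `genome_spec` (for the gene bodies used by the intergenic
#'   filter).
#' @return data.frame of assignments: `gene_id` plus the peak columns.
#' @export
assign_peaks_to_genes <- function(peaks, promoters, genome) {
  empty <- cbind(data.frame(gene_id = character(0), stringsAsFactors = FALSE),
                 peaks[0, , drop = FALSE])
  if (nrow(peaks) == 0) return(empty)
  summits <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$summit + 1L,
                                                     peaks$summit + 1L))
  g <- genome$genes
  bodies <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  intergenic <- GenomicRanges::countOverlaps(summits, bodies) == 0
  pk <- peaks[intergenic, , drop = FALSE]
  if (nrow(pk) == 0) return(empty)
  pr <- promoters[promoters$end > promoters$start, , drop = FALSE]
  if (nrow(pr) == 0) return(empty)
  pgr <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$start + 1L, pr$end))
  sgr <- GenomicRanges::GRanges(pk$chrom,
                                IRanges::IRanges(pk$summit + 1L, pk$summit + 1L))
  hits <- GenomicRanges::findOverlaps(sgr, pgr)
  out <- cbind(data.frame(gene_id = pr$gene_id[S4Vectors::subjectHits(hits)],
                          stringsAsFactors = FALSE),
               pk[S4Vectors::queryHits(hits), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Distance-decay binding score for one gene
#'
#' Each assigned peak contributes `log2(fold) * exp(-decay * d)` where `d` is
#' the summit's distance to the gene's transcription start expressed as a
#' fraction of the promoter length (0 at the start, 1 at the far end). Scores
#' are additive over peaks. A zero-length promoter takes `d = 0`.
#'
#' @param gene_peaks Peaks assigned to this gene (needs `summit`,
#'   `enrichment`, optionally `peak_id`).
#' @param promoter A single promoter row from [define_promoters()].
#' @param decay Decay constant; at the far promoter end the weight is
#'   `exp(-decay)` (about 0.7% of the proximal weight at the default 5).
#' @return List: `gene_id`, `score`, `peaks` (contributing peak ids).
#' @export
compute_binding_score <- function(gene_peaks, promoter, decay = 5) {
  if (nrow(gene_peaks) == 0) {
    return(list(gene_id = promoter$gene_id, score = 0, peaks = character(0)))
  }
  w <- distance_decay_weight(gene_peaks$summit, promoter, decay)
  list(gene_id = promoter$gene_id,
       score = sum(log2(gene_peaks$enrichment) * w),
       peaks = if (!is.null(gene_peaks$peak_id)) gene_peaks$peak_id else character(0))
}

distance_decay_weight <- function(summit, promoter, decay) {
  pl <- promoter$end - promoter$start
  tss <- if (promoter$strand == "+") promoter$end else promoter$start
  d <- if (pl <= 0) rep(0, length(summit)) else pmin(1, abs(summit - tss) / pl)
  exp(-decay * d)
}

#' Gene-by-stage binding score table
#'
#' Computes the distance-decay binding score of every gene at every stage from
#' the peak-to-gene assignments; genes with no assigned peaks score 0.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param promoters Promoter table.
#' @param genome A `genome_spec` (fixes the gene universe and ordering).
#' @param stages Stage labels (columns of the result); defaults to the stages
#'   present in the assignments.
#' @param decay Decay constant, see [compute_binding_score()].
#' @return data.frame with `gene_id` and one numeric score column per stage.
#' @export
binding_score_table <- function(assignments, promoters, genome,
                                stages = NULL, decay = 5) {
  if (is.null(stages)) stages <- unique(assignments$stage)
  ids <- genome$genes$gene_id
  scores <- matrix(0, nrow = length(ids), ncol = length(stages),
                   dimnames = list(ids, stages))
  if (nrow(assignments) > 0) {
    pr <- promoters[match(assignments$gene_id, promoters$gene_id), ]
    pl <- pr$end - pr$start
    tss <- ifelse(pr$strand == "+", pr$end, pr$start)
    d <- ifelse(pl <= 0, 0, pmin(1, abs(assignments$summit - tss) / pl))
    contrib <- log2(assignments$enrichment) * exp(-decay * d)
    for (st in stages) {
      sel <- assignments$stage == st
      if (any(sel)) {
        agg <- rowsum(contrib[sel], assignments$gene_id[sel])
        scores[rownames(agg), st] <- agg[, 1]
      }
    }
  }
  data.frame(gene_id = ids, scores, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes as bound per stage
#'
#' A gene is bound at a stage iff at least one peak assigned to its promoter
#' at that stage has enrichment strictly greater than `fold_min`. Also returns
#' the union across stages and the genes bound at exactly one stage.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param stages Stage labels to evaluate.
#' @param fold_min Fold-enrichment threshold (strict).
#' @return List: `per_stage` (named list of gene-id vectors), `union`,
#'   `single_stage` (named list of genes bound only at that stage),
#'   `n_stages` (data.frame gene_id / number of bound stages).
#' @export
classify_bound_genes <- function(assignments, stages = NULL, fold_min = 4) {
  if (is.null(stages)) stages <- unique(assignments$stage)
  hit <- assignments[assignments$enrichment > fold_min, , drop = FALSE]
  per_stage <- lapply(stages, function(st) {
    sort(unique(hit$gene_id[hit$stage == st]))
  })
  names(per_stage) <- stages
  all_genes <- sort(unique(unlist(per_stage)))
  n_st <- vapply(all_genes, function(g) {
    sum(vapply(per_stage, function(s) g %in% s, logical(1)))
  }, integer(1))
  single <- lapply(stages, function(st) {
    sort(intersect(per_stage[[st]], all_genes[n_st == 1]))
  })
  names(single) <- stages
  list(per_stage = per_stage, union = all_genes, single_stage = single,
       n_stages = data.frame(gene_id = all_genes, n_stages = unname(n_st),
                             stringsAsFactors = FALSE))
}
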