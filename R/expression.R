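#' Median-of-ratios normalization
#'
#' Size factors are per-sample medians of the count ratios to a geometric-mean
#' reference gene profile, computed over genes with all-positive counts;
#' factors are rescaled to have geometric mean 1 so that re-normalizing a
#' normalized matrix yields factors of 1.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @return List: `norm` (normalized matrix), `size_factors` (named vector).
#' @export
normalize_counts <- function(counts) {
  if (all(counts == 0)) stop("all-zero count matrix cannot be normalized")
  ref <- exp(rowMeans(log(counts)))  # geometric mean; 0 for rows with zeros
  use <- ref > 0
  if (!any(use)) stop("no gene has positive counts in every sample; cannot normalize")
  sf <- apply(counts[use, , drop = FALSE], 2, function(x) {
    stats::median(x / ref[use])
  })
  sf <- sf / exp(mean(log(sf)))
  list(norm = sweep(counts, 2, sf, "/"), size_factors = sf)
}

# Pooled method-of-moments NB dispersion from within-group means/variances:
# alpha = sum_g (v_g - m_g) / sum_g m_g^2, clamped at 0. The pooled ratio is
# used instead of a per-gene median because n=2 variance estimates are too
# noisy individually and their median is biased low.
estimate_dispersion <- function(norm, groups) {
  num <- 0
  den <- 0
  for (g in groups) {
    sub <- norm[, g, drop = FALSE]
    if (ncol(sub) < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    keep <- m > 1
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den == 0) return(0.01)  # no replication: fall back to mild overdispersion
  max(0, num / den)
}

#' Differential-expression test between two sample groups
#'
#' A negative-binomial exact-style test on the summed normalized counts of
#' each group: under the null the group-A sum is distributed
#' `NB(mean = n_A * mu0, size = n_A / alpha)` with `mu0` the pooled
#' per-sample mean and `alpha` a moment-matched dispersion shared across
#' genes (Poisson when `alpha = 0`). The two-sided p-value doubles the
#' smaller tail; q-values are Benjamini-Hochberg. Direction compares the
#' group means of normalized counts.
#'
#' @param norm Gene x sample matrix of normalized counts.
#' @param group_a,group_b Disjoint, non-empty sets of column names or indices.
#' @param fdr_max Significance threshold used downstream (strict).
#' @param comparison Optional label stored on each row.
#' @param dispersion Optional fixed dispersion; estimated from within-group
#'   variability when `NULL`.
#' @return data.frame: `gene_id`, `comparison`, `pvalue`, `fdr`, `direction`
#'   (`greater`/`lesser`/`equal`, A vs B), `mean_a`, `mean_b`, `score`
#'   (`NA` until [compute_de_score()]).
#' @export
call_de <- function(norm, group_a, group_b, fdr_max = 0.05,
                    comparison = NULL, dispersion = NULL) {
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  if (ncol(A) == 0 || ncol(B) == 0) stop("both groups must be non-empty")
  if (length(intersect(colnames(A), colnames(B))) > 0) {
    stop("groups must be disjoint")
  }
  if (sum(A) == 0 || sum(B) == 0) {
    stop("degenerate group: zero total counts")
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(norm, list(colnames(A), colnames(B)))
  }
  sa <- round(rowSums(A))
  sb <- round(rowSums(B))
  na <- ncol(A); nb <- ncol(B)
  mu <- na * (sa + sb) / (na + nb)
  if (dispersion > 0) {
    size <- na / dispersion
    p_lo <- stats::pnbinom(sa, mu = mu, size = size)
    p_hi <- 1 - stats::pnbinom(sa - 1, mu = mu, size = size)
  } else {
    p_lo <- stats::ppois(sa, mu)
    p_hi <- 1 - stats::ppois(sa - 1, mu)
  }
  p <- pmin(1, 2 * pmin(p_lo, p_hi))
  p[sa + sb == 0] <- 1
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  data.frame(
    gene_id = rownames(norm),
    comparison = if (is.null(comparison)) NA_character_ else comparison,
    pvalue = p,
    fdr = stats::p.adjust(p, method = "BH"),
    direction = ifelse(mean_a > mean_b, "greater",
                       ifelse(mean_a < mean_b, "lesser", "equal")),
    mean_a = mean_a, mean_b = mean_b, score = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression scores
#'
#' For genes passing the FDR gate the score is the log2 ratio of average
#' normalized expression between the two groups (with a pseudocount); all
#' other genes score exactly 0.
#'
#' @param de DE table from [call_de()] (or [import_de_results()] merged with
#'   group means).
#' @param fdr_max FDR gate (strict).
#' @param pseudocount Added to both means before the ratio.
#' @return `de` with the `score` column filled.
#' @export
compute_de_score <- function(de, fdr_max = 0.05, pseudocount = 1) {
  gate <- de$fdr < fdr_max
  if (!is.null(de$likelihood)) {
    gate <- gate & (is.na(de$likelihood) | de$likelihood > 0.9)
  }
  de$score <- ifelse(gate,
                     log2((de$mean_a + pseudocount) /
                          (de$mean_b + pseudocount)),
                     0)
  de
}

#' Categorize genes as UP, DOWN or NDE
#'
#' UP: significantly differentially expressed with higher average normalized
#' abundance in group A than B; DOWN: lower; NDE otherwise.
#'
#' @param de Scored DE table.
#' @param fdr_max FDR gate (strict).
#' @return Named character vector (gene_id -> category).
#' @export
categorize_updown <- function(de, fdr_max = 0.05) {
  gate <- de$fdr < fdr_max
  if (!is.null(de$likelihood)) {
    gate <- gate & (is.na(de$likelihood) | de$likelihood > 0.9)
  }
  cat <- ifelse(gate & de$mean_a > de$mean_b, "UP",
                ifelse(gate & de$mean_a < de$mean_b, "DOWN", "NDE"))
  stats::setNames(cat, de$gene_id)
}

#' Developmentally regulated genes within one genotype
#'
#' A gene is developmentally regulated when any comparison between consecutive
#' time points within the genotype is significant.
#'
#' @param norm Gene x sample matrix of normalized counts.
#' @param meta Sample sheet (`sample`, `genotype`, `timepoint`).
#' @param genotype Genotype label to analyse.
#' @param fdr_max FDR gate per comparison (strict).
#' @param dispersion Optional fixed dispersion passed to [call_de()].
#' @return List: `regulated` (gene ids), `comparisons` (named list of DE
#'   tables, one per consecutive-timepoint pair).
#' @export
developmental_regulation <- function(norm, meta, genotype, fdr_max = 0.05,
                                     dispersion = NULL) {
  sub <- meta[meta$genotype == genotype, , drop = FALSE]
  tps <- sort(unique(sub$timepoint))
  if (length(tps) < 2) stop("genotype has fewer than two time points")
  comparisons <- list()
  reg <- rep(FALSE, nrow(norm))
  for (i in seq_len(length(tps) - 1)) {
    ga <- sub$sample[sub$timepoint == tps[i]]
    gb <- sub$sample[sub$timepoint == tps[i + 1]]
    lab <- sprintf("%s_%gh_vs_%gh", genotype, tps[i], tps[i + 1])
    de <- call_de(norm, ga, gb, fdr_max = fdr_max, comparison = lab,
                  dispersion = dispersion)
    comparisons[[lab]] <- de
    reg <- reg | de$fdr < fdr_max
  }
  list(regulated = rownames(norm)[reg], comparisons = comparisons)
}

#' Genes developmentally regulated in the normal strains and
#' genotype-differential
#'
#' Returns genes that are developmentally regulated in every `normal` genotype
#' and differentially expressed between at least one (normal, aberrant)
#' genotype pair at some shared time point.
#'
#' @param norm Normalized count matrix.
#' @param meta Sample sheet.
#' @param normal,aberrant Genotype labels.
#' @param fdr_max FDR gate (strict).
#' @param dispersion Optional fixed dispersion.
#' @return Character vector of gene ids.
#' @export
strain_differential_genes <- function(norm, meta, normal = c("WT", "CM"),
                                      aberrant = c("KO", "CS"),
                                      fdr_max = 0.05, dispersion = NULL) {
  dev_sets <- lapply(normal, function(g) {
    developmental_regulation(norm, meta, g, fdr_max, dispersion)$regulated
  })
  dev <- Reduce(intersect, dev_sets)
  diff_any <- rep(FALSE, nrow(norm))
  for (gn in normal) {
    for (ga in aberrant) {
      tps <- intersect(meta$timepoint[meta$genotype == gn],
                       meta$timepoint[meta$genotype == ga])
      for (tp in sort(unique(tps))) {
        a <- meta$sample[meta$genotype == gn & meta$timepoint == tp]
        b <- meta$sample[meta$genotype == ga & meta$timepoint == tp]
        de <- call_de(norm, a, b, fdr_max = fdr_max,
                      comparison = sprintf("%s_vs_%s_%gh", gn, ga, tp),
                      dispersion = dispersion)
        diff_any <- diff_any | de$fdr < fdr_max
      }
    }
  }
  intersect(dev, rownames(norm)[diff_any])
}
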