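#' Rank product of binding and differential-expression evidence
#'
#' Genes are ranked by binding score (rank 1 = highest score) and by the
#' absolute DE score (rank 1 = largest change), with average ranks on ties.
#' The rank product is `(binding_rank * de_rank) / N^2`, which lies in
#' `(0, 1]` and makes the target threshold independent of the universe size.
#'
#' @param binding data.frame (`gene_id`, `score`) or named numeric vector of
#'   binding scores.
#' @param de data.frame (`gene_id`, `score`) or named numeric vector of
#'   (signed) DE scores.
#' @param stage Optional stage label stored on each row.
#' @return data.frame: `gene_id`, `stage`, `binding_rank`, `de_rank`, `rp`.
#' @export
compute_rank_product <- function(binding, de, stage = NA_character_) {
  b <- as_score_vector(binding)
  d <- as_score_vector(de)
  if (!setequal(names(b), names(d))) {
    stop("binding and DE tables cover different gene universes")
  }
  d <- d[names(b)]
  n <- length(b)
  rb <- rank(-b, ties.method = "average")
  rd <- rank(-abs(d), ties.method = "average")
  data.frame(gene_id = names(b), stage = stage,
             binding_rank = unname(rb), de_rank = unname(rd),
             rp = unname(rb * rd / n^2),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_score_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", "score") %in% names(x)))
    stats::setNames(x$score, x$gene_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a (gene_id, score) data.frame or a named numeric vector")
  }
}

#' Call direct targets from per-stage rank products
#'
#' A gene is a direct target when its rank product is strictly below the
#' threshold at any stage. Also reports per-stage target sets and the
#' Venn-sector partition over stages.
#'
#' @param rp A rank-product data.frame or a (possibly named) list of them,
#'   one per stage.
#' @param threshold Rank-product threshold (strict).
#' @return List: `targets` (gene ids), `per_stage` (named list),
#'   `venn` (named integer vector of sector counts, names like `"S&E"`),
#'   `table` (gene x stage logical membership with `min_rp`).
#' @export
call_targets <- function(rp, threshold = 0.005) {
  if (is.data.frame(rp)) rp <- list(rp)
  if (is.null(names(rp)) || any(!nzchar(names(rp)))) {
    names(rp) <- vapply(rp, function(d) {
      if (!all(is.na(d$stage))) as.character(d$stage[1]) else "stage1"
    }, character(1))
  }
  stages <- names(rp)
  universe <- rp[[1]]$gene_id
  per_stage <- lapply(rp, function(d) {
    if (!setequal(d$gene_id, universe)) {
      stop("rank-product tables cover different gene universes")
    }
    sort(d$gene_id[d$rp < threshold])
  })
  targets <- sort(unique(unlist(per_stage)))
  member <- vapply(per_stage, function(s) targets %in% s,
                   logical(length(targets)))
  member <- matrix(member, nrow = length(targets),
                   dimnames = list(targets, stages))
  sector <- apply(member, 1, function(m) paste(stages[m], collapse = "&"))
  venn <- table(factor(sector, levels = venn_sector_names(stages)))
  min_rp <- do.call(pmin, lapply(rp, function(d) {
    d$rp[match(universe, d$gene_id)]
  }))
  list(targets = targets, per_stage = per_stage,
       venn = stats::setNames(as.integer(venn), names(venn)),
       table = data.frame(gene_id = targets, member,
                          min_rp = min_rp[match(targets, universe)],
                          stringsAsFactors = FALSE, row.names = NULL))
}

venn_sector_names <- function(stages) {
  combos <- unlist(lapply(seq_along(stages), function(k) {
    utils::combn(stages, k, paste, collapse = "&")
  }))
  combos
}

#' Permutation test for gene-set overlap
#'
#' Draws, in each of `B` replicates, two random gene sets of the observed
#' sizes uniformly without replacement from the universe and records their
#' overlap. The empirical p-value uses the add-one convention
#' `p = (#{permuted >= observed} + 1) / (B + 1)`, so it is never exactly zero.
#'
#' @param set_a,set_b Gene-id vectors (subsets of `universe`).
#' @param universe Gene universe.
#' @param B Number of permutation replicates.
#' @param seed Optional integer seed.
#' @return An `overlap_test` list: `n_a`, `n_b`, `n_universe`, `observed`,
#'   `B`, `p`, `null_overlaps` (integer vector of permuted overlaps).
#' @export
overlap_permutation_test <- function(set_a, set_b, universe, B = 1e6,
                                     seed = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  n <- length(universe)
  na <- length(set_a); nb <- length(set_b)
  if (na > n || nb > n) stop("set larger than universe")
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  observed <- length(intersect(set_a, set_b))
  member <- logical(n)
  null_overlaps <- integer(B)
  for (i in seq_len(B)) {
    a <- sample.int(n, na)
    b <- sample.int(n, nb)
    member[a] <- TRUE
    null_overlaps[i] <- sum(member[b])
    member[a] <- FALSE
  }
  p <- (sum(null_overlaps >= observed) + 1) / (B + 1)
  structure(list(n_a = na, n_b = nb, n_universe = n, observed = observed,
                 B = as.integer(B), p = p, null_overlaps = null_overlaps),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap test: |A|=%d, |B|=%d, universe=%d, observed=%d, B=%d, p=%.3g\n",
              x$n_a, x$n_b, x$n_universe, x$observed, x$B, x$p))
  invisible(x)
}

#' Compare binding-score distributions across expression categories
#'
#' Two-sample Kolmogorov-Smirnov tests of UP-vs-NDE and DOWN-vs-NDE binding
#' scores (asymptotic p-values), plus exportable ECDF tables.
#'
#' @param scores Named numeric vector of binding scores (gene_id names) or a
#'   (`gene_id`, `score`) data.frame.
#' @param categories Named character vector (gene_id -> UP/DOWN/NDE).
#' @return List: `tests` (data.frame `comparison`, `D`, `pvalue`, `n1`, `n2`)
#'   and `ecdf` (data.frame `category`, `score`, `ecdf`). Comparisons with an
#'   empty category are skipped with a warning.
#' @export
compare_binding_distributions <- function(scores, categories) {
  s <- as_score_vector(if (is.data.frame(scores)) scores else scores)
  common <- intersect(names(s), names(categories))
  s <- s[common]; categories <- categories[common]
  nde <- s[categories == "NDE"]
  rows <- list()
  for (cmp in c("UP", "DOWN")) {
    grp <- s[categories == cmp]
    if (length(grp) == 0 || length(nde) == 0) {
      warning("empty category in ", cmp, "-vs-NDE comparison; skipped")
      next
    }
    kt <- suppressWarnings(stats::ks.test(grp, nde, exact = FALSE))
    rows[[cmp]] <- data.frame(comparison = paste0(cmp, "-vs-NDE"),
                              D = unname(kt$statistic),
                              pvalue = kt$p.value,
                              n1 = length(grp), n2 = length(nde),
                              stringsAsFactors = FALSE)
  }
  ecdf_tab <- do.call(rbind, lapply(unique(categories), function(cc) {
    v <- sort(s[categories == cc])
    if (length(v) == 0) return(NULL)
    data.frame(category = cc, score = v,
               ecdf = seq_along(v) / length(v),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(tests = do.call(rbind, rows), ecdf = ecdf_tab)
}

#' Temporal concordance of binding and expression profiles
#'
#' Spearman correlation, per gene, of the stage-wise binding-score profile
#' against the matched stage-wise expression profile; a gene is concordant
#' when the absolute ranked correlation strictly exceeds the threshold.
#' Constant profiles have undefined correlation and are flagged
#' non-concordant with a reason code.
#'
#' @param binding Gene x stage matrix of binding scores.
#' @param expression Gene x stage matrix of mean normalized expression over
#'   the same stages (matching column order).
#' @param threshold Absolute-correlation threshold (strict).
#' @return data.frame: `gene_id`, `rho`, `concordant`, `reason`
#'   (`"ok"` or `"constant_profile"`).
#' @export
temporal_concordance <- function(binding, expression, threshold = 0.5) {
  stopifnot(ncol(binding) >= 3, all(dim(binding) == dim(expression)))
  if (!identical(rownames(binding), rownames(expression))) {
    expression <- expression[rownames(binding), , drop = FALSE]
  }
  rho <- vapply(seq_len(nrow(binding)), function(i) {
    b <- binding[i, ]; e <- expression[i, ]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) return(NA_real_)
    suppressWarnings(stats::cor(b, e, method = "spearman"))
  }, numeric(1))
  data.frame(gene_id = rownames(binding), rho = rho,
             concordant = !is.na(rho) & abs(rho) > threshold,
             reason = ifelse(is.na(rho), "constant_profile", "ok"),
             stringsAsFactors = FALSE, row.names = NULL)
}
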