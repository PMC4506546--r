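#' Plant a temporal binding program on a synthetic genome
#'
#' Chooses a set of genes to be bound by the factor and, for each, a temporal
#' pattern over the developmental stages, an enrichment (fold coverage over
#' background in a 200-bp window at the summit), and a summit position inside
#' the gene's promoter. Roughly 60% of bound genes are bound at a single stage
#' only, mirroring the highly stage-specific occupancy seen in developmental
#' ChIP time courses.
#'
#' @param genome A `genome_spec`.
#' @param bound_genes Optional character vector of gene ids to plant; default
#'   samples `bound_fraction` of genes whose promoter is at least
#'   `min_promoter` bp long.
#' @param bound_fraction Fraction of genes to plant when `bound_genes` is NULL.
#' @param stages Stage labels (default starvation-sensing, early and late
#'   aggregation).
#' @param stage_weights Probabilities that a bound gene is bound at one, two or
#'   all three stages.
#' @param enrichment_range Uniform range for the planted fold enrichment
#'   (must be >= 1).
#' @param fragment_size ChIP fragment size in bp; sets the strand-shift
#'   structure of the simulated reads.
#' @param min_promoter Minimum promoter length (bp) for a gene to be eligible.
#' @param min_summit_spacing Minimum distance (bp) between planted summits;
#'   closer binding events would be unresolvable by fragment-scale peak
#'   calling. Applies only when `bound_genes` is sampled automatically.
#' @param seed Optional integer seed.
#'
#' @return A `binding_program`: data.frame with columns `gene_id`, `stage`,
#'   `enrichment`, `summit_offset` (bp upstream of the gene's transcription
#'   start), `fragment`. Stage set kept in `attr(, "stages")`.
#' @export
binding_program <- function(genome, bound_genes = NULL, bound_fraction = 0.1,
                            stages = c("S", "E", "L"),
                            stage_weights = c(0.60, 0.25, 0.15),
                            enrichment_range = c(8, 24),
                            fragment_size = 200L, min_promoter = 300L,
                            min_summit_spacing = 500L, seed = NULL) {
  stopifnot(enrichment_range[1] >= 1, length(stage_weights) == length(stages))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(bound_genes) && length(bound_genes) == 0) {
    out <- data.frame(gene_id = character(0), stage = character(0),
                      enrichment = numeric(0), summit_offset = integer(0),
                      fragment = integer(0), stringsAsFactors = FALSE)
    return(structure(out, stages = stages,
                     class = c("binding_program", "data.frame")))
  }
  prom <- define_promoters(genome)
  prom$length <- prom$end - prom$start
  # one summit per gene, shared across its bound stages: binding positions of
  # a factor are positionally concordant between developmental stages
  draw_offset <- function(plen) {
    max_off <- min(plen - 1L, 2000L)
    min(max_off, sample(seq.int(10L, max(10L, round(0.6 * max_off))), 1L))
  }
  if (is.null(bound_genes)) {
    eligible <- prom$gene_id[prom$length >= min_promoter]
    n_bound <- max(1L, round(bound_fraction * nrow(genome$genes)))
    if (length(eligible) < n_bound) {
      stop("not enough genes with promoters >= ", min_promoter, " bp")
    }
    # greedy spacing filter: planted summits closer than min_summit_spacing
    # would be unresolvable binding events, so candidates too close to an
    # already-kept summit are passed over
    cand <- sample(eligible)
    kept <- character(0)
    kept_off <- integer(0)
    kept_chrom <- character(0)
    kept_summit <- integer(0)
    for (gene in cand) {
      p <- prom[prom$gene_id == gene, ]
      off <- draw_offset(p$length)
      tss <- if (p$strand == "+") p$end else p$start
      smt <- if (p$strand == "+") tss - off else tss + off
      clash <- any(kept_chrom == p$chrom &
                   abs(kept_summit - smt) < min_summit_spacing)
      if (!clash) {
        kept <- c(kept, gene)
        kept_off <- c(kept_off, as.integer(off))
        kept_chrom <- c(kept_chrom, p$chrom)
        kept_summit <- c(kept_summit, as.integer(smt))
      }
      if (length(kept) == n_bound) break
    }
    if (length(kept) < n_bound) {
      stop("could not place ", n_bound, " summits at least ",
           min_summit_spacing, " bp apart; enlarge the genome or relax spacing")
    }
    ord <- order(kept)
    bound_genes <- kept[ord]
    offsets <- kept_off[ord]
    pr <- prom[match(bound_genes, prom$gene_id), ]
  } else {
    pr <- prom[match(bound_genes, prom$gene_id), ]
    if (anyNA(pr$gene_id)) stop("bound_genes not present in genome")
    offsets <- vapply(pr$length, draw_offset, numeric(1))
  }
  if (any(pr$length < 2)) stop("bound gene has a degenerate promoter")
  rows <- lapply(seq_along(bound_genes), function(i) {
    k <- sample(seq_along(stages), 1, prob = stage_weights)
    st <- sort(sample(seq_along(stages), k))
    data.frame(gene_id = bound_genes[i], stage = stages[st],
               enrichment = stats::runif(length(st), enrichment_range[1],
                                         enrichment_range[2]),
               summit_offset = as.integer(offsets[i]),
               fragment = as.integer(fragment_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, stages = stages, class = c("binding_program", "data.frame"))
}

# Absolute summit coordinate of each binding-program row (strand-aware:
# the offset runs upstream from the transcription start).
binding_summits <- function(program, genome) {
  g <- genome$genes
  i <- match(program$gene_id, g$gene_id)
  if (anyNA(i)) stop("binding program references genes absent from genome")
  tss <- ifelse(g$strand[i] == "+", g$start[i], g$end[i])
  summit <- ifelse(g$strand[i] == "+",
                   tss - program$summit_offset,
                   tss + program$summit_offset)
  data.frame(gene_id = program$gene_id, stage = program$stage,
             chrom = g$chrom[i], summit = as.integer(summit),
             enrichment = program$enrichment, fragment = program$fragment,
             stringsAsFactors = FALSE)
}

#' Plant genotype- and time-dependent expression programs
#'
#' Builds per-gene mean expression for every genotype and time point. All
#' genotypes share a lognormal baseline per gene. Genes bound in `binding`
#' receive a `de_fold` change (up or down) in the developmentally normal
#' genotypes (WT and the complemented mutant, CM) at the time points of their
#' bound stages, while the knockout (KO) and the binding-defective
#' cysteine-substitution strain (CS) stay at baseline. An independent set of
#' `dev_fraction` genes is developmentally regulated in all genotypes alike,
#' so that genotype-differential and merely time-varying genes coexist.
#'
#' @param genome A `genome_spec`.
#' @param binding Optional `binding_program`; its genes become
#'   genotype-differential at their bound stages.
#' @param genotypes Genotype labels.
#' @param timepoints Sampled developmental times (hours).
#' @param stage_timepoints Named list mapping stage labels to time points.
#' @param n_replicates Biological replicates per genotype x time.
#' @param base_log_mean,base_log_sd Lognormal baseline mean parameters.
#' @param dispersion Shared negative-binomial dispersion (0 gives Poisson).
#' @param de_fold Planted fold change for bound genes in WT/CM.
#' @param de_up_prob Probability a planted change is an up-regulation.
#' @param dev_fraction Fraction of genes developmentally regulated in all
#'   genotypes.
#' @param dev_fold Fold change of the shared developmental regulation.
#' @param lib_factor_range Uniform range of per-sample library-size factors.
#' @param seed Optional integer seed.
#'
#' @return An `expression_program`: list with `gene_ids`, `genotypes`,
#'   `timepoints`, `means` (gene x genotype x time array), `dispersion`,
#'   `meta` (sample sheet), `lib_factors` (named per sample), `planted`
#'   (data.frame of planted genotype-differential effects) and
#'   `stage_timepoints`.
#' @export
expression_program <- function(genome, binding = NULL,
                               genotypes = c("WT", "CM", "KO", "CS"),
                               timepoints = c(0, 1, 2, 5, 8),
                               stage_timepoints = list(S = c(1, 2), E = 5, L = 8),
                               n_replicates = 2L,
                               base_log_mean = log(200), base_log_sd = 1,
                               dispersion = 0.05,
                               de_fold = 8, de_up_prob = 0.7,
                               dev_fraction = 0.1, dev_fold = 4,
                               lib_factor_range = c(0.8, 1.25),
                               seed = NULL) {
  stopifnot(dispersion >= 0, de_fold > 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- genome$genes$gene_id
  ng <- length(ids)
  base <- stats::rlnorm(ng, base_log_mean, base_log_sd)
  means <- array(rep(base, times = length(genotypes) * length(timepoints)),
                 dim = c(ng, length(genotypes), length(timepoints)),
                 dimnames = list(ids, genotypes, paste0(timepoints, "h")))
  # shared developmental regulation: ramp up (or down) from a random onset
  n_dev <- round(dev_fraction * ng)
  dev_genes <- if (n_dev > 0) sample(ids, n_dev) else character(0)
  for (g in dev_genes) {
    onset <- sample(seq_along(timepoints)[-1], 1)
    dirn <- sample(c(dev_fold, 1 / dev_fold), 1)
    means[g, , onset:length(timepoints)] <-
      means[g, , onset:length(timepoints)] * dirn
  }
  planted <- NULL
  if (!is.null(binding)) {
    normal <- intersect(c("WT", "CM"), genotypes)
    dirs <- stats::setNames(
      sample(c(1, -1), length(unique(binding$gene_id)), replace = TRUE,
             prob = c(de_up_prob, 1 - de_up_prob)),
      unique(binding$gene_id))
    planted <- data.frame(gene_id = binding$gene_id, stage = binding$stage,
                          direction = unname(dirs[binding$gene_id]),
                          fold = de_fold, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(binding))) {
      tps <- stage_timepoints[[binding$stage[r]]]
      ti <- match(tps, timepoints)
      if (anyNA(ti)) stop("stage_timepoints refers to unsampled time points")
      f <- if (dirs[binding$gene_id[r]] > 0) de_fold else 1 / de_fold
      means[binding$gene_id[r], normal, ti] <-
        means[binding$gene_id[r], normal, ti] * f
    }
  }
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      timepoint = timepoints, genotype = genotypes,
                      stringsAsFactors = FALSE)[, 3:1]
  meta$sample <- sprintf("%s_%gh_r%d", meta$genotype, meta$timepoint,
                         meta$replicate)
  meta <- meta[, c("sample", "genotype", "timepoint", "replicate")]
  lib <- stats::setNames(stats::runif(nrow(meta), lib_factor_range[1],
                                      lib_factor_range[2]), meta$sample)
  structure(list(gene_ids = ids, genotypes = genotypes,
                 timepoints = timepoints, n_replicates = as.integer(n_replicates),
                 means = means, dispersion = dispersion, meta = meta,
                 lib_factors = lib, planted = planted,
                 stage_timepoints = stage_timepoints),
            class = "expression_program")
}

#' Simulate ChIP-seq read sets with planted promoter peaks
#'
#' For each stage of the binding program, emits a sample library (uniform
#' background plus planted peak reads) and a matched control library (uniform
#' background only). Peak reads model sonicated fragments: a fragment centre is
#' drawn near the summit, the read strand is random, and the 5' end sits half a
#' fragment upstream (`+` reads, left of the summit) or downstream (`-` reads,
#' right of the summit), reproducing the strand-shift structure of real ChIP
#' data. Exactly `depth` reads are emitted per library.
#'
#' @param genome A `genome_spec`.
#' @param program A `binding_program` (may be empty for a null run).
#' @param depth Reads per library.
#' @param summit_jitter_sd Gaussian sd (bp) of fragment centres around the
#'   summit; the default 50 bp corresponds to chromatin sheared to roughly
#'   100-300 bp fragments.
#' @param seed Optional integer seed.
#'
#' @return Named list (one element per stage) of lists with `sample` and
#'   `control` read data.frames (`chrom`, `pos` = 0-based 5' coordinate,
#'   `strand`).
#' @export
simulate_chip_reads <- function(genome, program, depth = 1e6,
                                summit_jitter_sd = 50, seed = NULL) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  stages <- attr(program, "stages")
  if (is.null(stages)) stages <- unique(program$stage)
  if (length(stages) == 0) stages <- "S"
  summits <- if (nrow(program) > 0) binding_summits(program, genome) else NULL
  if (!is.null(summits)) {
    L <- lens[summits$chrom]
    if (any(summits$summit < 0 | summits$summit >= L)) {
      stop("planted summit outside chromosome bounds")
    }
  }
  window_ref <- 200
  out <- list()
  for (st in stages) {
    rows <- if (is.null(summits)) NULL else summits[summits$stage == st, , drop = FALSE]
    peak_reads <- NULL
    n_peak_total <- 0L
    if (!is.null(rows) && nrow(rows) > 0) {
      L <- lens[rows$chrom]
      n_peak <- as.integer(round((rows$enrichment - 1) * depth * window_ref / L))
      n_peak_total <- sum(n_peak)
      if (n_peak_total >= depth) {
        stop("planted peaks require more reads than the requested depth")
      }
      centre <- rep(rows$summit, n_peak) +
        as.integer(round(stats::rnorm(n_peak_total, 0, summit_jitter_sd)))
      frag <- rep(rows$fragment, n_peak)
      chrom <- rep(rows$chrom, n_peak)
      plus <- sample(c(TRUE, FALSE), n_peak_total, replace = TRUE)
      pos <- ifelse(plus, centre - frag %/% 2L, centre + frag %/% 2L)
      pos <- pmax(0L, pmin(as.integer(lens[chrom]) - 1L, as.integer(pos)))
      peak_reads <- data.frame(chrom = chrom, pos = pos,
                               strand = ifelse(plus, "+", "-"),
                               stringsAsFactors = FALSE)
    }
    bg_sample <- uniform_reads(lens, depth - n_peak_total)
    smp <- rbind(bg_sample, peak_reads)
    ctl <- uniform_reads(lens, depth)
    rownames(smp) <- NULL
    out[[st]] <- list(sample = smp, control = ctl)
  }
  out
}

# `n` uniform background reads across the chromosomes, proportional to length.
uniform_reads <- function(lens, n) {
  n <- as.integer(n)
  chrom <- if (length(lens) == 1) {
    rep(names(lens), n)
  } else {
    sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  }
  pos <- as.integer(floor(stats::runif(n) * lens[chrom]))
  data.frame(chrom = chrom, pos = pos,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate raw RNA-seq count matrices
#'
#' Draws counts from a negative-binomial model with the program's per-cell
#' means, shared dispersion and per-sample library-size factors. A dispersion
#' of exactly zero gives the Poisson limit.
#'
#' @param genome A `genome_spec` (checked against the program's gene ids).
#' @param program An `expression_program`.
#' @param n_replicates Replicates per condition; defaults to the program's.
#' @param seed Optional integer seed.
#' @return List with `counts` (gene x sample integer matrix) and `meta`
#'   (sample sheet: `sample`, `genotype`, `timepoint`, `replicate`).
#' @export
simulate_counts <- function(genome, program,
                            n_replicates = program$n_replicates, seed = NULL) {
  stopifnot(inherits(program, "expression_program"), n_replicates >= 1)
  if (!identical(program$gene_ids, genome$genes$gene_id)) {
    stop("expression program does not match the genome's gene ids")
  }
  if (!is.null(seed)) set.seed(seed)
  meta <- program$meta
  if (n_replicates != program$n_replicates) {
    meta <- meta[meta$replicate <= n_replicates, , drop = FALSE]
  }
  ng <- length(program$gene_ids)
  counts <- matrix(0L, nrow = ng, ncol = nrow(meta),
                   dimnames = list(program$gene_ids, meta$sample))
  for (j in seq_len(nrow(meta))) {
    mu <- program$means[, meta$genotype[j], paste0(meta$timepoint[j], "h")] *
      program$lib_factors[meta$sample[j]]
    counts[, j] <- if (program$dispersion > 0) {
      stats::rnbinom(ng, mu = mu, size = 1 / program$dispersion)
    } else {
      stats::rpois(ng, mu)
    }
  }
  list(counts = counts, meta = meta)
}
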