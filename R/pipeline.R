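#' Call peaks for one stage from raw read sets
#'
#' Convenience wrapper running the full window caller: duplicate capping of
#' both libraries, window statistics, the label-swap empirical null (the same
#' libraries with sample and control exchanged), Benjamini-Hochberg q-values,
#' and threshold-based peak calling.
#'
#' @param sample,control Raw read data.frames (`chrom`, `pos`, `strand`).
#' @param genome A `genome_spec` or named chromosome-length vector.
#' @param cap Duplicate cap per coordinate (see [deduplicate_reads()]).
#' @param window Window size in bp.
#' @param stage Optional stage label stored on peaks.
#' @param ... Thresholds passed to [call_peaks()].
#' @return Peak data.frame.
#' @export
peak_call_stage <- function(sample, control, genome, cap = 5L, window = 200L,
                            stage = NA_character_, ...) {
  s <- deduplicate_reads(sample, cap)
  ctl <- deduplicate_reads(control, cap)
  stats <- compute_window_stats(s, ctl, genome, window = window)
  null_stats <- compute_window_stats(ctl, s, genome, window = window)
  stats <- estimate_window_fdr(stats, null_stats)
  call_peaks(stats, s, stage = stage, ...)
}

#' Run the integrated target-calling pipeline
#'
#' From per-stage ChIP read sets and an RNA-seq count matrix to direct-target
#' calls: peak calling per stage, promoter assignment and binding scores,
#' normalization, per-stage differential expression between the two contrast
#' genotypes, DE scores, rank products and the rank-product target set.
#'
#' @param chip Named list (per stage) of lists with `sample` and `control`
#'   read data.frames, as produced by [simulate_chip_reads()].
#' @param genome A `genome_spec`.
#' @param counts Raw count matrix (genes x samples).
#' @param meta Sample sheet (`sample`, `genotype`, `timepoint`, `replicate`).
#' @param stages Stage labels, in order.
#' @param stage_timepoints Named list mapping stages to RNA-seq time points;
#'   a stage's DE contrast pools its time points.
#' @param genotype_a,genotype_b Contrast genotypes (A vs B; canonically the
#'   complemented strain against the knockout).
#' @param decay Binding-score decay constant.
#' @param rp_threshold Rank-product target threshold (strict).
#' @param external_peaks Optional BED path or interval data.frame; when given,
#'   only internal peaks overlapping it are kept (consensus filtering against
#'   an independent caller).
#' @param ... Further threshold arguments for [call_peaks()].
#' @return List: `peaks` (per stage), `promoters`, `assignments`,
#'   `binding_scores` (gene x stage data.frame), `bound` (per-stage bound-gene
#'   sets), `norm`, `size_factors`, `de` (per stage, scored), `rp` (per
#'   stage), `targets` (from [call_targets()]).
#' @export
run_target_pipeline <- function(chip, genome, counts, meta,
                                stages = names(chip),
                                stage_timepoints = list(S = c(1, 2), E = 5, L = 8),
                                genotype_a = "CM", genotype_b = "KO",
                                decay = 5, rp_threshold = 0.005,
                                external_peaks = NULL, ...) {
  peaks <- lapply(stages, function(st) {
    pk <- peak_call_stage(chip[[st]]$sample, chip[[st]]$control, genome,
                          stage = st, ...)
    intersect_peaks(pk, external_peaks)
  })
  names(peaks) <- stages
  all_peaks <- do.call(rbind, peaks)
  promoters <- define_promoters(genome)
  assignments <- assign_peaks_to_genes(all_peaks, promoters, genome)
  binding_scores <- binding_score_table(assignments, promoters, genome,
                                        stages = stages, decay = decay)
  bound <- classify_bound_genes(assignments, stages = stages)
  nrm <- normalize_counts(counts)
  de <- lapply(stages, function(st) {
    tps <- stage_timepoints[[st]]
    ga <- meta$sample[meta$genotype == genotype_a & meta$timepoint %in% tps]
    gb <- meta$sample[meta$genotype == genotype_b & meta$timepoint %in% tps]
    d <- call_de(nrm$norm, ga, gb,
                 comparison = sprintf("%s-vs-%s@%s", genotype_a, genotype_b, st))
    compute_de_score(d)
  })
  names(de) <- stages
  rp <- lapply(stages, function(st) {
    compute_rank_product(
      stats::setNames(binding_scores[[st]], binding_scores$gene_id),
      stats::setNames(de[[st]]$score, de[[st]]$gene_id),
      stage = st)
  })
  names(rp) <- stages
  targets <- call_targets(rp, threshold = rp_threshold)
  list(peaks = peaks, promoters = promoters, assignments = assignments,
       binding_scores = binding_scores, bound = bound,
       norm = nrm$norm, size_factors = nrm$size_factors,
       de = de, rp = rp, targets = targets)
}

#' Simulate a complete synthetic study
#'
#' Generates a genome, plants a binding program and the matching expression
#' program, simulates per-stage ChIP libraries and the four-genotype RNA-seq
#' count matrix. The defaults describe the study conditions used throughout
#' the package's validation: see the methods vignette.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp (default sized to hold
#'   `n_genes` genes with ~1-kb intergenic gaps).
#' @param bound_fraction Fraction of genes planted as bound-and-regulated.
#' @param depth ChIP reads per library.
#' @param seed Integer seed (controls every random draw).
#' @param ... Passed to [binding_program()].
#' @return List: `genome`, `binding` (program), `expression` (program),
#'   `chip` (per-stage read sets), `counts`, `meta`, `truth` (planted target
#'   gene ids).
#' @export
simulate_study <- function(n_genes = 2000, chrom_length = NULL,
                           bound_fraction = 0.1, depth = 2e6, seed = 1, ...) {
  if (is.null(chrom_length)) chrom_length <- ceiling(n_genes * 2600)
  genome <- generate_genome(n_genes, chrom_length, seed = seed)
  bprog <- binding_program(genome, bound_fraction = bound_fraction,
                           seed = seed + 1L, ...)
  eprog <- expression_program(genome, binding = bprog, seed = seed + 2L)
  chip <- simulate_chip_reads(genome, bprog, depth = depth, seed = seed + 3L)
  sim <- simulate_counts(genome, eprog, seed = seed + 4L)
  list(genome = genome, binding = bprog, expression = eprog, chip = chip,
       counts = sim$counts, meta = sim$meta,
       truth = sort(unique(bprog$gene_id)))
}
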