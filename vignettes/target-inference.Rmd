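---
title: "Inferring direct transcription-factor targets from ChIP-seq and RNA-seq"
author: "chipTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring direct transcription-factor targets from ChIP-seq and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipTargets)
```

# The problem

A developmental transcription factor (TF) binds different promoters at
different stages, and genetic perturbations of the factor change the
expression of some — but not all — of the genes it touches. `chipTargets`
implements a complete route from raw evidence to *direct targets*: genes whose
promoters are bound by the factor **and** whose expression depends on the
factor's activity at the matching developmental stage.

The intended design is a time course with stage-matched data:

* **ChIP-seq** of the tagged factor against a tag-only control, per stage
  (here labelled S, E and L for starvation-sensing, early and late
  aggregation — the sampling stages of early *Dictyostelium* development).
* **RNA-seq** of four genotypes — wild type (WT), the null mutant (KO), the
  null complemented with the tagged factor (CM) and a DNA-binding-defective
  point mutant (CS) — across five time points (0, 1, 2, 5, 8 h), two
  replicates each. The genotype contrast used for target calling is CM vs KO:
  both carry the same background, and CM restores factor activity.

Every analysis stage is exercised against a synthetic-data generator that
plants known binding sites and expression programs, so the pipeline's
operating characteristics (calibration, recovery, precision/recall) are
measured against ground truth rather than assumed.

# Peak calling

Reads are reduced to 5' positions (0-based). At most five reads may share a
(chromosome, position, strand) coordinate; deeper piles are treated as PCR
duplicates and capped (`deduplicate_reads()`).

Each chromosome is tiled with 200-bp windows overlapping by 50%. For window
$w$ with sample count $c_s$ and control count $c_c$, and library sizes
$N_s, N_c$, the enrichment statistic is the scaled log ratio

$$
\mathrm{LR}(w) \;=\; \log_2
\frac{c_s/N_s + \varepsilon_s}{c_c/N_c + \varepsilon_c},
\qquad \varepsilon = \tfrac{1}{N},
$$

with a one-read pseudocount keeping ratios finite. 5-kb regions are a
processing partition only; window coordinates are identical regardless of the
partition.

**Empirical FDR.** No parametric null is assumed. Swapping the sample and
control labels on the same libraries produces a null window set whose log
ratios are the negation of the observed ones; each window's p-value is its
add-one exceedance probability under that null,
$p = (\#\{\mathrm{null} \ge \mathrm{LR}\} + 1)/(B+1)$, and q-values are
Benjamini–Hochberg across all windows. One consequence worth knowing: the
empirical p floor is $1/(B+1)$ with $B \approx$ the number of windows, so BH
can push $q$ below 0.01 only when roughly a hundred or more windows sit at
the floor. Experiments with very few true binding sites on a small genome
will therefore call nothing — a granularity property of the empirical null,
not a bug. At realistic scale (dozens of sites, each contributing several
enriched windows) the floor is cleared comfortably.

**Peaks.** Windows with fold $> 4$ and $q < 0.01$ (both strict) are merged
when overlapping or book-ended. Per candidate, the strand shift is estimated
by scanning offsets 0–200 bp (10-bp grid) for the maximal Pearson correlation
between the plus-strand profile and the left-shifted minus-strand profile;
ties break toward the smallest offset. Reads are then shifted toward each
other by half the offset. The summit is the leftmost maximum of the combined
shifted profile after a centred 51-bp moving-sum smoothing. Read support and
strand balance are evaluated on the shift-corrected reads inside the peak —
shifting first matters, because the two strand piles flank the true site by
about half a fragment and a narrow candidate may otherwise see only one pile.
Peaks need support $> 50$ and strand balance
$|\log_2(\mathrm{plus}/\mathrm{minus})| < 0.5$ (both strict); the reported
enrichment is $2^{\max_w \mathrm{LR}(w)}$ over the merged windows. An
externally produced peak list (e.g. from an independent caller) can be
intersected via `intersect_peaks()` to keep only consensus calls.

# Promoter assignment and binding scores

The promoter of a gene is the intergenic interval 5' of its ORF up to the
nearest annotated boundary of any other gene (strand-agnostic on the
neighbour side), or the chromosome end; divergent gene pairs share their
intergenic interval. Peaks are assigned by summit position, and summits
inside any gene body are discarded (intergenic-only rule).

Each gene's per-stage binding score sums over its assigned peaks:

$$
S_g \;=\; \sum_{p} \log_2(\mathrm{fold}_p)\;
e^{-\lambda\, d_p},
\qquad
d_p = \frac{|\mathrm{summit}_p - \mathrm{TSS}_g|}{\mathrm{promoter\ length}}
\in [0, 1].
$$

The decay constant defaults to $\lambda = 5$, putting the far-promoter weight
at $e^{-5} \approx 0.7\%$ of the proximal weight; the distance is a fraction
of the gene's own promoter so that genes with short and long promoters are
treated comparably. The exact decay is a package choice — the qualitative
requirement is only that proximal, strongly enriched peaks dominate — and it
is exposed as a parameter. A gene is *bound* at a stage when at least one
assigned peak there exceeds fourfold enrichment (strict).

# Expression analysis

Counts are normalized by median-of-ratios size factors (per-sample median of
count ratios to the geometric-mean reference over genes detected everywhere),
rescaled to geometric mean 1 so normalization is idempotent. This assumes
most genes are not changing; it is the standard choice for bulk NB counts.

The differential test is a negative-binomial exact-style test on summed
normalized counts. Under the null both groups share the pooled per-sample
mean $\hat\mu_0$; the group-A sum is modelled as
$\mathrm{NB}(n_A \hat\mu_0,\ \mathrm{size} = n_A/\hat\alpha)$ and the
two-sided p doubles the smaller tail. The shared dispersion $\hat\alpha$ is
moment-matched by pooling within-group means and variances across genes,
$\hat\alpha = \sum_g (v_g - m_g) / \sum_g m_g^2$ (clamped at 0 — the Poisson
limit). The pooled ratio is used rather than a per-gene median because
variance estimates from duplicate samples are so noisy that their median is
biased low by roughly half, which would make the test anticonservative. An
externally computed DE table (gene, comparison, likelihood, FDR, direction)
can be imported instead; rows whose posterior likelihood does not exceed 0.9
are treated as not differentially expressed.

DE scores are $\log_2((\bar{x}_A + 1)/(\bar{x}_B + 1))$ for genes with
FDR $< 0.05$ and exactly 0 otherwise; genes are UP (DOWN) when significant
with higher (lower) mean in the contrast genotype, else NDE. A gene is
*developmentally regulated* within a genotype when any comparison of
consecutive time points is significant, and the strain-differential set
intersects developmental regulation in both normal genotypes with a
significant normal-vs-aberrant contrast at any time point. For stage-level
contrasts the stages map to time points as S = {1, 2 h}, E = {5 h},
L = {8 h}; a stage's DE contrast pools its time points.

# Integration

Per stage, genes are ranked by binding score (rank 1 = highest) and by
absolute DE score (rank 1 = largest), average ranks on ties, and combined as
the **rank product**

$$
\mathrm{RP}_g = \frac{r^{\mathrm{bind}}_g \times r^{\mathrm{DE}}_g}{N^2}
\in (0, 1],
$$

normalized by $N^2$ so the threshold is independent of the universe size.
Genes with $\mathrm{RP} < 0.005$ (strict) at any stage are called direct
targets; per-stage sets and the Venn partition over stages are reported.

Supporting statistics:

* `overlap_permutation_test()` draws both gene sets uniformly without
  replacement from the universe in each replicate and reports the add-one
  empirical p (never exactly zero; one million replicates by default). It
  converges to the hypergeometric tail, which the tests verify on a
  six-gene universe where the tail is $1/20$ in closed form.
* `compare_binding_distributions()` contrasts binding scores of UP and DOWN
  genes against NDE genes with two-sample Kolmogorov–Smirnov tests
  (asymptotic p) and exports ECDF tables.
* `temporal_concordance()` computes, per gene, the Spearman correlation
  between the stage-wise binding-score profile and the matched expression
  profile; a gene is concordant when $|\rho| > 0.5$ (strict). With three
  stages $\rho$ can only take values in $\{-1, -0.5, 0, 0.5, 1\}$, so the
  strict inequality keeps exactly the monotone profiles. Constant profiles
  have undefined correlation and are flagged with a reason code instead.

# Transcriptome similarity

Sample distances are $D = 1 - \mathrm{SC}$ with SC the Spearman correlation
over genes. Embeddings use classical (Torgerson) MDS via `cmdscale`, with
axes of non-positive eigenvalue dropped (with a warning) and each axis's sign
fixed so its largest-magnitude coordinate is positive — embeddings are then
reproducible run to run. Clustering is complete-linkage on $D$; the leaf
order is then optimized over all subtree flips to minimize the sum of
adjacent-leaf distances, by the exact dynamic program over (first leaf,
last leaf) pairs of every subtree. Heatmap export uses per-row z-scores with
the population (divide-by-$n$) standard deviation; constant rows become zeros
with a warning.

# The synthetic-data generator

`simulate_study()` builds the whole validation world:

* **Genome** — one chromosome; stranded, non-overlapping gene models with
  uniform lengths of 0.6–2.4 kb and geometric intergenic gaps of mean 1 kb,
  resembling a compact, gene-dense amoebozoan genome.
* **Binding program** — 10% of genes are planted as bound. Temporal patterns
  are 60% single-stage, 25% two-stage, 15% all three, matching the strongly
  stage-specific occupancy such factors show. Enrichment is uniform on 8–24
  fold. Each gene gets one summit, shared across stages (binding positions
  are positionally concordant between stages), placed in the
  proximal-to-mid promoter, with planted summits kept at least 500 bp apart
  because closer events are unresolvable at fragment scale.
* **ChIP reads** — exactly `depth` reads per library. Control libraries are
  uniform background. Sample libraries add, per bound gene,
  $(m-1) \times \mathrm{depth} \times 200/L$ peak reads (so a 200-bp summit
  window reaches $m$-fold coverage over background). Fragment centres are
  Gaussian around the summit with sd 50 bp (chromatin sheared to roughly
  100–300 bp); the read strand is random and the 5' end sits half a fragment
  (100 bp) upstream or downstream, giving real data's strand-shift
  structure. Default depths: 1e6 reads on the 1-Mb calibration/recovery
  genomes and 2e6 on the 5.2-Mb end-to-end genome, i.e. about 80–200
  background reads per window — coverage at which the caller is meant to
  operate.
* **Counts** — negative binomial with shared dispersion 0.05 (typical for
  well-replicated bulk RNA-seq), lognormal baseline means
  ($e^{\mathcal{N}(\log 200,\ 1)}$), per-sample library factors uniform on
  0.8–1.25, two replicates. Planted targets get an 8-fold change (70% up,
  30% down) in WT and CM at their bound stages' time points; KO and CS stay
  at baseline, mirroring the phenotype in which the binding-defective
  mutant behaves transcriptionally like the null. A further 10% of genes are
  developmentally regulated in *all* genotypes, so genotype-differential and
  merely time-varying genes coexist.

What the generator does **not** model: mappability and GC bias, PCR
duplication beyond what the cap removes, gene-length effects on counts,
per-gene dispersion, isoforms, or partially active mutants. Passing the
planted-truth checks therefore demonstrates the statistical machinery is
correct and calibrated under the stated model — not that real libraries are
free of artifacts the model omits.

# Validation

`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` recompute, from
scratch at the study scale: the null-data window FDR (10 seeds, 1e6 reads on
1 Mb), recovery and summit accuracy of 50 planted peaks with the false-call
rate, exact agreement of window counts, rank products, Venn sectors, KS
statistics, Spearman distances and interval intersections with brute-force
oracles, convergence of the permutation p to the hypergeometric tail, DE
type-I rate and power, precision/recall of end-to-end target calling on a
2,000-gene study, exactness of classical MDS on plane-embeddable data, and
the strictness of every decision threshold at its boundary. Problem sizes
were chosen so the whole suite runs in about a minute on one CPU while
keeping every check at the scale described above.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) and
  BED (0-based half-open) are converted at the boundary.
* Ties: average ranks everywhere; leftmost maximum for summits; smallest
  offset for strand shifts; first-seen retention for duplicate capping.
* Empirical p-values use the add-one convention and are never zero.
* Zero-length promoters take distance 0; one-sided peaks have infinite
  strand balance and are discarded; all-zero count matrices, empty control
  libraries, empty null window sets and constant expression columns raise
  errors naming the problem.

# Limitations

The DE test is a deliberate, documented stand-in with the same decision
interface as posterior-likelihood engines, not a reimplementation of one;
for published analyses an external DE table can be imported verbatim. The
binding score's functional form is a declared choice with the stated shape
(exponential decay in fractional promoter distance, log-fold weighting).
Bootstrap support values for dendrograms are out of scope; the Newick export
carries merge heights so support can be added externally.
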