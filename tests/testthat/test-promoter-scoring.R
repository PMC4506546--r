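test_that("promoters run from the TSS to the nearest upstream gene boundary", {
  g <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = c("up", "plus"), chrom = "chr1",
               start = c(5000L, 10000L), end = c(7000L, 12000L),
               strand = c("+", "+"), stringsAsFactors = FALSE))
  pr <- define_promoters(g)
  expect_equal(pr[pr$gene_id == "plus", c("start", "end")],
               data.frame(start = 7000L, end = 10000L), ignore_attr = TRUE)
  # minus-strand mirror: promoter is 3' of the interval in genome coordinates
  g2 <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = c("minus", "next"), chrom = "chr1",
               start = c(3000L, 9000L), end = c(5000L, 11000L),
               strand = c("-", "+"), stringsAsFactors = FALSE))
  pr2 <- define_promoters(g2)
  expect_equal(pr2[pr2$gene_id == "minus", c("start", "end")],
               data.frame(start = 5000L, end = 9000L), ignore_attr = TRUE)
  # first gene on the chromosome reaches the chromosome boundary
  g3 <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = "first", chrom = "chr1", start = 4000L, end = 6000L,
               strand = "+", stringsAsFactors = FALSE))
  pr3 <- define_promoters(g3)
  expect_equal(c(pr3$start, pr3$end), c(0L, 4000L))
  # last minus-strand gene reaches the chromosome end
  g4 <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = "last", chrom = "chr1", start = 14000L, end = 16000L,
               strand = "-", stringsAsFactors = FALSE))
  pr4 <- define_promoters(g4)
  expect_equal(c(pr4$start, pr4$end), c(16000L, 20000L))
  # truncation keeps the TSS-proximal part
  pr3t <- define_promoters(g3, max_len = 1000)
  expect_equal(c(pr3t$start, pr3t$end), c(3000L, 4000L))
})

test_that("divergent genes share their intergenic promoter; abutting genes get none", {
  g <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = c("left", "right"), chrom = "chr1",
               start = c(2000L, 8000L), end = c(4000L, 10000L),
               strand = c("-", "+"), stringsAsFactors = FALSE))
  pr <- define_promoters(g)
  expect_equal(pr$start, c(4000L, 4000L))
  expect_equal(pr$end, c(8000L, 8000L))
  # abutting genes leave a zero-length promoter
  g2 <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = c("a", "b"), chrom = "chr1",
               start = c(2000L, 4000L), end = c(4000L, 6000L),
               strand = c("+", "+"), stringsAsFactors = FALSE))
  pr2 <- define_promoters(g2)
  expect_equal(pr2$end[2] - pr2$start[2], 0L)
})

test_that("peaks are assigned by summit, intergenic-only, to all owning promoters", {
  g <- genome_spec(
    data.frame(name = "chr1", length = 20000L),
    data.frame(gene_id = c("left", "right", "far"), chrom = "chr1",
               start = c(2000L, 8000L, 15000L), end = c(4000L, 10000L, 17000L),
               strand = c("-", "+", "+"), stringsAsFactors = FALSE))
  pr <- define_promoters(g)
  peaks <- data.frame(peak_id = c("p1", "p2", "p3"), chrom = "chr1",
                      start = c(5800L, 2800L, 13800L),
                      end = c(6200L, 3200L, 14200L),
                      summit = c(6000L, 3000L, 14000L),
                      enrichment = c(8, 8, 8), support = 100L, balance = 0,
                      stage = "E", stringsAsFactors = FALSE)
  asn <- assign_peaks_to_genes(peaks, pr, g)
  # p1 sits in the shared divergent promoter: both genes
  expect_setequal(asn$gene_id[asn$peak_id == "p1"], c("left", "right"))
  # p2's summit is inside a gene body: dropped
  expect_false("p2" %in% asn$peak_id)
  # p3 belongs to 'far' only
  expect_equal(asn$gene_id[asn$peak_id == "p3"], "far")
})

test_that("binding scores follow the exponential distance-decay form", {
  prom <- data.frame(gene_id = "gX", chrom = "chr1", start = 1000L,
                     end = 3000L, strand = "+", stringsAsFactors = FALSE)
  pk_at <- function(summit, fold) {
    data.frame(peak_id = "p", summit = summit, enrichment = fold,
               stringsAsFactors = FALSE)
  }
  # peak at the gene start: d = 0, score = log2(16) = 4
  expect_equal(compute_binding_score(pk_at(3000L, 16), prom)$score, 4)
  # peak at the far promoter end: d = 1, score = 4 * exp(-5)
  expect_equal(compute_binding_score(pk_at(1000L, 16), prom)$score,
               4 * exp(-5), tolerance = 1e-12)
  # additivity over peaks
  two <- rbind(pk_at(3000L, 16), pk_at(1000L, 16))
  expect_equal(compute_binding_score(two, prom)$score,
               4 + 4 * exp(-5), tolerance = 1e-12)
  # no peaks gives exactly zero
  expect_equal(compute_binding_score(pk_at(0L, 2)[0, ], prom)$score, 0)
  # zero-length promoter takes d = 0
  prom0 <- transform(prom, start = 3000L)
  expect_equal(compute_binding_score(pk_at(3000L, 16), prom0)$score, 4)
  # strictly increasing in fold, strictly decreasing in distance
  expect_gt(compute_binding_score(pk_at(2000L, 20), prom)$score,
            compute_binding_score(pk_at(2000L, 10), prom)$score)
  expect_gt(compute_binding_score(pk_at(2500L, 10), prom)$score,
            compute_binding_score(pk_at(2000L, 10), prom)$score)
})

test_that("the score table covers every gene and matches per-gene scoring", {
  set.seed(41)
  g <- generate_genome(30, 150000, seed = 41)
  bp <- binding_program(g, bound_fraction = 0.3, seed = 42)
  chip <- simulate_chip_reads(g, bp, depth = 2e5, seed = 43)
  pr <- define_promoters(g)
  peaks <- do.call(rbind, lapply(names(chip), function(st) {
    peak_call_stage(chip[[st]]$sample, chip[[st]]$control, g, stage = st,
                    fdr_max = 1)  # q granularity is too coarse at this scale
  }))
  asn <- assign_peaks_to_genes(peaks, pr, g)
  tab <- binding_score_table(asn, pr, g, stages = c("S", "E", "L"))
  expect_equal(tab$gene_id, g$genes$gene_id)
  for (st in c("S", "E", "L")) {
    sub <- asn[asn$stage == st, ]
    for (gene in unique(sub$gene_id)) {
      one <- compute_binding_score(sub[sub$gene_id == gene, ],
                                   pr[pr$gene_id == gene, ])
      expect_equal(tab[tab$gene_id == gene, st], one$score, tolerance = 1e-12)
    }
  }
  # gene order invariance
  g_rev <- g
  g_rev$genes <- g$genes[rev(seq_len(nrow(g$genes))), ]
  tab_rev <- binding_score_table(asn, pr, g_rev, stages = c("S", "E", "L"))
  m <- match(tab$gene_id, tab_rev$gene_id)
  expect_equal(tab$S, tab_rev$S[m])
})

test_that("bound-gene classification is strict at fourfold and partitions by stage", {
  asn <- data.frame(
    gene_id = c("a", "b", "b", "c", "d"),
    peak_id = sprintf("p%d", 1:5),
    stage = c("E", "S", "E", "L", "E"),
    enrichment = c(4.0, 6, 5, 9, 4.5),
    stringsAsFactors = FALSE)
  cls <- classify_bound_genes(asn, stages = c("S", "E", "L"))
  # enrichment exactly 4 is not bound
  expect_false("a" %in% cls$union)
  expect_setequal(cls$per_stage$E, c("b", "d"))
  expect_setequal(cls$union, c("b", "c", "d"))
  # d bound at E only: in the single-stage partition
  expect_true("d" %in% cls$single_stage$E)
  expect_false("b" %in% unlist(cls$single_stage))
  # random fixture: partition sizes match exhaustive set enumeration
  set.seed(44)
  rnd <- data.frame(gene_id = sample(letters, 60, replace = TRUE),
                    peak_id = sprintf("q%d", 1:60),
                    stage = sample(c("S", "E", "L"), 60, replace = TRUE),
                    enrichment = runif(60, 3, 10), stringsAsFactors = FALSE)
  cls2 <- classify_bound_genes(rnd, stages = c("S", "E", "L"))
  want <- lapply(c("S", "E", "L"), function(st) {
    sort(unique(rnd$gene_id[rnd$stage == st & rnd$enrichment > 4]))
  })
  names(want) <- c("S", "E", "L")
  expect_identical(cls2$per_stage, want)
  n1 <- sum(table(unlist(lapply(want, unique)))[cls2$union] == 1)
  expect_equal(length(unlist(cls2$single_stage)), n1)
})
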