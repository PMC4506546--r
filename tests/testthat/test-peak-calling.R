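test_that("duplicate capping keeps the first five reads per coordinate", {
  r <- make_reads(c(rep(100, 7), 200, 300), strand = "+")
  r$idx <- seq_len(nrow(r))
  d <- deduplicate_reads(r, cap = 5)
  expect_equal(sum(d$pos == 100), 5)
  expect_equal(d$idx[d$pos == 100], 1:5)  # first-seen retention
  # strand-specific triples are distinct coordinates
  r2 <- make_reads(rep(100, 4), strand = c("+", "+", "-", "-"))
  expect_equal(nrow(deduplicate_reads(r2, cap = 2)), 4)
  # all-distinct input is a no-op; capping is idempotent
  r3 <- make_reads(1:20, strand = "+")
  expect_equal(deduplicate_reads(r3), r3)
  expect_equal(deduplicate_reads(d), d)
})

test_that("window log ratios follow the scaled pseudocount formula", {
  # 80 sample vs 5 control reads in window [0, 200), equal library sizes:
  # log2((80+1)/(5+1)) = log2(81/6)
  s <- rbind(make_reads(seq(10, 89)), make_reads(seq(5000, 5019)))
  ctl <- rbind(make_reads(seq(20, 24)), make_reads(seq(5000, 5094)))
  st <- compute_window_stats(s, ctl, c(chr1 = 6000))
  expect_equal(st$log_ratio[st$start == 0], log2(81 / 6), tolerance = 1e-12)
  expect_equal(st$sample_count[st$start == 0], 80)
  expect_equal(st$control_count[st$start == 0], 5)
  # identical libraries give exactly zero everywhere
  st0 <- compute_window_stats(s, s, c(chr1 = 6000))
  expect_true(all(st0$log_ratio == 0))
  # windows tile at 50% overlap
  expect_equal(st$start, seq(0, 5800, by = 100))
  expect_true(all(st$end - st$start == 200))
  expect_error(compute_window_stats(s, s[0, ], c(chr1 = 6000)), "control")
})

test_that("window counts and ratios match a brute-force recount oracle", {
  set.seed(31)
  L <- 10100
  s <- make_reads(sample(0:(L - 1), 400, replace = TRUE),
                  strand = sample(c("+", "-"), 400, replace = TRUE))
  ctl <- make_reads(sample(0:(L - 1), 300, replace = TRUE),
                    strand = sample(c("+", "-"), 300, replace = TRUE))
  st <- compute_window_stats(s, ctl, c(chr1 = L))
  for (i in seq_len(nrow(st))) {
    cs <- sum(s$pos >= st$start[i] & s$pos < st$end[i])
    cc <- sum(ctl$pos >= st$start[i] & ctl$pos < st$end[i])
    expect_identical(st$sample_count[i], cs)
    expect_identical(st$control_count[i], cc)
    expect_equal(st$log_ratio[i],
                 log2(((cs + 1) / 400) / ((cc + 1) / 300)), tolerance = 1e-12)
  }
})

test_that("swapping sample and control negates every log ratio", {
  set.seed(32)
  s <- make_reads(sample(0:9999, 500, replace = TRUE))
  ctl <- make_reads(sample(0:9999, 500, replace = TRUE))
  a <- compute_window_stats(s, ctl, c(chr1 = 10000))
  b <- compute_window_stats(ctl, s, c(chr1 = 10000))
  expect_equal(a$log_ratio, -b$log_ratio, tolerance = 1e-12)
})

test_that("empirical p-values use the add-one convention and BH q-values", {
  obs <- make_stats(seq(0, 900, 100), log_ratio = c(5, rep(0, 9)), qvalue = NA)
  null <- make_stats(seq(0, 900, 100), log_ratio = rnorm(10, 0, 0.1), qvalue = NA)
  out <- estimate_window_fdr(obs, null)
  expect_equal(out$pvalue[1], 1 / 11)  # exceeds all B = 10 null windows
  # exchangeability: identical windows share identical p and q
  same <- estimate_window_fdr(
    make_stats(seq(0, 400, 100), log_ratio = rep(1, 5), qvalue = NA),
    make_stats(seq(0, 400, 100), log_ratio = rep(1, 5), qvalue = NA))
  expect_equal(length(unique(same$pvalue)), 1)
  expect_equal(length(unique(same$qvalue)), 1)
  expect_error(estimate_window_fdr(obs, null[0, ]), "null")
})

test_that("peak thresholds are strict and applied in conjunction", {
  reads <- rbind(make_reads(seq(40, 89), "+"), make_reads(seq(40, 89), "-"),
                 make_reads(seq(3000, 3099), "+"))
  base <- make_stats(seq(0, 3800, 100), log_ratio = 0, qvalue = 1)
  sig_at <- function(lr, q) {
    st <- base
    st$log_ratio[1] <- lr
    st$qvalue[1] <- q
    st
  }
  # passing example: fold 10, q = 0.001, support 100, balanced
  pk <- call_peaks(sig_at(log2(10), 0.001), reads)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$enrichment, 10)
  expect_equal(pk$support, 100L)
  expect_lt(abs(pk$summit - 64), 30)
  # fold 3.5 never yields a peak regardless of FDR
  expect_equal(nrow(call_peaks(sig_at(log2(3.5), 1e-6), reads)), 0)
  # fold exactly 4 fails the strict inequality
  expect_equal(nrow(call_peaks(sig_at(2, 0), reads)), 0)
  # q exactly 0.01 fails the strict inequality
  expect_equal(nrow(call_peaks(sig_at(log2(10), 0.01), reads)), 0)
  # missing q-values are refused
  expect_error(call_peaks(sig_at(log2(10), NA), reads), "q-values")
})

test_that("read support on the merged peak is strict at the boundary", {
  base <- make_stats(seq(0, 1800, 100), log_ratio = 0, qvalue = 1)
  base$log_ratio[1] <- log2(10); base$qvalue[1] <- 0.001
  # 25 + 25 co-located reads: support 50 is not > 50
  r50 <- rbind(make_reads(seq(50, 74), "+"), make_reads(seq(50, 74), "-"))
  expect_equal(nrow(call_peaks(base, r50)), 0)
  r51 <- rbind(r50, make_reads(100, "+"))
  expect_equal(nrow(call_peaks(base, r51)), 1)
})

test_that("strand balance is strict at the boundary and Inf for one-sided peaks", {
  expect_equal(strand_balance(30, 20), log2(1.5))
  expect_equal(strand_balance(10, 0), Inf)
  expect_equal(strand_balance(0, 0), Inf)
  base <- make_stats(seq(0, 1800, 100), log_ratio = 0, qvalue = 1)
  base$log_ratio[1] <- log2(10); base$qvalue[1] <- 0.001
  r <- rbind(make_reads(seq(40, 99, 2), "+"), make_reads(seq(40, 79, 2), "-"))
  # 30 plus vs 20 minus reads: balance == log2(1.5) exactly
  expect_equal(nrow(call_peaks(base, r, support_min = 10,
                               balance_max = log2(1.5))), 0)
  expect_equal(nrow(call_peaks(base, r, support_min = 10,
                               balance_max = log2(1.5) + 1e-9)), 1)
})

test_that("raising thresholds never adds a peak", {
  set.seed(33)
  g <- generate_genome(60, 300000, seed = 33)
  bp <- binding_program(g, bound_fraction = 0.4, stages = "S",
                        stage_weights = 1, enrichment_range = c(5, 20),
                        seed = 34)
  chip <- simulate_chip_reads(g, bp, depth = 3e5, seed = 35)
  s <- deduplicate_reads(chip$S$sample)
  ctl <- deduplicate_reads(chip$S$control)
  st <- estimate_window_fdr(compute_window_stats(s, ctl, g),
                            compute_window_stats(ctl, s, g))
  base <- call_peaks(st, s)
  # stricter thresholds can narrow merged peaks but never add new regions:
  # every stricter peak lies within some baseline peak, and counts shrink
  contained <- function(pk) {
    all(vapply(seq_len(nrow(pk)), function(i) {
      any(base$chrom == pk$chrom[i] & base$start <= pk$start[i] &
            base$end >= pk$end[i])
    }, logical(1)))
  }
  for (pk in list(call_peaks(st, s, fold_min = 6),
                  call_peaks(st, s, support_min = 200),
                  call_peaks(st, s, fdr_max = 0.001))) {
    expect_true(contained(pk))
    expect_lte(nrow(pk), nrow(base))
  }
})

test_that("peak intersection matches a quadratic all-pairs oracle", {
  set.seed(36)
  internal <- data.frame(peak_id = sprintf("p%d", 1:40), chrom = "chr1",
                         start = sample(0:5000, 40), stringsAsFactors = FALSE)
  internal$end <- internal$start + sample(50:400, 40, replace = TRUE)
  internal$summit <- internal$start
  external <- data.frame(chrom = "chr1", start = sample(0:5000, 30),
                         stringsAsFactors = FALSE)
  external$end <- external$start + sample(50:400, 30, replace = TRUE)
  got <- intersect_peaks(internal, external)
  want <- vapply(seq_len(nrow(internal)), function(i) {
    any(internal$start[i] < external$end & external$start < internal$end[i])
  }, logical(1))
  expect_setequal(got$peak_id, internal$peak_id[want])
  # identity and empty-list cases
  self_bed <- internal[, c("chrom", "start", "end")]
  expect_equal(intersect_peaks(internal, self_bed), internal)
  expect_equal(nrow(intersect_peaks(internal, external[0, ])), 0)
  expect_identical(intersect_peaks(internal, NULL), internal)
})

test_that("reads survive a BED6 round trip", {
  r <- make_reads(c(100, 250, 399), strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r, path)
  back <- read_reads_bed(path)
  expect_equal(back$pos, r$pos)
  expect_equal(back$strand, r$strand)
})

test_that("malformed BED lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\tnope"), path)
  expect_error(read_bed_intervals(path), "line 2")
  writeLines(c("track name=x", "chr1\t10\t20\tpk\t0\t+"), path)
  ok <- read_bed_intervals(path)
  expect_equal(ok$start, 10)
  expect_equal(ok$strand, "+")
})
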