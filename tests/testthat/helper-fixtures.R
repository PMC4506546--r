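# Small in-code fixtures shared across test files.

toy_genome <- function() {
  genome_spec(
    data.frame(name = "chr1", length = 20000L, stringsAsFactors = FALSE),
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = "chr1",
               start = c(3000L, 7000L, 12000L),
               end = c(5000L, 9000L, 14000L),
               strand = c("-", "+", "-"),
               stringsAsFactors = FALSE))
}

make_reads <- function(pos, strand = "+", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             stringsAsFactors = FALSE)
}

# a window-stats row vector builder for hand-crafted caller inputs
make_stats <- function(start, log_ratio, qvalue, chrom = "chr1",
                       window = 200L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + window),
             sample_count = NA_integer_, control_count = NA_integer_,
             log_ratio = log_ratio, pvalue = qvalue, qvalue = qvalue,
             stringsAsFactors = FALSE)
}

# independent average-tie ranking by pairwise counting; rank 1 goes to the
# LARGEST value (oracle path for the rank product)
counting_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x > x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# brute-force two-sample KS statistic by scanning every observed threshold
brute_ks <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  max(vapply(ts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Procrustes residual: best rigid alignment (rotation/reflection +
# translation) of X onto Y, no scaling
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$u %*% t(s$v)
  sqrt(sum((Xc %*% R - Yc)^2))
}

# enumerate all subtree flips of an hclust tree, returning the minimal
# adjacent-leaf-distance cost (oracle for optimal leaf ordering)
brute_olo_cost <- function(hc, dmat) {
  orders_of <- function(k) {
    if (k < 0) return(list(-k))
    a <- orders_of(hc$merge[k, 1])
    b <- orders_of(hc$merge[k, 2])
    out <- list()
    for (x in a) for (y in b) {
      out[[length(out) + 1]] <- c(x, y)
      out[[length(out) + 1]] <- c(y, x)
    }
    out
  }
  min(vapply(orders_of(nrow(hc$merge)),
             function(o) chipTargets:::leaf_order_cost(o, dmat),
             numeric(1)))
}
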