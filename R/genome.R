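#' Generate a synthetic genome with stranded, non-overlapping gene models
#'
#' Places `n_genes` gene models on a single chromosome, separated by
#' geometrically distributed intergenic gaps. Coordinates are 0-based,
#' half-open throughout the package; GFF3 export converts to the 1-based,
#' inclusive convention the format requires.
#'
#' @param n_genes Number of genes to place (>= 1).
#' @param chrom_length Chromosome length in bp.
#' @param intergenic_mean Mean intergenic gap in bp (geometric distribution).
#' @param gene_length_range Two-element integer range of gene lengths (bp),
#'   sampled uniformly.
#' @param seed Optional integer seed; a fixed seed gives a bit-identical genome.
#'
#' @return A `genome_spec` object: a list with `chromosomes`
#'   (data.frame: `name`, `length`) and `genes` (data.frame: `gene_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @export
#' @examples
#' g <- generate_genome(10, 100000, seed = 1)
#' head(g$genes)
generate_genome <- function(n_genes, chrom_length, intergenic_mean = 1000,
                            gene_length_range = c(600, 2400), seed = NULL) {
  stopifnot(n_genes >= 1, chrom_length > 0, intergenic_mean > 0,
            length(gene_length_range) == 2, gene_length_range[1] > 0)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes)
  gaps <- stats::rgeom(n_genes, prob = 1 / (intergenic_mean + 1))
  lens <- sample(seq.int(gene_length_range[1], gene_length_range[2]),
                 n_genes, replace = TRUE)
  # start_i = sum of gaps[1..i] + lens[1..i-1]
  starts <- cumsum(gaps + c(0L, lens[-n_genes]))
  ends <- starts + lens
  if (ends[n_genes] > chrom_length) {
    stop("genome too short: ", n_genes, " genes need ", ends[n_genes],
         " bp but chrom_length is ", chrom_length)
  }
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = "chr1",
    start = as.integer(starts),
    end = as.integer(ends),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genome_spec(data.frame(name = "chr1", length = as.integer(chrom_length),
                         stringsAsFactors = FALSE),
              genes)
}

#' Construct and validate a genome specification
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+` or `-`).
#' @return A validated `genome_spec` object.
#' @export
genome_spec <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(genes),
            all(c("name", "length") %in% names(chromosomes)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(genes$chrom %in% chromosomes$name)) {
    stop("gene chromosome not declared in chromosomes table")
  }
  clen <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(genes$start < 0) || any(genes$end > clen[genes$chrom])) {
    stop("gene interval outside chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "genes\n")
  invisible(x)
}

# Named chromosome-length vector from a genome_spec or a named numeric vector.
chrom_lengths <- function(genome) {
  if (inherits(genome, "genome_spec")) {
    stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop("expected a genome_spec or a named numeric vector of chromosome lengths")
  }
}

#' Write gene models as GFF3
#'
#' @param genome A `genome_spec`.
#' @param path Output file path (`.gff3`).
#' @export
write_genome_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    type = "gene",
    ID = g$gene_id,
    Name = g$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Rows of type `gene` become the gene table; coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @param chromosomes Optional data.frame (`name`, `length`); if absent,
#'   chromosome lengths are taken as the maximum annotated end per chromosome.
#' @return A `genome_spec`.
#' @export
read_genome_gff3 <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  genes <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (is.null(chromosomes)) {
    chromosomes <- do.call(rbind, lapply(split(genes, genes$chrom), function(d) {
      data.frame(name = d$chrom[1], length = max(d$end), stringsAsFactors = FALSE)
    }))
    rownames(chromosomes) <- NULL
  }
  genome_spec(chromosomes, genes)
}
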