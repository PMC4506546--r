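#' Spearman-correlation distance between samples
#'
#' Pairwise distance `D = 1 - SC` where SC is Spearman's correlation of the
#' two samples' expression profiles over genes (average ranks on ties).
#'
#' @param mat Gene x sample matrix (>= 3 genes, >= 2 samples).
#' @return Symmetric distance matrix with zero diagonal, entries in `[0, 2]`.
#' @export
spearman_distance <- function(mat) {
  stopifnot(ncol(mat) >= 2, nrow(mat) >= 3)
  const <- apply(mat, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    stop("constant expression column: Spearman correlation undefined for sample ",
         paste(colnames(mat)[const], collapse = ", "))
  }
  d <- 1 - stats::cor(mat, method = "spearman")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Classical multidimensional scaling
#'
#' Torgerson MDS: square the distances, double-centre, eigendecompose and
#' scale coordinates by the square root of the eigenvalues (via
#' `stats::cmdscale`). Axes with non-positive eigenvalues are dropped with a
#' warning. The sign of each axis is fixed by making its largest-magnitude
#' coordinate positive, so embeddings are reproducible.
#'
#' @param d Symmetric distance matrix.
#' @param k Embedding dimension (`k < nrow(d)`).
#' @return Sample x k coordinate matrix; eigenvalues in `attr(, "eig")`.
#' @export
classical_mds <- function(d, k = 2) {
  n <- nrow(d)
  if (k >= n) stop("embedding dimension k must be smaller than the number of samples")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[seq_len(k)] > max(abs(eig)) * 1e-10)
  if (pos < k) {
    warning("only ", pos, " positive eigenvalues; dropping ", k - pos, " axes")
  }
  pts <- fit$points[, seq_len(pos), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  attr(pts, "eig") <- eig
  pts
}

#' Complete-linkage clustering with optimal leaf ordering
#'
#' Agglomerates with complete linkage (via `stats::hclust`) and then reorders
#' the leaves, over all possible subtree flips, to minimize the sum of
#' distances between adjacent leaves (optimal leaf ordering by dynamic
#' programming over subtree end-leaf pairs).
#'
#' @param d Symmetric distance matrix with dimnames.
#' @return An `hclust` object whose `$order` attains the optimal-leaf-ordering
#'   cost; the achieved cost is stored in `attr(, "olo_cost")`.
#' @export
hier_cluster <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  res <- olo_order(hc, as.matrix(d))
  hc$order <- res$order
  attr(hc, "olo_cost") <- res$cost
  hc
}

# Optimal leaf ordering (dynamic programming).  For every internal node and
# every admissible (leftmost, rightmost) leaf pair, the minimal sum of
# adjacent-leaf distances of a linear arrangement of that subtree is computed;
# admissible pairs have their ends in different child subtrees because
# subtrees stay contiguous under flips.
olo_order <- function(hc, dmat) {
  n_nodes <- nrow(hc$merge)
  leaves <- vector("list", n_nodes)
  M <- vector("list", n_nodes)       # cost matrices, dimnames = leaf indices
  argR <- vector("list", n_nodes)    # argmin: last leaf of left child
  argL <- vector("list", n_nodes)    # argmin: first leaf of right child
  get_leaves <- function(k) if (k < 0) -k else leaves[[k]]
  get_M <- function(k) {
    if (k < 0) {
      matrix(0, 1, 1, dimnames = list(as.character(-k), as.character(-k)))
    } else M[[k]]
  }
  for (v in seq_len(n_nodes)) {
    a <- hc$merge[v, 1]; b <- hc$merge[v, 2]
    la <- get_leaves(a); lb <- get_leaves(b)
    Ma <- get_M(a); Mb <- get_M(b)
    leaves[[v]] <- c(la, lb)
    # C[u, l] = min_r Ma[u, r] + d(r, l): best cost of (A arrangement ending
    # at r) plus the junction edge, for each first-leaf l of B.
    D <- dmat[la, lb, drop = FALSE]
    nu <- length(la); nl <- length(lb)
    C <- matrix(Inf, nu, nl)
    Ridx <- matrix(NA_integer_, nu, nl)
    for (ri in seq_len(nu)) {
      cand <- outer(Ma[, ri], D[ri, ], `+`)  # nu x nl
      upd <- cand < C
      C[upd] <- cand[upd]
      Ridx[upd] <- ri
    }
    # T[u, w] = min_l C[u, l] + Mb[l, w]
    Tm <- matrix(Inf, nu, nl)
    Lidx <- matrix(NA_integer_, nu, nl)
    for (li in seq_len(nl)) {
      cand <- outer(C[, li], Mb[li, ], `+`)
      upd <- cand < Tm
      Tm[upd] <- cand[upd]
      Lidx[upd] <- li
    }
    all_leaves <- c(la, lb)
    nm <- as.character(all_leaves)
    full <- matrix(Inf, length(all_leaves), length(all_leaves),
                   dimnames = list(nm, nm))
    full[seq_len(nu), nu + seq_len(nl)] <- Tm
    full[nu + seq_len(nl), seq_len(nu)] <- t(Tm)
    M[[v]] <- full
    dimnames(Ridx) <- dimnames(Lidx) <- list(as.character(la), as.character(lb))
    argR[[v]] <- Ridx
    argL[[v]] <- Lidx
  }
  reconstruct <- function(v, u, w) {
    if (v < 0) return(-v)
    a <- hc$merge[v, 1]; b <- hc$merge[v, 2]
    la <- get_leaves(a); lb <- get_leaves(b)
    if (u %in% la) {
      lj <- argL[[v]][as.character(u), as.character(w)]
      ri <- argR[[v]][as.character(u), lj]
      c(reconstruct(a, u, la[ri]), reconstruct(b, lb[lj], w))
    } else {
      rev(reconstruct(v, w, u))
    }
  }
  root <- M[[n_nodes]]
  best <- which(root == min(root), arr.ind = TRUE)[1, ]
  u <- as.integer(rownames(root)[best[1]])
  w <- as.integer(colnames(root)[best[2]])
  list(order = reconstruct(n_nodes, u, w), cost = min(root))
}

# Sum of adjacent-leaf distances of a leaf order (the OLO objective).
leaf_order_cost <- function(order, dmat) {
  if (length(order) < 2) return(0)
  sum(dmat[cbind(order[-length(order)], order[-1])])
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights, so cluster support can be
#' recomputed externally.
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Row-standardize a matrix
#'
#' Centres each row to mean 0 and scales to population (divide-by-n) standard
#' deviation 1, the convention used for expression heatmaps. Constant rows are
#' emitted as zeros with a warning.
#'
#' @param mat Numeric matrix (gene x sample).
#' @return Matrix of the same shape.
#' @export
standardize_rows <- function(mat) {
  m <- rowMeans(mat)
  centred <- mat - m
  s <- sqrt(rowMeans(centred^2))
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) standardized to zeros")
    s[const] <- 1
  }
  out <- centred / s
  out[const, ] <- 0
  out
}
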