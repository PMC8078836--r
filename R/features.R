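#' Per-entity statistical feature blocks (F1)
#'
#' For each disease i: its number of known associations (row sum of the
#' association matrix), the mean of its integrated-similarity row, and the
#' `n_bins`-bin histogram proportions of that row over [0, 1]; symmetrically
#' for each metabolite j with column sums and the integrated metabolite
#' similarity. A pair's F1 feature is the concatenation of its disease and
#' metabolite blocks (width `2 * (2 + n_bins)`, 14 at the default
#' `n_bins = 5`).
#'
#' Bins are equal-width and left-closed, with the last bin closed on both
#' sides: `[0, 1/n), ..., [(n-1)/n, 1]`. Histogram proportions of an entity
#' sum to 1 (or are all zero for an entity with an empty similarity row).
#'
#' @param m an [AssociationMatrix-class].
#' @param ids integrated disease [SimilarityMatrix-class].
#' @param ims integrated metabolite [SimilarityMatrix-class].
#' @param n_bins number of histogram bins (default 5).
#' @return List with matrices `disease` (nd x (2 + n_bins)) and `metabolite`
#'   (nm x (2 + n_bins)), rows named by entity id.
#' @export
statisticalFeatures <- function(m, ids, ims, n_bins = 5) {
  stopifnot(is(m, "AssociationMatrix"), n_bins >= 1)
  A <- assocMatrix(m)
  list(disease = .entityStats(rowSums(A), simValues(ids), n_bins),
       metabolite = .entityStats(colSums(A), simValues(ims), n_bins))
}

.entityStats <- function(assoc_count, sim, n_bins) {
  n <- nrow(sim)
  hist_prop <- t(apply(sim, 1, .binProportions, n_bins = n_bins))
  if (n == 1L) hist_prop <- matrix(hist_prop, nrow = 1L)
  out <- cbind(assoc_count = assoc_count,
               sim_mean = rowMeans(sim),
               hist_prop)
  colnames(out) <- c("assoc_count", "sim_mean", paste0("hist", seq_len(n_bins)))
  rownames(out) <- rownames(sim)
  out
}

.binProportions <- function(x, n_bins) {
  if (!length(x)) return(numeric(n_bins))
  idx <- pmin(floor(x * n_bins) + 1L, n_bins)  # last bin right-closed
  tabulate(idx, nbins = n_bins) / length(x)
}

#' Threshold graph of a similarity matrix
#'
#' Unweighted, undirected, self-loop-free graph with an edge between two
#' entities iff their similarity strictly exceeds the arithmetic mean of all
#' matrix entries (diagonal included by default).
#'
#' @param s a [SimilarityMatrix-class].
#' @param exclude_diagonal drop diagonal entries from the mean (default
#'   `FALSE`).
#' @return An `igraph` graph with vertex names set to the entity labels and
#'   a `threshold` graph attribute holding the mean used.
#' @export
buildThresholdGraph <- function(s, exclude_diagonal = FALSE) {
  stopifnot(is(s, "SimilarityMatrix"))
  v <- simValues(s)
  thr <- if (exclude_diagonal && nrow(v) > 1L) {
    mean(v[row(v) != col(v)])
  } else mean(v)
  adj <- (v > thr) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::graph_attr(g, "threshold") <- thr
  g
}

#' Per-node graph-theoretic feature blocks (F2)
#'
#' For each node of a threshold graph: degree, betweenness centrality,
#' closeness centrality (reachable-vertex normalized), eigenvector
#' centrality (scaled to unit maximum) and PageRank (damping 0.85). Isolated
#' nodes get 0 for betweenness, closeness and eigenvector centrality and the
#' uniform dangling-adjusted teleport value for PageRank (dangling mass is
#' redistributed uniformly, so the PageRank vector sums to 1). A pair's F2
#' feature is the disease block followed by the metabolite block (width 10).
#'
#' @param g an undirected `igraph` graph, as from [buildThresholdGraph()].
#' @param damping PageRank damping factor (default 0.85).
#' @return Numeric matrix, one row per node (named), columns `degree`,
#'   `betweenness`, `closeness`, `eigenvector`, `pagerank`.
#' @export
graphFeatures <- function(g, damping = 0.85) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  eig <- if (igraph::ecount(g) > 0) {
    igraph::eigen_centrality(g)$vector
  } else rep(0, n)
  eig[deg == 0] <- 0
  pr <- igraph::page_rank(g, damping = damping)$vector
  out <- cbind(degree = deg, betweenness = btw, closeness = cls,
               eigenvector = eig, pagerank = pr)
  rownames(out) <- igraph::V(g)$name
  out
}

#' Nonnegative matrix factorization feature blocks (F3)
#'
#' Factorizes the disease-by-metabolite association matrix as
#' `M (nd x nm) ~ A (nd x k) B (k x nm)` with nonnegative factors, by
#' Frobenius-norm multiplicative updates from a seeded uniform nonnegative
#' initialization. The reconstruction error is non-increasing across
#' iterations. A pair (i, j)'s F3 feature is row i of A followed by column j
#' of B (width 2k).
#'
#' @param m an [AssociationMatrix-class] with at least one association.
#' @param k factorization rank, at most `min(nd, nm)` (default 20).
#' @param max_iter maximum multiplicative-update iterations (default 500).
#' @param seed integer seed for the random initialization.
#' @param tol relative change in reconstruction error below which updating
#'   stops early (default 1e-9).
#' @return List with `A` (nd x k), `B` (k x nm), `k` and the trajectory
#'   `error` of Frobenius reconstruction errors (one entry per recorded
#'   iteration, non-increasing).
#' @export
nmfFeatures <- function(m, k = 20, max_iter = 500, seed = 1, tol = 1e-9) {
  stopifnot(is(m, "AssociationMatrix"))
  M <- assocMatrix(m)
  if (sum(M) == 0) stop("association matrix is all zero; NMF undefined")
  if (k > min(dim(M)))
    stop("NMF rank k = ", k, " exceeds min(nd, nm) = ", min(dim(M)))
  eps <- .Machine$double.eps
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  A <- matrix(stats::runif(nrow(M) * k), nrow(M), k)
  B <- matrix(stats::runif(k * ncol(M)), k, ncol(M))
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- A * (M %*% t(B)) / (A %*% B %*% t(B) + eps)
    B <- B * (t(A) %*% M) / (t(A) %*% A %*% B + eps)
    if (it %% 10 == 0 || it == max_iter) {
      e <- sqrt(sum((M - A %*% B)^2))
      err <- c(err, e)
      if (is.finite(prev) && prev - e < tol * max(prev, 1)) break
      prev <- e
    }
  }
  rownames(A) <- rownames(M)
  colnames(B) <- colnames(M)
  list(A = A, B = B, k = k, error = err)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble per-pair features and reduce them with PCA
#'
#' Concatenates the F1, F2 and F3 blocks for each (disease, metabolite)
#' pair, standardizes every raw feature to zero mean and unit variance over
#' the training pairs, and projects onto the principal components retaining
#' at least `variance_kept` of the total variance. Standardization and the
#' projection are fit on the training pairs only (`train` indices) and
#' applied unchanged to all other (held-out) pairs, so no information leaks
#' from test pairs into the representation. Constant feature columns (zero
#' training variance) are dropped before PCA.
#'
#' @param pairs data.frame with columns `disease_id`, `metabolite_id`,
#'   `label`.
#' @param f1 output of [statisticalFeatures()].
#' @param f2 list with `disease` and `metabolite` node-feature matrices from
#'   [graphFeatures()].
#' @param f3 output of [nmfFeatures()].
#' @param variance_kept fraction of variance the retained components must
#'   reach, in (0, 1] (default 0.95).
#' @param train integer indices of the training pairs the reduction is fit
#'   on (default: all pairs).
#' @return A [PairFeatureTable-class] with `raw` and `reduced` features; the
#'   PCA fit (centers, scales, rotation) is attached as attribute
#'   `"projection"` of the reduced matrix.
#' @export
assembleAndReduce <- function(pairs, f1, f2, f3, variance_kept = 0.95,
                              train = seq_len(nrow(pairs))) {
  stopifnot(variance_kept > 0, variance_kept <= 1)
  raw <- .rawPairFeatures(pairs, f1, f2, f3)
  X <- raw[train, , drop = FALSE]
  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) < ncol(X))
    message("dropped ", ncol(X) - length(keep),
            " constant feature column(s) before PCA")
  if (!length(keep)) stop("all feature columns are constant on the training pairs")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, sdv[keep], "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  varr <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(varr) >= variance_kept - 1e-12)[1]
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  Zall <- sweep(sweep(raw[, keep, drop = FALSE], 2, ctr[keep]), 2,
                sdv[keep], "/")
  red <- Zall %*% rot
  attr(red, "projection") <- list(center = ctr[keep], scale = sdv[keep],
                                  keep = keep, rotation = rot,
                                  variance_ratio = varr[seq_len(ncomp)])
  PairFeatureTable(pairs, raw, reduced = red)
}

.rawPairFeatures <- function(pairs, f1, f2, f3) {
  di <- pairs$disease_id
  mi <- pairs$metabolite_id
  raw <- cbind(f1$disease[di, , drop = FALSE],
               f2$disease[di, , drop = FALSE],
               f3$A[di, , drop = FALSE],
               f1$metabolite[mi, , drop = FALSE],
               f2$metabolite[mi, , drop = FALSE],
               t(f3$B)[mi, , drop = FALSE])
  blockNames <- function(prefix, m, stem) {
    if (ncol(m) == 0L) return(character(0))   # paste0 recycles "" otherwise
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0(stem, seq_len(ncol(m)))
    paste0(prefix, cn)
  }
  colnames(raw) <- c(
    blockNames("d_", f1$disease, "stat"), blockNames("d_", f2$disease, "graph"),
    paste0("d_nmf", seq_len(f3$k)),
    blockNames("m_", f1$metabolite, "stat"),
    blockNames("m_", f2$metabolite, "graph"),
    paste0("m_nmf", seq_len(f3$k)))
  rownames(raw) <- NULL
  raw
}
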