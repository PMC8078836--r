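# Independent brute-force oracles: element-wise loops and textbook
# definitions only, no reuse of the package's vectorized code paths.

oracleHamming <- function(MP) {
  np <- nrow(MP); nm <- ncol(MP)
  out <- matrix(0, nm, nm)
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    mism <- 0
    for (k in seq_len(np)) if (MP[k, i] != MP[k, j]) mism <- mism + 1
    out[i, j] <- 1 - mism / np
  }
  diag(out) <- 1
  out
}

oracleEntropy <- function(counts, Tn) {
  h <- 0
  for (n in counts) h <- h - (n / Tn) * log2(n / Tn)
  h
}

oracleNmi <- function(catalog, Tn, rule = "min") {
  nd <- length(catalog)
  H <- vapply(catalog, oracleEntropy, numeric(1), Tn = Tn)
  out <- matrix(0, nd, nd)
  for (a in seq_len(nd)) for (b in seq_len(nd)) {
    if (a == b) { out[a, b] <- as.numeric(length(catalog[[a]]) > 0); next }
    sh <- intersect(names(catalog[[a]]), names(catalog[[b]]))
    if (!length(sh) || H[a] + H[b] <= 0) next
    n <- if (rule == "min") pmin(catalog[[a]][sh], catalog[[b]][sh])
         else catalog[[a]][sh] + catalog[[b]][sh]
    out[a, b] <- min(1, max(0, 2 * oracleEntropy(n, Tn) / (H[a] + H[b])))
  }
  out
}

oracleGip <- function(profiles, omega_prime = 1) {
  n <- nrow(profiles)
  ms <- 0
  for (i in seq_len(n)) ms <- ms + sum(profiles[i, ]^2)
  omega <- omega_prime / (ms / n)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- exp(-omega * sum((profiles[i, ] - profiles[j, ])^2))
  diag(out) <- 1
  out
}

# exact variance gain over all instances (GOSS estimator with a = 1)
oracleExactGain <- function(gradients, values, d) {
  left <- values <= d
  nl <- sum(left); nr <- sum(!left); n <- length(gradients)
  if (nl == 0 || nr == 0) return(-Inf)
  (sum(gradients[left])^2 / nl + sum(gradients[!left])^2 / nr) / n
}

# term-by-term evaluation of the one-side-sampling gain formula: amplified
# gradient sums over the sampled sets, full-data counts in the denominators
oracleGossGain <- function(A, B, amplifier, gradients, values, d) {
  nl <- sum(values <= d); nr <- sum(values > d)
  if (nl == 0 || nr == 0) return(-Inf)
  Al <- A[values[A] <= d]; Ar <- A[values[A] > d]
  Bl <- B[values[B] <= d]; Br <- B[values[B] > d]
  Sl <- sum(gradients[Al]) + amplifier * sum(gradients[Bl])
  Sr <- sum(gradients[Ar]) + amplifier * sum(gradients[Br])
  (Sl^2 / nl + Sr^2 / nr) / length(values)
}

# --- graph oracles on an adjacency matrix (undirected, 0/1) ----------------

oracleShortestPaths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# path counts via DP over distance layers, then pair-dependency sums
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracleShortestPaths(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dist in seq_len(n)) {
      for (v in which(d[s, ] == dist))
        sigma[s, v] <- sum(sigma[s, which(adj[, v] == 1 & d[s, ] == dist - 1)])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0)
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  btw
}

oracleCloseness <- function(adj) {
  d <- oracleShortestPaths(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(d[v, reach])   # reachable-only normalized closeness
  }, numeric(1))
}

oracleEigenCentrality <- function(adj, iters = 10000, tol = 1e-14) {
  x <- rep(1, nrow(adj))
  for (i in seq_len(iters)) {
    xn <- adj %*% x
    if (max(xn) == 0) return(rep(0, nrow(adj)))
    xn <- xn / sqrt(sum(xn^2))
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  as.numeric(x / max(x))
}

# PageRank as the exact solution of the linear system with dangling mass
# redistributed uniformly
oraclePagerank <- function(adj, damping = 0.85) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (deg[i] > 0) P[i, ] <- adj[i, ] / deg[i]
    else P[i, ] <- 1 / n                      # dangling: uniform
  }
  b <- rep((1 - damping) / n, n)
  as.numeric(solve(diag(n) - damping * t(P), b))
}

oracleAucEnum <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) tot <- tot + 1
    else if (scores[i] == scores[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# covariance eigen-decomposition oracle for PCA component variances
oracleCovEigenvalues <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  sort(ev, decreasing = TRUE)
}

# small planted dataset for protocol tests (kept tiny so folds are cheap)
smallPlanted <- function(seed = 11, ...) {
  generateSyntheticData(generatorConfig(
    n_diseases = 10, n_metabolites = 18, n_pathways = 6, n_symptoms = 8,
    n_blocks = 2, within_block_assoc_prob = 0.5,
    background_assoc_prob = 0.05, profile_coherence = 0.9, seed = seed, ...))
}

toyOpts <- function(...)
  do.call(pipelineOptions,
          utils::modifyList(list(nmf_rank = 3, nmf_max_iter = 100), list(...)))
toyConfig <- function(...)
  do.call(modelConfig,
          utils::modifyList(list(n_estimators = 30, min_data_in_leaf = 5),
                            list(...)))
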