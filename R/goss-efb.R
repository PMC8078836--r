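# Standalone implementations of the two sampling/bundling primitives of
# gradient boosting with one-side sampling: GOSS (keep the large-gradient
# instances, subsample the rest, reweight in the split gain) and EFB (bundle
# sparse, rarely co-nonzero features into single features with disjoint
# value ranges). The production classifier delegates tree growth to an
# established gradient-boosting backend; these functions expose the
# primitives for direct study and testing.

#' Gradient-based one-side sampling
#'
#' Ranks instances by absolute gradient (descending, ties broken by
#' ascending index), keeps the top `ceiling(a * n)` as set A, and samples
#' `ceiling(b * (n - |A|))` instances uniformly without replacement from the
#' complement as set B. Contributions of B are amplified in the
#' variance-gain estimate by the weight that normalizes the sampled subset
#' back to the full complement, `|A^c| / |B|`: under the sampling convention
#' of the gradient-boosting literature (B drawn as a fraction b of all n
#' instances) this weight is the familiar `(1 - a) / b`; with B drawn as a
#' fraction b of the complement, as here, it evaluates to `~ 1 / b`. Using
#' the exact count ratio keeps the amplified sums unbiased for the
#' complement sums under either convention.
#'
#' @param gradients numeric vector of per-instance gradients.
#' @param a fraction of instances kept by gradient magnitude, in (0, 1].
#' @param b sampling fraction applied to the remainder, in [0, 1].
#' @param seed integer seed making the B sample deterministic.
#' @return List with integer index vectors `A` and `B` (disjoint), `a`, `b`
#'   and the `amplifier` weight (0 when B is empty).
#' @examples
#' gossSample(c(3, -5, 1, 0), a = 0.5, b = 0.5, seed = 1)$A  # indices 2, 1
#' @export
gossSample <- function(gradients, a, b, seed = 1) {
  n <- length(gradients)
  stopifnot(n > 0, a > 0, a <= 1, b >= 0, b <= 1)
  nA <- ceiling(a * n)
  if (nA < 1 && b == 0)
    stop("empty training subset: a * n < 1 and b = 0")
  o <- order(-abs(gradients), seq_len(n))
  A <- sort(o[seq_len(nA)])
  comp <- sort(o[-seq_len(nA)])
  nB <- ceiling(b * length(comp))
  B <- if (nB > 0) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(seed)
    sort(comp[sample.int(length(comp), nB)])
  } else integer(0)
  amplifier <- if (length(B)) length(comp) / length(B) else 0
  list(A = A, B = B, a = a, b = b, amplifier = amplifier)
}

#' Estimated variance gain of a split under GOSS
#'
#' Evaluates the one-side-sampling estimate of the variance gain of
#' splitting a feature at point `d`:
#' \deqn{\tilde V(d) = \frac{1}{n}\left(
#'   \frac{(\sum_{A_l} g_i + w\sum_{B_l} g_i)^2}{\tilde n_l(d)} +
#'   \frac{(\sum_{A_r} g_i + w\sum_{B_r} g_i)^2}{\tilde n_r(d)}\right)}
#' where the left side holds instances with feature value `<= d`, the right
#' side those with value `> d`, and `w` is the sample's amplifier. Only the
#' gradient sums are subsampled: the instance counts `n_l`, `n_r` and the
#' leading `1/n` use all instances (feature values are known for the whole
#' dataset; `n` is the total instance count), and the amplified B sums are
#' unbiased for the complement sums. The estimate therefore converges to
#' the exact all-data variance gain as the sampling is repeated, and with
#' `a = 1` (B empty) it equals it. An empty side makes the split invalid
#' and the gain is `-Inf`.
#'
#' @param sample a GOSS sample from [gossSample()].
#' @param gradients numeric gradient vector aligned with `feature_values`.
#' @param feature_values numeric vector of one feature's values.
#' @param d split point.
#' @return List with `d`, `gain`, `n_left`, `n_right`.
#' @export
gossVarianceGain <- function(sample, gradients, feature_values, d) {
  stopifnot(length(gradients) == length(feature_values))
  amp <- sample$amplifier
  n <- length(feature_values)
  left_all <- feature_values <= d
  nl <- sum(left_all)
  nr <- n - nl
  if (nl == 0L || nr == 0L)
    return(list(d = d, gain = -Inf, n_left = nl, n_right = nr))
  A <- sample$A; B <- sample$B
  Sl <- sum(gradients[A[left_all[A]]]) + amp * sum(gradients[B[left_all[B]]])
  Sr <- sum(gradients[A[!left_all[A]]]) + amp * sum(gradients[B[!left_all[B]]])
  gain <- (Sl^2 / nl + Sr^2 / nr) / n
  list(d = d, gain = gain, n_left = nl, n_right = nr)
}

#' Candidate split points of a feature
#'
#' Midpoints between consecutive distinct sorted feature values.
#'
#' @param feature_values numeric vector.
#' @return Numeric vector of candidate split points (possibly empty).
#' @export
splitCandidates <- function(feature_values) {
  u <- sort(unique(feature_values))
  if (length(u) < 2L) return(numeric(0))
  (u[-length(u)] + u[-1L]) / 2
}

#' GOSS gain table over all candidate splits of every feature
#'
#' Convenience wrapper evaluating [gossVarianceGain()] at every candidate
#' split point of every feature column, for a given GOSS sample.
#'
#' @param sample a GOSS sample from [gossSample()].
#' @param gradients numeric gradient vector.
#' @param features numeric matrix, one column per feature.
#' @return data.frame with columns `feature`, `d`, `gain`, `n_left`,
#'   `n_right`.
#' @export
gossGainTable <- function(sample, gradients, features) {
  features <- as.matrix(features)
  rows <- lapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    cands <- splitCandidates(x)
    if (!length(cands)) return(NULL)
    do.call(rbind, lapply(cands, function(d) {
      ev <- gossVarianceGain(sample, gradients, x, d)
      data.frame(feature = j, d = d, gain = ev$gain,
                 n_left = ev$n_left, n_right = ev$n_right)
    }))
  })
  do.call(rbind, rows)
}

#' Greedy exclusive-feature bundling
#'
#' Counts, for every feature pair, the number of rows where both features
#' are nonzero (the conflict count), orders features by their total conflict
#' count descending (ties by ascending index), and assigns each feature to
#' the first existing bundle whose total internal conflict count stays
#' within the budget `K` after adding it; otherwise a new bundle is opened.
#'
#' @param feature_matrix numeric matrix of discretized feature values
#'   (nonzero pattern is what matters).
#' @param K nonnegative conflict budget per bundle.
#' @return List of bundles; each bundle is a list with `members` (feature
#'   indices in assignment order) and `conflict_count` (total pairwise
#'   conflicts inside the bundle, always `<= K`).
#' @export
greedyBundle <- function(feature_matrix, K = 0) {
  stopifnot(K >= 0)
  X <- as.matrix(feature_matrix) != 0
  nf <- ncol(X)
  conflicts <- crossprod(X * 1)   # pairwise co-nonzero row counts
  diag(conflicts) <- 0
  total <- rowSums(conflicts)
  ord <- order(-total, seq_len(nf))
  bundles <- list()
  for (f in ord) {
    placed <- FALSE
    for (bi in seq_along(bundles)) {
      added <- sum(conflicts[f, bundles[[bi]]$members])
      if (bundles[[bi]]$conflict_count + added <= K) {
        bundles[[bi]]$members <- c(bundles[[bi]]$members, f)
        bundles[[bi]]$conflict_count <- bundles[[bi]]$conflict_count + added
        placed <- TRUE
        break
      }
    }
    if (!placed)
      bundles[[length(bundles) + 1L]] <- list(members = f, conflict_count = 0)
  }
  bundles
}

#' Merge the features of one bundle into a single feature
#'
#' Shifts each member feature's value range by a cumulative offset so that
#' the ranges are disjoint, then encodes each row by the offset-shifted
#' value of its nonzero member (the first member in bundle order when
#' several conflict). [decodeBundle()] inverts the mapping exactly on
#' conflict-free rows.
#'
#' @param bundle one bundle from [greedyBundle()].
#' @param feature_matrix the matrix the bundle was built from (nonnegative
#'   discrete values).
#' @return List with `merged` (numeric vector, one value per row), `members`
#'   and `offsets` (per-member range offsets, strictly increasing).
#' @export
mergeExclusiveFeatures <- function(bundle, feature_matrix) {
  X <- as.matrix(feature_matrix)
  members <- bundle$members
  maxv <- apply(X[, members, drop = FALSE], 2, max)
  offsets <- cumsum(c(0, maxv[-length(maxv)]))
  names(offsets) <- as.character(members)
  merged <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    for (mi in seq_along(members)) {
      v <- X[r, members[mi]]
      if (v != 0) {             # first nonzero member in bundle order wins
        merged[r] <- offsets[mi] + v
        break
      }
    }
  }
  list(merged = merged, members = members, offsets = offsets)
}

#' Decode a merged bundle feature back to its member columns
#'
#' Inverts [mergeExclusiveFeatures()] on conflict-free rows: a merged value
#' `v` in `(offset_i, offset_i + max_i]` decodes to value `v - offset_i` of
#' member `i`; a merged 0 decodes to all-zero members.
#'
#' @param merged the list returned by [mergeExclusiveFeatures()].
#' @param n_rows number of rows to reconstruct.
#' @return Numeric matrix with one column per bundle member (named by the
#'   original feature index).
#' @export
decodeBundle <- function(merged, n_rows = length(merged$merged)) {
  members <- merged$members
  offsets <- merged$offsets
  out <- matrix(0, n_rows, length(members),
                dimnames = list(NULL, as.character(members)))
  for (r in seq_len(n_rows)) {
    v <- merged$merged[r]
    if (v == 0) next
    mi <- max(which(v > offsets))
    out[r, mi] <- v - offsets[mi]
  }
  out
}
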