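#' Metabolite functional similarity from pathway profiles
#'
#' Hamming similarity between the pathway membership columns of two
#' metabolites: `MHS(i, j) = 1 - (# pathways where the two membership bits
#' differ) / np`, where `np` is the number of pathways. Two metabolites
#' annotated to exactly the same pathways get similarity 1; metabolites
#' disagreeing on every pathway get 0. The diagonal is exactly 1.
#'
#' @param mp a [PathwayMembership-class] with at least one pathway row.
#' @return A metabolite-axis [SimilarityMatrix-class] of kind `"hamming"`.
#' @examples
#' mp <- PathwayMembership(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2,
#'        dimnames = list(paste0("p", 1:4), c("m1", "m2"))))
#' simValues(metaboliteHammingSimilarity(mp))  # off-diagonal 0.5
#' @export
metaboliteHammingSimilarity <- function(mp) {
  stopifnot(is(mp, "PathwayMembership"))
  m <- membershipMatrix(mp)
  np <- nrow(m)
  if (np == 0L) stop("pathway membership has zero pathways; Hamming similarity undefined")
  # mismatches between binary columns i,j: x_i'1 + x_j'1 - 2 x_i'x_j
  cs <- colSums(m)
  cross <- crossprod(m)
  mismatch <- outer(cs, cs, `+`) - 2 * cross
  vals <- 1 - mismatch / np
  diag(vals) <- 1
  SimilarityMatrix(vals, axis = "metabolite", kind = "hamming")
}

#' Information entropy of a disease's symptom set
#'
#' `H(S_d) = -sum_i p_i log2(p_i)` with `p_i = n_i / Tn`: each symptom's
#' probability mass is its occurrence count for this disease divided by the
#' catalog-wide total `Tn`, so the per-disease masses do not sum to 1 and the
#' "entropy" is a weight on how much of the global association mass the
#' disease's symptoms carry. An empty symptom set has entropy 0.
#'
#' @param disease disease identifier present in the catalog.
#' @param catalog a [SymptomCatalog-class] with `Tn > 0`.
#' @return Nonnegative entropy value.
#' @export
symptomEntropy <- function(disease, catalog) {
  stopifnot(is(catalog, "SymptomCatalog"))
  if (totalSymptomCount(catalog) <= 0)
    stop("symptom catalog total Tn is zero; entropy undefined")
  counts <- symptomCounts(catalog, disease)
  .entropyFromCounts(counts, totalSymptomCount(catalog))
}

.entropyFromCounts <- function(counts, Tn) {
  if (!length(counts)) return(0)
  p <- counts / Tn
  -sum(p * log2(p))
}

#' Disease functional similarity from shared symptoms
#'
#' Normalized mutual information over symptom sets:
#' `DNF(a, b) = 2 H(intersect(S_a, S_b)) / (H(S_a) + H(S_b))`, where the
#' intersection entropy sums the same `-p log2 p` terms over the shared
#' symptoms only. The count of a shared symptom is taken as the minimum of
#' the two diseases' counts (`shared_count = "min"`, conservative) or their
#' sum (`"sum"`). Pairs with an empty intersection or zero denominator get
#' 0; values are clamped to [0, 1] (the global-frequency entropy makes the
#' ratio exceed 1 on occasion). Self-similarity is forced to 1 for diseases
#' with a nonempty symptom set, 0 otherwise, so that the GIP kernel fallback
#' covers symptomless diseases during integration.
#'
#' @param catalog a [SymptomCatalog-class].
#' @param disease_ids ordered disease labels defining the matrix axes.
#' @param shared_count how to set the count of a shared symptom in the
#'   intersection entropy: `"min"` (default) or `"sum"`.
#' @return A disease-axis [SimilarityMatrix-class] of kind `"nmi"`.
#' @export
diseaseNmiSimilarity <- function(catalog, disease_ids,
                                 shared_count = c("min", "sum")) {
  stopifnot(is(catalog, "SymptomCatalog"))
  shared_count <- match.arg(shared_count)
  Tn <- totalSymptomCount(catalog)
  if (Tn <= 0) stop("symptom catalog total Tn is zero")
  nd <- length(disease_ids)
  sets <- lapply(disease_ids, function(d) symptomCounts(catalog, d))
  H <- vapply(sets, .entropyFromCounts, numeric(1), Tn = Tn)
  vals <- matrix(0, nd, nd, dimnames = list(disease_ids, disease_ids))
  comb <- if (shared_count == "min") pmin else `+`
  for (a in seq_len(nd)) {
    sa <- sets[[a]]
    if (!length(sa)) next
    for (b in seq_len(nd)) {
      if (b <= a) next
      sb <- sets[[b]]
      shared <- intersect(names(sa), names(sb))
      if (!length(shared) || (H[a] + H[b]) <= 0) next
      hint <- .entropyFromCounts(comb(sa[shared], sb[shared]), Tn)
      vals[a, b] <- vals[b, a] <- min(1, max(0, 2 * hint / (H[a] + H[b])))
    }
  }
  diag(vals) <- as.numeric(lengths(sets) > 0L)
  SimilarityMatrix(vals, axis = "disease", kind = "nmi")
}

#' Normalized Gaussian interaction profile kernel bandwidth
#'
#' The raw bandwidth `omega_prime` is normalized by the mean squared
#' Euclidean norm of the interaction profiles:
#' `omega = omega_prime / ((1/n) sum_i ||V_i||^2)`.
#'
#' @param profiles numeric matrix whose rows are the binary interaction
#'   profiles.
#' @param omega_prime positive raw bandwidth (default 1, the convention of
#'   the GIP kernel literature).
#' @param axis `"disease"` or `"metabolite"` (bookkeeping only).
#' @return A [GipBandwidth-class].
#' @export
gipBandwidth <- function(profiles, omega_prime = 1, axis = "disease") {
  stopifnot(omega_prime > 0)
  norm2 <- rowSums(profiles^2)
  mean_norm2 <- mean(norm2)
  if (mean_norm2 == 0)
    stop("all interaction profiles are zero; GIP bandwidth undefined")
  new("GipBandwidth", omega = omega_prime / mean_norm2,
      omegaPrime = omega_prime, axis = axis)
}

#' Gaussian interaction profile kernel similarity
#'
#' `K(i, j) = exp(-omega ||V_i - V_j||^2)` over the rows (disease axis) or
#' columns (metabolite axis) of the association matrix, with the bandwidth
#' `omega` normalized per [gipBandwidth()]. Identical profiles give 1 and
#' the diagonal is exactly 1.
#'
#' @param m an [AssociationMatrix-class].
#' @param axis `"disease"` (row profiles) or `"metabolite"` (column
#'   profiles).
#' @param omega_prime positive raw bandwidth (default 1).
#' @return A [SimilarityMatrix-class] of kind `"gip"`.
#' @export
gipSimilarity <- function(m, axis = c("disease", "metabolite"),
                          omega_prime = 1) {
  stopifnot(is(m, "AssociationMatrix"))
  axis <- match.arg(axis)
  prof <- if (axis == "disease") assocMatrix(m) else t(assocMatrix(m))
  bw <- gipBandwidth(prof, omega_prime, axis)
  norm2 <- rowSums(prof^2)
  d2 <- outer(norm2, norm2, `+`) - 2 * tcrossprod(prof)
  d2[d2 < 0] <- 0                     # numerical floor
  vals <- exp(-bw@omega * d2)
  diag(vals) <- 1
  dimnames(vals) <- list(rownames(prof), rownames(prof))
  SimilarityMatrix(vals, axis = axis, kind = "gip")
}

#' Integrate a primary similarity with a GIP fallback
#'
#' Entry-wise selection: keep the primary similarity where it is nonzero,
#' otherwise fall back (typically to the GIP kernel similarity, which is
#' defined for every pair). This guarantees similarity information exists
#' for every pair on each axis.
#'
#' @param primary,fallback [SimilarityMatrix-class] objects on the same axis
#'   with identical labels.
#' @return A [SimilarityMatrix-class] of kind `"integrated"`.
#' @export
integrateSimilarity <- function(primary, fallback) {
  stopifnot(is(primary, "SimilarityMatrix"), is(fallback, "SimilarityMatrix"))
  if (!identical(simAxis(primary), simAxis(fallback)))
    stop("cannot integrate similarities on different axes")
  if (!identical(rownames(simValues(primary)), rownames(simValues(fallback))))
    stop("cannot integrate similarities with different label sets")
  p <- simValues(primary)
  f <- simValues(fallback)
  vals <- ifelse(p != 0, p, f)
  SimilarityMatrix(vals, axis = simAxis(primary), kind = "integrated")
}
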