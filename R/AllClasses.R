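#' @import methods
NULL

.isBinary <- function(x) {
  length(x) == 0L || all(x == 0 | x == 1)
}

#' Binary disease-by-metabolite association matrix
#'
#' Wraps a binary incidence matrix whose rows are diseases and columns are
#' metabolites, together with the two label registries. An entry of 1 means
#' the disease-metabolite association is experimentally confirmed.
#'
#' @slot assoc binary numeric matrix, diseases in rows, metabolites in
#'   columns, with dimnames holding the identifiers.
#'
#' @seealso [readAssociationPairs()], [AssociationMatrix()]
#' @export
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  m <- object@assoc
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "assoc must carry disease row names and metabolite column names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate disease ids")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate metabolite ids")
  }
  if (!.isBinary(m)) msg <- c(msg, "entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationMatrix from a binary matrix
#'
#' @param assoc binary matrix with disease row names and metabolite column
#'   names.
#' @return An [AssociationMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("m1", "m2")))
#' AssociationMatrix(m)
#' @export
AssociationMatrix <- function(assoc) {
  storage.mode(assoc) <- "double"
  new("AssociationMatrix", assoc = assoc)
}

#' Binary pathway-by-metabolite membership matrix
#'
#' @slot membership binary numeric matrix, pathways in rows, metabolites in
#'   columns.
#' @seealso [readPathwayMembership()]
#' @export
setClass("PathwayMembership", representation(membership = "matrix"))

setValidity("PathwayMembership", function(object) {
  m <- object@membership
  msg <- character()
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "membership must carry pathway row names and metabolite column names")
  if (!.isBinary(m)) msg <- c(msg, "entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayMembership matrix
#' @param membership binary matrix, pathways in rows, metabolites in columns.
#' @return A [PathwayMembership-class] object.
#' @export
PathwayMembership <- function(membership) {
  storage.mode(membership) <- "double"
  new("PathwayMembership", membership = membership)
}

#' Per-disease symptom occurrence catalog
#'
#' Holds, for each disease, a named vector of symptom occurrence counts, plus
#' the grand total `Tn` of disease-symptom association counts used to turn
#' counts into frequencies for the entropy computation.
#'
#' @slot catalog named list: disease id -> named numeric vector of positive
#'   symptom counts (possibly empty).
#' @slot Tn numeric(1), the total count over all diseases and symptoms.
#' @seealso [readSymptomCatalog()], [symptomEntropy()]
#' @export
setClass("SymptomCatalog", representation(catalog = "list", Tn = "numeric"))

setValidity("SymptomCatalog", function(object) {
  msg <- character()
  if (is.null(names(object@catalog)) && length(object@catalog) > 0L)
    msg <- c(msg, "catalog entries must be named by disease id")
  counts <- unlist(object@catalog, use.names = FALSE)
  if (length(counts) && any(counts < 1)) msg <- c(msg, "all counts must be >= 1")
  total <- if (length(counts)) sum(counts) else 0
  if (!isTRUE(all.equal(total, object@Tn)))
    msg <- c(msg, "Tn must equal the sum of all per-disease symptom counts")
  if (length(msg)) msg else TRUE
})

#' Construct a SymptomCatalog
#' @param catalog named list mapping disease id to a named numeric vector of
#'   positive symptom counts.
#' @param Tn total number of disease-symptom associations; computed from
#'   `catalog` when omitted.
#' @return A [SymptomCatalog-class] object.
#' @export
SymptomCatalog <- function(catalog, Tn = NULL) {
  if (is.null(Tn)) {
    counts <- unlist(catalog, use.names = FALSE)
    Tn <- if (length(counts)) sum(counts) else 0
  }
  new("SymptomCatalog", catalog = catalog, Tn = as.numeric(Tn))
}

#' Square symmetric similarity matrix over one axis
#'
#' Values lie in [0, 1] and the matrix is symmetric. `axis` says whether the
#' labels are diseases or metabolites; `kind` records how the values were
#' computed (`"hamming"`, `"nmi"`, `"gip"` or `"integrated"`).
#'
#' @slot values square symmetric numeric matrix in [0, 1] with identical
#'   row/column names.
#' @slot axis `"disease"` or `"metabolite"`.
#' @slot kind one of `"hamming"`, `"nmi"`, `"gip"`, `"integrated"`.
#' @export
setClass("SimilarityMatrix",
         representation(values = "matrix", axis = "character",
                        kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (!identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must agree")
  if (nrow(v) && max(abs(v - t(v))) > 1e-12)
    msg <- c(msg, "values must be symmetric within 1e-12")
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msg <- c(msg, "values must lie in [0, 1]")
  if (!object@axis %in% c("disease", "metabolite"))
    msg <- c(msg, "axis must be 'disease' or 'metabolite'")
  if (!object@kind %in% c("hamming", "nmi", "gip", "integrated"))
    msg <- c(msg, "unknown kind")
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#' @param values square symmetric matrix in [0, 1] with labels as dimnames.
#' @param axis `"disease"` or `"metabolite"`.
#' @param kind similarity kind (`"hamming"`, `"nmi"`, `"gip"`,
#'   `"integrated"`).
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, axis, kind) {
  values <- (values + t(values)) / 2      # kill last-bit asymmetry
  values[values < 0] <- 0
  values[values > 1] <- 1
  new("SimilarityMatrix", values = values, axis = axis, kind = kind)
}

#' Normalized Gaussian interaction profile kernel bandwidth
#'
#' @slot omega normalized bandwidth (raw bandwidth divided by the mean
#'   squared norm of the interaction profiles).
#' @slot omegaPrime raw bandwidth.
#' @slot axis `"disease"` or `"metabolite"`.
#' @seealso [gipBandwidth()]
#' @export
setClass("GipBandwidth",
         representation(omega = "numeric", omegaPrime = "numeric",
                        axis = "character"))

setValidity("GipBandwidth", function(object) {
  if (object@omega <= 0 || object@omegaPrime <= 0)
    "bandwidths must be positive" else TRUE
})

#' One row per scored (disease, metabolite) pair
#'
#' @slot pairs data.frame with columns `disease_id`, `metabolite_id`,
#'   `label` (0/1) and, once scored, `known_flag`.
#' @slot raw numeric matrix of raw features, one row per pair (statistical,
#'   graph and factorization blocks concatenated).
#' @slot reduced numeric matrix of PCA-reduced features (possibly 0-column
#'   before reduction).
#' @slot score numeric vector of model scores in [0, 1] (length 0 before
#'   scoring).
#' @export
setClass("PairFeatureTable",
         representation(pairs = "data.frame", raw = "matrix",
                        reduced = "matrix", score = "numeric"))

setValidity("PairFeatureTable", function(object) {
  msg <- character()
  need <- c("disease_id", "metabolite_id", "label")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, "pairs must have disease_id, metabolite_id, label columns")
  n <- nrow(object@pairs)
  if (nrow(object@raw) && nrow(object@raw) != n)
    msg <- c(msg, "raw features must have one row per pair")
  if (nrow(object@reduced) && nrow(object@reduced) != n)
    msg <- c(msg, "reduced features must have one row per pair")
  if (length(object@score) && length(object@score) != n)
    msg <- c(msg, "score must have one value per pair")
  if (nrow(object@raw) && anyNA(object@raw))
    msg <- c(msg, "raw features must not contain missing values")
  if (length(msg)) msg else TRUE
})

PairFeatureTable <- function(pairs, raw,
                             reduced = matrix(numeric(0), 0, 0),
                             score = numeric(0)) {
  new("PairFeatureTable", pairs = pairs, raw = raw, reduced = reduced,
      score = score)
}

#' Cross-validation evaluation report
#'
#' @slot auc pooled rank-based AUC.
#' @slot precision,recall,f1 confusion-matrix metrics at the report's score
#'   threshold.
#' @slot rocPoints data.frame of (fpr, tpr) points from (0,0) to (1,1).
#' @slot perFoldAuc per-fold AUCs (k-fold only; length 0 for LOOCV).
#' @slot topKHits named numeric vector: k -> number of held-out positives
#'   ranked within the top k of their candidate list.
#' @slot protocol `"loocv"` or `"kfold"`.
#' @slot seed integer seed the protocol ran under.
#' @slot audit data.frame of per-fold leakage assertions (masked entry values
#'   in every association-derived input).
#' @export
setClass("EvaluationReport",
         representation(auc = "numeric", precision = "numeric",
                        recall = "numeric", f1 = "numeric",
                        rocPoints = "data.frame", perFoldAuc = "numeric",
                        topKHits = "numeric", protocol = "character",
                        seed = "integer", audit = "data.frame"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  for (s in c("auc", "precision", "recall", "f1")) {
    v <- slot(object, s)
    if (length(v) && (v < 0 || v > 1)) msg <- c(msg, paste(s, "must be in [0,1]"))
  }
  if (!object@protocol %in% c("loocv", "kfold"))
    msg <- c(msg, "protocol must be 'loocv' or 'kfold'")
  rp <- object@rocPoints
  if (nrow(rp)) {
    if (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
      msg <- c(msg, "roc points must be nondecreasing in both coordinates")
  }
  if (length(msg)) msg else TRUE
})
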