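#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @export
setGeneric("symptomCounts", function(x, disease) standardGeneric("symptomCounts"))

#' @rdname accessors
#' @export
setGeneric("totalSymptomCount", function(x) standardGeneric("totalSymptomCount"))

#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname accessors
#' @export
setGeneric("simAxis", function(x) standardGeneric("simAxis"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname accessors
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' @rdname accessors
#' @export
setGeneric("rawFeatures", function(x) standardGeneric("rawFeatures"))

#' @rdname accessors
#' @export
setGeneric("reducedFeatures", function(x) standardGeneric("reducedFeatures"))

#' @rdname accessors
#' @export
setGeneric("pairScores", function(x) standardGeneric("pairScores"))

#' Accessors for the core classes
#'
#' Small read-only accessors so user code never touches slots directly:
#' label registries, matrices, symptom counts, similarity values and
#' feature-table columns.
#'
#' @param x an object of one of the package's classes.
#' @param disease disease identifier (for `symptomCounts`).
#' @return The requested component (matrix, character vector, numeric vector
#'   or data.frame).
#' @name accessors
#' @aliases diseaseIds metaboliteIds assocMatrix membershipMatrix pathwayIds
#'   symptomCounts totalSymptomCount simValues simAxis simKind pairInfo
#'   rawFeatures reducedFeatures pairScores
NULL

setMethod("diseaseIds", "AssociationMatrix", function(x) rownames(x@assoc))
setMethod("metaboliteIds", "AssociationMatrix", function(x) colnames(x@assoc))
setMethod("assocMatrix", "AssociationMatrix", function(x) x@assoc)

setMethod("membershipMatrix", "PathwayMembership", function(x) x@membership)
setMethod("pathwayIds", "PathwayMembership", function(x) rownames(x@membership))
setMethod("metaboliteIds", "PathwayMembership", function(x) colnames(x@membership))

setMethod("diseaseIds", "SymptomCatalog", function(x) names(x@catalog))
setMethod("symptomCounts", "SymptomCatalog", function(x, disease) {
  if (!disease %in% names(x@catalog))
    stop("unknown disease id: ", disease)
  x@catalog[[disease]]
})
setMethod("totalSymptomCount", "SymptomCatalog", function(x) x@Tn)

setMethod("simValues", "SimilarityMatrix", function(x) x@values)
setMethod("simAxis", "SimilarityMatrix", function(x) x@axis)
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

setMethod("pairInfo", "PairFeatureTable", function(x) x@pairs)
setMethod("rawFeatures", "PairFeatureTable", function(x) x@raw)
setMethod("reducedFeatures", "PairFeatureTable", function(x) x@reduced)
setMethod("pairScores", "PairFeatureTable", function(x) x@score)

setMethod("show", "AssociationMatrix", function(object) {
  m <- object@assoc
  cat("AssociationMatrix:", nrow(m), "diseases x", ncol(m), "metabolites,",
      sum(m), "known associations\n")
})

setMethod("show", "PathwayMembership", function(object) {
  m <- object@membership
  cat("PathwayMembership:", nrow(m), "pathways x", ncol(m), "metabolites,",
      sum(m), "memberships\n")
})

setMethod("show", "SymptomCatalog", function(object) {
  cat("SymptomCatalog:", length(object@catalog), "diseases,",
      "Tn =", object@Tn, "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@kind, ", ", object@axis, " axis): ",
      nrow(object@values), " x ", ncol(object@values), "\n", sep = "")
})

setMethod("show", "PairFeatureTable", function(object) {
  cat("PairFeatureTable:", nrow(object@pairs), "pairs,",
      ncol(object@raw), "raw features,",
      ncol(object@reduced), "reduced features",
      if (length(object@score)) "(scored)" else "(unscored)", "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport [", object@protocol, "]\n", sep = "")
  cat("  AUC:", format(object@auc, digits = 4), "\n")
  cat("  precision/recall/F1:",
      paste(format(c(object@precision, object@recall, object@f1), digits = 4),
            collapse = " / "), "\n")
  if (length(object@perFoldAuc))
    cat("  per-fold AUC:",
        paste(format(object@perFoldAuc, digits = 4), collapse = ", "), "\n")
  if (length(object@topKHits))
    cat("  top-k hits:",
        paste(names(object@topKHits), object@topKHits, sep = ":",
              collapse = " "), "\n")
})
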