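#' Bundle the three aligned inputs into one dataset
#'
#' Checks label-registry alignment: the pathway membership columns must be
#' exactly the association matrix's metabolites (same order), and the
#' symptom catalog must cover exactly its diseases.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param pathways a [PathwayMembership-class].
#' @param symptoms a [SymptomCatalog-class].
#' @return A list of class `"mdaDataset"` with elements `assoc`, `pathways`,
#'   `symptoms`.
#' @export
mdaDataset <- function(assoc, pathways, symptoms) {
  stopifnot(is(assoc, "AssociationMatrix"),
            is(pathways, "PathwayMembership"),
            is(symptoms, "SymptomCatalog"))
  if (!identical(metaboliteIds(assoc), metaboliteIds(pathways)))
    stop("pathway membership metabolites are not aligned with the association matrix")
  if (!identical(diseaseIds(assoc), diseaseIds(symptoms)))
    stop("symptom catalog diseases are not aligned with the association matrix")
  structure(list(assoc = assoc, pathways = pathways, symptoms = symptoms),
            class = "mdaDataset")
}

#' Load a dataset from the three TSV files
#'
#' @param assoc_path association pair TSV (disease_id, metabolite_id).
#' @param pathway_path membership TSV (metabolite_id, pathway_id).
#' @param symptom_path symptom TSV (disease_id, symptom_id\[, count\]).
#' @param drop_profileless drop diseases without symptoms and metabolites
#'   without pathways instead of keeping them with GIP fallback (default
#'   `FALSE`, keeping the tool general).
#' @param header logical, forwarded to the readers.
#' @return An [mdaDataset()].
#' @export
readMdaDataset <- function(assoc_path, pathway_path, symptom_path,
                           drop_profileless = FALSE, header = FALSE) {
  am <- readAssociationPairs(assoc_path, header = header)
  mp <- readPathwayMembership(pathway_path, metaboliteIds(am), header = header)
  sc <- readSymptomCatalog(symptom_path, diseaseIds(am), header = header)
  if (drop_profileless) {
    keep_m <- colSums(membershipMatrix(mp)) > 0
    keep_d <- lengths(sc@catalog) > 0
    A <- assocMatrix(am)[keep_d, keep_m, drop = FALSE]
    am <- AssociationMatrix(A)
    mp <- PathwayMembership(membershipMatrix(mp)[, keep_m, drop = FALSE])
    sc <- SymptomCatalog(sc@catalog[keep_d])
    message("dropped ", sum(!keep_d), " disease(s) and ", sum(!keep_m),
            " metabolite(s) without profiles")
  }
  mdaDataset(am, mp, sc)
}

#' Feature-construction options
#'
#' @param n_bins similarity histogram bins for the statistical features
#'   (default 5).
#' @param nmf_rank rank k of the association-matrix factorization (default
#'   20).
#' @param nmf_max_iter multiplicative-update budget (default 500).
#' @param variance_kept PCA retained-variance fraction (default 0.95).
#' @param omega_prime_d,omega_prime_m raw GIP bandwidths (default 1).
#' @param shared_count intersection-count rule for the symptom NMI
#'   (`"min"` or `"sum"`).
#' @param exclude_diagonal exclude the diagonal from the threshold-graph
#'   mean (default `FALSE`).
#' @return A list of class `"PipelineOptions"`.
#' @export
pipelineOptions <- function(n_bins = 5, nmf_rank = 20, nmf_max_iter = 500,
                            variance_kept = 0.95, omega_prime_d = 1,
                            omega_prime_m = 1,
                            shared_count = c("min", "sum"),
                            exclude_diagonal = FALSE) {
  structure(list(n_bins = n_bins, nmf_rank = nmf_rank,
                 nmf_max_iter = nmf_max_iter, variance_kept = variance_kept,
                 omega_prime_d = omega_prime_d, omega_prime_m = omega_prime_m,
                 shared_count = match.arg(shared_count),
                 exclude_diagonal = exclude_diagonal),
            class = "PipelineOptions")
}

# one global seed deterministically derives every stage seed (kept < 2^31)
.deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(stage)) %% 2147483647)
}

#' Build the full feature set of a dataset
#'
#' Runs similarity construction (Hamming, symptom NMI, both GIP kernels,
#' integration), statistical, graph and factorization feature extraction on
#' the unmasked association matrix.
#'
#' @param dataset an [mdaDataset()].
#' @param opts a [pipelineOptions()].
#' @param seed seed for the NMF initialization.
#' @return List with feature blocks `f1`, `f2`, `f3` and the integrated
#'   similarity matrices `ids`, `ims`.
#' @export
buildFeatureSet <- function(dataset, opts = pipelineOptions(), seed = 1) {
  static <- .staticSimilarities(dataset, opts)
  .maskedFeatureSet(dataset$assoc, static, opts,
                    nmf_seed = .deriveSeed(seed, 1L))
}

#' Run the full prediction pipeline
#'
#' similarity -> features -> PCA -> train -> score every pair, then write
#' the ranked predictions, an evaluation report (of the configured
#' protocol), the ROC points and a provenance file into `out_dir`.
#'
#' @param dataset an [mdaDataset()].
#' @param out_dir output directory (created if missing).
#' @param config a [modelConfig()].
#' @param opts a [pipelineOptions()].
#' @param protocol evaluation protocol to run alongside scoring: `"kfold"`
#'   (default), `"loocv"` or `"none"`.
#' @param k folds for the k-fold protocol.
#' @param top_n rows kept in the predictions file (default: all).
#' @return Invisibly, a list with the scored [PairFeatureTable-class], the
#'   [EvaluationReport-class] (or `NULL`) and the output paths.
#' @export
runPipeline <- function(dataset, out_dir, config = modelConfig(),
                        opts = pipelineOptions(),
                        protocol = c("kfold", "loocv", "none"), k = 5,
                        top_n = Inf) {
  protocol <- match.arg(protocol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- scoreDataset(dataset, config, opts)
  pred_path <- file.path(out_dir, "predictions.tsv")
  writePredictions(scored, pred_path, top_n = top_n)
  report <- NULL
  paths <- list(predictions = pred_path)
  if (protocol != "none") {
    report <- if (protocol == "loocv") loocv(dataset, config, opts)
              else kfoldCv(dataset, k = k, config = config, opts = opts)
    paths$report <- file.path(out_dir, "report.json")
    writeEvaluationReport(report, paths$report)
    paths$roc <- file.path(out_dir, "roc.csv")
    utils::write.csv(report@rocPoints, paths$roc, row.names = FALSE)
  }
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(config = unclass(config), options = unclass(opts),
         protocol = protocol,
         n_diseases = length(diseaseIds(dataset$assoc)),
         n_metabolites = length(metaboliteIds(dataset$assoc)),
         n_positives = sum(assocMatrix(dataset$assoc)),
         package_version = as.character(utils::packageVersion("mdaBoost")),
         r_version = R.version.string),
    paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scored = scored, report = report, paths = paths))
}

#' Train on the full data and score every pair
#'
#' @inheritParams runPipeline
#' @return A scored [PairFeatureTable-class] covering every (disease,
#'   metabolite) pair.
#' @export
scoreDataset <- function(dataset, config = modelConfig(),
                         opts = pipelineOptions()) {
  M <- assocMatrix(dataset$assoc)
  fs <- buildFeatureSet(dataset, opts, seed = config$seed)
  posidx <- which(M == 1, arr.ind = TRUE)
  pos <- data.frame(disease_id = rownames(M)[posidx[, 1]],
                    metabolite_id = colnames(M)[posidx[, 2]])
  neg <- sampleNegatives(dataset$assoc, ratio = config$negative_ratio,
                         seed = .deriveSeed(config$seed, 2L))
  train <- rbind(cbind(pos, label = 1), cbind(neg, label = 0))
  all_pairs <- expand.grid(disease_id = rownames(M),
                           metabolite_id = colnames(M),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_pairs$label <- as.numeric(M[cbind(all_pairs$disease_id,
                                        all_pairs$metabolite_id)])
  pairs <- rbind(train, all_pairs)
  tab <- assembleAndReduce(pairs, fs$f1, fs$f2, fs$f3,
                           variance_kept = opts$variance_kept,
                           train = seq_len(nrow(train)))
  scorer <- trainScorer(.subsetPairs(tab, seq_len(nrow(train))), config)
  scoreAllPairs(scorer, .subsetPairs(tab, nrow(train) + seq_len(nrow(all_pairs))))
}

#' Write an evaluation report as JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(
    list(protocol = report@protocol,
         auc = report@auc,
         precision = report@precision,
         recall = report@recall,
         f1 = report@f1,
         per_fold_auc = report@perFoldAuc,
         top_k_hits = as.list(report@topKHits),
         seed = report@seed,
         leakage_max_masked_value =
           if (nrow(report@audit)) max(report@audit$masked_in_features) else 0),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Rank candidate metabolites for one disease
#'
#' Scores every pair, then returns the `top_n` highest-scored unconfirmed
#' metabolites of `disease_id`; the disease's known metabolites are returned
#' separately.
#'
#' @param dataset an [mdaDataset()].
#' @param disease_id disease label; unknown labels raise an error listing
#'   the closest matches.
#' @param top_n candidates to return (default 10).
#' @param scored optional pre-scored [PairFeatureTable-class] from
#'   [scoreDataset()] to avoid re-training.
#' @inheritParams runPipeline
#' @return List with data.frame `candidates` (rank, metabolite_id, score)
#'   and character vector `known`.
#' @export
rankForDisease <- function(dataset, disease_id, top_n = 10,
                           config = modelConfig(), opts = pipelineOptions(),
                           scored = NULL) {
  dids <- diseaseIds(dataset$assoc)
  if (!disease_id %in% dids) {
    near <- utils::head(dids[order(utils::adist(disease_id, dids))], 3)
    stop("unknown disease id '", disease_id, "'; closest labels: ",
         paste(near, collapse = ", "))
  }
  if (is.null(scored)) scored <- scoreDataset(dataset, config, opts)
  p <- pairInfo(scored)
  sc <- pairScores(scored)
  in_d <- p$disease_id == disease_id
  known <- p$metabolite_id[in_d & p$label == 1]
  cand <- which(in_d & p$label == 0)
  if (!length(cand)) {
    message("disease ", disease_id, " has no unconfirmed metabolites")
    return(list(candidates = data.frame(rank = integer(0),
                                        metabolite_id = character(0),
                                        score = numeric(0)),
                known = known))
  }
  o <- cand[order(-sc[cand], .lexRank(p$metabolite_id[cand]))]
  o <- utils::head(o, top_n)
  list(candidates = data.frame(rank = seq_along(o),
                               metabolite_id = p$metabolite_id[o],
                               score = sc[o]),
       known = known)
}

#' Hyperparameter grid sweep
#'
#' Evaluates the k-fold AUC over a small grid of classifier settings,
#' mirroring the shape of a one- or two-parameter sensitivity sweep.
#'
#' @param dataset an [mdaDataset()].
#' @param grid data.frame whose columns name [modelConfig()] arguments; one
#'   row per setting.
#' @param k folds per evaluation (default 5).
#' @inheritParams runPipeline
#' @return `grid` with an `auc` column appended.
#' @export
gridSearch <- function(dataset, grid, k = 5, config = modelConfig(),
                       opts = pipelineOptions()) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, setdiff(names(grid), "auc"), drop = FALSE])
    cfg <- do.call(modelConfig, utils::modifyList(unclass(config), args))
    kfoldCv(dataset, k = k, config = cfg, opts = opts)@auc
  }, numeric(1))
  grid
}
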