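#' Classifier configuration
#'
#' Hyperparameters of the gradient-boosted pair classifier. The defaults are
#' the tuned operating point of the method: 300 trees of depth at most 7
#' with at most 15 leaves, 45 histogram bins, a minimum of 51 samples per
#' leaf and learning rate 0.1. Training positives are balanced 1:1 against
#' negatives sampled from the unknown pairs by default.
#'
#' @param n_estimators number of boosting rounds (default 300).
#' @param max_depth maximum tree depth (default 7).
#' @param num_leaves maximum leaves per tree (default 15); must satisfy
#'   `num_leaves <= 2^max_depth`.
#' @param max_bin histogram bin budget per feature (default 45).
#' @param min_data_in_leaf minimum samples per leaf (default 51); enforced
#'   exactly as a count through the backend's hessian bound under the
#'   least-squares boosting objective (unit hessian per instance).
#' @param learning_rate shrinkage per round (default 0.1).
#' @param negative_ratio negatives sampled per positive (default 1).
#' @param seed integer seed for negative sampling and training.
#' @return A validated list of class `"ModelConfig"`.
#' @export
modelConfig <- function(n_estimators = 300, max_depth = 7, num_leaves = 15,
                        max_bin = 45, min_data_in_leaf = 51,
                        learning_rate = 0.1, negative_ratio = 1, seed = 1) {
  cfg <- list(n_estimators = as.integer(n_estimators),
              max_depth = as.integer(max_depth),
              num_leaves = as.integer(num_leaves),
              max_bin = as.integer(max_bin),
              min_data_in_leaf = as.integer(min_data_in_leaf),
              learning_rate = learning_rate,
              negative_ratio = negative_ratio,
              seed = as.integer(seed))
  stopifnot(cfg$n_estimators > 0, cfg$max_depth > 0, cfg$num_leaves > 1,
            cfg$max_bin > 1, cfg$min_data_in_leaf > 0, cfg$learning_rate > 0,
            cfg$negative_ratio > 0)
  if (cfg$num_leaves > 2^cfg$max_depth)
    stop("num_leaves must not exceed 2^max_depth")
  class(cfg) <- "ModelConfig"
  cfg
}

#' Read a classifier configuration from a JSON file
#'
#' The file holds a flat JSON object whose keys mirror the [modelConfig()]
#' arguments; keys not present keep their defaults, and `overrides` (e.g.
#' command-line flags) take precedence over the file.
#'
#' @param path path to a JSON config file.
#' @param overrides named list of settings that win over the file.
#' @return A validated `"ModelConfig"`.
#' @export
readModelConfig <- function(path, overrides = list()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(modelConfig))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown model config key(s): ", paste(bad, collapse = ", "))
  do.call(modelConfig, utils::modifyList(as.list(cfg), overrides))
}

#' Sample negative (unknown) pairs
#'
#' Draws `ceiling(ratio * n_positives)` zero-entry pairs uniformly without
#' replacement from the association matrix, never touching known positives
#' or the pairs in `exclude` (e.g. held-out test positives, which must not
#' become training negatives). Deterministic per seed.
#'
#' @param m an [AssociationMatrix-class].
#' @param ratio negatives per known positive (default 1).
#' @param seed integer seed.
#' @param exclude optional data.frame with `disease_id`, `metabolite_id`
#'   columns of pairs to keep out of the sample.
#' @return data.frame with columns `disease_id`, `metabolite_id`.
#' @export
sampleNegatives <- function(m, ratio = 1, seed = 1, exclude = NULL) {
  stopifnot(is(m, "AssociationMatrix"), ratio > 0)
  A <- assocMatrix(m)
  npos <- sum(A)
  want <- ceiling(ratio * npos)
  zeros <- which(A == 0)
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- (match(exclude$metabolite_id, colnames(A)) - 1L) * nrow(A) +
      match(exclude$disease_id, rownames(A))
    zeros <- setdiff(zeros, ex)
  }
  if (want > length(zeros))
    stop("requested ", want, " negatives but only ", length(zeros),
         " unknown pairs are available")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  pick <- zeros[sample.int(length(zeros), want)]
  ri <- (pick - 1L) %% nrow(A) + 1L
  ci <- (pick - 1L) %/% nrow(A) + 1L
  o <- order(ri, ci)
  data.frame(disease_id = rownames(A)[ri][o],
             metabolite_id = colnames(A)[ci][o])
}

#' Train the gradient-boosted pair classifier
#'
#' Fits a gradient-boosted tree ensemble (histogram splitting, leaf-wise
#' growth) on the reduced features of a [PairFeatureTable-class],
#' single-threaded and seeded so training is deterministic. Least-squares
#' boosting on the 0/1 labels is used so that the minimum-samples-per-leaf
#' constraint is enforced as an exact count (the squared-error hessian is 1
#' per instance); predictions are clipped to [0, 1].
#'
#' @param features a [PairFeatureTable-class] whose `reduced` (or, if
#'   absent, `raw`) features and `label` column define the training set.
#' @param config a [modelConfig()].
#' @return An object of class `"mdaScorer"` wrapping the fitted booster and
#'   the expected feature width.
#' @export
trainScorer <- function(features, config = modelConfig()) {
  stopifnot(is(features, "PairFeatureTable"), inherits(config, "ModelConfig"))
  X <- .featureInput(features)
  y <- pairInfo(features)$label
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; cannot fit a classifier")
  params <- list(objective = "reg:squarederror",
                 base_score = 0.5,
                 tree_method = "hist",
                 grow_policy = "lossguide",
                 max_depth = config$max_depth,
                 max_leaves = config$num_leaves,
                 max_bin = config$max_bin,
                 min_child_weight = config$min_data_in_leaf,
                 eta = config$learning_rate,
                 nthread = 1,
                 seed = config$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_estimators, verbose = 0)
  structure(list(booster = booster, n_features = ncol(X), config = config),
            class = "mdaScorer")
}

.featureInput <- function(features) {
  X <- reducedFeatures(features)
  if (!ncol(X)) X <- rawFeatures(features)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Score every pair of a feature table
#'
#' Applies a fitted scorer to all pairs, returning the table with the
#' `score` slot filled and a `known_flag` column marking the known training
#' positives.
#'
#' @param scorer a fitted `"mdaScorer"` from [trainScorer()].
#' @param features a [PairFeatureTable-class] with the same feature width as
#'   at training time.
#' @return The scored [PairFeatureTable-class].
#' @export
scoreAllPairs <- function(scorer, features) {
  stopifnot(inherits(scorer, "mdaScorer"), is(features, "PairFeatureTable"))
  X <- .featureInput(features)
  if (ncol(X) != scorer$n_features)
    stop("feature width mismatch: scorer expects ", scorer$n_features,
         " features, got ", ncol(X))
  sc <- predict(scorer$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  sc <- pmin(pmax(sc, 0), 1)
  p <- pairInfo(features)
  p$known_flag <- as.integer(p$label == 1)
  PairFeatureTable(p, rawFeatures(features), reducedFeatures(features),
                   score = as.numeric(sc))
}
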