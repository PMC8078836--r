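#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, ties counted 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary label vector (1 = positive).
#' @return AUC in [0, 1].
#' @export
rankAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)                      # mid-ranks handle ties as 1/2
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' (fpr, tpr) points of the empirical ROC curve, sweeping the threshold
#' through the distinct score values from high to low; tied scores move as
#' one block. Starts at (0, 0) and ends at (1, 1), nondecreasing in both
#' coordinates.
#'
#' @inheritParams rankAuc
#' @return data.frame with columns `fpr` and `tpr`.
#' @export
rocPoints <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  block_end <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie block
  tp <- cumsum(lab == 1)[block_end]
  fp <- cumsum(lab == 0)[block_end]
  data.frame(fpr = c(0, fp / max(sum(labels == 0), 1)),
             tpr = c(0, tp / max(sum(labels == 1), 1)))
}

#' Precision, recall and F1 at a score threshold
#'
#' Confusion-matrix metrics with predicted positive defined as
#' `score >= threshold`. When nothing is predicted positive, precision is
#' reported as 0 (with a message).
#'
#' @inheritParams rankAuc
#' @param threshold classification threshold (default 0.5).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precisionRecallF1 <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp + fp == 0L) {
    message("no predicted positives at threshold ", threshold,
            "; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Top-k hit counts from held-out ranks
#'
#' Number of held-out positives whose rank within their candidate list is at
#' most k, for each k. Nondecreasing in k and bounded by the number of
#' positives.
#'
#' @param ranks integer vector of per-positive ranks.
#' @param ks integer vector of cutoffs.
#' @return Named numeric vector, one entry per k.
#' @export
topKHits <- function(ranks, ks = c(50, 100, 200, 400)) {
  stats::setNames(vapply(ks, function(k) sum(ranks <= k), numeric(1)),
                  as.character(ks))
}

# ---- cross-validation protocols ------------------------------------------

#' Leave-one-out cross-validation over the known associations
#'
#' Each known (disease, metabolite) pair is held out in turn: its entry is
#' zeroed in the association matrix, every association-derived quantity (GIP
#' kernels, integrated similarities, statistical counts, threshold graphs,
#' NMF factors) is recomputed on the masked matrix, the classifier is
#' retrained on the remaining positives plus freshly sampled negatives, and
#' the held-out pair is scored against all unconfirmed metabolites of its
#' disease. Per-fold ranks are pooled into one ROC/AUC; ranks also feed the
#' top-k hit counts. Per-fold leakage assertions (the masked entry's value
#' in the feature inputs) are recorded in the report's `audit` slot.
#'
#' @param dataset an [mdaDataset()].
#' @param config a [modelConfig()].
#' @param opts a [pipelineOptions()].
#' @param ks top-k cutoffs for the hit counts.
#' @param progress print a fold counter every 50 folds (default `FALSE`).
#' @return An [EvaluationReport-class] with `protocol = "loocv"`.
#' @export
loocv <- function(dataset, config = modelConfig(), opts = pipelineOptions(),
                  ks = c(50, 100, 200, 400), progress = FALSE) {
  M <- assocMatrix(dataset$assoc)
  pos <- which(M == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("LOOCV needs at least 2 known associations")
  static <- .staticSimilarities(dataset, opts)
  pooled <- list(scores = numeric(0), labels = numeric(0), ranks = integer(0))
  audit <- vector("list", nrow(pos))
  for (f in seq_len(nrow(pos))) {
    hold <- data.frame(disease_id = rownames(M)[pos[f, 1]],
                       metabolite_id = colnames(M)[pos[f, 2]])
    fold <- .cvFold(dataset, static, mask = pos[f, , drop = FALSE],
                    test_pos = hold, config = config, opts = opts,
                    fold_id = f)
    pooled <- .poolCandidates(pooled, fold, hold)
    audit[[f]] <- fold$audit
    if (progress && f %% 50 == 0)
      message("loocv fold ", f, "/", nrow(pos))
  }
  .buildReport(pooled$scores, pooled$labels, pooled$ranks, ks,
               protocol = "loocv", per_fold = numeric(0),
               seed = config$seed, audit = do.call(rbind, audit))
}

#' k-fold cross-validation over the known associations
#'
#' The known positives are partitioned into k near-equal folds (sizes
#' differing by at most 1, seeded). For each fold, the fold's positives are
#' masked from the association matrix during feature construction and
#' training, and scored (together with all unconfirmed pairs) by a model
#' trained on the remaining positives. Reports per-fold AUCs and the pooled
#' AUC over concatenated fold scores.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed (default: the model config seed).
#' @return An [EvaluationReport-class] with `protocol = "kfold"`.
#' @export
kfoldCv <- function(dataset, k = 5, config = modelConfig(),
                    opts = pipelineOptions(), seed = config$seed,
                    ks = c(50, 100, 200, 400)) {
  M <- assocMatrix(dataset$assoc)
  pos <- which(M == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (k < 2L) stop("k must be at least 2")
  if (k > npos) stop("k exceeds the number of known associations")
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(.deriveSeed(seed, 104729L))
  assign_fold <- sample(rep(seq_len(k), length.out = npos))
  static <- .staticSimilarities(dataset, opts)
  pooled <- list(scores = numeric(0), labels = numeric(0), ranks = integer(0))
  per_fold <- numeric(k)
  audit <- vector("list", k)
  for (f in seq_len(k)) {
    mask <- pos[assign_fold == f, , drop = FALSE]
    test_pos <- data.frame(disease_id = rownames(M)[mask[, 1]],
                           metabolite_id = colnames(M)[mask[, 2]])
    fold <- .cvFold(dataset, static, mask = mask, test_pos = test_pos,
                    config = config, opts = opts, fold_id = f)
    fold_pool <- .poolCandidates(
      list(scores = numeric(0), labels = numeric(0), ranks = integer(0)),
      fold, test_pos)
    per_fold[f] <- rankAuc(fold_pool$scores, fold_pool$labels)
    pooled$scores <- c(pooled$scores, fold_pool$scores)
    pooled$labels <- c(pooled$labels, fold_pool$labels)
    pooled$ranks <- c(pooled$ranks, fold_pool$ranks)
    audit[[f]] <- fold$audit
  }
  .buildReport(pooled$scores, pooled$labels, pooled$ranks, ks,
               protocol = "kfold", per_fold = per_fold,
               seed = as.integer(seed), audit = do.call(rbind, audit))
}

# Pool each held-out positive against the unconfirmed metabolites of its
# disease: one (score, 1) entry for the positive, one (score, 0) entry per
# candidate, plus the positive's rank in that candidate list (ties resolved
# in the positive's favor). Identical candidate semantics for both
# protocols, so LOOCV and k-fold AUCs are directly comparable.
.poolCandidates <- function(pooled, fold, test_pos) {
  sc <- fold$test_scores
  tdf <- fold$test
  for (i in seq_len(nrow(test_pos))) {
    is_pos <- tdf$label == 1 &
      tdf$disease_id == test_pos$disease_id[i] &
      tdf$metabolite_id == test_pos$metabolite_id[i]
    cand <- tdf$label == 0 & tdf$disease_id == test_pos$disease_id[i]
    s <- sc[is_pos]
    pooled$scores <- c(pooled$scores, s, sc[cand])
    pooled$labels <- c(pooled$labels, 1, rep(0, sum(cand)))
    pooled$ranks <- c(pooled$ranks, 1L + sum(sc[cand] > s))
  }
  pooled
}

.buildReport <- function(scores, labels, ranks, ks, protocol, per_fold,
                         seed, audit) {
  prf <- precisionRecallF1(scores, labels)
  new("EvaluationReport",
      auc = rankAuc(scores, labels),
      precision = unname(prf["precision"]),
      recall = unname(prf["recall"]),
      f1 = unname(prf["f1"]),
      rocPoints = rocPoints(scores, labels),
      perFoldAuc = per_fold,
      topKHits = topKHits(ranks, ks),
      protocol = protocol,
      seed = seed,
      audit = audit)
}

# Similarities that do not depend on the association matrix, computed once.
.staticSimilarities <- function(dataset, opts) {
  list(mhs = metaboliteHammingSimilarity(dataset$pathways),
       dnf = diseaseNmiSimilarity(dataset$symptoms,
                                  diseaseIds(dataset$assoc),
                                  shared_count = opts$shared_count))
}

# One cross-validation fold: mask the test positives, rebuild every
# association-derived feature on the masked matrix, train, score the test
# pairs (test positives + all unconfirmed pairs).
.cvFold <- function(dataset, static, mask, test_pos, config, opts, fold_id) {
  M <- assocMatrix(dataset$assoc)
  Mm <- M
  Mm[mask] <- 0
  am_mask <- AssociationMatrix(Mm)
  fs <- .maskedFeatureSet(am_mask, static, opts,
                          nmf_seed = .deriveSeed(config$seed, fold_id))
  # leakage audit: the masked entries must be zero in the matrix every
  # association-derived feature was computed from
  audit <- data.frame(fold = fold_id,
                      masked_in_features = max(fs$assoc_used[mask]),
                      masked_in_nmf_input = max(fs$nmf_input[mask]),
                      n_masked = nrow(mask))
  train_pos <- data.frame(disease_id = rownames(M)[which(Mm == 1, arr.ind = TRUE)[, 1]],
                          metabolite_id = colnames(M)[which(Mm == 1, arr.ind = TRUE)[, 2]])
  neg <- sampleNegatives(am_mask, ratio = config$negative_ratio,
                         seed = .deriveSeed(config$seed, fold_id + 1000003L),
                         exclude = test_pos)
  train <- rbind(cbind(train_pos, label = 1), cbind(neg, label = 0))
  unknown <- which(M == 0, arr.ind = TRUE)
  test <- rbind(cbind(test_pos, label = 1),
                data.frame(disease_id = rownames(M)[unknown[, 1]],
                           metabolite_id = colnames(M)[unknown[, 2]],
                           label = 0))
  pairs <- rbind(train, test)
  tab <- assembleAndReduce(pairs, fs$f1, fs$f2, fs$f3,
                           variance_kept = opts$variance_kept,
                           train = seq_len(nrow(train)))
  train_tab <- .subsetPairs(tab, seq_len(nrow(train)))
  scorer <- trainScorer(train_tab, config)
  test_tab <- .subsetPairs(tab, nrow(train) + seq_len(nrow(test)))
  scored <- scoreAllPairs(scorer, test_tab)
  list(test = pairInfo(scored), test_scores = pairScores(scored),
       audit = audit)
}

.subsetPairs <- function(tab, idx) {
  PairFeatureTable(pairInfo(tab)[idx, , drop = FALSE],
                   rawFeatures(tab)[idx, , drop = FALSE],
                   reducedFeatures(tab)[idx, , drop = FALSE],
                   score = if (length(pairScores(tab))) pairScores(tab)[idx]
                           else numeric(0))
}

# Full feature set on a (possibly masked) association matrix, reusing the
# association-independent similarities in `static`.
.maskedFeatureSet <- function(am, static, opts, nmf_seed) {
  dgs <- gipSimilarity(am, "disease", opts$omega_prime_d)
  mgs <- gipSimilarity(am, "metabolite", opts$omega_prime_m)
  ids <- integrateSimilarity(static$dnf, dgs)
  ims <- integrateSimilarity(static$mhs, mgs)
  f1 <- statisticalFeatures(am, ids, ims, n_bins = opts$n_bins)
  gd <- buildThresholdGraph(ids, exclude_diagonal = opts$exclude_diagonal)
  gm <- buildThresholdGraph(ims, exclude_diagonal = opts$exclude_diagonal)
  f2 <- list(disease = graphFeatures(gd), metabolite = graphFeatures(gm))
  f3 <- nmfFeatures(am, k = opts$nmf_rank, max_iter = opts$nmf_max_iter,
                    seed = nmf_seed)
  list(f1 = f1, f2 = f2, f3 = f3, ids = ids, ims = ims,
       assoc_used = assocMatrix(am), nmf_input = assocMatrix(am))
}
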