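#' Planted-block generator configuration
#'
#' Configuration of the seeded synthetic dataset generator. Diseases and
#' metabolites are partitioned into `n_blocks` co-association blocks:
#' within-block pairs associate with probability `within_block_assoc_prob`,
#' all other pairs with `background_assoc_prob`. Each block carries a
#' template pathway set and symptom set (with one block-private anchor
#' pathway/symptom, so templates always differ); members copy each template
#' entry with probability `profile_coherence` and draw it at random
#' otherwise. The defaults are the study conditions of the end-to-end
#' checks: 40 diseases x 120 metabolites over 4 blocks with a strong planted
#' signal (0.3 within vs 0.01 background) and coherent profiles (0.9).
#'
#' @param n_diseases,n_metabolites,n_pathways,n_symptoms,n_blocks positive
#'   integers; `n_pathways` and `n_symptoms` must be at least `n_blocks`
#'   (one anchor each per block).
#' @param within_block_assoc_prob,background_assoc_prob association
#'   probabilities in [0, 1]; a planted-signal dataset needs
#'   `within > background` (`within == background` gives the null,
#'   signal-free dataset).
#' @param profile_coherence probability a block member copies its block's
#'   template entry, in [0, 1].
#' @param template_density probability a non-anchor pathway/symptom enters a
#'   block template, and the rate of random (non-copied) entries
#'   (default 0.3).
#' @param seed integer seed.
#' @return A validated list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(n_diseases = 40, n_metabolites = 120,
                            n_pathways = 15, n_symptoms = 25, n_blocks = 4,
                            within_block_assoc_prob = 0.3,
                            background_assoc_prob = 0.01,
                            profile_coherence = 0.9,
                            template_density = 0.3, seed = 7) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_metabolites = as.integer(n_metabolites),
              n_pathways = as.integer(n_pathways),
              n_symptoms = as.integer(n_symptoms),
              n_blocks = as.integer(n_blocks),
              within_block_assoc_prob = within_block_assoc_prob,
              background_assoc_prob = background_assoc_prob,
              profile_coherence = profile_coherence,
              template_density = template_density,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_diseases > 0, n_metabolites > 0, n_pathways > 0,
              n_symptoms > 0, n_blocks > 0,
              n_blocks <= min(n_diseases, n_metabolites),
              n_pathways >= n_blocks, n_symptoms >= n_blocks,
              within_block_assoc_prob >= 0, within_block_assoc_prob <= 1,
              background_assoc_prob >= 0, background_assoc_prob <= 1,
              within_block_assoc_prob >= background_assoc_prob,
              profile_coherence >= 0, profile_coherence <= 1)
  })
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Null (signal-free) variant of a generator configuration
#'
#' Same sizes, but associations are i.i.d. Bernoulli (within-block equals
#' background probability) and profiles are incoherent, so nothing is
#' learnable beyond chance.
#'
#' @param cfg a [generatorConfig()].
#' @param assoc_prob the flat association probability (default 0.05).
#' @return A `"GeneratorConfig"`.
#' @export
nullGeneratorConfig <- function(cfg = generatorConfig(), assoc_prob = 0.05) {
  cfg$within_block_assoc_prob <- assoc_prob
  cfg$background_assoc_prob <- assoc_prob
  cfg$profile_coherence <- 0
  cfg
}

#' Generate a seeded synthetic dataset with planted structure
#'
#' Draws an association matrix, pathway memberships and a symptom catalog
#' under the planted-block model of [generatorConfig()], together with a
#' truth ledger recording block memberships, the templates, and bookkeeping
#' totals (expected/actual positive counts, total symptom count) that tests
#' can check the outputs against.
#'
#' @param cfg a [generatorConfig()].
#' @return List with `dataset` (an [mdaDataset()]) and `ledger`.
#' @examples
#' gen <- generateSyntheticData(generatorConfig(n_diseases = 8,
#'   n_metabolites = 12, n_pathways = 6, n_symptoms = 6, n_blocks = 2))
#' gen$dataset$assoc
#' @export
generateSyntheticData <- function(cfg = generatorConfig()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(cfg$seed)
  dids <- sprintf("d%03d", seq_len(cfg$n_diseases))
  mids <- sprintf("m%03d", seq_len(cfg$n_metabolites))
  pids <- sprintf("p%03d", seq_len(cfg$n_pathways))
  sids <- sprintf("s%03d", seq_len(cfg$n_symptoms))
  dblock <- sort(rep(seq_len(cfg$n_blocks), length.out = cfg$n_diseases))
  mblock <- sort(rep(seq_len(cfg$n_blocks), length.out = cfg$n_metabolites))

  same <- outer(dblock, mblock, `==`)
  prob <- ifelse(same, cfg$within_block_assoc_prob, cfg$background_assoc_prob)
  M <- matrix(stats::rbinom(length(prob), 1, prob), nrow = cfg$n_diseases,
              dimnames = list(dids, mids))

  # block templates over pathways/symptoms; anchor row b belongs to block b only
  pw_template <- .blockTemplates(cfg$n_pathways, cfg$n_blocks,
                                 cfg$template_density)
  sy_template <- .blockTemplates(cfg$n_symptoms, cfg$n_blocks,
                                 cfg$template_density)

  MP <- .coherentProfiles(pw_template, mblock, cfg$profile_coherence,
                          cfg$template_density)
  dimnames(MP) <- list(pids, mids)

  SY <- .coherentProfiles(sy_template, dblock, cfg$profile_coherence,
                          cfg$template_density)
  dimnames(SY) <- list(sids, dids)
  catalog <- stats::setNames(vector("list", cfg$n_diseases), dids)
  for (i in seq_len(cfg$n_diseases)) {
    present <- which(SY[, i] == 1)
    counts <- if (length(present)) 1 + stats::rpois(length(present), 2)
              else numeric(0)
    catalog[[i]] <- stats::setNames(as.numeric(counts), sids[present])
  }

  n_within <- sum(same); n_between <- sum(!same)
  ledger <- list(
    disease_block = stats::setNames(dblock, dids),
    metabolite_block = stats::setNames(mblock, mids),
    pathway_template = pw_template,
    symptom_template = sy_template,
    n_positives = sum(M),
    expected_positives = n_within * cfg$within_block_assoc_prob +
      n_between * cfg$background_assoc_prob,
    sd_positives = sqrt(
      n_within * cfg$within_block_assoc_prob * (1 - cfg$within_block_assoc_prob) +
      n_between * cfg$background_assoc_prob * (1 - cfg$background_assoc_prob)),
    n_memberships = sum(MP),
    membership_colsums = colSums(MP),
    membership_rowsums = rowSums(MP),
    Tn = sum(unlist(catalog)),
    config = cfg)
  list(dataset = mdaDataset(AssociationMatrix(M), PathwayMembership(MP),
                            SymptomCatalog(catalog)),
       ledger = ledger)
}

# one private anchor row per block, remaining rows i.i.d. at `density`
.blockTemplates <- function(n_items, n_blocks, density) {
  tpl <- matrix(stats::rbinom(n_items * n_blocks, 1, density),
                n_items, n_blocks)
  tpl[seq_len(n_blocks), ] <- diag(n_blocks)
  tpl
}

# entity profile: copy the block template entry w.p. coherence, else random
.coherentProfiles <- function(template, block, coherence, density) {
  n_items <- nrow(template)
  out <- matrix(0, n_items, length(block))
  for (j in seq_along(block)) {
    copy <- stats::runif(n_items) < coherence
    rnd <- stats::rbinom(n_items, 1, density)
    out[, j] <- ifelse(copy, template[, block[j]], rnd)
  }
  out
}

#' Write a generated dataset to TSV files
#'
#' Emits the three input tables (associations, pathway memberships, symptom
#' records with counts) plus the truth ledger as JSON, all reloadable with
#' [readMdaDataset()].
#'
#' @param gen output of [generateSyntheticData()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeSyntheticDataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             symptoms = file.path(dir, "symptoms.tsv"),
             ledger = file.path(dir, "ledger.json"))
  writeAssociationPairs(gen$dataset$assoc, paths["associations"])
  MP <- membershipMatrix(gen$dataset$pathways)
  idx <- which(MP == 1, arr.ind = TRUE)
  o <- order(idx[, 2], idx[, 1])
  writeLines(paste(colnames(MP)[idx[o, 2]], rownames(MP)[idx[o, 1]],
                   sep = "\t"), paths["pathways"])
  sc <- gen$dataset$symptoms
  lines <- character(0)
  for (d in diseaseIds(sc)) {
    v <- symptomCounts(sc, d)
    if (length(v))
      lines <- c(lines, paste(d, names(v), as.integer(v), sep = "\t"))
  }
  writeLines(lines, paths["symptoms"])
  led <- gen$ledger
  led$config <- unclass(led$config)
  jsonlite::write_json(led, paths["ledger"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Hard-coded miniature dataset with hand-checkable similarities
#'
#' A fixed 4-disease x 6-metabolite dataset (4 pathways, 5 symptoms) small
#' enough that every similarity matrix can be evaluated by hand. Identical
#' across calls.
#'
#' @return An [mdaDataset()].
#' @export
tinyFixture <- function() {
  dids <- paste0("d", 1:4); mids <- paste0("m", 1:6)
  M <- matrix(c(1, 1, 0, 0, 0, 1,
                1, 0, 1, 0, 0, 0,
                0, 0, 0, 1, 1, 0,
                0, 0, 1, 0, 1, 0),
              4, 6, byrow = TRUE, dimnames = list(dids, mids))
  MP <- matrix(c(1, 1, 0, 0, 0, 0,
                 0, 1, 1, 0, 0, 1,
                 0, 0, 0, 1, 1, 0,
                 1, 0, 0, 0, 1, 1),
               4, 6, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), mids))
  catalog <- list(
    d1 = c(s1 = 2, s2 = 1),
    d2 = c(s1 = 1, s3 = 2),
    d3 = c(s3 = 1, s4 = 2),
    d4 = c(s5 = 1))
  mdaDataset(AssociationMatrix(M), PathwayMembership(MP),
             SymptomCatalog(catalog))
}
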