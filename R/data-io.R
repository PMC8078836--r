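.readTsv <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop("cannot read ", what, ": no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty ", what, " file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_min_cols)
  if (length(bad))
    stop("malformed row in ", what, " file ", path, " at line ", lineno[bad[1]],
         ": expected at least ", n_min_cols, " tab-separated columns")
  list(fields = fields, lineno = lineno)
}

#' Read disease-metabolite association pairs
#'
#' Reads a two-column tab-separated file of (disease_id, metabolite_id) pairs
#' and builds the binary association matrix. Labels are sorted
#' lexicographically (C locale) so the matrix orientation is deterministic
#' across runs; duplicate pairs are collapsed to a single 1 and the number of
#' duplicates is reported via `message()`.
#'
#' @param path path to a UTF-8 TSV file; lines starting with `#` are ignored.
#' @param header logical; skip the first (non-comment) line when `TRUE`.
#' @return An [AssociationMatrix-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("d1\tm1", "d1\tm2", "d2\tm1"), tf)
#' readAssociationPairs(tf)
#' @export
readAssociationPairs <- function(path, header = FALSE) {
  parsed <- .readTsv(path, 2L, "association")
  fields <- parsed$fields
  if (header) {
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("empty association file: ", path)
  }
  d <- vapply(fields, `[[`, character(1), 1L)
  m <- vapply(fields, `[[`, character(1), 2L)
  keys <- paste(d, m, sep = "\r")
  ndup <- sum(duplicated(keys))
  if (ndup > 0)
    message("collapsed ", ndup, " duplicate association pair(s)")
  uniq <- !duplicated(keys)
  d <- d[uniq]; m <- m[uniq]
  dids <- .lexSort(unique(d))
  mids <- .lexSort(unique(m))
  mat <- matrix(0, length(dids), length(mids), dimnames = list(dids, mids))
  mat[cbind(match(d, dids), match(m, mids))] <- 1
  AssociationMatrix(mat)
}

# radix sort is C-locale by construction, so ordering is machine-independent
.lexSort <- function(x) sort(x, method = "radix")

#' Read metabolite-pathway memberships
#'
#' Reads a TSV of (metabolite_id, pathway_id) pairs and builds the binary
#' pathway-by-metabolite membership matrix restricted to (and ordered by)
#' `metabolite_ids`. Metabolites that never occur in the file get an all-zero
#' column, reported via `message()`; rows in the file whose metabolite is not
#' in `metabolite_ids` are dropped.
#'
#' @param path path to the membership TSV.
#' @param metabolite_ids ordered metabolite label registry the columns must
#'   align with (usually `metaboliteIds()` of the association matrix).
#' @param header logical; skip the first line when `TRUE`.
#' @return A [PathwayMembership-class].
#' @export
readPathwayMembership <- function(path, metabolite_ids, header = FALSE) {
  parsed <- .readTsv(path, 2L, "pathway membership")
  fields <- parsed$fields
  if (header) fields <- fields[-1L]
  met <- vapply(fields, `[[`, character(1), 1L)
  pw <- vapply(fields, `[[`, character(1), 2L)
  keep <- met %in% metabolite_ids
  if (!any(keep))
    stop("no overlap between pathway-file metabolites and the metabolite registry")
  met <- met[keep]; pw <- pw[keep]
  pids <- .lexSort(unique(pw))
  mat <- matrix(0, length(pids), length(metabolite_ids),
                dimnames = list(pids, metabolite_ids))
  mat[cbind(match(pw, pids), match(met, metabolite_ids))] <- 1
  orphan <- metabolite_ids[colSums(mat) == 0]
  if (length(orphan))
    message(length(orphan), " metabolite(s) without pathway annotation ",
            "(all-zero column): ", paste(utils::head(orphan, 5), collapse = ", "),
            if (length(orphan) > 5) ", ..." else "")
  PathwayMembership(mat)
}

#' Read a disease-symptom catalog
#'
#' Reads a TSV of (disease_id, symptom_id\[, count\]) records. The optional
#' third column holds a positive integer occurrence count (default 1 when
#' absent). `Tn`, the total number of disease-symptom associations, is the
#' grand total of all counts. Diseases of `disease_ids` missing from the file
#' get empty symptom sets, reported via `message()`.
#'
#' @param path path to the symptom TSV.
#' @param disease_ids ordered disease label registry.
#' @param header logical; skip the first line when `TRUE`.
#' @return A [SymptomCatalog-class].
#' @export
readSymptomCatalog <- function(path, disease_ids, header = FALSE) {
  parsed <- .readTsv(path, 2L, "symptom")
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (header) { fields <- fields[-1L]; lineno <- lineno[-1L] }
  d <- vapply(fields, `[[`, character(1), 1L)
  s <- vapply(fields, `[[`, character(1), 2L)
  cnt <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 3L && nzchar(f[[3L]])) {
      v <- suppressWarnings(as.numeric(f[[3L]]))
      if (is.na(v) || v <= 0 || v != round(v))
        stop("non-positive or non-integer symptom count at line ", lineno[i],
             ": ", f[[3L]])
      v
    } else 1
  }, numeric(1))
  keep <- d %in% disease_ids
  d <- d[keep]; s <- s[keep]; cnt <- cnt[keep]
  catalog <- stats::setNames(vector("list", length(disease_ids)), disease_ids)
  for (i in seq_along(disease_ids)) catalog[[i]] <- numeric(0)
  if (length(d)) {
    agg <- tapply(cnt, list(d, s), sum)  # duplicates of the same record add up
    for (dd in rownames(agg)) {
      v <- stats::setNames(as.numeric(agg[dd, ]), colnames(agg))
      v <- v[!is.na(v)]
      catalog[[dd]] <- v[.lexSort(names(v))]
    }
  }
  empty <- disease_ids[lengths(catalog) == 0L]
  if (length(empty))
    message(length(empty), " disease(s) without symptom records: ",
            paste(utils::head(empty, 5), collapse = ", "),
            if (length(empty) > 5) ", ..." else "")
  SymptomCatalog(catalog)
}

#' Write ranked predictions to a TSV file
#'
#' Rows are sorted by descending score with a deterministic lexicographic
#' tie-break on (disease_id, metabolite_id). Columns: rank, disease_id,
#' metabolite_id, score, known_flag.
#'
#' @param scores a scored [PairFeatureTable-class].
#' @param path output file path.
#' @param top_n number of rows to keep (default: all).
#' @return The output path, invisibly.
#' @export
writePredictions <- function(scores, path, top_n = Inf) {
  stopifnot(is(scores, "PairFeatureTable"))
  sc <- pairScores(scores)
  if (!length(sc)) stop("PairFeatureTable has no scores yet")
  p <- pairInfo(scores)
  known <- if ("known_flag" %in% names(p)) p$known_flag else p$label
  o <- order(-sc, .lexRank(p$disease_id), .lexRank(p$metabolite_id))
  n <- min(length(o), top_n)
  o <- o[seq_len(n)]
  out <- data.frame(rank = seq_len(n),
                    disease_id = p$disease_id[o],
                    metabolite_id = p$metabolite_id[o],
                    score = sprintf("%.10g", sc[o]),
                    known_flag = as.integer(known[o]))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write predictions to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

.lexRank <- function(x) match(x, .lexSort(unique(x)))

#' Re-emit an association matrix as de-duplicated pairs
#'
#' Inverse of [readAssociationPairs()]: writes one (disease_id,
#' metabolite_id) line per 1-entry, in lexicographic order.
#'
#' @param am an [AssociationMatrix-class].
#' @param path output TSV path.
#' @return The output path, invisibly.
#' @export
writeAssociationPairs <- function(am, path) {
  m <- assocMatrix(am)
  idx <- which(m == 1, arr.ind = TRUE)
  d <- rownames(m)[idx[, 1]]
  mt <- colnames(m)[idx[, 2]]
  o <- order(.lexRank(d), .lexRank(mt))
  writeLines(paste(d[o], mt[o], sep = "\t"), path)
  invisible(path)
}
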