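# Delimited-text I/O for associations, ontology edges, matrices and
# rankings. Identifiers are case-preserved but matched case-insensitively
# after whitespace trimming; lines starting with "#" are comments.

.readLinesClean <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.splitFields <- function(lines, lineno, delimiter, minFields, what) {
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < minFields))
    stop(sprintf("malformed %s line %d: fewer than %d fields",
                 what, lineno[which(nf < minFields)[1]], minFields))
  lapply(parts, function(p) trimws(p))
}

.looksLikeHeader <- function(fields, col1, col2) {
  words <- c("lncrna", "lnc", "lncrnaid", "lncrna_id", "disease",
             "diseaseid", "disease_id", "id", "name", "parent", "child")
  key <- gsub("[^a-z]", "", tolower(fields[1:2]))
  if (all(key %in% words)) return(TRUE)
  # non-reoccurring first line: neither field is seen again in its column
  !(tolower(fields[1]) %in% tolower(col1)) &&
    !(tolower(fields[2]) %in% tolower(col2))
}

# registry keyed on lowercase trimmed form; first-seen case is preserved
.registry <- function(raw) {
  key <- tolower(raw)
  first <- !duplicated(key)
  ids <- raw[first]
  idx <- match(key, key[first])
  list(ids = ids, idx = idx)
}

#' Read known lncRNA-disease associations
#'
#' Parses a two-column delimited file of (lncRNA id, disease id) pairs into
#' an \linkS4class{AssociationMatrix}. Duplicate pairs collapse to a single
#' 1; identifiers are ordered by first appearance, matched
#' case-insensitively after trimming, and reported with their first-seen
#' case. Lines starting with \code{#} are skipped.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param header \code{"auto"} (detect a header as a first line whose
#'   fields never reoccur or look like conventional column names),
#'   \code{"none"}, or \code{"present"}.
#' @return An \linkS4class{AssociationMatrix}.
#' @export
readAssociations <- function(path, delimiter = "\t",
                             header = c("auto", "none", "present")) {
  header <- match.arg(header)
  raw <- .readLinesClean(path)
  if (!length(raw$lines)) stop("no associations")
  parts <- .splitFields(raw$lines, raw$lineno, delimiter, 2, "association")
  l <- vapply(parts, `[`, "", 1L)
  d <- vapply(parts, `[`, "", 2L)
  drop1 <- switch(header,
    none = FALSE,
    present = TRUE,
    auto = length(l) > 1 && .looksLikeHeader(c(l[1], d[1]), l[-1], d[-1]))
  if (drop1) { l <- l[-1]; d <- d[-1] }
  if (!length(l)) stop("no associations")
  rl <- .registry(l); rd <- .registry(d)
  m <- matrix(0, length(rl$ids), length(rd$ids))
  m[cbind(rl$idx, rd$idx)] <- 1
  AssociationMatrix(m, lncrnaIds = rl$ids, diseaseIds = rd$ids)
}

#' Write associations as a two-column file
#'
#' Emits one (lncRNA, disease) line per known association, ordered so that
#' re-reading the file reproduces the same identifier registries
#' (first-appearance orders) and matrix.
#'
#' @param x an \linkS4class{AssociationMatrix}.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
writeAssociations <- function(x, path, delimiter = "\t") {
  m <- as.matrix(x)
  idx <- which(m == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  # greedy schedule: a pair may be emitted once its endpoints are already
  # introduced or are the next entity in their registry order, so re-reading
  # reproduces both first-appearance orders
  n <- nrow(idx)
  emitted <- logical(n)
  ord <- integer(0)
  a <- 0L; b <- 0L
  repeat {
    ok <- !emitted & idx[, 1] <= a + 1L & idx[, 2] <= b + 1L
    if (!any(ok)) break
    ord <- c(ord, which(ok))
    emitted[ok] <- TRUE
    a <- max(a, idx[ok, 1]); b <- max(b, idx[ok, 2])
  }
  ord <- c(ord, which(!emitted))  # unreachable for file-derived registries
  writeLines(paste(lncrnaIds(x)[idx[ord, 1]], diseaseIds(x)[idx[ord, 2]],
                   sep = delimiter), path)
  invisible(path)
}

#' Read a disease ontology edge list
#'
#' Each non-comment line is a (parent, child) pair. Edges are deduplicated;
#' self-edges and cycles are rejected.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param header header handling as in \code{\link{readAssociations}}.
#' @return A \linkS4class{DiseaseOntology}; an empty file yields an empty
#'   ontology (all semantic similarities then fall back to the GIP kernel).
#' @export
readDiseaseDag <- function(path, delimiter = "\t",
                           header = c("auto", "none", "present")) {
  header <- match.arg(header)
  raw <- .readLinesClean(path)
  if (!length(raw$lines)) return(DiseaseOntology())
  parts <- .splitFields(raw$lines, raw$lineno, delimiter, 2, "ontology")
  p <- vapply(parts, `[`, "", 1L)
  c_ <- vapply(parts, `[`, "", 2L)
  drop1 <- switch(header,
    none = FALSE,
    present = TRUE,
    auto = length(p) > 1 && all(gsub("[^a-z]", "", tolower(c(p[1], c_[1])))
                                %in% c("parent", "child")))
  if (drop1) { p <- p[-1]; c_ <- c_[-1] }
  if (any(tolower(p) == tolower(c_))) {
    k <- which(tolower(p) == tolower(c_))[1]
    stop(sprintf("self-edge '%s' -> '%s' in ontology", p[k], c_[k]))
  }
  DiseaseOntology(cbind(p, c_))
}

.formatNum <- function(x) sprintf("%.17g", x)

.writeDenseTsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .formatNum(m[i, ])), collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

.readDenseTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write and read dense score matrices
#'
#' Scores round-trip losslessly (17 significant digits) through a dense
#' TSV with row and column identifier headers.
#'
#' @param scores a \linkS4class{ScoreMatrix}.
#' @param path file path.
#' @export
writeScoreMatrix <- function(scores, path) {
  .writeDenseTsv(as.matrix(scores), path)
}

#' @rdname writeScoreMatrix
#' @param stage stage tag to attach on read.
#' @return \code{readScoreMatrix} returns a \linkS4class{ScoreMatrix}.
#' @export
readScoreMatrix <- function(path, stage = "final") {
  m <- .readDenseTsv(path)
  if (stage == "disease_projection")
    ScoreMatrix(m, lncrnaIds = colnames(m), diseaseIds = rownames(m),
                stage = stage)
  else
    ScoreMatrix(m, lncrnaIds = rownames(m), diseaseIds = colnames(m),
                stage = stage)
}

#' Write and read similarity matrices
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param path file path.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  .writeDenseTsv(as.matrix(sim), path)
}

#' @rdname writeSimilarityMatrix
#' @param kind similarity kind tag to attach on read.
#' @return \code{readSimilarityMatrix} returns a
#'   \linkS4class{SimilarityMatrix}.
#' @export
readSimilarityMatrix <- function(path, kind) {
  m <- .readDenseTsv(path)
  SimilarityMatrix(m, entityIds = rownames(m), kind = kind)
}

#' Write a top-k candidate ranking for one disease
#'
#' Candidates (lncRNAs without a known association to the disease) are
#' sorted by descending score, ties broken by lncRNA id; ranks are 1-based.
#' Output columns: disease, lncRNA, rank, score.
#'
#' @param scores a \linkS4class{ScoreMatrix} (stage \code{final} or
#'   \code{primary}).
#' @param ld the \linkS4class{AssociationMatrix} defining known associates
#'   to exclude.
#' @param diseaseId disease to rank candidates for.
#' @param k number of top candidates to write (capped at the candidate
#'   count).
#' @param path output file path.
#' @export
writeRankings <- function(scores, ld, diseaseId, k, path) {
  rk <- rankCandidates(scores, ld, diseaseId, k)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("disease\tlncRNA\trank\tscore", con)
  if (nrow(rk))
    writeLines(paste(diseaseId, rk$lncrna, rk$rank, .formatNum(rk$score),
                     sep = "\t"), con)
  invisible(path)
}
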