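# LOOCV evaluation with pooled rank AUC, novel-lncRNA / isolated-disease
# protocols, the attenuation sweep and top-k candidate ranking.
#
# Pooling: each held-out positive is ranked against its own fold's
# candidate (never-known) pairs; its Mann-Whitney percentile is
# p = (#below + ties/2) / #candidates. The pooled AUC is the
# candidate-count-weighted mean of the percentiles, and the pooled ROC is
# the weighted pointwise average of the per-fold step/ramp curves, whose
# trapezoidal area equals that weighted mean exactly.

.pooledEvalResult <- function(events, provenance) {
  stopifnot(nrow(events) > 0)
  a <- events$nAbove / events$n              # FPR where the fold TPR starts
  b <- (events$nAbove + events$nTie) / events$n
  w <- events$n / sum(events$n)
  p <- 1 - (a + b) / 2                       # per-fold MW percentile
  aucVal <- sum(w * p)
  grid <- sort(unique(c(0, 1, a, b)))
  tprAt <- function(x, left) {
    g <- ifelse(b > a,
                pmin(1, pmax(0, (x - a) / (b - a))),
                as.numeric(if (left) x > a else x >= a))
    sum(w * g)
  }
  xs <- ys <- numeric(0)
  for (x in grid) {
    yl <- tprAt(x, left = TRUE); yr <- tprAt(x, left = FALSE)
    xs <- c(xs, x); ys <- c(ys, yl)
    if (yr > yl + 1e-15) { xs <- c(xs, x); ys <- c(ys, yr) }
  }
  roc <- cbind(FPR = xs, TPR = ys)
  folds <- data.frame(lncrna = events$lncrna, disease = events$disease,
                      rank = events$nAbove + 1 + events$nTie / 2,
                      candidates = events$n,
                      stringsAsFactors = FALSE)
  if (!is.null(events$colRank)) {
    folds$colRank <- events$colRank
    folds$colCandidates <- events$colCandidates
  }
  new("EvalResult", auc = aucVal, roc = roc, folds = folds,
      provenance = provenance)
}

#' ROC curve and AUC from score samples
#'
#' Threshold sweep over the union of observed scores: at each threshold
#' the true/false positive rates are accumulated (ties grouped), the AUC
#' is the trapezoidal area, equivalently the rank-based Mann-Whitney
#' estimate with midranks (ties contribute 1/2).
#'
#' @param positiveScores,negativeScores nonempty numeric vectors.
#' @param provenance optional provenance list stored in the result.
#' @return An \linkS4class{EvalResult} (empty per-fold table).
#' @examples
#' auc(rocAuc(c(0.8, 0.4), c(0.6, 0.2)))  # 0.75
#' @export
rocAuc <- function(positiveScores, negativeScores, provenance = list()) {
  if (!length(positiveScores)) stop("empty positive score list")
  if (!length(negativeScores)) stop("empty negative score list")
  np <- length(positiveScores); nn <- length(negativeScores)
  sc <- c(positiveScores, negativeScores)
  lab <- rep(c(1, 0), c(np, nn))
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; lab <- lab[o]
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # group ties
  tp <- cumsum(lab)[last] / np
  fp <- cumsum(1 - lab)[last] / nn
  roc <- cbind(FPR = c(0, fp), TPR = c(0, tp))
  aucVal <- sum(diff(roc[, 1]) * (roc[-1, 2] + roc[-nrow(roc), 2]) / 2)
  new("EvalResult", auc = aucVal, roc = roc,
      folds = data.frame(lncrna = character(), disease = character(),
                         rank = numeric(), candidates = numeric(),
                         stringsAsFactors = FALSE),
      provenance = provenance)
}

# recompute similarity layers after masking; `touched` is the lncRNA row
# whose disease set changed (functional row update), or NULL for a full
# functional recompute (isolated-disease folds change every set)
.foldLayers <- function(ldm, cache, touched) {
  ddG <- .gipKernel(t(ldm))
  llG <- .gipKernel(ldm)
  if (is.null(touched)) {
    dsets <- lapply(seq_len(nrow(ldm)), function(i) which(ldm[i, ] == 1))
    llFun <- .functionalFromSets(dsets, cache$ddm)
  } else {
    llFun <- cache$llFun
    Di <- which(ldm[touched, ] == 1)
    for (j in seq_len(nrow(ldm))[-touched]) {
      v <- .funcPair(Di, cache$dsets[[j]], cache$ddm)
      llFun[touched, j] <- llFun[j, touched] <- v
    }
  }
  list(llF = ifelse(llFun != 0, llFun, llG),
       ddF = ifelse(cache$ddSem != 0, cache$ddSem, ddG))
}

.evalCache <- function(ld, dag, config) {
  ddSem <- diseaseSemanticSimilarity(dag, diseaseIds(ld), config@decay)
  ddm <- as.matrix(ddSem)
  m <- as.matrix(ld)
  dsets <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1))
  list(ddSem = unname(ddm), ddm = unname(ddm), dsets = dsets,
       llFun = unname(.functionalFromSets(dsets, unname(ddm))))
}

# full-matrix layers used when refoldSimilarities = FALSE (optimistic mode)
.staticLayers <- function(ld, cache) {
  .foldLayers(as.matrix(ld), cache, touched = NULL)
}

#' Leave-one-out cross-validation
#'
#' Masks each known association in turn, recomputes the
#' association-derived similarity layers from the masked matrix (unless
#' \code{refoldSimilarities} is FALSE, an optimistic fast mode), reruns
#' the configured scoring solution, and ranks the held-out positive
#' against the permanent negatives (pairs unknown in the full dataset).
#' Per-fold percentiles are pooled into a weighted rank AUC and ROC; the
#' per-fold rank table also records each positive's rank within its own
#' disease column.
#'
#' @param ld an \linkS4class{AssociationMatrix} with at least two known
#'   associations.
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return An \linkS4class{EvalResult}.
#' @export
loocv <- function(ld, dag, config = pipelineConfig()) {
  m <- as.matrix(ld)
  pos <- which(m == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("LOOCV needs at least two known associations")
  negMask <- m == 0
  cache <- .evalCache(ld, dag, config)
  static <- if (!config@refoldSimilarities) .staticLayers(ld, cache)
  events <- vector("list", nrow(pos))
  for (f in seq_len(nrow(pos))) {
    i <- pos[f, 1]; j <- pos[f, 2]
    ldm <- m; ldm[i, j] <- 0
    lay <- if (config@refoldSimilarities)
      .foldLayers(ldm, cache, touched = i) else static
    S <- .scoreVariant(ldm, lay$llF, lay$ddF, config@K, config@variant)$values
    s <- S[i, j]
    negs <- S[negMask]
    colNegs <- S[negMask[, j], j]
    events[[f]] <- data.frame(
      lncrna = lncrnaIds(ld)[i], disease = diseaseIds(ld)[j],
      nAbove = sum(negs > s), nTie = sum(negs == s), n = length(negs),
      colRank = sum(colNegs > s) + 1 + sum(colNegs == s) / 2,
      colCandidates = length(colNegs), stringsAsFactors = FALSE)
  }
  .pooledEvalResult(do.call(rbind, events),
                    list(protocol = "loocv", variant = config@variant,
                         K = config@K, decay = config@decay))
}

#' Novel-lncRNA and isolated-disease cross-validation
#'
#' Simulates cold-start prediction: every lncRNA (or disease) with at
#' least one known association has its entire row (or column) removed,
#' the similarity layers are recomputed, and each removed association is
#' ranked against the permanent negatives of that row (or column).
#'
#' @param ld an \linkS4class{AssociationMatrix}.
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param mode \code{"new_lncrna"} (zero a row per fold) or
#'   \code{"isolated_disease"} (zero a column per fold).
#' @return An \linkS4class{EvalResult}.
#' @export
novelEntityCv <- function(ld, dag, config = pipelineConfig(),
                          mode = c("new_lncrna", "isolated_disease")) {
  mode <- match.arg(mode)
  m <- as.matrix(ld)
  cache <- .evalCache(ld, dag, config)
  events <- list()
  if (mode == "new_lncrna") {
    for (i in which(rowSums(m) > 0)) {
      ldm <- m; ldm[i, ] <- 0
      lay <- .foldLayers(ldm, cache, touched = i)
      S <- .scoreVariant(ldm, lay$llF, lay$ddF, config@K,
                         config@variant)$values
      if (any(!is.finite(S))) stop("non-finite scores in novel-lncRNA fold")
      negs <- S[i, m[i, ] == 0]
      for (j in which(m[i, ] == 1)) {
        s <- S[i, j]
        events[[length(events) + 1L]] <- data.frame(
          lncrna = lncrnaIds(ld)[i], disease = diseaseIds(ld)[j],
          nAbove = sum(negs > s), nTie = sum(negs == s), n = length(negs),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    for (j in which(colSums(m) > 0)) {
      ldm <- m; ldm[, j] <- 0
      lay <- .foldLayers(ldm, cache, touched = NULL)
      S <- .scoreVariant(ldm, lay$llF, lay$ddF, config@K,
                         config@variant)$values
      if (any(!is.finite(S)))
        stop("non-finite scores in isolated-disease fold")
      negs <- S[m[, j] == 0, j]
      for (i in which(m[, j] == 1)) {
        s <- S[i, j]
        events[[length(events) + 1L]] <- data.frame(
          lncrna = lncrnaIds(ld)[i], disease = diseaseIds(ld)[j],
          nAbove = sum(negs > s), nTie = sum(negs == s), n = length(negs),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(events)) stop("no associations to hold out")
  .pooledEvalResult(do.call(rbind, events),
                    list(protocol = mode, variant = config@variant,
                         K = config@K, decay = config@decay))
}

#' Sweep the attenuation scale factor K
#'
#' Runs one LOOCV per grid value and tabulates the AUCs; the default grid
#' is 0.1 to 0.9 in steps of 0.1.
#'
#' @param ld an \linkS4class{AssociationMatrix}.
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param config a \linkS4class{PipelineConfig} (its K is overridden).
#' @param grid numeric vector of K values in (0,1).
#' @return data.frame with columns \code{K} and \code{auc}; the argmax K
#'   is attached as attribute \code{bestK}.
#' @export
sweepK <- function(ld, dag, config = pipelineConfig(),
                   grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(all(grid > 0 & grid < 1))
  aucs <- vapply(grid, function(k) {
    cfg <- pipelineConfig(K = k, decay = config@decay,
                          variant = config@variant,
                          refoldSimilarities = config@refoldSimilarities)
    auc(loocv(ld, dag, cfg))
  }, 0)
  out <- data.frame(K = grid, auc = aucs)
  attr(out, "bestK") <- grid[which.max(aucs)]
  out
}

#' Rank candidate lncRNAs for a disease
#'
#' Candidates are the lncRNAs with no known association to the disease,
#' sorted by descending final score; ties are broken by lncRNA id in
#' C-locale lexicographic order so rankings are deterministic. Ranks are
#' 1-based.
#'
#' @param final a \linkS4class{ScoreMatrix} (stage \code{final} or
#'   \code{primary}).
#' @param ld the \linkS4class{AssociationMatrix} defining known
#'   associates.
#' @param diseaseId disease of interest.
#' @param k number of top candidates (capped at the candidate count).
#' @return data.frame with columns \code{lncrna}, \code{rank},
#'   \code{score}.
#' @export
rankCandidates <- function(final, ld, diseaseId, k) {
  stopifnot(k >= 1)
  j <- match(diseaseId, diseaseIds(ld))
  if (is.na(j)) stop(sprintf("unknown disease '%s'", diseaseId))
  if (!identical(lncrnaIds(final), lncrnaIds(ld)) ||
      !identical(diseaseIds(final), diseaseIds(ld)))
    stop("score and association registries differ")
  m <- as.matrix(ld)
  S <- as.matrix(final)
  cand <- which(m[, j] == 0)
  ids <- lncrnaIds(ld)[cand]
  sc <- S[cand, j]
  o <- order(-sc, ids, method = "radix")
  take <- utils::head(o, k)
  data.frame(lncrna = ids[take], rank = seq_along(take),
             score = sc[take], stringsAsFactors = FALSE)
}
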