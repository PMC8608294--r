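#' @rdname accessors
#' @export
setMethod("lncrnaIds", "AssociationMatrix", function(x) x@lncrnaIds)

#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationMatrix", function(x) x@diseaseIds)

#' @rdname accessors
#' @export
setMethod("lncrnaIds", "ScoreMatrix", function(x) x@lncrnaIds)

#' @rdname accessors
#' @export
setMethod("diseaseIds", "ScoreMatrix", function(x) x@diseaseIds)

#' @rdname accessors
#' @export
setMethod("lncrnaIds", "HeterogeneousAdjacency", function(x) x@lncrnaIds)

#' @rdname accessors
#' @export
setMethod("diseaseIds", "HeterogeneousAdjacency", function(x) x@diseaseIds)

#' @rdname accessors
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x) x@entityIds)

#' @rdname accessors
#' @export
setMethod("entityIds", "DiseaseOntology", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("scoreStage", "ScoreMatrix", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("auc", "EvalResult", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("rocPoints", "EvalResult", function(x) x@roc)

#' @rdname accessors
#' @export
setMethod("perFoldRanks", "EvalResult", function(x) x@folds)

#' @rdname accessors
#' @export
setMethod("ontologyEdges", "DiseaseOntology", function(x) x@edges)

#' Matrix views of the containers
#'
#' @param x container object.
#' @param ... unused.
#' @return The underlying numeric matrix (with id dimnames).
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@sim)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@scores)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "HeterogeneousAdjacency", function(x, ...) x@adj)

#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@assoc))

#' @export
setMethod("dim", "SimilarityMatrix", function(x) dim(x@sim))

#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d lncRNAs x %d diseases, %d known associations\n",
              nrow(object@assoc), ncol(object@assoc), sum(object@assoc)))
})

setMethod("show", "DiseaseOntology", function(object) {
  cat(sprintf("DiseaseOntology: %d nodes, %d parent-child edges\n",
              length(object@nodeIds), nrow(object@edges)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d\n", object@kind,
              nrow(object@sim), ncol(object@sim)))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix (stage %s): %d x %d, score range [%.4g, %.4g]\n",
              object@stage, nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
})

setMethod("show", "HeterogeneousAdjacency", function(object) {
  cat(sprintf("HeterogeneousAdjacency: (%d+%d) x (%d+%d)\n",
              object@nl, object@nd, object@nl, object@nd))
})

setMethod("show", "KatzParams", function(object) {
  cat(sprintf("KatzParams: K = %g, lambdaMax = %.6g, beta = %.6g\n",
              object@K, object@lambdaMax, object@beta))
})

setMethod("show", "EvalResult", function(object) {
  p <- object@provenance
  cat(sprintf("EvalResult: AUC = %.4f over %d held-out positives (%s)\n",
              object@auc, nrow(object@folds),
              paste(names(p), unlist(lapply(p, format)), sep = "=",
                    collapse = ", ")))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: variant=%s, K=%g, decay=%g, refold=%s\n",
              object@variant, object@K, object@decay,
              object@refoldSimilarities))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d x %d, %d blocks, density %g/%g, DAG depth %d x branch %d, seed %d\n",
    object@nl, object@nd, object@nBlocks, object@withinDensity,
    object@backgroundDensity, object@dagDepth, object@dagBranching,
    object@seed))
})

setMethod("show", "SemanticContribution", function(object) {
  cat(sprintf("SemanticContribution for '%s': %d ancestors, decay %g\n",
              object@diseaseId, length(object@contributions), object@decay))
})

#' Plot an ROC curve
#'
#' @param x an \linkS4class{EvalResult}.
#' @param y unused.
#' @param ... passed to \code{plot.default}.
#' @export
setMethod("plot", signature(x = "EvalResult", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@roc[, 1], x@roc[, 2], type = "l",
                   xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = sprintf("ROC (AUC = %.4f)", x@auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  })
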