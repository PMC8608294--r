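#' @import methods
NULL

.checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) return(sprintf("duplicated %s identifiers", what))
  if (any(!nzchar(ids))) return(sprintf("empty %s identifier", what))
  NULL
}

#' Boolean lncRNA-disease association matrix
#'
#' Container for the bipartite graph of known lncRNA-disease associations,
#' encoded as an \eqn{nl \times nd} Boolean matrix \eqn{LD} whose element
#' \eqn{ld_{ij}} is 1 when lncRNA \eqn{l_i} is known to relate to disease
#' \eqn{d_j}. Row and column identifier registries keep a stable id/index
#' mapping throughout the pipeline.
#'
#' @slot assoc numeric matrix of 0/1 values, \code{nl} rows (lncRNAs) by
#'   \code{nd} columns (diseases).
#' @slot lncrnaIds character vector of unique lncRNA identifiers (row order).
#' @slot diseaseIds character vector of unique disease identifiers (column
#'   order).
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  representation(assoc = "matrix", lncrnaIds = "character",
                 diseaseIds = "character"))

setValidity("AssociationMatrix", function(object) {
  m <- object@assoc
  if (!is.numeric(m)) return("association matrix must be numeric")
  if (nrow(m) != length(object@lncrnaIds))
    return("row count does not match lncRNA id registry")
  if (ncol(m) != length(object@diseaseIds))
    return("column count does not match disease id registry")
  msg <- c(.checkIds(object@lncrnaIds, "lncRNA"),
           .checkIds(object@diseaseIds, "disease"))
  if (length(msg)) return(msg[1])
  if (any(!(m == 0 | m == 1))) return("matrix elements must all be 0 or 1")
  if (all(m == 0)) return("at least one known association is required")
  TRUE
})

#' Construct an AssociationMatrix
#'
#' @param assoc 0/1 matrix (lncRNAs in rows, diseases in columns).
#' @param lncrnaIds,diseaseIds identifier vectors; default to the matrix
#'   dimnames.
#' @return An \linkS4class{AssociationMatrix}.
#' @examples
#' AssociationMatrix(matrix(c(1, 0, 1, 1), 2, 2),
#'                   lncrnaIds = c("l1", "l2"), diseaseIds = c("d1", "d2"))
#' @export
AssociationMatrix <- function(assoc,
                              lncrnaIds = rownames(assoc),
                              diseaseIds = colnames(assoc)) {
  assoc <- as.matrix(assoc)
  storage.mode(assoc) <- "double"
  if (is.null(lncrnaIds)) lncrnaIds <- paste0("l", seq_len(nrow(assoc)))
  if (is.null(diseaseIds)) diseaseIds <- paste0("d", seq_len(ncol(assoc)))
  dimnames(assoc) <- list(lncrnaIds, diseaseIds)
  new("AssociationMatrix", assoc = assoc,
      lncrnaIds = as.character(lncrnaIds),
      diseaseIds = as.character(diseaseIds))
}

#' Disease ontology as a parent-child edge list
#'
#' Stores the directed acyclic graph (DAG) used for disease semantic
#' similarity: a deduplicated set of (parent, child) edges plus the node
#' registry. Diseases absent from the ontology are tolerated downstream;
#' their semantic similarity falls back to the Gaussian interaction profile
#' kernel during integration.
#'
#' @slot edges two-column character matrix (parent, child), deduplicated.
#' @slot nodeIds character vector, union of all edge endpoints (plus any
#'   isolated nodes declared at construction).
#' @exportClass DiseaseOntology
setClass("DiseaseOntology",
  representation(edges = "matrix", nodeIds = "character"))

setValidity("DiseaseOntology", function(object) {
  e <- object@edges
  if (ncol(e) != 2 && length(e)) return("edges must have two columns")
  if (length(e) && !is.character(e)) return("edges must be character ids")
  if (length(e) && any(e[, 1] == e[, 2])) return("self-edge in ontology")
  bad <- .findCycleNode(e)
  if (!is.na(bad))
    return(sprintf("ontology contains a cycle through node '%s'", bad))
  TRUE
})

# Kahn pruning: returns NA when acyclic, else the id of one node on a cycle.
.findCycleNode <- function(edges) {
  if (!length(edges)) return(NA_character_)
  nodes <- unique(c(edges[, 1], edges[, 2]))
  indeg <- table(factor(edges[, 2], levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  alive <- rep(TRUE, nrow(edges))
  queue <- nodes[indeg == 0L]
  remaining <- length(nodes)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; remaining <- remaining - 1L
    out <- which(alive & edges[, 1] == v)
    for (k in out) {
      alive[k] <- FALSE
      ch <- edges[k, 2]
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (remaining == 0L) NA_character_ else names(indeg)[indeg > 0L][1]
}

#' Construct a DiseaseOntology
#'
#' @param edges two-column matrix or data.frame of (parent, child) ids.
#' @param nodeIds optional extra node ids (isolated ontology terms).
#' @return A \linkS4class{DiseaseOntology}.
#' @export
DiseaseOntology <- function(edges = matrix(character(), 0, 2),
                            nodeIds = character()) {
  edges <- as.matrix(edges)
  if (length(edges)) {
    storage.mode(edges) <- "character"
    edges <- unique(edges)
  } else {
    edges <- matrix(character(), 0, 2)
  }
  colnames(edges) <- c("parent", "child")
  nodeIds <- unique(c(as.character(nodeIds), as.vector(edges)))
  new("DiseaseOntology", edges = edges, nodeIds = nodeIds)
}

.SIM_KINDS <- c("disease_semantic", "lncrna_functional", "disease_gip",
                "lncrna_gip", "disease_final", "lncrna_final")

#' Square symmetric similarity matrix
#'
#' Holds one similarity layer for diseases or lncRNAs: semantic (from the
#' ontology DAG), functional (from shared associated-disease sets), Gaussian
#' interaction profile (GIP), or the integrated "final" layer. All layers
#' are symmetric with entries in [0, 1].
#'
#' @slot sim n-by-n numeric matrix.
#' @slot entityIds ordered identifiers for rows/columns.
#' @slot kind one of \code{disease_semantic}, \code{lncrna_functional},
#'   \code{disease_gip}, \code{lncrna_gip}, \code{disease_final},
#'   \code{lncrna_final}.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(sim = "matrix", entityIds = "character", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@sim
  if (nrow(m) != ncol(m)) return("similarity matrix must be square")
  if (nrow(m) != length(object@entityIds))
    return("dimension does not match entity id registry")
  msg <- .checkIds(object@entityIds, "entity")
  if (!is.null(msg)) return(msg)
  if (!(object@kind %in% .SIM_KINDS))
    return(sprintf("unknown similarity kind '%s'", object@kind))
  if (length(m)) {
    if (max(abs(m - t(m))) > 1e-12) return("matrix not symmetric (1e-12)")
    if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
      return("entries must lie in [0, 1]")
    d <- diag(m)
    if (object@kind == "disease_semantic") {
      # zero diagonal marks a disease absent from the ontology (GIP fallback)
      if (any(d != 0 & abs(d - 1) > 1e-12))
        return("semantic diagonal entries must be 0 (absent) or 1")
    } else if (any(abs(d - 1) > 1e-12)) {
      return("diagonal entries must equal 1")
    }
  }
  TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param sim square numeric matrix.
#' @param entityIds row/column identifiers; default dimnames.
#' @param kind similarity layer tag (see \linkS4class{SimilarityMatrix}).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(sim, entityIds = rownames(sim), kind) {
  sim <- as.matrix(sim)
  storage.mode(sim) <- "double"
  if (is.null(entityIds)) entityIds <- paste0("e", seq_len(nrow(sim)))
  dimnames(sim) <- list(entityIds, entityIds)
  new("SimilarityMatrix", sim = sim, entityIds = as.character(entityIds),
      kind = kind)
}

.SCORE_STAGES <- c("primary", "lncrna_projection", "disease_projection",
                   "final")

#' Real-valued prediction score matrix
#'
#' Scores produced by the KATZ stage (\code{primary}), the two space
#' projections, or their fusion (\code{final}). All stages except
#' \code{disease_projection} are lncRNA-by-disease; the disease projection
#' is stored disease-by-lncRNA so that its transpose aligns with the
#' primary score matrix.
#'
#' @slot scores numeric matrix of finite prediction scores.
#' @slot lncrnaIds,diseaseIds identifier registries.
#' @slot stage one of \code{primary}, \code{lncrna_projection},
#'   \code{disease_projection}, \code{final}.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(scores = "matrix", lncrnaIds = "character",
                 diseaseIds = "character", stage = "character"))

setValidity("ScoreMatrix", function(object) {
  m <- object@scores
  if (!(object@stage %in% .SCORE_STAGES))
    return(sprintf("unknown score stage '%s'", object@stage))
  nl <- length(object@lncrnaIds); nd <- length(object@diseaseIds)
  dims <- if (object@stage == "disease_projection") c(nd, nl) else c(nl, nd)
  if (!all(dim(m) == dims)) return("score matrix dimensions do not match ids")
  if (any(!is.finite(m))) return("scores must be finite")
  TRUE
})

#' Construct a ScoreMatrix
#'
#' @param scores numeric matrix.
#' @param lncrnaIds,diseaseIds identifier vectors.
#' @param stage pipeline stage tag (see \linkS4class{ScoreMatrix}).
#' @return A \linkS4class{ScoreMatrix}.
#' @export
ScoreMatrix <- function(scores, lncrnaIds, diseaseIds, stage = "final") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  dimnames(scores) <- if (stage == "disease_projection")
    list(diseaseIds, lncrnaIds) else list(lncrnaIds, diseaseIds)
  new("ScoreMatrix", scores = scores, lncrnaIds = as.character(lncrnaIds),
      diseaseIds = as.character(diseaseIds), stage = stage)
}

#' Heterogeneous adjacency matrix over lncRNA and disease nodes
#'
#' The \eqn{(nl+nd) \times (nl+nd)} block matrix
#' \eqn{A = [[LL^{(f)}, LD], [LD^T, DD^{(f)}]]} on which walks are counted.
#'
#' @slot adj numeric matrix.
#' @slot nl,nd block dimensions.
#' @slot lncrnaIds,diseaseIds identifier registries.
#' @exportClass HeterogeneousAdjacency
setClass("HeterogeneousAdjacency",
  representation(adj = "matrix", nl = "integer", nd = "integer",
                 lncrnaIds = "character", diseaseIds = "character"))

setValidity("HeterogeneousAdjacency", function(object) {
  n <- object@nl + object@nd
  if (!all(dim(object@adj) == c(n, n)))
    return("adjacency dimension must be (nl+nd) x (nl+nd)")
  if (max(abs(object@adj - t(object@adj))) > 1e-12)
    return("adjacency must be symmetric")
  TRUE
})

#' KATZ attenuation parameters
#'
#' @slot K scale factor in (0,1) applied to the spectral bound.
#' @slot beta attenuation factor, \code{K / lambdaMax}.
#' @slot lambdaMax largest eigenvalue of the (symmetric) adjacency matrix.
#' @exportClass KatzParams
setClass("KatzParams",
  representation(K = "numeric", beta = "numeric", lambdaMax = "numeric"))

setValidity("KatzParams", function(object) {
  if (object@K <= 0 || object@K >= 1) return("K must lie in (0, 1)")
  if (object@beta <= 0) return("beta must be positive")
  if (object@beta * object@lambdaMax >= 1)
    return("beta must be strictly below 1/lambdaMax (series divergence)")
  TRUE
})

#' Evaluation result: ROC curve, AUC and per-fold ranks
#'
#' @slot auc area under the ROC curve in [0,1]; equals the (weighted)
#'   rank-based Mann-Whitney estimate.
#' @slot roc two-column matrix of (FPR, TPR) points from (0,0) to (1,1).
#' @slot folds data.frame with one row per held-out positive: lncRNA id,
#'   disease id, midrank of the positive among its candidate set, candidate
#'   count, and (where applicable) the within-disease-column rank.
#' @slot provenance list with elements such as \code{variant}, \code{K},
#'   \code{decay}, \code{seed}.
#' @exportClass EvalResult
setClass("EvalResult",
  representation(auc = "numeric", roc = "matrix", folds = "data.frame",
                 provenance = "list"))

setValidity("EvalResult", function(object) {
  r <- object@roc
  if (ncol(r) != 2) return("roc must have two columns (FPR, TPR)")
  if (nrow(r) < 2) return("roc needs at least the two endpoints")
  if (any(abs(r[1, ] - c(0, 0)) > 1e-12)) return("roc must start at (0,0)")
  if (any(abs(r[nrow(r), ] - c(1, 1)) > 1e-12))
    return("roc must end at (1,1)")
  if (any(diff(r[, 1]) < -1e-12) || any(diff(r[, 2]) < -1e-12))
    return("roc coordinates must be non-decreasing")
  trap <- sum(diff(r[, 1]) * (r[-1, 2] + r[-nrow(r), 2]) / 2)
  if (abs(trap - object@auc) > 1e-9)
    return("auc does not match the trapezoidal area of the roc points")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    return("auc must lie in [0,1]")
  TRUE
})

#' Pipeline configuration
#'
#' @slot K attenuation scale factor (default 0.1).
#' @slot decay semantic-contribution decay per ontology generation
#'   (default 0.5).
#' @slot variant one of \code{"SP"}, \code{"KATZ"}, \code{"SPKATZ"},
#'   \code{"KATZSP"}.
#' @slot refoldSimilarities logical; recompute association-derived
#'   similarities inside each cross-validation fold (default TRUE).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(K = "numeric", decay = "numeric", variant = "character",
                 refoldSimilarities = "logical"))

.VARIANTS <- c("SP", "KATZ", "SPKATZ", "KATZSP")

setValidity("PipelineConfig", function(object) {
  if (!(object@variant %in% .VARIANTS))
    return(sprintf("variant must be one of %s",
                   paste(.VARIANTS, collapse = ", ")))
  if (object@K <= 0 || object@K >= 1) return("K must lie in (0, 1)")
  if (object@decay <= 0 || object@decay >= 1)
    return("decay must lie in (0, 1)")
  TRUE
})

#' Create a pipeline configuration
#'
#' @param K attenuation scale factor in (0,1); \code{beta = K / lambdaMax}.
#' @param decay semantic decay in (0,1).
#' @param variant scoring solution: \code{"KATZSP"} (KATZ then space
#'   projection, the default), \code{"KATZ"}, \code{"SP"}, or
#'   \code{"SPKATZ"}.
#' @param refoldSimilarities recompute LD-derived similarities per fold.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(K = 0.1, decay = 0.5, variant = "KATZSP",
                           refoldSimilarities = TRUE) {
  new("PipelineConfig", K = K, decay = decay, variant = variant,
      refoldSimilarities = refoldSimilarities)
}

#' Synthetic benchmark configuration
#'
#' Planted-block generator settings. The defaults describe the benchmark
#' condition used throughout the package's tests: 40 lncRNAs by 50
#' diseases, 4 aligned blocks, within-block association density 0.5 over a
#' background of 0.005, and a block-structured disease DAG.
#'
#' @slot nl,nd numbers of lncRNAs and diseases.
#' @slot nBlocks number of aligned (lncRNA group, disease group) blocks.
#' @slot withinDensity association probability inside a planted block.
#' @slot backgroundDensity association probability elsewhere.
#' @slot dagDepth,dagBranching shape of each block's ontology subtree.
#' @slot seed integer root seed; all generator stages derive substreams
#'   from it.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nl = "integer", nd = "integer", nBlocks = "integer",
                 withinDensity = "numeric", backgroundDensity = "numeric",
                 dagDepth = "integer", dagBranching = "integer",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nl < 1 || object@nd < 1) return("nl and nd must be positive")
  if (object@nBlocks < 1) return("nBlocks must be positive")
  if (object@nl < object@nBlocks || object@nd < object@nBlocks)
    return("nl and nd must be at least nBlocks")
  if (object@withinDensity <= 0 || object@withinDensity > 1)
    return("withinDensity must lie in (0, 1]")
  if (object@backgroundDensity < 0 || object@backgroundDensity >= 1)
    return("backgroundDensity must lie in [0, 1)")
  if (object@withinDensity < object@backgroundDensity)
    return("withinDensity must be at least backgroundDensity")
  if (object@dagDepth < 1 || object@dagBranching < 1)
    return("dagDepth and dagBranching must be positive")
  TRUE
})

#' Create a synthetic benchmark configuration
#'
#' @param nl,nd matrix dimensions (lncRNAs, diseases).
#' @param nBlocks number of planted blocks.
#' @param withinDensity,backgroundDensity association probabilities inside
#'   and outside blocks; equal values give a signal-free null benchmark.
#' @param dagDepth,dagBranching disease DAG shape; depth 1 yields a star.
#' @param seed root seed for all generator substreams.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nl = 40, nd = 50, nBlocks = 4,
                            withinDensity = 0.5, backgroundDensity = 0.005,
                            dagDepth = 3, dagBranching = 3, seed = 1) {
  new("SyntheticConfig", nl = as.integer(nl), nd = as.integer(nd),
      nBlocks = as.integer(nBlocks), withinDensity = withinDensity,
      backgroundDensity = backgroundDensity, dagDepth = as.integer(dagDepth),
      dagBranching = as.integer(dagBranching), seed = as.integer(seed))
}

#' Per-disease semantic contribution vector
#'
#' Contributions \eqn{D_{d_i}(d_t)} of each ancestor \eqn{d_t} (including
#' \eqn{d_i} itself) to the semantics of disease \eqn{d_i}, decaying by a
#' factor per generation with the max rule over children.
#'
#' @slot diseaseId the DAG node whose semantics are described.
#' @slot contributions named numeric vector over the ancestor closure.
#' @slot decay decay factor used.
#' @exportClass SemanticContribution
setClass("SemanticContribution",
  representation(diseaseId = "character", contributions = "numeric",
                 decay = "numeric"))

setValidity("SemanticContribution", function(object) {
  ct <- object@contributions
  if (is.null(names(ct))) return("contributions must be named")
  if (abs(ct[object@diseaseId] - 1) > 1e-12)
    return("self contribution must equal 1")
  strict <- ct[setdiff(names(ct), object@diseaseId)]
  if (length(strict) && any(strict > object@decay + 1e-12))
    return("a strict ancestor's contribution cannot exceed the decay")
  if (any(ct <= 0)) return("contributions must be positive")
  TRUE
})
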