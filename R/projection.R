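# Similarity-space projection refinement and the pipeline orchestrator
# with its four scoring solutions (SP, KATZ, SPKATZ, KATZSP).

.projectL <- function(L, P) {
  norms <- sqrt(colSums(P^2))
  out <- L %*% P
  nz <- norms > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, norms[nz], "/")
  out[, !nz] <- 0
  out
}

.projectD <- function(D, P) {
  norms <- sqrt(rowSums(P^2))
  out <- P %*% D  # (i,j) = LD^p(i,:) . DD^f(j,:) by symmetry of D
  nz <- norms > 0
  out[nz, ] <- sweep(out[nz, , drop = FALSE], 1, norms[nz], "/")
  out[!nz, ] <- 0
  t(out)
}

#' Project the primary scores onto the lncRNA similarity space
#'
#' Each refined score is the lncRNA similarity row projected onto the
#' corresponding primary score column, normalized by that column's 2-norm:
#' \eqn{ld^{pl}_{ij} = LL^{(f)}(i,:) \cdot LD^{(p)}(:,j) /
#' \|LD^{(p)}(:,j)\|}. Columns with zero norm yield zero scores.
#'
#' @param llFinal lncRNA \linkS4class{SimilarityMatrix}.
#' @param primary \linkS4class{ScoreMatrix} of primary scores (or the raw
#'   association matrix for the SP solution).
#' @return A \linkS4class{ScoreMatrix} of stage \code{lncrna_projection}.
#' @export
projectLncrnaSpace <- function(llFinal, primary) {
  P <- as.matrix(primary)
  L <- as.matrix(llFinal)
  if (ncol(L) != nrow(P)) stop("dimension mismatch in lncRNA projection")
  ScoreMatrix(.projectL(L, P), lncrnaIds = lncrnaIds(primary),
              diseaseIds = diseaseIds(primary),
              stage = "lncrna_projection")
}

#' Project the primary scores onto the disease similarity space
#'
#' \eqn{ld^{pd}_{ij} = DD^{(f)}(j,:) \cdot LD^{(p)}(i,:)^T /
#' \|LD^{(p)}(i,:)\|}; the result is stored disease-by-lncRNA so that its
#' transpose aligns with the primary score matrix. Rows with zero norm
#' yield zero scores.
#'
#' @param ddFinal disease \linkS4class{SimilarityMatrix}.
#' @param primary \linkS4class{ScoreMatrix} of primary scores.
#' @return A \linkS4class{ScoreMatrix} of stage \code{disease_projection}
#'   (dimensions nd x nl).
#' @export
projectDiseaseSpace <- function(ddFinal, primary) {
  P <- as.matrix(primary)
  D <- as.matrix(ddFinal)
  if (nrow(D) != ncol(P)) stop("dimension mismatch in disease projection")
  ScoreMatrix(.projectD(D, P), lncrnaIds = lncrnaIds(primary),
              diseaseIds = diseaseIds(primary),
              stage = "disease_projection")
}

#' Fuse the two space projections
#'
#' Final scores are the arithmetic mean of the lncRNA-space projection and
#' the transposed disease-space projection:
#' \eqn{LD^{(f)} = (LD^{(pl)} + (LD^{(pd)})^T)/2}.
#'
#' @param pl stage \code{lncrna_projection} \linkS4class{ScoreMatrix}
#'   (nl x nd).
#' @param pd stage \code{disease_projection} \linkS4class{ScoreMatrix}
#'   (nd x nl).
#' @return A \linkS4class{ScoreMatrix} of stage \code{final}.
#' @export
fuseProjections <- function(pl, pd) {
  mpl <- as.matrix(pl); mpd <- as.matrix(pd)
  if (!all(dim(mpl) == rev(dim(mpd))))
    stop("projection shapes do not align")
  ScoreMatrix((mpl + t(mpd)) / 2, lncrnaIds = lncrnaIds(pl),
              diseaseIds = diseaseIds(pl), stage = "final")
}

# space-projection scores of an arbitrary nl x nd matrix (matrix in/out)
.spScores <- function(ldm, LLf, DDf) {
  (.projectL(LLf, ldm) + t(.projectD(DDf, ldm))) / 2
}

# variant dispatch on plain matrices; returns list(values, stage)
.scoreVariant <- function(ldm, LLf, DDf, K, variant) {
  katzBlock <- function(off) {
    n <- nrow(off); m <- ncol(off)
    A <- rbind(cbind(LLf, off), cbind(t(off), DDf))
    ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- ev[1]
    if (lam <= 0) stop("largest eigenvalue is not positive")
    beta <- K / lam
    S <- solve(diag(n + m) - beta * A, beta * A)
    S[seq_len(n), n + seq_len(m), drop = FALSE]
  }
  switch(variant,
    KATZ = list(values = katzBlock(ldm), stage = "primary"),
    KATZSP = {
      P <- katzBlock(ldm)
      list(values = .spScores(P, LLf, DDf), stage = "final")
    },
    SP = list(values = .spScores(ldm, LLf, DDf), stage = "final"),
    SPKATZ = {
      sp <- .spScores(ldm, LLf, DDf)
      list(values = katzBlock(sp), stage = "final")
    },
    stop(sprintf("unknown variant '%s'", variant)))
}

# all four similarity layers for an association matrix; semantic layer may
# be passed in pre-computed (it does not depend on the associations)
.similarityLayers <- function(ld, dag, decay, ddSem = NULL) {
  if (is.null(ddSem))
    ddSem <- diseaseSemanticSimilarity(dag, diseaseIds(ld), decay)
  llFun <- lncrnaFunctionalSimilarity(ld, ddSem)
  ddF <- integrateSimilarity(ddSem, gipSimilarity(ld, "disease"))
  llF <- integrateSimilarity(llFun, gipSimilarity(ld, "lncrna"))
  list(ddSem = ddSem, llFun = llFun, llF = llF, ddF = ddF)
}

#' Run the full prediction pipeline
#'
#' Builds all similarity layers from the associations and the ontology,
#' then scores every lncRNA-disease pair with the configured solution:
#' \describe{
#'   \item{KATZSP (default)}{KATZ walk counting on the heterogeneous
#'     adjacency, then space-projection refinement of the primary block.}
#'   \item{KATZ}{primary KATZ block only.}
#'   \item{SP}{space projection applied directly to the Boolean
#'     association matrix.}
#'   \item{SPKATZ}{space-projection scores replace the association block
#'     of the adjacency, then KATZ runs once.}
#' }
#'
#' @param ld an \linkS4class{AssociationMatrix}.
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{ScoreMatrix} (stage \code{final}, or
#'   \code{primary} for the KATZ solution).
#' @examples
#' cfg <- syntheticConfig(nl = 12, nd = 15, nBlocks = 3, seed = 7)
#' dag <- generateDag(cfg)
#' ld <- generateAssociations(cfg, dag)$assoc
#' runPipeline(ld, dag, pipelineConfig())
#' @export
runPipeline <- function(ld, dag, config = pipelineConfig()) {
  sims <- .similarityLayers(ld, dag, config@decay)
  res <- .scoreVariant(as.matrix(ld), as.matrix(sims$llF),
                       as.matrix(sims$ddF), config@K, config@variant)
  ScoreMatrix(res$values, lncrnaIds = lncrnaIds(ld),
              diseaseIds = diseaseIds(ld), stage = res$stage)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: \code{K}, \code{decay}, \code{variant},
#' \code{refold_similarities} (or \code{refoldSimilarities}); missing keys
#' take their defaults.
#'
#' @param path YAML file path.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  refold <- y$refold_similarities
  if (is.null(refold)) refold <- y$refoldSimilarities
  pipelineConfig(
    K = if (is.null(y$K)) 0.1 else as.numeric(y$K),
    decay = if (is.null(y$decay)) 0.5 else as.numeric(y$decay),
    variant = if (is.null(y$variant)) "KATZSP" else as.character(y$variant),
    refoldSimilarities = if (is.null(refold)) TRUE else as.logical(refold))
}
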