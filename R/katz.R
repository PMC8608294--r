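# Walk counting on the heterogeneous network: adjacency assembly,
# attenuation-factor selection against the spectral bound, and the
# closed-form KATZ score (I - beta A)^{-1} - I, evaluated as a linear
# solve so only one factorization is needed.

#' Build the heterogeneous adjacency matrix
#'
#' Assembles \eqn{A = [[LL^{(f)}, LD], [LD^T, DD^{(f)}]]}: the integrated
#' lncRNA similarity, the Boolean association matrix, and the integrated
#' disease similarity as one symmetric \eqn{(nl+nd)^2} matrix.
#'
#' @param llFinal lncRNA \linkS4class{SimilarityMatrix}
#'   (kind \code{lncrna_final}).
#' @param ddFinal disease \linkS4class{SimilarityMatrix}
#'   (kind \code{disease_final}).
#' @param ld an \linkS4class{AssociationMatrix}; may also be a plain
#'   numeric matrix of weighted associations (used by the SPKATZ variant).
#' @return A \linkS4class{HeterogeneousAdjacency}.
#' @export
buildAdjacency <- function(llFinal, ddFinal, ld) {
  ldm <- if (is(ld, "AssociationMatrix")) as.matrix(ld) else as.matrix(ld)
  lids <- if (is(ld, "AssociationMatrix")) lncrnaIds(ld) else rownames(ldm)
  dids <- if (is(ld, "AssociationMatrix")) diseaseIds(ld) else colnames(ldm)
  if (!identical(entityIds(llFinal), lids) ||
      !identical(entityIds(ddFinal), dids))
    stop("identifier registries of similarity layers and associations differ")
  nl <- nrow(ldm); nd <- ncol(ldm)
  A <- rbind(cbind(as.matrix(llFinal), ldm),
             cbind(t(ldm), as.matrix(ddFinal)))
  new("HeterogeneousAdjacency", adj = unname(A), nl = nl, nd = nd,
      lncrnaIds = lids, diseaseIds = dids)
}

#' Select the KATZ attenuation factor
#'
#' Sets \eqn{\beta = K / \lambda_{max}(A)} with \eqn{\lambda_{max}} the
#' largest eigenvalue of the symmetrized adjacency. For the nonnegative
#' symmetric \eqn{A} built here the eigenvalue bound and the spectral-norm
#' bound \eqn{(0, \min\{1, 1/\|A\|_2\})} coincide; the code asserts the
#' agreement and verifies \eqn{\beta} is strictly admissible.
#'
#' @param a a \linkS4class{HeterogeneousAdjacency}.
#' @param K scale factor in (0,1); default 0.1.
#' @return A \linkS4class{KatzParams}.
#' @export
selectBeta <- function(a, K = 0.1) {
  stopifnot(K > 0, K < 1)
  sym <- (a@adj + t(a@adj)) / 2
  ev <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
  lam <- ev[1]
  if (lam <= 0) stop("largest eigenvalue is not positive")
  specNorm <- max(abs(ev))
  stopifnot(abs(lam - specNorm) <= 1e-8 * max(1, specNorm))
  beta <- K / lam
  stopifnot(beta < min(1, 1 / specNorm))
  new("KatzParams", K = K, beta = beta, lambdaMax = lam)
}

#' Closed-form KATZ scores
#'
#' Sums all walks between node pairs with geometric attenuation
#' \eqn{\beta^w} of walks of length \eqn{w}:
#' \eqn{S = \sum_{w \ge 1} \beta^w A^w = (I - \beta A)^{-1} - I},
#' evaluated by solving \eqn{(I - \beta A) S = \beta A}.
#'
#' @param a a \linkS4class{HeterogeneousAdjacency}.
#' @param params a \linkS4class{KatzParams} with
#'   \code{beta < 1/lambdaMax}.
#' @return \eqn{(nl+nd) \times (nl+nd)} numeric matrix of walk scores.
#' @export
katzScores <- function(a, params) {
  A <- a@adj
  n <- nrow(A)
  M <- diag(n) - params@beta * A
  S <- tryCatch(solve(M, params@beta * A), error = function(e)
    stop("(I - beta A) is numerically singular; use a smaller K"))
  S
}

#' Extract the primary prediction block
#'
#' Slices rows \code{1..nl} and columns \code{nl+1..nl+nd} of the KATZ
#' score matrix: the block aligned with the association matrix inside the
#' heterogeneous adjacency, i.e. the primary lncRNA-disease scores.
#'
#' @param sKatz square KATZ score matrix from \code{\link{katzScores}}.
#' @param a the \linkS4class{HeterogeneousAdjacency} it was computed on.
#' @return A \linkS4class{ScoreMatrix} of stage \code{primary}.
#' @export
extractPrimary <- function(sKatz, a) {
  n <- a@nl + a@nd
  if (!all(dim(sKatz) == c(n, n)))
    stop("score matrix dimension does not match the adjacency")
  ScoreMatrix(sKatz[seq_len(a@nl), a@nl + seq_len(a@nd), drop = FALSE],
              lncrnaIds = a@lncrnaIds, diseaseIds = a@diseaseIds,
              stage = "primary")
}
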