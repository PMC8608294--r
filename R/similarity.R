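# Four similarity layers: disease semantic (DAG ancestor contributions),
# lncRNA functional (shared associated-disease sets), Gaussian interaction
# profile kernels for both node types, and the structural-zero-fallback
# integration of matching pairs.

.parentsOf <- function(ont) {
  e <- ont@edges
  split(e[, 1], factor(e[, 2], levels = unique(e[, 2])))
}

.ancestorClosure <- function(parents, id) {
  seen <- id
  frontier <- id
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Semantic contributions of a disease's ancestors
#'
#' Computes the contribution \eqn{D_{d_i}(d_t)} of every ancestor
#' \eqn{d_t} (including \eqn{d_i} itself) to the semantics of disease
#' \eqn{d_i}: the self contribution is 1 and each strict ancestor
#' contributes \code{decay} times the maximum contribution among its
#' children inside the ancestor closure.
#'
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param diseaseId disease whose ancestor closure is evaluated; must be a
#'   node of the DAG.
#' @param decay decay factor per generation in (0,1); default 0.5.
#' @return A \linkS4class{SemanticContribution}.
#' @examples
#' dag <- DiseaseOntology(rbind(c("d1", "d2"), c("d2", "d3")))
#' semanticContributions(dag, "d3")  # d3: 1, d2: 0.5, d1: 0.25
#' @export
semanticContributions <- function(dag, diseaseId, decay = 0.5) {
  stopifnot(decay > 0, decay < 1)
  if (!(diseaseId %in% dag@nodeIds))
    stop(sprintf("disease '%s' is absent from the ontology", diseaseId))
  parents <- .parentsOf(dag)
  closure <- .ancestorClosure(parents, diseaseId)
  contrib <- stats::setNames(rep(0, length(closure)), closure)
  contrib[diseaseId] <- 1
  # relax child -> parent edges within the closure until the max-rule
  # fixpoint; order-invariant because max is associative and decay < 1
  e <- dag@edges
  inC <- e[, 1] %in% closure & e[, 2] %in% closure
  e <- e[inC, , drop = FALSE]
  if (nrow(e)) {
    repeat {
      v <- decay * contrib[e[, 2]]
      upd <- v > contrib[e[, 1]]
      if (!any(upd)) break
      # per-parent max over its updating children
      for (k in which(upd)) {
        p <- e[k, 1]
        if (v[k] > contrib[p]) contrib[p] <- v[k]
      }
    }
  }
  new("SemanticContribution", diseaseId = diseaseId,
      contributions = contrib, decay = decay)
}

#' Disease-disease semantic similarity
#'
#' For diseases \eqn{d_i, d_j} with ancestor closures \eqn{T_i, T_j}, the
#' similarity is the shared-ancestor contribution mass
#' \deqn{dd_{ij} = \frac{\sum_{t \in T_i \cap T_j} (D_i(t) + D_j(t))}
#'   {\sum_{t \in T_i} D_i(t) + \sum_{t \in T_j} D_j(t)}.}
#' Diseases absent from the ontology receive an all-zero row and column
#' (zero diagonal included) so that integration falls back to the GIP
#' kernel for them.
#'
#' @param dag a \linkS4class{DiseaseOntology}.
#' @param diseaseIds ordered disease identifiers for the matrix.
#' @param decay decay factor in (0,1).
#' @return A \linkS4class{SimilarityMatrix} of kind
#'   \code{disease_semantic}.
#' @export
diseaseSemanticSimilarity <- function(dag, diseaseIds, decay = 0.5) {
  n <- length(diseaseIds)
  present <- diseaseIds %in% dag@nodeIds
  contribs <- vector("list", n)
  for (i in which(present))
    contribs[[i]] <- semanticContributions(dag, diseaseIds[i],
                                           decay)@contributions
  totals <- vapply(contribs, function(ct) if (is.null(ct)) 0 else sum(ct), 0)
  dd <- matrix(0, n, n)
  for (i in which(present)) {
    ci <- contribs[[i]]
    dd[i, i] <- 1
    js <- which(present)
    js <- js[js > i]
    for (j in js) {
      cj <- contribs[[j]]
      shared <- intersect(names(ci), names(cj))
      if (length(shared)) {
        v <- sum(ci[shared] + cj[shared]) / (totals[i] + totals[j])
        dd[i, j] <- dd[j, i] <- v
      }
    }
  }
  SimilarityMatrix(dd, entityIds = diseaseIds, kind = "disease_semantic")
}

# best match of each disease in set Di against set Dj, averaged both ways
.funcPair <- function(Di, Dj, dd) {
  k <- length(Di); k2 <- length(Dj)
  if (k == 0L || k2 == 0L) return(0)
  m <- dd[Di, Dj, drop = FALSE]
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (k + k2)
}

.functionalFromSets <- function(dsets, ddm) {
  nl <- length(dsets)
  ll <- diag(1, nl)
  if (nl > 1) {
    for (i in seq_len(nl - 1)) {
      for (j in (i + 1):nl) {
        v <- .funcPair(dsets[[i]], dsets[[j]], ddm)
        ll[i, j] <- ll[j, i] <- v
      }
    }
  }
  ll
}

#' LncRNA-lncRNA functional similarity
#'
#' Two lncRNAs are functionally similar when their associated disease sets
#' are semantically similar: with \eqn{D(l_i)} the diseases linked to
#' \eqn{l_i} and \eqn{S(d, D)} the best semantic match of \eqn{d} within
#' \eqn{D}, the similarity averages the best matches in both directions
#' over \eqn{|D(l_i)| + |D(l_j)|}. An lncRNA with no associations gets 0
#' off-diagonal; diagonals are 1.
#'
#' @param ld an \linkS4class{AssociationMatrix}.
#' @param dd disease \linkS4class{SimilarityMatrix} covering all diseases
#'   of \code{ld} (typically the semantic layer).
#' @return A \linkS4class{SimilarityMatrix} of kind
#'   \code{lncrna_functional}.
#' @export
lncrnaFunctionalSimilarity <- function(ld, dd) {
  if (!all(diseaseIds(ld) %in% entityIds(dd)))
    stop("disease similarity does not cover all diseases of the association matrix")
  ddm <- as.matrix(dd)[diseaseIds(ld), diseaseIds(ld)]
  m <- as.matrix(ld)
  dsets <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1))
  ll <- .functionalFromSets(dsets, ddm)
  SimilarityMatrix(ll, entityIds = lncrnaIds(ld), kind = "lncrna_functional")
}

.gipKernel <- function(profiles) {
  sq <- rowSums(profiles^2)
  if (all(sq == 0)) stop("GIP bandwidth undefined: all profiles are zero")
  gamma <- length(sq) / sum(sq)   # 1 / mean squared profile norm
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  s <- exp(-gamma * d2)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Gaussian interaction profile kernel similarity
#'
#' Similarity between association profiles:
#' \eqn{\exp(-\gamma \|p_i - p_j\|^2)} where the profiles are the columns
#' (diseases) or rows (lncRNAs) of the association matrix and the
#' bandwidth \eqn{\gamma} is the reciprocal of the mean squared profile
#' norm.
#'
#' @param ld an \linkS4class{AssociationMatrix} with at least one known
#'   association.
#' @param axis \code{"disease"} (column profiles) or \code{"lncrna"} (row
#'   profiles).
#' @return A \linkS4class{SimilarityMatrix} of kind \code{disease_gip} or
#'   \code{lncrna_gip}.
#' @export
gipSimilarity <- function(ld, axis = c("disease", "lncrna")) {
  axis <- match.arg(axis)
  m <- as.matrix(ld)
  if (axis == "disease")
    SimilarityMatrix(.gipKernel(t(m)), entityIds = diseaseIds(ld),
                     kind = "disease_gip")
  else
    SimilarityMatrix(.gipKernel(m), entityIds = lncrnaIds(ld),
                     kind = "lncrna_gip")
}

.INTEGRATE_KINDS <- list(
  disease_semantic = c(gip = "disease_gip", final = "disease_final"),
  lncrna_functional = c(gip = "lncrna_gip", final = "lncrna_final"))

#' Integrate a base similarity layer with its GIP layer
#'
#' Element-wise structural fallback: the final similarity equals the base
#' (semantic or functional) value wherever that value is nonzero, and the
#' GIP value otherwise. Zeros in the base layer are structural (no shared
#' ancestry / no associations), so the comparison is exact, not
#' tolerance-based.
#'
#' @param base semantic or functional \linkS4class{SimilarityMatrix}.
#' @param gip the matching GIP \linkS4class{SimilarityMatrix}.
#' @return A \linkS4class{SimilarityMatrix} of kind \code{disease_final}
#'   or \code{lncrna_final}.
#' @export
integrateSimilarity <- function(base, gip) {
  spec <- .INTEGRATE_KINDS[[simKind(base)]]
  if (is.null(spec))
    stop("base must be a semantic or functional similarity matrix")
  if (simKind(gip) != spec[["gip"]])
    stop(sprintf("gip layer must have kind '%s'", spec[["gip"]]))
  if (!identical(entityIds(base), entityIds(gip)))
    stop("entity registries of base and gip layers differ")
  b <- as.matrix(base); g <- as.matrix(gip)
  final <- ifelse(b != 0, b, g)
  SimilarityMatrix(final, entityIds = entityIds(base),
                   kind = spec[["final"]])
}
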