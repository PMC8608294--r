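# Independent oracles and small fixture builders used across the suite.

# brute-force truncated walk sum: sum_{w=1}^{W} beta^w A^w
katzSeriesOracle <- function(A, beta, W = 60) {
  acc <- matrix(0, nrow(A), ncol(A))
  P <- diag(nrow(A))
  for (w in seq_len(W)) {
    P <- P %*% (beta * A)
    acc <- acc + P
  }
  acc
}

# exhaustive concordant-pair AUC with half-credit ties
aucPairOracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# per-fold Mann-Whitney percentiles and weighted pooled AUC from an
# EvalResult's fold table (independent re-derivation of the pooling rule)
pooledAucFromFolds <- function(res) {
  f <- perFoldRanks(res)
  p <- (f$candidates - (f$rank - 1)) / f$candidates
  sum(f$candidates * p) / sum(f$candidates)
}

# deterministic toy: 6 lncRNAs x 6 diseases with 8 known pairs and a
# two-branch ontology
makeToy <- function() {
  pairs <- rbind(c(1, 1), c(1, 2), c(2, 2), c(3, 3), c(4, 4), c(4, 5),
                 c(5, 5), c(6, 6))
  m <- matrix(0, 6, 6)
  m[pairs] <- 1
  ld <- AssociationMatrix(m, paste0("l", 1:6), paste0("d", 1:6))
  dag <- DiseaseOntology(rbind(
    c("root", "d1"), c("d1", "d2"), c("d1", "d3"),
    c("root", "d4"), c("d4", "d5"), c("d4", "d6")))
  list(ld = ld, dag = dag)
}

# random symmetric nonnegative matrix for spectral tests
randomSymmetric <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  (A + t(A)) / 2
}

writeTempLines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
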