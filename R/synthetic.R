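# Planted-block benchmark generator: aligned lncRNA/disease groups with
# dense within-block associations over a sparse background, plus a
# block-structured disease ontology so that same-block diseases share deep
# ancestors. One root seed; each generator stage draws from its own
# derived substream so the stages are independent and reproducible.

# evaluate expr under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-stage substream seeds derived from the root seed
.substreamSeeds <- function(seed) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, 2L))
}

.blockOf <- function(n, nBlocks) {
  ceiling(seq_len(n) / ceiling(n / nBlocks))
}

.syntheticIds <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

.treeDepths <- function(n, branching) {
  depth <- integer(n)
  depth[1] <- 1L
  for (t in seq_len(n)[-1])
    depth[t] <- depth[ceiling((t - 1) / branching)] + 1L
  depth
}

.ancestorAtDepth <- function(t, branching, depth, target) {
  while (depth[t] > target) t <- ceiling((t - 1) / branching)
  t
}

#' Generate a block-structured disease ontology
#'
#' Builds a rooted DAG over the configured diseases: block heads hang off
#' a shared root, and the remaining diseases of each block form a
#' branching tree (branching factor \code{dagBranching}, truncated at
#' \code{dagDepth}) under their head. Same-block diseases therefore share
#' deep ancestors while cross-block pairs share only the shallow root.
#' With \code{dagDepth = 1} the DAG degenerates to a star. The assignment
#' of diseases to tree positions is drawn from a seeded substream, so the
#' edge set is deterministic given the seed.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{DiseaseOntology} over the disease ids plus the
#'   synthetic root \code{"ROOT"}.
#' @export
generateDag <- function(config) {
  dagSeed <- .substreamSeeds(config@seed)[1]
  ids <- .syntheticIds("d", config@nd)
  if (config@dagDepth == 1L)
    return(DiseaseOntology(cbind("ROOT", ids)))
  blocks <- .blockOf(config@nd, config@nBlocks)
  .withSeed(dagSeed, {
    edges <- NULL
    for (b in unique(blocks)) {
      members <- sample(ids[blocks == b])  # random tree placement
      edges <- rbind(edges, c("ROOT", members[1]))
      if (length(members) > 1) {
        # heap-shaped tree: parent of the t-th member is member
        # ceiling((t-1)/branching), re-parented upward past dagDepth
        depth <- .treeDepths(length(members), config@dagBranching)
        for (t in 2:length(members)) {
          p <- if (depth[t] > config@dagDepth)
            .ancestorAtDepth(t, config@dagBranching, depth, config@dagDepth)
          else ceiling((t - 1) / config@dagBranching)
          edges <- rbind(edges, c(members[p], members[t]))
        }
      }
    }
    DiseaseOntology(edges)
  })
}

#' Generate a planted-block association matrix
#'
#' Partitions lncRNAs and diseases into \code{nBlocks} aligned groups and
#' samples each pair independently: probability \code{withinDensity}
#' inside an aligned block, \code{backgroundDensity} elsewhere. Resamples
#' if the draw is empty so the matrix always carries at least one
#' association. Deterministic given the seed.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dag the matching \linkS4class{DiseaseOntology} (checked for
#'   coverage).
#' @return list with \code{assoc} (an \linkS4class{AssociationMatrix}) and
#'   \code{truth} (logical nl x nd matrix marking aligned-block pairs).
#' @export
generateAssociations <- function(config, dag) {
  lids <- .syntheticIds("l", config@nl)
  dids <- .syntheticIds("d", config@nd)
  if (!all(dids %in% entityIds(dag)))
    stop("ontology does not cover the configured diseases")
  lb <- .blockOf(config@nl, config@nBlocks)
  db <- .blockOf(config@nd, config@nBlocks)
  truth <- outer(lb, db, "==")
  prob <- ifelse(truth, config@withinDensity, config@backgroundDensity)
  assocSeed <- .substreamSeeds(config@seed)[2]
  m <- .withSeed(assocSeed, {
    repeat {
      m <- matrix(as.double(stats::runif(length(prob)) < prob),
                  config@nl, config@nd)
      if (any(m == 1)) break
    }
    m
  })
  dimnames(truth) <- list(lids, dids)
  list(assoc = AssociationMatrix(m, lncrnaIds = lids, diseaseIds = dids),
       truth = truth)
}

#' Structure-recovery experiment on a planted benchmark
#'
#' Generates an ontology and association matrix from \code{config}, runs
#' LOOCV for each requested scoring solution, and summarizes: pooled AUC
#' per solution and, for the first solution, the fraction of held-out
#' positives recovered in the top 5 of their disease column.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param pipeline a \linkS4class{PipelineConfig} whose K, decay and
#'   refold settings are applied to every solution.
#' @param variants scoring solutions to evaluate.
#' @return list with \code{table} (data.frame of variant and AUC),
#'   \code{top5Fraction}, and \code{results} (named list of
#'   \linkS4class{EvalResult}).
#' @export
recoveryExperiment <- function(config, pipeline = pipelineConfig(),
                               variants = c("KATZSP", "KATZ", "SPKATZ",
                                            "SP")) {
  dag <- generateDag(config)
  gen <- generateAssociations(config, dag)
  results <- list()
  for (v in variants) {
    cfg <- pipelineConfig(K = pipeline@K, decay = pipeline@decay,
                          variant = v,
                          refoldSimilarities = pipeline@refoldSimilarities)
    results[[v]] <- loocv(gen$assoc, dag, cfg)
  }
  folds <- perFoldRanks(results[[1]])
  list(table = data.frame(variant = variants,
                          auc = unname(vapply(results, auc, 0))),
       top5Fraction = mean(folds$colRank <= 5),
       results = results)
}

#' Write a synthetic benchmark to disk
#'
#' Emits the association list, the ontology edge list and the planted
#' truth mask as TSV files in \code{dir}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the list from \code{\link{generateAssociations}}
#'   plus the \code{dag}.
#' @export
simulateDataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- generateDag(config)
  gen <- generateAssociations(config, dag)
  writeAssociations(gen$assoc, file.path(dir, "associations.tsv"))
  utils::write.table(ontologyEdges(dag), file.path(dir, "dag.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tm <- gen$truth
  utils::write.table(
    data.frame(lncrna = rownames(tm)[row(tm)[tm]],
               disease = colnames(tm)[col(tm)[tm]]),
    file.path(dir, "truth_mask.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(c(gen, list(dag = dag)))
}
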