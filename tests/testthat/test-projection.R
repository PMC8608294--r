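test_that("lncRNA-space projection normalizes by primary column norms", {
  ids <- list(l = c("l1", "l2"), d = c("d1", "d2"))
  primary <- ScoreMatrix(rbind(c(1, 3), c(2, 4)), ids$l, ids$d,
                         stage = "primary")
  I2 <- SimilarityMatrix(diag(2), ids$l, kind = "lncrna_final")
  pl <- as.matrix(projectLncrnaSpace(I2, primary))
  expect_equal(unname(pl),
               sweep(rbind(c(1, 3), c(2, 4)), 2, c(sqrt(5), 5), "/"))

  # hand example: row (1,1) dotted with column (3,4), norm 5 -> 1.4
  ll <- SimilarityMatrix(matrix(1, 2, 2), ids$l, kind = "lncrna_final")
  p2 <- ScoreMatrix(rbind(c(0, 3), c(0, 4)), ids$l, ids$d,
                    stage = "primary")
  expect_equal(as.matrix(projectLncrnaSpace(ll, p2))["l1", "d2"], 1.4)
  # zero-norm column yields a zero output column
  expect_equal(unname(as.matrix(projectLncrnaSpace(ll, p2))[, "d1"]),
               c(0, 0))
})

test_that("disease-space projection normalizes by primary row norms", {
  lids <- "l1"; dids <- paste0("d", 1:3)
  primary <- ScoreMatrix(matrix(c(1, 2, 2), 1, 3), lids, dids,
                         stage = "primary")
  dd <- SimilarityMatrix(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1)),
                         dids, kind = "disease_final")
  pd <- as.matrix(projectDiseaseSpace(dd, primary))
  expect_equal(dim(pd), c(3L, 1L))  # stored disease-by-lncRNA
  # row (1,2,2), similarity row (1,0,1): (1 + 0 + 2) / 3 = 1
  expect_equal(pd["d1", "l1"], 1)

  # identity similarity row-normalizes the primary scores
  I3 <- SimilarityMatrix(diag(3), dids, kind = "disease_final")
  pdI <- as.matrix(projectDiseaseSpace(I3, primary))
  expect_equal(unname(t(pdI)), matrix(c(1, 2, 2) / 3, 1, 3))

  # all-zero primary gives all-zero projections
  p0 <- ScoreMatrix(matrix(0, 1, 3), lids, dids, stage = "primary")
  expect_equal(unname(as.matrix(projectDiseaseSpace(dd, p0))),
               matrix(0, 3, 1))
})

test_that("projections are invariant to positive rescaling of the scores", {
  set.seed(13)
  P <- matrix(runif(12), 3, 4)
  lids <- paste0("l", 1:3); dids <- paste0("d", 1:4)
  sm <- function(m) ScoreMatrix(m, lids, dids, stage = "primary")
  ml <- randomSymmetric(3) / 2; diag(ml) <- 1
  md <- randomSymmetric(4) / 2; diag(md) <- 1
  L <- SimilarityMatrix(ml, lids, kind = "lncrna_final")
  D <- SimilarityMatrix(md, dids, kind = "disease_final")
  for (c_ in c(0.25, 7)) {
    expect_equal(as.matrix(projectLncrnaSpace(L, sm(c_ * P))),
                 as.matrix(projectLncrnaSpace(L, sm(P))), tolerance = 1e-12)
    expect_equal(as.matrix(projectDiseaseSpace(D, sm(c_ * P))),
                 as.matrix(projectDiseaseSpace(D, sm(P))), tolerance = 1e-12)
  }
})

test_that("fusion averages the aligned projections", {
  lids <- c("l1", "l2"); dids <- c("d1", "d2")
  pl <- ScoreMatrix(rbind(c(1.4, 0), c(0, 1)), lids, dids,
                    stage = "lncrna_projection")
  pd <- ScoreMatrix(rbind(c(1.0, 0), c(0, 1)), lids, dids,
                    stage = "disease_projection")
  fused <- as.matrix(fuseProjections(pl, pd))
  expect_equal(fused["l1", "d1"], 1.2)
  expect_equal(fused["l2", "d2"], 1)

  # pl equal to the transposed pd fuses to itself
  pd2 <- ScoreMatrix(t(as.matrix(pl)), lids, dids,
                     stage = "disease_projection")
  expect_equal(as.matrix(fuseProjections(pl, pd2)), as.matrix(pl))

  bad <- ScoreMatrix(matrix(0, 3, 2), c("l1", "l2"), paste0("d", 1:3),
                     stage = "disease_projection")
  expect_error(fuseProjections(pl, bad), "align")
})

test_that("the pipeline variants compose the exported operations", {
  toy <- makeToy()
  cfg <- pipelineConfig()

  dd <- diseaseSemanticSimilarity(toy$dag, diseaseIds(toy$ld), cfg@decay)
  llFun <- lncrnaFunctionalSimilarity(toy$ld, dd)
  ddF <- integrateSimilarity(dd, gipSimilarity(toy$ld, "disease"))
  llF <- integrateSimilarity(llFun, gipSimilarity(toy$ld, "lncrna"))
  a <- buildAdjacency(llF, ddF, toy$ld)
  prim <- extractPrimary(katzScores(a, selectBeta(a, cfg@K)), a)
  manual <- fuseProjections(projectLncrnaSpace(llF, prim),
                            projectDiseaseSpace(ddF, prim))

  expect_equal(as.matrix(runPipeline(toy$ld, toy$dag, cfg)),
               as.matrix(manual), tolerance = 1e-12)

  katzOnly <- runPipeline(toy$ld, toy$dag, pipelineConfig(variant = "KATZ"))
  expect_equal(as.matrix(katzOnly), as.matrix(prim), tolerance = 1e-12)
  expect_equal(scoreStage(katzOnly), "primary")

  # SP projects the raw Boolean associations
  spManual <- fuseProjections(
    projectLncrnaSpace(llF, ScoreMatrix(as.matrix(toy$ld),
                                        lncrnaIds(toy$ld),
                                        diseaseIds(toy$ld),
                                        stage = "primary")),
    projectDiseaseSpace(ddF, ScoreMatrix(as.matrix(toy$ld),
                                         lncrnaIds(toy$ld),
                                         diseaseIds(toy$ld),
                                         stage = "primary")))
  sp <- runPipeline(toy$ld, toy$dag, pipelineConfig(variant = "SP"))
  expect_equal(as.matrix(sp), as.matrix(spManual), tolerance = 1e-12)

  # SPKATZ runs KATZ on an adjacency whose off-diagonal block is the SP
  # score matrix
  aSp <- buildAdjacency(llF, ddF, as.matrix(spManual))
  spkManual <- extractPrimary(katzScores(aSp, selectBeta(aSp, cfg@K)), aSp)
  spk <- runPipeline(toy$ld, toy$dag, pipelineConfig(variant = "SPKATZ"))
  expect_equal(as.matrix(spk), as.matrix(spkManual), tolerance = 1e-12)
})

test_that("final scores are equivariant under consistent relabeling", {
  cfg <- syntheticConfig(nl = 8, nd = 10, nBlocks = 2, seed = 11)
  dag <- generateDag(cfg)
  ld <- generateAssociations(cfg, dag)$assoc
  S <- as.matrix(runPipeline(ld, dag, pipelineConfig()))
  set.seed(2)
  pl <- sample(8); pd <- sample(10)
  ldp <- AssociationMatrix(as.matrix(ld)[pl, pd], lncrnaIds(ld)[pl],
                           diseaseIds(ld)[pd])
  Sp <- as.matrix(runPipeline(ldp, dag, pipelineConfig()))
  expect_equal(unname(Sp), unname(S[pl, pd]), tolerance = 1e-9)
})

test_that("pipeline configurations validate and read from YAML", {
  expect_error(pipelineConfig(variant = "NOPE"), "variant")
  expect_error(pipelineConfig(K = 1.5), "K")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("K: 0.2", "variant: SP", "refold_similarities: false"), path)
  cfg <- readPipelineConfig(path)
  expect_equal(cfg@K, 0.2)
  expect_equal(cfg@variant, "SP")
  expect_false(cfg@refoldSimilarities)
  expect_equal(cfg@decay, 0.5)
})
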