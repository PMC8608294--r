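test_that("rocAuc handles separation, ties and hand-counted cases", {
  expect_equal(auc(rocAuc(0.9, c(0.1, 0.2))), 1.0)
  expect_equal(auc(rocAuc(c(0.5, 0.5), c(0.5, 0.5))), 0.5)
  expect_equal(auc(rocAuc(c(0.8, 0.4), c(0.6, 0.2))), 0.75)
  expect_error(rocAuc(numeric(), 1), "empty")
  expect_error(rocAuc(1, numeric()), "empty")

  r <- rocAuc(c(0.8, 0.4), c(0.6, 0.2))
  expect_equal(unname(rocPoints(r)[1, ]), c(0, 0))
  expect_equal(unname(rocPoints(r)[nrow(rocPoints(r)), ]), c(1, 1))
})

test_that("rocAuc equals exhaustive pair counting on random score sets", {
  set.seed(77)
  for (rep in 1:30) {
    np <- sample(50, 1); nn <- sample(50, 1)
    # coarse grid forces plenty of ties
    pos <- sample(seq(0, 1, by = 0.1), np, TRUE) + 0.2
    neg <- sample(seq(0, 1, by = 0.1), nn, TRUE)
    r <- rocAuc(pos, neg)
    expect_equal(auc(r), aucPairOracle(pos, neg), tolerance = 1e-9)
    # trapezoid over the stored roc points reproduces the stored auc
    roc <- rocPoints(r)
    trap <- sum(diff(roc[, 1]) * (roc[-1, 2] + roc[-nrow(roc), 2]) / 2)
    expect_equal(trap, auc(r), tolerance = 1e-12)
  }
})

test_that("rocAuc agrees with an independent ROC implementation", {
  set.seed(5)
  pos <- runif(40); neg <- runif(60) * 0.8
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), c(40, 60)), predictor = c(pos, neg),
    levels = c(0, 1), direction = "<"))
  expect_equal(auc(rocAuc(pos, neg)), as.numeric(ref), tolerance = 1e-9)
})

test_that("AUC and rankings are invariant under monotone transforms", {
  set.seed(19)
  pos <- runif(20); neg <- runif(30)
  f <- function(x) exp(3 * x) + 1
  expect_equal(auc(rocAuc(f(pos), f(neg))), auc(rocAuc(pos, neg)),
               tolerance = 1e-12)

  toy <- makeToy()
  sc <- runPipeline(toy$ld, toy$dag, pipelineConfig())
  sc2 <- ScoreMatrix(f(as.matrix(sc)), lncrnaIds(sc), diseaseIds(sc))
  r1 <- rankCandidates(sc, toy$ld, "d2", 4)
  r2 <- rankCandidates(sc2, toy$ld, "d2", 4)
  expect_equal(r1$lncrna, r2$lncrna)
})

test_that("loocv is deterministic and self-consistent", {
  toy <- makeToy()
  cfg <- pipelineConfig()
  r1 <- loocv(toy$ld, toy$dag, cfg)
  r2 <- loocv(toy$ld, toy$dag, cfg)
  expect_identical(auc(r1), auc(r2))
  expect_identical(perFoldRanks(r1), perFoldRanks(r2))
  expect_identical(rocPoints(r1), rocPoints(r2))

  # pooled AUC equals the weighted mean of per-fold percentiles
  expect_equal(auc(r1), pooledAucFromFolds(r1), tolerance = 1e-12)
  # one fold per known association
  expect_equal(nrow(perFoldRanks(r1)), sum(as.matrix(toy$ld)))
  # candidate pool is the permanent-negative set, identical across folds
  expect_true(all(perFoldRanks(r1)$candidates ==
                  sum(as.matrix(toy$ld) == 0)))
  expect_error(loocv(AssociationMatrix(matrix(1, 1, 1), "l1", "d1"),
                     toy$dag, cfg), "at least two")
})

test_that("the optimistic non-refold mode differs but stays valid", {
  toy <- makeToy()
  fast <- loocv(toy$ld, toy$dag, pipelineConfig(refoldSimilarities = FALSE))
  expect_s4_class(fast, "EvalResult")
  expect_true(auc(fast) >= 0 && auc(fast) <= 1)
})

test_that("novel-entity protocols return finite, pooled results", {
  toy <- makeToy()
  cfg <- pipelineConfig()
  rn <- novelEntityCv(toy$ld, toy$dag, cfg, "new_lncrna")
  expect_s4_class(rn, "EvalResult")
  expect_equal(nrow(perFoldRanks(rn)), sum(as.matrix(toy$ld)))
  expect_equal(auc(rn), pooledAucFromFolds(rn), tolerance = 1e-12)

  ri <- novelEntityCv(toy$ld, toy$dag, cfg, "isolated_disease")
  expect_equal(nrow(perFoldRanks(ri)), sum(as.matrix(toy$ld)))
  # candidate counts vary per row/column here; weighting must respect them
  expect_true(all(perFoldRanks(rn)$candidates ==
                  rowSums(as.matrix(toy$ld) == 0)[perFoldRanks(rn)$lncrna]))
})

test_that("sweepK tabulates one LOOCV per grid value", {
  toy <- makeToy()
  tab <- sweepK(toy$ld, toy$dag, pipelineConfig(), grid = c(0.1, 0.5))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(attr(tab, "bestK") %in% tab$K)
  expect_error(sweepK(toy$ld, toy$dag, pipelineConfig(), grid = c(0, 0.5)))
})

test_that("candidate ranking excludes known associates and breaks ties by id", {
  m <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0))
  ld <- AssociationMatrix(m, c("l1", "l2", "l3", "l4"), c("d1", "d2"))
  sc <- ScoreMatrix(rbind(c(0.1, 0.9), c(0.3, 0.5), c(0.2, 0.5),
                          c(0.4, 0.1)),
                    lncrnaIds(ld), diseaseIds(ld))
  rk <- rankCandidates(sc, ld, "d1", 10)
  expect_false("l1" %in% rk$lncrna)  # known associate excluded
  expect_equal(rk$lncrna, c("l4", "l2", "l3"))  # 0.4 > 0.3 > 0.2
  expect_equal(rk$rank, 1:3)

  tied <- rankCandidates(sc, ld, "d2", 3)
  expect_equal(tied$lncrna, c("l1", "l2", "l3"))  # tie at 0.5 broken by id

  expect_error(rankCandidates(sc, ld, "dX", 1), "unknown disease")
})
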