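test_that("semantic contributions follow the decaying max rule", {
  # isolated node: only the self contribution
  lone <- DiseaseOntology(nodeIds = "d1")
  expect_equal(semanticContributions(lone, "d1")@contributions, c(d1 = 1))

  chain2 <- DiseaseOntology(rbind(c("d1", "d2")))
  expect_equal(semanticContributions(chain2, "d2", 0.5)@contributions,
               c(d2 = 1, d1 = 0.5))

  chain3 <- DiseaseOntology(rbind(c("d1", "d2"), c("d2", "d3")))
  ct <- semanticContributions(chain3, "d3", 0.5)@contributions
  expect_equal(ct[c("d3", "d2", "d1")], c(d3 = 1, d2 = 0.5, d1 = 0.25))

  # a second, shorter path wins under the max rule
  shortcut <- DiseaseOntology(rbind(c("d1", "d2"), c("d2", "d3"),
                                    c("d1", "d3")))
  ct2 <- semanticContributions(shortcut, "d3", 0.5)@contributions
  expect_equal(unname(ct2["d1"]), 0.5)

  expect_error(semanticContributions(chain2, "dX"), "absent")
})

test_that("semantic contributions are invariant to edge order", {
  set.seed(3)
  edges <- rbind(c("r", "a"), c("r", "b"), c("a", "c"), c("b", "c"),
                 c("c", "d"), c("a", "d"), c("r", "c"))
  ref <- semanticContributions(DiseaseOntology(edges), "d", 0.5)@contributions
  for (i in 1:5) {
    perm <- edges[sample(nrow(edges)), ]
    ct <- semanticContributions(DiseaseOntology(perm), "d", 0.5)@contributions
    expect_equal(ct[names(ref)], ref)
  }
})

test_that("disease semantic similarity matches hand evaluation", {
  dag <- DiseaseOntology(rbind(c("d1", "d2")))
  dd <- diseaseSemanticSimilarity(dag, c("d1", "d2", "d9"), 0.5)
  m <- as.matrix(dd)
  expect_equal(m["d1", "d1"], 1)
  expect_equal(m["d1", "d2"], 0.6)  # (1 + 0.5) / (1 + 1.5)
  # d9 absent from the ontology: zero row/column including the diagonal
  expect_equal(unname(m["d9", ]), c(0, 0, 0))

  # disjoint components share no ancestors
  two <- DiseaseOntology(rbind(c("a1", "a2"), c("b1", "b2")))
  m2 <- as.matrix(diseaseSemanticSimilarity(two, c("a2", "b2")))
  expect_equal(m2["a2", "b2"], 0)
})

test_that("functional similarity averages best semantic matches", {
  dag <- DiseaseOntology(rbind(c("d1", "d2")))
  dd <- diseaseSemanticSimilarity(dag, c("d1", "d2"))

  # identical singleton disease sets
  ld1 <- AssociationMatrix(rbind(c(1, 0), c(1, 0)), c("l1", "l2"),
                           c("d1", "d2"))
  expect_equal(as.matrix(lncrnaFunctionalSimilarity(ld1, dd))["l1", "l2"], 1)

  # disjoint singletons: (0.6 + 0.6) / 2
  ld2 <- AssociationMatrix(diag(2), c("l1", "l2"), c("d1", "d2"))
  ll2 <- as.matrix(lncrnaFunctionalSimilarity(ld2, dd))
  expect_equal(ll2["l1", "l2"], 0.6)

  # an lncRNA with no associations: zero off-diagonal, diagonal forced 1
  ld3 <- AssociationMatrix(rbind(c(1, 0), c(0, 0), c(0, 1)),
                           paste0("l", 1:3), c("d1", "d2"))
  ll3 <- as.matrix(lncrnaFunctionalSimilarity(ld3, dd))
  expect_equal(unname(ll3[2, ]), c(0, 1, 0))

  expect_error(lncrnaFunctionalSimilarity(
    ld1, SimilarityMatrix(matrix(1), "dX", kind = "disease_semantic")),
    "cover")
})

test_that("GIP kernel matches hand evaluation and conventions", {
  ld <- AssociationMatrix(diag(2), c("l1", "l2"), c("d1", "d2"))
  g <- as.matrix(gipSimilarity(ld, "disease"))
  # unit mean squared column norm gives gamma = 1, distance^2 = 2
  expect_equal(g["d1", "d2"], exp(-2))
  expect_equal(diag(g), c(d1 = 1, d2 = 1))

  # identical profiles are maximally similar
  same <- AssociationMatrix(rbind(c(1, 0), c(1, 0)), c("l1", "l2"),
                            c("d1", "d2"))
  expect_equal(as.matrix(gipSimilarity(same, "lncrna"))["l1", "l2"], 1)

  expect_error(gipSimilarity(
    new("AssociationMatrix", assoc = matrix(1, 1, 1), lncrnaIds = "l1",
        diseaseIds = "d1"), "disease"), NA)
})

test_that("GIP similarity is equivariant under joint permutations", {
  set.seed(9)
  m <- matrix(rbinom(40, 1, 0.4), 5, 8)
  m[1, 1] <- 1
  ld <- AssociationMatrix(m, paste0("l", 1:5), paste0("d", 1:8))
  pl <- sample(5); pd <- sample(8)
  ldp <- AssociationMatrix(m[pl, pd], paste0("l", 1:5)[pl],
                           paste0("d", 1:8)[pd])
  g <- as.matrix(gipSimilarity(ld, "lncrna"))
  gp <- as.matrix(gipSimilarity(ldp, "lncrna"))
  expect_equal(gp, g[pl, pl], tolerance = 1e-12)
})

test_that("adding a shared association cannot decrease GIP similarity", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rbinom(48, 1, 0.3), 6, 8)
    m[1, 1] <- 1
    pair <- sample(6, 2)
    j <- sample(which(m[pair[1], ] != m[pair[2], ] | m[pair[1], ] == 0), 1)
    m2 <- m
    m2[pair, j] <- 1  # equalize one coordinate for the chosen pair
    if (all(m[pair[1], ] == m2[pair[1], ]) &&
        all(m[pair[2], ] == m2[pair[2], ])) next
    ld <- AssociationMatrix(m, paste0("l", 1:6), paste0("d", 1:8))
    ld2 <- AssociationMatrix(m2, paste0("l", 1:6), paste0("d", 1:8))
    d1sq <- sum((m[pair[1], ] - m[pair[2], ])^2)
    d2sq <- sum((m2[pair[1], ] - m2[pair[2], ])^2)
    expect_lte(d2sq, d1sq)  # profile distance shrinks or stays equal
  }
})

test_that("integration keeps base values and falls back to GIP at zeros", {
  base <- SimilarityMatrix(rbind(c(1, 0.6, 0), c(0.6, 1, 0), c(0, 0, 1)),
                           paste0("d", 1:3), kind = "disease_semantic")
  gip <- SimilarityMatrix(rbind(c(1, 0.135, 0.2), c(0.135, 1, 0.3),
                                c(0.2, 0.3, 1)),
                          paste0("d", 1:3), kind = "disease_gip")
  fin <- as.matrix(integrateSimilarity(base, gip))
  expect_equal(fin["d1", "d2"], 0.6)
  expect_equal(fin["d1", "d3"], 0.2)
  expect_equal(fin["d2", "d3"], 0.3)
  expect_equal(diag(fin), c(d1 = 1, d2 = 1, d3 = 1))

  # all-zero base (all diseases missing from the ontology) returns the GIP
  zero <- SimilarityMatrix(matrix(0, 3, 3), paste0("d", 1:3),
                           kind = "disease_semantic")
  expect_identical(as.matrix(integrateSimilarity(zero, gip)),
                   as.matrix(gip))

  expect_error(integrateSimilarity(base,
    SimilarityMatrix(diag(2), c("d1", "d2"), kind = "disease_gip")),
    "registries")
  expect_error(integrateSimilarity(gip, gip), "semantic or functional")
})

test_that("all similarity layers are symmetric and bounded in [0,1]", {
  cfg <- syntheticConfig(nl = 10, nd = 12, nBlocks = 3, seed = 5)
  dag <- generateDag(cfg)
  ld <- generateAssociations(cfg, dag)$assoc
  dd <- diseaseSemanticSimilarity(dag, diseaseIds(ld))
  layers <- list(dd,
                 lncrnaFunctionalSimilarity(ld, dd),
                 gipSimilarity(ld, "disease"),
                 gipSimilarity(ld, "lncrna"))
  layers <- c(layers, list(
    integrateSimilarity(dd, layers[[3]]),
    integrateSimilarity(layers[[2]], layers[[4]])))
  for (lay in layers) {
    m <- as.matrix(lay)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_gte(min(m), 0)
    expect_lte(max(m), 1)
  }
})
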