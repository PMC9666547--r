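test_that("true contacts use the strict 8 A minimum-heavy-atom definition", {
  a <- oneResidueStructure("A", namedAtoms(CA = c(0, 0, 0)))
  bNear <- oneResidueStructure("B", namedAtoms(CA = c(7.99, 0, 0)))
  bEdge <- oneResidueStructure("B", namedAtoms(CA = c(8.0, 0, 0)))
  expect_true(truthContacts(trueContacts(a, bNear))[1, 1])
  expect_false(truthContacts(trueContacts(a, bEdge))[1, 1])   # strict <

  # multi-atom residues: minimum over all atom pairs vs brute-force oracle
  set.seed(14)
  atomsA <- list(namedAtoms(CA = rnorm(3), CB = rnorm(3) + 2,
                            CG = rnorm(3) - 1),
                 namedAtoms(CA = rnorm(3) + 5, CB = rnorm(3) + 6,
                            CG = rnorm(3) + 7))
  atomsB <- list(namedAtoms(CA = rnorm(3) + 3, CB = rnorm(3) + 4))
  sA <- MonomerStructure("A", 1:2, c("A", "A"), atomsA)
  sB <- MonomerStructure("B", 1L, "A", atomsB)
  gt <- trueContacts(sA, sB)
  for (i in 1:2)
    expect_equal(truthDistances(gt)[i, 1],
                 bfMinHeavyDistance(atomsA[[i]], atomsB[[1]]))
})

test_that("precision, accuracy order and accuracy rate match hand counts", {
  truthMat <- matrix(FALSE, 4, 4)
  truthMat[cbind(c(1, 2, 4), c(2, 3, 1))] <- TRUE
  d <- matrix(10, 4, 4); d[truthMat] <- 5
  gt <- new("ContactGroundTruth", minHeavyDistances = d,
            contacts = truthMat, threshold = 8)

  rc <- RankedContactList(i = c(1, 3, 2, 4), j = c(2, 3, 3, 4),
                          prob = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(precisionAtK(rc, gt, 4), 2 / 4)         # hand-counted
  expect_equal(precisionAtK(rc, gt, 1), 1.0)
  expect_equal(accuracyOrder(rc, gt, 200), 5.0)        # 1000 * 1 / 200
  rc2 <- RankedContactList(i = rep(1, 10), j = c(3:11, 2),
                           prob = seq(0.9, 0.1, length.out = 10))
  # first correct at rank 10 in a 100-residue dimer
  gt2 <- new("ContactGroundTruth",
             minHeavyDistances = matrix(c(rep(10, 4), 5, rep(10, 4 * 11 - 5)),
                                        4, 11),
             contacts = matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 39)), 4, 11),
             threshold = 8)
  expect_equal(accuracyOrder(rc2, gt2, 100), 100.0)

  none <- RankedContactList(i = 3, j = 4, prob = 0.5)
  expect_true(is.na(accuracyOrder(none, gt, 100)))

  perDimer <- list(list(ranked = rc, truth = gt),
                   list(ranked = none, truth = gt),
                   list(ranked = none, truth = gt),
                   list(ranked = none, truth = gt))
  expect_equal(accuracyRate(perDimer), 25.0)
  expect_equal(accuracyRate(perDimer[1]), 100.0)
  expect_equal(accuracyRate(perDimer[2]), 0.0)
})

test_that("AUC equals the Mann-Whitney statistic with tie handling", {
  truthMat <- matrix(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE), 2, 3)
  d <- matrix(10, 2, 3); d[truthMat] <- 5
  gt <- new("ContactGroundTruth", minHeavyDistances = d,
            contacts = truthMat, threshold = 8)

  perfect <- matrix(0.1, 2, 3); perfect[truthMat] <- 0.9
  expect_equal(contactAUC(perfect, gt), 1.0)
  expect_equal(contactAUC(matrix(0.5, 2, 3), gt), 0.5)

  set.seed(15)
  for (rep in 1:20) {
    s <- matrix(sample(seq(0, 1, by = 0.25), 6, TRUE), 2, 3)
    expect_equal(contactAUC(s, gt), bfAUC(as.vector(s), as.vector(truthMat)))
    # invariance under a strictly monotone transform
    expect_equal(contactAUC(exp(3 * s), gt), contactAUC(s, gt))
  }
  allPos <- new("ContactGroundTruth",
                minHeavyDistances = matrix(5, 2, 3),
                contacts = matrix(TRUE, 2, 3), threshold = 8)
  expect_error(contactAUC(perfect, allPos), "undefined AUC")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  truthMat <- matrix(runif(64) < 0.3, 8, 8)
  if (!any(truthMat)) truthMat[1, 1] <- TRUE
  if (all(truthMat)) truthMat[2, 2] <- FALSE
  d <- matrix(10, 8, 8); d[truthMat] <- 5
  gt <- new("ContactGroundTruth", minHeavyDistances = d,
            contacts = truthMat, threshold = 8)
  s <- matrix(runif(64), 8, 8)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(truthMat), as.vector(s),
                                        quiet = TRUE, direction = "<")))
  expect_equal(contactAUC(s, gt), ref, tolerance = 1e-12)
})

test_that("a perfect oracle ranking achieves the ideal metric panel", {
  d <- generateToyDimer(12, 12, seed = 17)
  gt <- d$truth
  # oracle: rank by the true distances (closer first)
  ord <- order(truthDistances(gt))
  idx <- which(!is.na(truthDistances(gt)), arr.ind = TRUE)
  oracle <- RankedContactList(i = idx[ord, 1], j = idx[ord, 2],
                              prob = seq(1, 0.01, length.out = length(ord)))
  scores <- 1 / (1 + truthDistances(gt))
  rep <- evaluationReport(oracle, scores, gt, monomerLength = 12,
                          totalDimerResidues = 24)
  expect_true(all(rep$precisionAt[c("top5", "top10", "L/10", "L/5")] == 1))
  expect_equal(rep$accuracyOrderPermil, 1000 / 24)
  expect_equal(rep$auc, 1.0)
  expect_equal(rep$nTrueContacts, sum(truthContacts(gt)))
})

test_that("precision at the full list length equals overall accuracy", {
  set.seed(18)
  truthMat <- matrix(runif(36) < 0.3, 6, 6)
  if (!any(truthMat)) truthMat[3, 3] <- TRUE
  dm <- matrix(10, 6, 6); dm[truthMat] <- 5
  gt <- new("ContactGroundTruth", minHeavyDistances = dm,
            contacts = truthMat, threshold = 8)
  rc <- rankContacts(matrix(runif(36), 6, 6))
  e <- contactEntries(rc)
  expect_equal(precisionAtK(rc, gt, nrow(e)),
               sum(truthMat[cbind(e$i, e$j)]) / nrow(e))
})
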