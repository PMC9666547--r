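test_that("ensemble averaging preserves normalization and is idempotent", {
  p <- randomDistogram(4, seed = 1)
  expect_equal(heavyProbs(averageEnsemble(list(p, p))), heavyProbs(p))

  a <- oneHotDistogram(2, 0); b <- oneHotDistogram(2, 41)
  avg <- averageEnsemble(list(a, b))
  expect_equal(heavyProbs(avg)[1, 1, 1], 0.5)
  expect_equal(heavyProbs(avg)[1, 1, 42], 0.5)
  expect_equal(sum(heavyProbs(avg)[1, 1, ]), 1)

  q <- randomDistogram(4, seed = 2)
  s <- apply(heavyProbs(averageEnsemble(list(p, q))), c(1, 2), sum)
  expect_true(max(abs(s - 1)) < 1e-6)
  expect_error(averageEnsemble(list(p, randomDistogram(5, 3))), "shape")
})

test_that("two-order averaging transposes the BA inter-chain block", {
  l1 <- 2; l2 <- 3; n <- l1 + l2
  ab <- randomDistogram(n, seed = 4, lengths = c(l1, l2))
  # make the prediction pair-consistent: the (j, i) cell carries the same
  # distribution as the (i, j) cell, as for a physically coherent distogram
  consistent <- function(v) {
    for (b in 1:42) v[l1 + 1:l2, 1:l1, b] <- t(v[1:l1, l1 + 1:l2, b])
    v
  }
  ab@heavyProbs <- consistent(ab@heavyProbs)
  ab@cbProbs <- consistent(ab@cbProbs)
  # construct BA as the exact index swap of AB
  swap <- c((l1 + 1):n, 1:l1)
  ba <- new("DistogramPrediction",
            heavyProbs = heavyProbs(ab)[swap, swap, ],
            cbProbs = cbProbs(ab)[swap, swap, ],
            lengths = as.integer(c(l2, l1)))
  out <- averageTwoOrders(ab, ba, l1, l2)
  expect_identical(out$heavyProbs,
                   heavyProbs(ab)[1:l1, l1 + 1:l2, , drop = FALSE])
  expect_equal(dim(out$heavyProbs), c(l1, l2, 42L))

  # 1x1 toy: output is the plain average of the two cell distributions
  p1 <- randomDistogram(2, seed = 5, lengths = c(1, 1))
  p2 <- randomDistogram(2, seed = 6, lengths = c(1, 1))
  o <- averageTwoOrders(p1, p2, 1, 1)
  expect_equal(o$heavyProbs[1, 1, ],
               (heavyProbs(p1)[1, 2, ] + heavyProbs(p2)[1, 2, ]) / 2)

  # cells remain normalized
  s <- apply(o$heavyProbs, c(1, 2), sum)
  expect_true(max(abs(s - 1)) < 1e-6)
})

test_that("contact probability sums the bins below the threshold", {
  cell <- rep(0, 42); cell[1] <- 1
  expect_equal(contactProbability(cell), 1.0)
  cell41 <- rep(0, 42); cell41[42] <- 1
  expect_equal(contactProbability(cell41), 0.0)
  # 8 A is an exact boundary: bin 12 [7.5, 8) counts, bin 13 [8, 8.5) not
  straddle <- rep(0, 42); straddle[13] <- 0.5; straddle[14] <- 0.5
  expect_equal(contactProbability(straddle, 8), 0.5)
  # monotone in threshold
  set.seed(7); cellr <- rexp(42); cellr <- cellr / sum(cellr)
  th <- seq(0.5, 22, by = 0.5)
  probs <- vapply(th, function(t) contactProbability(cellr, t), numeric(1))
  expect_true(all(diff(probs) >= -1e-12))
  expect_error(contactProbability(cellr, 0), "threshold")
  expect_error(contactProbability(cellr, 23), "threshold")
})

test_that("ranking orders by probability with deterministic tie-breaks", {
  m <- matrix(c(0.1, 0.9, 0.9, 0.2), 2, 2, byrow = TRUE)
  deduped <- rankContacts(m, dedupeSymmetric = TRUE)
  e <- contactEntries(deduped)
  expect_equal(nrow(e), 3L)                            # (1,1) (1,2) (2,2)
  expect_equal(e$i[1], 1L); expect_equal(e$j[1], 2L)
  expect_equal(e$prob[1], 0.9)

  ties <- rankContacts(matrix(0.5, 2, 2))
  et <- contactEntries(ties)
  expect_equal(et$i, c(1L, 1L, 2L, 2L))
  expect_equal(et$j, c(1L, 2L, 1L, 2L))                # lexicographic

  expect_equal(nrow(contactEntries(rankContacts(matrix(runif(6), 2, 3)))), 6L)
})

test_that("confidence is the mean of the top floor(L/5) probabilities", {
  rc <- RankedContactList(i = 1:4, j = 1:4, prob = c(0.8, 0.6, 0.4, 0.2))
  expect_equal(confidenceScore(rc, 10), 0.7)           # top 2
  expect_equal(confidenceScore(rc, 4), 0.8)            # floor -> min 1
  flat <- RankedContactList(i = 1:5, j = 1:5, prob = rep(0.3, 5))
  expect_equal(confidenceScore(flat, 25), 0.3)
  # raising a top-k probability never lowers the score
  up <- RankedContactList(i = 1:4, j = 1:4, prob = c(0.9, 0.6, 0.4, 0.2))
  expect_gte(confidenceScore(up, 10), confidenceScore(rc, 10))
  expect_error(confidenceScore(RankedContactList(), 10), "empty")
})

test_that("homodimer score maps are exactly symmetric when symmetrized", {
  net <- buildNetwork(networkConfig(totalConvLayers = 6, filters = 4,
                                    seReduction = 2, seed = 8))
  d <- generateToyDimer(6, 6, seed = 9)
  mapA <- cbDistanceMap(d$structureA)
  p <- matrix(runif(36), 6, 6); p <- (p + t(p)) / 2
  co <- CoevolutionFeatures(p, array(runif(36 * 144), c(6, 6, 144)))
  pssm <- PositionSpecificScoringMatrix(matrix(rnorm(120), 6, 20))
  st <- stackFeatures(mapA, co, tilePSSM(pssm), c(6, 6), "homodimer")
  cm <- contactMap(forwardPass(net, st), symmetrize = TRUE)
  expect_identical(contactScores(cm), t(contactScores(cm)))
})

test_that("predictDimer returns ranked contacts with a confidence score", {
  net <- buildNetwork(networkConfig(totalConvLayers = 6, filters = 4,
                                    seReduction = 2, seed = 10))
  d <- generateToyDimer(6, 6, seed = 11)
  ex <- generateSyntheticFeatures(d, snr = 0.5, seed = 12)
  out <- predictDimer(net, ex$stack)
  expect_s4_class(out$contacts, "ContactScoreMap")
  expect_s4_class(out$ranked, "RankedContactList")
  expect_equal(dim(contactScores(out$contacts)), c(6L, 6L))
  expect_gte(out$confidence, 0); expect_lte(out$confidence, 1)
})
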