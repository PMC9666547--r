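test_that("cbDistanceMap computes Euclidean Cb distances with Ca fallback", {
  s <- MonomerStructure("A", 1:2, c("A", "A"),
                        list(namedAtoms(CB = c(0, 0, 0)),
                             namedAtoms(CB = c(3, 4, 0))))
  expect_equal(cbDistanceMap(s), matrix(c(0, 5, 5, 0), 2, 2))

  one <- oneResidueStructure("A", namedAtoms(CB = c(1, 1, 1)))
  expect_equal(cbDistanceMap(one), matrix(0, 1, 1))

  gly <- MonomerStructure("A", 1:2, c("G", "A"),
                          list(namedAtoms(CA = c(0, 0, 0)),
                               namedAtoms(CB = c(1, 0, 0))))
  expect_equal(cbDistanceMap(gly)[1, 2], 1.0)

  bad <- MonomerStructure("A", 1L, "A", list(namedAtoms(N = c(0, 0, 0))))
  expect_error(cbDistanceMap(bad), "no reference atom")
})

test_that("dimer distance channel places monomer maps on the diagonal blocks", {
  mA <- matrix(runif(9), 3, 3); mA <- (mA + t(mA)) / 2; diag(mA) <- 0
  expect_identical(assembleDimerDistanceChannel(mA), mA)   # homodimer

  m2 <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- assembleDimerDistanceChannel(m2, mA)
  expect_equal(dim(out), c(5L, 5L))
  expect_true(all(out[1:2, 3:5] == 0))                     # inter-chain zero
  expect_true(all(out[3:5, 1:2] == 0))
  expect_equal(sum(out), sum(m2) + sum(mA))                # conservation
  expect_equal(out[1:2, 1:2], m2)                          # block recovery
  expect_equal(out[3:5, 3:5], mA)
})

test_that("tilePSSM cross-concatenates profile rows", {
  r <- matrix(seq_len(20), 1, 20)
  t1 <- tilePSSM(PositionSpecificScoringMatrix(r))
  expect_equal(dim(t1), c(1L, 1L, 40L))
  expect_equal(as.vector(t1[1, 1, ]), c(r, r))

  rows <- matrix(rnorm(40), 2, 20)
  t2 <- tilePSSM(PositionSpecificScoringMatrix(rows))
  expect_equal(as.vector(t2[1, 2, 1:20]), rows[1, ])       # row_i part
  expect_equal(as.vector(t2[1, 2, 21:40]), rows[2, ])      # row_j part
  expect_equal(as.vector(t2[2, 1, 1:20]), rows[2, ])       # swapped
  expect_equal(as.vector(t2[2, 1, 21:40]), rows[1, ])

  a <- matrix(rnorm(20), 1, 20); b <- matrix(rnorm(20), 1, 20)
  th <- tilePSSM(PositionSpecificScoringMatrix(a),
                 PositionSpecificScoringMatrix(b))
  expect_equal(as.vector(th[1, 2, ]), c(a, b))             # vertical concat
})

test_that("stackFeatures builds the 186-channel tensor in fixed order", {
  mkCoevo <- function(n) {
    p <- matrix(runif(n * n), n, n); p <- (p + t(p)) / 2
    CoevolutionFeatures(p, array(runif(n * n * 144), c(n, n, 144)))
  }
  dist3 <- matrix(runif(9), 3, 3)
  st <- stackFeatures(dist3, mkCoevo(3),
                      array(0, c(3, 3, 40)), c(3, 3), "homodimer")
  expect_equal(dim(featureTensor(st)), c(3L, 3L, 186L))
  expect_equal(featureTensor(st)[, , 1], dist3)            # channel 0 exact
  expect_equal(sum(st@channelLayout), 186L)

  dist5 <- assembleDimerDistanceChannel(matrix(0, 2, 2), matrix(0, 3, 3))
  sh <- stackFeatures(dist5, mkCoevo(5), array(0, c(5, 5, 40)),
                      c(2, 3), "heterodimer")
  expect_equal(dim(featureTensor(sh))[1], 5L)

  expect_error(stackFeatures(dist3, mkCoevo(4), array(0, c(3, 3, 40)),
                             c(3, 3), "homodimer"),
               "feature length mismatch")
})

test_that("homodimer stacks are channel-wise symmetric for symmetric inputs", {
  set.seed(9)
  n <- 6
  p <- matrix(runif(n * n), n, n); p <- (p + t(p)) / 2
  att <- array(0, c(n, n, 144))
  for (c in 1:144) {
    m <- matrix(runif(n * n), n, n)
    att[, , c] <- (m + t(m)) / 2
  }
  dist <- matrix(runif(n * n), n, n); dist <- (dist + t(dist)) / 2
  pssm <- PositionSpecificScoringMatrix(matrix(rnorm(n * 20), n, 20))
  tile <- tilePSSM(pssm)
  st <- stackFeatures(dist, CoevolutionFeatures(p, att), tile,
                      c(n, n), "homodimer")
  x <- featureTensor(st)
  for (c in c(1, 2, 50, 146)) expect_equal(x[, , c], t(x[, , c]))
  # pssm tile transposes into its partner channel
  expect_equal(x[, , 147], t(x[, , 167]))
})
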