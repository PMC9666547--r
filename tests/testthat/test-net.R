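tinyCfg <- function(seed = 1) networkConfig(totalConvLayers = 6, filters = 4,
                                            maxoutGroups = 2, seReduction = 2,
                                            seed = seed)

test_that("the builder is seed-deterministic and counts layers as configured", {
  n1 <- buildNetwork(tinyCfg(3)); n2 <- buildNetwork(tinyCfg(3))
  expect_identical(n1$params, n2$params)
  n3 <- buildNetwork(tinyCfg(4))
  expect_false(identical(n1$params, n3$params))

  s <- networkSummary(n1)
  expect_equal(s$convLayers, 6L)
  expect_true(all(s$trunkFilters == 4L))
  expect_equal(s$bins, 42L)

  expect_error(networkConfig(totalConvLayers = 3), "at least 4")
  expect_error(networkConfig(totalConvLayers = 7), "2 \\* nBlocks")
  expect_warning(networkConfig(bins = 40L), "42")
})

test_that("forward pass yields normalized 42-bin heads of the input side", {
  net <- buildNetwork(tinyCfg())
  set.seed(2)
  x <- array(rnorm(8 * 8 * 186), c(8, 8, 186))
  p <- forwardPass(net, x)
  expect_equal(dim(heavyProbs(p)), c(8L, 8L, 42L))
  expect_equal(dim(cbProbs(p)), c(8L, 8L, 42L))
  sums <- apply(heavyProbs(p), c(1, 2), sum)
  expect_true(max(abs(sums - 1)) < 1e-5)

  x5 <- array(rnorm(5 * 5 * 186), c(5, 5, 186))
  expect_equal(dim(heavyProbs(forwardPass(net, x5)))[1], 5L)

  expect_identical(heavyProbs(forwardPass(net, x)),
                   heavyProbs(forwardPass(net, x)))     # inference determinism

  bad <- array(0, c(4, 4, 10))
  expect_error(forwardPass(net, bad), "feature shape mismatch")
})

test_that("maxout takes the maximum within consecutive channel groups", {
  x <- array(c(1, 3, 2, 0), c(1, 1, 4))
  expect_equal(as.vector(maxout(x, 2)), c(3, 2))
  expect_equal(maxout(x, 1), x)                         # identity
  const <- array(5, c(2, 2, 4))
  expect_equal(maxout(const, 2), array(5, c(2, 2, 2)))
  expect_error(maxout(x, 3), "maxout group mismatch")
})

test_that("RCIN standardization branches match hand-computed statistics", {
  # constant input: every branch reduces to the affine bias (zero via eps)
  const <- array(7, c(3, 3, 2))
  expect_equal(rcinNormalize(const), array(0, c(3, 3, 2)), tolerance = 1e-8)

  # 2x2 single-channel map: row branch standardizes each row
  x <- array(c(1, 5, 3, 7), c(2, 2, 1))                 # rows: (1,3), (5,7)
  r <- dimernet:::.standardizeFw(x, gamma = 1, beta = 0, axis = "row")$out
  for (i in 1:2) {
    row <- x[i, , 1]
    expected <- (row - mean(row)) / sqrt(var(row) / 2 * 1 + 1e-6)
    # population variance (divide by m, not m-1)
    expected <- (row - mean(row)) / sqrt(mean((row - mean(row))^2) + 1e-6)
    expect_equal(r[i, , 1], expected, tolerance = 1e-6)
  }

  # fusion restores the input channel count
  set.seed(4)
  y <- rcinNormalize(array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  expect_equal(dim(y), c(4L, 4L, 3L))
})

test_that("SE attention gates channels through the squeeze statistic", {
  set.seed(8)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  p <- dimernet:::withSeed(0L, dimernet:::.seInit(4L, 2L))
  fw <- dimernet:::.seFw(x, p)
  expect_true(all(fw$cache$g > 0 & fw$cache$g < 1))     # sigmoid range
  expect_equal(fw$cache$s, colMeans(matrix(x, 16, 4)))  # global-mean oracle

  expect_equal(seAttention(array(0, c(3, 3, 4)), reduction = 2),
               array(0, c(3, 3, 4)))                    # zeros preserved

  # doubling one channel changes only that channel's squeeze statistic
  x2 <- x; x2[, , 2] <- 2 * x2[, , 2]
  s2 <- dimernet:::.seFw(x2, p)$cache$s
  expect_equal(s2[-2], fw$cache$s[-2])
  expect_equal(s2[2], 2 * fw$cache$s[2])
})

test_that("spatial attention pools channels symmetrically", {
  set.seed(9)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  p <- dimernet:::withSeed(0L, dimernet:::.spaInit())
  fw <- dimernet:::.spaFw(x, p)
  expect_equal(dim(fw$cache$g), c(5L, 5L))              # one gate per position
  expect_true(all(fw$cache$g > 0 & fw$cache$g < 1))

  expect_equal(spatialAttention(array(0, c(3, 3, 2))),
               array(0, c(3, 3, 2)))

  # permuting channels leaves the pooled maps, hence the gate, unchanged
  xp <- x[, , c(4, 1, 6, 2, 5, 3)]
  expect_equal(dimernet:::.spaFw(xp, p)$cache$g, fw$cache$g)
})

test_that("analytic gradients agree with central differences", {
  net <- buildNetwork(tinyCfg(5))
  set.seed(11)
  n <- 4
  x <- array(rnorm(n * n * 186), c(n, n, 186))
  hb <- matrix(sample(0:41, n * n, TRUE), n, n)
  cbb <- matrix(sample(0:41, n * n, TRUE), n, n)
  mask <- buildInterchainMask(2, 2)
  lossOf <- function(model) {
    f <- dimernet:::.forwardFull(model, x)
    as.numeric(maskedCrossEntropy(f, hb, cbb, mask))
  }
  f <- dimernet:::.forwardFull(net, x, needCache = TRUE)
  g <- dimernet:::.backwardFull(
    net, f$cache,
    dimernet:::.headCEGradLogits(f$heavyProbs, hb, mask),
    dimernet:::.headCEGradLogits(f$cbProbs, cbb, mask))
  eps <- 1e-5
  set.seed(13)
  groups <- c("in.conv.w", "b001.rcin.row.gamma", "b001.rcin.fuse.w",
              "b001.conv1.w", "b001.se.w1", "b001.spa.w",
              "prehead.conv.w", "head.heavy.w", "head.cb.b")
  for (nm in groups) {
    ii <- sample(length(net$params[[nm]]), 2)
    for (i in ii) {
      up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("a small training step strictly decreases the one-example loss", {
  d <- generateToyDimer(8, 8, seed = 3)
  ex <- generateSyntheticFeatures(d, snr = 0.9, seed = 4)
  net <- buildNetwork(tinyCfg(6))
  l0 <- as.numeric(maskedCrossEntropy(forwardPass(net, ex$stack),
                                      ex$heavyBins, ex$cbBins, ex$mask))
  st <- dimernet:::.trainStep(net, ex, "sgd", 1e-3, NULL)
  l1 <- as.numeric(maskedCrossEntropy(forwardPass(st$model, ex$stack),
                                      ex$heavyBins, ex$cbBins, ex$mask))
  expect_lt(l1, l0)
})

test_that("checkpoints restore the exact model", {
  net <- buildNetwork(tinyCfg(7))
  f <- tempfile(fileext = ".ckpt")
  saveCheckpoint(net, f)
  back <- loadCheckpoint(f)
  expect_identical(back$params, net$params)
  expect_equal(back$config$totalConvLayers, net$config$totalConvLayers)
  set.seed(3)
  x <- array(rnorm(4 * 4 * 186), c(4, 4, 186))
  expect_identical(heavyProbs(forwardPass(back, x)),
                   heavyProbs(forwardPass(net, x)))
  unlink(f)
})
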