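## Distance discretization, inter-chain loss masking, dual-head masked
## cross-entropy and the two-phase training loop (Adam then SGD, batch 1).

#' Distance-bin edges
#'
#' The 42-bin discretization: bin 0 is `[0, 2)` Angstrom, bins 1..40 are the
#' uniform half-open 0.5-Angstrom bins from 2 to 22, and bin 41 is
#' `[22, Inf)`.
#'
#' @return Numeric vector of 43 boundaries (`0, 2, 2.5, ..., 22, Inf`).
#' @export
distanceBinEdges <- function() c(0, seq(2, 22, by = 0.5), Inf)

#' Discretize a distance into one of 42 bins
#'
#' Bins are half-open `[lo, hi)`: distances below 2 fall in bin 0, a
#' distance of exactly 22 falls in bin 41.
#'
#' @param d numeric vector/matrix of non-negative finite distances
#'   (Angstrom).
#' @return Integer bin indices in `0..41`, same shape as `d`.
#' @examples
#' discretizeDistance(c(1, 8, 25))   # 0, 13, 41
#' @export
discretizeDistance <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("invalid distance: distances must be finite and non-negative")
  b <- 1L + floor((d - 2) / 0.5)
  b[d < 2] <- 0L
  b[d >= 22] <- 41L
  out <- as.integer(b)
  if (!is.null(dim(d))) dim(out) <- dim(d)
  out
}

#' Midpoint of each distance bin
#'
#' Open-ended bins use their closed edge plus/minus a quarter bin width.
#'
#' @param bins integer bin indices in `0..41`.
#' @return Numeric midpoints (Angstrom).
#' @export
binMidpoints <- function(bins) {
  mids <- c(1, seq(2.25, 21.75, by = 0.5), 22.25)
  mids[bins + 1L]
}

#' Build the inter-chain loss mask
#'
#' Only inter-chain cells contribute to the training loss; intra-chain
#' distance predictions are ignored.  For a homodimer every cell of the
#' L x L grid is an inter-chain pair (residue i of chain A vs residue j of
#' chain B), so the mask is all-true; for a heterodimer only the two
#' off-diagonal L1 x L2 and L2 x L1 blocks are true.
#'
#' @param l1 length of chain A.
#' @param l2 optional length of chain B (absent for homodimers).
#' @return Logical matrix over the output grid.
#' @export
buildInterchainMask <- function(l1, l2 = NULL) {
  if (is.null(l2)) return(matrix(TRUE, l1, l1))
  n <- l1 + l2
  m <- matrix(FALSE, n, n)
  m[seq_len(l1), l1 + seq_len(l2)] <- TRUE
  m[l1 + seq_len(l2), seq_len(l1)] <- TRUE
  m
}

## per-head cross-entropy over masked cells; bins are 0-based
.headCE <- function(probs, bins, mask) {
  idx <- which(mask, arr.ind = TRUE)
  pt <- probs[cbind(idx[, 1L], idx[, 2L], bins[idx] + 1L)]
  -mean(log(pmax(pt, 1e-12)))
}

## gradient of the masked mean NLL with respect to the head logits
.headCEGradLogits <- function(probs, bins, mask) {
  n <- sum(mask)
  d <- dim(probs)
  m3 <- array(mask, d)
  dl <- probs * m3 / n
  idx <- which(mask, arr.ind = TRUE)
  tri <- cbind(idx[, 1L], idx[, 2L], bins[idx] + 1L)
  dl[tri] <- dl[tri] - 1 / n
  dl
}

#' Masked dual-head cross-entropy loss
#'
#' Mean over masked (inter-chain) cells of the negative log-probability of
#' the true bin, computed for the heavy-atom head against minimum
#' heavy-atom-distance bins and for the Cb head against Cb-Cb-distance
#' bins, and summed with equal weight.  Cells outside the mask contribute
#' nothing.
#'
#' @param pred a [DistogramPrediction-class] (or list with `heavyProbs`,
#'   `cbProbs`).
#' @param trueHeavyBins,trueCbBins integer matrices of 0-based bin labels.
#' @param mask logical matrix from [buildInterchainMask()].
#' @return Scalar loss, with per-head components as attribute `"perHead"`.
#' @export
maskedCrossEntropy <- function(pred, trueHeavyBins, trueCbBins, mask) {
  if (!any(mask)) stop("empty loss support: mask selects no cells")
  hp <- if (is(pred, "DistogramPrediction")) heavyProbs(pred) else pred$heavyProbs
  cp <- if (is(pred, "DistogramPrediction")) cbProbs(pred) else pred$cbProbs
  lh <- .headCE(hp, trueHeavyBins, mask)
  lc <- .headCE(cp, trueCbBins, mask)
  structure(lh + lc, perHead = c(heavy = lh, cb = lc))
}

#' Two-phase training schedule
#'
#' The published regimen: Adam at learning rate 1e-3 for the first 30
#' epochs (fast convergence), then plain stochastic gradient descent
#' starting at 1e-4 with a ten-fold reduction every 20 epochs for the
#' remaining 50 epochs.  Batch size is 1 (variable-size inputs need no
#' padding).
#'
#' @param phase1Epochs,phase1Lr Adam phase length and learning rate.
#' @param phase2Epochs,phase2Lr,phase2DecayEvery,phase2Decay SGD phase
#'   length, starting rate, decay interval (epochs) and decay factor.
#' @return A `TrainingSchedule` list.
#' @export
trainingSchedule <- function(phase1Epochs = 30L, phase1Lr = 1e-3,
                             phase2Epochs = 50L, phase2Lr = 1e-4,
                             phase2DecayEvery = 20L, phase2Decay = 0.1) {
  s <- list(phase1Epochs = as.integer(phase1Epochs), phase1Lr = phase1Lr,
            phase2Epochs = as.integer(phase2Epochs), phase2Lr = phase2Lr,
            phase2DecayEvery = as.integer(phase2DecayEvery),
            phase2Decay = phase2Decay, batchSize = 1L)
  s$totalEpochs <- s$phase1Epochs + s$phase2Epochs
  class(s) <- "TrainingSchedule"
  s
}

#' Optimizer and learning rate at a given epoch
#'
#' @param schedule a [trainingSchedule()].
#' @param epoch 0-based epoch index.
#' @return List with `optimizer` (`"adam"` or `"sgd"`) and `lr`.
#' @examples
#' lrAtEpoch(trainingSchedule(), 55)  # sgd, 1e-5
#' @export
lrAtEpoch <- function(schedule, epoch) {
  if (epoch < 0 || epoch >= schedule$totalEpochs)
    stop("schedule exhausted: epoch ", epoch, " outside 0..",
         schedule$totalEpochs - 1L)
  if (epoch < schedule$phase1Epochs)
    return(list(optimizer = "adam", lr = schedule$phase1Lr))
  e2 <- epoch - schedule$phase1Epochs
  list(optimizer = "sgd",
       lr = schedule$phase2Lr *
         schedule$phase2Decay^(e2 %/% schedule$phase2DecayEvery))
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gq <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gq
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gq^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.sgdStep <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

## one optimization step on a single example; returns updated model/state/loss
.trainStep <- function(model, example, optimizer, lr, adamState) {
  x <- if (is(example$stack, "FeatureStack")) featureTensor(example$stack)
       else example$stack
  f <- .forwardFull(model, x, needCache = TRUE)
  loss <- maskedCrossEntropy(list(heavyProbs = f$heavyProbs, cbProbs = f$cbProbs),
                             example$heavyBins, example$cbBins, example$mask)
  dheavy <- .headCEGradLogits(f$heavyProbs, example$heavyBins, example$mask)
  dcb <- .headCEGradLogits(f$cbProbs, example$cbBins, example$mask)
  grads <- .backwardFull(model, f$cache, dheavy, dcb)
  if (optimizer == "adam") {
    up <- .adamStep(model$params, grads, adamState, lr)
    model$params <- up$params
    adamState <- up$state
  } else {
    model$params <- .sgdStep(model$params, grads, lr)
  }
  list(model = model, adamState = adamState, loss = as.numeric(loss))
}

#' Train the network on a dataset of dimers
#'
#' Batch-size-1 training under the two-phase schedule: examples are
#' shuffled each epoch (deterministically from `seed`), the masked
#' dual-head cross-entropy is backpropagated through the full network, and
#' parameters are updated with Adam (phase 1) or SGD (phase 2).  Training
#' aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model a `DistogramNetwork`.
#' @param dataset list of examples, each a list with `stack` (a
#'   [FeatureStack-class] or array), `heavyBins`, `cbBins` (0-based label
#'   matrices) and `mask` (logical matrix).
#' @param schedule a [trainingSchedule()].
#' @param epochs optional cap on the number of epochs actually run
#'   (defaults to the full schedule).
#' @param seed integer seed for the shuffling stream.
#' @param checkpointDir optional directory receiving one checkpoint per
#'   epoch (`epoch_###.ckpt`).
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained) and `lossTrace` (data.frame with
#'   epoch, optimizer, lr, loss).
#' @export
trainLoop <- function(model, dataset, schedule = trainingSchedule(),
                      epochs = NULL, seed = 0L, checkpointDir = NULL,
                      verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  nepochs <- min(epochs %||% schedule$totalEpochs, schedule$totalEpochs)
  adamState <- .adamInit(model$params)
  trace <- data.frame(epoch = integer(), optimizer = character(),
                      lr = numeric(), loss = numeric())
  withSeed(seed, {
    for (ep in seq_len(nepochs) - 1L) {
      opt <- lrAtEpoch(schedule, ep)
      ord <- sample(length(dataset))
      losses <- numeric(length(ord))
      for (s in seq_along(ord)) {
        st <- .trainStep(model, dataset[[ord[s]]], opt$optimizer, opt$lr,
                         adamState)
        model <- st$model
        adamState <- st$adamState
        losses[s] <- st$loss
        if (!is.finite(losses[s]))
          stop("training diverged (NaN loss) at epoch ", ep, ", example ",
               ord[s])
      }
      trace <- rbind(trace, data.frame(epoch = ep, optimizer = opt$optimizer,
                                       lr = opt$lr, loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %3d  %-4s lr %.1e  loss %.4f", ep,
                        opt$optimizer, opt$lr, mean(losses)))
      if (!is.null(checkpointDir))
        saveCheckpoint(model, file.path(checkpointDir,
                                        sprintf("epoch_%03d.ckpt", ep)))
    }
  })
  list(model = model, lossTrace = trace)
}
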