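## Inference post-processing: ensemble averaging over MSAs, two-order
## (AB/BA) averaging for heterodimers, distogram -> contact-probability
## conversion, ranking and confidence scoring.

#' Average an ensemble of distogram predictions
#'
#' Elementwise mean per head over predictions made from different MSAs
#' (e.g. BFD- and Uniclust-derived inputs); the mean of per-cell
#' distributions is itself a distribution, so normalization is preserved.
#'
#' @param preds list of [DistogramPrediction-class] objects of one shape.
#' @return A [DistogramPrediction-class].
#' @export
averageEnsemble <- function(preds) {
  stopifnot(length(preds) >= 1L)
  d <- dim(heavyProbs(preds[[1L]]))
  for (p in preds)
    if (!identical(dim(heavyProbs(p)), d))
      stop("ensemble members must share a shape")
  hp <- Reduce(`+`, lapply(preds, heavyProbs)) / length(preds)
  cp <- Reduce(`+`, lapply(preds, cbProbs)) / length(preds)
  new("DistogramPrediction", heavyProbs = hp, cbProbs = cp,
      lengths = chainLengths(preds[[1L]]))
}

## inter-chain (top-right) block of a full heterodimer volume
.interBlock <- function(vol, lFirst, lSecond)
  vol[seq_len(lFirst), lFirst + seq_len(lSecond), , drop = FALSE]

#' Average the two chain-order predictions of a heterodimer
#'
#' A heterodimer can be presented to the network in either chain order (AB
#' or BA).  The inter-chain block of the BA prediction is extracted,
#' spatially transposed to the AB orientation, and averaged per bin and per
#' head with the AB inter-chain block, smoothing order-dependent variance.
#'
#' @param predAb prediction for the AB-ordered input (side `l1 + l2`).
#' @param predBa prediction for the BA-ordered input (side `l2 + l1`).
#' @param l1,l2 chain lengths.
#' @return An `InterChainDistogram`: list with `heavyProbs` and `cbProbs`
#'   (`l1 x l2 x 42` arrays) and `lengths`.
#' @export
averageTwoOrders <- function(predAb, predBa, l1, l2) {
  n <- l1 + l2
  if (dim(heavyProbs(predAb))[1L] != n || dim(heavyProbs(predBa))[1L] != n)
    stop("inconsistent lengths: predictions must have side l1 + l2")
  avg <- function(fab, fba) {
    ab <- .interBlock(fab, l1, l2)
    ba <- aperm(.interBlock(fba, l2, l1), c(2L, 1L, 3L))
    (ab + ba) / 2
  }
  structure(list(heavyProbs = avg(heavyProbs(predAb), heavyProbs(predBa)),
                 cbProbs = avg(cbProbs(predAb), cbProbs(predBa)),
                 lengths = as.integer(c(l1, l2))),
            class = "InterChainDistogram")
}

#' Contact probability of one distogram cell
#'
#' The probability that the distance falls below `threshold`: full bins
#' below the threshold contribute their whole mass, the straddling bin a
#' linear fraction.  The default 8-Angstrom threshold lies exactly on a bin
#' boundary (bins 0..12 contribute fully).
#'
#' @param cell normalized 42-vector of bin probabilities.
#' @param threshold Angstrom, in (0, 22].
#' @return Contact probability in `[0, 1]`.
#' @export
contactProbability <- function(cell, threshold = 8) {
  sum(cell * .binWeights(threshold))
}

.binWeights <- function(threshold) {
  if (threshold <= 0 || threshold > 22)
    stop("threshold must lie in (0, 22] Angstrom")
  e <- distanceBinEdges()
  lo <- e[-length(e)]; hi <- e[-1L]
  pmin(1, pmax(0, (threshold - lo) / (hi - lo)))
}

## convert an (a, b, 42) probability volume into an a x b score matrix
.volToScores <- function(vol, threshold) {
  d <- dim(vol)
  matrix(matrix(vol, d[1L] * d[2L], d[3L]) %*% .binWeights(threshold),
         d[1L], d[2L])
}

#' Convert a distogram into an inter-chain contact score map
#'
#' Uses the heavy-atom head by default, matching the 8-Angstrom
#' minimum-heavy-atom contact definition.  For a homodimer the full L x L
#' map is converted (optionally symmetrized with its transpose); for a
#' heterodimer the two inter-chain blocks of the full (L1+L2)-sided map are
#' converted and averaged into one L1 x L2 map (`blockAverage = FALSE`
#' keeps only the top-right block).  An `InterChainDistogram` from
#' [averageTwoOrders()] is converted directly.
#'
#' @param pred a [DistogramPrediction-class] or `InterChainDistogram`.
#' @param threshold contact threshold in Angstrom (default 8).
#' @param head `"heavy"` (default) or `"cb"`.
#' @param symmetrize average a homodimer score map with its transpose
#'   (default TRUE).
#' @param blockAverage average a heterodimer's two inter-chain blocks
#'   (default TRUE).
#' @return A [ContactScoreMap-class].
#' @export
contactMap <- function(pred, threshold = 8, head = c("heavy", "cb"),
                       symmetrize = TRUE, blockAverage = TRUE) {
  head <- match.arg(head)
  vol <- if (head == "heavy") {
    if (is(pred, "DistogramPrediction")) heavyProbs(pred) else pred$heavyProbs
  } else {
    if (is(pred, "DistogramPrediction")) cbProbs(pred) else pred$cbProbs
  }
  lengths <- if (is(pred, "DistogramPrediction")) chainLengths(pred)
             else pred$lengths
  n <- dim(vol)[1L]
  if (inherits(pred, "InterChainDistogram")) {
    scores <- .volToScores(vol, threshold)
  } else if (n == lengths[1L] && lengths[1L] == lengths[2L]) {   # homodimer
    scores <- .volToScores(vol, threshold)
    if (symmetrize) scores <- (scores + t(scores)) / 2
  } else {                                                       # heterodimer
    l1 <- lengths[1L]; l2 <- lengths[2L]
    stopifnot(n == l1 + l2)
    s <- .volToScores(.interBlock(vol, l1, l2), threshold)
    if (blockAverage) {
      s2 <- t(.volToScores(vol[l1 + seq_len(l2), seq_len(l1), , drop = FALSE],
                           threshold))
      s <- (s + s2) / 2
    }
    scores <- s
  }
  new("ContactScoreMap", scores = pmin(pmax(scores, 0), 1),
      threshold = threshold)
}

#' Rank contact predictions
#'
#' Orders all cells of a contact score map by descending probability with
#' lexicographic (i, j) tie-breaking.  For homodimers,
#' `dedupeSymmetric = TRUE` merges each pair (i, j)/(j, i) into a single
#' entry with `i <= j` carrying the larger score, since a contact and its
#' mirror are one prediction.
#'
#' @param scores a [ContactScoreMap-class] or bare numeric matrix.
#' @param dedupeSymmetric merge symmetric duplicates (square maps only).
#' @return A [RankedContactList-class].
#' @export
rankContacts <- function(scores, dedupeSymmetric = FALSE) {
  s <- if (is(scores, "ContactScoreMap")) contactScores(scores) else scores
  if (dedupeSymmetric) {
    if (nrow(s) != ncol(s)) stop("dedupeSymmetric needs a square score map")
    keep <- which(upper.tri(s, diag = TRUE), arr.ind = TRUE)
    prob <- pmax(s[keep], t(s)[keep])
    return(RankedContactList(i = keep[, 1L], j = keep[, 2L], prob = prob))
  }
  idx <- which(!is.na(s), arr.ind = TRUE)
  RankedContactList(i = idx[, 1L], j = idx[, 2L], prob = s[idx])
}

#' Confidence score of a ranked prediction
#'
#' The mean probability of the top floor(L/5) entries (minimum 1), which
#' tracks the realized top-L/5 precision and serves as a per-target
#' confidence estimate.
#'
#' @param ranked a [RankedContactList-class].
#' @param monomerLength L (homodimer monomer length, or the shorter chain
#'   for heterodimers).
#' @return Mean probability of the top floor(L/5) entries.
#' @export
confidenceScore <- function(ranked, monomerLength) {
  e <- contactEntries(ranked)
  if (nrow(e) == 0L) stop("empty contact list")
  k <- min(max(1L, monomerLength %/% 5L), nrow(e))
  mean(e$prob[seq_len(k)])
}

#' End-to-end prediction for one dimer
#'
#' Runs the network on one or more feature stacks (an ensemble over MSAs is
#' averaged), optionally averages the two chain orders for heterodimers,
#' converts to contact probabilities, ranks, and attaches a confidence
#' score.
#'
#' @param model a `DistogramNetwork`.
#' @param stacks a [FeatureStack-class] or list of stacks (AB order).
#' @param stacksBa optional stack(s) built in BA order (heterodimers).
#' @param threshold contact threshold in Angstrom.
#' @param dedupeSymmetric homodimer mirror-pair merging for the ranking.
#' @return List with `distogram`, `contacts` ([ContactScoreMap-class]),
#'   `ranked` ([RankedContactList-class]) and `confidence`.
#' @export
predictDimer <- function(model, stacks, stacksBa = NULL, threshold = 8,
                         dedupeSymmetric = TRUE) {
  if (is(stacks, "FeatureStack")) stacks <- list(stacks)
  pred <- averageEnsemble(lapply(stacks, function(s) forwardPass(model, s)))
  lengths <- chainLengths(pred)
  homo <- dimerKind(stacks[[1L]]) == "homodimer"
  if (!is.null(stacksBa)) {
    if (is(stacksBa, "FeatureStack")) stacksBa <- list(stacksBa)
    predBa <- averageEnsemble(lapply(stacksBa, function(s) forwardPass(model, s)))
    pred <- averageTwoOrders(pred, predBa, lengths[1L], lengths[2L])
  }
  cm <- contactMap(pred, threshold = threshold)
  ranked <- rankContacts(cm, dedupeSymmetric = homo && dedupeSymmetric)
  Lconf <- if (homo) lengths[1L] else min(lengths)
  list(distogram = pred, contacts = cm, ranked = ranked,
       confidence = confidenceScore(ranked, Lconf))
}
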