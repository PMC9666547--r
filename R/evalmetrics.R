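## Ground-truth contact extraction and the contact-evaluation statistics:
## top-k precision, accuracy order, accuracy rate and AUC.

#' True inter-chain contacts from two monomer structures
#'
#' For every residue pair (i in chain A, j in chain B) the minimum over all
#' heavy-atom pairs of the Euclidean distance is computed; a pair is in
#' contact when that distance is strictly below the threshold (8 Angstrom
#' by convention).
#'
#' @param structureA,structureB [MonomerStructure-class] objects.
#' @param threshold contact threshold in Angstrom (default 8).
#' @return A [ContactGroundTruth-class].
#' @export
trueContacts <- function(structureA, structureB, threshold = 8) {
  coordsOf <- function(s) {
    xyz <- do.call(rbind, lapply(seq_len(nResidues(s)), function(r)
      atomCoords(s, r)))
    grp <- rep(seq_len(nResidues(s)),
               vapply(seq_len(nResidues(s)),
                      function(r) nrow(atomCoords(s, r)), integer(1)))
    list(xyz = xyz, grp = grp)
  }
  a <- coordsOf(structureA); b <- coordsOf(structureB)
  # all heavy-atom pair distances, then min within each residue-pair group
  d2 <- outer(rowSums(a$xyz^2), rowSums(b$xyz^2), `+`) -
    2 * tcrossprod(a$xyz, b$xyz)
  d <- sqrt(pmax(d2, 0))
  la <- nResidues(structureA); lb <- nResidues(structureB)
  md <- matrix(Inf, la, lb)
  ia <- a$grp[row(d)]; ib <- b$grp[col(d)]
  ord <- order(d)                       # ascending: first hit per group is min
  key <- ia + (ib - 1L) * la
  first <- !duplicated(key[ord])
  md[key[ord][first]] <- d[ord][first]
  new("ContactGroundTruth", minHeavyDistances = md,
      contacts = md < threshold, threshold = threshold)
}

## is the k-th ranked entry a true contact?  For deduped homodimer rankings
## either orientation counts.
.entryCorrect <- function(entries, truth, symmetricPairs = FALSE) {
  tc <- truthContacts(truth)
  hit <- tc[cbind(entries$i, entries$j)]
  if (symmetricPairs && nrow(tc) == ncol(tc))
    hit <- hit | tc[cbind(entries$j, entries$i)]
  hit
}

#' Precision of the top-k contact predictions
#'
#' @param ranked a [RankedContactList-class].
#' @param truth a [ContactGroundTruth-class].
#' @param k number of top predictions considered (clipped to the list
#'   length).
#' @param symmetricPairs treat (i, j) and (j, i) as the same pair when
#'   checking correctness (homodimer deduped rankings).
#' @return Fraction of the top k that are true contacts.
#' @export
precisionAtK <- function(ranked, truth, k, symmetricPairs = FALSE) {
  e <- contactEntries(ranked)
  stopifnot(k >= 1L)
  k <- min(as.integer(k), nrow(e))
  if (k == 0L) return(0)
  hits <- .entryCorrect(e[seq_len(k), , drop = FALSE], truth, symmetricPairs)
  sum(hits) / k
}

#' Accuracy order (per mille)
#'
#' The 1-based rank of the first correct contact prediction divided by the
#' total number of residues of the dimer (L1 + L2; 2L for homodimers),
#' reported in per mille.  Lower is better; with no correct prediction the
#' value is undefined (`NA`) and excluded from set averages.
#'
#' @inheritParams precisionAtK
#' @param totalDimerResidues L1 + L2.
#' @return Accuracy order in per mille, or `NA_real_`.
#' @export
accuracyOrder <- function(ranked, truth, totalDimerResidues,
                          symmetricPairs = FALSE) {
  stopifnot(totalDimerResidues >= 1L)
  e <- contactEntries(ranked)
  if (nrow(e) == 0L) return(NA_real_)
  hits <- .entryCorrect(e, truth, symmetricPairs)
  if (!any(hits)) return(NA_real_)
  1000 * which(hits)[1L] / totalDimerResidues
}

#' Accuracy rate over a set of dimers
#'
#' The percentage of dimers for which at least one of the top 10 contact
#' predictions is correct.
#'
#' @param perDimer list of `list(ranked = , truth = )` pairs.
#' @param symmetricPairs see [precisionAtK()].
#' @return Percentage in `[0, 100]`.
#' @export
accuracyRate <- function(perDimer, symmetricPairs = FALSE) {
  stopifnot(length(perDimer) >= 1L)
  hit <- vapply(perDimer, function(d) {
    precisionAtK(d$ranked, d$truth, 10L, symmetricPairs) > 0
  }, logical(1))
  100 * mean(hit)
}

#' Rank-based AUC of a contact score map
#'
#' The area under the ROC curve over all inter-chain residue pairs, computed
#' as the Mann-Whitney statistic (ties contribute one half).
#'
#' @param scores a [ContactScoreMap-class] or numeric matrix.
#' @param truth a [ContactGroundTruth-class] of the same shape.
#' @return AUC in `[0, 1]`.
#' @export
contactAUC <- function(scores, truth) {
  s <- if (is(scores, "ContactScoreMap")) contactScores(scores) else scores
  y <- as.vector(truthContacts(truth))
  x <- as.vector(s)
  stopifnot(length(x) == length(y))
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined AUC: need at least one contact and one non-contact")
  r <- rank(x, ties.method = "average")
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Per-dimer evaluation report
#'
#' Computes the full metric panel for one dimer: precision of the top 5,
#' top 10, top L/10, L/5, L/2 and L predictions (floor, minimum 1; L is the
#' homodimer monomer length or the shorter heterodimer chain), accuracy
#' order in per mille, AUC, and the number of true contacts.
#'
#' @param ranked a [RankedContactList-class].
#' @param scores a [ContactScoreMap-class] (for the AUC).
#' @param truth a [ContactGroundTruth-class].
#' @param monomerLength L (or Ls).
#' @param totalDimerResidues L1 + L2.
#' @param symmetricPairs see [precisionAtK()].
#' @return List with `precisionAt` (named vector), `accuracyOrderPermil`,
#'   `auc`, `nTrueContacts`.
#' @export
evaluationReport <- function(ranked, scores, truth, monomerLength,
                             totalDimerResidues, symmetricPairs = FALSE) {
  ks <- c(top5 = 5L, top10 = 10L,
          `L/10` = max(1L, monomerLength %/% 10L),
          `L/5` = max(1L, monomerLength %/% 5L),
          `L/2` = max(1L, monomerLength %/% 2L),
          L = max(1L, as.integer(monomerLength)))
  prec <- vapply(ks, function(k) precisionAtK(ranked, truth, k, symmetricPairs),
                 numeric(1))
  list(precisionAt = prec,
       accuracyOrderPermil = accuracyOrder(ranked, truth, totalDimerResidues,
                                           symmetricPairs),
       auc = contactAUC(scores, truth),
       nTrueContacts = sum(truthContacts(truth)))
}

#' Write an evaluation report as TSV
#'
#' One row per dimer, columns in the customary order (top-k precisions,
#' accuracy order, AUC).
#'
#' @param reports named list of [evaluationReport()] results.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeEvaluationTSV <- function(reports, file) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(target = nm, t(r$precisionAt),
               AccOrder_permil = r$accuracyOrderPermil, AUC = r$auc,
               n_true_contacts = r$nTrueContacts, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
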