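#' @useDynLib dimernet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' PSI-BLAST PSSM residue column order
#'
#' The fixed 20-letter amino-acid order used by the log-odds columns of a
#' PSI-BLAST ASCII position-specific scoring matrix, and by all PSSM objects
#' in this package.
#'
#' @format Character vector of 20 one-letter amino-acid codes.
#' @export
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## number of input feature channels: 1 distance + 1 coupling + 144 attention
## + 40 tiled PSSM
N_INPUT_CHANNELS <- 186L
N_ATTENTION_CHANNELS <- 144L
N_PSSM_CHANNELS <- 40L
N_DISTANCE_BINS <- 42L

#' MonomerStructure: heavy-atom coordinates of one protein chain
#'
#' Holds, per residue of a single chain, the heavy (non-hydrogen) atom
#' coordinates in Angstrom.  This is the structural input from which the
#' intra-chain Cb distance channel and the heavy-atom ground-truth contacts
#' are computed.
#'
#' @slot chainId single chain identifier.
#' @slot residueIndex integer vector of residue numbers (strictly increasing
#'   order as encountered in the source file; insertion codes are folded into
#'   the ordering).
#' @slot residueName character vector of one-letter amino-acid codes.
#' @slot atoms list, one element per residue: a numeric matrix with one row
#'   per heavy atom (rownames are atom names such as "CA", "CB") and columns
#'   x, y, z.
#'
#' @seealso [readStructure()], [cbDistanceMap()], [trueContacts()]
#' @export
setClass("MonomerStructure",
  representation(chainId = "character",
                 residueIndex = "integer",
                 residueName = "character",
                 atoms = "list"))

setValidity("MonomerStructure", function(object) {
  L <- length(object@atoms)
  if (L < 1L) return("structure must contain at least one residue")
  if (length(object@residueIndex) != L || length(object@residueName) != L)
    return("residueIndex, residueName and atoms must have equal length")
  if (is.unsorted(object@residueIndex, strictly = FALSE))
    return("residue indices must be non-decreasing")
  nat <- vapply(object@atoms, nrow, integer(1))
  if (any(nat < 1L)) return("every residue needs at least one heavy atom")
  ok <- vapply(object@atoms, function(a) is.matrix(a) && ncol(a) == 3 &&
                 all(is.finite(a)), logical(1))
  if (!all(ok)) return("atom coordinates must be finite n x 3 matrices")
  TRUE
})

#' MultipleSequenceAlignment: an A3M/FASTA alignment with organism tags
#'
#' Alignment rows after A3M insertion-state (lowercase) removal, so all rows
#' share the query's column space.  Organism tags (UniProt "OX=" taxonomy IDs
#' or a trailing bracketed binomial) drive heterodimer MSA pairing.
#'
#' @slot sequences character vector of aligned rows (uppercase + gap), the
#'   first row being the ungapped query.
#' @slot ids character vector of row identifiers.
#' @slot organism character vector of organism tags (`NA` where the row
#'   carries none).
#'
#' @seealso [readMSA()], [pairByTaxonomy()], [computeNeff()]
#' @export
setClass("MultipleSequenceAlignment",
  representation(sequences = "character",
                 ids = "character",
                 organism = "character"))

setValidity("MultipleSequenceAlignment", function(object) {
  n <- length(object@sequences)
  if (n < 1L) return("alignment needs at least one row")
  if (length(object@ids) != n || length(object@organism) != n)
    return("ids and organism must match the number of rows")
  w <- nchar(object@sequences)
  if (length(unique(w)) != 1L) return("ragged alignment")
  if (grepl("-", object@sequences[1L], fixed = TRUE))
    return("query row must be ungapped")
  TRUE
})

#' PositionSpecificScoringMatrix: per-position amino-acid log-odds profile
#'
#' @slot scores numeric L x 20 matrix of log-odds values; columns follow
#'   [PSSM_ALPHABET].
#'
#' @seealso [readPSSM()], [tilePSSM()]
#' @export
setClass("PositionSpecificScoringMatrix",
  representation(scores = "matrix"))

setValidity("PositionSpecificScoringMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s) || ncol(s) != 20L) return("scores must be an L x 20 matrix")
  if (nrow(s) < 1L) return("PSSM must cover at least one position")
  if (!all(is.finite(s))) return("PSSM values must be finite")
  TRUE
})

#' RankedContactList: ranked inter-chain contact predictions
#'
#' @slot entries data.frame with columns `i` (1-based residue in chain A),
#'   `j` (1-based residue in chain B) and `prob` (contact probability),
#'   sorted by non-increasing probability.
#'
#' @seealso [rankContacts()], [writeContactList()], [precisionAtK()]
#' @export
setClass("RankedContactList",
  representation(entries = "data.frame"))

setValidity("RankedContactList", function(object) {
  e <- object@entries
  if (!all(c("i", "j", "prob") %in% names(e)))
    return("entries needs columns i, j, prob")
  if (nrow(e) > 0) {
    if (any(e$prob < 0 | e$prob > 1)) return("probabilities must lie in [0,1]")
    if (is.unsorted(rev(e$prob))) return("entries must be sorted by descending probability")
    if (any(e$i < 1L | e$j < 1L)) return("indices are 1-based")
  }
  TRUE
})

#' PairedMSA: a concatenated heterodimer alignment
#'
#' Rows are the concatenation (width L1 + L2) of one row from each monomer
#' MSA, matched by organism; the first row is the concatenated query pair.
#'
#' @slot sequences character vector of concatenated aligned rows.
#' @slot provenance data.frame with columns `rowA`, `rowB`: the source row
#'   index in each monomer MSA (1 = query).
#' @slot pairingMethod `"taxonomy"` or `"identity"`.
#' @slot widthA number of columns contributed by chain A.
#'
#' @seealso [pairByTaxonomy()], [pairByTopIdentity()]
#' @export
setClass("PairedMSA",
  representation(sequences = "character",
                 provenance = "data.frame",
                 pairingMethod = "character",
                 widthA = "integer"))

setValidity("PairedMSA", function(object) {
  if (length(object@sequences) < 1L) return("paired MSA needs the query pair")
  if (nrow(object@provenance) != length(object@sequences))
    return("provenance must have one row per sequence")
  if (length(unique(nchar(object@sequences))) != 1L)
    return("ragged paired alignment")
  if (!object@pairingMethod %in% c("taxonomy", "identity"))
    return("pairingMethod must be 'taxonomy' or 'identity'")
  TRUE
})

#' CoevolutionFeatures: pairwise co-evolutionary input channels
#'
#' The coupling-score matrix (CCMpred-style pseudo-likelihood scores) and the
#' stack of 144 row-attention maps (MSA-transformer-style) computed from a
#' dimer MSA.  Both are ingested from files or synthesized; this package does
#' not run the external tools.
#'
#' @slot plm numeric L x L symmetric matrix of coupling scores.
#' @slot attention numeric L x L x 144 array of attention maps.
#'
#' @seealso [stackFeatures()], [readTensorArchive()]
#' @export
setClass("CoevolutionFeatures",
  representation(plm = "matrix", attention = "array"))

setValidity("CoevolutionFeatures", function(object) {
  p <- object@plm
  if (nrow(p) != ncol(p)) return("plm matrix must be square")
  if (!all(is.finite(p))) return("plm values must be finite")
  if (max(abs(p - t(p))) > 1e-8) return("plm matrix must be symmetric")
  a <- object@attention
  if (length(dim(a)) != 3L || dim(a)[3L] != N_ATTENTION_CHANNELS)
    return(sprintf("attention stack must have exactly %d channels",
                   N_ATTENTION_CHANNELS))
  if (dim(a)[1L] != nrow(p) || dim(a)[2L] != ncol(p))
    return("attention maps and plm matrix must share the side length")
  if (!all(is.finite(a))) return("attention values must be finite")
  TRUE
})

#' FeatureStack: the assembled L x L x 186 network input
#'
#' Channel layout (fixed, self-describing through `channelLayout`):
#' channel 1 the intra-chain Cb distance map (raw Angstrom; for heterodimers
#' the two monomer maps occupy the diagonal blocks and the inter-chain blocks
#' are zero), channel 2 the coupling-score matrix, channels 3-146 the 144
#' attention maps, channels 147-186 the 40 tiled PSSM channels.
#'
#' @slot tensor numeric n x n x 186 array, n = L (homodimer) or L1 + L2.
#' @slot dimerKind `"homodimer"` or `"heterodimer"`.
#' @slot lengths integer vector (L1, L2); L1 = L2 = L for homodimers.
#' @slot channelLayout named integer vector giving the number of channels per
#'   feature group, in tensor order.
#'
#' @seealso [stackFeatures()], [forwardPass()]
#' @export
setClass("FeatureStack",
  representation(tensor = "array",
                 dimerKind = "character",
                 lengths = "integer",
                 channelLayout = "integer"))

setValidity("FeatureStack", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L || d[3L] != N_INPUT_CHANNELS)
    return(sprintf("feature tensor must have %d channels", N_INPUT_CHANNELS))
  if (d[1L] != d[2L]) return("feature tensor must be square in space")
  if (!object@dimerKind %in% c("homodimer", "heterodimer"))
    return("dimerKind must be 'homodimer' or 'heterodimer'")
  l <- object@lengths
  if (length(l) != 2L) return("lengths must be (L1, L2)")
  side <- if (object@dimerKind == "homodimer") l[1L] else sum(l)
  if (object@dimerKind == "homodimer" && l[1L] != l[2L])
    return("homodimer lengths must be equal")
  if (side != d[1L]) return("tensor side must match the dimer lengths")
  if (sum(object@channelLayout) != N_INPUT_CHANNELS)
    return("channelLayout must sum to the channel count")
  if (object@dimerKind == "heterodimer") {
    dc <- object@tensor[, , 1L]
    i1 <- seq_len(l[1L]); i2 <- l[1L] + seq_len(l[2L])
    if (any(dc[i1, i2] != 0) || any(dc[i2, i1] != 0))
      return("heterodimer distance channel must be zero off the diagonal blocks")
  }
  TRUE
})

#' DistogramPrediction: dual-head distance-bin probability volumes
#'
#' The network's output: for every residue pair, a probability distribution
#' over 42 distance bins, predicted twice — once for the minimum heavy-atom
#' distance and once for the Cb-Cb distance.
#'
#' @slot heavyProbs numeric n x n x 42 array (heavy-atom head).
#' @slot cbProbs numeric n x n x 42 array (Cb head).
#' @slot lengths integer (L1, L2).
#'
#' @seealso [forwardPass()], [averageEnsemble()], [averageTwoOrders()],
#'   [contactMap()]
#' @export
setClass("DistogramPrediction",
  representation(heavyProbs = "array", cbProbs = "array", lengths = "integer"))

setValidity("DistogramPrediction", function(object) {
  for (nm in c("heavyProbs", "cbProbs")) {
    p <- slot(object, nm)
    d <- dim(p)
    if (length(d) != 3L || d[3L] != N_DISTANCE_BINS)
      return(sprintf("%s must have %d bins", nm, N_DISTANCE_BINS))
    if (d[1L] != d[2L]) return("probability volumes must be spatially square")
    if (any(p < -1e-8) || any(p > 1 + 1e-8)) return("probabilities must lie in [0,1]")
    s <- apply(p, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-5) return("each cell must be a normalized distribution")
  }
  if (!identical(dim(object@heavyProbs), dim(object@cbProbs)))
    return("the two heads must share a shape")
  TRUE
})

#' ContactScoreMap: inter-chain contact probabilities
#'
#' @slot scores numeric L1 x L2 matrix of contact probabilities.
#' @slot threshold contact distance threshold in Angstrom (8 by default).
#'
#' @seealso [contactMap()], [rankContacts()], [contactAUC()]
#' @export
setClass("ContactScoreMap",
  representation(scores = "matrix", threshold = "numeric"))

setValidity("ContactScoreMap", function(object) {
  s <- object@scores
  if (any(s < -1e-9 | s > 1 + 1e-9)) return("scores must lie in [0,1]")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 22)
    return("threshold must lie in (0, 22] Angstrom")
  TRUE
})

#' ContactGroundTruth: true inter-chain contacts of a dimer
#'
#' @slot minHeavyDistances numeric L1 x L2 matrix: per residue pair, the
#'   minimum over all heavy-atom pairs of the Euclidean distance (Angstrom).
#' @slot contacts logical L1 x L2 matrix: distance strictly below threshold.
#' @slot threshold Angstrom threshold (8 by default).
#'
#' @seealso [trueContacts()], [precisionAtK()], [contactAUC()]
#' @export
setClass("ContactGroundTruth",
  representation(minHeavyDistances = "matrix", contacts = "matrix",
                 threshold = "numeric"))

setValidity("ContactGroundTruth", function(object) {
  d <- object@minHeavyDistances
  if (any(d <= 0)) return("distances must be positive")
  if (!identical(dim(d), dim(object@contacts)))
    return("contacts and distances must share a shape")
  if (!identical(unname(object@contacts), unname(d < object@threshold)))
    return("contacts must equal (distance < threshold) exactly")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "MonomerStructure", function(object) {
  cat(sprintf("MonomerStructure chain %s: %d residues, %d heavy atoms\n",
              object@chainId, length(object@atoms),
              sum(vapply(object@atoms, nrow, integer(1)))))
})

setMethod("show", "MultipleSequenceAlignment", function(object) {
  cat(sprintf("MultipleSequenceAlignment: %d rows x %d columns (%d with organism tag)\n",
              length(object@sequences), nchar(object@sequences[1L]),
              sum(!is.na(object@organism))))
})

setMethod("show", "PositionSpecificScoringMatrix", function(object) {
  cat(sprintf("PositionSpecificScoringMatrix: %d positions x 20 residues\n",
              nrow(object@scores)))
})

setMethod("show", "RankedContactList", function(object) {
  cat(sprintf("RankedContactList: %d entries", nrow(object@entries)))
  if (nrow(object@entries) > 0)
    cat(sprintf(", top (%d, %d) p=%.3f", object@entries$i[1L],
                object@entries$j[1L], object@entries$prob[1L]))
  cat("\n")
})

setMethod("show", "PairedMSA", function(object) {
  cat(sprintf("PairedMSA (%s pairing): %d rows x %d columns\n",
              object@pairingMethod, length(object@sequences),
              nchar(object@sequences[1L])))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("FeatureStack (%s, L1=%d, L2=%d): %d x %d x %d\n  layout: %s\n",
              object@dimerKind, object@lengths[1L], object@lengths[2L],
              d[1L], d[2L], d[3L],
              paste(sprintf("%s(%d)", names(object@channelLayout),
                            object@channelLayout), collapse = " + ")))
})

setMethod("show", "DistogramPrediction", function(object) {
  d <- dim(object@heavyProbs)
  cat(sprintf("DistogramPrediction: %d x %d x %d (heavy-atom + Cb heads)\n",
              d[1L], d[2L], d[3L]))
})

setMethod("show", "ContactScoreMap", function(object) {
  cat(sprintf("ContactScoreMap: %d x %d, threshold %.1f A, max score %.3f\n",
              nrow(object@scores), ncol(object@scores), object@threshold,
              if (length(object@scores)) max(object@scores) else NA_real_))
})

setMethod("show", "ContactGroundTruth", function(object) {
  cat(sprintf("ContactGroundTruth: %d x %d pairs, %d contacts (< %.1f A)\n",
              nrow(object@contacts), ncol(object@contacts),
              sum(object@contacts), object@threshold))
})
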