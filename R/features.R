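## Feature assembly: intra-chain Cb distance channel, co-evolution channels
## and tiled PSSM channels stacked into the L x L x 186 network input
## ((L1+L2) x (L1+L2) x 186 for heterodimers).

#' Per-residue Cb coordinates with glycine Ca fallback
#'
#' @param structure a [MonomerStructure-class].
#' @return L x 3 matrix of coordinates.
#' @keywords internal
.cbCoords <- function(structure) {
  L <- nResidues(structure)
  out <- matrix(NA_real_, L, 3L)
  for (r in seq_len(L)) {
    xyz <- atomCoords(structure, r)
    if ("CB" %in% rownames(xyz)) out[r, ] <- xyz["CB", ]
    else if ("CA" %in% rownames(xyz)) out[r, ] <- xyz["CA", ]
    else stop("no reference atom: residue ", r, " lacks both CB and CA")
  }
  out
}

#' Intra-chain Cb-Cb distance map
#'
#' Euclidean distances between the Cb atoms of all residue pairs of one
#' monomer (Ca substitutes for glycine, the usual convention).  This matrix
#' is the structural input channel of the network.
#'
#' @param structure a [MonomerStructure-class].
#' @return Symmetric L x L matrix of distances in Angstrom, zero diagonal.
#' @examples
#' d <- generateToyDimer(8, 8, seed = 1)
#' m <- cbDistanceMap(d$structureA)
#' stopifnot(isSymmetric(m), all(diag(m) == 0))
#' @export
cbDistanceMap <- function(structure) {
  cb <- .cbCoords(structure)
  m <- as.matrix(stats::dist(cb))
  dimnames(m) <- NULL
  diag(m) <- 0
  m
}

#' Assemble the dimer distance channel
#'
#' For a homodimer the single monomer map is used unchanged.  For a
#' heterodimer the two monomer maps become the top-left (L1 x L1) and
#' bottom-right (L2 x L2) diagonal blocks of an (L1+L2) x (L1+L2) matrix and
#' the inter-chain blocks are set to zero — the network must infer the
#' inter-chain geometry, it is never given it.
#'
#' @param mapA intra-chain distance map of chain A.
#' @param mapB optional intra-chain distance map of chain B (heterodimer).
#' @return The assembled square matrix.
#' @export
assembleDimerDistanceChannel <- function(mapA, mapB = NULL) {
  if (is.null(mapB)) return(mapA)
  l1 <- nrow(mapA); l2 <- nrow(mapB)
  out <- matrix(0, l1 + l2, l1 + l2)
  out[seq_len(l1), seq_len(l1)] <- mapA
  out[l1 + seq_len(l2), l1 + seq_len(l2)] <- mapB
  out
}

#' Tile a PSSM into pairwise sequential features
#'
#' Cross-concatenates the per-position profiles element by element:
#' `out[i, j, ] = c(row_i, row_j)` over the (for heterodimers, vertically
#' concatenated) PSSM rows, giving n x n x 40 sequential features.
#'
#' @param pssmA [PositionSpecificScoringMatrix-class] of chain A.
#' @param pssmB optional PSSM of chain B (heterodimer; rows are concatenated
#'   below chain A's).
#' @return n x n x 40 numeric array.
#' @export
tilePSSM <- function(pssmA, pssmB = NULL) {
  rows <- pssmScores(pssmA)
  if (!is.null(pssmB)) rows <- rbind(rows, pssmScores(pssmB))
  n <- nrow(rows)
  out <- array(0, c(n, n, 40L))
  for (c in 1:20) {
    out[, , c] <- matrix(rows[, c], n, n, byrow = FALSE)        # row_i part
    out[, , 20L + c] <- matrix(rows[, c], n, n, byrow = TRUE)   # row_j part
  }
  out
}

#' Stack all input channels into a FeatureStack
#'
#' Concatenates, in fixed order, the distance channel (1), the
#' coupling-score channel (1), the 144 attention maps and the 40 tiled PSSM
#' channels into the n x n x 186 network input.  Distances are passed
#' through raw (Angstrom) and attention maps unmodified; normalization is
#' the network's job (RCIN).
#'
#' @param distChannel square matrix from [assembleDimerDistanceChannel()].
#' @param coevo a [CoevolutionFeatures-class] with matching side length.
#' @param pssmTile n x n x 40 array from [tilePSSM()].
#' @param lengths integer (L1, L2); equal for homodimers.
#' @param dimerKind `"homodimer"` or `"heterodimer"`.
#' @return A [FeatureStack-class] object.
#' @export
stackFeatures <- function(distChannel, coevo, pssmTile, lengths,
                          dimerKind = c("homodimer", "heterodimer")) {
  dimerKind <- match.arg(dimerKind)
  n <- nrow(distChannel)
  if (ncol(distChannel) != n)
    stop("feature length mismatch: distance channel must be square")
  if (nrow(coevo@plm) != n || dim(pssmTile)[1L] != n || dim(pssmTile)[2L] != n)
    stop("feature length mismatch: all inputs must share the side length ", n)
  if (dim(pssmTile)[3L] != N_PSSM_CHANNELS)
    stop("feature length mismatch: PSSM tile must have 40 channels")
  tensor <- array(0, c(n, n, N_INPUT_CHANNELS))
  tensor[, , 1L] <- distChannel
  tensor[, , 2L] <- coevo@plm
  tensor[, , 2L + seq_len(N_ATTENTION_CHANNELS)] <- coevo@attention
  tensor[, , 2L + N_ATTENTION_CHANNELS + seq_len(N_PSSM_CHANNELS)] <- pssmTile
  layout <- c(distance = 1L, plm = 1L, attention = N_ATTENTION_CHANNELS,
              pssm = N_PSSM_CHANNELS)
  stopifnot(sum(layout) == N_INPUT_CHANNELS)
  new("FeatureStack", tensor = tensor, dimerKind = dimerKind,
      lengths = as.integer(lengths), channelLayout = layout)
}

#' Assemble a FeatureStack directly from structures, PSSMs and co-evolution
#' features
#'
#' Convenience wrapper chaining [cbDistanceMap()],
#' [assembleDimerDistanceChannel()], [tilePSSM()] and [stackFeatures()].
#' Supply only chain A for a homodimer.
#'
#' @param structureA,structureB [MonomerStructure-class] objects
#'   (`structureB = NULL` for a homodimer).
#' @param pssmA,pssmB PSSMs matching the structures.
#' @param coevo [CoevolutionFeatures-class] for the dimer.
#' @return A [FeatureStack-class].
#' @export
buildFeatureStack <- function(structureA, pssmA, coevo,
                              structureB = NULL, pssmB = NULL) {
  hetero <- !is.null(structureB)
  if (hetero != !is.null(pssmB))
    stop("feature length mismatch: provide both or neither of structureB/pssmB")
  mapA <- cbDistanceMap(structureA)
  mapB <- if (hetero) cbDistanceMap(structureB) else NULL
  if (nrow(pssmScores(pssmA)) != nrow(mapA))
    stop("feature length mismatch: PSSM A vs structure A")
  if (hetero && nrow(pssmScores(pssmB)) != nrow(mapB))
    stop("feature length mismatch: PSSM B vs structure B")
  dist <- assembleDimerDistanceChannel(mapA, mapB)
  tile <- tilePSSM(pssmA, pssmB)
  lengths <- if (hetero) c(nrow(mapA), nrow(mapB)) else rep(nrow(mapA), 2L)
  stackFeatures(dist, coevo, tile, lengths,
                if (hetero) "heterodimer" else "homodimer")
}
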