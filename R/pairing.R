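## Heterodimer MSA pairing and alignment-depth (Neff) diagnostics.
## Two monomer MSAs are joined into one dimer MSA by matching rows across
## organisms; within an organism the row most similar to the query wins.

#' Sequence identity of each MSA row to the query
#'
#' Identity is computed over the query's column space (all columns, since the
#' query is ungapped after A3M processing); gaps count as mismatches.
#'
#' @param msa a [MultipleSequenceAlignment-class].
#' @return Numeric vector of identities in `[0, 1]`, one per row.
#' @export
identityToQuery <- function(msa) {
  rows <- msaRows(msa)
  q <- strsplit(rows[1L], "")[[1]]
  vapply(rows, function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v == q & v != "-")
  }, numeric(1), USE.NAMES = FALSE)
}

## per organism tag, the row index with the highest identity to the query
## (ties -> earlier row); query row (1) and untagged rows are excluded
.bestRowPerSpecies <- function(msa) {
  org <- organismTags(msa)
  ident <- identityToQuery(msa)
  cand <- which(!is.na(org) & seq_along(org) > 1L)
  best <- integer(0)
  for (sp in unique(org[cand])) {
    idx <- cand[org[cand] == sp]
    best[sp] <- idx[which.max(ident[idx])]
  }
  best
}

.pairMSAs <- function(msaA, msaB, method) {
  bestA <- .bestRowPerSpecies(msaA)
  bestB <- .bestRowPerSpecies(msaB)
  shared <- intersect(names(bestA), names(bestB))
  shared <- shared[order(match(shared, names(bestA)))]   # stable, deterministic
  rowsA <- c(1L, unname(bestA[shared]))
  rowsB <- c(1L, unname(bestB[shared]))
  seqs <- paste0(msaRows(msaA)[rowsA], msaRows(msaB)[rowsB])
  new("PairedMSA", sequences = seqs,
      provenance = data.frame(rowA = rowsA, rowB = rowsB),
      pairingMethod = method, widthA = msaWidth(msaA))
}

#' Pair two monomer MSAs by organism taxonomy
#'
#' For every organism tag present in both alignments exactly one concatenated
#' row is emitted, built from the highest-identity-to-query row on each side
#' (FoldDock-style, the training-phase procedure).  The concatenated query
#' pair always comes first; untagged rows are ignored, and no shared
#' organisms yields a query-only paired MSA.
#'
#' @param msaA,msaB [MultipleSequenceAlignment-class] objects for the two
#'   monomers.
#' @return A [PairedMSA-class] with `pairingMethod = "taxonomy"`.
#' @export
pairByTaxonomy <- function(msaA, msaB) .pairMSAs(msaA, msaB, "taxonomy")

#' Pair two monomer MSAs by per-species top identity
#'
#' Per species, the single row with the highest sequence identity to the
#' monomer query is selected from each MSA and the two are concatenated
#' (EvComplex2-style, the test-phase procedure).  Species represented on
#' only one side contribute nothing.
#'
#' @inheritParams pairByTaxonomy
#' @return A [PairedMSA-class] with `pairingMethod = "identity"`.
#' @export
pairByTopIdentity <- function(msaA, msaB) .pairMSAs(msaA, msaB, "identity")

#' Write a paired MSA as FASTA plus a provenance sidecar
#'
#' @param paired a [PairedMSA-class].
#' @param file FASTA output path; the provenance table goes to
#'   `paste0(file, ".prov.tsv")`.
#' @return `file`, invisibly.
#' @export
writePairedMSA <- function(paired, file) {
  ids <- c("query_pair", paste0("pair_", seq_len(max(0L, length(paired@sequences) - 1L))))
  writeLines(paste0(">", ids[seq_along(paired@sequences)], "\n",
                    paired@sequences), file)
  utils::write.table(paired@provenance, paste0(file, ".prov.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Effective number of sequences (Neff)
#'
#' The standard alignment-depth measure: each row is down-weighted by the
#' size of its similarity cluster, `Neff = sum_i 1 / |{j : id(i, j) >=
#' threshold}|`, with pairwise identity counted over matching non-gap
#' characters across all alignment columns.
#'
#' @param msa a [MultipleSequenceAlignment-class] or [PairedMSA-class].
#' @param identityThreshold clustering threshold (default 0.8, the community
#'   convention).
#' @return Neff, a value in `[1, nrow]`.
#' @export
computeNeff <- function(msa, identityThreshold = 0.8) {
  rows <- msaRows(msa)
  n <- length(rows)
  if (n == 1L) return(1.0)
  w <- nchar(rows[1L])
  m <- matrix(unlist(strsplit(rows, "")), nrow = n, byrow = TRUE)
  gap <- m == "-"
  cluster <- integer(n)
  for (i in seq_len(n)) {
    same <- sweep(m, 2L, m[i, ], "==") & !gap
    ident <- rowSums(same) / w
    cluster[i] <- sum(ident >= identityThreshold)
  }
  sum(1 / cluster)
}
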