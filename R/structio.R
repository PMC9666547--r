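## Readers/writers for the standard formats the pipeline touches: PDB
## structures, A3M/FASTA alignments, PSI-BLAST ASCII PSSMs, CASP-RR-like
## contact lists, and RDS tensor archives for precomputed features.
## All serialized indices are 1-based (PDB / CASP convention).

#' Construct a MonomerStructure
#'
#' @param chainId single chain identifier.
#' @param residueIndex integer vector of residue numbers.
#' @param residueName one-letter amino-acid codes.
#' @param atoms list of per-residue heavy-atom coordinate matrices (rows named
#'   by atom, columns x/y/z in Angstrom).
#' @return A [MonomerStructure-class] object.
#' @export
MonomerStructure <- function(chainId, residueIndex, residueName, atoms) {
  new("MonomerStructure", chainId = as.character(chainId),
      residueIndex = as.integer(residueIndex),
      residueName = as.character(residueName), atoms = atoms)
}

#' Construct a MultipleSequenceAlignment
#'
#' @param sequences aligned rows (first row the ungapped query).
#' @param ids row identifiers (defaults to `seq_*`).
#' @param organism organism tags, `NA` where absent.
#' @return A [MultipleSequenceAlignment-class] object.
#' @export
MultipleSequenceAlignment <- function(sequences,
                                      ids = paste0("seq_", seq_along(sequences)),
                                      organism = rep(NA_character_,
                                                     length(sequences))) {
  new("MultipleSequenceAlignment", sequences = toupper(sequences),
      ids = as.character(ids), organism = as.character(organism))
}

#' Construct a PositionSpecificScoringMatrix
#'
#' @param scores numeric L x 20 matrix in [PSSM_ALPHABET] column order.
#' @return A [PositionSpecificScoringMatrix-class] object.
#' @export
PositionSpecificScoringMatrix <- function(scores) {
  scores <- as.matrix(scores)
  colnames(scores) <- PSSM_ALPHABET[seq_len(min(20L, ncol(scores)))]
  new("PositionSpecificScoringMatrix", scores = scores)
}

#' Construct a RankedContactList
#'
#' Entries are re-sorted by descending probability with lexicographic (i, j)
#' tie-breaking, so construction is always valid.
#'
#' @param i,j 1-based residue indices (chain A, chain B).
#' @param prob contact probabilities in `[0, 1]`.
#' @return A [RankedContactList-class] object.
#' @export
RankedContactList <- function(i = integer(), j = integer(), prob = numeric()) {
  e <- data.frame(i = as.integer(i), j = as.integer(j), prob = as.numeric(prob))
  e <- e[order(-e$prob, e$i, e$j), , drop = FALSE]
  rownames(e) <- NULL
  new("RankedContactList", entries = e)
}

#' Construct CoevolutionFeatures
#'
#' @param plm L x L symmetric coupling-score matrix.
#' @param attention L x L x 144 row-attention stack.
#' @return A [CoevolutionFeatures-class] object.
#' @export
CoevolutionFeatures <- function(plm, attention) {
  new("CoevolutionFeatures", plm = as.matrix(plm), attention = attention)
}

## hydrogen test on a bio3d atom table row: element symbol when present,
## otherwise the PDB atom-name convention (optional leading digit, then H)
.isHydrogen <- function(elety, elesy) {
  sy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  known <- sy %in% c("H", "D")
  unknown <- sy == ""
  byname <- grepl("^[0-9]?[HD]", toupper(trimws(elety)))
  known | (unknown & byname)
}

#' Read one chain of a PDB file into a MonomerStructure
#'
#' Parses ATOM records via [bio3d::read.pdb()], keeps the requested chain,
#' drops hydrogens, resolves alternate locations to the highest-occupancy
#' copy (ties broken by first occurrence) and preserves insertion-code
#' ordering.  Residues are returned in file (sequence) order.
#'
#' @param pdb PDB text (any string containing a newline or an ATOM record) or
#'   a path to a PDB file.
#' @param chain chain identifier to extract.
#' @return A [MonomerStructure-class] object.
#' @examples
#' pdb <- paste(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
#'   sep = "\n")
#' readStructure(pdb, "A")
#' @export
readStructure <- function(pdb, chain) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb) || grepl("^(ATOM|HETATM|HEADER)", pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
  }
  p <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                        rm.alt = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!chain %in% at$chain) stop("chain not found: ", chain)
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[!.isHydrogen(at$elety, at$elesy), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no heavy atoms for chain ", chain)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  reskey <- paste(at$resno, ins, sep = "|")
  keys <- unique(reskey)            # file order, insertion codes preserved
  resno <- integer(0); resnm <- character(0); atoms <- list()
  for (k in keys) {
    rows <- at[reskey == k, , drop = FALSE]
    # altloc: per atom name keep the highest occupancy, first occurrence wins ties
    keep <- !logical(nrow(rows))
    if (any(nzchar(ifelse(is.na(rows$alt), "", rows$alt)))) {
      occ <- ifelse(is.na(rows$o), 1, rows$o)
      keep <- rep(FALSE, nrow(rows))
      for (nm in unique(rows$elety)) {
        idx <- which(rows$elety == nm)
        keep[idx[which.max(occ[idx])]] <- TRUE
      }
    }
    rows <- rows[keep, , drop = FALSE]
    xyz <- cbind(x = rows$x, y = rows$y, z = rows$z)
    rownames(xyz) <- make.unique(trimws(rows$elety))
    resno <- c(resno, rows$resno[1L])
    resnm <- c(resnm, bio3d::aa321(rows$resid[1L]))
    atoms <- c(atoms, list(xyz))
  }
  if (length(atoms) == 0L) stop("empty structure: no parsable residues")
  MonomerStructure(chain, resno, resnm, atoms)
}

#' Write a MonomerStructure as PDB text
#'
#' Emits fixed-column ATOM records (heavy atoms only, by construction) that
#' round-trip through [readStructure()].
#'
#' @param structure a [MonomerStructure-class].
#' @param file optional path; when given the text is also written there.
#' @return The PDB text, invisibly when `file` is given.
#' @export
writeStructure <- function(structure, file = NULL) {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(nResidues(structure))) {
    xyz <- atomCoords(structure, r)
    res3 <- bio3d::aa123(residueNames(structure)[r])
    if (is.na(res3) || !nzchar(res3)) res3 <- "UNK"
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      nm <- rownames(xyz)[a]
      el <- substr(gsub("[^A-Za-z].*$", "", nm), 1L, 1L)
      nmfmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else substr(nm, 1L, 4L)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nmfmt, res3, chainId(structure),
        residueIndices(structure)[r], xyz[a, 1L], xyz[a, 2L], xyz[a, 3L],
        1, 0, el))
    }
  }
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

.parseFasta <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) && length(lines)) {       # bare alignment, one row per line
    return(list(ids = paste0("seq_", seq_along(lines)),
                desc = rep("", length(lines)), seqs = trimws(lines)))
  }
  starts <- which(hdr)
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(0); desc <- character(0); seqs <- character(0)
  for (s in seq_along(starts)) {
    h <- sub("^>", "", lines[starts[s]])
    ids <- c(ids, strsplit(trimws(h), "\\s+")[[1]][1])
    desc <- c(desc, trimws(h))
    body <- if (ends[s] >= starts[s] + 1L)
      paste(lines[(starts[s] + 1L):ends[s]], collapse = "") else ""
    seqs <- c(seqs, gsub("\\s", "", body))
  }
  list(ids = ids, desc = desc, seqs = seqs)
}

.organismFromHeader <- function(desc) {
  ox <- regmatches(desc, regexpr("OX=([0-9]+)", desc))
  if (length(ox) && nzchar(ox)) return(sub("OX=", "", ox))
  br <- regmatches(desc, regexpr("\\[([^][]+)\\]\\s*$", desc))
  if (length(br) && nzchar(br)) return(gsub("^\\[|\\]\\s*$", "", br))
  NA_character_
}

#' Read an A3M/FASTA multiple sequence alignment
#'
#' Lowercase insertion-state columns are removed (A3M convention), after
#' which all rows must match the query width.  Organism tags are parsed from
#' UniProt-style `OX=<taxid>` fields or a trailing bracketed binomial in the
#' header; rows without either simply carry no tag.
#'
#' @param text A3M/FASTA text or a file path.
#' @return A [MultipleSequenceAlignment-class] object; the first row is the
#'   query.
#' @export
readMSA <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && !grepl("^>", text) &&
      file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  p <- .parseFasta(text)
  if (length(p$seqs) == 0L) stop("empty alignment")
  seqs <- gsub("[a-z.]", "", p$seqs)     # strip insertion states
  seqs <- gsub("\\*", "", seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: rows differ in width after insertion removal")
  org <- vapply(p$desc, .organismFromHeader, character(1), USE.NAMES = FALSE)
  MultipleSequenceAlignment(seqs, p$ids, org)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard `psiblast -out_ascii_pssm` layout: one row per query
#' position carrying the position number, the query residue and 20 log-odds
#' columns in [PSSM_ALPHABET] order.  Trailing weighted-percentage and
#' information-content columns are ignored.
#'
#' @param text PSSM text or a file path.
#' @return A [PositionSpecificScoringMatrix-class] object.
#' @export
readPSSM <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2L) next
    if (!grepl("^[0-9]+$", f[1L]) || !grepl("^[A-Za-z]$", f[2L])) next
    if (length(f) < 22L) stop("malformed PSSM: fewer than 20 score columns")
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (any(is.na(v))) stop("malformed PSSM: non-numeric score column")
    rows[[length(rows) + 1L]] <- v
  }
  if (length(rows) == 0L) stop("malformed PSSM: no score rows found")
  PositionSpecificScoringMatrix(do.call(rbind, rows))
}

#' Write a ranked contact list in CASP-RR-like text
#'
#' Each entry becomes a line `i j 0 8 prob`, sorted by descending
#' probability; an empty list yields header-only output.  Round-trips
#' through [readContactList()].
#'
#' @param contacts a [RankedContactList-class].
#' @param file optional output path.
#' @return The text, invisibly when `file` is given.
#' @export
writeContactList <- function(contacts, file = NULL) {
  e <- contactEntries(contacts)
  body <- if (nrow(e)) sprintf("%d %d 0 8 %.6f", e$i, e$j, e$prob) else character(0)
  txt <- paste(c("PFRMAT RR", body, "END"), collapse = "\n")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Read a CASP-RR-like contact list
#'
#' @param text contact-list text or a file path.
#' @return A [RankedContactList-class] object.
#' @export
readContactList <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[grepl("^\\s*[0-9]", lines)]
  if (!length(lines)) return(RankedContactList())
  f <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x)
    as.numeric(x[c(1, 2, length(x))])))
  RankedContactList(i = f[, 1L], j = f[, 2L], prob = f[, 3L])
}

#' Write named arrays to a tensor archive
#'
#' A self-describing container (RDS) holding named numeric arrays plus shape
#' and channel-layout metadata, used for precomputed co-evolution features,
#' feature stacks and model checkpoints.
#'
#' @param arrays named list of numeric arrays/matrices.
#' @param file output path.
#' @param metadata optional named list stored alongside (e.g. channel layout).
#' @return `file`, invisibly.
#' @export
writeTensorArchive <- function(arrays, file, metadata = list()) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  obj <- list(format = "dimernet-tensor-archive/1",
              shapes = lapply(arrays, function(a) dim(a) %||% length(a)),
              metadata = metadata, arrays = arrays)
  saveRDS(obj, file)
  invisible(file)
}

#' Read a tensor archive
#'
#' @param file path written by [writeTensorArchive()].
#' @return List with elements `arrays`, `metadata`, `shapes`.
#' @export
readTensorArchive <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "dimernet-tensor-archive/1"))
    stop("not a dimernet tensor archive: ", file)
  for (nm in names(obj$arrays)) {
    d <- dim(obj$arrays[[nm]]) %||% length(obj$arrays[[nm]])
    if (!identical(as.integer(d), as.integer(obj$shapes[[nm]])))
      stop("corrupt tensor archive: shape mismatch for ", nm)
  }
  obj
}

#' Load CoevolutionFeatures from a tensor archive
#'
#' Expects arrays named `plm` (L x L) and `attention` (L x L x 144).
#'
#' @param file archive path.
#' @return A [CoevolutionFeatures-class] object.
#' @export
readCoevolutionFeatures <- function(file) {
  obj <- readTensorArchive(file)
  if (!all(c("plm", "attention") %in% names(obj$arrays)))
    stop("archive must contain 'plm' and 'attention' arrays")
  CoevolutionFeatures(obj$arrays$plm, obj$arrays$attention)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
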