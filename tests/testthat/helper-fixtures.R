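# Shared fixtures and independent brute-force oracles.  Fixtures are built
# in code; oracles are deliberately naive (double loops, exhaustive
# enumeration) and never share code with the implementation they check.

pdbLine <- function(serial, name, res3, chain, resno, x, y, z, occ = 1,
                    element = substr(name, 1, 1), alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, res3, chain, resno, x, y, z, occ, 0, element)
}

# two-residue ALA chain with CB at given coordinates
twoResiduePdb <- function(cb1 = c(0, 0, 0), cb2 = c(3.8, 0, 0)) {
  paste(
    pdbLine(1, "CA", "ALA", "A", 1, cb1[1] - 1, cb1[2], cb1[3]),
    pdbLine(2, "CB", "ALA", "A", 1, cb1[1], cb1[2], cb1[3]),
    pdbLine(3, "CA", "ALA", "A", 2, cb2[1] - 1, cb2[2], cb2[3]),
    pdbLine(4, "CB", "ALA", "A", 2, cb2[1], cb2[2], cb2[3]),
    "END", sep = "\n")
}

# random normalized distogram volumes for a given side length
randomDistogram <- function(n, seed, lengths = c(n, n)) {
  set.seed(seed)
  mk <- function() {
    v <- array(stats::rexp(n * n * 42), c(n, n, 42))
    s <- apply(v, c(1, 2), sum)
    v / array(s, c(n, n, 42))
  }
  new("DistogramPrediction", heavyProbs = mk(), cbProbs = mk(),
      lengths = as.integer(lengths))
}

# probability volume with all mass in one bin (0-based) everywhere
oneHotDistogram <- function(n, bin, lengths = c(n, n)) {
  v <- array(0, c(n, n, 42))
  v[, , bin + 1] <- 1
  new("DistogramPrediction", heavyProbs = v, cbProbs = v,
      lengths = as.integer(lengths))
}

# ---- brute-force metric oracles --------------------------------------------

bfPrecisionAtK <- function(entries, truthMat, k) {
  k <- min(k, nrow(entries))
  hits <- 0
  for (r in seq_len(k))
    if (truthMat[entries$i[r], entries$j[r]]) hits <- hits + 1
  hits / k
}

bfAccuracyOrder <- function(entries, truthMat, totalResidues) {
  for (r in seq_len(nrow(entries)))
    if (truthMat[entries$i[r], entries$j[r]])
      return(1000 * r / totalResidues)
  NA_real_
}

bfAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

bfMinHeavyDistance <- function(atomsA, atomsB) {
  best <- Inf
  for (a in seq_len(nrow(atomsA))) for (b in seq_len(nrow(atomsB)))
    best <- min(best, sqrt(sum((atomsA[a, ] - atomsB[b, ])^2)))
  best
}

# single-residue structure with explicit atoms
oneResidueStructure <- function(chain, atoms, aa = "A") {
  MonomerStructure(chain, 1L, aa, list(atoms))
}

namedAtoms <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("x", "y", "z")
  m
}
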