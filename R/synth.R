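## Synthetic fixture generator: toy dimer geometries with a genuine
## interface, MSAs with species tags, and co-evolution channels carrying a
## plantable inter-chain signal.  Everything is a pure function of its seed.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## idealized helical backbone: Ca on a helix (radius 2.3 A, rise 1.5 A/res,
## 100 deg/res), Cb and a pseudo side-chain atom CG displaced outward.
.helixChain <- function(l, chain, jitterSd, mirrorShift = NULL, phase = 0) {
  t <- seq_len(l) - 1L
  th <- phase + t * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * t)
  u <- cbind(cos(th), sin(th), 0)
  cb <- ca + 1.55 * u
  cg <- ca + 2.9 * u + cbind(0, 0, rep(0.4, l))
  coords <- list(CA = ca, CB = cb, CG = cg)
  if (!is.null(mirrorShift)) {
    # mirror in x and translate: the side chains face the partner chain
    coords <- lapply(coords, function(m)
      cbind(mirrorShift[1L] - m[, 1L], m[, 2L] + mirrorShift[2L],
            m[, 3L] + mirrorShift[3L]))
  }
  coords <- lapply(coords, function(m)
    m + matrix(stats::rnorm(3L * l, sd = jitterSd), l, 3L))
  atoms <- lapply(seq_len(l), function(r) {
    xyz <- rbind(CA = coords$CA[r, ], CB = coords$CB[r, ], CG = coords$CG[r, ])
    colnames(xyz) <- c("x", "y", "z")
    xyz
  })
  MonomerStructure(chain, seq_len(l),
                   sample(setdiff(.AA20, "G"), l, replace = TRUE), atoms)
}

#' Generate a toy dimer with a genuine interface
#'
#' Two idealized helical chains (three pseudo-heavy atoms per residue: CA,
#' CB and an outward CG, so minimum-heavy-atom and Cb-Cb distances differ
#' measurably) are placed side by side with small coordinate jitter.  The
#' helix phases and the axial offset between the chains are drawn from the
#' seed, so the interface patch sits at a different residue range in every
#' dimer — the inter-chain docking pose is not predictable from the
#' intra-chain geometry, as in real data.  The inter-axis distance is
#' reduced in bounded steps until the interface carries at least
#' `max(2, min(l1, l2) / 4)` residue pairs under 8 Angstrom.
#' Bit-identical regeneration from the seed.
#'
#' @param l1,l2 chain lengths (at least 4).
#' @param seed integer seed.
#' @return A `SyntheticDimer` list: `structureA`, `structureB`, `truth`
#'   ([ContactGroundTruth-class]), `l1`, `l2`, `seed`.
#' @export
generateToyDimer <- function(l1, l2, seed) {
  stopifnot(l1 >= 4L, l2 >= 4L)
  need <- max(2L, floor(min(l1, l2) / 4))
  withSeed(seed, {
    phaseA <- stats::runif(1, 0, 2 * pi)
    phaseB <- stats::runif(1, 0, 2 * pi)
    zoff <- 1.5 * (l1 - l2) / 2 +
      stats::runif(1, -0.25, 0.25) * 1.5 * min(l1, l2)
    dimer <- NULL
    for (d in seq(9.5, 6, by = -0.5)) {
      a <- .helixChain(l1, "A", jitterSd = 0.15, phase = phaseA)
      b <- .helixChain(l2, "B", jitterSd = 0.15, mirrorShift = c(d, 0, zoff),
                       phase = phaseB)
      truth <- trueContacts(a, b)
      if (sum(truthContacts(truth)) >= need) {
        dimer <- list(structureA = a, structureB = b, truth = truth,
                      l1 = as.integer(l1), l2 = as.integer(l2),
                      seed = as.integer(seed))
        break
      }
    }
    if (is.null(dimer))
      stop("toy dimer placement failed: no interface of ", need,
           " contacts found")
    class(dimer) <- "SyntheticDimer"
    dimer
  })
}

#' @export
print.SyntheticDimer <- function(x, ...) {
  cat(sprintf("SyntheticDimer (seed %d): chains %d + %d, %d true contacts\n",
              x$seed, x$l1, x$l2, sum(truthContacts(x$truth))))
  invisible(x)
}

#' Interface density (analytic random-ranking baseline)
#'
#' The fraction of inter-chain residue pairs that are true contacts — the
#' expected precision of a uniformly random ranking at any depth.
#'
#' @param truth a [ContactGroundTruth-class].
#' @return Contact density in `[0, 1]`.
#' @export
interfaceDensity <- function(truth) {
  mean(truthContacts(truth))
}

## 3x3 zero-padded box blur
.boxBlur3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  p <- matrix(0, n1 + 2L, n2 + 2L)
  p[1L + seq_len(n1), 1L + seq_len(n2)] <- m
  out <- matrix(0, n1, n2)
  for (di in 0:2) for (dj in 0:2)
    out <- out + p[di + seq_len(n1), dj + seq_len(n2)]
  out / 9
}

## symmetric uniform noise matrix
.symNoise <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

## minimum heavy-atom distance matrix including intra-chain pairs (internal;
## unlike trueContacts this tolerates the zero diagonal)
.fullDistances <- function(dimer) {
  sAll <- list(dimer$structureA, dimer$structureB)
  n <- dimer$l1 + dimer$l2
  cb <- rbind(.cbCoords(dimer$structureA), .cbCoords(dimer$structureB))
  cbFull <- as.matrix(stats::dist(cb)); dimnames(cbFull) <- NULL
  heavyFull <- matrix(0, n, n)
  off <- c(0L, dimer$l1)
  for (p in 1:2) for (q in 1:2) {
    if (p == q) {
      s <- sAll[[p]]
      md <- matrix(0, nResidues(s), nResidues(s))
      for (i in seq_len(nResidues(s))) for (j in seq_len(nResidues(s))) {
        if (i == j) next
        dd <- sqrt(outer(rowSums(atomCoords(s, i)^2),
                         rowSums(atomCoords(s, j)^2), `+`) -
                     2 * tcrossprod(atomCoords(s, i), atomCoords(s, j)))
        md[i, j] <- min(dd)
      }
    } else {
      md <- truthDistances(trueContacts(sAll[[p]], sAll[[q]]))
    }
    heavyFull[off[p] + seq_len(nrow(md)), off[q] + seq_len(ncol(md))] <- md
  }
  list(heavy = heavyFull, cb = cbFull)
}

#' Generate synthetic network inputs with planted inter-chain signal
#'
#' Builds a complete training example from a toy dimer.  The distance
#' channel is computed from the monomer structures exactly as the real
#' pipeline would.  The coupling-score channel and the first 8 attention
#' channels carry `snr * signal + (1 - snr) * noise`, where the signal is
#' built from an *observed* contact indicator emulating shallow-MSA
#' co-evolution: each true contact is visible with probability `snr`, and
#' `round((1 - snr) * n_true)` spurious contacts are planted on
#' non-contact cells.  The observed indicator is drawn once per example
#' and shared by all signal channels (so channel averaging cannot undo the
#' corruption), then augmented with a scaled 3x3 neighbourhood blur;
#' observed cells saturate at 1, so `snr = 1` (nothing hidden, nothing
#' spurious) separates true contacts perfectly while `snr = 0` carries no
#' information.  The remaining 136 attention channels and the PSSM
#' channels are pure noise, so the SE channel attention has a genuine
#' selection task.  Labels are the discretized true minimum-heavy-atom and
#' Cb-Cb distances; the mask is the inter-chain mask.
#'
#' @param dimer a [generateToyDimer()] result.
#' @param snr signal fraction in `[0, 1]`.
#' @param seed integer seed for the noise draws.
#' @return List with `stack` ([FeatureStack-class]), `heavyBins`, `cbBins`,
#'   `mask`, `snr`, `dimer`.
#' @export
generateSyntheticFeatures <- function(dimer, snr = 0.8, seed = 0L) {
  stopifnot(snr >= 0, snr <= 1)
  l1 <- dimer$l1; l2 <- dimer$l2; n <- l1 + l2
  withSeed(seed, {
    tc <- truthContacts(dimer$truth)
    # observed indicator: true contacts visible with prob snr, plus
    # round((1 - snr) * ntrue) spurious contacts on non-contact cells
    obs <- tc & (matrix(stats::runif(l1 * l2), l1, l2) < snr | snr == 1)
    nSpur <- round((1 - snr) * sum(tc))
    free <- which(!tc)
    if (nSpur > 0 && length(free) > 0)
      obs[free[sample.int(length(free), min(nSpur, length(free)))]] <- TRUE
    contacts <- matrix(0, n, n)
    contacts[seq_len(l1), l1 + seq_len(l2)] <- obs + 0
    contacts[l1 + seq_len(l2), seq_len(l1)] <- t(obs + 0)
    signal <- pmin(1, contacts + 0.49 * .boxBlur3(contacts))
    plm <- snr * signal + (1 - snr) * .symNoise(n)
    att <- array(stats::runif(n * n * N_ATTENTION_CHANNELS),
                 c(n, n, N_ATTENTION_CHANNELS))
    for (c in 1:8)
      att[, , c] <- pmin(1, pmax(0, snr * signal +
                                   (1 - snr) * matrix(stats::runif(n * n), n, n)))
    pssmA <- PositionSpecificScoringMatrix(matrix(stats::rnorm(l1 * 20), l1, 20))
    pssmB <- PositionSpecificScoringMatrix(matrix(stats::rnorm(l2 * 20), l2, 20))
    dist <- assembleDimerDistanceChannel(cbDistanceMap(dimer$structureA),
                                         cbDistanceMap(dimer$structureB))
    stack <- stackFeatures(dist, CoevolutionFeatures(plm, att),
                           tilePSSM(pssmA, pssmB), c(l1, l2), "heterodimer")
    fd <- .fullDistances(dimer)
    list(stack = stack, heavyBins = discretizeDistance(fd$heavy),
         cbBins = discretizeDistance(fd$cb),
         mask = buildInterchainMask(l1, l2), snr = snr, dimer = dimer)
  })
}

#' Generate a pair of synthetic MSAs with controllable species overlap
#'
#' A random query per chain; homolog rows mutate each position
#' independently at `mutationRate` (replacement drawn uniformly from the
#' 20-letter alphabet).  The first `nSharedSpecies` homologs on each side
#' carry matching organism tags; the remainder carry side-specific tags.
#'
#' @param l alignment width.
#' @param depth rows per MSA (query included).
#' @param mutationRate per-position mutation probability in `[0, 1]`.
#' @param nSharedSpecies number of organism tags present in both MSAs.
#' @param seed integer seed.
#' @return List with `msaA` and `msaB`
#'   ([MultipleSequenceAlignment-class]).
#' @export
generateSyntheticMSA <- function(l, depth, mutationRate = 0.3,
                                 nSharedSpecies = 3L, seed = 0L) {
  stopifnot(depth >= 1L, nSharedSpecies <= depth - 1L || depth == 1L)
  withSeed(seed, {
    mk <- function(side) {
      q <- sample(.AA20, l, replace = TRUE)
      rows <- c(paste(q, collapse = ""),
                vapply(seq_len(depth - 1L), function(r) {
                  v <- q
                  mut <- stats::runif(l) < mutationRate
                  v[mut] <- sample(.AA20, sum(mut), replace = TRUE)
                  paste(v, collapse = "")
                }, character(1)))
      nh <- depth - 1L
      org <- c(NA_character_,
               if (nh > 0) ifelse(seq_len(nh) <= nSharedSpecies,
                                  paste0("900", seq_len(nh)),
                                  paste0("7", side, "0", seq_len(nh))))
      MultipleSequenceAlignment(rows,
                                ids = c("query", paste0("hom", seq_len(nh))),
                                organism = org)
    }
    list(msaA = mk(1L), msaB = mk(2L))
  })
}

#' Generate a full synthetic dimer dataset
#'
#' `n` toy dimers with planted-signal features, seeded reproducibly from a
#' single master seed.  Optionally writes each dimer's PDB structures, its
#' feature-stack tensor archive and its label/mask archive to a directory.
#'
#' @param n number of dimers.
#' @param l chain length (both chains).
#' @param snr signal fraction, scalar or vector recycled over dimers.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return List of [generateSyntheticFeatures()] results.
#' @export
makeSyntheticDataset <- function(n, l = 24L, snr = 0.8, seed = 7L,
                                 dir = NULL) {
  snr <- rep(snr, length.out = n)
  out <- lapply(seq_len(n), function(i) {
    dimer <- generateToyDimer(l, l, seed = seed + 1000L * i)
    generateSyntheticFeatures(dimer, snr = snr[i], seed = seed + 1000L * i + 1L)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(out)) {
      ex <- out[[i]]
      writeStructure(ex$dimer$structureA,
                     file.path(dir, sprintf("dimer%03d_A.pdb", i)))
      writeStructure(ex$dimer$structureB,
                     file.path(dir, sprintf("dimer%03d_B.pdb", i)))
      writeTensorArchive(
        list(tensor = featureTensor(ex$stack), heavyBins = ex$heavyBins,
             cbBins = ex$cbBins, mask = ex$mask * 1L),
        file.path(dir, sprintf("dimer%03d_features.ckpt", i)),
        metadata = list(snr = ex$snr, lengths = chainLengths(ex$stack)))
    }
  }
  out
}
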