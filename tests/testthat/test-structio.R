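test_that("readStructure extracts residues, coordinates and handles glycine", {
  s <- readStructure(twoResiduePdb(), "A")
  expect_equal(nResidues(s), 2L)
  expect_equal(unname(atomCoords(s, 1)["CB", ]), c(0, 0, 0))
  expect_equal(unname(atomCoords(s, 2)["CB", ]), c(3.8, 0, 0))

  # glycine has no CB; the residue is kept with its CA
  gly <- paste(pdbLine(1, "CA", "GLY", "A", 1, 1, 2, 3),
               pdbLine(2, "CA", "ALA", "A", 2, 4, 5, 6),
               pdbLine(3, "CB", "ALA", "A", 2, 4.5, 5, 6),
               "END", sep = "\n")
  s <- readStructure(gly, "A")
  expect_true("CA" %in% rownames(atomCoords(s, 1)))
  expect_false("CB" %in% rownames(atomCoords(s, 1)))
  expect_equal(residueNames(s), c("G", "A"))
})

test_that("readStructure selects the requested chain (line-count oracle)", {
  set.seed(5)
  mkChain <- function(chain, n, serial0) paste(
    vapply(seq_len(n), function(r)
      pdbLine(serial0 + r, "CA", "ALA", chain, r,
              rnorm(1), rnorm(1), rnorm(1)), character(1)),
    collapse = "\n")
  txt <- paste(mkChain("A", 4, 0), mkChain("B", 7, 100), "END", sep = "\n")
  sB <- readStructure(txt, "B")
  # oracle: count ATOM records belonging to chain B in the raw text
  lines <- strsplit(txt, "\n")[[1]]
  nB <- sum(grepl("^ATOM", lines) & substr(lines, 22, 22) == "B")
  expect_equal(nResidues(sB), nB)
  expect_equal(chainId(sB), "B")
  expect_error(readStructure(txt, "C"), "chain not found")
})

test_that("readStructure drops hydrogens and resolves altlocs by occupancy", {
  txt <- paste(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdbLine(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdbLine(3, "CB", "ALA", "A", 1, 1, 0, 0),
    pdbLine(4, "HB1", "ALA", "A", 1, 2, 0, 0, element = "H"),
    "END", sep = "\n")
  s <- readStructure(txt, "A")
  expect_equal(nrow(atomCoords(s, 1)), 2L)           # CA + CB, no hydrogen
  expect_equal(unname(atomCoords(s, 1)["CA", ]), c(9, 9, 9))  # occ 0.6 wins
  expect_false(any(grepl("^H", rownames(atomCoords(s, 1)))))
})

test_that("readMSA strips insertion states and parses organism tags", {
  one <- readMSA(">q\nACDEF\n")
  expect_equal(length(msaRows(one)), 1L)
  expect_equal(msaWidth(one), 5L)

  a3m <- ">q\nACDEF\n>r1 OS=Homo sapiens OX=9606\nAC-gaDE\n>r2\nAAAAA\n>r3 OX=9606\nACDEF\n>r4 [Escherichia coli]\nACDEA\n"
  m <- readMSA(a3m)
  expect_equal(msaWidth(m), 5L)                       # "ga" stripped
  expect_equal(msaRows(m)[2], "AC-DE")
  expect_equal(sum(organismTags(m) == "9606", na.rm = TRUE), 2L)
  expect_equal(organismTags(m)[5], "Escherichia coli")
  expect_true(is.na(organismTags(m)[3]))

  expect_error(readMSA(">q\nACDEF\n>bad\nACD\n"), "ragged")
})

test_that("readPSSM parses the PSI-BLAST layout and ignores trailing columns", {
  hdr <- "\nLast position-specific scoring matrix computed\n            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V\n"
  rows <- vapply(1:3, function(i)
    paste(c(sprintf("%5d %s", i, c("A", "C", "D")[i]),
            sprintf("%4d", (1:20) + i),
            sprintf("%4d", rep(0, 20)), " 0.36 0.12"), collapse = " "),
    character(1))
  p <- readPSSM(paste(c(hdr, rows), collapse = "\n"))
  expect_equal(dim(pssmScores(p)), c(3L, 20L))
  expect_equal(unname(pssmScores(p)[2, ]), (1:20) + 2)   # hand-parsed row
  expect_error(readPSSM(""), "malformed PSSM")
  expect_error(readPSSM("1 A 1 2 3"), "malformed PSSM")
})

test_that("contact lists round-trip and preserve ranking order", {
  expect_equal(writeContactList(RankedContactList()), "PFRMAT RR\nEND")

  rc <- RankedContactList(i = c(3L, 1L, 2L), j = c(1L, 2L, 3L),
                          prob = c(0.5, 0.9, 0.1))
  txt <- writeContactList(rc)
  body <- strsplit(txt, "\n")[[1]]
  expect_equal(length(body), 5L)                      # header + 3 + END
  expect_match(body[2], "^1 2 0 8 0.9")

  set.seed(31)
  big <- RankedContactList(i = sample(50), j = sample(50), prob = runif(50))
  back <- readContactList(writeContactList(big))
  expect_equal(contactEntries(back)$i, contactEntries(big)$i)
  expect_equal(contactEntries(back)$prob, contactEntries(big)$prob,
               tolerance = 1e-6)
})

test_that("structures round-trip through the PDB writer", {
  d <- generateToyDimer(6, 8, seed = 4)
  for (s in list(d$structureA, d$structureB)) {
    back <- readStructure(writeStructure(s), chainId(s))
    expect_equal(nResidues(back), nResidues(s))
    for (r in seq_len(nResidues(s)))
      expect_equal(unname(atomCoords(back, r)), unname(atomCoords(s, r)),
                   tolerance = 1e-3)
  }
})

test_that("tensor archives round-trip named arrays with shape checks", {
  f <- tempfile()
  plm <- matrix(1:9 / 10, 3, 3); plm <- (plm + t(plm)) / 2
  arrays <- list(plm = plm,
                 attention = array(runif(3 * 3 * 144), c(3, 3, 144)))
  writeTensorArchive(arrays, f, metadata = list(note = "x"))
  back <- readTensorArchive(f)
  expect_identical(back$arrays$plm, arrays$plm)
  expect_equal(back$metadata$note, "x")
  co <- readCoevolutionFeatures(f)
  expect_s4_class(co, "CoevolutionFeatures")
  unlink(f)
})
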