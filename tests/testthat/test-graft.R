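# Shared toy: scaffold and insert with one loop each, fully paired flanks.
toySingle <- function() {
  scaf <- mkSeqStructure("AAAAAGGGAAAAA")             # sse1 0-4, coil 5-7, sse2 8-12
  ins <- mkSeqStructure("CCCCCPPPPCCCCC", id = "i", chain = "B")
  lpS <- mkLoop("L", c(0, 4), c(5, 7), c(8, 12))
  lpI <- mkLoop("M", c(0, 4), c(5, 8), c(9, 13))
  pairing <- mkPairing(c(0:4, 8:12), c(0:4, 9:13), nScaffold = 13,
                       nInsert = 14)
  list(scaf = scaf, ins = ins, pair = pairLoops(lpS, lpI),
       pairing = pairing)
}

test_that("a single-loop chimera splices insert between the boundaries", {
  t <- toySingle()
  d <- buildChimera(t$scaf, t$ins, t$pair, c(2L, 2L), c(10L, 11L))
  expect_equal(designSequence(d), "AACCCPPPPCCCAA")
  expect_equal(nchar(designSequence(d)), 5 + 4 + 5)
  expect_equal(d@provenance,
               c(rep("scaffold", 2), rep("insert", 10), rep("scaffold", 2)))
  expect_error(buildChimera(t$scaf, t$ins, t$pair, c(10L, 11L), c(2L, 2L)),
               "invalid boundary order")
})

test_that("the scaffold-inclusive convention keeps boundary residues from the scaffold", {
  t <- toySingle()
  d <- buildChimera(t$scaf, t$ins, t$pair, c(2L, 2L), c(10L, 11L),
                    convention = "scaffold_inclusive")
  # scaffold[0..2] + insert[3..10] + scaffold[10..12]
  expect_equal(designSequence(d), "AAACCPPPPCCAAA")
})

test_that("fully paired flanks yield one boundary candidate per SSE position", {
  t <- toySingle()
  cb <- candidateBoundaries(t$pair, t$pairing)
  expect_equal(nrow(cb$n), 5L)
  expect_equal(nrow(cb$c), 5L)
  expect_false(any(cb$n$rescue) || any(cb$c$rescue))
})

test_that("unpaired SSE positions are rescued against the gap flank", {
  t <- toySingle()
  # unpair scaffold position 2 (mid sse1)
  d <- t$pairing@doublets
  pairing <- mkPairing(d$scaffoldIdx[d$scaffoldIdx != 2],
                       d$insertIdx[d$scaffoldIdx != 2],
                       nScaffold = 13, nInsert = 14)
  cb <- candidateBoundaries(t$pair, pairing)
  # 4 surviving doublets plus one rescue per unpaired side
  expect_equal(nrow(cb$n), 6L)
  resc <- cb$n[cb$n$rescue, ]
  # scaffold 2 rescued against the partner of its nearest paired
  # neighbour (tie 1 vs 3 resolves N-terminal -> partner of 1), and
  # insert 2 symmetrically
  expect_true(any(resc$scaffoldIdx == 2L & resc$insertIdx == 1L))
  expect_true(any(resc$scaffoldIdx == 1L & resc$insertIdx == 2L))
})

test_that("flanks with no paired residues yield no designs", {
  t <- toySingle()
  pairing <- mkPairing(8:12, 9:13, nScaffold = 13, nInsert = 14)
  cb <- candidateBoundaries(t$pair, pairing)
  expect_equal(nrow(cb$n), 0L)
  designs <- enumerateDesigns(list(t$pair), pairing, t$scaf, t$ins)
  expect_length(designs, 0)
})

test_that("enumeration matches the string-level oracle on the single-loop toy", {
  t <- toySingle()
  designs <- enumerateDesigns(list(t$pair), t$pairing, t$scaf, t$ins)
  expect_length(designs, 25)
  oracle <- oracleEnumerate("AAAAAGGGAAAAA", "CCCCCPPPPCCCCC",
                            list(list(n = 0:4, nI = 0:4, c = 8:12,
                                      cI = 9:13)))
  expect_setequal(vapply(designs, designSequence, ""), oracle)
})

test_that("identical sequences admit no designs", {
  scaf <- mkSeqStructure("AAAAAGGGAAAAA")
  ins <- mkSeqStructure("AAAAAGGGAAAAA", id = "i", chain = "B")
  pair <- pairLoops(mkLoop("L", c(0, 4), c(5, 7), c(8, 12)),
                    mkLoop("M", c(0, 4), c(5, 7), c(8, 12)))
  pairing <- mkPairing(0:12, 0:12)
  expect_length(enumerateDesigns(list(pair), pairing, scaf, ins), 0)
})

test_that("multi-loop enumeration satisfies the partition identity and the oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    scafSeq <- paste(sample(c("A", "D", "E", "F"), 18, TRUE), collapse = "")
    insSeq <- paste(sample(c("K", "L", "N", "Q"), 18, TRUE), collapse = "")
    scaf <- mkSeqStructure(scafSeq)
    ins <- mkSeqStructure(insSeq, id = "i", chain = "B")
    l1 <- pairLoops(mkLoop("L1", c(0, 3), c(4, 6), c(7, 10)),
                    mkLoop("M1", c(0, 3), c(4, 6), c(7, 10)))
    l2 <- pairLoops(mkLoop("L2", c(7, 10), c(11, 13), c(14, 17)),
                    mkLoop("M2", c(7, 10), c(11, 13), c(14, 17)))
    pairing <- mkPairing(0:17, 0:17)
    designs <- enumerateDesigns(list(l1, l2), pairing, scaf, ins)
    counts <- attr(designs, "counts")
    expect_equal(sum(counts), length(designs))
    oracle <- oracleEnumerate(scafSeq, insSeq,
      list(list(n = 0:3, nI = 0:3, c = 7:10, cI = 7:10),
           list(n = 7:10, nI = 7:10, c = 14:17, cI = 14:17)))
    expect_setequal(vapply(designs, designSequence, ""), oracle)
    # no duplicated sequences
    expect_false(anyDuplicated(vapply(designs, designSequence, "")) > 0)
  }
})

test_that("every design grafts the whole insert coil and drops the scaffold coil", {
  t <- toySingle()
  designs <- enumerateDesigns(list(t$pair), t$pairing, t$scaf, t$ins)
  coilIns <- 5:8
  coilScaf <- 5:7
  for (d in designs) {
    insPos <- d@srcIndex[d@provenance == "insert"]
    expect_true(all(coilIns %in% insPos))
    scafPos <- d@srcIndex[d@provenance == "scaffold"]
    expect_false(any(coilScaf %in% scafPos))
  }
})

test_that("enumeration is deterministic across runs", {
  t <- toySingle()
  d1 <- enumerateDesigns(list(t$pair), t$pairing, t$scaf, t$ins)
  d2 <- enumerateDesigns(list(t$pair), t$pairing, t$scaf, t$ins)
  expect_identical(vapply(d1, designId, ""), vapply(d2, designId, ""))
})

test_that("overlapping coil selections are rejected", {
  scaf <- mkSeqStructure("AAAAAGGGAAAAA")
  ins <- mkSeqStructure("CCCCCPPPCCCCC", id = "i", chain = "B")
  p1 <- pairLoops(mkLoop("L1", c(0, 4), c(5, 7), c(8, 12)),
                  mkLoop("M1", c(0, 4), c(5, 7), c(8, 12)))
  p2 <- pairLoops(mkLoop("L2", c(0, 3), c(4, 6), c(7, 12)),
                  mkLoop("M2", c(0, 3), c(4, 6), c(7, 12)))
  pairing <- mkPairing(0:12, 0:12)
  expect_error(enumerateDesigns(list(p1, p2), pairing, scaf, ins),
               "overlapping loop selections")
})

test_that("automatic loop pairing maps counterparts through the pairing", {
  s <- syntheticStructure(list(c("H", 10), c("C", 3), c("H", 8), c("C", 4),
                               c("H", 9)), seed = 15)
  ann <- annotationFromStates(attr(s, "truth")$states)
  loops <- extractLoops(ann, s)
  pairing <- mkPairing(0:(nResidues(s) - 1), 0:(nResidues(s) - 1))
  ap <- autoPairLoops(loops, loops, pairing)
  expect_length(ap$pairs, 2)
  for (p in ap$pairs)
    expect_equal(p$scaffoldLoop@label, p$insertLoop@label)
  # no pairing information: loops are reported unpaired
  empty <- new("ResiduePairing",
               doublets = data.frame(scaffoldIdx = integer(0),
                                     insertIdx = integer(0),
                                     dist = numeric(0)),
               gaps = list(scaffold = integer(0), insert = integer(0)),
               params = pairingParams())
  ap2 <- autoPairLoops(loops, loops, empty)
  expect_length(ap2$pairs, 0)
  expect_equal(ap2$unpaired, vapply(loops, loopLabel, ""))
})

test_that("design JSON reports boundaries in author numbering", {
  t <- toySingle()
  designs <- enumerateDesigns(list(t$pair), t$pairing, t$scaf, t$ins)
  f <- tempfile(fileext = ".json")
  writeDesignsJson(designs, t$scaf, t$ins, f)
  j <- jsonlite::read_json(f)
  expect_length(j, 25)
  expect_equal(j[[1]]$n_loops, 1L)
  expect_equal(nchar(j[[1]]$sequence), j[[1]]$length)
  b <- j[[1]]$boundaries$L
  expect_true(b$n$scaffold >= 1 && b$n$scaffold <= 5)
  unlink(f)
})
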