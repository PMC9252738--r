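fixturePair <- function(seed = 21) {
  hp <- syntheticHomologPair(list(c("H", 6), c("C", 4), c("H", 6),
                                  c("C", 3), c("H", 6)),
                             noiseSigma = 0.2, seed = seed,
                             divergeFlanks = TRUE)
  annS <- annotationFromStates(attr(hp$scaffold, "truth")$states)
  annI <- annotationFromStates(attr(hp$insert, "truth")$states)
  loopsS <- extractLoops(annS, hp$scaffold)
  loopsI <- extractLoops(annI, hp$insert)
  sp <- superpose(hp$scaffold, hp$insert)
  pr <- greedyPairing(hp$scaffold, hp$insert, sp)
  ap <- autoPairLoops(loopsS, loopsI, pr)
  designs <- enumerateDesigns(ap$pairs, pr, hp$scaffold, hp$insert)
  list(hp = hp, pairs = ap$pairs, pairing = pr, designs = designs)
}

test_that("the scaffold template drops exactly the grafted coil", {
  fx <- fixturePair()
  d <- fx$designs[[1]]
  bundle <- prepareTemplates(d, fx$hp$scaffold, fx$hp$insert, fx$pairs,
                             fx$pairing)
  lab <- names(d@boundaries)
  p <- fx$pairs[[which(vapply(fx$pairs, function(q) q$scaffoldLoop@label,
                              "") == lab)]]
  coilLen <- diff(p$scaffoldLoop@coil) + 1L
  expect_equal(nResidues(bundle$scaffoldTemplate),
               nResidues(fx$hp$scaffold) - coilLen)
  expect_length(bundle$fragments, 1)
  expect_equal(nResidues(bundle$fragments[[1]]),
               length(loopRange(p$insertLoop)))
})

test_that("identical inputs produce an alignment without mismatches", {
  s <- syntheticStructure(list(c("H", 10), c("C", 3), c("H", 9)), seed = 5)
  ann <- annotationFromStates(attr(s, "truth")$states)
  loops <- extractLoops(ann, s)
  s2 <- s
  s2@id <- "copy"
  pairing <- mkPairing(0:(nResidues(s) - 1), 0:(nResidues(s) - 1))
  pair <- pairLoops(loops[[1]], loops[[1]])
  d <- buildChimera(s, s2, pair, c(2L, 2L), c(16L, 16L))
  bundle <- prepareTemplates(d, s, s2, list(pair), pairing)
  aln <- bundle$alignment
  tgt <- strsplit(aln[["target"]], "")[[1]]
  for (row in setdiff(names(aln), "target")) {
    rc <- strsplit(aln[[row]], "")[[1]]
    both <- tgt != "-" & rc != "-"
    expect_true(all(tgt[both] == rc[both]))
  }
})

test_that("template coverage satisfies the per-position invariant", {
  fx <- fixturePair()
  pick <- unique(c(1, length(fx$designs) %/% 2, length(fx$designs)))
  labs <- vapply(fx$pairs, function(q) q$scaffoldLoop@label, "")
  for (k in pick) {
    d <- fx$designs[[k]]
    bundle <- prepareTemplates(d, fx$hp$scaffold, fx$hp$insert, fx$pairs,
                               fx$pairing)
    aln <- bundle$alignment
    tgt <- strsplit(aln[["target"]], "")[[1]]
    cols <- which(tgt != "-")
    rows <- setdiff(names(aln), "target")
    cov <- vapply(rows, function(r)
      strsplit(aln[[r]], "")[[1]][cols] != "-", logical(length(cols)))
    # every design position covered by at least one template row
    expect_true(all(rowSums(cov) >= 1))
    grafted <- fx$pairs[match(names(d@boundaries), labs)]
    graftRanges <- unlist(lapply(grafted, function(p)
      loopRange(p$scaffoldLoop)))
    for (p in grafted) {
      lab <- p$scaffoldLoop@label
      coilPos <- which(d@provenance == "insert" &
                       d@srcIndex %in% coilRange(p$insertLoop))
      # grafted coil positions: only the fragment row
      expect_true(all(cov[coilPos, lab]))
      expect_false(any(cov[coilPos, "scaffold"]))
    }
    outside <- which(d@provenance == "scaffold" &
                     !(d@srcIndex %in% graftRanges))
    # positions outside the grafted loops: only the scaffold row
    expect_true(all(cov[outside, "scaffold"]))
    if (length(rows) > 1)
      expect_false(any(cov[outside, setdiff(rows, "scaffold")]))
    # ungapped rows reproduce the template sequences
    degap <- function(x) gsub("-", "", x)
    expect_equal(degap(aln[["scaffold"]]),
                 residueSequence(bundle$scaffoldTemplate, collapse = TRUE))
  }
})

test_that("PIR output has one entry per template plus the target and round-trips", {
  fx <- fixturePair()
  oneLoop <- fx$designs[[which(vapply(fx$designs, function(d) d@nLoops,
                                      integer(1)) == 1)[1]]]
  twoLoop <- fx$designs[[which(vapply(fx$designs, function(d) d@nLoops,
                                      integer(1)) == 2)[1]]]
  b1 <- prepareTemplates(oneLoop, fx$hp$scaffold, fx$hp$insert, fx$pairs,
                         fx$pairing)
  b2 <- prepareTemplates(twoLoop, fx$hp$scaffold, fx$hp$insert, fx$pairs,
                         fx$pairing)
  f <- tempfile(fileext = ".pir")
  writePirAlignment(b1, f)
  p1 <- readPir(f)
  expect_equal(nrow(p1), 3L)
  expect_equal(p1$type, c("structureX", "structureX", "sequence"))
  expect_equal(p1$sequence[nrow(p1)], unname(b1$alignment[["target"]]))
  expect_equal(p1$sequence[1], unname(b1$alignment[["scaffold"]]))
  p2 <- readPir(writePirAlignment(b2))
  expect_equal(nrow(p2), 4L)
  unlink(f)
})

test_that("score ingestion assigns dense ranks with lower = better", {
  t3 <- lapply(c("AAA", "CCC", "GGG"), function(s)
    new("ChimericDesign", designId = chimeragraft:::fnv1a32(s),
        sequence = s, provenance = rep("insert", 3),
        boundaries = list(), srcIndex = 0:2, nLoops = 1L))
  ids <- vapply(t3, designId, "")
  tab <- ingestScores(t3, dope = data.frame(design_id = ids,
                                            score = c(1839, 1716, 2458)))
  expect_equal(tab$dopeRank, c(2L, 1L, 3L))
  # ties share a dense rank
  tab2 <- ingestScores(t3, dope = data.frame(design_id = ids,
                                             score = c(5, 5, 7)))
  expect_equal(tab2$dopeRank, c(1L, 1L, 2L))
  # missing metric flagged, not ranked
  tab3 <- ingestScores(t3,
    dope = data.frame(design_id = ids, score = 1:3),
    rosetta = data.frame(design_id = ids[1:2], score = c(-10, -20)))
  expect_true(is.na(tab3$rosettaRank[3]))
  expect_match(tab3$flags[3], "missing_rosetta")
  expect_error(ingestScores(t3, dope = data.frame(design_id = "nope",
                                                  score = 1)),
               "orphan score")
})

test_that("the synthetic score fixture reproduces its frozen ranking", {
  dopeF <- system.file("extdata", "synthetic_scores_dope.tsv",
                       package = "chimeragraft")
  rosF <- system.file("extdata", "synthetic_scores_rosetta.tsv",
                      package = "chimeragraft")
  ids <- sprintf("design_%02d", 1:18)
  designs <- lapply(ids, function(id)
    new("ChimericDesign", designId = id, sequence = "AAA",
        provenance = rep("scaffold", 3), boundaries = list(),
        srcIndex = 0:2, nLoops = 1L))
  tab <- ingestScores(designs, dope = dopeF, rosetta = rosF)
  # two designs tie on the DOPE value 1839 and share rank 4; dense ranks
  # then run to 17
  expect_equal(sort(unique(tab$dopeRank)), 1:17)
  expect_equal(tab$dopeRank[tab$dope == 1839], c(4L, 4L))
  expect_equal(tab$dopeRank[which.min(tab$dope)], 1L)
  # design_07 has no recorded second score
  expect_true(is.na(tab$rosetta[tab$designId == "design_07"]))
  expect_match(tab$flags[tab$designId == "design_07"], "missing_rosetta")
  expect_equal(tab$rosettaRank[which.min(tab$rosetta)], 1L)
})
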