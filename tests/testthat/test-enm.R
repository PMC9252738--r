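test_that("GNM on a 3-bead path graph matches the analytic pseudo-inverse", {
  s <- mkCaStructure(cbind(c(0, 4, 8), 0, 0))
  modes <- gnmModes(s, enmParams(gnmCutoff = 5))
  msf <- residueValues(gnmBfactors(s, enmParams(gnmCutoff = 5)))
  expect_equal(msf, c(5, 2, 5) / 9, tolerance = 1e-10)
  expect_equal(msf[1] / msf[2], 2.5, tolerance = 1e-10)
  # end-to-end correlation from the same pseudo-inverse: (-4/9)/(5/9)
  cc <- crossCorrelation(modes)
  expect_equal(correlationMatrix(cc)[1, 3], -0.8, tolerance = 1e-10)
})

test_that("a fully connected triangle has equal fluctuations", {
  s <- mkCaStructure(rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3.46, 0)))
  msf <- residueValues(gnmBfactors(s, enmParams(gnmCutoff = 5)))
  expect_equal(max(msf) - min(msf), 0, tolerance = 1e-10)
})

test_that("a disconnected contact graph is rejected", {
  s <- mkCaStructure(cbind(c(0, 4, 50, 54), 0, 0))
  expect_error(gnmModes(s, enmParams(gnmCutoff = 5)), "increase cutoff")
  expect_error(gnmBfactors(mkCaStructure(cbind(c(0, 4), 0, 0))), "too small")
})

test_that("ANM discards exactly six rigid-body modes", {
  tet <- mkTetrahedron()
  modes <- anmModes(tet)
  expect_length(modes$values, 3 * 4 - 6)
  expect_true(all(modes$values > 0))
  b <- residueValues(anmBfactors(modes))
  expect_equal(max(b) - min(b), 0, tolerance = 1e-8)
  for (seed in 1:3) {
    s <- syntheticStructure(list(c("H", 9), c("C", 3), c("H", 8)),
                            seed = seed, noiseSigma = 0.1)
    m <- anmModes(s)
    expect_length(m$values, 3 * nResidues(s) - 6)
    expect_true(all(m$values > 0))
    expect_true(all(diff(m$values) >= -1e-10))
  }
})

test_that("cross-correlation maps are symmetric with unit diagonal", {
  s <- syntheticStructure(list(c("H", 10), c("C", 4), c("H", 8)), seed = 2)
  cc <- crossCorrelation(anmModes(s))
  m <- correlationMatrix(cc)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, nrow(m)))
  expect_true(all(m >= -1 - 1e-9 & m <= 1 + 1e-9))
  expect_true(validObject(cc))
})

test_that("theoretical B-factors agree with an independent ENM package", {
  s <- syntheticStructure(list(c("H", 9), c("C", 3), c("H", 8)), seed = 6)
  f <- tempfile(fileext = ".pdb")
  writeStructurePdb(s, f)
  pdb <- bio3d::read.pdb(f)
  unlink(f)
  gRef <- bio3d::gnm(pdb, cutoff = 10)
  gOur <- residueValues(gnmBfactors(s))
  expect_gt(stats::cor(gRef$fluctuations, gOur), 0.99)
  nRef <- bio3d::nma(pdb, ff = "anm", cutoff = 15, mass = FALSE,
                     temp = NULL)
  aOur <- residueValues(anmBfactors(anmModes(s)))
  expect_gt(stats::cor(nRef$fluctuations, aOur), 0.99)
})

test_that("ENM outputs are invariant under rigid motion and scale with the spring constant", {
  s <- syntheticStructure(list(c("H", 9), c("C", 3), c("E", 5)), seed = 4,
                          noiseSigma = 0.1)
  b0 <- residueValues(anmBfactors(anmModes(s)))
  c0 <- correlationMatrix(crossCorrelation(anmModes(s)))
  R <- chimeragraft:::quatToRot(c(0.5, 0.5, 0.5, 0.5))
  s2 <- s
  s2@ca[, , 1] <- chimeragraft:::applyTransform(s2@ca[, , 1], R, c(3, 9, -4))
  expect_equal(residueValues(anmBfactors(anmModes(s2))), b0,
               tolerance = 1e-8)
  expect_equal(correlationMatrix(crossCorrelation(anmModes(s2))), c0,
               tolerance = 1e-8)
  # doubling the spring constant halves fluctuations, correlations unchanged
  p2 <- enmParams(springConstant = 2)
  expect_equal(residueValues(anmBfactors(anmModes(s, p2))), b0 / 2,
               tolerance = 1e-10)
  expect_equal(correlationMatrix(crossCorrelation(anmModes(s, p2))), c0,
               tolerance = 1e-10)
  g0 <- residueValues(gnmBfactors(s))
  expect_equal(residueValues(gnmBfactors(s, p2)), g0 / 2, tolerance = 1e-10)
})

test_that("segment cross-correlation is a block mean with the expected bounds", {
  s <- syntheticStructure(list(c("H", 10), c("C", 4), c("H", 8)), seed = 3)
  cc <- crossCorrelation(anmModes(s))
  expect_equal(segmentCrossCorrelation(cc, 4, 4), 1)
  block <- correlationMatrix(cc)[1:5 + 1, 12:18 + 1]
  v <- segmentCrossCorrelation(cc, 1:5, 12:18)
  expect_gte(v, min(block))
  expect_lte(v, max(block))
  expect_equal(v, mean(block))
  expect_error(segmentCrossCorrelation(cc, integer(0), 1:3), "empty segment")
})

test_that("flexibility method agreement behaves like a correlation matrix", {
  s <- syntheticStructure(list(c("H", 10), c("C", 4), c("H", 9)), seed = 5,
                          bFactors = "auto")
  g <- gnmBfactors(s)
  a <- anmBfactors(anmModes(s), s)
  m <- methodAgreement(list(gnm = g, anm = a))
  expect_equal(m["gnm", "gnm"], 1)
  expect_gt(m["gnm", "anm"], 0.7)
  neg <- new("FlexibilityProfile", source = "crystal",
             residueValues = -residueValues(g), segmentValues = numeric(0),
             loopValues = numeric(0))
  m2 <- methodAgreement(list(gnm = g, neg = neg))
  expect_equal(m2["gnm", "neg"], -1)
  flat <- new("FlexibilityProfile", source = "crystal",
              residueValues = rep(3, nResidues(s)),
              segmentValues = numeric(0), loopValues = numeric(0))
  m3 <- methodAgreement(list(gnm = g, flat = flat))
  expect_true(is.na(m3["gnm", "flat"]))
})

test_that("segment and loop averages are arithmetic means", {
  s <- syntheticStructure(list(c("H", 10), c("C", 4), c("H", 9)), seed = 5,
                          bFactors = "auto")
  ann <- annotationFromStates(attr(s, "truth")$states)
  loops <- extractLoops(ann, s)
  for (prof in list(crystalBfactors(s), gnmBfactors(s),
                    anmBfactors(anmModes(s), s))) {
    p <- segmentAverages(prof, ann, loops)
    seg <- ann@segments
    for (k in seq_len(nrow(seg)))
      expect_equal(p@segmentValues[k],
                   mean(residueValues(p)[(seg$start[k]:seg$end[k]) + 1L]))
    expect_equal(unname(p@loopValues[1]),
                 mean(residueValues(p)[loopRange(loops[[1]]) + 1L]))
  }
})
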