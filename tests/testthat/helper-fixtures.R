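# Shared fixture builders. All structures here are built in code; nothing
# is read from disk except the small score tables under extdata.

# Structure with given CA coordinates and (optionally) sequence; backbone
# atoms absent (enough for everything except secondary-structure
# assignment).
mkCaStructure <- function(ca, seq = NULL, id = "x", chain = "A",
                          bFactor = NA_real_) {
  n <- nrow(ca)
  if (is.null(seq)) seq <- rep("A", n)
  if (length(seq) == 1 && nchar(seq) > 1) seq <- strsplit(seq, "")[[1]]
  res <- data.frame(seqIndex = 0:(n - 1L), authorNumber = seq_len(n),
                    insCode = "", aa = seq, bFactor = bFactor,
                    breakAfter = FALSE, stringsAsFactors = FALSE)
  new("ProteinStructure", id = id, chainId = chain, residues = res,
      ca = array(ca, dim = c(n, 3, 1)),
      backbone = list(N = matrix(NA_real_, n, 3),
                      C = matrix(NA_real_, n, 3),
                      O = matrix(NA_real_, n, 3)),
      nModels = 1L)
}

# Structure from a sequence laid out as a straight bead chain.
mkSeqStructure <- function(seq, id = "s", chain = "A") {
  s <- strsplit(seq, "")[[1]]
  mkCaStructure(cbind(3.8 * (seq_along(s) - 1), 0, 0), seq = s, id = id,
                chain = chain)
}

mkLoop <- function(label, sse1, coil, sse2, s1 = "H", s2 = "H",
                   user = FALSE) {
  new("LoopRecord", label = label, sse1 = as.integer(sse1),
      coil = as.integer(coil), sse2 = as.integer(sse2),
      sse1State = s1, sse2State = s2, userDefined = user)
}

# Pairing object built directly from an index table.
mkPairing <- function(scaffoldIdx, insertIdx, dist = 0,
                      nScaffold = max(scaffoldIdx) + 1L,
                      nInsert = max(insertIdx) + 1L) {
  d <- data.frame(scaffoldIdx = as.integer(scaffoldIdx),
                  insertIdx = as.integer(insertIdx),
                  dist = rep_len(dist, length(scaffoldIdx)))
  new("ResiduePairing", doublets = d,
      gaps = list(scaffold = setdiff(0:(nScaffold - 1L), d$scaffoldIdx),
                  insert = setdiff(0:(nInsert - 1L), d$insertIdx)),
      params = pairingParams())
}

# Regular tetrahedron of CA beads (all pairwise distances equal).
mkTetrahedron <- function(edge = 6) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mkCaStructure(v * edge / (2 * sqrt(2)))
}

# Independent string-level oracle for design enumeration (insert-inclusive
# convention): generate every subset x boundary combination, drop
# conflicting multi-loop combinations, deduplicate sequences, drop the
# scaffold sequence. `loops` is a list of list(n = <scaffold idx vector>,
# nI = <insert idx vector>, c = ..., cI = ...) with matched candidate
# vectors (n[k] pairs with nI[k]).
oracleEnumerate <- function(scafSeq, insSeq, loops) {
  sub <- function(s, a, b) if (a > b) "" else substr(s, a + 1, b + 1)
  L <- nchar(scafSeq)
  results <- character(0)
  nL <- length(loops)
  for (size in seq_len(nL)) {
    for (ss in utils::combn(nL, size, simplify = FALSE)) {
      grids <- lapply(ss, function(k)
        expand.grid(n = seq_along(loops[[k]]$n),
                    c = seq_along(loops[[k]]$c)))
      combo <- expand.grid(lapply(grids, function(g) seq_len(nrow(g))))
      for (r in seq_len(nrow(combo))) {
        pieces <- ""
        cursor <- 0
        ok <- TRUE
        for (pos in seq_along(ss)) {
          k <- ss[pos]
          g <- grids[[pos]][combo[r, pos], ]
          nS <- loops[[k]]$n[g$n]; nI <- loops[[k]]$nI[g$n]
          cS <- loops[[k]]$c[g$c]; cI <- loops[[k]]$cI[g$c]
          if (nS < cursor) { ok <- FALSE; break }
          pieces <- paste0(pieces, sub(scafSeq, cursor, nS - 1),
                           sub(insSeq, nI, cI))
          cursor <- cS + 1
        }
        if (!ok) next
        results <- c(results, paste0(pieces, sub(scafSeq, cursor, L - 1)))
      }
    }
  }
  setdiff(unique(results), scafSeq)
}

# Rotation matrix about a unit axis (Rodrigues), used as an independent
# geometric construction in loop-geometry tests.
rotAbout <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
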