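# Synthetic structures with known ground truth.
#
# Backbones are built residue by residue from ideal bond lengths and angles
# (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A, C-O 1.231 A) with canonical
# dihedrals per state: helix phi/psi = -57/-47, strand -139/135, coil a
# semi-extended -70/140. Coordinate noise, when requested, is a per-residue
# rigid displacement applied to all backbone atoms so local geometry stays
# intact. All randomness is fixed by the seed.

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8)

STATE_DIHEDRALS <- list(H = c(phi = -57, psi = -47),
                        E = c(phi = -139, psi = 135),
                        C = c(phi = -70, psi = 140))

# Place atom D from reference atoms A-B-C given bond |CD|, angle B-C-D and
# dihedral A-B-C-D (degrees); the standard internal-to-Cartesian step.
placeAtom <- function(A, B, C, bond, angle, torsion) {
  ar <- angle * pi / 180
  tr <- torsion * pi / 180
  bc <- unitv(C - B)
  nrm <- unitv(cross3(B - A, bc))
  m <- cbind(bc, cross3(nrm, bc), nrm)
  d <- bond * c(-cos(ar), sin(ar) * cos(tr), sin(ar) * sin(tr))
  as.vector(C + m %*% d)
}

# Build N/CA/C/O coordinates for a state string; returns list of n x 3
# matrices. Dihedrals: phi_i belongs to residue i, psi_i links i to i+1.
buildBackbone <- function(states) {
  g <- IDEAL_GEOM
  n <- length(states)
  phi <- vapply(states, function(s) STATE_DIHEDRALS[[s]]["phi"], numeric(1))
  psi <- vapply(states, function(s) STATE_DIHEDRALS[[s]]["psi"], numeric(1))
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$b_n_ca, g$a_c_n_ca, 180)
      C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ],
                        g$b_c_o, g$a_ca_c_o, psi[i] - 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Rotation axis of the per-residue screw motion of a regular segment,
# oriented N to C; independent of the principal-axis fit used elsewhere.
axisFromScrew <- function(ca) {
  k <- nrow(ca)
  stopifnot(k >= 5)
  fit <- kabsch(ca[2:k, , drop = FALSE], ca[1:(k - 1), , drop = FALSE])
  ev <- eigen(fit$rotation)
  i <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, i])
  ax <- unitv(ax)
  if (sum(ax * (ca[k, ] - ca[1, ])) < 0) ax <- -ax
  ax
}

normArchitecture <- function(architecture) {
  if (is.data.frame(architecture))
    return(data.frame(state = as.character(architecture$state),
                      len = as.integer(architecture$len),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(architecture, function(el)
    data.frame(state = as.character(el[[1]]), len = as.integer(el[[2]]),
               stringsAsFactors = FALSE)))
}

# Per-residue displacement field with the requested per-coordinate SD,
# spatially correlated along the chain (Gaussian kernel, bandwidth 2
# residues) so that neighbouring residues move together and bond geometry
# stays physical -- uncorrelated noise of the same magnitude would stretch
# consecutive CA-CA distances far beyond anything seen in real chains.
chainCorrelatedNoise <- function(n, sigma, bandwidth = 2) {
  W <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * bandwidth^2))
  W <- W / sqrt(rowSums(W^2))
  (W %*% matrix(stats::rnorm(3 * n), n, 3)) * sigma
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

#' Generate a synthetic protein structure with known ground truth
#'
#' Builds an ideal backbone for the requested architecture (alternating
#' secondary-structure runs) from canonical dihedrals, optionally perturbed
#' by chain-correlated per-residue Gaussian rigid displacements. The
#' returned structure carries a \code{"truth"} attribute with the
#' generating states, the noise-free axes of every regular segment (both
#' the principal-axis and the screw-rotation conventions), and the noise
#' level, for use as ground truth in tests.
#'
#' @param architecture List of \code{c(state, length)} runs, e.g.
#'   \code{list(c("H", 11), c("C", 4), c("H", 11))}.
#' @param sequence One-letter sequence (string or vector); defaults to a
#'   seed-deterministic random sequence.
#' @param noiseSigma Per-coordinate displacement standard deviation in
#'   Angstrom.
#' @param seed Integer seed fixing all randomness.
#' @param id,chain Structure label and chain id.
#' @param bFactors Per-residue B-factors to store (e.g. to emulate a crystal
#'   structure); \code{"auto"} fills in a smooth synthetic profile; NULL
#'   leaves them absent.
#' @return A \linkS4class{ProteinStructure} with a \code{"truth"} attribute.
#' @examples
#' s <- syntheticStructure(list(c("H", 12)), seed = 7)
#' attr(s, "truth")$states[1:5]
#' @export
syntheticStructure <- function(architecture, sequence = NULL, noiseSigma = 0,
                               seed = 1L, id = "synth", chain = "A",
                               bFactors = NULL) {
  arch <- normArchitecture(architecture)
  states <- rep(arch$state, arch$len)
  n <- length(states)
  withSeed(seed, {
    if (is.null(sequence)) {
      sequence <- sample(AA1, n, replace = TRUE)
    } else if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
      sequence <- strsplit(sequence, "")[[1]]
    }
    stopifnot(length(sequence) == n)
    bb <- buildBackbone(states)
    # generation axes of each regular element, from the noise-free
    # coordinates: the principal axis (sseVector convention) and,
    # independently, the rotation axis of the per-residue screw motion
    segAxis <- function(ca) {
      centered <- sweep(ca, 2, colMeans(ca))
      ax <- svd(centered)$v[, 1]
      if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
      as.numeric(ax)
    }
    trueAxes <- lapply(seq_len(nrow(arch)), function(k) {
      if (arch$state[k] == "C" || arch$len[k] < 5) return(NULL)
      first <- sum(arch$len[seq_len(k - 1)]) + 1L
      ca <- bb$CA[first:(first + arch$len[k] - 1L), , drop = FALSE]
      list(axis = segAxis(ca), screwAxis = axisFromScrew(ca))
    })
    if (noiseSigma > 0) {
      disp <- chainCorrelatedNoise(n, noiseSigma)
      for (at in names(bb)) bb[[at]] <- bb[[at]] + disp
    }
    if (identical(bFactors, "auto"))
      bFactors <- 15 + 8 * sin(seq_len(n) / 3) + 4 * cos(seq_len(n) / 7)
    res <- data.frame(seqIndex = 0:(n - 1L), authorNumber = seq_len(n),
                      insCode = "", aa = sequence,
                      bFactor = if (is.null(bFactors)) NA_real_ else bFactors,
                      breakAfter = FALSE, stringsAsFactors = FALSE)
    ca <- array(bb$CA, dim = c(n, 3, 1))
    s <- new("ProteinStructure", id = id, chainId = chain, residues = res,
             ca = ca, backbone = list(N = bb$N, C = bb$C, O = bb$O),
             nModels = 1L)
    attr(s, "truth") <- list(states = states, axes = trueAxes,
                             architecture = arch, noiseSigma = noiseSigma,
                             seed = seed)
    s
  })
}

#' Generate a pair of synthetic homologs with known residue correspondence
#'
#' Scaffold and insert share the same secondary-structure architecture while
#' coil segments may differ in sequence and length; each structure receives
#' independent coordinate noise and the insert is additionally moved by a
#' recorded random rigid transform. The truth map lists the residue
#' correspondence (all residues when coil lengths match; regular-segment
#' residues plus positionally matched coil prefixes otherwise).
#'
#' @param architecture Shared architecture as in
#'   \code{\link{syntheticStructure}} (coil lengths give the scaffold).
#' @param insertCoilLengths Optional integer vector, one per coil run in
#'   \code{architecture}, overriding the insert's coil lengths.
#' @param noiseSigma,seed Noise level (applied to both chains independently)
#'   and master seed.
#' @param divergeCoils If TRUE (default) insert coil sequences are resampled
#'   so they differ from the scaffold's.
#' @param divergeFlanks If TRUE, regular-segment sequences are also
#'   resampled (structures stay congruent), emulating sequence-diverged
#'   homologs; default FALSE keeps flank letters shared.
#' @return List with \code{scaffold}, \code{insert}
#'   (\linkS4class{ProteinStructure}), \code{truth} (data.frame
#'   \code{scaffoldIdx}, \code{insertIdx}; 0-based) and \code{transform}
#'   (recorded rotation/translation applied to the insert).
#' @export
syntheticHomologPair <- function(architecture, insertCoilLengths = NULL,
                                 noiseSigma = 0, seed = 1L,
                                 divergeCoils = TRUE, divergeFlanks = FALSE) {
  arch <- normArchitecture(architecture)
  coilRuns <- which(arch$state == "C")
  archIns <- arch
  if (!is.null(insertCoilLengths)) {
    stopifnot(length(insertCoilLengths) == length(coilRuns))
    archIns$len[coilRuns] <- as.integer(insertCoilLengths)
  }
  withSeed(seed, {
    seqScaf <- sample(AA1, sum(arch$len), replace = TRUE)
    # insert: same letters on shared runs, fresh letters on coils
    seqIns <- character(0)
    offS <- offI <- 0L
    truth <- NULL
    for (k in seq_len(nrow(arch))) {
      lS <- arch$len[k]; lI <- archIns$len[k]
      sS <- seqScaf[(offS + 1):(offS + lS)]
      diverge <- if (arch$state[k] == "C") divergeCoils else divergeFlanks
      if (diverge) {
        sI <- sample(AA1, lI, replace = TRUE)
      } else {
        sI <- rep(sS, length.out = lI)
      }
      seqIns <- c(seqIns, sI)
      lShared <- min(lS, lI)
      truth <- rbind(truth, data.frame(
        scaffoldIdx = offS + seq_len(lShared) - 1L,
        insertIdx = offI + seq_len(lShared) - 1L))
      offS <- offS + lS; offI <- offI + lI
    }
    seedS <- sample.int(2^31 - 1, 3)
    scaffold <- syntheticStructure(arch, sequence = seqScaf,
      noiseSigma = noiseSigma, seed = seedS[1],
      id = "scaf", chain = "A", bFactors = "auto")
    insert <- syntheticStructure(archIns, sequence = seqIns,
      noiseSigma = noiseSigma, seed = seedS[2],
      id = "ins", chain = "B", bFactors = "auto")
    # recorded random rigid motion of the insert
    set.seed(seedS[3])
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- quatToRot(q)
    tr <- stats::runif(3, -20, 20)
    insert@ca[, , 1] <- applyTransform(insert@ca[, , 1], R, tr)
    for (at in c("N", "C", "O"))
      insert@backbone[[at]] <- applyTransform(insert@backbone[[at]], R, tr)
    list(scaffold = scaffold, insert = insert, truth = truth,
         transform = list(rotation = R, translation = tr))
  })
}

quatToRot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic multi-model ensemble with known fluctuations
#'
#' Starting from an ideal single-model structure, adds \code{nEnsModels}
#' models whose alpha carbons are displaced by independent isotropic
#' Gaussian noise with a per-residue amplitude; the population
#' root-mean-squared fluctuation \code{amplitude * sqrt(3)} is recorded as
#' truth.
#'
#' @param architecture,seed As in \code{\link{syntheticStructure}}.
#' @param nEnsModels Number of models (>= 2).
#' @param amplitudes Per-residue per-coordinate displacement SD in Angstrom
#'   (recycled).
#' @return A multi-model \linkS4class{ProteinStructure} with a
#'   \code{"truth"} attribute containing \code{rmsf}.
#' @export
syntheticEnsemble <- function(architecture, nEnsModels = 10L,
                              amplitudes = 0.3, seed = 1L) {
  stopifnot(nEnsModels >= 2)
  base <- syntheticStructure(architecture, seed = seed)
  n <- nResidues(base)
  amplitudes <- rep_len(amplitudes, n)
  withSeed(seed + 1L, {
    ca <- array(NA_real_, dim = c(n, 3, nEnsModels))
    for (m in seq_len(nEnsModels))
      ca[, , m] <- base@ca[, , 1] +
        matrix(stats::rnorm(3 * n, sd = rep(amplitudes, 3)), n, 3)
    base@ca <- ca
    base@nModels <- as.integer(nEnsModels)
    tr <- attr(base, "truth")
    tr$rmsf <- amplitudes * sqrt(3)
    attr(base, "truth") <- tr
    base
  })
}

#' PDB text for a small helix carrying an alternate-location duplicate
#'
#' Writes a 12-residue ideal helix and duplicates one residue's atoms as
#' altloc A/B with different occupancies, for exercising altloc resolution.
#'
#' @param seed Seed for the underlying helix.
#' @return Character vector of PDB lines.
#' @export
syntheticAltlocPdb <- function(seed = 1L) {
  s <- syntheticStructure(list(c("H", 12)), seed = seed)
  lines <- writeStructurePdb(s)
  # duplicate residue 6 atom records as altloc A (occ 0.6) and B (occ 0.4),
  # displacing the B copy
  isRes6 <- grepl("^ATOM", lines) & substr(lines, 23, 26) == "   6"
  out <- character(0)
  for (ln in lines) {
    if (grepl("^ATOM", ln) && substr(ln, 23, 26) == "   6") {
      a <- ln
      substr(a, 17, 17) <- "A"
      substr(a, 55, 60) <- "  0.60"
      b <- ln
      substr(b, 17, 17) <- "B"
      substr(b, 55, 60) <- "  0.40"
      x <- as.numeric(substr(b, 31, 38)) + 0.8
      substr(b, 31, 38) <- sprintf("%8.3f", x)
      out <- c(out, a, b)
    } else out <- c(out, ln)
  }
  out
}
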