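# Elastic-network flexibility: Gaussian (GNM) and anisotropic (ANM) network
# models on alpha carbons, theoretical B-factors, residue and segment
# cross-correlations, and agreement between flexibility sources.
#
# Defaults follow common ENM practice: 10 A GNM cutoff, 15 A ANM cutoff,
# uniform spring constant 1, all non-trivial modes. Zero modes are
# eigenvalues below 1e-8 times the largest.

ZERO_MODE_TOL <- 1e-8

#' Default elastic-network parameters
#'
#' @param gnmCutoff GNM contact cutoff in Angstrom.
#' @param anmCutoff ANM contact cutoff in Angstrom.
#' @param springConstant Uniform force constant (arbitrary units).
#' @return Named list of parameters.
#' @export
enmParams <- function(gnmCutoff = 10, anmCutoff = 15, springConstant = 1) {
  stopifnot(gnmCutoff > 0, anmCutoff > 0, springConstant > 0)
  list(gnmCutoff = gnmCutoff, anmCutoff = anmCutoff,
       springConstant = springConstant)
}

#' Gaussian network model modes
#'
#' Builds the Kirchhoff (connectivity) matrix from alpha-carbon contacts
#' within the cutoff and diagonalises it. Exactly one zero eigenvalue is
#' expected; more indicate a disconnected contact graph.
#'
#' @param structure A \linkS4class{ProteinStructure} (>= 3 residues).
#' @param params See \code{\link{enmParams}}.
#' @return List with \code{vectors} (n x K), \code{values} (K non-zero
#'   eigenvalues, ascending), \code{n}, \code{type = "gnm"}.
#' @export
gnmModes <- function(structure, params = enmParams()) {
  ca <- caCoords(structure)
  n <- nrow(ca)
  if (n < 3) stop("too small: GNM needs at least 3 residues", call. = FALSE)
  d <- as.matrix(stats::dist(ca))
  contact <- d <= params$gnmCutoff & upper.tri(d)
  gamma <- params$springConstant
  K <- matrix(0, n, n)
  K[contact] <- -gamma
  K <- K + t(K)
  diag(K) <- -colSums(K)
  e <- eigen(K, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  nzero <- sum(vals < ZERO_MODE_TOL * max(vals))
  if (nzero > 1)
    stop("increase cutoff: contact graph has ", nzero,
         " connected components", call. = FALSE)
  list(vectors = vecs[, -seq_len(nzero), drop = FALSE],
       values = vals[-seq_len(nzero)], n = n, type = "gnm")
}

#' Anisotropic network model modes
#'
#' Builds the 3N x 3N Hessian from pairwise terms within the cutoff
#' (\eqn{H_{ij} = -\gamma\, d d^T / |d|^2} for contacts, diagonal blocks the
#' negative sum) and diagonalises it. Exactly six zero eigenvalues
#' (rigid-body translations and rotations) are discarded; more indicate an
#' ill-conditioned network.
#'
#' @param structure A \linkS4class{ProteinStructure} (>= 4 non-collinear
#'   residues).
#' @param params See \code{\link{enmParams}}.
#' @return List with \code{vectors} (3n x K, ascending eigenvalue),
#'   \code{values}, \code{n}, \code{type = "anm"}.
#' @export
anmModes <- function(structure, params = enmParams()) {
  ca <- caCoords(structure)
  n <- nrow(ca)
  if (n < 4) stop("too small: ANM needs at least 4 residues", call. = FALSE)
  gamma <- params$springConstant
  H <- matrix(0, 3 * n, 3 * n)
  cut2 <- params$anmCutoff^2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- ca[j, ] - ca[i, ]
      r2 <- sum(dv * dv)
      if (r2 > cut2) next
      blk <- -gamma * tcrossprod(dv) / r2
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  e <- eigen(H, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  nzero <- sum(vals < ZERO_MODE_TOL * max(vals))
  if (nzero > 6)
    stop("ill-conditioned network: ", nzero, " near-zero modes",
         call. = FALSE)
  if (nzero < 6)
    stop("degenerate geometry: expected 6 rigid-body modes, found ", nzero,
         call. = FALSE)
  list(vectors = vecs[, -seq_len(6), drop = FALSE],
       values = vals[-seq_len(6)], n = n, type = "anm")
}

enmMsf <- function(modes) {
  inv <- 1 / modes$values
  if (modes$type == "gnm") {
    drop((modes$vectors^2) %*% inv)
  } else {
    v2 <- modes$vectors^2
    per <- v2[seq(1, 3 * modes$n, by = 3), , drop = FALSE] +
           v2[seq(2, 3 * modes$n, by = 3), , drop = FALSE] +
           v2[seq(3, 3 * modes$n, by = 3), , drop = FALSE]
    drop(per %*% inv)
  }
}

scaleToExperimental <- function(values, structure) {
  b <- structure@residues$bFactor
  if (!any(is.na(b))) values * mean(b) / mean(values) else values
}

#' Theoretical B-factors from a Gaussian network model
#'
#' Per-residue mean-square fluctuations are proportional to the diagonal of
#' the Kirchhoff pseudo-inverse over non-zero modes. When the structure
#' carries experimental B-factors the profile is rescaled so its mean
#' matches the experimental mean; otherwise raw values are returned (only
#' relative values drive loop selection).
#'
#' @param structure A \linkS4class{ProteinStructure}.
#' @param params See \code{\link{enmParams}}.
#' @return A \linkS4class{FlexibilityProfile} with source \code{"gnm"}.
#' @export
gnmBfactors <- function(structure, params = enmParams()) {
  msf <- enmMsf(gnmModes(structure, params))
  new("FlexibilityProfile", source = "gnm",
      residueValues = scaleToExperimental(msf, structure),
      segmentValues = numeric(0), loopValues = numeric(0))
}

#' Theoretical B-factors from anisotropic network modes
#'
#' Per-residue mean-square fluctuation is the inverse-eigenvalue-weighted
#' squared norm of each mode restricted to the residue's three coordinates,
#' summed over modes; scaled as in \code{\link{gnmBfactors}} when a
#' structure with experimental B-factors is supplied.
#'
#' @param modes Result of \code{\link{anmModes}}.
#' @param structure Optional \linkS4class{ProteinStructure} used for
#'   rescaling to the experimental mean.
#' @return A \linkS4class{FlexibilityProfile} with source \code{"anm"}.
#' @export
anmBfactors <- function(modes, structure = NULL) {
  msf <- enmMsf(modes)
  if (!is.null(structure)) msf <- scaleToExperimental(msf, structure)
  new("FlexibilityProfile", source = "anm", residueValues = msf,
      segmentValues = numeric(0), loopValues = numeric(0))
}

#' Residue-to-residue cross-correlation map
#'
#' Normalised covariance of residue displacements over the network modes,
#' \eqn{C_{ij} = \langle \Delta R_i \cdot \Delta R_j \rangle /
#' \sqrt{\langle \Delta R_i^2\rangle \langle \Delta R_j^2\rangle}} with the
#' covariance \eqn{\sum_k \lambda_k^{-1} u_{k,i} \cdot u_{k,j}}. Works for
#' both ANM (3-vector displacements) and GNM (scalar) modes.
#'
#' @param modes Result of \code{\link{anmModes}} or \code{\link{gnmModes}}.
#' @return A \linkS4class{CrossCorrelationMap}.
#' @export
crossCorrelation <- function(modes) {
  inv <- 1 / modes$values
  if (modes$type == "gnm") {
    cov <- modes$vectors %*% (inv * t(modes$vectors))
  } else {
    n <- modes$n
    w <- modes$vectors * rep(sqrt(inv), each = 3 * n)
    cov3 <- tcrossprod(w)  # 3N x 3N covariance
    cov <- matrix(0, n, n)
    for (a in 1:3)
      cov <- cov + cov3[seq(a, 3 * n, by = 3), seq(a, 3 * n, by = 3)]
  }
  s <- sqrt(diag(cov))
  C <- cov / tcrossprod(s)
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  new("CrossCorrelationMap", matrix = C,
      modeCount = length(modes$values))
}

#' Mean cross-correlation between two residue segments
#'
#' Arithmetic mean of the map entries over all pairs (i in segA, j in
#' segB); used both loop-to-loop (full super-secondary ranges) and
#' coil-to-SSE.
#'
#' @param map A \linkS4class{CrossCorrelationMap}.
#' @param segA,segB Integer vectors of 0-based residue indices.
#' @return Scalar in [-1, 1].
#' @export
segmentCrossCorrelation <- function(map, segA, segB) {
  if (!length(segA) || !length(segB)) stop("empty segment", call. = FALSE)
  mean(map@matrix[segA + 1L, segB + 1L])
}

#' Loop-to-loop cross-correlation matrix
#'
#' For each selected loop, the mean cross-correlation of its full
#' super-secondary range with the full range of every other loop, and the
#' mean cross-correlation of its coil segment with the flanking SSEs of
#' every other loop.
#'
#' @param map A \linkS4class{CrossCorrelationMap}.
#' @param selected List of selected \linkS4class{LoopRecord}.
#' @param loops List of all \linkS4class{LoopRecord} in the protein.
#' @return List of two matrices (\code{loopLoop}, \code{coilSse}), rows =
#'   selected loops, columns = all loops.
#' @export
loopCorrelationSummary <- function(map, selected, loops) {
  ll <- matrix(NA_real_, length(selected), length(loops),
               dimnames = list(vapply(selected, loopLabel, ""),
                               vapply(loops, loopLabel, "")))
  cs <- ll
  for (a in seq_along(selected)) {
    for (b in seq_along(loops)) {
      ll[a, b] <- segmentCrossCorrelation(map, loopRange(selected[[a]]),
                                          loopRange(loops[[b]]))
      sse <- c(loops[[b]]@sse1[1]:loops[[b]]@sse1[2],
               loops[[b]]@sse2[1]:loops[[b]]@sse2[2])
      cs[a, b] <- segmentCrossCorrelation(map, coilRange(selected[[a]]), sse)
    }
  }
  list(loopLoop = ll, coilSse = cs)
}

#' Agreement between flexibility sources
#'
#' Pairwise Pearson correlation of the per-residue values of two or more
#' flexibility profiles over the same residues; a constant profile yields
#' NA against everything else.
#'
#' @param profiles Named list of \linkS4class{FlexibilityProfile}.
#' @return Symmetric matrix of correlations.
#' @export
methodAgreement <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  nm <- names(profiles)
  if (is.null(nm)) nm <- vapply(profiles, function(p) p@source, "")
  k <- length(profiles)
  m <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k)) {
    for (b in a:k) {
      x <- profiles[[a]]@residueValues
      y <- profiles[[b]]@residueValues
      r <- if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) NA_real_
           else stats::cor(x, y)
      m[a, b] <- m[b, a] <- r
    }
  }
  diag(m)[!is.na(diag(m))] <- 1
  m
}

#' Fill segment and loop averages of a flexibility profile
#'
#' Segment and loop values are arithmetic means of the per-residue values
#' over the segment's (or the loop's full super-secondary) residue range.
#'
#' @param profile A \linkS4class{FlexibilityProfile}.
#' @param annotation An \linkS4class{SSEAnnotation}.
#' @param loops Optional list of \linkS4class{LoopRecord}.
#' @return The profile with \code{segmentValues} and \code{loopValues} set.
#' @export
segmentAverages <- function(profile, annotation, loops = NULL) {
  v <- profile@residueValues
  seg <- annotation@segments
  profile@segmentValues <- vapply(seq_len(nrow(seg)), function(k)
    mean(v[(seg$start[k]:seg$end[k]) + 1L]), numeric(1))
  if (!is.null(loops))
    profile@loopValues <- vapply(loops, function(lp)
      mean(v[loopRange(lp) + 1L]),
      numeric(1), USE.NAMES = FALSE) |>
      stats::setNames(vapply(loops, loopLabel, ""))
  profile
}
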