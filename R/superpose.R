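# Rigid-body superposition of the insert onto the scaffold and derivation
# of the filtered residue-doublet pairing that defines structural
# equivalence between the two chains.

#' Pairing parameters
#'
#' @param distanceCutoff Maximum alpha-carbon distance for a residue doublet
#'   (Angstrom; default 1.9).
#' @param outlierK Sequence-offset outlier multiplier: doublets whose
#'   scaffold-minus-insert index offset deviates from the median by more
#'   than \code{outlierK} standard deviations are unpaired (default 4).
#' @return Named list of parameters.
#' @export
pairingParams <- function(distanceCutoff = 1.9, outlierK = 4) {
  stopifnot(distanceCutoff > 0, outlierK > 0)
  list(distanceCutoff = distanceCutoff, outlierK = outlierK)
}

# Maximum-cardinality subset of doublets strictly increasing in both
# indices; ties broken by smaller total distance, then by lower scaffold
# index. O(n^2) dynamic programme over doublets sorted by scaffold index.
maxIncreasingSubset <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(d)
  ord <- order(d$scaffoldIdx, d$insertIdx)
  d <- d[ord, , drop = FALSE]
  len <- rep(1L, n)
  cost <- d$dist
  prev <- rep(0L, n)
  for (k in seq_len(n)) {
    for (p in seq_len(k - 1)) {
      if (d$scaffoldIdx[p] < d$scaffoldIdx[k] &&
          d$insertIdx[p] < d$insertIdx[k]) {
        cand_len <- len[p] + 1L
        cand_cost <- cost[p] + d$dist[k]
        if (cand_len > len[k] ||
            (cand_len == len[k] && cand_cost < cost[k] - 1e-12)) {
          len[k] <- cand_len
          cost[k] <- cand_cost
          prev[k] <- p
        }
      }
    }
  }
  best <- which(len == max(len))
  best <- best[order(cost[best], d$scaffoldIdx[best])][1]
  keep <- integer(0)
  k <- best
  while (k > 0) { keep <- c(k, keep); k <- prev[k] }
  d[keep, , drop = FALSE]
}

fragmentRmsd <- function(a, b) kabsch(a, b)$rmsd

#' Superpose the insert structure onto the scaffold
#'
#' Sequence-independent rigid-body alignment. The internal method seeds the
#' alignment with the best-superposing pair of contiguous alpha-carbon
#' fragments, then alternates between assigning mutually nearest
#' alpha-carbon pairs within 4 Angstrom (kept sequence-collinear via a
#' maximum increasing subset) and least-squares refitting, until the pair
#' set converges. The \code{"ce"} method delegates to an external
#' combinatorial-extension aligner when one is configured.
#'
#' @param scaffold,insert \linkS4class{ProteinStructure} objects (>= 20
#'   residues each).
#' @param method \code{"internal"} (default) or \code{"ce"}.
#' @param fragLen Seed fragment length (internal method).
#' @param seedStep Stride of the seed search (internal method).
#' @param minPairs Minimum aligned pairs for a valid superposition.
#' @return A \linkS4class{Superposition} mapping insert coordinates onto
#'   the scaffold frame.
#' @export
superpose <- function(scaffold, insert, method = c("internal", "ce"),
                      fragLen = 8L, seedStep = 2L, minPairs = 20L) {
  method <- match.arg(method)
  if (method == "ce")
    stop("backend unavailable: no external CE aligner configured",
         call. = FALSE)
  caS <- caCoords(scaffold)
  caI <- caCoords(insert)
  n1 <- nrow(caS); n2 <- nrow(caI)
  if (n1 < minPairs || n2 < minPairs)
    stop("structures not superposable: fewer than ", minPairs, " residues",
         call. = FALSE)
  # seed search: regular elements are self-similar under their screw
  # symmetry, so a single best fragment pair can lock a shifted local
  # minimum; rank all fragment pairs, keep several well-separated top
  # seeds and refine each.
  seeds <- NULL
  for (i in seq(1L, n1 - fragLen + 1L, by = seedStep)) {
    fa <- caS[i:(i + fragLen - 1L), , drop = FALSE]
    for (j in seq(1L, n2 - fragLen + 1L, by = seedStep)) {
      fb <- caI[j:(j + fragLen - 1L), , drop = FALSE]
      seeds <- rbind(seeds, c(i, j, fragmentRmsd(fa, fb)))
    }
  }
  seeds <- seeds[order(seeds[, 3]), , drop = FALSE]
  picked <- NULL
  for (k in seq_len(nrow(seeds))) {
    if (is.null(picked) ||
        all(abs(picked[, 1] - seeds[k, 1]) + abs(picked[, 2] - seeds[k, 2]) >
            fragLen))
      picked <- rbind(picked, seeds[k, ])
    if (nrow(picked) >= 12L) break
  }

  refine <- function(fit) {
    prevPairs <- NULL
    for (iter in 1:40) {
      moved <- applyTransform(caI, fit$rotation, fit$translation)
      d2 <- outer(rowSums(caS^2), rep(1, n2)) +
            outer(rep(1, n1), rowSums(moved^2)) - 2 * caS %*% t(moved)
      d2[d2 < 0] <- 0
      nnI <- apply(d2, 1, which.min)           # nearest insert per scaffold
      nnS <- apply(d2, 2, which.min)           # nearest scaffold per insert
      mutual <- which(nnS[nnI] == seq_len(n1))
      dd <- sqrt(d2[cbind(mutual, nnI[mutual])])
      ok <- dd <= 4
      pairs <- data.frame(scaffoldIdx = mutual[ok] - 1L,
                          insertIdx = nnI[mutual][ok] - 1L, dist = dd[ok])
      pairs <- maxIncreasingSubset(pairs)
      if (nrow(pairs) < 3) break
      if (!is.null(prevPairs) &&
          identical(unname(as.matrix(prevPairs[1:2])),
                    unname(as.matrix(pairs[1:2])))) break
      prevPairs <- pairs
      fit <- kabsch(caS[pairs$scaffoldIdx + 1L, , drop = FALSE],
                    caI[pairs$insertIdx + 1L, , drop = FALSE])
    }
    if (is.null(prevPairs)) return(NULL)
    list(pairs = prevPairs, fit = fit)
  }

  best <- NULL
  for (k in seq_len(nrow(picked))) {
    i <- picked[k, 1]; j <- picked[k, 2]
    fit0 <- kabsch(caS[i:(i + fragLen - 1L), , drop = FALSE],
                   caI[j:(j + fragLen - 1L), , drop = FALSE])
    res <- refine(fit0)
    if (is.null(res)) next
    if (is.null(best) || nrow(res$pairs) > nrow(best$pairs) ||
        (nrow(res$pairs) == nrow(best$pairs) && res$fit$rmsd < best$fit$rmsd))
      best <- res
  }
  if (is.null(best) || nrow(best$pairs) < minPairs)
    stop("structures not superposable: no alignment with >= ", minPairs,
         " pairs", call. = FALSE)
  pairs <- best$pairs
  fit <- kabsch(caS[pairs$scaffoldIdx + 1L, , drop = FALSE],
                caI[pairs$insertIdx + 1L, , drop = FALSE])
  new("Superposition", rotation = fit$rotation, translation = fit$translation,
      rmsd = fit$rmsd,
      alignedPairs = as.matrix(pairs[, c("scaffoldIdx", "insertIdx")]))
}

#' Check input similarity against recommended limits
#'
#' Loop grafting assumes globally similar inputs; the recommended limits
#' are a superposition RMSD below 8 Angstrom and a sequence-length
#' difference below 20 percent. Violations produce warnings in the report,
#' never failures.
#'
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param superposition The computed \linkS4class{Superposition}.
#' @return List with \code{rmsd}, \code{lengthDiffPct}, \code{ok} and a
#'   character vector \code{warnings}.
#' @export
inputCompatibility <- function(scaffold, insert, superposition) {
  n1 <- nResidues(scaffold); n2 <- nResidues(insert)
  pct <- 100 * abs(n1 - n2) / max(n1, n2)
  w <- character(0)
  if (superposition@rmsd >= 8)
    w <- c(w, sprintf("superposition RMSD %.2f A exceeds the recommended 8 A",
                      superposition@rmsd))
  if (pct >= 20)
    w <- c(w, sprintf("sequence length difference %.1f%% exceeds the recommended 20%%",
                      pct))
  for (msg in w) warning(msg, call. = FALSE)
  list(rmsd = superposition@rmsd, lengthDiffPct = pct, ok = !length(w),
       warnings = w)
}

#' Greedy residue-doublet pairing
#'
#' Derives the structural residue equivalence from a superposition in three
#' passes: (1) all cross-chain alpha-carbon pairs within the distance
#' cutoff are sorted by ascending distance and accepted greedily when both
#' residues are still unused; (2) correlativity enforcement: the
#' maximum-cardinality subset strictly increasing in both sequence
#' positions is kept (ties broken by smaller total distance), so doublets
#' crossing the sequence order of either chain are unpaired; (3) outlier
#' removal: with the per-doublet sequence offset (scaffold index minus
#' insert index), doublets deviating from the median offset by more than
#' \code{outlierK} standard deviations (computed over all doublets before
#' removal, single pass) are unpaired. Deterministic: ties are resolved by
#' distance, then scaffold, then insert index.
#'
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param superposition \linkS4class{Superposition} mapping insert onto
#'   scaffold.
#' @param params See \code{\link{pairingParams}}.
#' @return A \linkS4class{ResiduePairing}.
#' @export
greedyPairing <- function(scaffold, insert, superposition,
                          params = pairingParams()) {
  caS <- caCoords(scaffold)
  caI <- applyTransform(caCoords(insert), superposition@rotation,
                        superposition@translation)
  n1 <- nrow(caS); n2 <- nrow(caI)
  d2 <- outer(rowSums(caS^2), rep(1, n2)) +
        outer(rep(1, n1), rowSums(caI^2)) - 2 * caS %*% t(caI)
  d2[d2 < 0] <- 0
  cut2 <- params$distanceCutoff^2
  cand <- which(d2 <= cut2, arr.ind = TRUE)
  if (!nrow(cand))
    stop("no structural equivalence at cutoff", call. = FALSE)
  cd <- data.frame(scaffoldIdx = cand[, 1] - 1L, insertIdx = cand[, 2] - 1L,
                   dist = sqrt(d2[cand]))
  cd <- cd[order(cd$dist, cd$scaffoldIdx, cd$insertIdx), , drop = FALSE]
  usedS <- rep(FALSE, n1); usedI <- rep(FALSE, n2)
  keep <- logical(nrow(cd))
  for (k in seq_len(nrow(cd))) {
    s <- cd$scaffoldIdx[k] + 1L; i <- cd$insertIdx[k] + 1L
    if (!usedS[s] && !usedI[i]) {
      keep[k] <- TRUE
      usedS[s] <- TRUE; usedI[i] <- TRUE
    }
  }
  doub <- cd[keep, , drop = FALSE]
  doub <- maxIncreasingSubset(doub)
  # single-pass sequence-offset outlier filter
  delta <- doub$scaffoldIdx - doub$insertIdx
  if (nrow(doub) > 1) {
    sdev <- stats::sd(delta)
    if (is.finite(sdev) && sdev > 0) {
      keepO <- abs(delta - stats::median(delta)) <= params$outlierK * sdev
      doub <- doub[keepO, , drop = FALSE]
    }
  }
  if (!nrow(doub))
    stop("no structural equivalence at cutoff", call. = FALSE)
  doub <- doub[order(doub$scaffoldIdx), , drop = FALSE]
  rownames(doub) <- NULL
  new("ResiduePairing", doublets = doub,
      gaps = list(scaffold = setdiff(0:(n1 - 1L), doub$scaffoldIdx),
                  insert = setdiff(0:(n2 - 1L), doub$insertIdx)),
      params = params)
}

#' Export a pairing as a table in author numbering
#'
#' @param pairing A \linkS4class{ResiduePairing}.
#' @param scaffold,insert The paired \linkS4class{ProteinStructure} objects.
#' @return \code{data.frame} with author numbers and distances.
#' @export
pairingTable <- function(pairing, scaffold, insert) {
  d <- pairing@doublets
  data.frame(scaffoldAuthor = authorNumbers(scaffold)[d$scaffoldIdx + 1L],
             insertAuthor = authorNumbers(insert)[d$insertIdx + 1L],
             dist = d$dist)
}
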