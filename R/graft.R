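# Loop pairing between scaffold and insert, enumeration of recombination
# boundaries on the flanking SSEs, and generation of the deduplicated
# chimeric sequence library.
#
# Boundary-membership convention: with the default "insert_inclusive"
# convention both boundary residues are contributed by the insert (the
# chimera is scaffold[.. nS-1] + insert[nI .. cI] + scaffold[cS+1 ..]); the
# alternative "scaffold_inclusive" convention keeps the boundary residues
# from the scaffold (scaffold[.. nS] + insert[nI+1 .. cI-1] + scaffold[cS
# ..]). Either way the grafted region contains the whole insert coil.

#' Pair scaffold loops with their insert equivalents
#'
#' For each selected scaffold loop, maps its coil midpoint through the
#' residue pairing (via the nearest paired scaffold position; ties to the
#' N-terminal side) and picks the insert loop whose coil midpoint is
#' closest to the mapped position. Loops that cannot be mapped are
#' reported unpaired.
#'
#' @param scaffoldLoops List of selected scaffold \linkS4class{LoopRecord}.
#' @param insertLoops List of candidate insert \linkS4class{LoopRecord}.
#' @param pairing A \linkS4class{ResiduePairing}.
#' @return List with \code{pairs} (list of loop pairs, each a list with
#'   \code{scaffoldLoop}, \code{insertLoop}, \code{autoPaired = TRUE}) and
#'   \code{unpaired} (labels of unmapped scaffold loops).
#' @export
autoPairLoops <- function(scaffoldLoops, insertLoops, pairing) {
  d <- pairing@doublets
  pairs <- list()
  unpaired <- character(0)
  for (lp in scaffoldLoops) {
    mid <- floor((lp@coil[1] + lp@coil[2]) / 2)
    if (!nrow(d) || !length(insertLoops)) {
      unpaired <- c(unpaired, lp@label)
      next
    }
    off <- abs(d$scaffoldIdx - mid)
    # ties to the N-terminal (lower-index) side
    cand <- which(off == min(off))
    k <- cand[which.min(d$scaffoldIdx[cand])]
    target <- d$insertIdx[k] + (mid - d$scaffoldIdx[k])
    midI <- vapply(insertLoops, function(il)
      floor((il@coil[1] + il@coil[2]) / 2), numeric(1))
    best <- which.min(abs(midI - target))
    pairs[[length(pairs) + 1L]] <- list(scaffoldLoop = lp,
                                        insertLoop = insertLoops[[best]],
                                        autoPaired = TRUE)
  }
  list(pairs = pairs, unpaired = unpaired)
}

#' Manually pair two loops
#'
#' @param scaffoldLoop,insertLoop \linkS4class{LoopRecord} objects.
#' @return A loop pair (list with \code{autoPaired = FALSE}).
#' @export
pairLoops <- function(scaffoldLoop, insertLoop) {
  list(scaffoldLoop = scaffoldLoop, insertLoop = insertLoop,
       autoPaired = FALSE)
}

# Rescue doublet for an unpaired position: pair it with the partner of the
# nearest paired neighbour in its own sequence (ties to the N-terminal
# side), i.e. the residue flanking the gap in the other sequence.
rescuePartner <- function(pos, own, partner) {
  if (!length(own)) return(NA_integer_)
  off <- abs(own - pos)
  cand <- which(off == min(off))
  k <- cand[which.min(own[cand])]
  partner[k]
}

#' Candidate recombination boundaries of a loop pair
#'
#' Every residue doublet whose scaffold position lies on the scaffold
#' loop's flanking SSE and whose insert position lies on the insert loop's
#' corresponding SSE is a potential boundary. SSE positions unpaired in the
#' global pairing are rescued by pairing them with the residue flanking the
#' gap in the other sequence (the partner of the nearest paired neighbour;
#' ties to the N-terminal side), provided the rescue partner also lies on
#' the corresponding SSE.
#'
#' @param loopPair A loop pair from \code{\link{autoPairLoops}} or
#'   \code{\link{pairLoops}}.
#' @param pairing A \linkS4class{ResiduePairing}.
#' @return List with data.frames \code{n} and \code{c} (columns
#'   \code{scaffoldIdx}, \code{insertIdx}, \code{rescue}); either may have
#'   zero rows, in which case the pair yields no designs.
#' @export
candidateBoundaries <- function(loopPair, pairing) {
  d <- pairing@doublets
  flank <- function(sseS, sseI) {
    sS <- sseS[1]:sseS[2]
    sI <- sseI[1]:sseI[2]
    inS <- d$scaffoldIdx %in% sS & d$insertIdx %in% sI
    out <- data.frame(scaffoldIdx = d$scaffoldIdx[inS],
                      insertIdx = d$insertIdx[inS],
                      rescue = logical(sum(inS)))
    # rescue unpaired scaffold SSE positions
    for (s in setdiff(sS, d$scaffoldIdx)) {
      ip <- rescuePartner(s, d$scaffoldIdx, d$insertIdx)
      if (!is.na(ip) && ip %in% sI)
        out <- rbind(out, data.frame(scaffoldIdx = s, insertIdx = ip,
                                     rescue = TRUE))
    }
    # rescue unpaired insert SSE positions
    for (i in setdiff(sI, d$insertIdx)) {
      sp <- rescuePartner(i, d$insertIdx, d$scaffoldIdx)
      if (!is.na(sp) && sp %in% sS)
        out <- rbind(out, data.frame(scaffoldIdx = sp, insertIdx = i,
                                     rescue = TRUE))
    }
    out <- unique(out)
    out[order(out$scaffoldIdx, out$insertIdx), , drop = FALSE]
  }
  list(n = flank(loopPair$scaffoldLoop@sse1, loopPair$insertLoop@sse1),
       c = flank(loopPair$scaffoldLoop@sse2, loopPair$insertLoop@sse2))
}

# Assemble a chimeric sequence for several ordered, non-overlapping grafts.
# grafts: list of list(label, n = c(s, i), c = c(s, i)).
assembleChimera <- function(scaffoldSeq, insertSeq, grafts,
                            convention = "insert_inclusive") {
  segs <- character(0)
  prov <- character(0)
  src <- integer(0)
  cursor <- 0L  # next scaffold index to emit
  boundaries <- list()
  for (g in grafts) {
    nS <- g$n[1]; nI <- g$n[2]; cS <- g$c[1]; cI <- g$c[2]
    if (nS > cS || nI > cI) stop("invalid boundary order", call. = FALSE)
    if (nS < cursor) stop("conflicting boundaries between adjacent grafts",
                          call. = FALSE)
    if (convention == "insert_inclusive") {
      scafEnd <- nS - 1L            # last scaffold idx before the graft
      insFrom <- nI; insTo <- cI
      resume <- cS + 1L
    } else {
      scafEnd <- nS
      insFrom <- nI + 1L; insTo <- cI - 1L
      resume <- cS
    }
    if (scafEnd >= cursor) {
      idx <- cursor:scafEnd
      segs <- c(segs, scaffoldSeq[idx + 1L])
      prov <- c(prov, rep("scaffold", length(idx)))
      src <- c(src, idx)
    }
    if (insFrom <= insTo) {
      idx <- insFrom:insTo
      segs <- c(segs, insertSeq[idx + 1L])
      prov <- c(prov, rep("insert", length(idx)))
      src <- c(src, idx)
    }
    cursor <- resume
    boundaries[[g$label]] <- list(n = g$n, c = g$c)
  }
  if (cursor <= length(scaffoldSeq) - 1L) {
    idx <- cursor:(length(scaffoldSeq) - 1L)
    segs <- c(segs, scaffoldSeq[idx + 1L])
    prov <- c(prov, rep("scaffold", length(idx)))
    src <- c(src, idx)
  }
  seqStr <- paste(segs, collapse = "")
  new("ChimericDesign", designId = fnv1a32(seqStr), sequence = seqStr,
      provenance = prov, boundaries = boundaries,
      srcIndex = as.integer(src), nLoops = length(grafts))
}

#' Build a single-loop chimera from one boundary pair
#'
#' The chimeric sequence keeps the scaffold outside the graft and the
#' insert between the boundaries; under the default insert-inclusive
#' convention the insert segment includes both boundary residues and the
#' scaffold contributes up to, but excluding, its boundary residues. The
#' grafted region always contains the whole insert coil.
#'
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param loopPair A loop pair.
#' @param nBoundary,cBoundary Integer vectors \code{c(scaffoldIdx,
#'   insertIdx)} (0-based) for the N- and C-terminal boundary doublets.
#' @param convention \code{"insert_inclusive"} (default) or
#'   \code{"scaffold_inclusive"}.
#' @return A \linkS4class{ChimericDesign}.
#' @export
buildChimera <- function(scaffold, insert, loopPair, nBoundary, cBoundary,
                         convention = c("insert_inclusive",
                                        "scaffold_inclusive")) {
  convention <- match.arg(convention)
  assembleChimera(residueSequence(scaffold), residueSequence(insert),
                  list(list(label = loopPair$scaffoldLoop@label,
                            n = nBoundary, c = cBoundary)),
                  convention)
}

#' Enumerate the complete deduplicated chimeric design library
#'
#' For every non-empty subset of the selected loop pairs and every
#' combination of candidate N- and C-terminal boundaries of the included
#' loops, a chimera is built; designs identical in sequence to the scaffold
#' or to a previously constructed design are rejected. Construction order
#' is deterministic: subsets with fewer loops first, boundary combinations
#' in lexicographic order, so the library and its design identifiers are
#' reproducible.
#'
#' @param loopPairs List of loop pairs (all loops selected for grafting).
#' @param pairing A \linkS4class{ResiduePairing}.
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param convention Boundary-membership convention, see
#'   \code{\link{buildChimera}}.
#' @return List of \linkS4class{ChimericDesign}, with an attribute
#'   \code{"counts"}: per-subset design counts after global deduplication.
#' @export
enumerateDesigns <- function(loopPairs, pairing, scaffold, insert,
                             convention = c("insert_inclusive",
                                            "scaffold_inclusive")) {
  convention <- match.arg(convention)
  if (!length(loopPairs)) return(list())
  # order loops by position; coil regions must not overlap (adjacent loops
  # may share a flanking SSE; boundary combinations that conflict there are
  # skipped during enumeration)
  starts <- vapply(loopPairs, function(p) p$scaffoldLoop@sse1[1], numeric(1))
  loopPairs <- loopPairs[order(starts)]
  coils <- lapply(loopPairs, function(p) p$scaffoldLoop@coil)
  if (length(coils) > 1) {
    for (k in 2:length(coils))
      if (coils[[k]][1] <= coils[[k - 1]][2])
        stop("overlapping loop selections", call. = FALSE)
  }
  cands <- lapply(loopPairs, candidateBoundaries, pairing = pairing)
  scafSeq <- residueSequence(scaffold)
  insSeq <- residueSequence(insert)
  scafStr <- paste(scafSeq, collapse = "")

  nL <- length(loopPairs)
  subsets <- list()
  for (size in seq_len(nL)) {
    combs <- utils::combn(nL, size, simplify = FALSE)
    subsets <- c(subsets, combs)
  }
  designs <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  counts <- integer(length(subsets))
  names(counts) <- vapply(subsets, function(ss)
    paste(vapply(loopPairs[ss], function(p) p$scaffoldLoop@label, ""),
          collapse = "+"), "")
  for (si in seq_along(subsets)) {
    ss <- subsets[[si]]
    grids <- lapply(ss, function(k) {
      cn <- cands[[k]]$n; cc <- cands[[k]]$c
      if (!nrow(cn) || !nrow(cc)) return(NULL)
      expand.grid(n = seq_len(nrow(cn)), c = seq_len(nrow(cc)),
                  KEEP.OUT.ATTRS = FALSE)
    })
    if (any(vapply(grids, is.null, logical(1)))) next
    combo <- expand.grid(lapply(grids, function(g) seq_len(nrow(g))),
                         KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combo))) {
      grafts <- lapply(seq_along(ss), function(pos) {
        k <- ss[pos]
        g <- grids[[pos]][combo[r, pos], ]
        list(label = loopPairs[[k]]$scaffoldLoop@label,
             n = c(cands[[k]]$n$scaffoldIdx[g$n], cands[[k]]$n$insertIdx[g$n]),
             c = c(cands[[k]]$c$scaffoldIdx[g$c], cands[[k]]$c$insertIdx[g$c]))
      })
      des <- tryCatch(assembleChimera(scafSeq, insSeq, grafts, convention),
                      error = function(e) NULL)
      if (is.null(des)) next
      if (des@sequence == scafStr) next
      if (!is.null(seen[[des@sequence]])) next
      assign(des@sequence, TRUE, envir = seen)
      designs[[length(designs) + 1L]] <- des
      counts[si] <- counts[si] + 1L
    }
  }
  attr(designs, "counts") <- counts
  designs
}

#' Summary table of a design library
#'
#' @param designs List of \linkS4class{ChimericDesign}.
#' @return \code{data.frame} with designId, nLoops, length, sequence.
#' @export
designTable <- function(designs) {
  data.frame(designId = vapply(designs, function(d) d@designId, ""),
             nLoops = vapply(designs, function(d) d@nLoops, integer(1)),
             length = vapply(designs, function(d) nchar(d@sequence),
                             integer(1)),
             sequence = vapply(designs, function(d) d@sequence, ""),
             stringsAsFactors = FALSE)
}

#' Write a design library as JSON
#'
#' Boundaries are reported in author numbering of the two input chains.
#'
#' @param designs List of \linkS4class{ChimericDesign}.
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param path Output file.
#' @return Invisibly, the JSON string.
#' @export
writeDesignsJson <- function(designs, scaffold, insert, path = NULL) {
  anS <- authorNumbers(scaffold)
  anI <- authorNumbers(insert)
  payload <- lapply(designs, function(d) {
    list(design_id = d@designId,
         n_loops = d@nLoops,
         length = nchar(d@sequence),
         sequence = d@sequence,
         provenance = paste(ifelse(d@provenance == "insert", "I", "S"),
                            collapse = ""),
         boundaries = lapply(d@boundaries, function(b)
           list(n = list(scaffold = anS[b$n[1] + 1L],
                         insert = anI[b$n[2] + 1L]),
                c = list(scaffold = anS[b$c[1] + 1L],
                         insert = anI[b$c[2] + 1L]))))
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' Write design sequences as FASTA
#'
#' @param designs List of \linkS4class{ChimericDesign}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeDesignsFasta <- function(designs, path) {
  seqinr::write.fasta(lapply(designs, function(d)
                        strsplit(d@sequence, "")[[1]]),
                      names = vapply(designs, function(d) d@designId, ""),
                      file.out = path)
  invisible(path)
}
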