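# Loop extraction and super-secondary-structure geometry.
#
# A loop is an SSE-coil-SSE triple. Its geometry is summarised by four
# parameters in the ArchDB convention: the distance D between the two
# bracing-element anchor points, the packing angle theta between the element
# axes, the hoist angle delta between the first axis and the inter-anchor
# line, and the meridian angle rho, the signed dihedral of the second axis
# about the inter-anchor line measured from the plane spanned by the first
# axis and that line. Axes are principal axes of the element's alpha
# carbons, oriented N to C; anchors are the projections of the coil-side
# terminal alpha carbon onto the axis line.

#' Extract loops from an annotation
#'
#' One \linkS4class{LoopRecord} per consecutive (regular, coil, regular)
#' segment triple. Triples spanning a flagged chain break are skipped.
#' Labels are \code{<id>_<chain>_<n>} with \code{n} the author number of the
#' first loop residue.
#'
#' @param annotation An \linkS4class{SSEAnnotation}.
#' @param structure The annotated \linkS4class{ProteinStructure}.
#' @return List of \linkS4class{LoopRecord} (possibly empty).
#' @examples
#' s <- syntheticStructure(list(c("H", 6), c("C", 3), c("H", 6)), seed = 1)
#' ann <- annotationFromStates(attr(s, "truth")$states)
#' extractLoops(ann, s)
#' @export
extractLoops <- function(annotation, structure) {
  seg <- annotation@segments
  loops <- list()
  if (nrow(seg) < 3) return(loops)
  brk <- structure@residues$breakAfter
  for (k in seq_len(nrow(seg) - 2)) {
    s1 <- seg[k, ]; co <- seg[k + 1, ]; s2 <- seg[k + 2, ]
    if (s1$state == "C" || co$state != "C" || s2$state == "C") next
    if (any(brk[(s1$start + 1L):s2$end])) next
    label <- sprintf("%s_%s_%d", structure@id, structure@chainId,
                     structure@residues$authorNumber[s1$start + 1L])
    loops[[length(loops) + 1L]] <- new("LoopRecord", label = label,
      sse1 = c(s1$start, s1$end), coil = c(co$start, co$end),
      sse2 = c(s2$start, s2$end), sse1State = s1$state,
      sse2State = s2$state, userDefined = FALSE)
  }
  loops
}

#' Define a loop from user-chosen residue ranges
#'
#' Builds a user-defined \linkS4class{LoopRecord} from three contiguous
#' author-numbered ranges (first flank, coil, second flank), e.g. to bypass
#' a small structure element inside the region of interest. Geometry is
#' computable regardless of the underlying secondary-structure states.
#'
#' @param structure A \linkS4class{ProteinStructure}.
#' @param sse1Range,coilRange,sse2Range Integer vectors \code{c(first,
#'   last)} in author numbering; must be contiguous, non-overlapping and in
#'   order.
#' @param name Loop name (used as label).
#' @param annotation Optional \linkS4class{SSEAnnotation} used to record the
#'   flank states.
#' @return A \linkS4class{LoopRecord} with \code{userDefined = TRUE}.
#' @export
defineCustomLoop <- function(structure, sse1Range, coilRange, sse2Range,
                             name, annotation = NULL) {
  an <- authorNumbers(structure)
  toIdx <- function(r) {
    i <- which(an >= r[1] & an <= r[2])
    if (!length(i)) stop("range out of bounds", call. = FALSE)
    c(i[1] - 1L, i[length(i)] - 1L)
  }
  i1 <- toIdx(sse1Range); ic <- toIdx(coilRange); i2 <- toIdx(sse2Range)
  if (i1[2] + 1L != ic[1] || ic[2] + 1L != i2[1])
    stop("ranges must be contiguous", call. = FALSE)
  stateAt <- function(idx) {
    if (is.null(annotation)) "C" else annotation@states[idx + 1L]
  }
  new("LoopRecord", label = name, sse1 = i1, coil = ic, sse2 = i2,
      sse1State = stateAt(i1[1]), sse2State = stateAt(i2[1]),
      userDefined = TRUE)
}

#' Axis and anchor of a secondary-structure element
#'
#' The axis is the principal axis (largest-variance direction) of the
#' element's alpha carbons, sign-oriented so it points from the N- to the
#' C-terminal end of the element. The anchor is the projection of the
#' coil-side terminal alpha carbon onto the axis line through the element
#' centroid.
#'
#' @param structure A \linkS4class{ProteinStructure}.
#' @param segment Integer vector \code{c(start, end)} (0-based inclusive).
#' @param coilEnd Which end of the element faces the coil: \code{"C"} (the
#'   element precedes the coil) or \code{"N"} (it follows).
#' @return List with unit \code{axis} and \code{anchor} point (Angstrom).
#' @export
sseVector <- function(structure, segment, coilEnd = c("C", "N")) {
  coilEnd <- match.arg(coilEnd)
  idx <- (segment[1]:segment[2]) + 1L
  if (length(idx) < 2) stop("segment too short", call. = FALSE)
  ca <- caCoords(structure)[idx, , drop = FALSE]
  centered <- sweep(ca, 2, colMeans(ca))
  if (max(abs(centered)) < 1e-9) stop("segment too short", call. = FALSE)
  ax <- svd(centered)$v[, 1]
  dirNC <- ca[nrow(ca), ] - ca[1, ]
  if (sum(ax * dirNC) < 0) ax <- -ax
  terminal <- if (coilEnd == "C") ca[nrow(ca), ] else ca[1, ]
  centroid <- colMeans(ca)
  anchor <- centroid + sum((terminal - centroid) * ax) * ax
  list(axis = as.numeric(ax), anchor = as.numeric(anchor))
}

#' Loop geometry parameters (D, delta, theta, rho)
#'
#' Computes the four ArchDB-style geometry parameters of a loop from the
#' axes and anchors of its bracing elements: \code{D} the inter-anchor
#' distance (Angstrom), \code{theta} (packing) the angle between the two
#' axes, \code{delta} (hoist) the angle between the first axis and the
#' inter-anchor unit vector, and \code{rho} (meridian) the right-handed
#' signed dihedral of the second axis about the inter-anchor line relative
#' to the plane of the first axis and that line. Angles in degrees; theta,
#' delta in [0, 180], rho in (-180, 180]. With coincident anchors rho is
#' undefined and reported as 0 with \code{degenerate = TRUE}.
#'
#' @param structure A \linkS4class{ProteinStructure}.
#' @param loop A \linkS4class{LoopRecord}.
#' @return List with \code{D}, \code{delta}, \code{theta}, \code{rho},
#'   \code{degenerate}.
#' @export
loopGeometry <- function(structure, loop) {
  v1 <- sseVector(structure, loop@sse1, coilEnd = "C")
  v2 <- sseVector(structure, loop@sse2, coilEnd = "N")
  d <- v2$anchor - v1$anchor
  D <- vnorm(d)
  theta <- vangle(v1$axis, v2$axis)
  if (D < 1e-8) {
    return(list(D = 0, delta = NA_real_, theta = theta, rho = 0,
                degenerate = TRUE))
  }
  m <- d / D
  delta <- vangle(v1$axis, m)
  rho <- signedDihedral(v1$axis, v2$axis, m)
  degenerate <- is.na(rho)
  if (degenerate) rho <- 0
  list(D = D, delta = delta, theta = theta, rho = rho,
       degenerate = degenerate)
}

#' Geometry table for a list of loops
#'
#' @param structure A \linkS4class{ProteinStructure}.
#' @param loops List of \linkS4class{LoopRecord}.
#' @return \code{data.frame} with columns label, D, delta, theta, rho.
#' @export
geometryTable <- function(structure, loops) {
  rows <- lapply(loops, function(lp) {
    g <- loopGeometry(structure, lp)
    data.frame(label = lp@label, D = g$D, delta = g$delta, theta = g$theta,
               rho = g$rho, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(label = character(0), D = numeric(0),
                      delta = numeric(0), theta = numeric(0),
                      rho = numeric(0)))
  do.call(rbind, rows)
}
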