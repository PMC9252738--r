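#' @import methods
NULL

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

#' Protein chain with backbone coordinates
#'
#' Holds a single selected chain: one row per residue having an alpha carbon,
#' with author numbering, one-letter amino acid codes, per-residue B-factors
#' (when present in the source file) and chain-break flags. Alpha-carbon
#' coordinates are stored per model (NMR-style ensembles keep all models);
#' backbone N, C and O atoms of the first model are kept for
#' secondary-structure assignment.
#'
#' @slot id Short structure label (e.g. a PDB code).
#' @slot chainId One-character chain identifier.
#' @slot residues \code{data.frame} with columns \code{seqIndex} (0-based,
#'   contiguous), \code{authorNumber}, \code{insCode}, \code{aa},
#'   \code{bFactor}, \code{breakAfter} (TRUE when a chain break follows).
#' @slot ca Numeric array \code{n x 3 x nModels} of alpha-carbon coordinates
#'   in Angstrom.
#' @slot backbone List with matrices \code{N}, \code{C}, \code{O}
#'   (\code{n x 3}, first model; rows may be NA when an atom is absent).
#' @slot nModels Number of coordinate models (>= 1).
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(id = "character", chainId = "character",
                 residues = "data.frame", ca = "array",
                 backbone = "list", nModels = "integer"))

setValidity("ProteinStructure", function(object) {
  n <- nrow(object@residues)
  msg <- character()
  need <- c("seqIndex", "authorNumber", "insCode", "aa", "bFactor", "breakAfter")
  if (!all(need %in% names(object@residues)))
    msg <- c(msg, "residues must have seqIndex/authorNumber/insCode/aa/bFactor/breakAfter")
  else {
    if (n > 0 && !identical(as.integer(object@residues$seqIndex), 0:(n - 1L)))
      msg <- c(msg, "seqIndex must be 0-based and contiguous")
    if (!all(object@residues$aa %in% c(AA1, "X")))
      msg <- c(msg, "aa must be one of the 20 standard letters or 'X'")
  }
  if (object@nModels < 1L) msg <- c(msg, "nModels must be >= 1")
  d <- dim(object@ca)
  if (length(d) != 3 || d[1] != n || d[2] != 3 || d[3] != object@nModels)
    msg <- c(msg, "ca must be an n x 3 x nModels array")
  else if (!all(is.finite(object@ca)))
    msg <- c(msg, "alpha-carbon coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-residue secondary-structure assignment
#'
#' Three-state (H = helix, E = strand, C = coil) assignment aligned to the
#' residues of a \linkS4class{ProteinStructure}, plus the derived segment
#' list. Segments partition the chain; consecutive segments differ in state.
#'
#' @slot states Character vector of per-residue states in \code{c("H","E","C")}.
#' @slot segments \code{data.frame} with columns \code{state}, \code{start},
#'   \code{end} (0-based inclusive residue indices).
#'
#' @exportClass SSEAnnotation
setClass("SSEAnnotation",
  representation(states = "character", segments = "data.frame"))

setValidity("SSEAnnotation", function(object) {
  msg <- character()
  if (!all(object@states %in% c("H", "E", "C")))
    msg <- c(msg, "states must be H, E or C")
  seg <- object@segments
  if (nrow(seg)) {
    if (seg$start[1] != 0L || seg$end[nrow(seg)] != length(object@states) - 1L)
      msg <- c(msg, "segments must cover the full residue range")
    if (nrow(seg) > 1) {
      if (!all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
        msg <- c(msg, "segments must tile the range without gaps or overlap")
      if (any(seg$state[-1] == seg$state[-nrow(seg)]))
        msg <- c(msg, "consecutive segments must have different states")
    }
  } else if (length(object@states)) {
    msg <- c(msg, "non-empty annotation must have segments")
  }
  if (length(msg)) msg else TRUE
})

#' Loop (SSE-coil-SSE super-secondary structure)
#'
#' A loop is the unit of grafting: two regular secondary-structure elements
#' (helix or strand) and the coil segment joining them. Ranges are 0-based
#' inclusive residue indices into the parent structure.
#'
#' @slot label Loop identifier, \code{<id>_<chain>_<authorNumber>} using the
#'   author number of the first loop residue.
#' @slot sse1,coil,sse2 Integer vectors \code{c(start, end)}.
#' @slot sse1State,sse2State \code{"H"} or \code{"E"} (any state when
#'   user-defined).
#' @slot userDefined TRUE for loops drawn by the user rather than extracted
#'   from the annotation.
#'
#' @exportClass LoopRecord
setClass("LoopRecord",
  representation(label = "character", sse1 = "integer", coil = "integer",
                 sse2 = "integer", sse1State = "character",
                 sse2State = "character", userDefined = "logical"))

setValidity("LoopRecord", function(object) {
  msg <- character()
  if (object@sse1[2] + 1L != object@coil[1] || object@coil[2] + 1L != object@sse2[1])
    msg <- c(msg, "sse1, coil, sse2 must be contiguous and in order")
  if (any(c(diff(object@sse1), diff(object@coil), diff(object@sse2)) < 0))
    msg <- c(msg, "segment ranges must satisfy start <= end")
  if (!object@userDefined &&
      !(object@sse1State %in% c("H", "E") && object@sse2State %in% c("H", "E")))
    msg <- c(msg, "flanking segments must be regular (H or E) unless user-defined")
  if (length(msg)) msg else TRUE
})

#' Per-residue flexibility profile
#'
#' B-factor-scale flexibility values from one source: crystallographic
#' temperature factors, NMR-ensemble fluctuations, or theoretical values from
#' a Gaussian or anisotropic elastic network model. Segment and loop averages
#' are arithmetic means of the per-residue values.
#'
#' @slot source One of \code{"crystal"}, \code{"nmr_ensemble"}, \code{"gnm"},
#'   \code{"anm"}.
#' @slot residueValues Per-residue values (Angstrom^2 for experimental
#'   sources; elastic-network values are in the same units after rescaling to
#'   the experimental mean, otherwise arbitrary).
#' @slot segmentValues Mean value per annotation segment (may be empty).
#' @slot loopValues Mean value per loop, named by loop label (may be empty).
#'
#' @exportClass FlexibilityProfile
setClass("FlexibilityProfile",
  representation(source = "character", residueValues = "numeric",
                 segmentValues = "numeric", loopValues = "numeric"))

setValidity("FlexibilityProfile", function(object) {
  if (!object@source %in% c("crystal", "nmr_ensemble", "gnm", "anm"))
    return("source must be crystal, nmr_ensemble, gnm or anm")
  TRUE
})

#' Residue-to-residue cross-correlation map
#'
#' Normalised covariances of residue displacement vectors computed from
#' elastic-network modes: symmetric, unit diagonal, values in [-1, 1].
#'
#' @slot matrix N x N numeric matrix.
#' @slot modeCount Number of modes used.
#'
#' @exportClass CrossCorrelationMap
setClass("CrossCorrelationMap",
  representation(matrix = "matrix", modeCount = "integer"))

setValidity("CrossCorrelationMap", function(object) {
  m <- object@matrix
  tol <- 1e-9
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else {
    if (max(abs(m - t(m))) > tol) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(m) - 1)) > tol) msg <- c(msg, "diagonal must be 1")
    if (any(m > 1 + tol | m < -1 - tol)) msg <- c(msg, "values must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition result
#'
#' Transform mapping insert coordinates onto the scaffold frame
#' (\code{x -> x R + t}, row-vector convention), with the RMSD over the
#' aligned alpha-carbon pairs used for the final fit.
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation Length-3 translation in Angstrom.
#' @slot rmsd RMSD in Angstrom over aligned pairs.
#' @slot alignedPairs Integer matrix, columns \code{scaffoldIdx},
#'   \code{insertIdx} (0-based).
#'
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", alignedPairs = "matrix"))

setValidity("Superposition", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)) || abs(det(R) - 1) > 1e-6 ||
      max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "rotation must be a proper orthonormal 3 x 3 matrix")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Filtered residue-doublet pairing
#'
#' Ordered list of structurally equivalent residue pairs (scaffold index,
#' insert index, alpha-carbon distance) derived from a superposition by
#' greedy closest-atom pairing, correlativity enforcement and sequence-offset
#' outlier removal. Indices are 0-based and strictly increasing on both
#' sides.
#'
#' @slot doublets \code{data.frame} with columns \code{scaffoldIdx},
#'   \code{insertIdx}, \code{dist}.
#' @slot gaps List with integer vectors \code{scaffold} and \code{insert} of
#'   unpaired residue indices.
#' @slot params List with \code{distanceCutoff} and \code{outlierK}.
#'
#' @exportClass ResiduePairing
setClass("ResiduePairing",
  representation(doublets = "data.frame", gaps = "list", params = "list"))

setValidity("ResiduePairing", function(object) {
  d <- object@doublets
  msg <- character()
  if (nrow(d) > 1) {
    if (any(diff(d$scaffoldIdx) <= 0) || any(diff(d$insertIdx) <= 0))
      msg <- c(msg, "doublets must be strictly increasing in both indices")
  }
  if (anyDuplicated(d$scaffoldIdx) || anyDuplicated(d$insertIdx))
    msg <- c(msg, "each residue may appear in at most one doublet")
  if (!is.null(object@params$distanceCutoff) && nrow(d) &&
      any(d$dist > object@params$distanceCutoff + 1e-9))
    msg <- c(msg, "doublet distances must respect the cutoff")
  if (length(msg)) msg else TRUE
})

#' A single chimeric design
#'
#' Full-length chimeric sequence produced by grafting one or more loops,
#' with per-position provenance (scaffold or insert) and the boundary
#' doublets that define each graft.
#'
#' @slot designId Stable hash of the sequence.
#' @slot sequence One-letter chimeric sequence.
#' @slot provenance Character vector (\code{"scaffold"}/\code{"insert"}) per
#'   position.
#' @slot boundaries Named list (by scaffold loop label); each element has
#'   integer vectors \code{n} and \code{c}, each \code{c(scaffoldIdx,
#'   insertIdx)} (0-based).
#' @slot srcIndex 0-based residue index into the source chain (scaffold or
#'   insert according to \code{provenance}) for every position.
#' @slot nLoops Number of loops grafted.
#'
#' @exportClass ChimericDesign
setClass("ChimericDesign",
  representation(designId = "character", sequence = "character",
                 provenance = "character", boundaries = "list",
                 srcIndex = "integer", nLoops = "integer"))

setValidity("ChimericDesign", function(object) {
  if (length(object@provenance) != nchar(object@sequence))
    return("provenance must have one tag per sequence position")
  if (!all(object@provenance %in% c("scaffold", "insert")))
    return("provenance tags must be 'scaffold' or 'insert'")
  if (length(object@srcIndex) != length(object@provenance))
    return("srcIndex must have one entry per position")
  TRUE
})
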