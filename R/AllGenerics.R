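#' @include AllClasses.R
NULL

#' Number of residues
#' @param x A \linkS4class{ProteinStructure}.
#' @return Integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of coordinate models
#' @param x A \linkS4class{ProteinStructure}.
#' @return Integer model count (1 for crystal structures).
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Alpha-carbon coordinates
#' @param x A \linkS4class{ProteinStructure}.
#' @param model Model number (1-based).
#' @return \code{n x 3} matrix in Angstrom.
#' @export
setGeneric("caCoords", function(x, model = 1L) standardGeneric("caCoords"))

#' One-letter residue sequence
#' @param x A \linkS4class{ProteinStructure}.
#' @param collapse If TRUE return a single string, else a character vector.
#' @return Character vector or string.
#' @export
setGeneric("residueSequence",
  function(x, collapse = FALSE) standardGeneric("residueSequence"))

#' Author residue numbers
#' @param x A \linkS4class{ProteinStructure}.
#' @return Integer vector of author numbers.
#' @export
setGeneric("authorNumbers", function(x) standardGeneric("authorNumbers"))

setMethod("nResidues", "ProteinStructure", function(x) nrow(x@residues))
setMethod("nModels", "ProteinStructure", function(x) x@nModels)
setMethod("caCoords", "ProteinStructure", function(x, model = 1L) {
  stopifnot(model >= 1L, model <= x@nModels)
  m <- x@ca[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
setMethod("residueSequence", "ProteinStructure", function(x, collapse = FALSE) {
  s <- x@residues$aa
  if (collapse) paste(s, collapse = "") else s
})
setMethod("authorNumbers", "ProteinStructure", function(x) x@residues$authorNumber)

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s' chain %s: %d residues, %d model(s)\n",
              object@id, object@chainId, nResidues(object), object@nModels))
  if (nResidues(object)) {
    an <- object@residues$authorNumber
    cat(sprintf("  author numbering %d..%d; %d chain break(s)\n",
                an[1], an[length(an)], sum(object@residues$breakAfter)))
  }
  invisible(object)
})

setMethod("show", "SSEAnnotation", function(object) {
  tab <- table(factor(object@states, levels = c("H", "E", "C")))
  cat(sprintf("SSEAnnotation: %d residues (H %d, E %d, C %d), %d segments\n",
              length(object@states), tab["H"], tab["E"], tab["C"],
              nrow(object@segments)))
  invisible(object)
})

setMethod("show", "LoopRecord", function(object) {
  cat(sprintf("LoopRecord %s: %s[%d-%d] C[%d-%d] %s[%d-%d]%s\n",
              object@label, object@sse1State, object@sse1[1], object@sse1[2],
              object@coil[1], object@coil[2],
              object@sse2State, object@sse2[1], object@sse2[2],
              if (object@userDefined) " (user-defined)" else ""))
  invisible(object)
})

setMethod("show", "FlexibilityProfile", function(object) {
  cat(sprintf("FlexibilityProfile (%s): %d residues, mean %.3g\n",
              object@source, length(object@residueValues),
              mean(object@residueValues)))
  invisible(object)
})

setMethod("show", "CrossCorrelationMap", function(object) {
  cat(sprintf("CrossCorrelationMap: %d x %d, %d modes\n",
              nrow(object@matrix), ncol(object@matrix), object@modeCount))
  invisible(object)
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: %d aligned pairs, RMSD %.3f A\n",
              nrow(object@alignedPairs), object@rmsd))
  invisible(object)
})

setMethod("show", "ResiduePairing", function(object) {
  cat(sprintf("ResiduePairing: %d doublets (cutoff %.2f A), %d + %d unpaired\n",
              nrow(object@doublets), object@params$distanceCutoff,
              length(object@gaps$scaffold), length(object@gaps$insert)))
  invisible(object)
})

setMethod("show", "ChimericDesign", function(object) {
  cat(sprintf("ChimericDesign %s: %d aa, %d loop(s) grafted, %d insert positions\n",
              object@designId, nchar(object@sequence), object@nLoops,
              sum(object@provenance == "insert")))
  invisible(object)
})

#' Loop label accessor
#' @param x A \linkS4class{LoopRecord}.
#' @return Character label.
#' @export
setGeneric("loopLabel", function(x) standardGeneric("loopLabel"))

#' @rdname loopLabel
setMethod("loopLabel", "LoopRecord", function(x) x@label)

#' Full 0-based residue range of a loop (sse1 start to sse2 end)
#' @param x A \linkS4class{LoopRecord}.
#' @return Integer vector of residue indices.
#' @export
loopRange <- function(x) x@sse1[1]:x@sse2[2]

#' Coil residue indices of a loop (0-based)
#' @param x A \linkS4class{LoopRecord}.
#' @return Integer vector of residue indices.
#' @export
coilRange <- function(x) x@coil[1]:x@coil[2]

#' Per-residue values of a flexibility profile
#' @param x A \linkS4class{FlexibilityProfile}.
#' @return Numeric vector.
#' @export
residueValues <- function(x) x@residueValues

#' Doublet table of a residue pairing
#' @param x A \linkS4class{ResiduePairing}.
#' @return \code{data.frame} with scaffoldIdx, insertIdx, dist.
#' @export
doublets <- function(x) x@doublets

#' Cross-correlation matrix accessor
#' @param x A \linkS4class{CrossCorrelationMap}.
#' @return Numeric matrix.
#' @export
correlationMatrix <- function(x) x@matrix

#' Chimeric sequence accessor
#' @param x A \linkS4class{ChimericDesign}.
#' @return One-letter sequence string.
#' @export
designSequence <- function(x) x@sequence

#' Design identifier accessor
#' @param x A \linkS4class{ChimericDesign}.
#' @return Character id (sequence hash).
#' @export
designId <- function(x) x@designId
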