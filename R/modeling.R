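# Per-design modelling inputs: trimmed scaffold template, locally
# superposed insert fragments, target-template alignment (PIR), and
# ingestion/ranking of externally computed model scores. The external
# modelling and scoring tools themselves are never run here; adapters only
# prepare their inputs and parse their outputs.

# Subset of a structure by 0-based residue indices (kept in order);
# excision points are flagged as chain breaks.
subsetStructure <- function(x, keepIdx0) {
  keep <- sort(unique(as.integer(keepIdx0)))
  rows <- keep + 1L
  res <- x@residues[rows, , drop = FALSE]
  gapAfter <- c(diff(keep) > 1L, FALSE)
  res$breakAfter <- res$breakAfter | gapAfter
  res$seqIndex <- 0:(length(rows) - 1L)
  rownames(res) <- NULL
  new("ProteinStructure", id = x@id, chainId = x@chainId, residues = res,
      ca = x@ca[rows, , , drop = FALSE],
      backbone = lapply(x@backbone, function(m) m[rows, , drop = FALSE]),
      nModels = x@nModels)
}

transformStructure <- function(x, rotation, translation) {
  for (m in seq_len(x@nModels))
    x@ca[, , m] <- applyTransform(x@ca[, , m], rotation, translation)
  x@backbone <- lapply(x@backbone, function(mat) {
    ok <- !is.na(mat[, 1])
    mat[ok, ] <- applyTransform(mat[ok, , drop = FALSE], rotation, translation)
    mat
  })
  x
}

#' Prepare modelling templates and alignment for one design
#'
#' Builds the per-design template bundle: (i) the scaffold template with
#' the coil segments of every grafted loop removed; (ii) one insert
#' fragment per grafted loop (the whole super-secondary range: coil plus
#' flanking SSEs), each independently superposed onto the corresponding
#' scaffold region using the residue doublets of that region and then
#' re-paired locally; and (iii) a target-template alignment whose gap
#' placement follows the local pairings. In the alignment, grafted coil
#' positions are covered only by the insert fragment, positions outside
#' the grafted loops only by the scaffold template, and overlaid flanking
#' SSE positions by both (so that downstream modelling receives spatial
#' restraints from both templates there).
#'
#' @param design A \linkS4class{ChimericDesign}.
#' @param scaffold,insert \linkS4class{ProteinStructure} objects.
#' @param loopPairs The loop pairs used for enumeration.
#' @param pairing The global \linkS4class{ResiduePairing}.
#' @return List with \code{scaffoldTemplate}, \code{fragments} (named list
#'   of transformed \linkS4class{ProteinStructure}), \code{alignment}
#'   (named character vector of gapped rows: \code{target},
#'   \code{scaffold}, one per fragment) and \code{design}.
#' @export
prepareTemplates <- function(design, scaffold, insert, loopPairs, pairing) {
  labels <- names(design@boundaries)
  pairsByLabel <- stats::setNames(loopPairs,
    vapply(loopPairs, function(p) p$scaffoldLoop@label, ""))
  grafted <- pairsByLabel[labels]
  if (any(vapply(grafted, is.null, logical(1))))
    stop("design references unknown loop labels", call. = FALSE)

  nS <- nResidues(scaffold)
  removed <- unlist(lapply(grafted, function(p) coilRange(p$scaffoldLoop)))
  keepScaf <- setdiff(0:(nS - 1L), removed)
  scafTemplate <- subsetStructure(scaffold, keepScaf)

  d <- pairing@doublets
  fragments <- list()
  localPairings <- list()
  for (lab in labels) {
    p <- grafted[[lab]]
    regIdx <- loopRange(p$scaffoldLoop)
    fragIdx <- loopRange(p$insertLoop)
    seedS <- d$scaffoldIdx %in% regIdx & d$insertIdx %in% fragIdx
    if (sum(seedS) < 3) stop("fragment not alignable", call. = FALSE)
    fit <- kabsch(caCoords(scaffold)[d$scaffoldIdx[seedS] + 1L, , drop = FALSE],
                  caCoords(insert)[d$insertIdx[seedS] + 1L, , drop = FALSE])
    frag <- subsetStructure(insert, fragIdx)
    regS <- subsetStructure(scaffold, regIdx)
    spLocal <- new("Superposition", rotation = fit$rotation,
                   translation = fit$translation, rmsd = fit$rmsd,
                   alignedPairs = matrix(integer(0), 0, 2))
    lp <- tryCatch(greedyPairing(regS, frag, spLocal),
                   error = function(e) NULL)
    if (is.null(lp)) stop("fragment not alignable", call. = FALSE)
    ld <- lp@doublets
    localPairings[[lab]] <- data.frame(
      scaffoldIdx = regIdx[1] + ld$scaffoldIdx,
      insertIdx = fragIdx[1] + ld$insertIdx)
    fragments[[lab]] <- transformStructure(frag, fit$rotation,
                                           fit$translation)
  }

  alignment <- buildDesignAlignment(design, scaffold, insert, grafted,
                                    keepScaf, localPairings)
  list(scaffoldTemplate = scafTemplate, fragments = fragments,
       alignment = alignment, design = design)
}

# Multiple alignment of target, trimmed scaffold template and fragments.
# Aligned columns follow the design positions; template residues without a
# target position become insertion columns (target gap).
buildDesignAlignment <- function(design, scaffold, insert, grafted,
                                 keepScaf, localPairings) {
  L <- nchar(design@sequence)
  seqT <- strsplit(design@sequence, "")[[1]]
  seqS <- residueSequence(scaffold)
  seqI <- residueSequence(insert)
  labels <- names(grafted)
  nRows <- 1L + length(labels)  # scaffold template + one row per fragment

  # per-row residue lists (global indices, emitted in order)
  rowRes <- c(list(scaffold = keepScaf),
              stats::setNames(lapply(grafted, function(p)
                loopRange(p$insertLoop)), labels))
  rowChar <- c(list(scaffold = seqS),
               stats::setNames(rep(list(seqI), length(labels)), labels))

  # alignTo[[row]][as.character(residueIdx)] = design position (0-based)
  alignTo <- lapply(rowRes, function(r)
    stats::setNames(rep(NA_integer_, length(r)), r))
  coilOf <- lapply(grafted, function(p) coilRange(p$insertLoop))
  graftSpan <- lapply(labels, function(lab)
    design@boundaries[[lab]])
  names(graftSpan) <- labels
  pairBySIdx <- lapply(localPairings, function(lp)
    stats::setNames(lp$insertIdx, lp$scaffoldIdx))
  pairByIIdx <- lapply(localPairings, function(lp)
    stats::setNames(lp$scaffoldIdx, lp$insertIdx))

  for (p in seq_len(L) - 1L) {
    src <- design@srcIndex[p + 1L]
    if (design@provenance[p + 1L] == "scaffold") {
      alignTo$scaffold[as.character(src)] <- p
      for (lab in labels) {
        # fragment flank residue paired to this scaffold residue
        i <- pairBySIdx[[lab]][as.character(src)]
        if (!is.na(i) && i %in% rowRes[[lab]] && !(i %in% coilOf[[lab]]))
          alignTo[[lab]][as.character(i)] <- p
      }
    } else {
      for (lab in labels) {
        if (src %in% rowRes[[lab]] &&
            src >= graftSpan[[lab]]$n[2] && src <= graftSpan[[lab]]$c[2]) {
          alignTo[[lab]][as.character(src)] <- p
          # scaffold SSE residue paired to this insert residue (never for
          # coil positions: the scaffold coil is removed from the template)
          if (!(src %in% coilOf[[lab]])) {
            s <- pairByIIdx[[lab]][as.character(src)]
            if (!is.na(s) && s %in% keepScaf)
              alignTo$scaffold[as.character(s)] <- p
          }
        }
      }
    }
  }

  rowNames <- c("scaffold", labels)
  out <- stats::setNames(rep(list(character(0)), nRows + 1L),
                         c("target", rowNames))
  ptr <- stats::setNames(rep(1L, nRows), rowNames)
  emitInsertions <- function(row, upto) {
    # flush row residues with no (or an already-passed) target position as
    # insertion columns, up to the next residue aligned at >= upto
    while (ptr[[row]] <= length(rowRes[[row]])) {
      a <- alignTo[[row]][ptr[[row]]]
      if (!is.na(a) && a >= upto) break
      for (nm in names(out))
        out[[nm]] <<- c(out[[nm]],
          if (nm == row) rowChar[[row]][rowRes[[row]][ptr[[row]]] + 1L]
          else "-")
      ptr[row] <<- ptr[[row]] + 1L
    }
  }
  for (p in seq_len(L) - 1L) {
    for (row in rowNames) emitInsertions(row, p)
    col <- stats::setNames(rep("-", nRows + 1L), c("target", rowNames))
    col["target"] <- seqT[p + 1L]
    for (row in rowNames) {
      if (ptr[[row]] <= length(rowRes[[row]])) {
        a <- alignTo[[row]][ptr[[row]]]
        if (!is.na(a) && a == p) {
          col[row] <- rowChar[[row]][rowRes[[row]][ptr[[row]]] + 1L]
          ptr[row] <- ptr[[row]] + 1L
        }
      }
    }
    for (nm in names(out)) out[[nm]] <- c(out[[nm]], col[[nm]])
  }
  for (row in rowNames) emitInsertions(row, Inf)
  vapply(out, paste, character(1), collapse = "")
}

#' Write a template bundle as a PIR alignment
#'
#' One structure entry per template (trimmed scaffold, then each insert
#' fragment) and a final sequence entry for the design; the dialect is the
#' one consumed by homology-modelling tools (structure rows reference the
#' template coordinate files).
#'
#' @param bundle Result of \code{\link{prepareTemplates}}.
#' @param path Output file; NULL returns the text invisibly.
#' @return Invisibly, the PIR text as a character vector of lines.
#' @export
writePirAlignment <- function(bundle, path = NULL) {
  aln <- bundle$alignment
  design <- bundle$design
  wrap <- function(s) {
    starts <- seq(1, nchar(s), by = 60)
    substring(s, starts, pmin(starts + 59, nchar(s)))
  }
  lines <- character(0)
  entry <- function(name, header, seq) {
    c(sprintf(">P1;%s", name), header, wrap(paste0(seq, "*")))
  }
  scafName <- "scaffold_template"
  lines <- c(lines, entry(scafName,
    sprintf("structureX:%s:FIRST:%s:LAST:%s::::", scafName,
            bundle$scaffoldTemplate@chainId,
            bundle$scaffoldTemplate@chainId),
    aln[["scaffold"]]))
  fragNames <- setdiff(names(aln), c("target", "scaffold"))
  for (k in seq_along(fragNames)) {
    nm <- sprintf("fragment_%d", k)
    lines <- c(lines, entry(nm,
      sprintf("structureX:%s:FIRST:%s:LAST:%s::::", nm,
              bundle$fragments[[fragNames[k]]]@chainId,
              bundle$fragments[[fragNames[k]]]@chainId),
      aln[[fragNames[k]]]))
  }
  lines <- c(lines, entry(design@designId,
    sprintf("sequence:%s::::::::", design@designId), aln[["target"]]))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a PIR alignment file
#'
#' @param path File path or character vector of PIR lines.
#' @return \code{data.frame} with columns name, type, sequence (gapped,
#'   without the terminal asterisk).
#' @export
readPir <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else path
  starts <- grep("^>P1;", lines)
  if (!length(starts)) stop("not a PIR file", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  rows <- lapply(seq_along(starts), function(k) {
    name <- sub("^>P1;", "", lines[starts[k]])
    header <- lines[starts[k] + 1L]
    seq <- paste(lines[(starts[k] + 2L):ends[k]], collapse = "")
    seq <- sub("\\*.*$", "", gsub("[[:space:]]", "", seq))
    data.frame(name = name, type = sub(":.*$", "", header), sequence = seq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ingest external model scores and rank designs
#'
#' Merges per-design model-energy scores from the two external evaluation
#' routes (a DOPE-style model energy and a Rosetta-style combined score)
#' and assigns dense ranks per metric, lower score = better = rank 1; ties
#' share a rank. Designs missing a metric are flagged and left unranked
#' for it.
#'
#' @param designs List of \linkS4class{ChimericDesign} (the library the
#'   scores refer to).
#' @param dope,rosetta \code{data.frame} with columns \code{design_id},
#'   \code{score}, or a path to a TSV file with those columns; either may
#'   be NULL.
#' @return \code{data.frame} with designId, nLoops, length, dope,
#'   dopeRank, rosetta, rosettaRank, flags.
#' @export
ingestScores <- function(designs, dope = NULL, rosetta = NULL) {
  ids <- vapply(designs, function(d) d@designId, "")
  readScores <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x))
      x <- utils::read.table(x, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("design_id", "score") %in% names(x)))
    orphan <- setdiff(x$design_id, ids)
    if (length(orphan))
      stop("orphan score: unknown design_id ", paste(orphan, collapse = ", "),
           call. = FALSE)
    stats::setNames(x$score, x$design_id)
  }
  dv <- readScores(dope)
  rv <- readScores(rosetta)
  denseRank <- function(v) {
    r <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    r[ok] <- match(v[ok], sort(unique(v[ok])))
    r
  }
  dCol <- if (is.null(dv)) rep(NA_real_, length(ids)) else unname(dv[ids])
  rCol <- if (is.null(rv)) rep(NA_real_, length(ids)) else unname(rv[ids])
  flags <- mapply(function(a, b) {
    f <- c(if (is.na(a)) "missing_dope", if (is.na(b)) "missing_rosetta")
    paste(f, collapse = ";")
  }, dCol, rCol)
  data.frame(designId = ids,
             nLoops = vapply(designs, function(d) d@nLoops, integer(1)),
             length = vapply(designs, function(d) nchar(d@sequence),
                             integer(1)),
             dope = dCol, dopeRank = denseRank(dCol),
             rosetta = rCol, rosettaRank = denseRank(rCol),
             flags = unname(flags), stringsAsFactors = FALSE)
}
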