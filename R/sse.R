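# Secondary-structure assignment and user overrides.

MIN_SSE_LEN <- c(H = 3L, E = 2L)

# Runs of equal states as a segment table (0-based inclusive).
rleSegments <- function(states) {
  r <- rle(states)
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = as.integer(end - r$lengths),
             end = as.integer(end - 1L), stringsAsFactors = FALSE)
}

# Absorb H/E runs shorter than the minimum element length into coil.
enforceMinSseLen <- function(states, minLen = MIN_SSE_LEN) {
  seg <- rleSegments(states)
  for (k in seq_len(nrow(seg))) {
    st <- seg$state[k]
    if (st %in% names(minLen) &&
        (seg$end[k] - seg$start[k] + 1L) < minLen[[st]])
      states[(seg$start[k] + 1L):(seg$end[k] + 1L)] <- "C"
  }
  states
}

#' Build an annotation from a per-residue state vector
#'
#' Constructs an \linkS4class{SSEAnnotation} from given three-state
#' assignments, enforcing the minimum element lengths (3 residues for
#' helices, 2 for strands; shorter runs are absorbed into coil).
#'
#' @param states Character vector (or single string) of \code{"H"},
#'   \code{"E"}, \code{"C"}.
#' @param enforceMin Apply the minimum-length rule (default TRUE).
#' @return An \linkS4class{SSEAnnotation}.
#' @export
annotationFromStates <- function(states, enforceMin = TRUE) {
  if (length(states) == 1 && nchar(states[1]) > 1)
    states <- strsplit(states, "")[[1]]
  if (enforceMin) states <- enforceMinSseLen(states)
  new("SSEAnnotation", states = states, segments = rleSegments(states))
}

# Kabsch-Sander hydrogen-bond energies. hbond[i, j] is the electrostatic
# energy (kcal/mol) of the CO group of residue i with the NH group of
# residue j; a bond exists when the energy is below -0.5.
ksHbondEnergy <- function(structure) {
  n <- nResidues(structure)
  ca <- caCoords(structure)
  Nc <- structure@backbone$N
  Cc <- structure@backbone$C
  Oc <- structure@backbone$O
  if (any(is.na(Oc)) || any(is.na(Nc)) || any(is.na(Cc)))
    stop("incomplete backbone", call. = FALSE)
  brk <- structure@residues$breakAfter
  # amide H: 1 A from N, along the C=O direction of the preceding residue
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (brk[i - 1]) next
    H[i, ] <- Nc[i, ] + unitv(Cc[i - 1, ] - Oc[i - 1, ])
  }
  hasDonor <- !is.na(H[, 1]) & structure@residues$aa != "P"
  E <- matrix(Inf, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !hasDonor[j]) next
      if (sum((ca[i, ] - ca[j, ])^2) > 81) next  # CA-CA > 9 A: no bond
      rON <- vnorm(Oc[i, ] - Nc[j, ])
      rCH <- vnorm(Cc[i, ] - H[j, ])
      rOH <- vnorm(Oc[i, ] - H[j, ])
      rCN <- vnorm(Cc[i, ] - Nc[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) {
        E[i, j] <- -9.9
      } else {
        E[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      }
    }
  }
  E
}

assignSSEInternal <- function(structure) {
  n <- nResidues(structure)
  if (n < 3) return(rep("C", n))
  E <- ksHbondEnergy(structure)
  bond <- E < -0.5
  brk <- structure@residues$breakAfter
  spansBreak <- function(i, j) any(brk[seq(min(i, j), max(i, j) - 1L)])
  turn <- function(nt) {
    ok <- rep(FALSE, n)
    idx <- seq_len(n - nt)
    for (i in idx) if (bond[i, i + nt] && !spansBreak(i, i + nt)) ok[i] <- TRUE
    ok
  }
  helix <- rep(FALSE, n)
  for (nt in c(4L, 3L, 5L)) {
    tn <- turn(nt)
    for (i in seq_len(n)) {
      # minimal helix: two consecutive n-turns starting at i-1 and i
      if (i >= 2 && i + nt <= n && tn[i - 1] && tn[i])
        helix[i:(i + nt - 1L)] <- TRUE
    }
  }
  bridge <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      par <- (i > 1 && i < n && bond[i - 1, j] && bond[j, i + 1]) ||
             (j > 1 && j < n && bond[j - 1, i] && bond[i, j + 1])
      anti <- (bond[i, j] && bond[j, i]) ||
              (i > 1 && j < n && i < n && j > 1 &&
               bond[i - 1, j + 1] && bond[j - 1, i + 1])
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  states <- rep("C", n)
  states[bridge] <- "E"
  states[helix] <- "H"  # helix takes precedence in the 3-state collapse
  states
}

#' Assign per-residue secondary structure
#'
#' Three-state secondary structure (H = helix, E = strand, C = coil) for a
#' chain. The internal backend implements the Kabsch-Sander hydrogen-bond
#' energy \eqn{E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
#' 1/r_{CN})} kcal/mol with a bond threshold of \eqn{E < -0.5} and the
#' standard n-turn helix and bridge/ladder strand patterns; 8-state detail
#' (3-10 and pi helices, isolated bridges) is collapsed to three states
#' (helical patterns to H, bridges to E, everything else to C). The
#' \code{"dssp"} backend shells out to an installed DSSP executable and
#' parses its classic output with the same collapse. Helix runs shorter
#' than 3 residues and strand runs shorter than 2 are absorbed into coil.
#'
#' @param structure A \linkS4class{ProteinStructure} with backbone N, CA, C,
#'   O atoms (internal backend).
#' @param backend \code{"internal"} (default) or \code{"dssp"}.
#' @param dsspExe Path to the DSSP executable for the adapter backend;
#'   defaults to \code{mkdssp}/\code{dssp} found on the PATH.
#' @return An \linkS4class{SSEAnnotation}.
#' @examples
#' h <- syntheticStructure(list(c("H", 12)), seed = 1)
#' table(assignSSE(h)@states)
#' @export
assignSSE <- function(structure, backend = c("internal", "dssp"),
                      dsspExe = NULL) {
  backend <- match.arg(backend)
  states <- if (backend == "internal") {
    assignSSEInternal(structure)
  } else {
    assignSSEDssp(structure, dsspExe)
  }
  annotationFromStates(states)
}

# Adapter around an external DSSP executable (classic output format).
assignSSEDssp <- function(structure, dsspExe = NULL) {
  if (is.null(dsspExe)) {
    dsspExe <- Sys.which(c("mkdssp", "dssp"))
    dsspExe <- dsspExe[dsspExe != ""][1]
  }
  if (is.na(dsspExe) || !nzchar(dsspExe))
    stop("backend unavailable: no DSSP executable found", call. = FALSE)
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".dssp")
  on.exit(unlink(c(pdb, out)), add = TRUE)
  writeStructurePdb(structure, pdb)
  status <- system2(dsspExe, c(pdb, out), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out))
    stop("backend unavailable: DSSP run failed", call. = FALSE)
  lines <- readLines(out)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("backend unavailable: unrecognised DSSP output",
                         call. = FALSE)
  body <- lines[(hdr[1] + 1):length(lines)]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ss8 <- substr(body, 17, 17)
  keep <- !is.na(resno) & substr(body, 12, 12) == structure@chainId
  map <- setNames(ss8[keep], resno[keep])
  collapse <- function(s) {
    if (s %in% c("H", "G", "I")) "H" else if (s %in% c("E", "B")) "E" else "C"
  }
  states <- vapply(as.character(authorNumbers(structure)), function(an) {
    s <- map[an]
    if (is.na(s)) "C" else collapse(s)
  }, character(1))
  unname(states)
}

#' Override the secondary-structure state of a residue range
#'
#' Replaces the assignment over an author-numbered residue range (e.g. to
#' delete a small helical element before loop extraction) and recomputes the
#' segment list; the minimum element-length rule is re-applied so that
#' short leftover regular fragments are absorbed into the surrounding coil.
#' The operation is idempotent, and overrides of disjoint ranges commute.
#'
#' @param annotation An \linkS4class{SSEAnnotation}.
#' @param structure The annotated \linkS4class{ProteinStructure} (provides
#'   the author-number mapping).
#' @param authorRange Integer vector \code{c(first, last)} in author
#'   numbering (inclusive).
#' @param newState \code{"H"}, \code{"E"} or \code{"C"}.
#' @return A new \linkS4class{SSEAnnotation}.
#' @export
applyOverride <- function(annotation, structure, authorRange, newState) {
  stopifnot(newState %in% c("H", "E", "C"))
  an <- authorNumbers(structure)
  idx <- which(an >= authorRange[1] & an <= authorRange[length(authorRange)])
  if (!length(idx) || authorRange[1] < min(an) ||
      authorRange[length(authorRange)] > max(an))
    stop("range out of bounds", call. = FALSE)
  states <- annotation@states
  states[idx] <- newState
  annotationFromStates(states)
}
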