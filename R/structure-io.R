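#' Parse a protein chain from a PDB file
#'
#' Reads ATOM/HETATM records via \pkg{bio3d}, selects one chain and builds a
#' \linkS4class{ProteinStructure}: one residue per alpha carbon, hetero
#' groups and waters excluded, modified residues carrying a backbone kept
#' with amino acid \code{"X"}, alternate locations resolved to the
#' highest-occupancy conformer (ties to the first encountered). Chain breaks
#' (author-number gaps or consecutive alpha carbons more than 4.2 Angstrom
#' apart) are flagged; loops never span a flagged break.
#'
#' @param pdb Path to a PDB file, or PDB-format text (anything containing a
#'   newline is treated as text).
#' @param chain One-character chain identifier.
#' @param modelPolicy \code{"first"} keeps only the first coordinate model;
#'   \code{"all"} retains every model (NMR-style ensembles).
#' @param id Structure label; defaults to the file base name.
#' @return A \linkS4class{ProteinStructure}.
#' @examples
#' s <- syntheticStructure(architecture = list(c("H", 8)), seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePdb(s, f)
#' parseStructure(f, chain = "A")
#' @export
parseStructure <- function(pdb, chain, modelPolicy = c("first", "all"),
                           id = NULL) {
  modelPolicy <- match.arg(modelPolicy)
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE)) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(paste(pdb, collapse = "\n"), tf)
    if (is.null(id)) id <- "structure"
    pdb <- tf
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  parsed <- tryCatch(
    bio3d::read.pdb(pdb, multi = (modelPolicy == "all"), rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("inconsistent ensemble or unreadable PDB: ",
                             conditionMessage(e), call. = FALSE))
  atom <- parsed$atom
  if (!any(atom$chain %in% chain)) stop("chain not found: ", chain, call. = FALSE)
  atom$row <- seq_len(nrow(atom))
  atom <- atom[atom$chain %in% chain, , drop = FALSE]
  atom <- atom[atom$resid != "HOH", , drop = FALSE]

  # Resolve altlocs: keep the highest-occupancy copy of each named atom.
  key <- paste(atom$resno, atom$insert, atom$elety)
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    ord <- order(key, -occ, atom$row)
    atom <- atom[ord, , drop = FALSE]
    atom <- atom[!duplicated(paste(atom$resno, atom$insert, atom$elety)), ,
                 drop = FALSE]
    atom <- atom[order(atom$row), , drop = FALSE]
  }

  rkey <- paste(atom$resno, atom$insert)
  residues <- unique(rkey)
  # A residue qualifies as polypeptide if it has a CA plus peptide N or C,
  # or is a standard amino acid (guards against e.g. calcium ions, whose
  # atom is also named CA).
  keep <- vapply(residues, function(k) {
    i <- rkey == k
    el <- atom$elety[i]
    ("CA" %in% el) &&
      (any(c("N", "C") %in% el) || atom$resid[i][1] %in% names(AA3TO1))
  }, logical(1))
  residues <- residues[keep]
  if (!length(residues)) stop("no protein backbone in chain ", chain, call. = FALSE)

  n <- length(residues)
  sel <- function(k, name) {
    i <- which(rkey == k & atom$elety == name)
    if (length(i)) i[1] else NA_integer_
  }
  caRow <- vapply(residues, sel, integer(1), name = "CA")
  nRow <- vapply(residues, sel, integer(1), name = "N")
  cRow <- vapply(residues, sel, integer(1), name = "C")
  oRow <- vapply(residues, sel, integer(1), name = "O")

  nm <- if (modelPolicy == "all" && !is.null(parsed$xyz) &&
            is.matrix(parsed$xyz)) nrow(parsed$xyz) else 1L
  ca <- array(NA_real_, dim = c(n, 3, nm))
  for (m in seq_len(nm)) {
    xyz <- if (is.matrix(parsed$xyz)) parsed$xyz[m, ] else parsed$xyz
    idx <- atom$row[caRow]
    ca[, , m] <- matrix(xyz[as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))],
                        ncol = 3, byrow = TRUE)
  }
  if (!all(is.finite(ca))) stop("inconsistent ensemble: missing alpha-carbon ",
                                "coordinates in some model", call. = FALSE)

  getxyz <- function(rows) {
    out <- matrix(NA_real_, n, 3)
    ok <- !is.na(rows)
    out[ok, ] <- as.matrix(atom[rows[ok], c("x", "y", "z")])
    out
  }

  aa <- unname(AA3TO1[atom$resid[caRow]])
  aa[is.na(aa)] <- "X"
  bf <- atom$b[caRow]
  resno <- atom$resno[caRow]
  insc <- atom$insert[caRow]
  insc[is.na(insc)] <- ""

  breakAfter <- rep(FALSE, n)
  if (n > 1) {
    gap <- diff(resno) > 1L
    dca <- sqrt(rowSums((ca[-1, , 1, drop = FALSE] -
                         ca[-n, , 1, drop = FALSE])^2))
    breakAfter[-n] <- gap | (dca > 4.2)
  }

  res <- data.frame(seqIndex = 0:(n - 1L), authorNumber = resno,
                    insCode = insc, aa = aa, bFactor = bf,
                    breakAfter = breakAfter, stringsAsFactors = FALSE)
  new("ProteinStructure", id = id, chainId = chain, residues = res, ca = ca,
      backbone = list(N = getxyz(nRow), C = getxyz(cRow), O = getxyz(oRow)),
      nModels = as.integer(nm))
}

#' Write a structure as PDB text
#'
#' Emits backbone N, CA, C, O records per residue (atoms with missing
#' coordinates are skipped) using author numbering; multi-model structures
#' are written as MODEL/ENDMDL blocks of alpha-carbon records so every model
#' carries the same atom set.
#'
#' @param x A \linkS4class{ProteinStructure}.
#' @param path Output file path; when NULL the text is returned invisibly.
#' @return Invisibly, the PDB text as a character vector of lines.
#' @export
writeStructurePdb <- function(x, path = NULL) {
  res <- x@residues
  fmt <- function(serial, name, resid, resno, ins, xyz, b) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resid, x@chainId, resno,
            ifelse(ins == "", " ", ins), xyz[1], xyz[2], xyz[3], 1.00,
            if (is.na(b)) 0 else b)
  }
  lines <- character(0)
  multi <- x@nModels > 1L
  for (m in seq_len(x@nModels)) {
    if (multi) lines <- c(lines, sprintf("MODEL %8d", m))
    serial <- 0L
    for (i in seq_len(nrow(res))) {
      resid <- AA1TO3[res$aa[i]]
      if (is.na(resid)) resid <- "UNK"
      atoms <- if (!multi)
        list(N = x@backbone$N[i, ], CA = x@ca[i, , 1], C = x@backbone$C[i, ],
             O = x@backbone$O[i, ])
      else list(CA = x@ca[i, , m])
      for (nm in names(atoms)) {
        xyz <- atoms[[nm]]
        if (any(is.na(xyz))) next
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, nm, resid, res$authorNumber[i],
                              res$insCode[i], xyz, res$bFactor[i]))
      }
    }
    lines <- c(lines, if (multi) "ENDMDL" else "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Experimental B-factors from a crystal structure
#'
#' Copies the per-residue alpha-carbon temperature factors read from the
#' input file into a flexibility profile.
#'
#' @param x A \linkS4class{ProteinStructure} with B-factors for every residue.
#' @return A \linkS4class{FlexibilityProfile} with source \code{"crystal"}.
#' @export
crystalBfactors <- function(x) {
  b <- x@residues$bFactor
  if (any(is.na(b))) stop("no experimental B-factors", call. = FALSE)
  new("FlexibilityProfile", source = "crystal", residueValues = as.numeric(b),
      segmentValues = numeric(0), loopValues = numeric(0))
}

#' B-factors from an NMR-style ensemble
#'
#' Converts the per-residue root-mean-squared fluctuation across the models
#' of an ensemble into B-factor units, \eqn{B_i = (8\pi^2/3)\,RMSF_i^2}.
#' Before measuring fluctuations, every model is least-squares superposed on
#' the first model over all alpha carbons, so rigid-body drift between
#' models does not inflate the apparent mobility; the RMSF is then taken
#' about the mean alpha-carbon position across the superposed models.
#'
#' @param x A \linkS4class{ProteinStructure} with at least two models.
#' @return A \linkS4class{FlexibilityProfile} with source
#'   \code{"nmr_ensemble"}, values in Angstrom^2.
#' @export
ensembleBfactors <- function(x) {
  if (x@nModels < 2L) stop("ensemble required", call. = FALSE)
  n <- nResidues(x)
  coords <- array(NA_real_, dim = c(n, 3, x@nModels))
  coords[, , 1] <- x@ca[, , 1]
  ref <- x@ca[, , 1]
  for (m in 2:x@nModels) {
    fit <- kabsch(ref, x@ca[, , m])
    coords[, , m] <- applyTransform(x@ca[, , m], fit$rotation, fit$translation)
  }
  mean_pos <- apply(coords, c(1, 2), mean)
  dev2 <- sapply(seq_len(x@nModels), function(m)
    rowSums((coords[, , m] - mean_pos)^2))
  rmsf <- sqrt(rowMeans(dev2))
  new("FlexibilityProfile", source = "nmr_ensemble",
      residueValues = (8 * pi^2 / 3) * rmsf^2,
      segmentValues = numeric(0), loopValues = numeric(0))
}
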