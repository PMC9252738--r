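# Orchestration of the six-step grafting workflow: secondary structure,
# loop exploration, flexibility, correlation, pairing, grafting, plus
# template preparation and score ranking. Each stage writes its tables
# into the run directory and a state file so later stages (or single-stage
# reruns) can pick up where a previous invocation stopped.

PIPELINE_STAGES <- c("sse", "loops", "flex", "corr", "pair", "graft",
                     "prep", "rank")

#' Assemble and validate a run configuration
#'
#' @param scaffoldFile,insertFile PDB file paths.
#' @param scaffoldChain,insertChain Chain identifiers.
#' @param outDir Output run directory (created if needed).
#' @param modelPolicy \code{"first"} or \code{"all"} (NMR ensembles).
#' @param sseOverrides List of overrides, each
#'   \code{list(target = "scaffold"|"insert", range = c(first, last),
#'   state = "H"|"E"|"C")} in author numbering.
#' @param customLoops List of user loops, each \code{list(target =,
#'   sse1 =, coil =, sse2 =, name =)} with author-number ranges.
#' @param selectedLoops Labels of scaffold loops to graft (empty = all).
#' @param loopMap Optional named character vector mapping scaffold loop
#'   labels to insert loop labels (manual pairing); NULL = automatic.
#' @param pairing See \code{\link{pairingParams}}.
#' @param enm See \code{\link{enmParams}}.
#' @param boundaryConvention \code{"insert_inclusive"} or
#'   \code{"scaffold_inclusive"}.
#' @param dopeScores,rosettaScores Optional TSV paths with external model
#'   scores (columns design_id, score).
#' @param seed Integer seed recorded with the run.
#' @return Validated configuration list.
#' @export
runConfig <- function(scaffoldFile, scaffoldChain, insertFile, insertChain,
                      outDir, modelPolicy = "first", sseOverrides = list(),
                      customLoops = list(), selectedLoops = character(0),
                      loopMap = NULL, pairing = pairingParams(),
                      enm = enmParams(),
                      boundaryConvention = "insert_inclusive",
                      dopeScores = NULL, rosettaScores = NULL, seed = 1L) {
  stopifnot(is.character(scaffoldFile), is.character(insertFile),
            nchar(scaffoldChain) == 1, nchar(insertChain) == 1,
            modelPolicy %in% c("first", "all"),
            boundaryConvention %in% c("insert_inclusive",
                                      "scaffold_inclusive"))
  list(scaffoldFile = scaffoldFile, scaffoldChain = scaffoldChain,
       insertFile = insertFile, insertChain = insertChain, outDir = outDir,
       modelPolicy = modelPolicy, sseOverrides = sseOverrides,
       customLoops = customLoops, selectedLoops = selectedLoops,
       loopMap = loopMap, pairing = pairing, enm = enm,
       boundaryConvention = boundaryConvention, dopeScores = dopeScores,
       rosettaScores = rosettaScores, seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of \code{\link{runConfig}}.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$pairing <- do.call(pairingParams, as.list(y$pairing %||% list()))
  y$enm <- do.call(enmParams, as.list(y$enm %||% list()))
  y$selectedLoops <- as.character(y$selectedLoops %||% character(0))
  do.call(runConfig, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeLog <- function(state, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(state$config$outDir, "run.log"),
      append = TRUE)
}

loadState <- function(outDir, needed) {
  f <- file.path(outDir, "state.rds")
  if (!file.exists(f))
    stop("run stage ", needed, " first", call. = FALSE)
  readRDS(f)
}

saveState <- function(state) {
  saveRDS(state, file.path(state$config$outDir, "state.rds"))
  state
}

#' Run the grafting pipeline
#'
#' Executes the workflow stages in order: \code{sse} (secondary structure
#' and overrides), \code{loops} (loop extraction and geometry),
#' \code{flex} (flexibility profiles and method agreement), \code{corr}
#' (cross-correlation analysis), \code{pair} (superposition and residue
#' pairing), \code{graft} (design enumeration), \code{prep} (modelling
#' templates and alignments) and \code{rank} (score ingestion, when score
#' files are configured). Stage outputs are plain-text tables, JSON and
#' FASTA/PIR files in the run directory; a state file lets individual
#' stages be rerun from cached upstream results. Missing upstream results
#' abort with the stage to run first.
#'
#' @param config Configuration list from \code{\link{runConfig}} /
#'   \code{\link{readRunConfig}}, or a YAML path.
#' @param stages Stages to execute (default: all, in order).
#' @return Invisibly, the final pipeline state (list).
#' @export
runPipeline <- function(config, stages = PIPELINE_STAGES) {
  if (is.character(config)) config <- readRunConfig(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  first <- PIPELINE_STAGES[min(match(stages, PIPELINE_STAGES))]
  state <- if (first == "sse") list(config = config, done = character(0))
           else { s <- loadState(config$outDir,
                                 PIPELINE_STAGES[match(first, PIPELINE_STAGES) - 1L])
                  s$config <- config; s }
  yaml::write_yaml(config[setdiff(names(config), c("pairing", "enm"))],
                   file.path(config$outDir, "config.yaml"))
  set.seed(config$seed)
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    prev <- PIPELINE_STAGES[match(st, PIPELINE_STAGES) - 1L]
    if (length(prev) && !(prev %in% state$done) && !(prev %in% stages) &&
        st != "sse")
      stop("run stage ", prev, " first", call. = FALSE)
    t0 <- Sys.time()
    state <- switch(st,
      sse = stageSse(state), loops = stageLoops(state),
      flex = stageFlex(state), corr = stageCorr(state),
      pair = stagePair(state), graft = stageGraft(state),
      prep = stagePrep(state), rank = stageRank(state))
    state$done <- union(state$done, st)
    pipeLog(state, sprintf("stage %s done in %.2f s", st,
                           as.numeric(Sys.time() - t0, units = "secs")))
    saveState(state)
  }
  invisible(state)
}

stageSse <- function(state) {
  cfg <- state$config
  state$scaffold <- parseStructure(cfg$scaffoldFile, cfg$scaffoldChain,
                                   modelPolicy = cfg$modelPolicy)
  state$insert <- parseStructure(cfg$insertFile, cfg$insertChain,
                                 modelPolicy = cfg$modelPolicy)
  state$annScaffold <- assignSSE(state$scaffold)
  state$annInsert <- assignSSE(state$insert)
  for (ov in cfg$sseOverrides) {
    tgt <- ov$target %||% "scaffold"
    if (tgt == "scaffold")
      state$annScaffold <- applyOverride(state$annScaffold, state$scaffold,
                                         unlist(ov$range), ov$state)
    else
      state$annInsert <- applyOverride(state$annInsert, state$insert,
                                       unlist(ov$range), ov$state)
  }
  for (side in c("scaffold", "insert")) {
    s <- state[[side]]
    ann <- if (side == "scaffold") state$annScaffold else state$annInsert
    writeTsv(data.frame(authorNumber = authorNumbers(s),
                        aa = residueSequence(s), state = ann@states),
             file.path(cfg$outDir, sprintf("sse_%s.tsv", side)))
  }
  pipeLog(state, sprintf("sse: scaffold %d res, insert %d res",
                         nResidues(state$scaffold), nResidues(state$insert)))
  state
}

stageLoops <- function(state) {
  cfg <- state$config
  state$loopsScaffold <- extractLoops(state$annScaffold, state$scaffold)
  state$loopsInsert <- extractLoops(state$annInsert, state$insert)
  for (cl in cfg$customLoops) {
    tgt <- cl$target %||% "scaffold"
    s <- state[[tgt]]
    ann <- if (tgt == "scaffold") state$annScaffold else state$annInsert
    lp <- defineCustomLoop(s, unlist(cl$sse1), unlist(cl$coil),
                           unlist(cl$sse2), cl$name, ann)
    slot <- if (tgt == "scaffold") "loopsScaffold" else "loopsInsert"
    state[[slot]] <- c(state[[slot]], lp)
  }
  for (side in c("scaffold", "insert")) {
    s <- state[[side]]
    loops <- if (side == "scaffold") state$loopsScaffold else state$loopsInsert
    writeTsv(geometryTable(s, loops),
             file.path(cfg$outDir, sprintf("geometry_%s.tsv", side)))
  }
  pipeLog(state, sprintf("loops: %d scaffold, %d insert",
                         length(state$loopsScaffold),
                         length(state$loopsInsert)))
  state
}

stageFlex <- function(state) {
  cfg <- state$config
  s <- state$scaffold
  profiles <- list()
  if (!any(is.na(s@residues$bFactor)))
    profiles$crystal <- crystalBfactors(s)
  if (nModels(s) >= 2) {
    profiles$nmr_ensemble <- ensembleBfactors(s)
  } else {
    pipeLog(state, "flex: single-model input, NMR-ensemble source skipped")
  }
  profiles$gnm <- gnmBfactors(s, cfg$enm)
  state$anmModes <- anmModes(s, cfg$enm)
  profiles$anm <- anmBfactors(state$anmModes, s)
  profiles <- lapply(profiles, segmentAverages,
                     annotation = state$annScaffold,
                     loops = state$loopsScaffold)
  state$profiles <- profiles
  tab <- data.frame(authorNumber = authorNumbers(s))
  for (nm in names(profiles)) tab[[nm]] <- profiles[[nm]]@residueValues
  writeTsv(tab, file.path(cfg$outDir, "flexibility.tsv"))
  loopTab <- data.frame(label = names(profiles[[1]]@loopValues))
  for (nm in names(profiles)) loopTab[[nm]] <- unname(profiles[[nm]]@loopValues)
  writeTsv(loopTab, file.path(cfg$outDir, "flexibility_loops.tsv"))
  if (length(profiles) >= 2) {
    ag <- methodAgreement(profiles)
    utils::write.table(ag, file.path(cfg$outDir, "agreement.tsv"),
                       sep = "\t", quote = FALSE)
  }
  pipeLog(state, sprintf("flex: %d sources (%s)", length(profiles),
                         paste(names(profiles), collapse = ", ")))
  state
}

stageCorr <- function(state) {
  cfg <- state$config
  map <- crossCorrelation(state$anmModes)
  state$corrMap <- map
  utils::write.table(round(map@matrix, 4),
                     file.path(cfg$outDir, "crosscorrelation.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  selected <- selectedLoopRecords(state)
  if (length(selected) && length(state$loopsScaffold)) {
    cs <- loopCorrelationSummary(map, selected, state$loopsScaffold)
    utils::write.table(round(cs$loopLoop, 4),
                       file.path(cfg$outDir, "corr_loop_loop.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(round(cs$coilSse, 4),
                       file.path(cfg$outDir, "corr_coil_sse.tsv"),
                       sep = "\t", quote = FALSE)
  }
  pipeLog(state, sprintf("corr: %d x %d map, %d modes", nrow(map@matrix),
                         ncol(map@matrix), map@modeCount))
  state
}

selectedLoopRecords <- function(state) {
  sel <- state$config$selectedLoops
  if (!length(sel)) return(state$loopsScaffold)
  labs <- vapply(state$loopsScaffold, loopLabel, "")
  missing <- setdiff(sel, labs)
  if (length(missing))
    stop("unknown loop label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  state$loopsScaffold[labs %in% sel]
}

stagePair <- function(state) {
  cfg <- state$config
  sp <- superpose(state$scaffold, state$insert)
  state$superposition <- sp
  compat <- withCallingHandlers(
    inputCompatibility(state$scaffold, state$insert, sp),
    warning = function(w) invokeRestart("muffleWarning"))
  for (w in compat$warnings) pipeLog(state, paste("pair:", w))
  state$pairing <- greedyPairing(state$scaffold, state$insert, sp,
                                 cfg$pairing)
  writeTsv(pairingTable(state$pairing, state$scaffold, state$insert),
           file.path(cfg$outDir, "pairing.tsv"))
  movedInsert <- transformStructure(state$insert, sp@rotation,
                                    sp@translation)
  writeStructurePdb(movedInsert,
                    file.path(cfg$outDir, "insert_superposed.pdb"))
  selected <- selectedLoopRecords(state)
  if (is.null(cfg$loopMap)) {
    ap <- autoPairLoops(selected, state$loopsInsert, state$pairing)
    state$loopPairs <- ap$pairs
    for (u in ap$unpaired) pipeLog(state, paste("pair: unpaired loop", u))
  } else {
    labsI <- vapply(state$loopsInsert, loopLabel, "")
    state$loopPairs <- lapply(selected, function(lp) {
      tgt <- cfg$loopMap[[lp@label]]
      if (is.null(tgt) || !(tgt %in% labsI))
        stop("no insert loop mapped for ", lp@label, call. = FALSE)
      pairLoops(lp, state$loopsInsert[[which(labsI == tgt)[1]]])
    })
  }
  pipeLog(state, sprintf(
    "pair: rmsd %.2f A, length diff %.1f%%, %d doublets, %d loop pairs",
    compat$rmsd, compat$lengthDiffPct, nrow(state$pairing@doublets),
    length(state$loopPairs)))
  state
}

stageGraft <- function(state) {
  cfg <- state$config
  designs <- enumerateDesigns(state$loopPairs, state$pairing,
                              state$scaffold, state$insert,
                              convention = cfg$boundaryConvention)
  state$designs <- designs
  writeDesignsJson(designs, state$scaffold, state$insert,
                   file.path(cfg$outDir, "designs.json"))
  if (length(designs)) {
    writeDesignsFasta(designs, file.path(cfg$outDir, "designs.fasta"))
    writeTsv(designTable(designs), file.path(cfg$outDir, "designs.tsv"))
  }
  counts <- attr(designs, "counts")
  pipeLog(state, sprintf("graft: %d designs (%s)", length(designs),
                         paste(sprintf("%s=%d", names(counts), counts),
                               collapse = ", ")))
  state
}

stagePrep <- function(state) {
  cfg <- state$config
  tplDir <- file.path(cfg$outDir, "templates")
  dir.create(tplDir, showWarnings = FALSE)
  nOk <- 0L
  for (d in state$designs) {
    bundle <- tryCatch(
      prepareTemplates(d, state$scaffold, state$insert, state$loopPairs,
                       state$pairing),
      error = function(e) NULL)
    if (is.null(bundle)) next
    base <- file.path(tplDir, d@designId)
    writePirAlignment(bundle, paste0(base, ".pir"))
    writeStructurePdb(bundle$scaffoldTemplate,
                      paste0(base, "_scaffold.pdb"))
    for (k in seq_along(bundle$fragments))
      writeStructurePdb(bundle$fragments[[k]],
                        sprintf("%s_fragment_%d.pdb", base, k))
    nOk <- nOk + 1L
  }
  pipeLog(state, sprintf("prep: %d/%d template bundles written", nOk,
                         length(state$designs)))
  state
}

stageRank <- function(state) {
  cfg <- state$config
  if (is.null(cfg$dopeScores) && is.null(cfg$rosettaScores)) {
    pipeLog(state, "rank: no score files configured, skipping")
    return(state)
  }
  tab <- ingestScores(state$designs, dope = cfg$dopeScores,
                      rosetta = cfg$rosettaScores)
  ord <- order(is.na(tab$dopeRank), tab$dopeRank, tab$designId)
  state$scoreTable <- tab[ord, ]
  writeTsv(state$scoreTable, file.path(cfg$outDir, "score_table.tsv"))
  pipeLog(state, sprintf("rank: %d designs scored",
                         sum(!is.na(tab$dope) | !is.na(tab$rosetta))))
  state
}
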