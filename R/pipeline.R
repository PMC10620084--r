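#' Collapse an epoch mask to controlled / uncontrolled / undefined
#'
#' Pools the two uncontrolled classes; the headline epoch comparison is
#' controlled versus uncontrolled retinal input.
#'
#' @param mask factor from [buildEpochMask()].
#' @return factor with levels controlled, uncontrolled, undefined.
#' @export
collapseEpochMask <- function(mask) {
  out <- as.character(mask)
  out[out %in% c("uncontrolled_inferable", "uncontrolled_other")] <-
    "uncontrolled"
  factor(out, levels = c("controlled", "uncontrolled", "undefined"))
}

#' Run the full synthetic-session analysis pipeline
#'
#' Orchestrates every stage from one configuration: synthetic session
#' generation (with optional retinal confound), motion decomposition of
#' both camera views, design-matrix assembly, crossvalidated ridge fits,
#' unit filtering, unique-variance partition by epoch, movement-modulation
#' classification, SDF validation, model-free modulation indices and the
#' paired permutation test comparing unique variance across epochs. Every
#' random stage's seed derives from the config seed, so identical configs
#' reproduce all numeric outputs bit-identically.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized fields: `task`, `nTrials`, `nUnits`, `seed`,
#'   `couplings`, `confoundGain`, `includeEye`, `topComponents`,
#'   `segmentSeconds`, `threshold`, `nPermutations`, `outputDir`, plus any
#'   [sessionConfig()] argument.
#' @return a `RunReport` list (class `movencReport`) with the config
#'   snapshot, seeds, summary tables and (if `outputDir` is set) the paths
#'   of the exported delimited tables.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(task = "fixation", nTrials = 60L, nUnits = 6L, seed = 1L,
                   couplings = list(), confoundGain = 0, includeEye = FALSE,
                   topComponents = 30L, segmentSeconds = 60,
                   threshold = 0.1, nPermutations = 1000L, outputDir = NULL)
  unknownOk <- names(formals(sessionConfig))
  extra <- setdiff(names(config), c(names(defaults), unknownOk))
  if (length(extra))
    stop(sprintf("configuration error: unknown field '%s'", extra[1L]))
  cfg <- utils::modifyList(defaults, config)

  scArgs <- cfg[intersect(names(cfg), unknownOk)]
  scArgs$task <- cfg$task
  sc <- do.call(sessionConfig, scArgs)
  session <- simulateSession(sc)
  if (cfg$confoundGain > 0)
    session <- applyRetinalConfound(session, cfg$confoundGain)
  p <- sc@params

  profiles <- lapply(list(session@face, session@body), function(fs) {
    mm <- computeMotionMatrix(fs)
    k <- min(cfg$topComponents, nrow(mm@M), ncol(mm@M))
    comps <- segmentedSvd(mm, cfg$segmentSeconds, k)
    list(motion = mm,
         profiles = projectMotion(mm, comps, min(cfg$topComponents, k)))
  })

  blockBounds <- NULL
  driftAnchors <- NULL
  if (p$task == "discrimination") {
    tt <- session@trialTable@trials
    blockBounds <- tt$start[seq(1L, nrow(tt), by = p$blockLength)]
    if (length(blockBounds) > 1L) {
      pairDur <- 2 * stats::median(diff(blockBounds))
      driftAnchors <- max(2L, min(8L, floor(session@trialTable@sessionEnd /
                                              pairDur) + 1L))
    } else blockBounds <- NULL
  }
  design <- assembleDesign(session@trialTable, session@bins,
                           profiles[[1L]]$profiles, profiles[[2L]]$profiles,
                           eyeTrace = if (cfg$includeEye) session@eye,
                           variant = p$task, binWidth = p$binWidth,
                           driftAnchors = driftAnchors,
                           blockBounds = blockBounds)
  plan <- makeFoldPlan(unique(design@bins$trial), 10L, cfg$seed + 100L)
  fit <- crossvalFitPredict(design, session@spikes, plan)

  geometry <- list(screenHalfWidth = p$screenHalfWidth,
                   screenHalfHeight = p$screenHalfHeight,
                   rfOffset = p$rfOffset, rfRadius = p$rfRadius)
  mask <- buildEpochMask(design, session@eye, geometry)
  mask2 <- collapseEpochMask(mask)

  filt <- filterUnits(session@spikes, design, fit, mask2)

  uv <- list(
    face = uniqueVariance(design, session@spikes, fit, "face", mask2,
                          seed = cfg$seed + 200L),
    body = uniqueVariance(design, session@spikes, fit, "body", mask2,
                          seed = cfg$seed + 201L),
    movement = uniqueVariance(design, session@spikes, fit,
                              c("face", "body"), mask2,
                              seed = cfg$seed + 202L))

  mv <- uv$movement
  areas <- SummarizedExperiment::rowData(session@spikes)$area
  cls <- lapply(c(controlled = "controlled", uncontrolled = "uncontrolled"),
                function(ep) {
                  sub <- mv[mv$epoch == ep, , drop = FALSE]
                  sub <- sub[filt$included, , drop = FALSE]
                  classifyModulated(sub, cfg$threshold,
                                    area = areas[filt$included])
                })

  sdf <- sdfAndVE(design, session@spikes, fit)

  dvC <- mv$dve[mv$epoch == "controlled"]
  dvU <- mv$dve[mv$epoch == "uncontrolled"]
  permTest <- if (length(dvC) >= 2L)
    pairedPermutationTest(dvU, dvC, cfg$nPermutations, cfg$seed + 300L)

  trFace <- averageMotionTrace(profiles[[1L]]$motion)
  trBody <- averageMotionTrace(profiles[[2L]]$motion)
  epochDefaults <- if (p$task == "fixation") c(80, 50) else c(90, 20)
  epochs <- detectMovementEpochs(list(trFace, trBody),
                                 epochDefaults[1L], epochDefaults[2L])
  pairsTab <- matchEpochConditions(epochs, session@trialTable, session@bins,
                                   p$task, p$binWidth)
  modulation <- modulationIndices(session@spikes, session@trialTable,
                                  pairsTab, p$task, fit = fit,
                                  design = design)

  unitSummary <- data.frame(
    unit = fit@units,
    area = SummarizedExperiment::rowData(session@spikes)$area,
    lambda = fit@lambda, ve = fit@ve,
    veControlled = filt$veControlled, veUncontrolled = filt$veUncontrolled,
    veSDF = sdf$ve, included = filt$included)

  report <- list(
    config = cfg, version = as.character(utils::packageVersion("movenc")),
    seeds = c(session = cfg$seed, folds = cfg$seed + 100L,
              shuffle = cfg$seed + 200L, permutation = cfg$seed + 300L),
    nBins = nrow(session@bins), nModeledBins = nrow(design@bins),
    unitSummary = unitSummary,
    uniqueVariance = do.call(rbind, uv),
    classification = lapply(cls, `[[`, "proportions"),
    permutationTest = permTest,
    modulation = modulation,
    nMatchedPairs = nrow(pairsTab))
  class(report) <- "movencReport"

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      unitSummary = file.path(cfg$outputDir, "unit_summary.tsv"),
      uniqueVariance = file.path(cfg$outputDir, "unique_variance.tsv"),
      modulation = file.path(cfg$outputDir, "modulation_indices.tsv"))
    write.table(report$unitSummary, paths["unitSummary"], sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(report$uniqueVariance, paths["uniqueVariance"], sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(report$modulation, paths["modulation"], sep = "\t",
                row.names = FALSE, quote = FALSE)
    yaml::write_yaml(cfg[setdiff(names(cfg), "outputDir")],
                     file.path(cfg$outputDir, "config_snapshot.yaml"))
    report$paths <- paths
  }
  report
}

#' @export
print.movencReport <- function(x, ...) {
  cat(sprintf("movenc run report (v%s): %s task, %d trials, %d units\n",
              x$version, x$config$task, x$config$nTrials, x$config$nUnits))
  cat(sprintf("  bins: %d total, %d modeled; matched MI pairs: %d\n",
              x$nBins, x$nModeledBins, x$nMatchedPairs))
  cat(sprintf("  crossvalidated %%VE: median %.2f; SDF %%VE median %.1f\n",
              stats::median(x$unitSummary$ve),
              stats::median(x$unitSummary$veSDF)))
  mv <- x$uniqueVariance
  for (ep in c("controlled", "uncontrolled")) {
    d <- mv$dve[mv$group == "face+body" & mv$epoch == ep]
    if (length(d))
      cat(sprintf("  movement unique variance (%s): mean %.3f %%VE\n", ep,
                  mean(d)))
  }
  if (!is.null(x$permutationTest))
    cat(sprintf("  epoch difference permutation p (add-one): %.4g\n",
                x$permutationTest$pValueAddOne))
  invisible(x)
}
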