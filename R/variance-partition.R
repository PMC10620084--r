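#' Classify modeled bins by retinal-input state
#'
#' Bins where the animal maintained fixation are `controlled` (the retinal
#' image is the known stimulus or blank screen). Among the remaining bins,
#' those where the gaze keeps the units' receptive field on the known blank
#' screen are `uncontrolled_inferable`; bins where the receptive field may
#' leave the screen (or cover unknown visual structure) are
#' `uncontrolled_other`. Bins with undefined eye-tracker samples are
#' `undefined`. The classes are mutually exclusive and exhaustive.
#'
#' @param design the modeled [DesignMatrix-class] (supplies the bin grid).
#' @param eyeTrace optional [EyeTrace-class] on the session bin grid;
#'   without it every non-fixation bin is `uncontrolled_other`.
#' @param geometry list with `screenHalfWidth`, `screenHalfHeight` (deg),
#'   `rfOffset` (deg, c(x, y) relative to gaze) and `rfRadius` (deg).
#' @return factor of length `nrow(designValues(design))` with levels
#'   controlled, uncontrolled_inferable, uncontrolled_other, undefined.
#' @export
buildEpochMask <- function(design, eyeTrace = NULL, geometry = NULL) {
  bi <- design@bins
  if (is.null(bi$fixation))
    stop("configuration error: the design's bin grid lacks fixation bounds")
  cls <- ifelse(bi$fixation, "controlled", "uncontrolled_other")
  if (!is.null(eyeTrace)) {
    x <- eyeTrace@x[bi$binIndex]
    y <- eyeTrace@y[bi$binIndex]
    if (!is.null(geometry)) {
      rfx <- x + geometry$rfOffset[1L]
      rfy <- y + geometry$rfOffset[2L]
      onScreen <- (abs(rfx) + geometry$rfRadius <= geometry$screenHalfWidth) &
        (abs(rfy) + geometry$rfRadius <= geometry$screenHalfHeight)
      # the screen is blank outside stimulus presentations, so an on-screen
      # receptive field implies inferable (blank) retinal input there
      infer <- !bi$fixation & onScreen & !bi$stimOn
      cls[infer] <- "uncontrolled_inferable"
    }
    cls[!eyeTrace@defined[bi$binIndex]] <- "undefined"
  }
  factor(cls, levels = c("controlled", "uncontrolled_inferable",
                         "uncontrolled_other", "undefined"))
}

# Shuffle-in-time reduced design: one random permutation of the modeled
# bins applied jointly to all columns of the named groups, leaving every
# other column bit-identical. The reduced model keeps the same number of
# parameters as the full model.
.shuffleGroups <- function(design, groups, seed) {
  grp <- design@columnMeta$group
  cols <- grp %in% groups
  if (!any(cols))
    stop(sprintf("naming error: no design columns in group(s) %s",
                 paste(groups, collapse = ", ")))
  perm <- .withSeed(seed, sample.int(nrow(design@X)))
  design@X[, cols] <- design@X[perm, cols, drop = FALSE]
  design
}

#' Unique variance of a regressor group
#'
#' Builds a reduced model by permuting in time only the group's columns
#' (jointly, preserving within-group covariance while destroying alignment
#' to the spikes), refits with each unit's already-selected penalty and the
#' same fold plan, and reports `dVE = %VE_full - %VE_shuffled` per unit,
#' evaluated overall and within each retinal-input epoch class (both the
#' residual and data variance restricted to the epoch's bins).
#'
#' @param design the full [DesignMatrix-class].
#' @param spikes the [BinnedSpikes-class].
#' @param fit the full-model [FitResult-class].
#' @param groups group name(s) shuffled jointly (e.g. `"face"`, or
#'   `c("face", "body")` for all movement covariates).
#' @param epochMask optional epoch factor from [buildEpochMask()].
#' @param seed permutation seed (recorded in the output).
#' @param nShuffles number of permutations averaged (default 1).
#' @return data.frame: unit, epoch (`overall` plus epoch classes present),
#'   `veFull`, `veShuffled`, `dve`, `seed`, `nShuffles`.
#' @export
uniqueVariance <- function(design, spikes, fit, groups, epochMask = NULL,
                           seed = 1L, nShuffles = 1L) {
  obs <- t(spikeCounts(spikes)[, design@bins$binIndex, drop = FALSE])
  U <- length(fit@units)
  masks <- list(overall = rep(TRUE, nrow(obs)))
  if (!is.null(epochMask)) {
    for (lv in levels(epochMask)) {
      m <- epochMask == lv
      if (any(m)) masks[[lv]] <- m
    }
  }
  veF <- sapply(masks, function(m) vapply(seq_len(U), function(u)
    percentVE(fit@predictions[u, ], obs[, u], m), numeric(1)),
    simplify = FALSE)
  veSacc <- lapply(masks, function(m) matrix(0, U, nShuffles))
  for (s in seq_len(nShuffles)) {
    red <- .shuffleGroups(design, groups, seed + s - 1L)
    rfit <- crossvalFitPredict(red, spikes, fit@plan, lambda = fit@lambda,
                               clipNegative = fit@clipNegative)
    for (m in names(masks))
      veSacc[[m]][, s] <- vapply(seq_len(U), function(u)
        percentVE(rfit@predictions[u, ], obs[, u], masks[[m]]), numeric(1))
  }
  out <- do.call(rbind, lapply(names(masks), function(m) {
    veS <- rowMeans(veSacc[[m]])
    data.frame(unit = fit@units, epoch = m, veFull = veF[[m]],
               veShuffled = veS, dve = veF[[m]] - veS,
               seed = seed, nShuffles = nShuffles)
  }))
  rownames(out) <- NULL
  out$group <- paste(groups, collapse = "+")
  out
}

#' Task-only model: %VE with the movement contribution removed
#'
#' The "task-only" model is the full model with the movement groups'
#' contribution removed by the same shuffle-and-refit contract (a single
#' joint permutation of the movement columns), so it retains the same
#' number of parameters. Returns the task-only %VE per unit and the
#' difference `full - taskOnly`, which by construction equals the unique
#' variance of the joint movement group.
#'
#' @inheritParams uniqueVariance
#' @param removedGroups groups removed (default face and body).
#' @return data.frame: unit, epoch, `veFull`, `veTaskOnly`, `dve`.
#' @export
reducedModelVE <- function(design, spikes, fit,
                           removedGroups = c("face", "body"),
                           epochMask = NULL, seed = 1L) {
  uv <- uniqueVariance(design, spikes, fit, removedGroups,
                       epochMask = epochMask, seed = seed)
  names(uv)[names(uv) == "veShuffled"] <- "veTaskOnly"
  uv
}

#' Flag movement-modulated units and per-area proportions
#'
#' A unit counts as modulated iff its unique variance strictly exceeds the
#' threshold (default 0.1 %VE points). Supports a threshold sweep, whose
#' proportions are monotonically nonincreasing in the threshold.
#'
#' @param uv a data.frame with columns `unit` and `dve` (one epoch class;
#'   subset the [uniqueVariance()] output first).
#' @param threshold %VE-point threshold(s) (default 0.1).
#' @param area optional per-unit area labels for per-area proportions.
#' @return list with `flags` (unit x threshold logical matrix) and
#'   `proportions` (data.frame: threshold, area incl. `"all"`, n,
#'   nModulated, proportion).
#' @export
classifyModulated <- function(uv, threshold = 0.1, area = NULL) {
  flags <- vapply(threshold, function(th) uv$dve > th,
                  logical(nrow(uv)))
  flags <- matrix(flags, nrow = nrow(uv),
                  dimnames = list(uv$unit, as.character(threshold)))
  if (is.null(area)) area <- rep("all", nrow(uv))
  props <- do.call(rbind, lapply(seq_along(threshold), function(i) {
    byArea <- lapply(split(flags[, i], area), function(f)
      c(n = length(f), nModulated = sum(f)))
    byArea$all <- c(n = nrow(flags), nModulated = sum(flags[, i]))
    data.frame(threshold = threshold[i],
               area = names(byArea),
               n = vapply(byArea, `[[`, numeric(1), "n"),
               nModulated = vapply(byArea, `[[`, numeric(1), "nModulated"))
  }))
  props$proportion <- props$nModulated / props$n
  rownames(props) <- NULL
  list(flags = flags, proportions = props)
}
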