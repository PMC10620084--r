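#' Detect movement and no-movement epochs from motion traces
#'
#' Times where the pixel-averaged motion strictly exceeds the high
#' percentile in either view are movement epochs; times strictly below the
#' low percentile in every view (and not already movement epochs) are
#' no-movement epochs, so the two sets are disjoint by construction.
#' Percentiles use linear interpolation. Defaults follow the fixation-task
#' convention (80th / 50th); discrimination-task sessions use 90th / 20th.
#'
#' @param traces a numeric vector (one view) or list of vectors (both
#'   views), each one value per frame interval.
#' @param hiPct,loPct percentiles in (0, 100), `loPct < hiPct`.
#' @return list with `with` and `without` (bin indices on the session grid:
#'   frame interval `t` maps to bin `t + 1`), the percentiles and the
#'   per-view thresholds.
#' @export
detectMovementEpochs <- function(traces, hiPct = 80, loPct = 50) {
  if (!(loPct > 0 && hiPct < 100 && loPct < hiPct))
    stop("configuration error: need 0 < loPct < hiPct < 100")
  if (!is.list(traces)) traces <- list(traces)
  hiThr <- vapply(traces, function(x) unname(quantile(x, hiPct / 100)),
                  numeric(1))
  loThr <- vapply(traces, function(x) unname(quantile(x, loPct / 100)),
                  numeric(1))
  if (all(vapply(traces, function(x) .popVar(x) < 1e-24, logical(1)))) {
    warning("constant motion trace: no movement epochs detectable")
    return(list(with = integer(0), without = integer(0),
                hiPct = hiPct, loPct = loPct, hiThr = hiThr, loThr = loThr))
  }
  anyHi <- Reduce(`|`, Map(function(x, th) x > th, traces, as.list(hiThr)))
  allLo <- Reduce(`&`, Map(function(x, th) x < th, traces, as.list(loThr)))
  with <- which(anyHi) + 1L
  without <- setdiff(which(allLo) + 1L, with)
  list(with = with, without = without, hiPct = hiPct, loPct = loPct,
       hiThr = hiThr, loThr = loThr)
}

# Candidate epochs: one row per (stimulus presentation, bout onset), where a
# bout onset is an entry into the with- (or without-) movement bin set
# inside the presentation window.
.epochCandidates <- function(binSet, trialTable, bins, binWidth, variant) {
  st <- trialTable@stimuli
  if (variant == "discrimination")
    st <- st[!duplicated(st$trial), , drop = FALSE]
  inSet <- logical(nrow(bins))
  inSet[binSet[binSet <= nrow(bins)]] <- TRUE
  onsetBins <- which(inSet & !c(FALSE, inSet[-length(inSet)]))
  out <- vector("list", nrow(st))
  prevOff <- c(NA_real_, st$offset[-nrow(st)])
  for (i in seq_len(nrow(st))) {
    b0 <- .binAt(st$onset[i], binWidth)
    b1 <- .binAt(st$offset[i], binWidth) - 1L
    bouts <- onsetBins[onsetBins >= b0 & onsetBins <= b1]
    if (!length(bouts)) next
    out[[i]] <- data.frame(
      stimRow = i, trial = st$trial[i], sample = st$sample[i],
      onset = st$onset[i], label = st$label[i],
      lag = bins$time[bouts] - st$onset[i],
      prevGap = st$onset[i] - prevOff[i])
  }
  do.call(rbind, out)
}

#' Match movement and no-movement epochs on stimulus conditions
#'
#' Pairs movement and no-movement stimulus epochs so that differences in
#' activity between them cannot be driven by systematic stimulus
#' differences. Fixation variant: pairs must share the stimulus contrast,
#' the sample position within the trial and the preceding stimulus'
#' contrast, with the stimulus-to-bout lag matched to within 10 ms and the
#' interstimulus interval to within 50 ms. Discrimination variant: pairs
#' share the stimulus type (disparity of the task-relevant side and the
#' attention condition), lag within 10 ms and intertrial interval within
#' 300 ms. Matching is greedy nearest-lag, one-to-one without replacement,
#' so every epoch is consumed at most once and a presentation is never
#' paired with itself.
#'
#' @param epochs output of [detectMovementEpochs()].
#' @param trialTable a [TrialTable-class].
#' @param bins the session bin grid.
#' @param variant `"fixation"` or `"discrimination"`.
#' @param binWidth seconds.
#' @param lagTol,gapTol tolerances in seconds; `gapTol` defaults to 0.05
#'   (interstimulus) for fixation and 0.3 (intertrial) for discrimination.
#' @return data.frame of matched pairs with the attributes of both members;
#'   zero rows when no admissible pairs exist.
#' @export
matchEpochConditions <- function(epochs, trialTable, bins,
                                 variant = c("fixation", "discrimination"),
                                 binWidth = 1 / 60,
                                 lagTol = 0.010, gapTol = NULL) {
  variant <- match.arg(variant)
  if (is.null(gapTol)) gapTol <- if (variant == "fixation") 0.05 else 0.3
  tr <- trialTable@trials
  cw <- .epochCandidates(epochs$with, trialTable, bins, binWidth, variant)
  co <- .epochCandidates(epochs$without, trialTable, bins, binWidth, variant)
  if (is.null(cw) || is.null(co)) return(.emptyPairs())
  decorate <- function(cc) {
    st <- trialTable@stimuli
    if (variant == "fixation") {
      prevLab <- c("none", st$label[-nrow(st)])
      cc$prevLabel <- prevLab[cc$stimRow]
      cc$key <- paste(cc$label, cc$sample, cc$prevLabel)
    } else {
      # stimulus type: the full stimulus configuration (disparity in each
      # hemifield) plus the attention condition
      stAll <- trialTable@stimuli
      lab2 <- vapply(cc$trial, function(tn) {
        rows <- stAll$trial == tn
        paste(stAll$label[rows][order(stAll$hemifield[rows])],
              collapse = "|")
      }, character(1))
      cc$attended <- tr$attended[match(cc$trial, tr$trial)]
      cc$key <- paste(lab2, cc$attended)
    }
    cc
  }
  cw <- decorate(cw); co <- decorate(co)
  used <- logical(nrow(co))
  pairs <- vector("list", nrow(cw))
  for (i in seq_len(nrow(cw))) {
    ok <- !used & co$key == cw$key[i] & co$stimRow != cw$stimRow[i] &
      abs(co$lag - cw$lag[i]) <= lagTol + 1e-12
    gw <- cw$prevGap[i]
    ok <- ok & ((is.na(gw) & is.na(co$prevGap)) |
                  (!is.na(gw) & !is.na(co$prevGap) &
                     abs(co$prevGap - gw) <= gapTol + 1e-12))
    ok[is.na(ok)] <- FALSE
    if (!any(ok)) next
    j <- which(ok)[which.min(abs(co$lag[ok] - cw$lag[i]))]
    used[j] <- TRUE
    pairs[[i]] <- data.frame(
      withTrial = cw$trial[i], withStimRow = cw$stimRow[i],
      withOnset = cw$onset[i], withLag = cw$lag[i],
      woTrial = co$trial[j], woStimRow = co$stimRow[j],
      woOnset = co$onset[j], woLag = co$lag[j],
      key = cw$key[i], lagDiff = abs(co$lag[j] - cw$lag[i]),
      gapDiff = abs(co$prevGap[j] - cw$prevGap[i]))
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) return(.emptyPairs())
  rownames(out) <- NULL
  out
}

.emptyPairs <- function() {
  data.frame(withTrial = integer(0), withStimRow = integer(0),
             withOnset = numeric(0), withLag = numeric(0),
             woTrial = integer(0), woStimRow = integer(0),
             woOnset = numeric(0), woLag = numeric(0),
             key = character(0), lagDiff = numeric(0), gapDiff = numeric(0))
}

#' Rate modulation index
#'
#' `(rA - rB) / (rA + rB)`, in `[-1, 1]`; antisymmetric in its arguments
#' and `NA` (undefined, flagged) when the denominator is zero. Used for
#' both the movement modulation index (MI) and the attention index (AI) on
#' drift-corrected mean rates.
#'
#' @param rA,rB nonnegative mean rates (spikes/s).
#' @return the index, or `NA` if `rA + rB == 0`.
#' @export
rateModulationIndex <- function(rA, rB) {
  if (any(c(rA, rB) < 0, na.rm = TRUE))
    stop("rates must be nonnegative")
  out <- (rA - rB) / (rA + rB)
  out[!is.finite(out)] <- NA_real_
  out
}

# Mean drift-corrected rate per unit over the window after each onset:
# rate minus the fitted drift-term prediction plus the session mean of that
# prediction.
.windowRates <- function(spikes, onsets, rateWindow, corr = NULL) {
  cnt <- spikeCounts(spikes)
  bw <- spikes@binWidth
  n <- ncol(cnt)
  r <- matrix(NA_real_, nrow(cnt), length(onsets))
  for (i in seq_along(onsets)) {
    b0 <- .binAt(onsets[i] + rateWindow[1L], bw)
    b1 <- .binAt(onsets[i] + rateWindow[2L], bw) - 1L
    b1 <- min(b1, n)
    if (b1 < b0) next
    r[, i] <- rowMeans(cnt[, b0:b1, drop = FALSE]) / bw
    if (!is.null(corr))
      r[, i] <- r[, i] - rowMeans(corr[, b0:b1, drop = FALSE])
  }
  r
}

# Drift-term correction on the session bin grid: the de-normalized drift
# prediction minus its session mean, zero outside the modeled bins.
.driftCorrection <- function(fit, design, nBins) {
  cols <- design@columnMeta$group == "drift"
  contrib <- design@X[, cols, drop = FALSE] %*%
    fit@weights[cols, , drop = FALSE]           # modeled bins x U, counts/bin
  contrib <- sweep(contrib, 2L, colMeans(contrib), "-") / design@binWidth
  out <- matrix(0, ncol(contrib), nBins)
  out[, design@bins$binIndex] <- t(contrib)
  out
}

#' Movement and attention modulation indices
#'
#' Computes, per unit, the movement modulation index
#' `MI = (R_with - R_without) / (R_with + R_without)` over the matched
#' movement/no-movement epoch pairs, and (discrimination sessions) the
#' attention index `AI = (R_in - R_out) / (R_in + R_out)` over
#' attention-in/out trial pairs matched on the stimulus type. Rates are
#' averaged over the variant's rate window (0.15-0.45 s after stimulus
#' onset for fixation, 0.15-2 s for discrimination) and, when a model fit
#' is supplied, corrected for slow nonstationarities by subtracting the
#' fitted drift-term prediction and adding back its session mean.
#'
#' @param spikes a [BinnedSpikes-class].
#' @param trialTable the [TrialTable-class].
#' @param pairs matched pairs from [matchEpochConditions()].
#' @param variant `"fixation"` or `"discrimination"`.
#' @param rateWindow optional `c(from, to)` seconds after onset; defaults
#'   by variant.
#' @param fit,design optional full-model [FitResult-class] and its
#'   [DesignMatrix-class] for drift correction.
#' @return data.frame per unit: `MI`, `AI`, the four mean rates, `nPairs`,
#'   `nAttPairs` and the rate window used. Indices are `NA` where no pairs
#'   exist or the denominator is zero.
#' @export
modulationIndices <- function(spikes, trialTable, pairs,
                              variant = c("fixation", "discrimination"),
                              rateWindow = NULL, fit = NULL, design = NULL) {
  variant <- match.arg(variant)
  if (is.null(rateWindow))
    rateWindow <- if (variant == "fixation") c(0.15, 0.45) else c(0.15, 2)
  cnt <- spikeCounts(spikes)
  corr <- if (!is.null(fit)) .driftCorrection(fit, design, ncol(cnt))
  U <- nrow(cnt)
  units <- rownames(cnt)
  rWith <- rWo <- rep(NA_real_, U)
  if (nrow(pairs)) {
    rw <- .windowRates(spikes, pairs$withOnset, rateWindow, corr)
    ro <- .windowRates(spikes, pairs$woOnset, rateWindow, corr)
    rWith <- rowMeans(rw, na.rm = TRUE)
    rWo <- rowMeans(ro, na.rm = TRUE)
  }
  mi <- rateModulationIndex(pmax(rWith, 0), pmax(rWo, 0))

  ai <- rIn <- rOut <- rep(NA_real_, U)
  nAtt <- 0L
  if (variant == "discrimination") {
    ap <- .attentionPairs(trialTable)
    nAtt <- nrow(ap)
    if (nAtt) {
      ri <- .windowRates(spikes, ap$inOnset, rateWindow, corr)
      ro <- .windowRates(spikes, ap$outOnset, rateWindow, corr)
      rIn <- rowMeans(ri, na.rm = TRUE)
      rOut <- rowMeans(ro, na.rm = TRUE)
      ai <- rateModulationIndex(pmax(rIn, 0), pmax(rOut, 0))
    }
  }
  data.frame(unit = units, MI = mi, AI = ai,
             RWith = rWith, RWithout = rWo,
             RAttIn = rIn, RAttOut = rOut,
             nPairs = nrow(pairs), nAttPairs = nAtt,
             windowFrom = rateWindow[1L], windowTo = rateWindow[2L])
}

# Attention-in / attention-out trial pairs matched on the full stimulus
# configuration (disparity in each hemifield), greedy in time order,
# one-to-one.
.attentionPairs <- function(trialTable) {
  tr <- trialTable@trials
  st <- trialTable@stimuli
  relLab <- vapply(seq_len(nrow(tr)), function(i) {
    rows <- st$trial == tr$trial[i]
    paste(st$label[rows][order(st$hemifield[rows])], collapse = "|")
  }, character(1))
  tin <- which(tr$attended %in% TRUE)
  tout <- which(tr$attended %in% FALSE)
  used <- logical(length(tout))
  out <- vector("list", length(tin))
  firstOn <- vapply(split(st$onset, st$trial), min, numeric(1))
  for (i in seq_along(tin)) {
    ok <- !used & relLab[tout] == relLab[tin[i]]
    if (!any(ok)) next
    j <- which(ok)[1L]
    used[j] <- TRUE
    out[[i]] <- data.frame(
      inTrial = tr$trial[tin[i]], outTrial = tr$trial[tout[j]],
      inOnset = unname(firstOn[as.character(tr$trial[tin[i]])]),
      outOnset = unname(firstOn[as.character(tr$trial[tout[j]])]),
      label = relLab[tin[i]])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(inTrial = integer(0), outTrial = integer(0),
                      inOnset = numeric(0), outOnset = numeric(0),
                      label = character(0))
  res
}
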