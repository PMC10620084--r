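#' Evaluate a set of tent basis functions
#'
#' Tent (piecewise-linear "hat") bases: basis `j` is 1 at its anchor, falls
#' linearly to 0 at the neighboring anchors and is 0 beyond them. Between two
#' adjacent anchors the weights sum to 1 (partition of unity). Boundary
#' anchors have no outer neighbor; with `boundary = "taper"` they fall to 0
#' over the adjacent anchor gap (so three anchors at -100/0/+100 ms span a
#' 400-ms window), with `boundary = "clamp"` they extend at the constant
#' value 1, which keeps the partition of unity at the session edges and is
#' what the drift block uses.
#'
#' @param anchors strictly increasing anchor times (seconds).
#' @param t times at which to evaluate.
#' @param boundary `"taper"` or `"clamp"`.
#' @return matrix `length(t) x length(anchors)` of weights.
#' @export
tentBasisEval <- function(anchors, t, boundary = c("taper", "clamp")) {
  boundary <- match.arg(boundary)
  m <- length(anchors)
  if (m < 1L) stop("configuration error: need at least one anchor")
  if (m > 1L && any(diff(anchors) <= 0))
    stop("configuration error: anchors must be strictly increasing")
  W <- matrix(0, length(t), m)
  if (m == 1L) {
    W[, 1L] <- if (boundary == "clamp") 1 else pmax(0, 1 - 0 * t)
    return(W)
  }
  gaps <- diff(anchors)
  for (j in seq_len(m)) {
    gl <- if (j > 1L) gaps[j - 1L] else gaps[1L]
    gr <- if (j < m) gaps[j] else gaps[m - 1L]
    w <- numeric(length(t))
    left <- t <= anchors[j]
    w[left] <- pmax(0, 1 - (anchors[j] - t[left]) / gl)
    w[!left] <- pmax(0, 1 - (t[!left] - anchors[j]) / gr)
    if (boundary == "clamp") {
      if (j == 1L) w[t <= anchors[1L]] <- 1
      if (j == m) w[t >= anchors[m]] <- 1
    } else {
      if (j > 1L) w[t < anchors[j - 1L]] <- 0
      if (j < m) w[t > anchors[j + 1L]] <- 0
    }
    W[, j] <- w
  }
  W
}

# Time-shifted copies of a base regressor, restricted to trials: the value a
# column takes at bin b for shift d comes from the base at bin b - d only if
# both bins belong to the same trial; event kernels therefore never straddle
# trials (and so never straddle crossvalidation folds).
.shiftedColumns <- function(base, shifts, trial) {
  n <- length(base)
  out <- matrix(0, n, length(shifts))
  for (j in seq_along(shifts)) {
    d <- shifts[j]
    if (d >= n || d <= -n) next
    if (d >= 0) {
      dst <- (1L + d):n
      src <- 1L:(n - d)
    } else {
      dst <- 1L:(n + d)
      src <- (1L - d):n
    }
    v <- base[src]
    ok <- !is.na(trial[dst]) & !is.na(trial[src]) & trial[dst] == trial[src]
    v[!ok] <- 0
    out[dst, j] <- v
  }
  out
}

#' Event-kernel columns: shifted copies of an event regressor
#'
#' Places each event's value at its onset bin (half-open bins, an event at an
#' exact bin edge lands in the later bin) and expands it into one column per
#' bin shift inside the window, so a linear model can express a temporal
#' response profile. The window is `(pre_s, post_s)`: shifts run from
#' `-pre_s/binWidth` to `post_s/binWidth - 1`, e.g. a 250-ms post-event
#' window at 60 Hz gives 15 columns. Kernels are constructed at the level of
#' individual trials and never bleed across trial boundaries.
#'
#' @param onsets event times in seconds from session start.
#' @param values event values (e.g. 1, or +/-1 for signed events).
#' @param window numeric `c(pre_s, post_s)`, both nonnegative.
#' @param binWidth bin width in seconds.
#' @param bins data.frame with per-bin `time` and `trial` (NA outside trials).
#' @return matrix `nrow(bins) x n_shifts` with the shifts as an attribute.
#' @export
eventKernelColumns <- function(onsets, values, window, binWidth, bins) {
  if (binWidth <= 0) stop("configuration error: binWidth must be positive")
  if (any(window < 0)) stop("configuration error: window spans must be nonnegative")
  n <- nrow(bins)
  base <- numeric(n)
  if (length(onsets)) {
    b <- .binAt(onsets, binWidth)
    if (any(b < 1L | b > n))
      stop("bounds error: event outside the session")
    for (i in seq_along(b)) base[b[i]] <- base[b[i]] + values[i]
  }
  nPre <- round(window[1L] / binWidth)
  nPost <- max(1L, round(window[2L] / binWidth))
  shifts <- seq.int(-nPre, nPost - 1L)
  out <- .shiftedColumns(base, shifts, bins$trial)
  attr(out, "shifts") <- shifts
  out
}

#' One-hot stimulus columns
#'
#' One binary indicator per distinct stimulus value, 1 over the presentation
#' window and 0 elsewhere, expanded by [eventKernelColumns()] with the
#' 250-ms post-event window. The fixation variant further splits each
#' stimulus value by its sample position within the trial (blank stimuli
#' carry their own indicator); the discrimination variant splits by the
#' hemifield of the presentation.
#'
#' @param trialTable a [TrialTable-class].
#' @param bins the session bin grid (`time`, `trial`).
#' @param variant `"fixation"` or `"discrimination"`.
#' @param binWidth seconds.
#' @param window post-event kernel window in seconds (default 0.25).
#' @return list with the column matrix `X` and a `meta` data.frame
#'   (`group`, `source`, `shift`).
#' @export
oneHotStimulusColumns <- function(trialTable, bins, variant, binWidth,
                                  window = 0.25) {
  st <- trialTable@stimuli
  if (variant == "fixation") {
    fam <- interaction(st$label, st$sample, drop = FALSE, sep = "_s")
  } else {
    # the hemifield split is what encodes the attention condition: separate
    # indicators for each disparity by presentation hemifield and by which
    # hemifield was task-relevant (attended), so block-wise attentional
    # gain is expressible by the stimulus kernels rather than leaking into
    # the drift term
    if (is.null(st$relevant))
      stop("labeling error: discrimination stimuli need a 'relevant' column")
    fam <- interaction(st$label, st$hemifield, st$relevant,
                       drop = FALSE, sep = "_")
  }
  lv <- levels(fam)
  if (anyNA(fam))
    stop(sprintf("labeling error: unknown stimulus label in trial %s",
                 paste(unique(st$trial[is.na(fam)]), collapse = ", ")))
  n <- nrow(bins)
  nShift <- max(1L, round(window / binWidth))
  shifts <- 0:(nShift - 1L)
  Xs <- vector("list", length(lv))
  meta <- vector("list", length(lv))
  for (i in seq_along(lv)) {
    rows <- which(fam == lv[i])
    base <- numeric(n)
    for (r in rows) {
      b0 <- .binAt(st$onset[r], binWidth)
      b1 <- .binAt(st$offset[r], binWidth) - 1L
      if (b0 < 1L || b1 > n)
        stop("bounds error: stimulus presentation outside the session")
      if (b1 >= b0) base[b0:b1] <- 1
    }
    Xs[[i]] <- .shiftedColumns(base, shifts, bins$trial)
    meta[[i]] <- data.frame(group = "stimulus",
                            source = paste0("stim_", lv[i]),
                            shift = shifts)
  }
  list(X = do.call(cbind, Xs), meta = do.call(rbind, meta))
}

#' Drift columns from session-spanning tent bases
#'
#' Anchors are placed at regular intervals over the session and the clamped
#' tent bases evaluated at every bin, so each row of the drift block sums
#' to 1 and a slowly varying rate offset is expressible as a linear
#' combination. With attention block structure, the anchor spacing must be
#' wide enough that no more than one anchor falls within any pair of
#' successive alternating blocks, so the drift term cannot absorb the
#' block-wise attention alternation.
#'
#' @param bins the bin grid (`time`).
#' @param nAnchors number of anchors (>= 2); 10 for fixation-task sessions,
#'   8 for discrimination-task sessions.
#' @param sessionEnd session duration in seconds.
#' @param blockBounds optional vector of attention block start times; used to
#'   enforce the anchor-spacing constraint.
#' @return list with `X`, `meta` and the `anchors` used.
#' @export
driftColumns <- function(bins, nAnchors, sessionEnd, blockBounds = NULL) {
  if (nAnchors < 2L)
    stop("configuration error: nAnchors must be at least 2")
  anchors <- seq(0, sessionEnd, length.out = nAnchors)
  if (!is.null(blockBounds) && length(blockBounds) > 1L) {
    pairDur <- 2 * stats::median(diff(blockBounds))
    if (anchors[2L] - anchors[1L] < pairDur)
      stop(sprintf(paste0("configuration error: %d anchors put more than one ",
                          "anchor per pair of attention blocks; at most %d ",
                          "anchors are feasible"),
                   nAnchors, floor(sessionEnd / pairDur) + 1L))
  }
  X <- tentBasisEval(anchors, bins$time, boundary = "clamp")
  list(X = X,
       meta = data.frame(group = "drift",
                         source = sprintf("drift_a%02d", seq_len(nAnchors)),
                         shift = 0L),
       anchors = anchors)
}

#' Analog regressor columns via tent-basis convolution
#'
#' Convolves each analog profile (a movement component's temporal profile,
#' or an eye/pupil trace) with each tent basis, yielding one column per
#' (profile, anchor). Movement components use anchors at -100/0/+100 ms
#' (a 400-ms window; 30 components give 90 columns per view), eye and pupil
#' signals use -50/0/+50 ms (200 ms).
#'
#' @param profiles numeric matrix, one row per profile, columns are bins; a
#'   vector is treated as a single profile.
#' @param anchors tent anchor times relative to the signal (seconds),
#'   strictly increasing.
#' @param binWidth seconds.
#' @param group group name recorded in the metadata.
#' @param sources optional profile names.
#' @return list with `X` and `meta`.
#' @export
analogTentColumns <- function(profiles, anchors, binWidth, group = "face",
                              sources = NULL) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  if (any(diff(anchors) <= 0))
    stop("configuration error: anchors must be strictly increasing")
  if (is.null(sources))
    sources <- sprintf("%s_sv%03d", group, seq_len(nrow(profiles)))
  gap <- if (length(anchors) > 1L) diff(anchors) else binWidth
  lo <- floor((anchors[1L] - gap[1L]) / binWidth)
  hi <- ceiling((anchors[length(anchors)] + gap[length(gap)]) / binWidth)
  lags <- lo:hi
  W <- tentBasisEval(anchors, lags * binWidth, boundary = "taper")
  n <- ncol(profiles)
  out <- matrix(0, n, nrow(profiles) * length(anchors))
  meta <- data.frame(group = rep(group, ncol(out)),
                     source = rep(sources, each = length(anchors)),
                     shift = rep(round(anchors / binWidth), nrow(profiles)))
  col <- 0L
  for (i in seq_len(nrow(profiles))) {
    x <- profiles[i, ]
    for (a in seq_along(anchors)) {
      col <- col + 1L
      acc <- numeric(n)
      for (j in seq_along(lags)) {
        w <- W[j, a]
        if (w == 0) next
        d <- lags[j]          # response at t depends on signal at t - d
        if (d >= 0) {
          if (d < n) acc[(1L + d):n] <- acc[(1L + d):n] + w * x[1L:(n - d)]
        } else {
          if (-d < n) acc[1L:(n + d)] <- acc[1L:(n + d)] + w * x[(1L - d):n]
        }
      }
      out[, col] <- acc
    }
  }
  list(X = out, meta = meta)
}

# Map per-frame-interval motion profiles onto the session bin grid: the
# interval between frames t and t+1 is assigned to bin t+1 (the bin the new
# frame falls in); bin 1 has no preceding frame and gets 0.
.profilesToBins <- function(profiles, nBins) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  out <- matrix(0, nrow(profiles), nBins)
  k <- min(ncol(profiles), nBins - 1L)
  out[, 1L + seq_len(k)] <- profiles[, seq_len(k)]
  out
}

#' Assemble the full session design matrix
#'
#' Concatenates the regressor groups present for the task variant, z-scores
#' every column over the modeled bins, and records the normalization so raw
#' columns can be reconstructed. The fixation variant contains the stimulus,
#' time, reward, drift, face and body groups; the discrimination variant
#' adds choice-target, binary-choice and saccade groups. Eye/pupil
#' regressors are optional (a control analysis); when they are included,
#' bins with undefined eye-tracker samples are excluded from the design.
#' All-constant columns are kept as zeros with a flag and excluded from
#' fitting.
#'
#' @param trialTable a [TrialTable-class].
#' @param bins session-wide bin grid with `time`, `trial`, `modeled`,
#'   `fixation`, `stimOn` columns.
#' @param faceProfiles,bodyProfiles movement temporal profiles
#'   (components x frame intervals) from [projectMotion()].
#' @param eyeTrace optional [EyeTrace-class]; adds the eye group.
#' @param variant `"fixation"` or `"discrimination"`.
#' @param binWidth seconds (default 1/60).
#' @param driftAnchors number of drift anchors (default 10 for fixation,
#'   8 for discrimination).
#' @param movementAnchors,eyeAnchors tent anchors in seconds.
#' @param stimWindow,saccadeWindow event-kernel windows in seconds.
#' @param blockBounds optional attention block start times (drift
#'   constraint).
#' @return a [DesignMatrix-class] over the modeled bins.
#' @export
assembleDesign <- function(trialTable, bins, faceProfiles, bodyProfiles,
                           eyeTrace = NULL,
                           variant = c("fixation", "discrimination"),
                           binWidth = 1 / 60,
                           driftAnchors = NULL,
                           movementAnchors = c(-0.1, 0, 0.1),
                           eyeAnchors = c(-0.05, 0, 0.05),
                           stimWindow = 0.25,
                           saccadeWindow = c(0.5, 0.5),
                           blockBounds = NULL) {
  variant <- match.arg(variant)
  if (is.null(driftAnchors))
    driftAnchors <- if (variant == "fixation") 10L else 8L
  n <- nrow(bins)
  tr <- trialTable@trials
  st <- trialTable@stimuli

  blocks <- list()
  blocks$stimulus <- oneHotStimulusColumns(trialTable, bins, variant,
                                           binWidth, window = stimWindow)

  # time regressors: impulse at the trial's first stimulus onset, shifted
  # one copy per bin through the stimulus period and the post-window
  firstOn <- vapply(split(st$onset, st$trial), min, numeric(1))
  span <- max(tr$end - firstOn[as.character(tr$trial)])
  tX <- eventKernelColumns(unname(firstOn), rep(1, length(firstOn)),
                           c(0, span), binWidth, bins)
  blocks$time <- list(X = tX,
                      meta = data.frame(group = "time", source = "stim_onset",
                                        shift = attr(tX, "shifts")))

  rw <- tr$rewardTime[!is.na(tr$rewardTime)]
  rX <- eventKernelColumns(rw, rep(1, length(rw)), c(0, stimWindow),
                           binWidth, bins)
  blocks$reward <- list(X = rX,
                        meta = data.frame(group = "reward", source = "reward",
                                          shift = attr(rX, "shifts")))

  if (variant == "discrimination") {
    tg <- vector("list", 2L)
    for (i in 1:2) {
      side <- c("left", "right")[i]
      ons <- tr$targetTime[!is.na(tr$targetTime) & tr$targetSide == side]
      gX <- eventKernelColumns(ons, rep(1, length(ons)), c(0, stimWindow),
                               binWidth, bins)
      tg[[i]] <- list(X = gX,
                      meta = data.frame(group = "target",
                                        source = paste0("target_", side),
                                        shift = attr(gX, "shifts")))
    }
    blocks$target <- list(X = cbind(tg[[1]]$X, tg[[2]]$X),
                          meta = rbind(tg[[1]]$meta, tg[[2]]$meta))

    ok <- !is.na(tr$choiceTime)
    cX <- eventKernelColumns(tr$choiceTime[ok], tr$choice[ok],
                             c(0, stimWindow), binWidth, bins)
    blocks$choice <- list(X = cX,
                          meta = data.frame(group = "choice",
                                            source = "choice",
                                            shift = attr(cX, "shifts")))

    ok <- !is.na(tr$saccadeTime)
    sX <- eventKernelColumns(tr$saccadeTime[ok], tr$saccadeDir[ok],
                             saccadeWindow, binWidth, bins)
    blocks$saccade <- list(X = sX,
                           meta = data.frame(group = "saccade",
                                             source = "saccade",
                                             shift = attr(sX, "shifts")))
  }

  blocks$drift <- driftColumns(bins, driftAnchors, trialTable@sessionEnd,
                               blockBounds = blockBounds)[c("X", "meta")]

  blocks$face <- analogTentColumns(.profilesToBins(faceProfiles, n),
                                   movementAnchors, binWidth, group = "face")
  blocks$body <- analogTentColumns(.profilesToBins(bodyProfiles, n),
                                   movementAnchors, binWidth, group = "body")

  eyeDefined <- rep(TRUE, n)
  if (!is.null(eyeTrace)) {
    sig <- rbind(eyeTrace@x, eyeTrace@y, eyeTrace@speed,
                 eyeTrace@pupil, eyeTrace@pupilD)
    if (ncol(sig) != n)
      stop("alignment error: eye trace is not on the session bin grid")
    eyeDefined <- eyeTrace@defined
    sig[, !eyeDefined] <- 0   # undefined samples are flagged, never interpolated
    blocks$eye <- analogTentColumns(sig, eyeAnchors, binWidth, group = "eye",
                                    sources = c("eye_x", "eye_y", "eye_speed",
                                                "pupil", "pupil_d"))
  }

  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  meta <- do.call(rbind, lapply(blocks, `[[`, "meta"))
  rownames(meta) <- NULL

  keep <- bins$modeled
  if (!is.null(eyeTrace)) keep <- keep & eyeDefined
  X <- X[keep, , drop = FALSE]
  binsOut <- bins[keep, c("time", "trial", "fixation", "stimOn"), drop = FALSE]
  binsOut$binIndex <- which(keep)
  rownames(binsOut) <- NULL

  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  zero <- !is.finite(scl) | scl < 1e-12
  scl[zero] <- 1
  X <- sweep(X, 2L, ctr, "-")
  X <- sweep(X, 2L, scl, "/")
  X[, zero] <- 0

  new("DesignMatrix", X = X, columnMeta = meta, center = ctr, scale = scl,
      zeroVar = zero, bins = binsOut, binWidth = binWidth)
}

#' Reconstruct raw (de-normalized) design columns
#'
#' Inverts the z-scoring recorded at assembly: `raw = X * scale + center`.
#'
#' @param design a [DesignMatrix-class].
#' @param columns optional column subset.
#' @return numeric matrix of raw columns.
#' @export
rawDesign <- function(design, columns = NULL) {
  if (is.null(columns)) columns <- seq_len(ncol(design@X))
  X <- design@X[, columns, drop = FALSE]
  X <- sweep(X, 2L, design@scale[columns], "*")
  sweep(X, 2L, design@center[columns], "+")
}
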