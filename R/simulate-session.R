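#' Configure a synthetic recording session
#'
#' Bundles every parameter of the synthetic-session generator. Defaults
#' follow the study conditions the pipeline is built for: 16.67-ms analysis
#' bins, a 300-ms pre-stimulus and 1,000-ms post-stimulus window per trial,
#' and either a fixation task (four 450-ms stimulus samples per trial
#' separated by 50-ms blanks, contrasts 0/6.25/25/100%) or a discrimination
#' task (one 2-s disparity stimulus per hemifield, block-wise alternation of
#' spatial attention, choice targets, a choice saccade and reward).
#'
#' @param task `"fixation"` or `"discrimination"`.
#' @param nTrials,nUnits counts (>= 1).
#' @param seed integer seed; regenerating with the same config reproduces
#'   the session bit-identically.
#' @param binWidth analysis bin width in seconds (default 1/60).
#' @param preWindow,postWindow per-trial pre-/post-stimulus windows (s).
#' @param stimulusEpochsPerTrial stimulus samples per fixation trial.
#' @param sampleDuration,isiDuration fixation-task sample length and
#'   interstimulus blank (s).
#' @param contrastLevels fixation-task contrast values in percent
#'   (0 = blank, which carries its own one-hot indicator).
#' @param stimDuration discrimination-task stimulus duration (s).
#' @param disparityLevels discrimination-task signal labels.
#' @param blockLength trials per attention block.
#' @param itiDuration time from the last stimulus offset to the next trial's
#'   pre-window (s). When shorter than `postWindow`, the earlier trial's
#'   post-window is truncated to the nonoverlapping bins.
#' @param fixLead,fixLag fixation is maintained from `fixLead` before the
#'   first stimulus onset to `fixLag` after the last offset; those bins are
#'   the controlled-retinal-input epochs.
#' @param nLatents number of latent movement factors (split between the face
#'   and body views; latent 1 is shared with eye velocity so that blinks and
#'   saccade-like movements are visible in the face camera).
#' @param latentAr AR(1) coefficient of the latent factors. The movement
#'   autocorrelation of real animals is unknown, so this is a free
#'   parameter, not an assertion.
#' @param frameRate video frame rate (Hz); default equals the bin rate.
#' @param cameraRate optional lower camera rate (e.g. 12.5 or 20 Hz); frames
#'   are generated at this rate and profiles upsampled to the bin grid by
#'   nearest-bin assignment.
#' @param frameHeight,frameWidth video resolution per view.
#' @param videoNoiseSd additive pixel noise s.d. (intensity units).
#' @param baselineRate baseline firing per unit (spikes/s); a scalar is
#'   shared by all units.
#' @param couplings named list of dimensionless coupling scales for the
#'   regressor groups (`stimulus`, `reward`, `drift`, `face`, `body`). A
#'   coupling of 0 gives exactly zero true weights for that group.
#' @param attnGainMean,attnGainSd mean and s.d. of the per-unit
#'   multiplicative attention gain (discrimination task only).
#' @param eyeCoupling dimensionless coupling of the free-viewing saccade
#'   probability to the shared movement latent (0 decouples gaze shifts
#'   from the fidgeting latent).
#' @param blinkRate rate of blink bouts (per second) during which the eye
#'   signal is undefined.
#' @param screenHalfWidth,screenHalfHeight,rfOffset,rfRadius screen and
#'   receptive-field geometry in degrees, used to classify uncontrolled bins
#'   into retinal-input-inferable versus not.
#' @return a validated [SessionConfig-class].
#' @export
sessionConfig <- function(task = c("fixation", "discrimination"),
                          nTrials = 100L, nUnits = 10L, seed = 1L,
                          binWidth = 1 / 60,
                          preWindow = 0.3, postWindow = 1.0,
                          stimulusEpochsPerTrial = 4L,
                          sampleDuration = 0.45, isiDuration = 0.05,
                          contrastLevels = c(0, 6.25, 25, 100),
                          stimDuration = 2.0,
                          disparityLevels = c("near", "far"),
                          blockLength = 50L,
                          itiDuration = 1.5,
                          fixLead = 0.15, fixLag = 0.05,
                          nLatents = 6L, latentAr = 0.8,
                          frameRate = 60, cameraRate = NULL,
                          frameHeight = 16L, frameWidth = 16L,
                          videoNoiseSd = 0.05,
                          baselineRate = 10,
                          couplings = list(),
                          attnGainMean = 0.25, attnGainSd = 0.1,
                          eyeCoupling = 0.25,
                          blinkRate = 0.02,
                          screenHalfWidth = 16, screenHalfHeight = 9,
                          rfOffset = c(3, -2), rfRadius = 2) {
  task <- match.arg(task)
  cpl <- list(stimulus = 1, reward = 1, drift = 1, face = 0, body = 0)
  cpl[names(couplings)] <- couplings
  p <- list(task = task, nTrials = as.integer(nTrials),
            nUnits = as.integer(nUnits), seed = as.integer(seed),
            binWidth = binWidth, preWindow = preWindow,
            postWindow = postWindow,
            stimulusEpochsPerTrial = as.integer(stimulusEpochsPerTrial),
            sampleDuration = sampleDuration, isiDuration = isiDuration,
            contrastLevels = contrastLevels, stimDuration = stimDuration,
            disparityLevels = disparityLevels,
            blockLength = as.integer(blockLength),
            itiDuration = itiDuration, fixLead = fixLead, fixLag = fixLag,
            nLatents = as.integer(nLatents), latentAr = latentAr,
            frameRate = frameRate,
            cameraRate = if (is.null(cameraRate)) frameRate else cameraRate,
            frameHeight = as.integer(frameHeight),
            frameWidth = as.integer(frameWidth),
            videoNoiseSd = videoNoiseSd, baselineRate = baselineRate,
            couplings = cpl, attnGainMean = attnGainMean,
            attnGainSd = attnGainSd, eyeCoupling = eyeCoupling,
            blinkRate = blinkRate, screenHalfWidth = screenHalfWidth,
            screenHalfHeight = screenHalfHeight, rfOffset = rfOffset,
            rfRadius = rfRadius)
  cfg <- new("SessionConfig", params = p)
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  p <- cfg@params
  for (f in c("binWidth", "preWindow", "postWindow", "sampleDuration",
              "stimDuration", "itiDuration", "frameRate"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("configuration error: field '%s' must be > 0", f),
           call. = FALSE)
  if (p$nTrials < 1L)
    stop("configuration error: field 'nTrials' must be >= 1", call. = FALSE)
  if (p$nUnits < 1L)
    stop("configuration error: field 'nUnits' must be >= 1", call. = FALSE)
  if (any(p$baselineRate < 0))
    stop("configuration error: field 'baselineRate' must be nonnegative",
         call. = FALSE)
  if (p$nLatents < 2L)
    stop("configuration error: field 'nLatents' must be >= 2", call. = FALSE)
  if (p$latentAr < 0 || p$latentAr >= 1)
    stop("configuration error: field 'latentAr' must lie in [0, 1)",
         call. = FALSE)
  if (p$task == "discrimination" && p$blockLength < 1L)
    stop("configuration error: field 'blockLength' must be >= 1",
         call. = FALSE)
  invisible(TRUE)
}

# --- trial tables -----------------------------------------------------------

.fixationTrialTable <- function(p) {
  nS <- p$stimulusEpochsPerTrial
  stimSpan <- nS * p$sampleDuration + (nS - 1L) * p$isiDuration
  trialStart <- numeric(p$nTrials)
  t0 <- 0
  trials <- vector("list", p$nTrials)
  stimuli <- vector("list", p$nTrials)
  labels <- matrix(sample(as.character(p$contrastLevels),
                          p$nTrials * nS, replace = TRUE),
                   nrow = p$nTrials)
  for (i in seq_len(p$nTrials)) {
    start <- t0
    firstOn <- start + p$preWindow
    ons <- firstOn + (seq_len(nS) - 1L) * (p$sampleDuration + p$isiDuration)
    offs <- ons + p$sampleDuration
    lastOff <- offs[nS]
    nominalEnd <- lastOff + p$postWindow
    nextStart <- lastOff + p$itiDuration
    end <- if (i < p$nTrials) min(nominalEnd, nextStart) else nominalEnd
    trials[[i]] <- data.frame(
      trial = i, start = start, end = end,
      fixStart = firstOn - p$fixLead, fixEnd = lastOff + p$fixLag,
      rewardTime = lastOff + 0.05, attended = NA, relevantSide = NA,
      targetTime = NA_real_, targetSide = NA_character_,
      choiceTime = NA_real_, choice = NA_real_,
      saccadeTime = NA_real_, saccadeDir = NA_real_)
    stimuli[[i]] <- data.frame(trial = i, sample = seq_len(nS),
                               onset = ons, offset = offs,
                               label = labels[i, ], hemifield = "center")
    t0 <- nextStart
  }
  tr <- do.call(rbind, trials)
  new("TrialTable", trials = tr, stimuli = do.call(rbind, stimuli),
      sessionEnd = max(tr$end))
}

.discriminationTrialTable <- function(p, rfSide = "left") {
  trials <- vector("list", p$nTrials)
  stimuli <- vector("list", p$nTrials)
  t0 <- 0
  sides <- c("left", "right")
  for (i in seq_len(p$nTrials)) {
    block <- (i - 1L) %/% p$blockLength
    relevant <- sides[(block %% 2L) + 1L]
    start <- t0
    on <- start + p$preWindow
    off <- on + p$stimDuration
    sacc <- off + runif(1, 0.2, 0.35)
    dispL <- sample(p$disparityLevels, 1L)
    dispR <- sample(p$disparityLevels, 1L)
    relDisp <- if (relevant == "left") dispL else dispR
    correct <- runif(1) < 0.85
    choice <- if (xor(relDisp == p$disparityLevels[1L], !correct)) 1 else -1
    reward <- if (correct) sacc + 0.15 else NA_real_
    nominalEnd <- off + p$postWindow
    nextStart <- off + p$itiDuration
    end <- if (i < p$nTrials) min(nominalEnd, nextStart) else nominalEnd
    trials[[i]] <- data.frame(
      trial = i, start = start, end = end,
      fixStart = on - p$fixLead, fixEnd = off,
      rewardTime = reward, attended = (relevant == rfSide),
      relevantSide = relevant,
      targetTime = off, targetSide = relevant,
      choiceTime = sacc, choice = choice,
      saccadeTime = sacc, saccadeDir = sample(c(-1, 1), 1L))
    stimuli[[i]] <- data.frame(trial = i, sample = 1L,
                               onset = c(on, on), offset = c(off, off),
                               label = c(dispL, dispR),
                               hemifield = sides, relevant = relevant)
    t0 <- nextStart
  }
  tr <- do.call(rbind, trials)
  st <- do.call(rbind, stimuli)
  # per-trial onsets must be strictly ordered; the two hemifield
  # presentations share an onset, so keep one row per (trial, hemifield)
  # and order by hemifield for determinism
  st <- st[order(st$trial, st$hemifield), ]
  st$onset <- st$onset + ifelse(st$hemifield == "right", 1e-6, 0)
  rownames(st) <- NULL
  new("TrialTable", trials = tr, stimuli = st, sessionEnd = max(tr$end))
}

# --- bin grid ---------------------------------------------------------------

.sessionBins <- function(tt, binWidth) {
  nBins <- .binAt(tt@sessionEnd, binWidth) - 1L
  time <- (seq_len(nBins) - 1L) * binWidth
  trial <- rep(NA_integer_, nBins)
  fixation <- rep(FALSE, nBins)
  modeled <- rep(FALSE, nBins)
  tr <- tt@trials
  for (i in seq_len(nrow(tr))) {
    b0 <- .binAt(tr$start[i], binWidth)
    b1 <- .binAt(tr$end[i], binWidth) - 1L
    if (b1 >= b0) {
      idx <- b0:min(b1, nBins)
      trial[idx] <- tr$trial[i]
      modeled[idx] <- TRUE
    }
    f0 <- .binAt(tr$fixStart[i], binWidth)
    f1 <- .binAt(tr$fixEnd[i], binWidth) - 1L
    if (f1 >= f0) fixation[f0:min(f1, nBins)] <- TRUE
  }
  stimOn <- rep(FALSE, nBins)
  st <- tt@stimuli
  for (r in seq_len(nrow(st))) {
    b0 <- .binAt(st$onset[r], binWidth)
    b1 <- .binAt(st$offset[r], binWidth) - 1L
    if (b1 >= b0) stimOn[b0:min(b1, nBins)] <- TRUE
  }
  data.frame(time = time, trial = trial, modeled = modeled,
             fixation = fixation, stimOn = stimOn)
}

# --- video ------------------------------------------------------------------

#' Simulate video frames from latent movement factors
#'
#' Each frame is a weighted sum of per-factor spatial maps, weights given by
#' the latent activations, plus independent pixel noise. With disjoint
#' nonnegative maps and zero noise, the absolute frame-difference (motion)
#' matrix of the result is exactly rank-`n_latents`.
#'
#' @param latents matrix `n_frames x n_factors` of factor activations.
#' @param maps list of `height x width` spatial maps, one per factor,
#'   sharing one pixel grid.
#' @param noiseSd additive pixel noise s.d.
#' @param seed integer seed.
#' @param frameRate Hz.
#' @param view `"face"` or `"body"`.
#' @return a [FrameStack-class].
#' @export
simulateMotionFrames <- function(latents, maps, noiseSd = 0, seed = 1L,
                                 frameRate = 60, view = "face") {
  if (is.null(dim(latents))) latents <- matrix(latents, ncol = 1L)
  if (length(maps) != ncol(latents))
    stop("dimension error: one spatial map per latent factor is required")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension error: spatial maps must share one pixel grid")
  h <- dims[1, 1]; w <- dims[2, 1]
  nF <- nrow(latents)
  mapMat <- vapply(maps, as.numeric, numeric(h * w))   # (h*w) x K
  flat <- latents %*% t(mapMat)                        # nF x (h*w)
  if (noiseSd > 0)
    flat <- flat + .withSeed(seed, matrix(rnorm(length(flat), 0, noiseSd),
                                          nrow = nF))
  new("FrameStack", frames = array(flat, c(nF, h, w)),
      frameRate = frameRate, view = view)
}

# Two small eye-region patches near the top of the face frame, disjoint
# from the latent maps; driven by horizontal and vertical gaze position.
.eyeRegionMaps <- function(latentMaps, h, w) {
  taken <- Reduce(`|`, lapply(latentMaps, function(m) m > 0))
  mk <- function(cr, cc) {
    g <- outer(seq_len(h), seq_len(w), function(r, c)
      exp(-((r - cr)^2 + (c - cc)^2) / (2 * 1.2^2)))
    g[g < 0.05] <- 0
    g[taken] <- 0
    g
  }
  list(mk(round(h * 0.12) + 1L, round(w * 0.3)),
       mk(round(h * 0.12) + 1L, round(w * 0.7)))
}

# Disjoint Gaussian-bump spatial maps on an h x w grid, one per factor.
.latentMaps <- function(nMaps, h, w) {
  centers <- cbind(
    row = round(seq(h * 0.2, h * 0.8, length.out = nMaps)),
    col = round(seq(w * 0.25, w * 0.75, length.out = nMaps)))
  sigma <- max(1, min(h, w) / (2.5 * nMaps))
  maps <- vector("list", nMaps)
  taken <- matrix(FALSE, h, w)
  for (k in seq_len(nMaps)) {
    g <- outer(seq_len(h), seq_len(w), function(r, c)
      exp(-((r - centers[k, 1])^2 + (c - centers[k, 2])^2) / (2 * sigma^2)))
    g[g < 0.05] <- 0
    g[taken] <- 0            # keep supports disjoint
    taken <- taken | (g > 0)
    maps[[k]] <- g
  }
  maps
}

# --- the generator ----------------------------------------------------------

#' Simulate a complete synthetic session
#'
#' Generates a session with known generative structure: a trial/event table,
#' latent-factor-driven face and body videos, an eye trace whose velocity
#' shares a latent factor with the face view (so blinks/saccade-like events
#' are visible in the face camera), and Poisson spike counts whose rate is a
#' rectified linear combination of the true design (stimulus, time, reward,
#' drift, face/body movement) built by the same design-matrix machinery the
#' analysis uses. The full ground truth is stored in the returned session.
#'
#' Controlled-retinal-input bins are exactly the fixation-maintained bins.
#' Regenerating with the same config reproduces every field bit-identically.
#'
#' @param config a [SessionConfig-class].
#' @return a [SyntheticSession-class].
#' @export
simulateSession <- function(config) {
  .validateConfig(config)
  p <- config@params
  seed <- p$seed

  tt <- .withSeed(seed + 1L, {
    if (p$task == "fixation") .fixationTrialTable(p)
    else .discriminationTrialTable(p)
  })
  bins <- .sessionBins(tt, p$binWidth)
  n <- nrow(bins)

  # latent movement factors, AR(1), unit marginal variance
  K <- p$nLatents
  lat <- .withSeed(seed + 2L, {
    e <- matrix(rnorm(n * K), n, K)
    z <- matrix(0, n, K)
    z[1L, ] <- e[1L, ]
    s <- sqrt(1 - p$latentAr^2)
    for (t in 2L:n) z[t, ] <- p$latentAr * z[t - 1L, ] + s * e[t, ]
    z
  })
  nFace <- ceiling(K / 2)
  faceIdx <- seq_len(nFace)           # latent 1 (shared with eye) is facial
  bodyIdx <- setdiff(seq_len(K), faceIdx)

  faceMaps <- .latentMaps(nFace, p$frameHeight, p$frameWidth)
  bodyMaps <- .latentMaps(length(bodyIdx), p$frameHeight, p$frameWidth)

  # eye trace: fixational jitter inside fixation, latent-coupled free
  # viewing outside; speed is the first difference of position
  dz1 <- c(0, diff(lat[, 1L]))
  eye <- .withSeed(seed + 5L, {
    free <- !bins$fixation
    # saccadic free viewing: saccade probability per bin is elevated when
    # the shared movement latent is active (gaze shifts co-occur with
    # fidgeting), targets are drawn around the screen center, and the eye
    # drifts slowly between saccades; during fixation the gaze decays onto
    # the fixation point with small fixational jitter
    pSac <- pmin(0.3, 0.01 + 0.24 * p$eyeCoupling * abs(dz1)) * free
    sac <- runif(n) < pSac
    tx <- rnorm(n, 0, 6); ty <- rnorm(n, 0, 3.5)
    driftX <- rnorm(n, 0, 0.02); driftY <- rnorm(n, 0, 0.02)
    jitX <- rnorm(n, 0, 0.01); jitY <- rnorm(n, 0, 0.01)
    x <- numeric(n); y <- numeric(n)
    for (t in 2L:n) {
      if (bins$fixation[t]) {
        x[t] <- 0.6 * x[t - 1L] + jitX[t]
        y[t] <- 0.6 * y[t - 1L] + jitY[t]
      } else if (sac[t]) {
        x[t] <- tx[t]; y[t] <- ty[t]
      } else {
        x[t] <- x[t - 1L] + driftX[t]
        y[t] <- y[t - 1L] + driftY[t]
      }
    }
    speed <- c(0, sqrt(diff(x)^2 + diff(y)^2)) / p$binWidth
    pup <- stats::filter(rnorm(n), 0.995, method = "recursive")
    pup <- 1 + 0.05 * as.numeric(pup) / max(1, sd(pup))
    defined <- rep(TRUE, n)
    nBlink <- rpois(1L, p$blinkRate * tt@sessionEnd)
    if (nBlink > 0) {
      starts <- sample.int(n, nBlink)
      for (b in starts) {
        idx <- b:min(n, b + round(0.15 / p$binWidth))
        defined[idx] <- FALSE
      }
    }
    new("EyeTrace", x = x, y = y, speed = speed, pupil = pup,
        pupilD = c(0, diff(pup)) / p$binWidth, defined = defined,
        sampleRate = 1 / p$binWidth)
  })

  # the eye region of the face view: two small patches whose intensity
  # follows gaze position, so eye movements are visible in the face camera
  # (this is what lets eye-driven retinal confounds load on face
  # components, and what the eye-region-removal control removes)
  eyeMaps <- .eyeRegionMaps(faceMaps, p$frameHeight, p$frameWidth)
  eyeRegion <- (eyeMaps[[1L]] > 0) | (eyeMaps[[2L]] > 0)

  camStep <- max(1L, round(p$frameRate / p$cameraRate))
  camRows <- seq(1L, n, by = camStep)
  faceDrivers <- cbind(lat[, faceIdx, drop = FALSE], eye@x, eye@y)
  face <- simulateMotionFrames(faceDrivers[camRows, , drop = FALSE],
                               c(faceMaps, eyeMaps),
                               p$videoNoiseSd, seed + 3L,
                               p$frameRate / camStep, "face")
  body <- simulateMotionFrames(lat[camRows, bodyIdx, drop = FALSE], bodyMaps,
                               p$videoNoiseSd, seed + 4L,
                               p$frameRate / camStep, "body")

  # true movement temporal profiles: motion energy of each latent
  profFace <- t(abs(apply(lat[, faceIdx, drop = FALSE], 2L, diff)))
  profBody <- t(abs(apply(lat[, bodyIdx, drop = FALSE], 2L, diff)))

  # true design, raw units, over the full bin grid
  stim <- oneHotStimulusColumns(tt, bins, p$task, p$binWidth)
  drift <- driftColumns(bins, if (p$task == "fixation") 10L else 8L,
                        tt@sessionEnd,
                        blockBounds = NULL)
  rw <- tt@trials$rewardTime[!is.na(tt@trials$rewardTime)]
  rX <- eventKernelColumns(rw, rep(1, length(rw)), c(0, 0.25),
                           p$binWidth, bins)
  faceX <- analogTentColumns(.profilesToBins(profFace, n),
                             c(-0.1, 0, 0.1), p$binWidth, "face")
  bodyX <- analogTentColumns(.profilesToBins(profBody, n),
                             c(-0.1, 0, 0.1), p$binWidth, "body")

  U <- p$nUnits
  cpl <- lapply(p$couplings, rep_len, U)   # per-unit coupling scales
  truthW <- .withSeed(seed + 6L, {
    nFam <- length(unique(stim$meta$source))
    nShift <- sum(stim$meta$source == stim$meta$source[1L])
    shape <- 0.3 + 0.7 * exp(-(seq_len(nShift) - 1L) / 4)
    tune <- if (p$task == "fixation") {
      lv <- sub("_s.*$", "", unique(stim$meta$source))
      cv <- as.numeric(sub("^stim_", "", lv))
      setNames((cv / max(cv))^0.5, unique(stim$meta$source))
    } else {
      fam <- unique(stim$meta$source)
      # source is "stim_<label>_<hemifield>_<relevant>"; RF on the left
      # hemifield, so only left presentations drive responses; near/far
      # preference varies across units (handled per unit)
      hemi <- vapply(strsplit(sub("^stim_", "", fam), "_"),
                     `[[`, character(1), 2L)
      setNames(as.numeric(hemi == "left"), fam)
    }
    wStim <- matrix(0, nrow(stim$meta), U)
    amp <- runif(U, 4, 10)
    pref <- sample(c(1, -1), U, replace = TRUE)
    for (u in seq_len(U)) {
      famJit <- setNames(runif(nFam, 0.8, 1.2), unique(stim$meta$source))
      tu <- tune
      if (p$task == "discrimination") {
        nearFam <- grepl(p$disparityLevels[1L], names(tu))
        tu <- tu * ifelse(xor(nearFam, pref[u] < 0), 1, 0.4)
      }
      wStim[, u] <- cpl$stimulus[u] * amp[u] *
        tu[stim$meta$source] * famJit[stim$meta$source] *
        shape[match(stim$meta$shift, sort(unique(stim$meta$shift)))]
    }
    # random drift shape with a fixed RMS amplitude (25% of baseline), so
    # every unit carries an identifiable slow-drift component
    wDrift <- matrix(rnorm(ncol(drift$X) * U), ncol(drift$X), U)
    wDrift <- sweep(wDrift, 2L, sqrt(colMeans(wDrift^2)), "/")
    wDrift <- sweep(wDrift, 2L,
                    cpl$drift * 0.25 * rep_len(p$baselineRate, U), "*")
    wReward <- matrix(0, ncol(rX), U)
    for (u in seq_len(U))
      wReward[, u] <- cpl$reward[u] * runif(1, 2, 5) * shape
    wFace <- sweep(matrix(rnorm(ncol(faceX$X) * U, 0, 2),
                          ncol(faceX$X), U), 2L, cpl$face, "*")
    wBody <- sweep(matrix(rnorm(ncol(bodyX$X) * U, 0, 2),
                          ncol(bodyX$X), U), 2L, cpl$body, "*")
    attnGain <- if (p$task == "discrimination")
      rnorm(U, p$attnGainMean, p$attnGainSd) else rep(0, U)
    driveSens <- runif(U, 0.5, 1.5)
    list(stimulus = wStim, drift = wDrift, reward = wReward,
         face = wFace, body = wBody, attnGain = attnGain,
         driveSens = driveSens)
  })

  baseline <- rep(p$baselineRate, length.out = U)
  attnIn <- !is.na(bins$trial) &
    tt@trials$attended[match(bins$trial, tt@trials$trial)] %in% TRUE
  gainMat <- 1 + outer(as.numeric(attnIn), truthW$attnGain)
  contrib <- list(stimulus = (stim$X %*% truthW$stimulus) * gainMat,
                  drift = drift$X %*% truthW$drift,
                  reward = rX %*% truthW$reward,
                  face = faceX$X %*% truthW$face,
                  body = bodyX$X %*% truthW$body)        # each n x U
  linear <- sweep(Reduce(`+`, contrib), 2L, baseline, "+")
  rates <- t(pmax(linear, 0))                            # U x n, spikes/s

  drive <- eye@speed * as.numeric(!bins$fixation)        # zero on controlled

  spikeSeed <- seed + 7L
  counts <- simulateSpikes(rates, p$binWidth, spikeSeed)

  truth <- list(
    weights = truthW[c("stimulus", "drift", "reward", "face", "body")],
    columnMeta = rbind(stim$meta,
                       data.frame(group = "drift",
                                  source = sprintf("drift_a%02d",
                                                   seq_len(ncol(drift$X))),
                                  shift = 0L),
                       data.frame(group = "reward", source = "reward",
                                  shift = attr(rX, "shifts")),
                       faceX$meta, bodyX$meta),
    baseline = baseline, attnGain = truthW$attnGain,
    driveSens = truthW$driveSens,
    profilesFace = profFace, profilesBody = profBody,
    latents = lat, contrib = contrib, linear = linear,
    rates = rates, drive = drive, eyeRegion = eyeRegion,
    confoundGain = 0, spikeSeed = spikeSeed,
    couplings = cpl)

  spikes <- .binnedSpikes(counts, p$binWidth, bins, U)

  new("SyntheticSession", config = config, trialTable = tt,
      face = face, body = body, eye = eye, spikes = spikes,
      bins = bins, truth = truth)
}

.binnedSpikes <- function(counts, binWidth, bins, U) {
  rd <- S4Vectors::DataFrame(
    unit = sprintf("u%03d", seq_len(U)),
    area = rep(c("V1", "V2", "V3/V3A"), length.out = U),
    animal = "sim1")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rd,
    colData = S4Vectors::DataFrame(bins))
  rownames(se) <- rd$unit
  new("BinnedSpikes", se, binWidth = binWidth)
}

#' Draw Poisson spike counts from per-bin rates
#'
#' Independent Poisson counts per unit and bin with mean
#' `rate * binWidth`; rates must already be rectified (nonnegative).
#'
#' @param rates matrix `n_units x n_bins` of rates in spikes/s.
#' @param binWidth seconds.
#' @param seed integer seed; identical seeds give identical counts.
#' @return integer matrix of counts, same shape as `rates`.
#' @export
simulateSpikes <- function(rates, binWidth, seed = 1L) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1L)
  if (any(rates < 0))
    stop("configuration error: rates must be nonnegative (rectify first)")
  .withSeed(seed, {
    matrix(rpois(length(rates), rates * binWidth),
           nrow = nrow(rates))
  })
}

#' Add an eye-movement-driven retinal confound to a session
#'
#' Adds to each unit's generative rate a term
#' `gain * sensitivity_u * eyeSpeed(t)` that is exactly zero on
#' controlled (fixation) bins, then redraws the Poisson spikes with the
#' session's stored spike seed, so `gain = 0` reproduces the session
#' unchanged. The eye trace is already correlated with the face-view
#' movement latents (shared factor), so this models movements that change
#' the retinal input without any direct movement drive on the neurons.
#'
#' @param session a [SyntheticSession-class].
#' @param gain nonnegative confound gain (spikes/s per deg/s of eye speed).
#' @return the modified [SyntheticSession-class].
#' @export
applyRetinalConfound <- function(session, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0)
    stop("configuration error: gain must be a single nonnegative number")
  tr <- session@truth
  add <- outer(tr$drive, gain * tr$driveSens)            # n x U
  base <- tr$linear - if (is.null(tr$contrib$retinal)) 0 else tr$contrib$retinal
  tr$linear <- base + add
  tr$contrib$retinal <- add
  rates <- t(pmax(tr$linear, 0))
  counts <- simulateSpikes(rates, session@config@params$binWidth,
                           tr$spikeSeed)
  tr$rates <- rates
  tr$confoundGain <- gain
  session@truth <- tr
  session@spikes <- .binnedSpikes(counts, session@config@params$binWidth,
                                  session@bins,
                                  nrow(counts))
  session
}
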