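# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixtureSession <- function() {
  if (is.null(.fixtures$session)) {
    .fixtures$session <- simulateSession(sessionConfig(
      nTrials = 30L, nUnits = 4L, seed = 101L,
      couplings = list(face = 1)))
  }
  .fixtures$session
}

# design built from the true movement profiles, plus its fit
fixtureFit <- function() {
  if (is.null(.fixtures$fit)) {
    s <- fixtureSession()
    tr <- sessionTruth(s)
    d <- assembleDesign(s@trialTable, s@bins, tr$profilesFace,
                        tr$profilesBody, variant = "fixation")
    plan <- makeFoldPlan(unique(binInfo(d)$trial), 10L, seed = 7L)
    fit <- suppressWarnings(crossvalFitPredict(d, s@spikes, plan))
    .fixtures$fit <- list(design = d, plan = plan, fit = fit)
  }
  .fixtures$fit
}

fixtureGeometry <- function() {
  list(screenHalfWidth = 16, screenHalfHeight = 9,
       rfOffset = c(3, -2), rfRadius = 2)
}

# small deterministic frame stack with planted orthogonal components
plantedFrames <- function(nFrames = 600L, h = 12L, w = 12L, k = 5L,
                          noiseSd = 0, seed = 5L) {
  maps <- lapply(seq_len(k), function(i) {
    m <- matrix(0, h, w)
    m[, (1L + (i - 1L) * 2L):(i * 2L)] <- 1   # disjoint pixel bands
    m
  })
  lat <- matrix(0, nFrames, k)
  lat[] <- stats::rnorm(nFrames * k)
  set.seed(seed)
  lat[] <- stats::rnorm(nFrames * k)
  list(frames = simulateMotionFrames(lat, maps, noiseSd = noiseSd,
                                     seed = seed + 1L, frameRate = 60,
                                     view = "face"),
       maps = maps, latents = lat)
}
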