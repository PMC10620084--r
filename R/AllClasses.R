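#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var quantile rnorm rpois runif sd cor median
#'   t.test cor.test p.adjust setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Session configuration for the synthetic-session generator
#'
#' A validated bag of parameters describing one simulated recording session:
#' trial structure, stimulus schedule, camera geometry, latent-movement model
#' and spiking model. Build one with [sessionConfig()]; all downstream
#' generator functions consume it.
#'
#' @slot params named list of configuration values (see [sessionConfig()]).
#' @export
setClass("SessionConfig", representation(params = "list"))

#' A stack of grayscale video frames
#'
#' @slot frames numeric array, `n_frames x height x width`, finite intensities.
#' @slot frameRate sampling rate in Hz.
#' @slot view camera label, `"face"` or `"body"`.
#' @export
setClass("FrameStack",
         representation(frames = "array", frameRate = "numeric",
                        view = "character"))

setValidity("FrameStack", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be an n_frames x height x width array")
  if (dim(object@frames)[1L] < 2L)
    return("need at least 2 frames")
  if (!all(is.finite(object@frames)))
    return("frame intensities must be finite")
  if (!(object@view %in% c("face", "body")))
    return("view must be 'face' or 'body'")
  TRUE
})

#' Region-of-interest mask over a video frame
#'
#' @slot include logical matrix (height x width); `TRUE` pixels enter the
#'   motion matrix.
#' @slot excluded named list of logical matrices marking labeled subregions
#'   (for example the eye region) that have been removed from `include`.
#' @export
setClass("RoiMask",
         representation(include = "matrix", excluded = "list"))

setValidity("RoiMask", function(object) {
  if (!is.logical(object@include)) return("include must be a logical matrix")
  if (!any(object@include)) return("mask must include at least one pixel")
  TRUE
})

#' Motion-energy matrix of a video
#'
#' Rows are ROI pixels, columns are frame intervals; entry `[p, t]` is the
#' absolute intensity difference of pixel `p` between frames `t` and `t + 1`.
#'
#' @slot M nonnegative matrix, `n_roi_pixels x (n_frames - 1)`.
#' @slot pixelIndex integer index of each row into the flattened
#'   (height x width) frame, so spatial maps can be painted back.
#' @slot frameDim integer c(height, width) of the source frames.
#' @slot frameRate Hz.
#' @slot view camera label.
#' @export
setClass("MotionMatrix",
         representation(M = "matrix", pixelIndex = "integer",
                        frameDim = "integer", frameRate = "numeric",
                        view = "character"))

setValidity("MotionMatrix", function(object) {
  if (any(object@M < 0)) return("motion energy must be nonnegative")
  if (nrow(object@M) != length(object@pixelIndex))
    return("pixelIndex length must match rows of M")
  TRUE
})

#' Movement components of a motion matrix
#'
#' Orthonormal spatial maps with their singular values and temporal profiles
#' (the projections of the motion matrix onto the maps).
#'
#' @slot spatial `n_roi_pixels x k` matrix with unit-norm columns.
#' @slot d nonincreasing nonnegative singular values, length k.
#' @slot temporal `k x (n_frames - 1)` temporal profiles.
#' @slot pixelIndex,frameDim,view provenance copied from the motion matrix.
#' @export
setClass("MotionComponents",
         representation(spatial = "matrix", d = "numeric",
                        temporal = "matrix", pixelIndex = "integer",
                        frameDim = "integer", view = "character"))

setValidity("MotionComponents", function(object) {
  k <- ncol(object@spatial)
  if (length(object@d) != k) return("one singular value per component")
  if (is.unsorted(rev(object@d))) return("singular values must be nonincreasing")
  if (any(object@d < 0)) return("singular values must be nonnegative")
  nrm <- sqrt(colSums(object@spatial^2))
  if (any(abs(nrm - 1) > 1e-6)) return("spatial maps must have unit norm")
  if (nrow(object@temporal) != k) return("temporal rows must match k")
  TRUE
})

#' Eye-tracker trace sampled on the analysis bin grid
#'
#' @slot x,y gaze position in degrees.
#' @slot speed eye speed in deg/s (first difference of position).
#' @slot pupil,pupilD pupil size (a.u.) and its derivative (a.u./s).
#' @slot defined logical; `FALSE` where the tracker signal was undefined
#'   (blinks, eccentric gaze). Undefined samples are flagged, never
#'   interpolated.
#' @slot sampleRate Hz.
#' @export
setClass("EyeTrace",
         representation(x = "numeric", y = "numeric", speed = "numeric",
                        pupil = "numeric", pupilD = "numeric",
                        defined = "logical", sampleRate = "numeric"))

setValidity("EyeTrace", function(object) {
  n <- length(object@x)
  if (any(lengths(list(object@y, object@speed, object@pupil,
                       object@pupilD, object@defined)) != n))
    return("all trace fields must have equal length")
  TRUE
})

#' Trial and event table of one session
#'
#' @slot trials one row per trial: identifiers, window bounds, fixation
#'   interval, task events (reward, choice target, choice, saccade) and
#'   condition labels (attention block, relevant side).
#' @slot stimuli one row per stimulus presentation: trial, sample position,
#'   onset/offset (seconds from session start), label and hemifield.
#' @slot sessionEnd session duration in seconds.
#' @export
setClass("TrialTable",
         representation(trials = "data.frame", stimuli = "data.frame",
                        sessionEnd = "numeric"))

setValidity("TrialTable", function(object) {
  st <- object@stimuli
  if (nrow(st)) {
    if (any(st$onset < 0 | st$offset > object@sessionEnd))
      return("stimulus events must lie within the session")
    bad <- vapply(split(st$onset, st$trial),
                  function(o) is.unsorted(o, strictly = TRUE), logical(1))
    if (any(bad)) return("per-trial stimulus onsets must be strictly ordered")
  }
  TRUE
})

#' Binned spike counts with unit and bin annotation
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are units (rowData
#' carries `area` and `animal`), columns are time bins (colData carries bin
#' `time`, `trial`, `modeled`, `fixation` and `stimOn` flags), and the single
#' assay `"counts"` holds nonnegative integer spike counts.
#'
#' @slot binWidth bin width in seconds.
#' @export
setClass("BinnedSpikes",
         contains = "SummarizedExperiment",
         representation(binWidth = "numeric"))

setValidity("BinnedSpikes", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be nonnegative integers")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    return("binWidth must be a positive scalar")
  TRUE
})

#' Design matrix with regressor-group annotation
#'
#' Rows are the modeled time bins of a session, columns are regressors. Each
#' column belongs to exactly one group (stimulus, time, reward, target,
#' choice, saccade, drift, face, body, eye); columns are z-scored over the
#' modeled session and the normalization is recorded so raw columns can be
#' reconstructed exactly.
#'
#' @slot X numeric matrix, `n_modeled_bins x n_columns`, z-scored.
#' @slot columnMeta data.frame with `group`, `source` and `shift` (bins) per
#'   column.
#' @slot center,scale per-column normalization applied to the raw columns.
#' @slot zeroVar logical per column; `TRUE` marks all-constant raw columns
#'   that are kept (as zeros) but excluded from fitting.
#' @slot bins data.frame describing each row: `binIndex` (column index into
#'   the session-wide bin grid), `time`, `trial`, `fixation`, `stimOn`.
#' @slot binWidth seconds.
#' @export
setClass("DesignMatrix",
         representation(X = "matrix", columnMeta = "data.frame",
                        center = "numeric", scale = "numeric",
                        zeroVar = "logical", bins = "data.frame",
                        binWidth = "numeric"))

setValidity("DesignMatrix", function(object) {
  p <- ncol(object@X)
  if (nrow(object@columnMeta) != p) return("one meta row per column")
  if (any(lengths(list(object@center, object@scale, object@zeroVar)) != p))
    return("normalization vectors must match column count")
  if (anyNA(object@columnMeta$group)) return("every column needs a group")
  if (nrow(object@bins) != nrow(object@X))
    return("bins must describe every design row")
  TRUE
})

#' Trial-blocked crossvalidation fold plan
#'
#' @slot trial modeled trial ids.
#' @slot fold fold assignment in `1..nFolds`, one per trial.
#' @slot nFolds number of folds.
#' @slot seed RNG seed used for the assignment.
#' @export
setClass("FoldPlan",
         representation(trial = "integer", fold = "integer",
                        nFolds = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (length(object@trial) != length(object@fold))
    return("one fold per trial")
  if (any(object@fold < 1L | object@fold > object@nFolds))
    return("folds must lie in 1..nFolds")
  if (anyDuplicated(object@trial)) return("each trial appears exactly once")
  TRUE
})

#' Per-unit ridge fit with crossvalidated predictions
#'
#' @slot weights final full-data ridge weights on the z-scored columns
#'   (`n_columns x n_units`); de-normalize with the design's `scale` to get
#'   weights per raw regressor unit.
#' @slot intercept unpenalized intercept per unit (counts per bin).
#' @slot lambda selected ridge penalty per unit.
#' @slot lambdaGrid the candidate grid searched.
#' @slot predictions crossvalidated prediction per unit and modeled bin
#'   (`n_units x n_modeled_bins`); each bin is predicted only by folds not
#'   trained on it.
#' @slot ve overall crossvalidated %VE per unit.
#' @slot plan the \linkS4class{FoldPlan} used.
#' @slot units unit identifiers.
#' @slot columnMeta copy of the design's column metadata.
#' @slot clipNegative whether predictions were clipped at zero.
#' @export
setClass("FitResult",
         representation(weights = "matrix", intercept = "numeric",
                        lambda = "numeric", lambdaGrid = "numeric",
                        predictions = "matrix", ve = "numeric",
                        plan = "FoldPlan", units = "character",
                        columnMeta = "data.frame", clipNegative = "logical"))

setValidity("FitResult", function(object) {
  u <- length(object@units)
  if (ncol(object@weights) != u) return("one weight column per unit")
  if (length(object@lambda) != u) return("one penalty per unit")
  if (any(!is.finite(object@lambda)) || any(object@lambda < 0))
    return("penalties must be finite and nonnegative")
  if (nrow(object@predictions) != u) return("one prediction row per unit")
  TRUE
})

#' A complete synthetic session with ground truth
#'
#' @slot config the generating \linkS4class{SessionConfig}.
#' @slot trialTable the \linkS4class{TrialTable}.
#' @slot face,body \linkS4class{FrameStack} videos for the two camera views.
#' @slot eye \linkS4class{EyeTrace} on the bin grid.
#' @slot spikes \linkS4class{BinnedSpikes} over all session bins.
#' @slot bins session-wide bin grid (`time`, `trial`, `modeled`, `fixation`,
#'   `stimOn`).
#' @slot truth list with the generative ground truth: per-group true weights,
#'   baseline rates, true movement profiles, latents, noise-free rates,
#'   retinal-drive trace and confound gain.
#' @export
setClass("SyntheticSession",
         representation(config = "SessionConfig", trialTable = "TrialTable",
                        face = "FrameStack", body = "FrameStack",
                        eye = "EyeTrace", spikes = "BinnedSpikes",
                        bins = "data.frame", truth = "list"))
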