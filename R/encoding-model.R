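#' Trial-blocked crossvalidation fold plan
#'
#' Trials are randomly permuted and assigned round-robin to folds, so every
#' modeled trial lands in exactly one test fold. Because event kernels are
#' constructed at the level of individual trials, no kernel ever spans
#' samples from both the training and the test set.
#'
#' @param trials modeled trial ids.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @export
makeFoldPlan <- function(trials, nFolds = 10L, seed = 1L) {
  trials <- as.integer(unique(trials))
  perm <- .withSeed(seed, sample(trials))
  fold <- rep_len(seq_len(nFolds), length(perm))
  new("FoldPlan", trial = perm, fold = as.integer(fold),
      nFolds = as.integer(nFolds), seed = as.integer(seed))
}

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes `||y - Xw - b||^2 + lambda * ||w||^2` by the normal equations
#' (direct Cholesky solve; deterministic, no stochastic optimizer). At
#' `lambda = 0` on a full-rank problem this is ordinary least squares.
#'
#' @param X design block (finite values).
#' @param y response vector, or a matrix with one column per response.
#' @param lambda nonnegative penalty.
#' @param intercept include an unpenalized intercept (default `TRUE`).
#' @return list with `weights` (p x n_responses) and `intercept`.
#' @export
ridgeFit <- function(X, y, lambda, intercept = TRUE) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("numeric error: non-finite values in the inputs")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      !is.finite(lambda))
    stop("numeric error: lambda must be a single finite nonnegative number")
  y <- as.matrix(y)
  p <- ncol(X)
  if (intercept) {
    Xa <- cbind(X, 1)
    pen <- c(rep(lambda, p), 0)
  } else {
    Xa <- X
    pen <- rep(lambda, p)
  }
  G <- crossprod(Xa) + diag(pen, ncol(Xa))
  W <- solve(G, crossprod(Xa, y))
  if (intercept)
    list(weights = W[seq_len(p), , drop = FALSE],
         intercept = as.numeric(W[p + 1L, ]))
  else
    list(weights = W, intercept = rep(0, ncol(y)))
}

#' Crossvalidated percentage of variance explained
#'
#' `%VE = 100 * (1 - var(obs - pred) / var(obs))`, both variances computed
#' over the masked bins with their own means (population convention). Can be
#' negative; if the observations have zero variance within the mask the
#' result is `NA` with a warning (undefined, flagged rather than
#' fabricated).
#'
#' @param pred,obs aligned per-bin prediction and observation vectors.
#' @param mask optional logical or integer bin subset (default all bins).
#' @return a scalar %VE.
#' @export
percentVE <- function(pred, obs, mask = NULL) {
  if (length(pred) != length(obs))
    stop("pred and obs must be aligned")
  if (!is.null(mask)) {
    pred <- pred[mask]
    obs <- obs[mask]
  }
  if (!length(obs)) stop("mask selects no bins")
  v <- .popVar(obs)
  if (v < .Machine$double.eps) {
    warning("zero variance of the observations in the mask; %VE undefined")
    return(NA_real_)
  }
  100 * (1 - .popVar(obs - pred) / v)
}

# Internal fitting core on precomputed Gram pieces. Returns crossvalidated
# predictions plus full-data refit weights for a fixed per-unit lambda.
.cvCore <- function(Xa, Y, rowFold, plan, lambda, penMask) {
  n <- nrow(Xa); pAll <- ncol(Xa); U <- ncol(Y)
  G <- crossprod(Xa)
  TT <- crossprod(Xa, Y)
  pred <- matrix(NA_real_, n, U)
  iInt <- pAll                      # intercept is the last column
  for (f in seq_len(plan@nFolds)) {
    te <- which(rowFold == f)
    if (!length(te)) next
    Xte <- Xa[te, , drop = FALSE]
    Gte <- crossprod(Xte)
    Gtr <- G - Gte
    Ttr <- TT - crossprod(Xte, Y[te, , drop = FALSE])
    nTr <- Gtr[iInt, iInt]
    cs <- Gtr[, iInt]
    cvar <- diag(Gtr) / nTr - (cs / nTr)^2
    keep <- which(cvar > 1e-12 | seq_len(pAll) == iInt)
    if (length(keep) < pAll)
      warning(sprintf("fold %d: %d column(s) constant within the training trials were dropped for that fold",
                      f, pAll - length(keep)))
    for (lam in unique(lambda)) {
      us <- which(lambda == lam)
      A <- Gtr[keep, keep, drop = FALSE]
      diag(A) <- diag(A) + lam * penMask[keep]
      W <- solve(A, Ttr[keep, us, drop = FALSE])
      pred[te, us] <- Xte[, keep, drop = FALSE] %*% W
    }
  }
  Wfull <- matrix(0, pAll, U)
  for (lam in unique(lambda)) {
    us <- which(lambda == lam)
    A <- G
    diag(A) <- diag(A) + lam * penMask
    Wfull[, us] <- solve(A, TT[, us, drop = FALSE])
  }
  list(pred = pred, weights = Wfull)
}

# Per-unit penalty selection on an inner trial-blocked 80/20 split of the
# first fold's training trials; the winner is reused in all folds.
.selectLambdaInner <- function(Xa, Y, rowTrial, plan, grid, penMask) {
  trainTrials <- plan@trial[plan@fold != 1L]
  nVal <- max(1L, round(0.2 * length(trainTrials)))
  valTrials <- .withSeed(plan@seed + 1000L, sample(trainTrials, nVal))
  fitTrials <- setdiff(trainTrials, valTrials)
  rFit <- which(rowTrial %in% fitTrials)
  rVal <- which(rowTrial %in% valTrials)
  Xf <- Xa[rFit, , drop = FALSE]
  Xv <- Xa[rVal, , drop = FALSE]
  G <- crossprod(Xf)
  TT <- crossprod(Xf, Y[rFit, , drop = FALSE])
  Yv <- Y[rVal, , drop = FALSE]
  U <- ncol(Y)
  ve <- matrix(-Inf, length(grid), U)
  for (i in seq_along(grid)) {
    A <- G
    diag(A) <- diag(A) + grid[i] * penMask
    W <- solve(A, TT)
    P <- Xv %*% W
    for (u in seq_len(U)) {
      v <- .popVar(Yv[, u])
      if (v > 0) ve[i, u] <- 100 * (1 - .popVar(Yv[, u] - P[, u]) / v)
    }
  }
  grid[apply(ve, 2L, which.max)]
}

#' Per-unit ridge penalty selection
#'
#' Chooses the penalty maximizing held-out %VE on an inner trial-blocked
#' 80/20 split of the supplied training data. The grid defaults to 17
#' logarithmically spaced values spanning under- to over-regularized
#' regimes on the z-scored design scale.
#'
#' @param X training design block (z-scored columns).
#' @param y training response (one unit).
#' @param grid candidate penalties (nonempty, nonnegative).
#' @param trial trial id per row of `X` (blocks of the inner split).
#' @param seed integer seed for the split.
#' @return the selected penalty.
#' @export
selectPenalty <- function(X, y, grid = 10^seq(-2, 6, length.out = 17),
                          trial = seq_len(nrow(X)), seed = 1L) {
  if (!length(grid)) stop("configuration error: empty penalty grid")
  if (any(grid < 0)) stop("configuration error: penalties must be nonnegative")
  if (length(grid) == 1L) return(grid)
  trials <- unique(trial)
  nVal <- max(1L, round(0.2 * length(trials)))
  valTrials <- .withSeed(seed, sample(trials, nVal))
  rVal <- trial %in% valTrials
  ve <- vapply(grid, function(lam) {
    fit <- ridgeFit(X[!rVal, , drop = FALSE], y[!rVal], lam)
    p <- X[rVal, , drop = FALSE] %*% fit$weights + fit$intercept
    percentVE(p, y[rVal])
  }, numeric(1))
  grid[which.max(ve)]
}

#' Fit the encoding model with trial-blocked tenfold crossvalidation
#'
#' For every unit: select the ridge penalty during the first
#' crossvalidation fold (inner 80/20 trial split of its training data),
#' then, for each fold, fit on the training trials and predict the test
#' trials, assembling a full-session crossvalidated prediction; finally
#' refit on all modeled trials for the reported weights. Columns flagged as
#' all-constant at assembly are excluded; a column constant within one
#' fold's training trials is dropped for that fold with a warning. The
#' intercept is unpenalized.
#'
#' @param design a [DesignMatrix-class].
#' @param spikes a [BinnedSpikes-class] covering the session bin grid.
#' @param plan a [FoldPlan-class] covering all modeled trials.
#' @param lambdaGrid candidate penalties (used when `lambda` is `NULL`).
#' @param lambda optional per-unit penalties to reuse (skips selection);
#'   recycled across units.
#' @param clipNegative clip crossvalidated predictions at zero before %VE
#'   (default `FALSE`: the model is purely linear).
#' @return a [FitResult-class].
#' @export
crossvalFitPredict <- function(design, spikes, plan,
                               lambdaGrid = 10^seq(-2, 6, length.out = 17),
                               lambda = NULL, clipNegative = FALSE) {
  bi <- design@bins
  cnt <- spikeCounts(spikes)
  Y <- t(cnt[, bi$binIndex, drop = FALSE]) * 1.0
  U <- ncol(Y)
  if (!setequal(unique(bi$trial), plan@trial))
    stop("fold plan must cover exactly the modeled trials")
  act <- which(!design@zeroVar)
  Xa <- cbind(design@X[, act, drop = FALSE], 1)
  penMask <- c(rep(1, length(act)), 0)
  rowFold <- plan@fold[match(bi$trial, plan@trial)]

  if (is.null(lambda)) {
    if (!length(lambdaGrid))
      stop("configuration error: empty penalty grid")
    lambda <- .selectLambdaInner(Xa, Y, bi$trial, plan, sort(lambdaGrid),
                                 penMask)
  } else {
    lambda <- rep_len(lambda, U)
  }

  core <- .cvCore(Xa, Y, rowFold, plan, lambda, penMask)
  pred <- core$pred
  if (clipNegative) pred <- pmax(pred, 0)

  ve <- vapply(seq_len(U), function(u) percentVE(pred[, u], Y[, u]),
               numeric(1))
  p <- ncol(design@X)
  W <- matrix(0, p, U)
  W[act, ] <- core$weights[seq_along(act), , drop = FALSE]
  units <- rownames(cnt)
  if (is.null(units)) units <- sprintf("u%03d", seq_len(U))
  new("FitResult", weights = W,
      intercept = as.numeric(core$weights[length(act) + 1L, ]),
      lambda = as.numeric(lambda), lambdaGrid = as.numeric(lambdaGrid),
      predictions = t(pred), ve = ve, plan = plan, units = units,
      columnMeta = design@columnMeta, clipNegative = clipNegative)
}

#' Spike density function of binned counts
#'
#' Peristimulus time histogram averaged over trials and convolved with a
#' causal half-Gaussian kernel (support at and after the spike, s.d. 16 ms
#' by default, normalized to integrate to 1), returning a rate trace in
#' spikes/s.
#'
#' @param trialCounts matrix `n_trials x n_bins` of aligned per-trial counts
#'   (a vector is one trial).
#' @param binWidth seconds.
#' @param sd kernel standard deviation in seconds (default 0.016).
#' @return numeric rate trace (spikes/s), one value per aligned bin.
#' @export
spikeDensityFunction <- function(trialCounts, binWidth, sd = 0.016) {
  if (sd <= 0) stop("configuration error: sd must be positive")
  if (is.null(dim(trialCounts))) trialCounts <- matrix(trialCounts, nrow = 1L)
  psth <- colMeans(trialCounts) / binWidth
  k <- .halfGaussianKernel(sd, binWidth)
  .causalSmooth(psth, k, binWidth)
}

#' SDF-level model validation
#'
#' Aligns observed counts and crossvalidated predictions to stimulus onset,
#' averages over trials, smooths both with the causal half-Gaussian
#' (s.d. 16 ms) and computes the %VE between the two spike density
#' functions per unit. This trial-averaged comparison suppresses the
#' single-bin spike-count variability that dominates bin-level %VE.
#'
#' @param design the [DesignMatrix-class] the fit was computed on.
#' @param spikes the [BinnedSpikes-class].
#' @param fit the [FitResult-class].
#' @param sd smoothing s.d. in seconds.
#' @return list with per-unit `ve` (named vector), the aligned `sdfObs` and
#'   `sdfPred` matrices (units x aligned bins) and the aligned `time` axis.
#' @export
sdfAndVE <- function(design, spikes, fit, sd = 0.016) {
  bi <- design@bins
  ord <- order(bi$trial, bi$time)
  byTrial <- split(ord, bi$trial[ord])
  if (length(byTrial) < 1L) stop("alignment error: no trials")
  L <- min(lengths(byTrial))
  idx <- matrix(unlist(lapply(byTrial, function(r) r[seq_len(L)])),
                ncol = L, byrow = TRUE)
  cnt <- spikeCounts(spikes)[, bi$binIndex, drop = FALSE]
  pred <- fit@predictions
  U <- nrow(cnt)
  sdfO <- matrix(0, U, L)
  sdfP <- matrix(0, U, L)
  ve <- numeric(U)
  for (u in seq_len(U)) {
    oc <- matrix(cnt[u, idx], nrow(idx), L)
    pc <- matrix(pred[u, idx], nrow(idx), L)
    sdfO[u, ] <- spikeDensityFunction(oc, design@binWidth, sd)
    sdfP[u, ] <- spikeDensityFunction(pc, design@binWidth, sd)
    ve[u] <- percentVE(sdfP[u, ], sdfO[u, ])
  }
  list(ve = setNames(ve, fit@units), sdfObs = sdfO, sdfPred = sdfP,
       time = (seq_len(L) - 1L) * design@binWidth)
}

#' Unit inclusion filters
#'
#' Model-based inclusion keeps units with (1) a mean firing rate of at
#' least `minRate` spikes/s during stimulus presentation epochs in each of
#' the four session quartiles and (2) a full-model %VE of at least 0 during
#' both retinal-input-controlled and -uncontrolled epochs. Model-free
#' analyses apply only the first criterion.
#'
#' @param spikes a [BinnedSpikes-class].
#' @param design the modeled [DesignMatrix-class] (for bin lookup).
#' @param fit optional [FitResult-class]; when `NULL` only the rate
#'   criterion is applied.
#' @param epochMask optional per-modeled-bin epoch factor from
#'   [buildEpochMask()] (required with `fit`).
#' @param minRate spikes/s threshold (default 2).
#' @return data.frame per unit: quartile rates, epoch %VE and the
#'   `included` flag.
#' @export
filterUnits <- function(spikes, design, fit = NULL, epochMask = NULL,
                        minRate = 2) {
  bi <- binInfo(spikes)
  cnt <- spikeCounts(spikes)
  stimBins <- which(bi$stimOn)
  qcut <- cut(bi$time[stimBins],
              breaks = quantile(bi$time, probs = seq(0, 1, 0.25)),
              include.lowest = TRUE, labels = FALSE)
  bw <- spikes@binWidth
  rates <- vapply(1:4, function(q) {
    b <- stimBins[qcut == q]
    if (!length(b)) return(rep(0, nrow(cnt)))
    rowSums(cnt[, b, drop = FALSE]) / (length(b) * bw)
  }, numeric(nrow(cnt)))
  out <- data.frame(unit = rownames(cnt),
                    q1 = rates[, 1], q2 = rates[, 2],
                    q3 = rates[, 3], q4 = rates[, 4])
  out$rateOK <- apply(rates >= minRate, 1L, all)
  out$included <- out$rateOK
  if (!is.null(fit)) {
    if (is.null(epochMask))
      stop("the model criterion needs an epoch mask")
    obs <- t(spikeCounts(spikes)[, design@bins$binIndex, drop = FALSE])
    ctrl <- epochMask == "controlled"
    unctrl <- epochMask %in% c("uncontrolled", "uncontrolled_inferable",
                               "uncontrolled_other")
    out$veControlled <- vapply(seq_len(nrow(cnt)), function(u)
      percentVE(fit@predictions[u, ], obs[, u], ctrl), numeric(1))
    out$veUncontrolled <- vapply(seq_len(nrow(cnt)), function(u)
      percentVE(fit@predictions[u, ], obs[, u], unctrl), numeric(1))
    out$included <- out$rateOK & out$veControlled >= 0 & out$veUncontrolled >= 0
  }
  out
}

#' Kernel recovery against synthetic ground truth
#'
#' For each unit and regressor group, correlates the fitted model's
#' noise-free group contribution (`X_group %*% w_group` over modeled bins)
#' with the generative ground-truth contribution stored in the session.
#' Comparing contributions rather than raw weights makes the check
#' invariant to the basis of the movement regressors and to the exact
#' split of shared response components between collinear groups; the
#' stimulus group is therefore evaluated jointly with the time group, whose
#' columns span the trial-locked response it shares.
#'
#' @param fit a [FitResult-class].
#' @param design the fitted [DesignMatrix-class].
#' @param session the generating [SyntheticSession-class].
#' @param groups groups to evaluate (default stimulus, drift, face).
#' @return data.frame: unit x group correlation, plus a `total` column
#'   correlating the full noise-free prediction with the true rate.
#' @export
kernelRecovery <- function(fit, design, session,
                           groups = c("stimulus", "drift", "face")) {
  truth <- session@truth
  rows <- design@bins$binIndex
  grp <- design@columnMeta$group
  U <- length(fit@units)
  out <- data.frame(unit = fit@units)
  for (g in groups) {
    cols <- if (g == "stimulus") grp %in% c("stimulus", "time") else grp == g
    contribFit <- design@X[, cols, drop = FALSE] %*%
      fit@weights[cols, , drop = FALSE]
    contribTrue <- truth$contrib[[g]][rows, , drop = FALSE]
    out[[g]] <- vapply(seq_len(U), function(u) {
      if (.popVar(contribTrue[, u]) < 1e-12) return(NA_real_)
      cor(contribFit[, u], contribTrue[, u])
    }, numeric(1))
  }
  predFull <- t(fit@predictions)
  trueRate <- t(truth$rates)[rows, , drop = FALSE]
  out$total <- vapply(seq_len(U), function(u)
    cor(predFull[, u], trueRate[, u]), numeric(1))
  out
}
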