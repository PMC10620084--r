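#' Paired two-sided permutation test
#'
#' Tests whether the mean of `x - y` differs from zero without assuming
#' normality: on each permutation every pair's condition labels are flipped
#' independently with probability 1/2, and the p value is the fraction of
#' permutations whose absolute mean difference is at least the observed
#' absolute mean difference. Both the plain fraction and the add-one
#' convention `(b + 1) / (nPerm + 1)` (which avoids p = 0) are reported;
#' the add-one value is the one to use for decisions.
#'
#' @param x,y paired value vectors of equal length (>= 2).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed (recorded in the result).
#' @return list with `observed` (mean difference), `pValue` (plain
#'   fraction), `pValueAddOne`, `nPerm`, `seed` and `sidedness`.
#' @export
pairedPermutationTest <- function(x, y, nPerm = 10000L, seed = 1L) {
  if (length(x) != length(y))
    stop("input error: x and y must be paired vectors of equal length")
  if (length(x) < 2L) stop("input error: need at least 2 pairs")
  if (nPerm < 1L) stop("input error: nPerm must be >= 1")
  d <- x - y
  obs <- mean(d)
  exceed <- .withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), nPerm * length(d), replace = TRUE),
                    nrow = nPerm)
    permMeans <- as.numeric(signs %*% d) / length(d)
    sum(abs(permMeans) >= abs(obs) - 1e-15)
  })
  list(observed = obs,
       pValue = exceed / nPerm,
       pValueAddOne = (exceed + 1) / (nPerm + 1),
       nPerm = as.integer(nPerm), seed = as.integer(seed),
       sidedness = "two-sided")
}

#' Compare two index distributions (plumbing)
#'
#' Routine comparison of, for example, attention-index versus
#' movement-index distributions: Student's t-tests per area with
#' multiplicity correction (Bonferroni by default) and the correlation
#' between the paired indices per area. Delegated to stock routines; the
#' substance lives in how the indices were computed.
#'
#' @param a,b paired index vectors (NAs dropped pairwise).
#' @param area optional per-unit area labels.
#' @param method multiplicity correction passed to [stats::p.adjust()].
#' @return data.frame per area: n, `meanA`, `meanB`, t-test p (adjusted),
#'   correlation and its p value.
#' @export
compareDistributions <- function(a, b, area = NULL, method = "bonferroni") {
  if (is.null(area)) area <- rep("all", length(a))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]; area <- area[keep]
  sp <- split(seq_along(a), area)
  res <- do.call(rbind, lapply(names(sp), function(ar) {
    i <- sp[[ar]]
    tt <- t.test(a[i], b[i], paired = TRUE)
    ct <- suppressWarnings(cor.test(a[i], b[i]))
    data.frame(area = ar, n = length(i),
               meanA = mean(a[i]), meanB = mean(b[i]),
               tP = tt$p.value, cor = unname(ct$estimate),
               corP = ct$p.value)
  }))
  res$tPAdjusted <- p.adjust(res$tP, method = method)
  res
}
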