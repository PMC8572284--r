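#' Estimate person abilities by weighted likelihood
#'
#' Warm-type weighted (bias-corrected) likelihood estimates of each
#' person's latent ability given a fixed item calibration, with standard
#' errors from the test information. Persons with extreme raw scores
#' (zero, or the maximum over their answered items) have no finite
#' maximum-likelihood ability; they receive the ability whose expected
#' total score equals the raw score adjusted inward by
#' \code{adjustment}, and are flagged.
#'
#' @param data a [ResponseMatrix-class].
#' @param items an [ItemParameters-class] covering the data's items.
#' @param adjustment score adjustment for extreme raw scores (default 0.3).
#' @param tol score-equation tolerance (default 1e-8).
#' @return a [PersonEstimates-class].
#' @export
estimatePersons <- function(data, items, adjustment = 0.3, tol = 1e-8) {
  x <- data@responses
  idx <- match(colnames(x), items@itemIds)
  if (anyNA(idx))
    stop("calibration lacks item(s): ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  if (any(rowSums(!is.na(x)) == 0L))
    stop("person(s) with all items missing: ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0L], collapse = ", "))
  est <- pcmEstimateAbility(x, items@thresholds[idx], adjustment, tol)
  new("PersonEstimates",
      personIds = rownames(x),
      theta = est$theta,
      se = est$se,
      extreme = est$extreme,
      rawScore = est$raw,
      nObserved = as.integer(rowSums(!is.na(x))))
}

# Core ability estimation on a raw response matrix (columns aligned with
# thr); also used for subset estimates where a subset may hold one item.
pcmEstimateAbility <- function(x, thr, adjustment = 0.3, tol = 1e-8) {
  mVec <- lengths(thr)
  raw <- rowSums(x, na.rm = TRUE)
  maxRaw <- drop((!is.na(x)) %*% mVec)
  extreme <- raw == 0 | raw == maxRaw
  target <- raw
  target[raw == 0] <- adjustment
  perfect <- raw == maxRaw & raw > 0
  target[perfect] <- maxRaw[perfect] - adjustment
  thetaHat <- pcmSolveAbility(x, thr, target, warm = !extreme, tol = tol)
  info <- pcmTestInfo(x, thr, thetaHat)
  list(theta = thetaHat, se = 1 / sqrt(pmax(info, 1e-12)),
       extreme = extreme, raw = as.numeric(raw))
}

# Vectorized Newton solve of the (optionally Warm-corrected) score
# equation target - sum E_i(theta) + warm * sum M3 / (2 sum V) = 0.
pcmSolveAbility <- function(x, thr, target, warm, tol = 1e-8,
                            maxit = 200L, bound = 15) {
  n <- nrow(x)
  theta <- numeric(n)
  active <- rep(TRUE, n)
  for (it in seq_len(maxit)) {
    E <- V <- M3 <- numeric(n)
    idxA <- which(active)
    th <- theta[idxA]
    for (i in seq_along(thr)) {
      obs <- !is.na(x[idxA, i])
      if (!any(obs)) next
      mom <- pcmMoments(th[obs], thr[[i]])
      w <- which(obs)
      E[idxA[w]] <- E[idxA[w]] + mom$E
      V[idxA[w]] <- V[idxA[w]] + mom$V
      M3[idxA[w]] <- M3[idxA[w]] + mom$M3
    }
    f <- target[idxA] - E[idxA] +
      ifelse(warm[idxA], M3[idxA] / (2 * pmax(V[idxA], 1e-12)), 0)
    step <- f / pmax(V[idxA], 1e-6)
    step <- pmin(pmax(step, -2), 2)
    theta[idxA] <- pmin(pmax(theta[idxA] + step, -bound), bound)
    done <- abs(f) < tol | (abs(theta[idxA]) >= bound & abs(step) >= 1e-6)
    active[idxA[done]] <- FALSE
    if (!any(active)) break
  }
  theta
}

# Test information (sum of conditional score variances over answered
# items) at the given abilities.
pcmTestInfo <- function(x, thr, theta) {
  V <- numeric(length(theta))
  for (i in seq_along(thr)) {
    obs <- which(!is.na(x[, i]))
    if (!length(obs)) next
    V[obs] <- V[obs] + scoreVariance(theta[obs], thr[[i]])
  }
  V
}
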