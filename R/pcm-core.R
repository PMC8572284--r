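#' Partial credit model category probabilities
#'
#' Probability of each response category 0..m for a person at ability
#' \code{theta} on an item with thresholds \code{delta}:
#' \deqn{P(X = x \mid \theta) = \frac{\exp \sum_{k \le x} (\theta - \delta_k)}
#'   {\sum_{h=0}^{m} \exp \sum_{k \le h} (\theta - \delta_k)}}
#' with the empty sum for x = 0 equal to zero. An optional discrimination
#' multiplies the exponent (the generalized PCM used by the synthetic
#' generator); the Rasch case is \code{a = 1}.
#'
#' @param theta numeric vector of abilities (logits).
#' @param delta numeric vector of m thresholds (logits).
#' @param a discrimination (scalar, default 1).
#' @return matrix \code{length(theta) x (m + 1)} of probabilities; rows sum
#'   to 1.
#' @examples
#' categoryProbs(0, c(-1, 1))      # (1, e, 1) / (2 + e)
#' @export
categoryProbs <- function(theta, delta, a = 1) {
  stopifnot(all(is.finite(delta)), length(delta) >= 1L)
  m <- length(delta)
  cumd <- c(0, cumsum(delta))
  eta <- a * (outer(theta, 0:m) -
                matrix(cumd, length(theta), m + 1L, byrow = TRUE))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

# First four conditional moments of the category score, vectorized over
# theta. Returns list(E, V, M3, M4); M3/M4 are central moments.
pcmMoments <- function(theta, delta, a = 1) {
  p <- categoryProbs(theta, delta, a)
  x <- 0:length(delta)
  E <- drop(p %*% x)
  d <- outer(rep(1, length(theta)), x) - E
  V <- rowSums(p * d^2)
  M3 <- rowSums(p * d^3)
  M4 <- rowSums(p * d^4)
  list(E = E, V = V, M3 = M3, M4 = M4)
}

#' Expected item score under the partial credit model
#'
#' \eqn{E[X \mid \theta] = \sum_x x P(X = x \mid \theta)}; strictly
#' increasing in \code{theta}.
#'
#' @inheritParams categoryProbs
#' @return numeric vector of expected scores in \code{[0, m]}.
#' @export
expectedScore <- function(theta, delta, a = 1) {
  pcmMoments(theta, delta, a)$E
}

#' Conditional score variance under the partial credit model
#'
#' \eqn{Var[X \mid \theta] = E[X^2] - E[X]^2}; for the PCM this equals the
#' derivative of the expected score with respect to theta (the item
#' information for the raw score).
#'
#' @inheritParams categoryProbs
#' @return numeric vector of variances (>= 0).
#' @export
scoreVariance <- function(theta, delta, a = 1) {
  pcmMoments(theta, delta, a)$V
}

#' Test characteristic curve
#'
#' Sum of expected item scores at each ability, the monotone map inverted
#' by [buildConversionTable()].
#'
#' @param theta numeric vector of abilities.
#' @param items an [ItemParameters-class].
#' @return numeric vector of expected total scores.
#' @export
testCharacteristicCurve <- function(theta, items) {
  tot <- numeric(length(theta))
  for (d in items@thresholds) tot <- tot + expectedScore(theta, d)
  tot
}

#' Category probability curve data
#'
#' Long-format category characteristic curves for plotting or export:
#' P(X = x | theta) for every item and category over a theta grid. These
#' are the curves inspected for disordered thresholds (a category that is
#' nowhere modal signals disorder).
#'
#' @param items an [ItemParameters-class].
#' @param thetaGrid numeric grid (default 121 points spanning the
#'   thresholds plus 2 logits).
#' @return data frame with columns item, category, theta, probability.
#' @export
categoryCurves <- function(items, thetaGrid = NULL) {
  if (is.null(thetaGrid)) {
    rng <- range(unlist(items@thresholds))
    thetaGrid <- seq(rng[1L] - 2, rng[2L] + 2, length.out = 121L)
  }
  out <- vector("list", length(items@itemIds))
  for (i in seq_along(items@itemIds)) {
    p <- categoryProbs(thetaGrid, items@thresholds[[i]])
    m <- ncol(p) - 1L
    out[[i]] <- data.frame(
      item = items@itemIds[i],
      category = rep(0:m, each = length(thetaGrid)),
      theta = rep(thetaGrid, m + 1L),
      probability = as.vector(p))
  }
  do.call(rbind, out)
}

#' Construct item parameters by hand
#'
#' For simulation truths, anchored subsets and imported calibrations.
#'
#' @param thresholds named list of numeric threshold vectors.
#' @param seThresholds optional list of standard errors.
#' @param latentMean,latentSD latent distribution parameters.
#' @return an [ItemParameters-class].
#' @export
itemParameters <- function(thresholds, seThresholds = list(),
                           latentMean = 0, latentSD = 1) {
  ids <- names(thresholds)
  if (is.null(ids)) ids <- sprintf("item%02d", seq_along(thresholds))
  names(thresholds) <- ids
  new("ItemParameters",
      itemIds = ids,
      thresholds = lapply(thresholds, as.numeric),
      seThresholds = seThresholds,
      locations = vapply(thresholds, mean, numeric(1)),
      seLocations = rep(NA_real_, length(ids)),
      latentMean = latentMean, latentSD = latentSD)
}

#' Subset item parameters
#'
#' Extracts an anchored sub-calibration (thresholds unchanged), e.g. for
#' the subset ability estimates of the unidimensionality t-test.
#'
#' @param items an [ItemParameters-class].
#' @param ids item ids to keep.
#' @return an [ItemParameters-class].
#' @export
subsetItems <- function(items, ids) {
  idx <- match(ids, items@itemIds)
  if (anyNA(idx)) stop("unknown item id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  new("ItemParameters",
      itemIds = items@itemIds[idx],
      thresholds = items@thresholds[idx],
      seThresholds = if (length(items@seThresholds))
        items@seThresholds[idx] else list(),
      paramCov = if (length(items@paramCov)) {
        keep <- rep(items@itemIds, lengths(items@thresholds)) %in% ids
        items@paramCov[keep, keep, drop = FALSE]
      } else matrix(numeric(), 0L, 0L),
      locations = items@locations[idx],
      seLocations = items@seLocations[idx],
      latentMean = items@latentMean, latentSD = items@latentSD,
      logLik = NA_real_, converged = items@converged,
      iterations = items@iterations)
}

#' Export / import item parameters as CSV
#'
#' Freezes a calibration as a plain-text table (item id, threshold index,
#' estimate, SE) so it can be re-used, e.g. to build conversion tables
#' without re-estimation.
#'
#' @param items an [ItemParameters-class].
#' @param path CSV file path.
#' @return \code{path} (export) or an [ItemParameters-class] (import).
#' @export
exportItemParameters <- function(items, path) {
  rows <- do.call(rbind, lapply(seq_along(items@itemIds), function(i) {
    d <- items@thresholds[[i]]
    se <- if (length(items@seThresholds))
      items@seThresholds[[i]] else rep(NA_real_, length(d))
    data.frame(item = items@itemIds[i], index = seq_along(d),
               estimate = d, se = se)
  }))
  meta <- data.frame(item = "<latent>", index = 1:2,
                     estimate = c(items@latentMean, items@latentSD),
                     se = NA_real_)
  write.csv(rbind(rows, meta), path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportItemParameters
#' @export
importItemParameters <- function(path) {
  df <- read.csv(path)
  latent <- df[df$item == "<latent>", ]
  df <- df[df$item != "<latent>", ]
  ids <- unique(df$item)
  thr <- lapply(ids, function(id) {
    sub <- df[df$item == id, ]
    sub$estimate[order(sub$index)]
  })
  se <- lapply(ids, function(id) {
    sub <- df[df$item == id, ]
    sub$se[order(sub$index)]
  })
  names(thr) <- names(se) <- ids
  itemParameters(thr, se,
                 latentMean = if (nrow(latent)) latent$estimate[1L] else 0,
                 latentSD = if (nrow(latent) > 1L) latent$estimate[2L] else 1)
}

# Gauss-Hermite quadrature for a N(0, sd^2) latent density:
# returns nodes and normalized weights.
ghQuadrature <- function(n, sd = 1) {
  gh <- pracma::gaussHermite(n)
  list(nodes = sqrt(2) * sd * gh$x, weights = gh$w / sqrt(pi))
}
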