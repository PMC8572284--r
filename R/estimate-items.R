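#' Calibrate partial credit model items by marginal maximum likelihood
#'
#' Estimates the category thresholds of every item (and the latent normal
#' distribution) by an EM algorithm with fixed-node Gauss-Hermite
#' quadrature. Identification: item locations sum to zero and the latent
#' mean is free. Standard errors come from the empirical (cross-product)
#' observed information of the marginal likelihood; persons with extreme
#' (zero or perfect) raw scores contribute to the likelihood but are
#' excluded from the information matrix.
#'
#' Missing responses contribute nothing to the likelihood (missingness is
#' assumed ignorable). Thresholds of rarely or never observed categories
#' are kept finite by a weak ridge penalty and a hard clamp; both affect
#' well-populated categories negligibly and are reported in the returned
#' object's metadata.
#'
#' @param data a [ResponseMatrix-class] with at least 2 items, each
#'   observed in at least 2 distinct categories.
#' @param nQuad number of Gauss-Hermite nodes (default 41).
#' @param maxit maximum EM iterations (default 500).
#' @param reltol relative log-likelihood convergence tolerance
#'   (default 1e-8).
#' @param ridge quadratic penalty weight on thresholds, stabilizing
#'   sparsely observed categories (default 0.01).
#' @param clamp hard bound on |threshold| in logits (default 8).
#' @param onNonconvergence \code{"error"} (default) aborts with
#'   diagnostics when \code{maxit} is reached; \code{"warn"} returns the
#'   last iterate flagged unconverged.
#' @return an [ItemParameters-class].
#' @examples
#' cfg <- simulationConfig(nPersons = 150, nItems = 5, seed = 42)
#' sim <- simulateResponses(cfg)
#' fit <- estimateItems(sim$data)
#' itemLocations(fit)
#' @export
estimateItems <- function(data, nQuad = 41L, maxit = 500L, reltol = 1e-8,
                          ridge = 0.01, clamp = 8,
                          onNonconvergence = c("error", "warn")) {
  onNonconvergence <- match.arg(onNonconvergence)
  x <- data@responses
  allMiss <- rowSums(!is.na(x)) == 0L
  if (any(allMiss)) {
    warning(sum(allMiss), " person(s) with no responses dropped")
    x <- x[!allMiss, , drop = FALSE]
  }
  n <- nrow(x)
  I <- ncol(x)
  if (I < 2L) stop("at least 2 items are required")
  mVec <- data@spec@maxCategory
  for (i in seq_len(I)) {
    obs <- unique(x[!is.na(x[, i]), i])
    if (length(obs) < 2L)
      stop("item '", colnames(x)[i],
           "' has observations in fewer than 2 categories")
  }

  # smoothed log-odds of adjacent category counts as starting values
  delta <- vector("list", I)
  for (i in seq_len(I)) {
    cnt <- tabulate(x[, i] + 1L, nbins = mVec[i] + 1L)
    delta[[i]] <- log((cnt[-length(cnt)] + 0.5) / (cnt[-1L] + 0.5))
  }
  sigma <- 1
  gh <- pracma::gaussHermite(nQuad)
  baseNodes <- sqrt(2) * gh$x
  logw <- log(gh$w) - 0.5 * log(pi)

  oneHot <- lapply(seq_len(I), function(i) {
    h <- matrix(0, n, mVec[i] + 1L)
    obs <- which(!is.na(x[, i]))
    h[cbind(obs, x[obs, i] + 1L)] <- 1
    h
  })

  llOld <- -Inf
  converged <- FALSE
  iter <- 0L
  post <- NULL
  nodes <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    nodes <- sigma * baseNodes
    # E step
    L <- matrix(rep(logw, each = n), n, nQuad)
    probList <- vector("list", I)
    for (i in seq_len(I)) {
      p <- categoryProbs(nodes, delta[[i]])
      probList[[i]] <- p
      tlp <- t(log(p))
      obs <- which(!is.na(x[, i]))
      L[obs, ] <- L[obs, ] + tlp[x[obs, i] + 1L, , drop = FALSE]
    }
    rowMax <- apply(L, 1L, max)
    post <- exp(L - rowMax)
    marg <- rowSums(post)
    ll <- sum(log(marg) + rowMax) -
      ridge * sum(unlist(delta)^2)
    post <- post / marg
    # M step: thresholds per item
    for (i in seq_len(I)) {
      r <- crossprod(oneHot[[i]], post)        # (m+1) x Q expected counts
      delta[[i]] <- pcmThresholdNewton(delta[[i]], r, nodes, ridge, clamp)
    }
    # M step: latent SD (mean fixed at 0 during estimation)
    sigma <- sqrt(sum(post %*% nodes^2) / n)
    sigma <- min(max(sigma, 0.05), 10)
    if (is.finite(llOld) &&
        abs(ll - llOld) < reltol * (abs(llOld) + reltol)) {
      converged <- TRUE
      llOld <- ll
      break
    }
    llOld <- ll
  }
  if (!converged) {
    msg <- sprintf(
      "EM did not converge in %d iterations (last logLik %.6f, sigma %.4f)",
      maxit, llOld, sigma)
    if (onNonconvergence == "error") stop(msg) else warning(msg)
  }

  # standard errors from the empirical cross-product information
  rawScore <- rowSums(x, na.rm = TRUE)
  maxScore <- (!is.na(x)) %*% mVec
  extreme <- rawScore == 0 | rawScore == maxScore
  se <- pcmItemSE(x, delta, post, nodes, exclude = extreme)

  # recenter to sum-to-zero item locations; latent mean absorbs the shift
  loc <- vapply(delta, mean, numeric(1))
  shift <- mean(loc)
  delta <- lapply(delta, function(d) d - shift)
  ids <- colnames(x)
  names(delta) <- ids
  names(se$seThr) <- ids
  new("ItemParameters",
      itemIds = ids,
      thresholds = delta,
      seThresholds = se$seThr,
      paramCov = se$covAll,
      locations = vapply(delta, mean, numeric(1)),
      seLocations = se$seLoc,
      latentMean = -shift,
      latentSD = sigma,
      logLik = llOld,
      converged = converged,
      iterations = iter)
}

# Penalized Newton update for one item's thresholds given expected
# category counts r ((m+1) x Q) at quadrature nodes.
pcmThresholdNewton <- function(delta, r, nodes, ridge, clamp,
                               innerIter = 3L) {
  m <- length(delta)
  nq <- colSums(r)
  Rgeq <- apply(r, 2L, function(col) rev(cumsum(rev(col))))[-1L, ,
                                                            drop = FALSE]
  obj <- function(d) {
    p <- categoryProbs(nodes, d)
    sum(r * t(log(pmax(p, 1e-300)))) - ridge * sum(d^2)
  }
  fOld <- obj(delta)
  for (it in seq_len(innerIter)) {
    p <- categoryProbs(nodes, delta)
    Pgeq <- vapply(seq_len(m), function(k)
      rowSums(p[, (k + 1L):(m + 1L), drop = FALSE]), numeric(length(nodes)))
    grad <- colSums(nq * Pgeq) - rowSums(Rgeq) - 2 * ridge * delta
    H <- matrix(0, m, m)
    for (k in seq_len(m)) for (l in k:m) {
      v <- -sum(nq * (Pgeq[, max(k, l)] - Pgeq[, k] * Pgeq[, l]))
      H[k, l] <- v
      H[l, k] <- v
    }
    diag(H) <- diag(H) - 2 * ridge - 1e-10
    step <- tryCatch(solve(H, grad), error = function(e) grad / diag(H))
    fac <- 1
    repeat {
      cand <- pmin(pmax(delta - fac * step, -clamp), clamp)
      fNew <- obj(cand)
      if (fNew >= fOld - 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    if (fNew < fOld) break
    delta <- cand
    if (fNew - fOld < 1e-10) { fOld <- fNew; break }
    fOld <- fNew
  }
  delta
}

# Empirical information SEs for thresholds (latent parameters treated as
# fixed). Returns per-item SE vectors and location SEs.
pcmItemSE <- function(x, delta, post, nodes, exclude) {
  n <- nrow(x)
  I <- ncol(x)
  mVec <- lengths(delta)
  P <- sum(mVec)
  G <- matrix(0, n, P)
  off <- 0L
  for (i in seq_len(I)) {
    m <- mVec[i]
    p <- categoryProbs(nodes, delta[[i]])
    Pgeq <- vapply(seq_len(m), function(k)
      rowSums(p[, (k + 1L):(m + 1L), drop = FALSE]), numeric(length(nodes)))
    obs <- which(!is.na(x[, i]))
    expGeq <- post[obs, , drop = FALSE] %*% Pgeq
    obsGeq <- outer(x[obs, i], seq_len(m), `>=`)
    G[obs, off + seq_len(m)] <- expGeq - obsGeq
    off <- off + m
  }
  keep <- !exclude
  J <- crossprod(G[keep, , drop = FALSE])
  cov <- tryCatch(solve(J + diag(1e-8, P)),
                  error = function(e) matrix(NA_real_, P, P))
  seAll <- sqrt(pmax(diag(cov), 0))
  seThr <- vector("list", I)
  seLoc <- numeric(I)
  off <- 0L
  for (i in seq_len(I)) {
    idx <- off + seq_len(mVec[i])
    seThr[[i]] <- seAll[idx]
    block <- cov[idx, idx, drop = FALSE]
    seLoc[i] <- sqrt(max(sum(block), 0)) / mVec[i]
    off <- off + mVec[i]
  }
  dimnames(cov) <- list(
    paste(rep(colnames(x), mVec), unlist(lapply(mVec, seq_len)), sep = "."),
    paste(rep(colnames(x), mVec), unlist(lapply(mVec, seq_len)), sep = "."))
  list(seThr = seThr, seLoc = seLoc, covAll = cov)
}
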