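# Independent brute-force maximizer of the PCM marginal likelihood,
# used as an oracle against estimateItems. Deliberately shares no code
# with the package internals: trapezoid quadrature over a fixed theta
# grid and cyclic coordinate descent over successively refined grids.

oracleMarginalLogLik <- function(x, thrList, sigma,
                                 grid = seq(-6, 6, by = 0.05)) {
  n <- nrow(x)
  prior <- exp(-0.5 * (grid / sigma)^2) / sigma
  prior <- prior / sum(prior)
  L <- matrix(0, n, length(grid))
  for (i in seq_along(thrList)) {
    d <- thrList[[i]]
    m <- length(d)
    eta <- outer(grid, 0:m) -
      matrix(c(0, cumsum(d)), length(grid), m + 1L, byrow = TRUE)
    p <- exp(eta - apply(eta, 1, max))
    p <- p / rowSums(p)
    obs <- which(!is.na(x[, i]))
    L[obs, ] <- L[obs, ] + t(log(p))[x[obs, i] + 1L, , drop = FALSE]
  }
  rowMax <- apply(L, 1, max)
  sum(log(colSums(t(exp(L - rowMax)) * prior)) + rowMax)
}

oracleGridSearch <- function(x, mVec, sweeps = 40L) {
  I <- ncol(x)
  thr <- lapply(mVec, function(m) rep(0, m))
  sigma <- 1
  span <- 1.6
  for (s in seq_len(sweeps)) {
    for (i in seq_len(I)) for (k in seq_len(mVec[i])) {
      cand <- thr[[i]][k] + seq(-span, span, length.out = 7L)
      lls <- vapply(cand, function(v) {
        t2 <- thr; t2[[i]][k] <- v
        oracleMarginalLogLik(x, t2, sigma)
      }, numeric(1))
      thr[[i]][k] <- cand[which.max(lls)]
    }
    candS <- pmax(sigma + seq(-span, span, length.out = 7L) / 2, 0.2)
    llsS <- vapply(candS, function(v) oracleMarginalLogLik(x, thr, v),
                   numeric(1))
    sigma <- candS[which.max(llsS)]
    span <- max(span * 0.55, 1e-4)
  }
  # same identification as the package: sum-zero item locations
  shift <- mean(vapply(thr, mean, numeric(1)))
  list(thresholds = lapply(thr, function(d) d - shift), sigma = sigma)
}
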