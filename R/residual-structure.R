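#' Residual correlations and local dependence screening
#'
#' Pearson correlations of the standardized residuals for every item pair
#' (pairwise-complete observations, extreme persons excluded). Under local
#' independence the residual correlations scatter around a slightly
#' negative mean; a pair exceeding the mean off-diagonal correlation by
#' more than 0.2 is flagged as locally dependent.
#'
#' @param residuals a [ResidualMatrix-class].
#' @param minPairObs minimum pairwise-complete observations for a
#'   correlation to be used (default 20); sparser pairs are set missing
#'   and excluded from the mean.
#' @param margin flagging margin above the mean correlation (default 0.2).
#' @return a [DependenceReport-class].
#' @export
residualCorrelations <- function(residuals, minPairObs = 20L,
                                 margin = 0.2) {
  z <- residuals@z[!residuals@extreme, , drop = FALSE]
  if (ncol(z) < 3L) stop("need at least 3 items")
  q3 <- suppressWarnings(cor(z, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(z))
  q3[counts < minPairObs] <- NA_real_
  diag(q3) <- 1
  ut <- upper.tri(q3)
  meanQ3 <- mean(q3[ut], na.rm = TRUE)
  thr <- meanQ3 + margin
  hit <- which(ut & !is.na(q3) & q3 > thr, arr.ind = TRUE)
  pairs <- data.frame(
    item1 = colnames(q3)[hit[, 1L]],
    item2 = colnames(q3)[hit[, 2L]],
    correlation = q3[hit])
  pairs <- pairs[order(-pairs$correlation), , drop = FALSE]
  rownames(pairs) <- NULL
  new("DependenceReport", q3 = q3, meanQ3 = meanQ3, threshold = thr,
      flaggedPairs = pairs)
}

#' Differential item functioning by two-way ANOVA on residuals
#'
#' For each item, fits a two-way ANOVA of the standardized residuals on
#' the covariate group, the ability class interval, and their interaction
#' (marginal, type-III sums of squares to tolerate unbalanced groups).
#' The covariate main effect tests uniform DIF (a constant group shift);
#' the interaction tests non-uniform DIF (a group shift that changes along
#' the ability continuum). Flags apply the Bonferroni rule across items
#' within the covariate. Group-by-stratum cells with fewer than
#' \code{minCell} observations trigger merging of adjacent strata for that
#' item (with a warning); if only one stratum survives, the non-uniform
#' test is not available for that item.
#'
#' @param residuals a [ResidualMatrix-class].
#' @param data the [ResponseMatrix-class] carrying the covariates.
#' @param covariate name of a covariate column (a factor with >= 2 levels).
#' @param alpha familywise level (default 0.05).
#' @param minCell minimum observations per group-by-stratum cell
#'   (default 2).
#' @return a [DIFReport-class].
#' @export
difAnova <- function(residuals, data, covariate, alpha = 0.05,
                     minCell = 2L) {
  if (!covariate %in% names(data@covariates))
    stop("unknown covariate: ", covariate)
  keep <- !residuals@extreme
  z <- residuals@z[keep, , drop = FALSE]
  grp <- droplevels(factor(data@covariates[[covariate]][keep]))
  if (nlevels(grp) < 2L)
    stop("covariate '", covariate, "' has fewer than 2 levels")
  strat <- residuals@classInterval[keep]
  I <- ncol(z)
  uniP <- nonP <- rep(NA_real_, I)
  merged <- FALSE
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  for (i in seq_len(I)) {
    obs <- !is.na(z[, i]) & !is.na(strat) & !is.na(grp)
    zi <- z[obs, i]
    gi <- droplevels(grp[obs])
    si <- strat[obs]
    # merge adjacent strata until all cells are adequately filled
    repeat {
      lev <- sort(unique(si))
      tab <- table(gi, factor(si, levels = lev))
      if (length(lev) <= 1L || all(tab >= minCell)) break
      badCol <- which.min(apply(tab, 2L, min))
      tgt <- if (badCol == 1L) 2L else badCol - 1L
      si[si == lev[badCol]] <- lev[tgt]
      merged <- TRUE
    }
    si <- factor(si)
    if (nlevels(gi) < 2L) next
    if (nlevels(si) < 2L) {
      uniP[i] <- stats::anova(lm(zi ~ gi))[["Pr(>F)"]][1L]
      next
    }
    fit <- lm(zi ~ gi * si)
    a3 <- car::Anova(fit, type = 3)
    uniP[i] <- a3["gi", "Pr(>F)"]
    nonP[i] <- a3["gi:si", "Pr(>F)"]
  }
  if (merged)
    warning("sparse group-by-stratum cells: strata merged for some items")
  bon <- alpha / I
  tab <- data.frame(
    item = colnames(z),
    covariate = covariate,
    uniformP = uniP,
    nonuniformP = nonP,
    uniformFlag = !is.na(uniP) & uniP < bon,
    nonuniformFlag = !is.na(nonP) & nonP < bon)
  new("DIFReport", table = tab, bonferroniAlpha = bon)
}

#' Unidimensionality t-test on principal-component item subsets
#'
#' Principal component analysis of the residual correlation matrix
#' identifies the most discordant item grouping: items with positive
#' first-component loadings versus items with negative loadings. Each
#' person's ability is then re-estimated on the two subsets (item
#' parameters anchored at the full calibration) and compared with
#' \eqn{t = (\hat\theta_1 - \hat\theta_2) / \sqrt{SE_1^2 + SE_2^2}}
#' against a standard normal reference. The scale passes as unidimensional
#' when at most 5 percent of persons differ significantly, or when the
#' Wilson 95 percent confidence interval for that proportion reaches down
#' to 5 percent.
#'
#' @param residuals a [ResidualMatrix-class].
#' @param data the [ResponseMatrix-class].
#' @param items the full-calibration [ItemParameters-class] (anchors).
#' @param alpha per-person test level and unidimensionality criterion
#'   (default 0.05).
#' @return a [DimensionalityReport-class].
#' @export
unidimensionalityTtest <- function(residuals, data, items, alpha = 0.05) {
  z <- residuals@z[!residuals@extreme, , drop = FALSE]
  q3 <- suppressWarnings(cor(z, use = "pairwise.complete.obs"))
  if (anyNA(q3)) {
    warning("residual correlations undefined for some pairs; treated as 0")
    q3[is.na(q3)] <- 0
  }
  diag(q3) <- 1
  ev <- eigen((q3 + t(q3)) / 2, symmetric = TRUE)
  load <- ev$vectors[, 1L]
  names(load) <- colnames(z)
  if (load[which.max(abs(load))] < 0) load <- -load
  pos <- names(load)[load >= -1e-12]
  neg <- names(load)[load < -1e-12]
  minSide <- if (ncol(z) <= 3L) 1L else 2L  # testlet-level scales split 1+1
  if (length(pos) < minSide || length(neg) < minSide) {
    warning("first component does not split the items; ",
            "verdict trivially unidimensional")
    return(new("DimensionalityReport", loadings = load,
               positiveSet = pos, negativeSet = neg,
               tStats = numeric(), propSignificant = 0, ciLower = 0,
               unidimensional = TRUE, nTested = 0L, nExcluded = 0L))
  }
  hasBoth <- rowSums(!is.na(data@responses[, pos, drop = FALSE])) > 0L &
    rowSums(!is.na(data@responses[, neg, drop = FALSE])) > 0L
  nExcluded <- sum(!hasBoth)
  xa <- data@responses[hasBoth, pos, drop = FALSE]
  xb <- data@responses[hasBoth, neg, drop = FALSE]
  thrAll <- items@thresholds[match(colnames(data@responses),
                                   items@itemIds)]
  names(thrAll) <- colnames(data@responses)
  est1 <- pcmEstimateAbility(xa, thrAll[pos])
  est2 <- pcmEstimateAbility(xb, thrAll[neg])
  tt <- (est1$theta - est2$theta) / sqrt(est1$se^2 + est2$se^2)
  names(tt) <- rownames(xa)
  sig <- abs(tt) > qnorm(1 - alpha / 2)
  prop <- mean(sig)
  ciLow <- wilsonLower(sum(sig), length(sig))
  new("DimensionalityReport",
      loadings = load, positiveSet = pos, negativeSet = neg,
      tStats = tt, propSignificant = prop, ciLower = ciLow,
      unidimensional = prop <= alpha || ciLow <= alpha,
      nTested = length(sig), nExcluded = as.integer(nExcluded))
}

# Wilson 95% lower confidence bound for a binomial proportion.
wilsonLower <- function(k, n, conf = 0.95) {
  if (n == 0L) return(0)
  zq <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  (p + zq^2 / (2 * n) - zq * sqrt(p * (1 - p) / n + zq^2 / (4 * n^2))) /
    (1 + zq^2 / n)
}

#' Shared (common non-error) variance between two ability estimates
#'
#' Disattenuated squared correlation between two sets of person ability
#' estimates: \eqn{r^2 / (rel_A \, rel_B)} with each reliability computed
#' as (Var - mean SE^2) / Var, clipped to [0, 1]. Used to quantify how
#' much of the non-error variance two testlet-based estimates share.
#'
#' @param estimatesA,estimatesB [PersonEstimates-class] objects with at
#'   least 10 paired persons.
#' @return numeric fraction in [0, 1].
#' @export
sharedVariance <- function(estimatesA, estimatesB) {
  common <- intersect(estimatesA@personIds, estimatesB@personIds)
  ia <- match(common, estimatesA@personIds)
  ib <- match(common, estimatesB@personIds)
  keep <- !estimatesA@extreme[ia] & !estimatesB@extreme[ib]
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) < 10L) stop("need at least 10 paired persons")
  relA <- (var(estimatesA@theta[ia]) - mean(estimatesA@se[ia]^2)) /
    var(estimatesA@theta[ia])
  relB <- (var(estimatesB@theta[ib]) - mean(estimatesB@se[ib]^2)) /
    var(estimatesB@theta[ib])
  if (!is.finite(relA) || !is.finite(relB) || relA <= 0 || relB <= 0)
    stop(sprintf(
      "non-positive reliability (A: %.3f, B: %.3f): shared variance undefined",
      relA, relB))
  r <- cor(estimatesA@theta[ia], estimatesB@theta[ib])
  min(max(r^2 / (relA * relB), 0), 1)
}
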