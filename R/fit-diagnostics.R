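#' Standardized response residuals
#'
#' Computes z_ni = (x_ni - E[X_ni]) / sqrt(Var[X_ni]) at the estimated
#' person abilities, stores the model's conditional moments alongside, and
#' assigns each (non-extreme) person to an ability-ordered class interval.
#' Cells with numerically zero model variance get a missing residual with
#' a warning.
#'
#' The default number of class intervals is 3 for samples up to 150
#' persons, and min(10, floor(n / 50)) beyond that; strata are split at
#' quantiles of the estimated abilities with ties kept together, and
#' strata smaller than \code{minStratum} are merged with their nearer
#' neighbour.
#'
#' @param data a [ResponseMatrix-class].
#' @param items an [ItemParameters-class].
#' @param persons a [PersonEstimates-class].
#' @param nClassIntervals integer, or \code{NULL} for the default rule.
#' @param minStratum minimum persons per stratum (default 10).
#' @return a [ResidualMatrix-class].
#' @export
standardizedResiduals <- function(data, items, persons,
                                  nClassIntervals = NULL, minStratum = 10L) {
  x <- data@responses
  idx <- match(colnames(x), items@itemIds)
  if (anyNA(idx))
    stop("calibration lacks item(s): ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  thr <- items@thresholds[idx]
  th <- persons@theta[match(rownames(x), persons@personIds)]
  n <- nrow(x); I <- ncol(x)
  E <- V <- M4 <- matrix(NA_real_, n, I, dimnames = dimnames(x))
  for (i in seq_len(I)) {
    obs <- which(!is.na(x[, i]))
    if (!length(obs)) next
    mom <- pcmMoments(th[obs], thr[[i]])
    E[obs, i] <- mom$E
    V[obs, i] <- mom$V
    M4[obs, i] <- mom$M4
  }
  degenerate <- !is.na(V) & V < 1e-10
  if (any(degenerate)) {
    warning(sum(degenerate), " cell(s) with zero model variance; ",
            "residual set to missing")
    V[degenerate] <- NA_real_
  }
  z <- (x - E) / sqrt(V)
  infoPerson <- rowSums(V, na.rm = TRUE)
  extreme <- persons@extreme[match(rownames(x), persons@personIds)]
  ci <- rep(NA_integer_, n)
  ci[!extreme] <- classIntervals(th[!extreme], nClassIntervals, minStratum)
  new("ResidualMatrix", z = z, expected = E, variance = V, m4 = M4,
      thetaHat = th, infoPerson = infoPerson, classInterval = ci,
      extreme = extreme)
}

# Ability-ordered strata: quantile cuts with ties kept together and small
# strata merged toward the nearer neighbour.
classIntervals <- function(theta, G = NULL, minStratum = 10L) {
  n <- length(theta)
  if (is.null(G))
    G <- if (n <= 150L) 3L else min(10L, max(2L, n %/% 50L))
  G <- max(2L, min(G, n %/% max(2L, minStratum)))
  cuts <- unique(quantile(theta, probs = seq_len(G - 1L) / G, type = 1L))
  g <- findInterval(theta, cuts, left.open = TRUE) + 1L
  g <- as.integer(factor(g))
  # merge undersized strata with the nearer (smaller) neighbour
  repeat {
    tab <- tabulate(g)
    small <- which(tab > 0L & tab < minStratum)
    if (!length(small) || length(tab[tab > 0L]) <= 2L) break
    s <- small[1L]
    neighbours <- c(s - 1L, s + 1L)
    neighbours <- neighbours[neighbours >= 1L & neighbours <= length(tab) &
                               tabulate(g)[pmax(neighbours, 1L)] > 0L]
    if (!length(neighbours)) break
    tgt <- neighbours[which.min(tab[neighbours])]
    g[g == s] <- tgt
    g <- as.integer(factor(g))
  }
  g
}

#' Item or person fit residuals
#'
#' Aggregates each item's (or person's) squared standardized residuals and
#' transforms the sum to an approximately standard normal statistic under
#' the model. The sum is matched to a scaled chi-square via its
#' model-implied first two moments (the second moment uses the model's
#' conditional kurtosis; the first is reduced by the share of the person
#' information each cell consumes, accounting for ability estimation), and
#' the scaled chi-square is carried to normality by the Wilson-Hilferty
#' cube-root transform. Values beyond ±2.5 conventionally flag misfit.
#' Persons with extreme scores are excluded.
#'
#' @param residuals a [ResidualMatrix-class].
#' @param margin \code{"item"} or \code{"person"}.
#' @param minObs minimum observed cells required (default 2, so person
#'   fit is still defined after collapsing a scale into two testlets).
#' @return named numeric vector of fit residuals (\code{NA} where too few
#'   observations, with a warning).
#' @export
fitResiduals <- function(residuals, margin = c("item", "person"),
                         minObs = 2L) {
  margin <- match.arg(margin)
  keep <- !residuals@extreme
  z <- residuals@z[keep, , drop = FALSE]
  V <- residuals@variance[keep, , drop = FALSE]
  info <- residuals@infoPerson[keep]
  kurt <- residuals@m4[keep, , drop = FALSE] / V^2
  shrink <- 1 - sweep(V, 1L, pmax(info, 1e-8), `/`)  # E[z^2] correction
  shrink <- pmax(shrink, 0.05)
  dim <- if (margin == "item") 2L else 1L
  S <- apply(z^2, dim, sum, na.rm = TRUE)
  mu <- apply(shrink * !is.na(z), dim, sum, na.rm = TRUE)
  v2 <- apply((kurt - shrink^2) * !is.na(z), dim, sum, na.rm = TRUE)
  nObs <- apply(!is.na(z), dim, sum)
  out <- rep(NA_real_, length(S))
  ok <- nObs >= minObs & v2 > 0 & mu > 0
  if (any(!ok))
    warning(sum(!ok), " ", margin,
            "(s) with too few observations for a fit residual")
  nu <- 2 * mu[ok]^2 / v2[ok]
  scale <- v2[ok] / (2 * mu[ok])
  ratio <- pmax(S[ok] / (scale * nu), 1e-12)
  out[ok] <- (ratio^(1 / 3) - (1 - 2 / (9 * nu))) / sqrt(2 / (9 * nu))
  names(out) <- if (margin == "item") colnames(z)
  else rownames(z)
  out
}

#' Item-trait interaction chi-square
#'
#' For each item, compares the observed item scores with their
#' model-expected values across the ability-ordered class intervals:
#' \deqn{\chi^2_i = \sum_g \frac{(\sum_{n \in g} (x_{ni} - E_{ni}))^2}
#'   {\sum_{n \in g} V_{ni}}, \qquad df = G_i - 1.}
#' The expectation and variance of each response are taken conditional on
#' the person's total raw score over their answered items — the sufficient
#' statistic for ability under the partial credit model — so the test is
#' free of ability-estimation error and stays calibrated even for scales
#' of two highly informative super-items. No adjustment is made for item
#' threshold estimation, which makes the test mildly conservative (null
#' rejection a little below nominal), the safe direction for a fit
#' criterion. Persons with extreme totals carry degenerate conditionals
#' and drop out naturally. Strata with no
#' observations for an item are merged (warning). Per-item p-values are
#' judged against the Bonferroni threshold alpha / I; the total statistic
#' sums the per-item chi-squares with df = sum(G_i - 1).
#'
#' @param residuals a [ResidualMatrix-class] (supplies the class
#'   intervals and extreme-person flags).
#' @param data the [ResponseMatrix-class] the residuals came from.
#' @param items the [ItemParameters-class] of the calibration.
#' @param alpha familywise significance level (default 0.05).
#' @return list with \code{itemTable} (data frame: item, chisq, df, p,
#'   flagged), \code{total} (list chisq, df, p), and
#'   \code{bonferroniAlpha}.
#' @export
itemTraitChisq <- function(residuals, data, items, alpha = 0.05) {
  keep <- !residuals@extreme
  x <- data@responses[keep, , drop = FALSE]
  g <- residuals@classInterval[keep]
  thetaRef <- stats::median(residuals@thetaHat[keep])
  ord <- match(colnames(x), items@itemIds)
  thr <- items@thresholds[ord]
  cm <- conditionalMoments(x, thr, thetaRef)
  I <- ncol(x)
  G <- length(unique(g[!is.na(g)]))
  chisq <- df <- numeric(I)
  for (i in seq_len(I)) {
    obs <- !is.na(x[, i]) & cm$V[, i] > 1e-10 & !is.na(g)
    gi <- g[obs]
    num <- tapply(x[obs, i] - cm$E[obs, i], gi, sum)
    den <- tapply(cm$V[obs, i], gi, sum)
    present <- !is.na(num) & den > 0
    if (sum(present) < G)
      warning("item '", colnames(x)[i],
              "': empty class interval(s) merged")
    chisq[i] <- sum(num[present]^2 / den[present])
    df[i] <- max(sum(present) - 1L, 1L)
  }
  p <- pchisq(chisq, df, lower.tail = FALSE)
  bon <- alpha / I
  list(
    itemTable = data.frame(item = colnames(x), chisq = chisq, df = df,
                           p = p, flagged = p < bon),
    total = list(chisq = sum(chisq), df = sum(df),
                 p = pchisq(sum(chisq), sum(df), lower.tail = FALSE)),
    bonferroniAlpha = bon)
}

# Conditional mean and variance of each observed response given the
# person's raw total over answered items (the PCM sufficient statistic).
# Computed by polynomial convolution of the category weight vectors;
# theta cancels from the conditional, but a reference theta stabilizes
# the weights numerically. Persons are grouped by missingness pattern.
conditionalMoments <- function(x, thr, thetaRef = 0) {
  n <- nrow(x); I <- ncol(x)
  E <- V <- matrix(NA_real_, n, I, dimnames = dimnames(x))
  pat <- apply(!is.na(x), 1L, paste, collapse = "")
  conv <- function(a, b) {
    out <- pmax(stats::convolve(a, rev(b), type = "open"), 0)
    out / max(out)
  }
  for (pt in unique(pat)) {
    rows <- which(pat == pt)
    itemsIn <- which(!is.na(x[rows[1L], ]))
    if (length(itemsIn) < 2L) next
    w <- lapply(itemsIn, function(i) {
      m <- length(thr[[i]])
      lc <- (0:m) * thetaRef - c(0, cumsum(thr[[i]]))
      exp(lc - max(lc))
    })
    k <- length(w)
    pre <- vector("list", k + 1L)
    suf <- vector("list", k + 2L)
    pre[[1L]] <- 1
    for (j in seq_len(k)) pre[[j + 1L]] <- conv(pre[[j]], w[[j]])
    suf[[k + 2L]] <- 1
    for (j in rev(seq_len(k))) suf[[j + 1L]] <- conv(suf[[j + 2L]], w[[j]])
    tot <- rowSums(x[rows, itemsIn, drop = FALSE])
    for (j in seq_len(k)) {
      i <- itemsIn[j]
      Dmi <- conv(pre[[j]], suf[[j + 2L]])
      m <- length(w[[j]]) - 1L
      idx <- outer(tot, 0:m, `-`) + 1L          # n_p x (m+1), 1-based
      ok <- idx >= 1L & idx <= length(Dmi)
      P <- matrix(0, length(rows), m + 1L)
      P[ok] <- Dmi[idx[ok]]
      P <- P * rep(w[[j]], each = length(rows))
      s <- rowSums(P)
      P <- P / s
      xs <- 0:m
      Ei <- drop(P %*% xs)
      Vi <- drop(P %*% xs^2) - Ei^2
      E[rows, i] <- Ei
      V[rows, i] <- pmax(Vi, 0)
    }
  }
  list(E = E, V = V)
}

#' Detect items with disordered thresholds
#'
#' An item's thresholds should increase with the category index so that
#' every response category is the modal choice somewhere along the latent
#' continuum; a non-increasing threshold vector marks disordered
#' categories (visible as a category characteristic curve that is nowhere
#' on top).
#'
#' @param items an [ItemParameters-class].
#' @return character vector of disordered item ids. The full curve data
#'   for plotting come from [categoryCurves()].
#' @export
checkThresholdOrder <- function(items) {
  disordered <- vapply(items@thresholds,
                       function(d) any(diff(d) <= 0), logical(1))
  items@itemIds[disordered]
}

#' Remove misfitting persons
#'
#' Drops persons whose absolute person fit residual exceeds the threshold
#' (±2.5 by convention). The removed ids are attached as the
#' \code{"removedPersons"} attribute of the result.
#'
#' @param data a [ResponseMatrix-class].
#' @param personFit named numeric vector from
#'   \code{fitResiduals(res, "person")}.
#' @param threshold absolute fit-residual cutoff (default 2.5).
#' @return a [ResponseMatrix-class] (unchanged when nobody exceeds the
#'   threshold).
#' @export
removeMisfittingPersons <- function(data, personFit, threshold = 2.5) {
  bad <- names(personFit)[!is.na(personFit) & abs(personFit) > threshold]
  keep <- setdiff(rownames(data@responses), bad)
  if (length(keep) < 10L)
    stop("removal would leave fewer than 10 persons")
  out <- new("ResponseMatrix",
             responses = data@responses[keep, , drop = FALSE],
             spec = data@spec,
             covariates = data@covariates[keep, , drop = FALSE])
  attr(out, "removedPersons") <- bad
  out
}

#' Person Separation Index
#'
#' Rasch reliability analogue: the proportion of observed ability variance
#' not attributable to estimation error,
#' PSI = (Var(theta) - mean(SE^2)) / Var(theta), computed over non-extreme
#' persons. Can be negative for uninformative data and is reported as-is.
#'
#' @param persons a [PersonEstimates-class].
#' @return numeric scalar <= 1.
#' @export
personSeparationIndex <- function(persons) {
  keep <- !persons@extreme
  if (sum(keep) < 2L) stop("need at least 2 non-extreme persons")
  v <- var(persons@theta[keep])
  if (v < 1e-12) stop("zero variance of ability estimates: PSI undefined")
  (v - mean(persons@se[keep]^2)) / v
}

#' Assemble the fit report for one calibration
#'
#' Convenience wrapper running [fitResiduals()] (both margins),
#' [itemTraitChisq()], [checkThresholdOrder()] and
#' [personSeparationIndex()] into a single [FitReport-class].
#'
#' @param residuals a [ResidualMatrix-class].
#' @param data the [ResponseMatrix-class] analysed.
#' @param items the [ItemParameters-class].
#' @param persons the [PersonEstimates-class].
#' @param alpha familywise level for the Bonferroni rule (default 0.05).
#' @param fitThreshold absolute fit-residual misfit bound (default 2.5).
#' @param rummSign if \code{TRUE}, item locations are negated for display
#'   (the convention in which negative locations mark harder items).
#' @return a [FitReport-class].
#' @export
fitReport <- function(residuals, data, items, persons, alpha = 0.05,
                      fitThreshold = 2.5, rummSign = FALSE) {
  itemFR <- fitResiduals(residuals, "item")
  personFR <- fitResiduals(residuals, "person")
  chi <- itemTraitChisq(residuals, data, items, alpha)
  loc <- items@locations[match(colnames(data@responses), items@itemIds)]
  seLoc <- items@seLocations[match(colnames(data@responses),
                                   items@itemIds)]
  itemFit <- data.frame(
    item = chi$itemTable$item,
    location = if (rummSign) -loc else loc,
    seLocation = seLoc,
    fitResidual = itemFR[chi$itemTable$item],
    chisq = chi$itemTable$chisq,
    df = chi$itemTable$df,
    p = chi$itemTable$p,
    flagged = (!is.na(itemFR[chi$itemTable$item]) &
                 abs(itemFR[chi$itemTable$item]) > fitThreshold) |
      chi$itemTable$flagged,
    row.names = NULL)
  personFit <- data.frame(
    person = names(personFR),
    fitResidual = personFR,
    flagged = !is.na(personFR) & abs(personFR) > fitThreshold,
    row.names = NULL)
  new("FitReport",
      itemFit = itemFit,
      personFit = personFit,
      summaryStats = list(
        meanItemFit = mean(itemFR, na.rm = TRUE),
        sdItemFit = sd(itemFR, na.rm = TRUE),
        meanPersonFit = mean(personFR, na.rm = TRUE),
        sdPersonFit = sd(personFR, na.rm = TRUE)),
      totalChisq = chi$total,
      psi = personSeparationIndex(persons),
      disorderedItems = checkThresholdOrder(items),
      nClassIntervals = length(unique(na.omit(residuals@classInterval))),
      bonferroniAlpha = chi$bonferroniAlpha)
}
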