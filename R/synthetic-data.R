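#' Configure the synthetic response generator
#'
#' Builds a [SimulationConfig-class] for the generalized partial credit
#' generating model. With all discriminations at 1, no testlets and no
#' DIF, the generator reduces to the pure partial credit model — the
#' baseline every diagnostic in the package should pass at nominal rates.
#' Each violation knob plants one structure: testlet effect SDs create
#' within-cluster residual correlations (local dependence), DIF offsets
#' shift one covariate group's effective ability on chosen items, and
#' discriminations away from 1 create item misfit (under-discriminating
#' items, a < 1, tend toward positive fit residuals).
#'
#' @param nPersons number of persons.
#' @param nItems number of items (ignored when \code{thresholds} given).
#' @param maxCategory categories are 0..maxCategory (default 4,
#'   five-category items).
#' @param thresholds optional named list of threshold vectors; by default
#'   item locations are spread evenly over \code{locationRange} with
#'   centered threshold steps \code{stepRange}.
#' @param locationRange range of default item locations (logits).
#' @param stepRange half-spread of the default within-item threshold steps.
#' @param discrimination per-item discriminations (recycled; default 1).
#' @param thetaMean,thetaSD latent normal parameters.
#' @param testlets named list of \code{list(items =, sd =)} entries.
#' @param dif list of \code{list(item =, covariate =, offset =)} entries;
#'   the offset (logits) is subtracted from the effective ability of the
#'   covariate's second level.
#' @param covariates named list of named level-probability vectors.
#' @param missing per-item missingness probabilities (recycled; default 0).
#' @param optionalItems item ids flagged optional in the emitted spec.
#' @param seed integer seed stored with the config.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nPersons, nItems = 10L, maxCategory = 4L,
                             thresholds = NULL,
                             locationRange = c(-1.2, 1.2),
                             stepRange = 1.5,
                             discrimination = 1,
                             thetaMean = 0, thetaSD = 1,
                             testlets = list(), dif = list(),
                             covariates = list(), missing = 0,
                             optionalItems = character(),
                             seed = NA_integer_) {
  if (is.null(thresholds)) {
    loc <- if (nItems > 1L)
      seq(locationRange[1L], locationRange[2L], length.out = nItems)
    else mean(locationRange)
    steps <- seq(-stepRange, stepRange, length.out = maxCategory)
    thresholds <- lapply(loc, function(l) l + steps)
    names(thresholds) <- sprintf("item%02d", seq_len(nItems))
  }
  ids <- names(thresholds)
  if (is.null(ids)) {
    ids <- sprintf("item%02d", seq_along(thresholds))
    names(thresholds) <- ids
  }
  new("SimulationConfig",
      nPersons = as.integer(nPersons),
      itemIds = ids,
      thresholds = lapply(thresholds, as.numeric),
      discrimination = rep_len(as.numeric(discrimination), length(ids)),
      thetaMean = thetaMean, thetaSD = thetaSD,
      testlets = testlets, dif = dif, covariates = covariates,
      missing = rep_len(as.numeric(missing), length(ids)),
      optionalItems = as.character(optionalItems),
      seed = as.integer(seed))
}

#' Simulate polytomous responses
#'
#' Draws person abilities, covariates, testlet effects and responses from
#' the generalized partial credit model described by the configuration:
#' person n answers item i from category probabilities with effective
#' ability theta_n + testlet effect (if the item sits in a testlet) minus
#' the DIF offset (if the person belongs to the disadvantaged group),
#' weighted by the item's discrimination. Identical seeds give
#' bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides the config's stored seed.
#' @return list with \code{data} (a [ResponseMatrix-class]) and
#'   \code{truth} (list: theta, thresholds, discrimination,
#'   testletEffects, dif, misfitItems).
#' @export
simulateResponses <- function(config, seed = config@seed) {
  validObject(config)
  if (!is.na(seed)) set.seed(seed)
  n <- config@nPersons
  ids <- config@itemIds
  I <- length(ids)
  personIds <- sprintf("P%04d", seq_len(n))
  th <- rnorm(n, config@thetaMean, config@thetaSD)

  cov <- data.frame(row.names = personIds)
  for (cn in names(config@covariates)) {
    p <- config@covariates[[cn]]
    cov[[cn]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                        levels = names(p))
  }

  gamma <- matrix(0, n, I, dimnames = list(personIds, ids))
  tlEffects <- list()
  for (tn in names(config@testlets)) {
    tl <- config@testlets[[tn]]
    eff <- rnorm(n, 0, tl$sd)
    tlEffects[[tn]] <- eff
    gamma[, tl$items] <- gamma[, tl$items] + eff
  }

  shift <- matrix(0, n, I, dimnames = list(personIds, ids))
  for (d in config@dif) {
    lev <- levels(cov[[d$covariate]])
    hit <- cov[[d$covariate]] == lev[2L]
    shift[hit, d$item] <- shift[hit, d$item] + d$offset
  }

  x <- matrix(NA_integer_, n, I, dimnames = list(personIds, ids))
  for (i in seq_len(I)) {
    eff <- th + gamma[, i] - shift[, i]
    p <- categoryProbs(eff, config@thresholds[[i]],
                       a = config@discrimination[i])
    u <- runif(n)
    cp <- t(apply(p, 1L, cumsum))
    x[, i] <- as.integer(rowSums(u > cp))
    if (config@missing[i] > 0)
      x[runif(n) < config@missing[i], i] <- NA_integer_
  }

  spec <- scaleSpec(ids,
                    maxCategory = lengths(config@thresholds),
                    optionalFlags = ids %in% config@optionalItems,
                    testletMap = if (length(config@testlets))
                      lapply(config@testlets, `[[`, "items"))
  data <- new("ResponseMatrix", responses = x, spec = spec,
              covariates = cov)
  truth <- list(theta = setNames(th, personIds),
                thresholds = config@thresholds,
                discrimination = setNames(config@discrimination, ids),
                testletEffects = tlEffects,
                dif = config@dif,
                misfitItems = ids[config@discrimination != 1])
  list(data = data, truth = truth)
}

#' Preset emulating a DASH-like 30-item instrument
#'
#' Thirty five-category items: twenty activity-limitation items
#' (\code{item01}..\code{item20}) forming one dependence cluster, an
#' optional item (\code{item21}) with high missingness, and nine
#' impairment items (\code{item22}..\code{item30}) forming a second
#' cluster. Defaults mirror the structure such instruments display in
#' clinic samples: 109 persons, standard-normal abilities, strong
#' within-cluster local dependence (testlet effect SD 0.8), 54 percent
#' missingness on the optional item, and covariates with realistic
#' marginal frequencies (sex 58/42, age split at the median, surgery
#' 37/63, dominant side 66/34).
#'
#' @param nPersons sample size (default 109).
#' @param testletSD named or unnamed numeric of length 2: activity and
#'   impairment testlet effect SDs (default 0.8 each; set both to 0 for a
#'   pure PCM instrument).
#' @param optionalMissing missingness probability of the optional item
#'   (default 0.54).
#' @param dif optional DIF entries passed through.
#' @param discrimination per-item discriminations (default all 1).
#' @param seed stored seed.
#' @return a [SimulationConfig-class].
#' @export
dashLikePreset <- function(nPersons = 109L, testletSD = c(0.8, 0.8),
                           optionalMissing = 0.54, dif = list(),
                           discrimination = 1, seed = NA_integer_) {
  ids <- sprintf("item%02d", 1:30)
  # evenly spread locations, deterministically shuffled across item order
  loc <- seq(-1.2, 1.2, length.out = 30L)
  loc <- loc[rank(sin(1:30 * 2.3), ties.method = "first")]
  steps <- c(-1.5, -0.5, 0.5, 1.5)
  thresholds <- setNames(lapply(loc, function(l) l + steps), ids)
  activity <- ids[1:20]
  impairment <- ids[22:30]
  testlets <- list()
  if (testletSD[1L] > 0)
    testlets$activity <- list(items = activity, sd = testletSD[1L])
  if (testletSD[2L] > 0)
    testlets$impairment <- list(items = impairment, sd = testletSD[2L])
  missing <- rep(0, 30)
  missing[21L] <- optionalMissing
  simulationConfig(
    nPersons = nPersons,
    thresholds = thresholds,
    discrimination = discrimination,
    testlets = testlets,
    dif = dif,
    covariates = list(
      sex = c(male = 0.578, female = 0.422),
      age_group = c(under42 = 0.5, over42 = 0.5),
      surgery = c(no = 0.633, yes = 0.367),
      affected_side = c(dominant = 0.661, nondominant = 0.339)),
    missing = missing,
    optionalItems = "item21",
    seed = seed)
}
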