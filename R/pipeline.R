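#' Run the full multi-stage structural validation
#'
#' Orchestrates the standard three-run sequence for a polytomous scale:
#' \enumerate{
#'   \item initial calibration and full diagnostic battery on all persons;
#'   \item re-analysis after removing persons with absolute fit residuals
#'     beyond the threshold;
#'   \item re-analysis after collapsing locally dependent items into
#'     testlet super-items.
#' }
#' Each run recomputes item calibration, person estimation, residuals,
#' fit statistics, local dependence, DIF for every covariate, the
#' unidimensionality t-test and the PSI. Later runs are skipped with a
#' notice when an earlier run is already satisfactory (non-significant
#' total item-trait chi-square and a unidimensional verdict). A
#' conversion table is built from the final run's calibration.
#'
#' @param data a [ResponseMatrix-class].
#' @param testletMap named list of item-id vectors for run 3; defaults to
#'   the spec's stored map. When absent, a heuristic average-linkage
#'   clustering of the residual correlations into two groups is used
#'   (labelled as such in the report).
#' @param covariateNames covariates to test for DIF (default: all columns
#'   of the data's covariate frame).
#' @param nClassIntervals strata count or \code{NULL} for the default rule.
#' @param fitThreshold person/item fit-residual bound (default 2.5).
#' @param alpha familywise level (default 0.05).
#' @param maxit EM iteration cap passed to [estimateItems()]
#'   (default 2000; testlet super-items carry many thresholds and converge
#'   more slowly than single items).
#' @param stopWhenSatisfactory skip remaining runs once fit is
#'   satisfactory (default TRUE).
#' @param rummSign negate item locations for display (default FALSE).
#' @param verbose print per-run progress (default FALSE).
#' @return a [ValidationReport-class].
#' @export
runValidation <- function(data, testletMap = NULL, covariateNames = NULL,
                          nClassIntervals = NULL, fitThreshold = 2.5,
                          alpha = 0.05, maxit = 2000L,
                          stopWhenSatisfactory = TRUE, rummSign = FALSE,
                          verbose = FALSE) {
  if (is.null(covariateNames))
    covariateNames <- names(data@covariates)
  covariateNames <- covariateNames[
    vapply(covariateNames, function(cn)
      nlevels(droplevels(factor(data@covariates[[cn]]))) >= 2L,
      logical(1))]
  runs <- list()
  note <- function(...) if (verbose) message(sprintf(...))

  doRun <- function(d, label) {
    items <- estimateItems(d, maxit = maxit, onNonconvergence = "warn")
    persons <- estimatePersons(d, items)
    res <- standardizedResiduals(d, items, persons, nClassIntervals)
    fit <- fitReport(res, d, items, persons, alpha, fitThreshold,
                     rummSign)
    dep <- if (ncol(d@responses) >= 3L) residualCorrelations(res)
    else NULL  # two super-items leave no room for a dependence screen
    dif <- lapply(covariateNames, function(cn)
      difAnova(res, d, cn, alpha))
    names(dif) <- covariateNames
    dim <- unidimensionalityTtest(res, d, items, alpha)
    list(label = label, n = nrow(d@responses), data = d, items = items,
         persons = persons, residuals = res, fit = fit, dependence = dep,
         dif = dif, dimensionality = dim,
         satisfactory = fit@totalChisq$p >= alpha && dim@unidimensional)
  }

  note("run 1: initial analysis (n = %d)", nrow(data@responses))
  runs$run1 <- doRun(data, "initial analysis")
  current <- data

  if (!(stopWhenSatisfactory && runs$run1$satisfactory)) {
    pf <- setNames(runs$run1$fit@personFit$fitResidual,
                   runs$run1$fit@personFit$person)
    flagged <- sum(!is.na(pf) & abs(pf) > fitThreshold)
    if (flagged > 0L) {
      current <- removeMisfittingPersons(data, pf, fitThreshold)
      note("run 2: %d misfitting person(s) removed",
           length(attr(current, "removedPersons")))
      runs$run2 <- doRun(current, "misfitting persons removed")
      runs$run2$removedPersons <- attr(current, "removedPersons")
    } else note("run 2 skipped: no misfitting persons")
  } else note("runs 2-3 skipped: initial fit satisfactory")

  lastRun <- runs[[length(runs)]]
  if (!(stopWhenSatisfactory && lastRun$satisfactory)) {
    map <- testletMap %||% current@spec@testletMap
    heuristic <- FALSE
    if (is.null(map) || !length(map)) {
      map <- clusterTestlets(lastRun$dependence)
      heuristic <- TRUE
      if (is.null(map))
        stop("run 3 needs a testlet map: none supplied, none stored in ",
             "the spec, and residual clustering found no usable split")
      note("run 3: heuristic residual-correlation testlets used")
    }
    collapsed <- collapseTestlets(current, map)
    note("run 3: items grouped into %d testlet(s)", length(map))
    runs$run3 <- doRun(collapsed, "items grouped into testlets")
    runs$run3$testletMap <- map
    runs$run3$heuristicTestlets <- heuristic
  }

  final <- runs[[length(runs)]]
  conv <- tryCatch(buildConversionTable(final$items),
                   error = function(e) {
                     warning("conversion table not built: ",
                             conditionMessage(e))
                     NULL
                   })
  new("ValidationReport", runs = runs, conversionTable = conv,
      config = list(fitThreshold = fitThreshold, alpha = alpha,
                    nClassIntervals = nClassIntervals,
                    covariates = covariateNames,
                    stopWhenSatisfactory = stopWhenSatisfactory))
}

# Heuristic two-group testlet derivation: average-linkage clustering on
# 1 - residual correlation.
clusterTestlets <- function(dependence) {
  q3 <- dependence@q3
  q3[is.na(q3)] <- 0
  d <- stats::as.dist(1 - q3)
  grp <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
  if (min(table(grp)) < 2L) return(NULL)
  split(colnames(q3), paste0("testlet", grp))
}
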