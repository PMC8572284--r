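#' @import methods
#' @importFrom stats cor format.pval lm median na.omit pchisq pnorm qnorm
#'   quantile rnorm runif sd setNames uniroot var
#' @importFrom utils read.csv write.csv write.table
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))
setClassUnion("CharacterOrNULL", c("character", "NULL"))

#' Scale specification for a polytomous instrument
#'
#' A \code{ScaleSpec} describes the fixed structure of a questionnaire:
#' the ordered item identifiers, the maximum category code of each item
#' (responses are coded 0..m_i internally, even when the printed form
#' numbers its boxes 1..m_i+1), which items are optional, the category
#' labels, and an optional partition of items into named testlets.
#'
#' @slot itemIds character vector of unique item identifiers, in scale order.
#' @slot maxCategory integer vector, one per item; m_i >= 1.
#' @slot optionalFlags logical vector, one per item; \code{TRUE} marks items
#'   that respondents may legitimately skip.
#' @slot categoryLabels list of character vectors (length m_i + 1 each), or
#'   empty list when labels are not supplied.
#' @slot testletMap named list mapping testlet names to character vectors of
#'   member item ids, or \code{NULL}. Items may belong to at most one testlet.
#'
#' @seealso [scaleSpec()] for the user-facing constructor.
#' @export
setClass("ScaleSpec",
  representation(
    itemIds = "character",
    maxCategory = "integer",
    optionalFlags = "logical",
    categoryLabels = "list",
    testletMap = "ListOrNULL"
  ),
  prototype(testletMap = NULL, categoryLabels = list())
)

setValidity("ScaleSpec", function(object) {
  msgs <- character()
  n <- length(object@itemIds)
  if (n < 1L) msgs <- c(msgs, "at least one item is required")
  if (anyDuplicated(object@itemIds))
    msgs <- c(msgs, "item ids must be unique")
  if (length(object@maxCategory) != n)
    msgs <- c(msgs, "maxCategory must have one entry per item")
  else if (any(object@maxCategory < 1L))
    msgs <- c(msgs, "every item needs maxCategory >= 1")
  if (length(object@optionalFlags) != n)
    msgs <- c(msgs, "optionalFlags must have one entry per item")
  if (length(object@categoryLabels) &&
      length(object@categoryLabels) != n)
    msgs <- c(msgs, "categoryLabels must be empty or one vector per item")
  if (!is.null(object@testletMap)) {
    members <- unlist(object@testletMap, use.names = FALSE)
    if (anyDuplicated(members))
      msgs <- c(msgs, "an item cannot belong to two testlets")
    bad <- setdiff(members, object@itemIds)
    if (length(bad))
      msgs <- c(msgs, paste0("testlet members not in the scale: ",
                             paste(bad, collapse = ", ")))
    if (is.null(names(object@testletMap)) ||
        any(!nzchar(names(object@testletMap))))
      msgs <- c(msgs, "testlets must be named")
  }
  if (length(msgs)) msgs else TRUE
})

#' Persons-by-items ordinal response matrix
#'
#' The central data container: an integer matrix of 0-based category codes
#' (rows = persons, columns = items, \code{NA} = missing), together with the
#' [ScaleSpec-class] it conforms to and a data frame of per-person
#' categorical covariates (e.g. sex, age group, surgical status, affected
#' side) used for differential item functioning.
#'
#' @slot responses integer matrix with person ids as row names and item ids
#'   as column names; entry (n, i) lies in 0..m_i or is \code{NA}.
#' @slot spec the [ScaleSpec-class] the columns conform to.
#' @slot covariates data frame of per-person factors, row-aligned with
#'   \code{responses} (zero columns allowed).
#'
#' @seealso [responseMatrix()], [readResponses()]
#' @export
setClass("ResponseMatrix",
  representation(
    responses = "matrix",
    spec = "ScaleSpec",
    covariates = "data.frame"
  )
)

setValidity("ResponseMatrix", function(object) {
  msgs <- character()
  r <- object@responses
  sp <- object@spec
  if (!identical(colnames(r), sp@itemIds))
    msgs <- c(msgs, "column names must equal the spec item ids, in order")
  if (is.null(rownames(r)) || anyDuplicated(rownames(r)))
    msgs <- c(msgs, "person ids (row names) must be present and unique")
  if (nrow(r) < 2L || ncol(r) < 2L)
    msgs <- c(msgs, "need at least 2 persons and 2 items")
  if (!length(msgs)) {
    for (i in seq_len(ncol(r))) {
      v <- r[, i]
      bad <- which(!is.na(v) & (v < 0L | v > sp@maxCategory[i] |
                                  v != round(v)))
      if (length(bad)) {
        msgs <- c(msgs, sprintf(
          "person '%s', item '%s': value %s outside 0..%d",
          rownames(r)[bad[1L]], sp@itemIds[i], v[bad[1L]],
          sp@maxCategory[i]))
        break
      }
    }
  }
  if (nrow(object@covariates) &&
      nrow(object@covariates) != nrow(r))
    msgs <- c(msgs, "covariates must have one row per person")
  if (length(msgs)) msgs else TRUE
})

#' Partial credit model item parameters
#'
#' Item-side output of a calibration: for each item an ordered-by-index
#' vector of category thresholds delta_i1..delta_im (logits; delta_i0 = 0
#' implicitly), their standard errors, the item locations (mean of the
#' thresholds) and their standard errors, plus the latent-distribution
#' estimates. Under the package's sign convention higher theta means a
#' higher expected item score (more limitation on symptom scales); use
#' \code{rummSign = TRUE} in reporting functions to print locations in the
#' convention where negative locations mark harder items.
#'
#' @slot itemIds character vector.
#' @slot thresholds named list of numeric threshold vectors (length m_i).
#' @slot seThresholds named list of numeric vectors (may be empty).
#' @slot paramCov covariance matrix of all threshold estimates, rows and
#'   columns ordered item-by-item (may be empty; used by the item-trait
#'   chi-square to account for parameter estimation).
#' @slot locations numeric vector, mean of each item's thresholds.
#' @slot seLocations numeric vector (may be \code{NA}).
#' @slot latentMean,latentSD numeric scalars for the fitted normal latent
#'   distribution.
#' @slot logLik numeric marginal log-likelihood at convergence (\code{NA}
#'   for hand-built parameter sets).
#' @slot converged logical.
#' @slot iterations integer EM iteration count.
#' @export
setClass("ItemParameters",
  representation(
    itemIds = "character",
    thresholds = "list",
    seThresholds = "list",
    paramCov = "matrix",
    locations = "numeric",
    seLocations = "numeric",
    latentMean = "numeric",
    latentSD = "numeric",
    logLik = "numeric",
    converged = "logical",
    iterations = "integer"
  ),
  prototype(latentMean = 0, latentSD = 1, logLik = NA_real_,
            converged = NA, iterations = 0L,
            paramCov = matrix(numeric(), 0L, 0L))
)

setValidity("ItemParameters", function(object) {
  msgs <- character()
  n <- length(object@itemIds)
  if (length(object@thresholds) != n)
    msgs <- c(msgs, "one threshold vector per item required")
  if (length(object@locations) != n)
    msgs <- c(msgs, "one location per item required")
  if (!length(msgs)) {
    loc <- vapply(object@thresholds, mean, numeric(1))
    if (any(abs(loc - object@locations) > 1e-8))
      msgs <- c(msgs, "location must equal the mean of the thresholds")
    if (any(!vapply(object@thresholds, function(d) all(is.finite(d)),
                    logical(1))))
      msgs <- c(msgs, "thresholds must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Person ability estimates
#'
#' Person-side output: latent ability theta (logits), its standard error,
#' the observed raw score, and a flag marking extreme (zero or perfect)
#' raw scores whose theta is extrapolated from a score-adjusted likelihood.
#'
#' @slot personIds character vector.
#' @slot theta numeric abilities (logits), finite for all persons.
#' @slot se numeric standard errors (> 0).
#' @slot extreme logical extreme-score flags.
#' @slot rawScore numeric observed raw scores over answered items.
#' @slot nObserved integer count of answered items.
#' @export
setClass("PersonEstimates",
  representation(
    personIds = "character",
    theta = "numeric",
    se = "numeric",
    extreme = "logical",
    rawScore = "numeric",
    nObserved = "integer"
  )
)

setValidity("PersonEstimates", function(object) {
  n <- length(object@personIds)
  msgs <- character()
  if (length(object@theta) != n || length(object@se) != n ||
      length(object@extreme) != n)
    msgs <- c(msgs, "theta, se and extreme must align with personIds")
  if (any(!is.finite(object@theta)))
    msgs <- c(msgs, "theta must be finite (extreme scores are extrapolated)")
  if (any(!object@extreme & !(object@se > 0), na.rm = TRUE))
    msgs <- c(msgs, "se must be positive for non-extreme persons")
  if (length(msgs)) msgs else TRUE
})

#' Standardized residual matrix with ability class intervals
#'
#' Person-by-item standardized residuals z_ni = (x_ni - E[X_ni]) /
#' sqrt(Var[X_ni]) evaluated at the estimated abilities, together with the
#' model moments needed by the downstream fit statistics and the
#' ability-ordered class-interval (stratum) labels. Residuals are defined
#' only for observed cells; persons with extreme raw scores carry residuals
#' but no stratum and are excluded from aggregate fit statistics.
#'
#' @slot z numeric matrix of standardized residuals (\code{NA} where the
#'   response is missing).
#' @slot expected,variance,m4 numeric matrices of the model's conditional
#'   mean, variance and fourth central moment per observed cell.
#' @slot thetaHat numeric vector of person abilities used.
#' @slot infoPerson numeric vector, per-person test information
#'   (sum of cell variances over answered items).
#' @slot classInterval integer stratum label per person (\code{NA} for
#'   extreme persons).
#' @slot extreme logical per-person extreme flags.
#' @export
setClass("ResidualMatrix",
  representation(
    z = "matrix",
    expected = "matrix",
    variance = "matrix",
    m4 = "matrix",
    thetaHat = "numeric",
    infoPerson = "numeric",
    classInterval = "integer",
    extreme = "logical"
  )
)

setValidity("ResidualMatrix", function(object) {
  msgs <- character()
  d <- dim(object@z)
  if (!identical(dim(object@expected), d) ||
      !identical(dim(object@variance), d))
    msgs <- c(msgs, "z, expected and variance must share dimensions")
  if (length(object@classInterval) != d[1L])
    msgs <- c(msgs, "one class interval per person required")
  if (length(msgs)) msgs else TRUE
})

#' Model-fit report for one analysis run
#'
#' Bundles the fit evidence for a single calibration: per-item fit
#' residuals and item-trait chi-square tests (with Bonferroni-adjusted
#' flags), per-person fit residuals, summary means/SDs, the total
#' item-trait interaction chi-square, the Person Separation Index, and
#' the list of items with disordered thresholds.
#'
#' @slot itemFit data frame: item, location, seLocation, fitResidual,
#'   chisq, df, p, flagged.
#' @slot personFit data frame: person, fitResidual, flagged.
#' @slot summaryStats named list with meanItemFit, sdItemFit,
#'   meanPersonFit, sdPersonFit.
#' @slot totalChisq named list with chisq, df, p.
#' @slot psi numeric Person Separation Index.
#' @slot disorderedItems character vector of item ids.
#' @slot nClassIntervals integer number of strata used.
#' @slot bonferroniAlpha numeric per-item significance threshold (0.05 / I).
#' @export
setClass("FitReport",
  representation(
    itemFit = "data.frame",
    personFit = "data.frame",
    summaryStats = "list",
    totalChisq = "list",
    psi = "numeric",
    disorderedItems = "character",
    nClassIntervals = "integer",
    bonferroniAlpha = "numeric"
  )
)

#' Local dependence (residual correlation) report
#'
#' @slot q3 item-by-item Pearson correlation matrix of standardized
#'   residuals (unit diagonal).
#' @slot meanQ3 numeric mean of the off-diagonal correlations.
#' @slot threshold numeric flagging threshold, meanQ3 + 0.2.
#' @slot flaggedPairs data frame (item1, item2, correlation) sorted by
#'   descending correlation; every listed correlation exceeds the threshold.
#' @export
setClass("DependenceReport",
  representation(
    q3 = "matrix",
    meanQ3 = "numeric",
    threshold = "numeric",
    flaggedPairs = "data.frame"
  )
)

setValidity("DependenceReport", function(object) {
  msgs <- character()
  q <- object@q3
  if (nrow(q) != ncol(q) || max(abs(q - t(q)), na.rm = TRUE) > 1e-10)
    msgs <- c(msgs, "q3 must be square and symmetric")
  if (any(abs(diag(q) - 1) > 1e-10, na.rm = TRUE))
    msgs <- c(msgs, "q3 must have unit diagonal")
  if (nrow(object@flaggedPairs) &&
      any(object@flaggedPairs$correlation <= object@threshold))
    msgs <- c(msgs, "flagged pairs must exceed the threshold")
  if (length(msgs)) msgs else TRUE
})

#' Differential item functioning report
#'
#' Per item and covariate, the p-value of the covariate main effect
#' (uniform DIF) and of the covariate-by-class-interval interaction
#' (non-uniform DIF) from a two-way ANOVA on standardized residuals,
#' with Bonferroni flags across items within each covariate.
#'
#' @slot table data frame: item, covariate, uniformP, nonuniformP,
#'   uniformFlag, nonuniformFlag.
#' @slot bonferroniAlpha numeric per-item threshold (0.05 / I).
#' @export
setClass("DIFReport",
  representation(
    table = "data.frame",
    bonferroniAlpha = "numeric"
  )
)

#' Unidimensionality (principal component t-test) report
#'
#' @slot loadings named numeric vector, first-principal-component loadings
#'   of the residual correlation matrix.
#' @slot positiveSet,negativeSet character item sets split by loading sign.
#' @slot tStats numeric per-person t statistics comparing the two subset
#'   ability estimates.
#' @slot propSignificant numeric fraction of persons with |t| beyond the
#'   two-sided 5 percent bound.
#' @slot ciLower numeric lower bound of the Wilson 95 percent interval for
#'   that fraction.
#' @slot unidimensional logical verdict.
#' @slot nTested,nExcluded integer person counts.
#' @export
setClass("DimensionalityReport",
  representation(
    loadings = "numeric",
    positiveSet = "character",
    negativeSet = "character",
    tStats = "numeric",
    propSignificant = "numeric",
    ciLower = "numeric",
    unidimensional = "logical",
    nTested = "integer",
    nExcluded = "integer"
  )
)

#' Raw-to-interval score conversion table
#'
#' Maps every total raw score (complete responses over the calibrated
#' items) to the latent metric by test-characteristic-curve inversion,
#' rescaled so 0 maps to 0 and the maximum raw score to 100.
#'
#' @slot table data frame with columns raw, theta, scaled; one row per raw
#'   score 0..sum(m_i), theta and scaled strictly increasing.
#' @slot itemIds character items the table applies to.
#' @slot provenance list with calibration metadata.
#' @export
setClass("ConversionTable",
  representation(
    table = "data.frame",
    itemIds = "character",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("ConversionTable", function(object) {
  tab <- object@table
  msgs <- character()
  if (!all(c("raw", "theta", "scaled") %in% names(tab)))
    msgs <- c(msgs, "table needs raw, theta, scaled columns")
  else {
    if (!identical(as.integer(tab$raw), seq.int(0L, nrow(tab) - 1L)))
      msgs <- c(msgs, "raw scores must run contiguously from 0")
    if (any(diff(tab$theta) <= 0))
      msgs <- c(msgs, "theta must be strictly increasing in raw score")
    if (any(diff(tab$scaled) <= 0))
      msgs <- c(msgs, "scaled must be strictly increasing")
    if (abs(tab$scaled[1L]) > 1e-9 ||
        abs(tab$scaled[nrow(tab)] - 100) > 1e-9)
      msgs <- c(msgs, "scaled must anchor at 0 and 100")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic response generator configuration
#'
#' Describes a generalized partial credit generating model: person
#' abilities are normal; items have fixed thresholds and discriminations
#' (discrimination 1 for all items recovers the pure PCM); testlets add a
#' person-specific normal effect shared by member items (producing the
#' within-cluster residual correlations typical of locally dependent
#' scales); uniform DIF shifts the effective ability of one covariate
#' group on selected items; responses go missing item-wise at configured
#' rates.
#'
#' @slot nPersons integer.
#' @slot itemIds character.
#' @slot thresholds list of numeric vectors (length m_i).
#' @slot discrimination numeric vector (a_i >= 0, default 1).
#' @slot thetaMean,thetaSD numeric latent distribution parameters.
#' @slot testlets named list; each element list(items = character,
#'   sd = numeric).
#' @slot dif list of list(item, covariate, offset) entries; the offset (in
#'   logits) is subtracted from the effective ability of the covariate's
#'   second level.
#' @slot covariates named list mapping covariate names to named probability
#'   vectors over levels.
#' @slot missing numeric per-item missingness probabilities.
#' @slot optionalItems character ids marked optional in the emitted spec.
#' @slot seed integer default seed for [simulateResponses()].
#' @export
setClass("SimulationConfig",
  representation(
    nPersons = "integer",
    itemIds = "character",
    thresholds = "list",
    discrimination = "numeric",
    thetaMean = "numeric",
    thetaSD = "numeric",
    testlets = "list",
    dif = "list",
    covariates = "list",
    missing = "numeric",
    optionalItems = "character",
    seed = "integer"
  ),
  prototype(thetaMean = 0, thetaSD = 1, testlets = list(), dif = list(),
            covariates = list(), optionalItems = character(),
            seed = NA_integer_)
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  n <- length(object@itemIds)
  if (object@nPersons < 2L) msgs <- c(msgs, "nPersons must be >= 2")
  if (length(object@thresholds) != n)
    msgs <- c(msgs, "one threshold vector per item required")
  if (length(object@discrimination) != n)
    msgs <- c(msgs, "one discrimination per item required")
  else if (any(object@discrimination < 0))
    msgs <- c(msgs, "discriminations must be >= 0")
  if (object@thetaSD < 0) msgs <- c(msgs, "thetaSD must be >= 0")
  if (length(object@missing) != n)
    msgs <- c(msgs, "one missing probability per item required")
  else if (any(object@missing < 0 | object@missing > 1))
    msgs <- c(msgs, "missing probabilities must lie in [0, 1]")
  for (tl in object@testlets) {
    if (!all(tl$items %in% object@itemIds))
      msgs <- c(msgs, "testlet member not among the items")
    if (tl$sd < 0) msgs <- c(msgs, "testlet effect SD must be >= 0")
  }
  members <- unlist(lapply(object@testlets, `[[`, "items"))
  if (anyDuplicated(members))
    msgs <- c(msgs, "an item cannot sit in two testlets")
  for (d in object@dif) {
    if (!d$item %in% object@itemIds)
      msgs <- c(msgs, paste0("DIF item not among the items: ", d$item))
    if (!d$covariate %in% names(object@covariates))
      msgs <- c(msgs, paste0("DIF covariate not configured: ", d$covariate))
  }
  for (p in object@covariates) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      msgs <- c(msgs, "covariate level probabilities must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Consolidated multi-run validation report
#'
#' Output of [runValidation()]: one entry per analysis run (initial fit,
#' misfitting-person removal, testlet accommodation), each holding the
#' calibration, fit report, dependence report, DIF tables and
#' dimensionality verdict for that run, plus the conversion table built
#' from the final run.
#'
#' @slot runs list of per-run result lists.
#' @slot conversionTable a [ConversionTable-class] or \code{NULL}.
#' @slot config list of the settings the pipeline ran with.
#' @export
setClass("ValidationReport",
  representation(
    runs = "list",
    conversionTable = "ANY",
    config = "list"
  )
)
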