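#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: item and person
#' identifiers, the raw response matrix, covariates, the scale
#' specification, thresholds and locations, abilities and their standard
#' errors, and extreme-score flags.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested component; see the class documentation pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))
#' @rdname accessors
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))
#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("itemSpec", function(x) standardGeneric("itemSpec"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("itemLocations", function(x) standardGeneric("itemLocations"))
#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))
#' @rdname accessors
#' @export
setGeneric("isExtreme", function(x) standardGeneric("isExtreme"))
#' @rdname accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))
#' @rdname accessors
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' @rdname accessors
setMethod("itemIds", "ScaleSpec", function(x) x@itemIds)
#' @rdname accessors
setMethod("itemIds", "ResponseMatrix", function(x) x@spec@itemIds)
#' @rdname accessors
setMethod("itemIds", "ItemParameters", function(x) x@itemIds)
#' @rdname accessors
setMethod("itemIds", "ConversionTable", function(x) x@itemIds)
#' @rdname accessors
setMethod("personIds", "ResponseMatrix", function(x) rownames(x@responses))
#' @rdname accessors
setMethod("personIds", "PersonEstimates", function(x) x@personIds)
#' @rdname accessors
setMethod("responses", "ResponseMatrix", function(x) x@responses)
#' @rdname accessors
setMethod("covariates", "ResponseMatrix", function(x) x@covariates)
#' @rdname accessors
setMethod("itemSpec", "ResponseMatrix", function(x) x@spec)
#' @rdname accessors
setMethod("thresholds", "ItemParameters", function(x) x@thresholds)
#' @rdname accessors
setMethod("itemLocations", "ItemParameters", function(x)
  setNames(x@locations, x@itemIds))
#' @rdname accessors
setMethod("theta", "PersonEstimates", function(x)
  setNames(x@theta, x@personIds))
#' @rdname accessors
setMethod("standardErrors", "PersonEstimates", function(x)
  setNames(x@se, x@personIds))
#' @rdname accessors
setMethod("standardErrors", "ItemParameters", function(x) x@seThresholds)
#' @rdname accessors
setMethod("isExtreme", "PersonEstimates", function(x)
  setNames(x@extreme, x@personIds))
#' @rdname accessors
setMethod("nItems", "ScaleSpec", function(x) length(x@itemIds))
#' @rdname accessors
setMethod("nItems", "ResponseMatrix", function(x) ncol(x@responses))
#' @rdname accessors
setMethod("nItems", "ItemParameters", function(x) length(x@itemIds))
#' @rdname accessors
setMethod("nPersons", "ResponseMatrix", function(x) nrow(x@responses))
#' @rdname accessors
setMethod("nPersons", "PersonEstimates", function(x) length(x@personIds))

setMethod("show", "ScaleSpec", function(object) {
  cat("ScaleSpec:", length(object@itemIds), "items, categories 0..",
      paste(unique(object@maxCategory), collapse = "/"), "\n")
  if (any(object@optionalFlags))
    cat("  optional:", paste(object@itemIds[object@optionalFlags],
                             collapse = ", "), "\n")
  if (!is.null(object@testletMap))
    cat("  testlets:", paste(sprintf("%s (%d items)",
        names(object@testletMap),
        lengths(object@testletMap)), collapse = "; "), "\n")
})

setMethod("show", "ResponseMatrix", function(object) {
  r <- object@responses
  cat("ResponseMatrix:", nrow(r), "persons x", ncol(r), "items;",
      sprintf("%.1f%% missing", 100 * mean(is.na(r))), "\n")
  if (ncol(object@covariates))
    cat("  covariates:", paste(names(object@covariates), collapse = ", "),
        "\n")
})

setMethod("show", "ItemParameters", function(object) {
  cat("ItemParameters:", length(object@itemIds), "items;",
      "latent N(", sprintf("%.3f", object@latentMean), ",",
      sprintf("%.3f", object@latentSD), "^2 )\n")
  if (!is.na(object@logLik))
    cat(sprintf("  logLik %.3f after %d EM iterations (converged: %s)\n",
                object@logLik, object@iterations, object@converged))
  loc <- range(object@locations)
  cat(sprintf("  item locations in [%.3f, %.3f]\n", loc[1], loc[2]))
})

setMethod("show", "PersonEstimates", function(object) {
  cat("PersonEstimates:", length(object@personIds), "persons;",
      sum(object@extreme), "extreme\n")
  cat(sprintf("  theta mean %.3f, sd %.3f; median SE %.3f\n",
              mean(object@theta), sd(object@theta), median(object@se)))
})

setMethod("show", "ResidualMatrix", function(object) {
  cat("ResidualMatrix:", nrow(object@z), "persons x", ncol(object@z),
      "items;", length(unique(na.omit(object@classInterval))),
      "class intervals\n")
})

setMethod("show", "FitReport", function(object) {
  s <- object@summaryStats
  cat("FitReport\n")
  cat(sprintf("  item fit residual  mean %6.3f  SD %5.3f\n",
              s$meanItemFit, s$sdItemFit))
  cat(sprintf("  person fit residual mean %6.3f  SD %5.3f\n",
              s$meanPersonFit, s$sdPersonFit))
  cat(sprintf("  item-trait interaction chi^2 %.2f (df %d), p %s\n",
              object@totalChisq$chisq, object@totalChisq$df,
              format.pval(object@totalChisq$p, digits = 3)))
  cat(sprintf("  PSI %.3f; %d misfitting item(s); %d disordered item(s)\n",
              object@psi, sum(object@itemFit$flagged),
              length(object@disorderedItems)))
})

setMethod("show", "DependenceReport", function(object) {
  cat(sprintf(
    "DependenceReport: mean residual correlation %.3f, threshold %.3f\n",
    object@meanQ3, object@threshold))
  cat("  flagged pairs:", nrow(object@flaggedPairs), "\n")
})

setMethod("show", "DIFReport", function(object) {
  tab <- object@table
  cat("DIFReport:", length(unique(tab$item)), "items x",
      length(unique(tab$covariate)), "covariate(s);",
      sum(tab$uniformFlag), "uniform and",
      sum(tab$nonuniformFlag), "non-uniform DIF flag(s)\n")
})

setMethod("show", "DimensionalityReport", function(object) {
  cat(sprintf(
    "DimensionalityReport: %.2f%% significant t-tests (95%% CI lower %.2f%%)\n",
    100 * object@propSignificant, 100 * object@ciLower))
  cat("  verdict:",
      if (object@unidimensional) "unidimensional" else "multidimensional",
      "\n")
})

setMethod("show", "ConversionTable", function(object) {
  tab <- object@table
  cat("ConversionTable:", nrow(tab), "rows (raw 0..",
      max(tab$raw), "), theta in [",
      sprintf("%.3f", tab$theta[1]), ",",
      sprintf("%.3f", tab$theta[nrow(tab)]), "]\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPersons, "persons x",
      length(object@itemIds), "items\n")
  if (length(object@testlets))
    cat("  testlets:", paste(sprintf("%s (%d items, sd %.2f)",
        names(object@testlets),
        vapply(object@testlets, function(t) length(t$items), integer(1)),
        vapply(object@testlets, `[[`, numeric(1), "sd")),
        collapse = "; "), "\n")
  if (length(object@dif)) cat("  DIF entries:", length(object@dif), "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", length(object@runs), "run(s)\n")
  for (i in seq_along(object@runs)) {
    run <- object@runs[[i]]
    fr <- run$fit
    cat(sprintf(
      "  run %d (%s): n=%d, chi^2 %.2f (df %d) p %s, PSI %.3f, %s\n",
      i, run$label, run$n, fr@totalChisq$chisq, fr@totalChisq$df,
      format.pval(fr@totalChisq$p, digits = 3), fr@psi,
      if (run$dimensionality@unidimensional) "unidimensional"
      else "multidimensional"))
  }
  if (!is.null(object@conversionTable))
    cat("  conversion table:", nrow(object@conversionTable@table), "rows\n")
})
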