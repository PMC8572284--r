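#' Write a validation report to disk
#'
#' Exports every table of a [ValidationReport-class] as CSV plus a
#' machine-readable JSON index: a run summary (one row per run with fit
#' residual means/SDs, total chi-square, PSI and the t-test percentage),
#' per-run item tables (location, SE, fit residual, chi-square, p,
#' threshold ordering), residual-correlation pair listings, DIF tables, a
#' dimensionality summary, category curve data for plotting, and the
#' conversion table when one was built.
#'
#' @param report a [ValidationReport-class].
#' @param outDir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
renderReport <- function(report, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("cannot write to directory: ", outDir)
  files <- character()
  put <- function(df, name) {
    path <- file.path(outDir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  summaryRows <- lapply(seq_along(report@runs), function(i) {
    run <- report@runs[[i]]
    fr <- run$fit
    data.frame(
      run = i, analysis = run$label, n = run$n,
      itemFitMean = fr@summaryStats$meanItemFit,
      itemFitSD = fr@summaryStats$sdItemFit,
      personFitMean = fr@summaryStats$meanPersonFit,
      personFitSD = fr@summaryStats$sdPersonFit,
      chisq = fr@totalChisq$chisq, df = fr@totalChisq$df,
      p = fr@totalChisq$p, psi = fr@psi,
      pctSignificantTtests = 100 * run$dimensionality@propSignificant,
      unidimensional = run$dimensionality@unidimensional)
  })
  put(do.call(rbind, summaryRows), "run_summary.csv")

  for (i in seq_along(report@runs)) {
    run <- report@runs[[i]]
    itemTab <- run$fit@itemFit
    itemTab$orderedThresholds <-
      !itemTab$item %in% run$fit@disorderedItems
    put(itemTab, sprintf("run%d_items.csv", i))
    if (!is.null(run$dependence))
      put(run$dependence@flaggedPairs,
          sprintf("run%d_dependent_pairs.csv", i))
    if (length(run$dif))
      put(do.call(rbind, lapply(run$dif, function(d) d@table)),
          sprintf("run%d_dif.csv", i))
    dimTab <- data.frame(
      item = names(run$dimensionality@loadings),
      loading = run$dimensionality@loadings,
      set = ifelse(names(run$dimensionality@loadings) %in%
                     run$dimensionality@positiveSet, "positive",
                   "negative"))
    put(dimTab, sprintf("run%d_pc_loadings.csv", i))
    put(categoryCurves(run$items), sprintf("run%d_curves.csv", i))
  }
  if (!is.null(report@conversionTable))
    put(report@conversionTable@table, "conversion_table.csv")

  index <- list(
    runs = lapply(seq_along(report@runs), function(i) {
      run <- report@runs[[i]]
      list(run = i, label = run$label, n = run$n,
           chisq = run$fit@totalChisq$chisq,
           df = run$fit@totalChisq$df,
           p = run$fit@totalChisq$p,
           psi = run$fit@psi,
           propSignificantTtests = run$dimensionality@propSignificant,
           unidimensional = run$dimensionality@unidimensional,
           misfittingItems = run$fit@itemFit$item[run$fit@itemFit$flagged],
           disorderedItems = run$fit@disorderedItems,
           flaggedPairs = if (!is.null(run$dependence))
             nrow(run$dependence@flaggedPairs) else NA,
           removedPersons = run$removedPersons,
           testletMap = run$testletMap,
           satisfactory = run$satisfactory)
    }),
    config = report@config,
    files = basename(files))
  idx <- file.path(outDir, "index.json")
  jsonlite::write_json(index, idx, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, idx)
  invisible(files)
}
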