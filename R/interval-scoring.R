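#' Build a raw-to-interval score conversion table
#'
#' For every total raw score r over the calibrated items (complete
#' responses assumed), finds the ability whose expected total score —
#' the test characteristic curve (TCC) — equals r, by monotone root
#' finding. Extreme raw scores (0 and the maximum), whose likelihood has
#' no finite maximum, use the ability at the score adjusted inward by
#' \code{adjustment}. The theta column is then affinely rescaled so the
#' table runs exactly from 0 to 100; because the rescaling is affine, the
#' 0-100 column retains the interval-scale property of the logit metric.
#' For limitation/symptom scales under the package's sign convention, 100
#' represents the worst functional level.
#'
#' @param items an [ItemParameters-class] covering all scale items.
#' @param adjustment extreme-score adjustment (default 0.3).
#' @param tol root-finding tolerance on the score scale (default 1e-8).
#' @return a [ConversionTable-class] with sum(m_i) + 1 rows.
#' @export
buildConversionTable <- function(items, adjustment = 0.3, tol = 1e-8) {
  maxRaw <- sum(lengths(items@thresholds))
  targets <- c(adjustment, seq_len(maxRaw - 1L), maxRaw - adjustment)
  lo <- -40; hi <- 40
  theta <- vapply(targets, function(r) {
    uniroot(function(t) testCharacteristicCurve(t, items) - r,
            lower = lo, upper = hi, tol = tol)$root
  }, numeric(1))
  if (any(diff(theta) <= 0))
    stop("internal error: test characteristic curve not monotone")
  scaled <- 100 * (theta - theta[1L]) / (theta[length(theta)] - theta[1L])
  scaled[1L] <- 0
  scaled[length(scaled)] <- 100
  new("ConversionTable",
      table = data.frame(raw = 0:maxRaw, theta = theta, scaled = scaled),
      itemIds = items@itemIds,
      provenance = list(adjustment = adjustment,
                        latentMean = items@latentMean,
                        latentSD = items@latentSD))
}

#' Apply a conversion table to response data
#'
#' Looks up each person's total raw score in the table. Only persons with
#' complete responses on the table's items receive a score; incomplete
#' persons get a missing value with a warning.
#'
#' @param data a [ResponseMatrix-class] whose items match the table.
#' @param table a [ConversionTable-class].
#' @return data frame with person, raw, theta and scaled columns.
#' @export
applyConversion <- function(data, table) {
  r <- data@responses[, table@itemIds, drop = FALSE]
  complete <- rowSums(is.na(r)) == 0L
  if (any(!complete))
    warning(sum(!complete),
            " person(s) with incomplete responses: score set missing")
  raw <- rep(NA_integer_, nrow(r))
  raw[complete] <- as.integer(rowSums(r[complete, , drop = FALSE]))
  maxRaw <- max(table@table$raw)
  if (any(raw > maxRaw | raw < 0, na.rm = TRUE))
    stop("raw score outside the table range 0..", maxRaw)
  hit <- match(raw, table@table$raw)
  data.frame(person = rownames(r), raw = raw,
             theta = table@table$theta[hit],
             scaled = table@table$scaled[hit], row.names = NULL)
}

#' Export / import a conversion table as CSV
#'
#' @param table a [ConversionTable-class].
#' @param path CSV file path.
#' @return \code{path} (export) or a [ConversionTable-class] (import).
#' @export
exportConversionTable <- function(table, path) {
  tab <- table@table
  tab$items <- c(paste(table@itemIds, collapse = ";"),
                 rep("", nrow(tab) - 1L))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportConversionTable
#' @export
importConversionTable <- function(path) {
  tab <- read.csv(path, colClasses = c(items = "character"))
  ids <- strsplit(tab$items[1L], ";", fixed = TRUE)[[1L]]
  new("ConversionTable",
      table = tab[c("raw", "theta", "scaled")],
      itemIds = ids,
      provenance = list(source = path))
}
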