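#' Construct a scale specification
#'
#' @param itemIds character vector of unique item identifiers.
#' @param maxCategory integer, maximum 0-based category code per item
#'   (recycled if scalar). A five-category item has \code{maxCategory = 4}.
#' @param optionalFlags logical per item (recycled); optional items may be
#'   dropped wholesale (see [dropItem()]) when heavily missing.
#' @param categoryLabels optional list of character vectors, length
#'   m_i + 1 each.
#' @param testletMap optional named list of item-id vectors defining
#'   testlets (super-items) for [collapseTestlets()].
#' @return a [ScaleSpec-class].
#' @examples
#' sp <- scaleSpec(paste0("item", 1:5), maxCategory = 4)
#' @export
scaleSpec <- function(itemIds, maxCategory, optionalFlags = FALSE,
                      categoryLabels = list(), testletMap = NULL) {
  n <- length(itemIds)
  new("ScaleSpec",
      itemIds = as.character(itemIds),
      maxCategory = as.integer(rep_len(maxCategory, n)),
      optionalFlags = rep_len(as.logical(optionalFlags), n),
      categoryLabels = categoryLabels,
      testletMap = testletMap)
}

#' Construct a response matrix from values already in 0-based coding
#'
#' @param values numeric/integer matrix, persons in rows, items in columns;
#'   \code{NA} marks a missing response. Row and column names are used as
#'   person and item ids (defaults are generated when absent).
#' @param spec a [ScaleSpec-class]; built from the matrix dimensions when
#'   omitted (all items share \code{maxCategory}).
#' @param covariates optional data frame of per-person factors.
#' @param maxCategory used only when \code{spec} is omitted (default 4).
#' @details Objects support \code{data[i, j]} subsetting of persons
#'   (\code{i}) and items (\code{j}); the spec and covariates are subset
#'   consistently.
#' @return a [ResponseMatrix-class].
#' @rawNamespace exportMethods("[")
#' @export
responseMatrix <- function(values, spec = NULL, covariates = NULL,
                           maxCategory = 4L) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(spec)) {
    if (is.null(colnames(values)))
      colnames(values) <- sprintf("item%02d", seq_len(ncol(values)))
    spec <- scaleSpec(colnames(values), maxCategory)
  } else {
    if (is.null(colnames(values))) colnames(values) <- spec@itemIds
    values <- values[, spec@itemIds, drop = FALSE]
  }
  storage.mode(values) <- "integer"
  if (is.null(covariates))
    covariates <- data.frame(row.names = rownames(values))
  else {
    covariates <- as.data.frame(covariates)
    rownames(covariates) <- rownames(values)
  }
  new("ResponseMatrix", responses = values, spec = spec,
      covariates = covariates)
}

#' Read item responses from a delimited text file
#'
#' Reads a CSV/TSV file with one row per person, validates every response
#' against the scale specification, recodes to the internal 0-based
#' categories and marks empty cells (or a sentinel) as missing. Responses
#' are never imputed. Columns that are neither the person id nor a scale
#' item are kept as covariates.
#'
#' @param path file path.
#' @param spec a [ScaleSpec-class].
#' @param idColumn name of the person-id column (default \code{"person"}).
#' @param baseCategory the code the file uses for the lowest category
#'   (default 1, as printed on many questionnaires; use 0 for files already
#'   0-based). Internally responses are stored as 0..m_i.
#' @param naStrings values treated as missing in addition to empty cells.
#' @param sep field separator, inferred from the extension when \code{NULL}.
#' @return a [ResponseMatrix-class].
#' @examples
#' sp <- scaleSpec(c("i1", "i2"), 4)
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("person,i1,i2", "A,1,5", "B,3,"), f)
#' rm <- readResponses(f, sp)
#' responses(rm)   # A: 0, 4;  B: 2, NA
#' @export
readResponses <- function(path, spec, idColumn = "person",
                          baseCategory = 1L, naStrings = c("", "NA"),
                          sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 na.strings = naStrings, colClasses = "character",
                 strip.white = TRUE)
  if (!idColumn %in% names(df))
    stop("person id column '", idColumn, "' not found in ", path)
  missingItems <- setdiff(spec@itemIds, names(df))
  if (length(missingItems))
    stop("file lacks item column(s): ", paste(missingItems, collapse = ", "))
  ids <- df[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate person id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_integer_, nrow(df), length(spec@itemIds),
                 dimnames = list(ids, spec@itemIds))
  for (i in seq_along(spec@itemIds)) {
    item <- spec@itemIds[i]
    raw <- df[[item]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("person '%s', item '%s': non-numeric response '%s'",
                   ids[bad[1L]], item, raw[bad[1L]]))
    code <- num - baseCategory
    out <- which(!is.na(code) & (code < 0 | code > spec@maxCategory[i] |
                                   code != round(code)))
    if (length(out))
      stop(sprintf(
        "person '%s', item '%s': response '%s' outside the valid range %d..%d",
        ids[out[1L]], item, raw[out[1L]], baseCategory,
        baseCategory + spec@maxCategory[i]))
    vals[, i] <- as.integer(code)
  }
  covCols <- setdiff(names(df), c(idColumn, spec@itemIds))
  cov <- if (length(covCols))
    data.frame(lapply(df[covCols], factor), row.names = ids,
               check.names = FALSE)
  else data.frame(row.names = ids)
  new("ResponseMatrix", responses = vals, spec = spec, covariates = cov)
}

#' Write a response matrix back to delimited text
#'
#' Inverse of [readResponses()]: responses are re-coded to the file's
#' category base and missing cells written empty, so a read/write/read
#' cycle is lossless.
#'
#' @param data a [ResponseMatrix-class].
#' @param path output file path.
#' @param idColumn,baseCategory,sep as in [readResponses()].
#' @return \code{path}, invisibly.
#' @export
writeResponses <- function(data, path, idColumn = "person",
                           baseCategory = 1L, sep = ",") {
  out <- as.data.frame(data@responses + baseCategory)
  out <- cbind(setNames(data.frame(rownames(data@responses),
                                   stringsAsFactors = FALSE), idColumn),
               out, data@covariates)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read a scale specification from YAML or JSON
#'
#' The document must contain \code{item_ids} and \code{max_category}
#' (scalar or per item) and may contain \code{optional_items},
#' \code{category_labels} and \code{testlets} (name to item-id list).
#'
#' @param path file path; format chosen by extension
#'   (\code{.yaml}/\code{.yml} vs \code{.json}).
#' @return a [ScaleSpec-class].
#' @export
readScaleSpec <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$item_ids) || is.null(doc$max_category))
    stop("scale spec needs 'item_ids' and 'max_category'")
  ids <- as.character(doc$item_ids)
  optional <- ids %in% as.character(doc$optional_items %||% character())
  testlets <- if (!is.null(doc$testlets))
    lapply(doc$testlets, as.character)
  scaleSpec(ids, doc$max_category, optional,
            categoryLabels = doc$category_labels %||% list(),
            testletMap = testlets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop an item from a response matrix
#'
#' Removes one item (e.g. an optional item answered too rarely to
#' calibrate) leaving all other responses untouched.
#'
#' @param data a [ResponseMatrix-class].
#' @param itemId the item to remove.
#' @return a [ResponseMatrix-class] without the item.
#' @export
dropItem <- function(data, itemId) {
  sp <- data@spec
  idx <- match(itemId, sp@itemIds)
  if (is.na(idx)) stop("unknown item id: ", itemId)
  if (ncol(data@responses) <= 2L)
    stop("cannot drop '", itemId, "': at least 2 items must remain")
  keepSpec <- scaleSpec(sp@itemIds[-idx], sp@maxCategory[-idx],
                        sp@optionalFlags[-idx],
                        if (length(sp@categoryLabels))
                          sp@categoryLabels[-idx] else list(),
                        testletMap = if (!is.null(sp@testletMap))
                          lapply(sp@testletMap, setdiff, y = itemId))
  new("ResponseMatrix",
      responses = data@responses[, -idx, drop = FALSE],
      spec = keepSpec, covariates = data@covariates)
}

#' Classic (summary) scale scoring on the 0-100 metric
#'
#' The conventional summary score: the mean of the answered 0-based item
#' codes times 25 (equivalently, on 1..5 printed codes, subtract 1 from
#' the mean item score and multiply by 25), prorated over answered items.
#' Persons missing more than \code{maxMissingFraction} of the items get a
#' missing score.
#'
#' @param data a [ResponseMatrix-class].
#' @param maxMissingFraction largest tolerated fraction of missing items
#'   (default 0.1, the instrument's customary rule of thumb).
#' @return named numeric vector of scores in \code{[0, 100]} (\code{NA}
#'   where too much is missing).
#' @export
classicScore <- function(data, maxMissingFraction = 0.1) {
  r <- data@responses
  missFrac <- rowMeans(is.na(r))
  score <- rowMeans(r, na.rm = TRUE) * 25
  score[missFrac > maxMissingFraction] <- NA_real_
  setNames(score, rownames(r))
}

# Subset persons (i) and/or items (j) with bracket syntax; the spec and
# covariates are subset consistently. Exported via the responseMatrix doc
# block's rawNamespace directive.
setMethod("[", "ResponseMatrix", function(x, i, j, ..., drop = FALSE) {
  r <- x@responses
  if (missing(i)) i <- seq_len(nrow(r))
  if (missing(j)) j <- seq_len(ncol(r))
  jIdx <- if (is.character(j)) match(j, colnames(r)) else
    seq_len(ncol(r))[j]
  sp <- x@spec
  newSpec <- scaleSpec(sp@itemIds[jIdx], sp@maxCategory[jIdx],
                       sp@optionalFlags[jIdx],
                       if (length(sp@categoryLabels))
                         sp@categoryLabels[jIdx] else list())
  new("ResponseMatrix",
      responses = r[i, jIdx, drop = FALSE],
      spec = newSpec,
      covariates = x@covariates[i, , drop = FALSE])
})

#' Collapse testlets into super-items
#'
#' Sums the member items of each testlet into one polytomous super-item
#' (maximum category = sum of member maxima), absorbing their shared
#' variance so the partial credit model can be re-fitted at testlet level.
#' A person's super-item score is defined only when every member item was
#' answered; non-testlet items pass through unchanged.
#'
#' @param data a [ResponseMatrix-class].
#' @param testletMap named list of item-id vectors; defaults to the map
#'   stored in the scale specification.
#' @return a [ResponseMatrix-class] with one column per super-item followed
#'   by the untouched items.
#' @export
collapseTestlets <- function(data, testletMap = NULL) {
  sp <- data@spec
  if (is.null(testletMap)) testletMap <- sp@testletMap
  if (is.null(testletMap) || !length(testletMap))
    stop("no testlet map available: supply one or store it in the spec")
  testletMap <- lapply(testletMap, as.character)
  bad <- setdiff(unlist(testletMap), sp@itemIds)
  if (length(bad))
    stop("testlet members not in the data: ", paste(bad, collapse = ", "))
  r <- data@responses
  cols <- list()
  maxCat <- integer()
  for (tn in names(testletMap)) {
    members <- testletMap[[tn]]
    sub <- r[, members, drop = FALSE]
    val <- rowSums(sub)                    # NA if any member missing
    cols[[tn]] <- as.integer(val)
    maxCat[tn] <- sum(sp@maxCategory[match(members, sp@itemIds)])
  }
  rest <- setdiff(sp@itemIds, unlist(testletMap))
  for (it in rest) {
    cols[[it]] <- r[, it]
    maxCat[it] <- sp@maxCategory[match(it, sp@itemIds)]
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- rownames(r)
  newSpec <- scaleSpec(names(cols), maxCat,
                       optionalFlags = c(
                         rep(FALSE, length(testletMap)),
                         sp@optionalFlags[match(rest, sp@itemIds)]))
  new("ResponseMatrix", responses = vals, spec = newSpec,
      covariates = data@covariates)
}
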