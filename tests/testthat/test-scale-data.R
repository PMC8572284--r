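test_that("readResponses recodes 1-based categories, keeps missing, and validates", {
  f <- writeTinyResponseFile()
  rm <- readResponses(f, tinySpec())
  expect_identical(unname(responses(rm)["A", ]), c(0L, 2L, 4L))
  expect_true(is.na(responses(rm)["B", "i2"]))
  expect_false(any(responses(rm)["B", c("i1", "i3")] == 0L))
  expect_identical(levels(covariates(rm)$sex), c("female", "male"))

  # out-of-range value names the offending cell
  bad <- tempfile(fileext = ".csv")
  writeLines(c("person,i1,i2,i3", "A,1,7,2"), bad)
  expect_error(readResponses(bad, tinySpec()), "A.*i2.*7")

  # duplicate person ids rejected
  dup <- tempfile(fileext = ".csv")
  writeLines(c("person,i1,i2,i3", "A,1,1,1", "A,2,2,2"), dup)
  expect_error(readResponses(dup, tinySpec()), "duplicate")
})

test_that("read -> write -> read round-trips exactly", {
  f <- writeTinyResponseFile()
  rm1 <- readResponses(f, tinySpec())
  f2 <- tempfile(fileext = ".csv")
  writeResponses(rm1, f2)
  rm2 <- readResponses(f2, tinySpec())
  expect_identical(responses(rm1), responses(rm2))
  expect_identical(covariates(rm1)$sex, covariates(rm2)$sex)
})

test_that("scale spec documents load from YAML and JSON", {
  fy <- tempfile(fileext = ".yaml")
  writeLines(c(
    "item_ids: [i1, i2, i3, i4]",
    "max_category: 4",
    "optional_items: [i3]",
    "testlets:",
    "  left: [i1, i2]",
    "  right: [i3, i4]"), fy)
  sp <- readScaleSpec(fy)
  expect_identical(itemIds(sp), c("i1", "i2", "i3", "i4"))
  expect_identical(sp@optionalFlags, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(sp@testletMap$left, c("i1", "i2"))

  fj <- tempfile(fileext = ".json")
  writeLines('{"item_ids": ["a", "b"], "max_category": [2, 3]}', fj)
  spj <- readScaleSpec(fj)
  expect_identical(spj@maxCategory, c(2L, 3L))
})

test_that("dropItem removes exactly one item and errors on unknown ids", {
  sim <- simulateResponses(dashLikePreset(nPersons = 40, seed = 5))
  d <- sim$data
  expect_identical(ncol(responses(d)), 30L)
  d29 <- dropItem(d, "item21")
  expect_identical(ncol(responses(d29)), 29L)
  expect_false("item21" %in% itemIds(d29))
  expect_identical(responses(d29), responses(d)[, itemIds(d29)])
  # maximum attainable raw total over the remaining items
  expect_identical(sum(itemSpec(d29)@maxCategory), 116L)
  expect_error(dropItem(d, "item99"), "item99")
})

test_that("classicScore maps mean item codes onto 0-100 and honours the missing cap", {
  vals <- rbind(low = rep(0L, 10), high = rep(4L, 10),
                half = c(rep(2L, 5), rep(NA, 5)),
                one = c(NA, rep(2L, 9)))
  rm <- responseMatrix(vals)
  sc <- classicScore(rm, maxMissingFraction = 0.1)
  expect_equal(unname(sc["low"]), 0)
  expect_equal(unname(sc["high"]), 100)
  expect_true(is.na(sc["half"]))          # 50% missing > 10% cap
  expect_equal(unname(sc["one"]), 50)     # prorated over answered items

  # invariance to item order; linear in the mean code with slope 25
  shuf <- rm[, sample(colnames(responses(rm)))]
  expect_equal(classicScore(shuf), sc)
  mixed <- responseMatrix(rbind(p = c(1L, 3L, 2L, 0L, 4L),
                                q = c(0L, 0L, 0L, 0L, 0L)))
  expect_equal(unname(classicScore(mixed)["p"]), mean(c(1, 3, 2, 0, 4)) * 25)
})

test_that("collapseTestlets builds super-items preserving totals and missingness", {
  vals <- rbind(a = c(3L, 4L, 2L, 1L),
                b = c(0L, NA, 1L, 2L))
  colnames(vals) <- c("i1", "i2", "i3", "i4")
  rm <- responseMatrix(vals)
  coll <- collapseTestlets(rm, list(T1 = c("i1", "i2")))
  expect_identical(itemIds(coll), c("T1", "i3", "i4"))
  expect_identical(unname(responses(coll)["a", "T1"]), 7L)
  expect_identical(itemSpec(coll)@maxCategory[match("T1", itemIds(coll))],
                   8L)
  expect_true(is.na(responses(coll)["b", "T1"]))
  # totals over covered items preserved exactly for complete persons
  expect_identical(sum(responses(coll)["a", ]), sum(vals["a", ]))

  # DASH-style two-testlet collapse: 80 + 36 super-item maxima
  sim <- simulateResponses(dashLikePreset(nPersons = 40, seed = 5))
  d29 <- dropItem(sim$data, "item21")
  c2 <- collapseTestlets(d29)
  expect_identical(unname(itemSpec(c2)@maxCategory),
                   c(80L, 36L))
  complete <- !is.na(rowSums(responses(d29)))
  expect_identical(rowSums(responses(c2))[complete],
                   rowSums(responses(d29))[complete])
})
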