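test_that("conversion table anchors, row count, and monotonicity", {
  sim <- simFixture(n = 600, items = 6, seed = 71)
  fit <- estimateItems(sim$data)
  tab <- buildConversionTable(fit)
  t <- tab@table
  expect_identical(nrow(t), 25L)               # 6 items x 4 + 1
  expect_identical(t$scaled[1], 0)
  expect_identical(t$scaled[25], 100)
  expect_true(all(diff(t$theta) > 0))
  expect_true(all(diff(t$scaled) > 0))
  # affine relation between theta and scaled columns
  fitLm <- lm(scaled ~ theta, data = t)
  expect_lt(max(abs(residuals(fitLm))), 1e-6)
  expect_gt(coef(fitLm)[2], 0)
  # single symmetric item: the centre raw score maps to theta 0
  one <- itemParameters(list(s = c(0, 0, 0, 0)))
  tabOne <- buildConversionTable(one)
  expect_equal(tabOne@table$theta[tabOne@table$raw == 2], 0,
               tolerance = 1e-7)
})

test_that("TCC inversion is self-consistent", {
  sim <- simFixture(n = 600, items = 6, seed = 72)
  fit <- estimateItems(sim$data)
  tab <- buildConversionTable(fit)
  t <- tab@table
  interior <- t$raw > 0 & t$raw < max(t$raw)
  back <- testCharacteristicCurve(t$theta[interior], fit)
  expect_lt(max(abs(back - t$raw[interior])), 0.5)
})

test_that("applyConversion keys on the raw total and guards missingness", {
  sim <- simFixture(n = 50, items = 6, seed = 73)
  fit <- estimateItems(sim$data)
  tab <- buildConversionTable(fit)
  sc <- applyConversion(sim$data, tab)
  x <- responses(sim$data)
  # two persons with equal totals but different patterns score identically
  tot <- rowSums(x)
  twins <- which(duplicated(tot) & !is.na(tot))[1]
  if (!is.na(twins)) {
    mate <- which(tot == tot[twins])[1]
    expect_identical(sc$scaled[twins], sc$scaled[mate])
  }
  # raw 0 person maps to exactly 0
  x0 <- x
  x0[1, ] <- 0L
  sc0 <- applyConversion(responseMatrix(x0), tab)
  expect_identical(sc0$scaled[1], 0)
  # a person with a missing item gets a missing score, with warning
  xm <- x
  xm[2, 3] <- NA_integer_
  expect_warning(scm <- applyConversion(responseMatrix(xm), tab),
                 "incomplete")
  expect_true(is.na(scm$scaled[2]))
})

test_that("conversion table CSV export round-trips", {
  sim <- simFixture(n = 300, items = 5, seed = 74)
  fit <- estimateItems(sim$data)
  tab <- buildConversionTable(fit)
  f <- tempfile(fileext = ".csv")
  exportConversionTable(tab, f)
  back <- importConversionTable(f)
  expect_equal(back@table$theta, tab@table$theta, tolerance = 1e-10)
  expect_identical(back@itemIds, tab@itemIds)
})
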