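test_that("categoryProbs matches the closed form and sums to one", {
  # symmetric item: all categories equally likely at theta 0
  expect_equal(drop(categoryProbs(0, c(0, 0, 0, 0))), rep(0.2, 5))
  # direct evaluation of the closed form for thresholds (-1, 1)
  e <- exp(1)
  expect_equal(drop(categoryProbs(0, c(-1, 1))),
               c(1, e, 1) / (2 + e), tolerance = 1e-12)
  # mass migrates to the top category as theta grows
  expect_gt(categoryProbs(30, c(0, 0, 0, 0))[1, 5], 1 - 1e-9)
  # probabilities sum to 1 for random draws
  set.seed(42)
  for (r in 1:200) {
    p <- categoryProbs(rnorm(5, 0, 3), sort(rnorm(4, 0, 2)))
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_true(all(p >= 0))
  }
})

test_that("expectedScore is monotone with correct limits", {
  expect_equal(expectedScore(0, c(0, 0, 0, 0)), 2)
  expect_lt(expectedScore(-30, c(0, 0, 0, 0)), 1e-9)
  set.seed(7)
  for (r in 1:20) {
    d <- sort(rnorm(4, 0, 1.5))
    th <- rnorm(1, 0, 2)
    expect_gt(expectedScore(th + 1, d), expectedScore(th, d))
  }
})

test_that("scoreVariance equals the derivative of the expected score", {
  expect_equal(scoreVariance(0, c(0, 0, 0, 0)), 2)
  expect_lt(scoreVariance(35, c(0, 0, 0, 0)), 1e-9)
  set.seed(11)
  for (r in 1:20) {
    d <- sort(rnorm(sample(2:5, 1), 0, 1.5))
    th <- rnorm(1, 0, 2)
    h <- 1e-5
    dEdtheta <- (expectedScore(th + h, d) - expectedScore(th - h, d)) / (2 * h)
    expect_equal(scoreVariance(th, d), dEdtheta, tolerance = 1e-6)
  }
})

test_that("estimateItems recovers known thresholds and honours invariances", {
  sim <- simFixture(n = 1000, items = 10, seed = 31)
  fit <- estimateItems(sim$data)
  expect_true(fit@converged)
  # identification: item locations average to zero
  expect_lt(abs(mean(itemLocations(fit))), 1e-8)
  # recovery of the generating thresholds
  rmse <- sqrt(mean((unlist(thresholds(fit)) -
                       unlist(sim$truth$thresholds))^2))
  expect_lt(rmse, 0.15)
  # permutation invariance over persons
  perm <- sample(nrow(responses(sim$data)))
  fit2 <- estimateItems(sim$data[perm, ])
  expect_equal(thresholds(fit2), thresholds(fit), tolerance = 1e-6)
  # item-order invariance up to reordering
  ord <- rev(itemIds(sim$data))
  fit3 <- estimateItems(sim$data[, ord])
  expect_equal(thresholds(fit3)[itemIds(fit)], thresholds(fit),
               tolerance = 1e-4)
})

test_that("estimateItems rejects single-category items", {
  vals <- cbind(i1 = rep(2L, 30), i2 = sample(0:4, 30, TRUE))
  rownames(vals) <- sprintf("P%02d", 1:30)
  expect_error(estimateItems(responseMatrix(vals)), "i1")
})

test_that("estimatePersons recovers abilities, ties, and symmetry", {
  sim <- simFixture(n = 1000, items = 10, seed = 32)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  expect_gt(cor(pers@theta, sim$truth$theta), 0.9)
  # identical response vectors give identical estimates
  x <- responses(sim$data)
  dup <- which(duplicated(apply(x, 1, paste, collapse = ",")))[1]
  if (!is.na(dup)) {
    twin <- which(apply(x, 1, paste, collapse = ",") ==
                    paste(x[dup, ], collapse = ","))[1]
    expect_equal(pers@theta[dup], pers@theta[twin], tolerance = 1e-9)
  }
  # symmetric items: scoring the expected score at theta 0 lands near 0
  flat <- itemParameters(list(a = c(-1, 0, 1) * 0, b = c(0, 0, 0)))
  v <- cbind(a = c(1L, 1L), b = c(2L, 1L))  # person 1: raw 3 of 6 (centre)
  rownames(v) <- c("mid", "low")
  est <- estimatePersons(responseMatrix(v, maxCategory = 3), flat)
  expect_lt(abs(theta(est)[["mid"]]), 1e-6)
  # extreme scores are flagged and finite
  ve <- cbind(a = c(0L, 3L), b = c(0L, 3L))
  rownames(ve) <- c("zero", "top")
  ee <- estimatePersons(responseMatrix(ve, maxCategory = 3), flat)
  expect_true(all(ee@extreme))
  expect_true(all(is.finite(ee@theta)))
  expect_lt(theta(ee)[["zero"]], 0)
  expect_gt(theta(ee)[["top"]], 0)
})

test_that("item parameter CSV export round-trips", {
  sim <- simFixture(n = 200, items = 4, seed = 33)
  fit <- estimateItems(sim$data)
  f <- tempfile(fileext = ".csv")
  exportItemParameters(fit, f)
  back <- importItemParameters(f)
  expect_equal(thresholds(back), thresholds(fit), tolerance = 1e-12)
  expect_equal(back@latentSD, fit@latentSD, tolerance = 1e-12)
})
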