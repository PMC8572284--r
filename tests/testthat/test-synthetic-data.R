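test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(nPersons = 100, nItems = 5, seed = 7,
                          covariates = list(g = c(A = 0.5, B = 0.5)),
                          missing = 0.1)
  a <- simulateResponses(cfg)
  b <- simulateResponses(cfg)
  expect_identical(responses(a$data), responses(b$data))
  expect_identical(a$truth$theta, b$truth$theta)
  expect_identical(covariates(a$data)$g, covariates(b$data)$g)
})

test_that("category frequencies follow the closed form at scale", {
  cfg <- simulationConfig(nPersons = 50000, nItems = 2,
                          thresholds = list(i1 = c(0, 0, 0, 0),
                                            i2 = c(0, 0, 0, 0)),
                          thetaSD = 0, seed = 8)
  sim <- simulateResponses(cfg)
  freq <- tabulate(responses(sim$data)[, 1] + 1L, 5) / 50000
  expect_true(all(abs(freq - 0.2) < 0.005))
})

test_that("zero-variance configs give exchangeable persons", {
  cfg <- simulationConfig(nPersons = 4000,
                          thresholds = list(i = c(-0.5, 0, 0.5, 1),
                                            j = c(-0.5, 0, 0.5, 1)),
                          thetaSD = 0, seed = 9)
  sim <- simulateResponses(cfg)
  x <- responses(sim$data)[, 1]
  half <- seq_len(2000)
  tab <- rbind(tabulate(x[half] + 1L, 5), tabulate(x[-half] + 1L, 5))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("invalid configurations fail before sampling", {
  expect_error(simulationConfig(nPersons = 100, nItems = 3,
                                discrimination = -1), "discrimination")
  expect_error(simulationConfig(nPersons = 100, nItems = 3,
                                missing = 1.5), "missing")
  expect_error(simulationConfig(nPersons = 100, nItems = 3,
    dif = list(list(item = "item09", covariate = "g", offset = 1)),
    covariates = list(g = c(A = 0.5, B = 0.5))), "item09")
})

test_that("the DASH-like preset mirrors the instrument's structure", {
  cfg <- dashLikePreset(seed = 10)
  expect_identical(length(cfg@itemIds), 30L)
  expect_identical(cfg@nPersons, 109L)
  expect_identical(cfg@optionalItems, "item21")
  expect_equal(cfg@missing[21], 0.54)
  expect_identical(cfg@testlets$activity$items, sprintf("item%02d", 1:20))
  expect_identical(cfg@testlets$impairment$items, sprintf("item%02d", 22:30))
  sim <- simulateResponses(cfg)
  expect_identical(ncol(responses(sim$data)), 30L)
  d29 <- dropItem(sim$data, "item21")
  expect_identical(ncol(responses(d29)), 29L)
  # emitted CSV dialect reads back identically through scale_data
  f <- tempfile(fileext = ".csv")
  writeResponses(sim$data, f)
  back <- readResponses(f, itemSpec(sim$data))
  expect_identical(responses(back), responses(sim$data))
})
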