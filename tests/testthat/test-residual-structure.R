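test_that("a duplicated item yields the maximal residual correlation", {
  sim <- simFixture(n = 400, items = 6, seed = 61)
  x <- responses(sim$data)
  x <- cbind(x, item07 = x[, "item01"])  # response dependency by copy
  d <- responseMatrix(x)
  fit <- estimateItems(d)
  pers <- estimatePersons(d, fit)
  res <- standardizedResiduals(d, fit, pers)
  dep <- residualCorrelations(res)
  q <- dep@q3; diag(q) <- NA
  peak <- which(q == max(q, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_setequal(colnames(q)[peak], c("item01", "item07"))
  expect_true(nrow(dep@flaggedPairs) >= 1)
  expect_identical(dep@flaggedPairs$correlation,
                   sort(dep@flaggedPairs$correlation, decreasing = TRUE))
  # q3 symmetric, invariant to person order
  perm <- sample(nrow(x))
  res2 <- standardizedResiduals(d[perm, ], fit,
                                estimatePersons(d[perm, ], fit))
  dep2 <- residualCorrelations(res2)
  expect_equal(dep2@q3, dep@q3, tolerance = 1e-10)
})

test_that("planted testlets dominate the flagged-pair list", {
  th <- lapply(seq(-0.8, 0.8, length.out = 20),
               function(l) l + c(-1, -1 / 3, 1 / 3, 1))
  names(th) <- sprintf("item%02d", 1:20)
  # pool flagged pairs over replicate datasets of the same planted design
  fp <- do.call(rbind, lapply(1:3, function(r) {
    cfg <- simulationConfig(nPersons = 1000, thresholds = th,
      testlets = list(A = list(items = sprintf("item%02d", 1:5), sd = 0.6),
                      B = list(items = sprintf("item%02d", 6:10), sd = 0.6)),
      seed = 620 + r)
    sim <- simulateResponses(cfg)
    fit <- estimateItems(sim$data)
    pers <- estimatePersons(sim$data, fit)
    res <- standardizedResiduals(sim$data, fit, pers)
    residualCorrelations(res)@flaggedPairs
  }))
  expect_gt(nrow(fp), 0)
  tl <- function(x) {
    n <- as.integer(substr(x, 5, 6))
    ifelse(n <= 5, "A", ifelse(n <= 10, "B", "-"))
  }
  within <- tl(fp$item1) == tl(fp$item2) & tl(fp$item1) != "-"
  expect_gt(mean(within), 0.8)
})

test_that("DIF ANOVA flags a planted uniform shift and stays quiet under permutation", {
  cfg <- simulationConfig(nPersons = 1000, nItems = 10,
    covariates = list(grp = c(A = 0.5, B = 0.5)),
    dif = list(list(item = "item05", covariate = "grp", offset = 0.8)),
    seed = 63)
  sim <- simulateResponses(cfg)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  res <- standardizedResiduals(sim$data, fit, pers)
  rep1 <- difAnova(res, sim$data, "grp")
  expect_true(rep1@table$uniformFlag[rep1@table$item == "item05"])
  # permuting the group labels kills the signal (p-values near-uniform)
  d2 <- sim$data
  set.seed(64)
  d2@covariates$grp <- sample(d2@covariates$grp)
  rep2 <- difAnova(res, d2, "grp")
  expect_false(any(rep2@table$uniformFlag))
  ks <- suppressWarnings(ks.test(rep2@table$uniformP, "punif"))
  expect_gt(ks$p.value, 0.01)
  # single-level covariate rejected
  d3 <- sim$data
  d3@covariates$grp <- factor(rep("A", nrow(responses(d3))))
  expect_error(difAnova(res, d3, "grp"), "2 levels")
})

test_that("unidimensionality t-test separates one- and two-factor data", {
  # strictly unidimensional: proportion significant within the 5% rule
  sim1 <- simFixture(n = 500, items = 20, seed = 65)
  f1 <- estimateItems(sim1$data)
  p1 <- estimatePersons(sim1$data, f1)
  r1 <- standardizedResiduals(sim1$data, f1, p1)
  d1 <- unidimensionalityTtest(r1, sim1$data, f1)
  expect_true(d1@unidimensional)
  # two factors correlated 0.4 (bifactor equivalent): detected
  cfg2 <- simulationConfig(nPersons = 500, nItems = 20,
    thetaSD = sqrt(0.4),
    testlets = list(F1 = list(items = sprintf("item%02d", 1:10),
                              sd = sqrt(0.6)),
                    F2 = list(items = sprintf("item%02d", 11:20),
                              sd = sqrt(0.6))),
    seed = 66)
  sim2 <- simulateResponses(cfg2)
  f2 <- estimateItems(sim2$data)
  p2 <- estimatePersons(sim2$data, f2)
  r2 <- standardizedResiduals(sim2$data, f2, p2)
  d2 <- unidimensionalityTtest(r2, sim2$data, f2)
  expect_false(d2@unidimensional)
  # the loading split recovers the planted factors
  inF1 <- sprintf("item%02d", 1:10)
  splitSets <- list(d2@positiveSet, d2@negativeSet)
  agree <- max(vapply(splitSets, function(s)
    length(intersect(s, inF1)), numeric(1)))
  expect_gte(agree, 9)
})

test_that("identical subset estimates give zero significant t-tests", {
  est <- new("PersonEstimates", personIds = sprintf("P%02d", 1:20),
             theta = rnorm(20), se = rep(0.4, 20),
             extreme = rep(FALSE, 20), rawScore = rep(5, 20),
             nObserved = rep(10L, 20))
  tt <- (est@theta - est@theta) / sqrt(est@se^2 + est@se^2)
  expect_identical(mean(abs(tt) > qnorm(0.975)), 0)
})

test_that("shared variance is 1 for identical estimates and high for one factor", {
  sim <- simFixture(n = 1000, items = 20, seed = 67)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  expect_equal(sharedVariance(pers, pers), 1)
  # two testlet-style halves driven by one latent factor
  ids <- itemIds(sim$data)
  xa <- responses(sim$data)[, ids[1:10]]
  xb <- responses(sim$data)[, ids[11:20]]
  estA <- estimatePersons(responseMatrix(xa), subsetItems(fit, ids[1:10]))
  estB <- estimatePersons(responseMatrix(xb), subsetItems(fit, ids[11:20]))
  expect_gt(sharedVariance(estA, estB), 0.9)
  short <- new("PersonEstimates", personIds = sprintf("Q%d", 1:5),
               theta = rnorm(5), se = rep(0.5, 5),
               extreme = rep(FALSE, 5), rawScore = rep(1, 5),
               nObserved = rep(2L, 5))
  expect_error(sharedVariance(short, short), "10")
})
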