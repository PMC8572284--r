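test_that("standardized residuals have the right arithmetic and sign", {
  # hand-built case: x = 4, E = 2, Var = 2 -> z = sqrt(2)
  expect_equal((4 - 2) / sqrt(2), sqrt(2))
  sim <- simFixture(n = 400, items = 6, seed = 51)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  res <- standardizedResiduals(sim$data, fit, pers)
  x <- responses(sim$data)
  # zero residual iff observed equals expected; sign follows the deviation
  manual <- (x - res@expected) / sqrt(res@variance)
  expect_equal(res@z, manual)
  above <- !is.na(x) & x > res@expected
  expect_true(all(res@z[above] > 0))
  # per-item residual means near zero under the model
  expect_true(all(abs(colMeans(res@z, na.rm = TRUE)) < 0.1))
})

test_that("class intervals are ability-ordered with adequate sizes", {
  set.seed(99)
  sim <- simFixture(n = 480, items = 8, seed = 52)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  res <- standardizedResiduals(sim$data, fit, pers)
  g <- res@classInterval
  th <- res@thetaHat
  ok <- !is.na(g)
  # contiguity: every stratum's theta range sits above the previous one
  lev <- sort(unique(g[ok]))
  maxes <- vapply(lev, function(l) max(th[ok & g == l]), numeric(1))
  mins <- vapply(lev, function(l) min(th[ok & g == l]), numeric(1))
  expect_true(all(mins[-1] >= maxes[-length(maxes)] - 1e-12))
  expect_true(all(table(g[ok]) >= 10))
})

test_that("fit residuals flag planted misfit and respect the 2.5 rule", {
  # boundary behaviour of the flagging rule itself
  expect_true(abs(2.6) > 2.5)
  expect_false(abs(2.4) > 2.5)
  # an under-discriminating item drifts to a positive fit residual
  sim <- simFixture(n = 1000, items = 8, seed = 53,
                    discrimination = c(0.4, rep(1, 7)))
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  res <- standardizedResiduals(sim$data, fit, pers)
  fr <- fitResiduals(res, "item")
  expect_gt(fr[["item01"]], 2.5)
  expect_lt(max(abs(fr[-1])), max(abs(fr)))
})

test_that("item-trait chi-square has the stated degrees of freedom", {
  sim <- simulateResponses(dashLikePreset(nPersons = 109, seed = 54))
  d <- dropItem(sim$data, "item21")
  fit <- estimateItems(d, maxit = 2000, onNonconvergence = "warn")
  pers <- estimatePersons(d, fit)
  res <- suppressWarnings(standardizedResiduals(d, fit, pers))
  chi <- itemTraitChisq(res, d, fit)
  # 29 items x (3 class intervals - 1)
  expect_identical(chi$total$df, 58)
  expect_equal(chi$bonferroniAlpha, 0.05 / 29)
  # collapsing to two testlets: df = 2 x (3 - 1)
  coll <- collapseTestlets(d)
  f3 <- estimateItems(coll, maxit = 3000, onNonconvergence = "warn")
  p3 <- estimatePersons(coll, f3)
  r3 <- suppressWarnings(standardizedResiduals(coll, f3, p3))
  c3 <- itemTraitChisq(r3, coll, f3)
  expect_identical(c3$total$df, 4)
})

test_that("threshold ordering checks agree with modal-category coverage", {
  ordered <- c(-2, -1, 0, 1)
  disordered <- c(-1, -1.5, 0, 1)
  ip <- itemParameters(list(ok = ordered, bad = disordered))
  expect_identical(checkThresholdOrder(ip), "bad")
  # ordered item: every category is modal somewhere on a dense grid
  grid <- seq(-6, 6, by = 0.01)
  pOk <- categoryProbs(grid, ordered)
  expect_identical(sort(unique(max.col(pOk))), 1:5)
  # disordered item: at least one category is nowhere modal
  pBad <- categoryProbs(grid, disordered)
  expect_lt(length(unique(max.col(pBad))), 5)
})

test_that("misfitting-person removal is targeted and idempotent", {
  set.seed(77)
  sim <- simFixture(n = 500, items = 10, seed = 55)
  x <- responses(sim$data)
  # plant 5 random responders
  aberrant <- sprintf("P%04d", 1:5)
  x[aberrant, ] <- matrix(sample(0:4, 50, TRUE), 5)
  d <- responseMatrix(x)
  fit <- estimateItems(d)
  pers <- estimatePersons(d, fit)
  res <- standardizedResiduals(d, fit, pers)
  pf <- fitResiduals(res, "person")
  cleaned <- removeMisfittingPersons(d, pf)
  removed <- attr(cleaned, "removedPersons")
  expect_gte(sum(aberrant %in% removed), 3)
  # re-applying with the same fit residuals changes nothing
  again <- removeMisfittingPersons(cleaned, pf[rownames(responses(cleaned))])
  expect_identical(responses(again), responses(cleaned))
  # a single offender beyond the bound is removed exactly
  pf2 <- setNames(rep(0, nrow(x)), rownames(x))
  pf2["P0100"] <- 3.1
  one <- removeMisfittingPersons(d, pf2)
  expect_identical(attr(one, "removedPersons"), "P0100")
})

test_that("PSI behaves at its limits and tracks true reliability", {
  mk <- function(theta, se) new("PersonEstimates",
    personIds = sprintf("P%03d", seq_along(theta)), theta = theta,
    se = se, extreme = rep(FALSE, length(theta)),
    rawScore = rep(1, length(theta)), nObserved = rep(5L, length(theta)))
  th <- rnorm(50)
  expect_equal(personSeparationIndex(mk(th, rep(1e-9, 50))), 1,
               tolerance = 1e-6)
  v <- var(th)
  expect_equal(personSeparationIndex(mk(th, rep(sqrt(v), 50))), 0,
               tolerance = 1e-12)
  expect_error(personSeparationIndex(mk(rep(1, 50), rep(0.1, 50))),
               "variance")
  # simulation: PSI close to the generating reliability
  sim <- simFixture(n = 1000, items = 20, seed = 56)
  fit <- estimateItems(sim$data)
  pers <- estimatePersons(sim$data, fit)
  psi <- personSeparationIndex(pers)
  keep <- !pers@extreme
  trueRel <- 1 / (1 + mean(pers@se[keep]^2))
  expect_lt(abs(psi - trueRel), 0.05)
})
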