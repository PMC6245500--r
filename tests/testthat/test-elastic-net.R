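# Small regression problems with closed-form solutions. Predictors are
# centred and scaled to unit *population* SD so the penalised solutions have
# textbook forms when standardize = FALSE.

popScale <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

test_that("the mixed penalty evaluates per its definition", {
  expect_equal(elasticPenalty(c(1, -2), alpha = 0.5),
               0.25 * (1 + 4) + 0.5 * (1 + 2))   # 2.75
  expect_equal(elasticPenalty(c(1, -2), alpha = 1), 3)
  expect_equal(elasticPenalty(c(1, -2), alpha = 0), 2.5)
})

test_that("the path starts at an all-zero model predicting the mean age", {
  set.seed(50)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- 30 + rnorm(60, sd = 8)
  fit <- elasticNetPath(X, y, alpha = 0.5, nFolds = 5, seed = 1)
  expect_length(fit@lambdaGrid, 100)
  expect_equal(unname(fit@betaPath[, 1]), rep(0, 8))
  expect_equal(fit@beta0Path[1], mean(y), tolerance = 1e-6)
  expect_true(fit@lambdaStar %in% fit@lambdaGrid)
})

test_that("lasso limit matches the soft-threshold closed form", {
  set.seed(51)
  n <- 80
  x <- popScale(matrix(rnorm(n), n, 1))
  colnames(x) <- "f"
  y <- 2 * x[, 1] + rnorm(n, sd = 0.5)
  rho <- mean(x[, 1] * y)                 # x'y / N on the standardised scale
  lams <- sort(c(exp(seq(log(abs(rho) * 1.001), log(abs(rho) * 1e-4),
                         length.out = 99)), abs(rho) * 0.35),
               decreasing = TRUE)
  fit <- elasticNetPath(x, y, alpha = 1, nFolds = 5, seed = 2,
                        standardize = FALSE, lambda = lams)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (j in c(20, 50, 80, 100))
    expect_equal(unname(fit@betaPath[1, j]),
                 soft(rho, fit@lambdaGrid[j]) / mean(x[, 1]^2),
                 tolerance = 1e-6)
})

test_that("ridge limit matches its closed form on standardised data", {
  set.seed(52)
  n <- 50; p <- 4
  X <- popScale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("v", 1:p)
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(n, sd = 0.3)
  lams <- exp(seq(log(50), log(5e-3), length.out = 100))
  fit <- elasticNetPath(X, y, alpha = 0, nFolds = 5, seed = 3,
                        standardize = FALSE, lambda = lams)
  yc <- y - mean(y)
  for (j in c(10, 40, 70, 100)) {
    lam <- fit@lambdaGrid[j]
    closed <- solve(crossprod(X) / n + lam * diag(p), crossprod(X, yc) / n)
    expect_equal(unname(fit@betaPath[, j]), as.numeric(closed),
                 tolerance = 1e-6)
  }
})

test_that("the fitted path never does worse than the null model (descent)", {
  set.seed(53)
  X <- matrix(rnorm(70 * 10), 70, 10)
  y <- X %*% rnorm(10) + rnorm(70)
  fit <- elasticNetPath(X, y, alpha = 0.5, nFolds = 5, seed = 4)
  for (j in seq(1, 100, by = 9)) {
    lam <- fit@lambdaGrid[j]
    objFit <- elasticObjective(X, y, fit@beta0Path[j], fit@betaPath[, j],
                               lam, alpha = 0.5)
    objNull <- elasticObjective(X, y, mean(y), rep(0, 10), lam, alpha = 0.5)
    expect_lte(objFit, objNull + 1e-8)
  }
})

test_that("duplicated predictors share their coefficient at alpha = 0.5", {
  set.seed(54)
  n <- 100
  z <- rnorm(n)
  X <- cbind(a = z, b = z, c = rnorm(n))
  y <- 3 * z + rnorm(n, sd = 0.5)
  fit <- elasticNetPath(X, y, alpha = 0.5, nFolds = 5, seed = 5)
  j <- 60   # well inside the path, both duplicates active
  expect_equal(unname(fit@betaPath["a", j]), unname(fit@betaPath["b", j]),
               tolerance = 0.02)
  expect_gt(fit@betaPath["a", j], 0)
})

test_that("degenerate inputs are rejected or dropped with a warning", {
  X <- cbind(a = rnorm(30), flat = rep(1, 30))
  y <- rnorm(30, 50, 10)
  expect_warning(fit <- elasticNetPath(X, y, nFolds = 5, seed = 1),
                 "zero-variance.*flat")
  expect_identical(fit@dropped, "flat")
  expect_error(elasticNetPath(matrix(rnorm(30), 30, 1), rep(44, 30),
                              nFolds = 5),
               "constant response")
})

test_that("metabolic age reproduces the hand-computed scaling", {
  fluxes <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "pwyA"))
  pred <- metabolicAge(fluxes, c(pwyA = 0.7), ages = c(20, 30, 40))
  expect_equal(unname(scaledAges(pred)), c(20, 30, 40))
  expect_equal(scaledAges(pred)[[2]], 30)   # M at its mean -> age mean
  expect_error(metabolicAge(fluxes, c(pwyA = 0)), "no predictor selected")
})

test_that("metabolic age matches the cohort age mean and SD on any cohort", {
  set.seed(55)
  fluxes <- matrix(runif(40 * 6, 5, 15), 40, 6,
                   dimnames = list(NULL, paste0("pwy", 1:6)))
  beta <- setNames(c(0.5, -0.2, 0, 0, 0.1, 0), colnames(fluxes))
  a <- sample(18:80, 40, replace = TRUE)
  pred <- metabolicAge(fluxes, beta, a)
  expect_equal(mean(scaledAges(pred)), mean(a), tolerance = 1e-9)
  expect_equal(sd(scaledAges(pred)), sd(a), tolerance = 1e-9)
})

test_that("age correlation behaves like Pearson's r", {
  a <- c(20, 35, 50, 65, 80)
  expect_equal(ageCorrelation(a, a)$r, 1)
  set.seed(56)
  x <- rnorm(1000); yy <- rnorm(1000)
  expect_lt(abs(ageCorrelation(x, yy)$r), 0.1)
  r1 <- ageCorrelation(x, yy)
  r2 <- ageCorrelation(3 * x + 7, yy)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-12)
  expect_error(ageCorrelation(rep(1, 5), a), "zero variance")
})

test_that("null flux cohorts yield no cross-validated predictive gain", {
  # planted-signal-free cohorts: the minimum CV MSE should sit within a few
  # percent of the null-model MSE (the curve's value at lambda_max)
  hits <- 0L
  for (s in 1:10) {
    spec <- SyntheticSpec(effectScale = 0, plantedPathways = character(0),
                          seed = 100 + s)
    mod <- makeToyModel(spec)
    coh <- makeCohort(spec, mod)
    fp <- cohortFluxomics(mod, normaliseProbes(coh$expr))
    pm <- pathwayFluxMatrix(fp)
    pm <- pm[, grepl("^PWY", colnames(pm)), drop = FALSE]
    fit <- suppressWarnings(
      elasticNetPath(pm, unname(ages(fp)), seed = 200 + s))
    if (min(fit@cvMse) >= 0.95 * fit@cvMse[1]) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})
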