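test_that("two perfectly correlated variables split the first component", {
  set.seed(40)
  z <- rnorm(50)
  pca <- fitGroupPCA(cbind(a = z, b = 2 * z + 3), "toy")
  expect_equal(pca@eigenvalues[1], 2, tolerance = 1e-9)
  expect_equal(unname(pca@contributions[, 1]), c(50, 50), tolerance = 1e-9)
})

test_that("independent variables give near-unit eigenvalues at large n", {
  set.seed(41)
  x <- matrix(rnorm(10000 * 5), 10000, 5)
  pca <- fitGroupPCA(x, "iid")
  expect_equal(unname(pca@eigenvalues), rep(1, 5), tolerance = 0.05)
})

test_that("contribution columns always sum to 100 and constants are dropped", {
  set.seed(42)
  x <- cbind(matrix(rnorm(30 * 6), 30, 6), const = rep(2, 30))
  colnames(x)[1:6] <- paste0("v", 1:6)
  pca <- fitGroupPCA(x, "g")
  expect_equal(unname(colSums(pca@contributions)),
               rep(100, ncol(pca@contributions)), tolerance = 1e-9)
  expect_identical(pca@dropped, "const")
  expect_error(fitGroupPCA(x[1:2, ], "few"), "at least 3")
  expect_error(fitGroupPCA(matrix(1, 10, 3), "const"), "constant")
})

test_that("eigen-decomposition matches a correlation-matrix oracle", {
  set.seed(43)
  for (rep in 1:5) {
    p <- sample(3:10, 1)
    x <- matrix(rnorm(40 * p), 40, p) %*% matrix(runif(p * p), p, p)
    colnames(x) <- paste0("v", seq_len(p))
    pca <- fitGroupPCA(x, "orc")
    eo <- eigen(cor(x), symmetric = TRUE)
    expect_equal(pca@eigenvalues, eo$values, tolerance = 1e-8)
    expect_equal(abs(pca@contributions / 100),
                 abs(eo$vectors^2), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("retention applies Kaiser, the row threshold and the 50% floor", {
  mk <- function(ev, n) {
    p <- length(ev)
    contrib <- matrix(100 / p, p, p,
                      dimnames = list(paste0("v", 1:p), NULL))
    new("PCAContribution", groupLabel = "g", nIndividuals = as.integer(n),
        eigenvalues = ev, contributions = contrib,
        nRetained = NA_integer_, totals = numeric(0), dropped = character(0))
  }
  # Kaiser keeps one; its 75% variance already clears the 50% floor
  expect_equal(retainComponents(mk(c(3, 0.5, 0.5), 100))@nRetained, 1L)
  # Kaiser keeps one (37.5%); floor extends the count to reach 50%
  expect_equal(retainComponents(mk(c(1.5, 0.9, 0.9, 0.7), 100))@nRetained, 2L)
  # row threshold can veto a Kaiser-passing axis: n = 3 -> threshold 50%
  expect_equal(retainComponents(mk(c(1.9, 1.2, 0.9), 3))@nRetained, 2L)
})

test_that("weighted totals follow T = sum E_i V_i and are conserved", {
  contrib <- matrix(c(30, 70, 60, 40), 2, 2,
                    dimnames = list(c("v1", "v2"), NULL))
  pca <- new("PCAContribution", groupLabel = "g", nIndividuals = 10L,
             eigenvalues = c(2, 1), contributions = contrib,
             nRetained = 2L, totals = numeric(0), dropped = character(0))
  pca <- totalContribution(pca)
  expect_equal(pca@totals[["v1"]], 2 * 30 + 1 * 60)   # 120
  expect_equal(pca@totals[["v2"]], 2 * 70 + 1 * 40)
  expect_equal(sum(pca@totals), 100 * sum(pca@eigenvalues))
  # single retained component: totals reduce to E1 * V1
  pca1 <- pca; pca1@nRetained <- 1L
  expect_equal(totalContribution(pca1)@totals[["v2"]], 140)
})

test_that("age group boundaries are 21 and under, 22-49, 50 and over", {
  g <- ageGroups(c(10, 21, 22, 49, 50, 80))
  expect_equal(as.character(g),
               c("21-", "21-", "22-49", "22-49", "50+", "50+"))
})

test_that("a planted structural shift ranks its pathway first", {
  # standardised PCA is scale-free, so the planted between-group difference
  # must be structural, not a pure variance change: both groups share a
  # common latent factor, but in the older group one pathway decouples from
  # it and earns a near-private retained component (~100% contribution)
  set.seed(44)
  n <- 400
  mk <- function() matrix(rnorm(n * 6, 10, 1), n, 6,
                          dimnames = list(NULL, paste0("pwy", 1:6)))
  base <- mk(); shifted <- mk()
  latentY <- rnorm(n); latentO <- rnorm(n)
  for (j in 1:6) base[, j] <- base[, j] + 0.8 * latentY
  for (j in c(1, 2, 4, 5, 6)) shifted[, j] <- shifted[, j] + 0.8 * latentO
  ty <- totalContribution(retainComponents(fitGroupPCA(base, "young")))
  to <- totalContribution(retainComponents(fitGroupPCA(shifted, "old")))
  ranking <- groupDifferenceRanking(list(young = ty@totals, old = to@totals))
  expect_equal(ranking$young_vs_old$variable[1], "pwy3")
  # sign convention: difference = older - younger
  expect_equal(ranking$young_vs_old$difference,
               ranking$young_vs_old$older - ranking$young_vs_old$younger)
  # identical groups -> all differences zero
  r0 <- groupDifferenceRanking(list(a = ty@totals, b = ty@totals))
  expect_equal(r0$a_vs_b$difference, rep(0, nrow(r0$a_vs_b)))
  expect_error(groupDifferenceRanking(list(a = c(x = 1), b = c(y = 2))),
               "no variables")
})

test_that("per-age-group driver covers the three cohort groups", {
  set.seed(45)
  ages <- c(sample(15:21, 10, TRUE), sample(22:49, 25, TRUE),
            sample(50:80, 10, TRUE))
  mat <- matrix(rnorm(45 * 8, 10), 45, 8,
                dimnames = list(NULL, paste0("p", 1:8)))
  res <- pcaByAgeGroup(mat, ages)
  expect_setequal(names(res$groups), c("21-", "22-49", "50+"))
  expect_length(res$differences, 3)
  expect_lte(nrow(res$differences[[1]]), 20)
})
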