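test_that("the bound map phi has its stated fixed points and symmetry", {
  expect_equal(boundCoefficient(1), 1)
  expect_equal(boundCoefficient(exp(1), gamma = 1), 2)
  expect_equal(boundCoefficient(exp(-1), gamma = 1), 0.5)
  th <- c(0.01, 0.3, 0.9, 1, 1.3, 4, 20)
  expect_equal(boundCoefficient(th) * boundCoefficient(1 / th), rep(1, 7))
  # monotone non-decreasing in theta
  grid <- seq(0.05, 5, by = 0.05)
  expect_true(all(diff(boundCoefficient(grid)) >= -1e-12))
  # gamma scales the response
  expect_equal(boundCoefficient(exp(1), gamma = 3), 4)
})

test_that("bound transformation only touches gene-associated reactions", {
  mod <- chainModel(uptake = 5)
  cfg <- FluxSolverConfig()
  b <- applyExpressionBounds(mod, rep(1, 5), cfg)
  expect_equal(b$lower, unname(lowerBounds(mod)))
  expect_equal(b$upper, unname(upperBounds(mod)))
  theta <- c(2, exp(1), 2, 2, 2)   # only CONV (index 2) has a GPR
  b2 <- applyExpressionBounds(mod, theta, cfg)
  expect_equal(b2$upper[2], 2000)
  expect_equal(b2$upper[-2], unname(upperBounds(mod))[-2])
  # theta = 0 is floored, not -Inf: coefficient is tiny but positive
  b3 <- applyExpressionBounds(mod, c(1, 0, 1, 1, 1), cfg)
  expect_gt(b3$upper[2], 0)
  expect_lt(b3$upper[2], 1000 / (1 + 0.9 * log(1e6)))
})

test_that("bilevel FBA on a linear chain matches hand arithmetic", {
  mod <- chainModel(uptake = 5, burnCap = 2)
  sol <- bilevelFBA(mod)
  # LP1: growth limited by uptake; LP2 burns nothing because growth is fixed
  expect_equal(sol$primary, 5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["GROW"]), 5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["BURN"]), 0, tolerance = 1e-9)
  # halving the gene-gated conversion bound via phi halves the optimum
  theta <- c(1, exp(-1), 1, 1, 1)
  mod2 <- chainModel(uptake = 5, burnCap = 2)
  mod2@upperBounds[2] <- 8   # make CONV limiting: 8 * 0.5 = 4 < uptake 5
  b <- applyExpressionBounds(mod2, theta, FluxSolverConfig())
  sol2 <- bilevelFBA(mod2, b$lower, b$upper)
  expect_equal(sol2$primary, 4, tolerance = 1e-9)
  # the surplus uptake (5 - 4 = 1) is burned for ATP by the secondary solve
  expect_equal(sol2$secondary, 1, tolerance = 1e-9)
})

test_that("epsilon = 0 keeps the primary objective at its optimum", {
  mod <- chainModel(uptake = 5, burnCap = 1000)
  sol <- bilevelFBA(mod, config = FluxSolverConfig(epsilonPrimary = 0))
  expect_equal(unname(sol$fluxes["GROW"]), sol$primary, tolerance = 1e-8)
  # with slack allowed, the secondary objective trades growth for ATP
  solEps <- bilevelFBA(mod, config = FluxSolverConfig(epsilonPrimary = 0.2))
  expect_gte(solEps$secondary, sol$secondary)
  expect_gte(unname(solEps$fluxes["GROW"]), 0.8 * sol$primary - 1e-8)
})

test_that("infeasible and unbounded models are reported as such", {
  mod <- chainModel()
  mod@lowerBounds[3] <- 20   # demand 20 > uptake capacity 5
  expect_error(bilevelFBA(mod, individual = "ind_7"),
               "infeasible individual model.*ind_7")

  # a driven reversible cycle with an open bound is unbounded
  S <- matrix(c(1, -1), 1, 2, dimnames = list("X", c("f1", "f2")))
  cyc <- MetabolicModel(c("f1", "f2"), "X", S, c(-Inf, -Inf), c(Inf, Inf),
                        biomassIndex = 1, maintenanceIndex = 2)
  expect_error(bilevelFBA(cyc), "unbounded")
})

test_that("bilevel FBA agrees with vertex enumeration on random networks", {
  set.seed(11)
  tested <- 0
  while (tested < 25) {
    nm <- sample(2:4, 1)
    nr <- sample((nm + 1):6, 1)
    mod <- randomTinyModel(nm, nr)
    orc <- oracleBilevel(stoichiometry(mod),
                         f = as.numeric(seq_len(nr) == 1),
                         g = as.numeric(seq_len(nr) == 2),
                         lb = unname(lowerBounds(mod)),
                         ub = unname(upperBounds(mod)))
    sol <- bilevelFBA(mod)
    expect_equal(sol$primary, orc$primary, tolerance = 1e-6)
    expect_equal(sol$secondary, orc$secondary, tolerance = 1e-6)
    # returned flux satisfies steady state and bounds
    expect_lt(max(abs(stoichiometry(mod) %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= lowerBounds(mod) - 1e-8))
    expect_true(all(sol$fluxes <= upperBounds(mod) + 1e-8))
    tested <- tested + 1
  }
})

test_that("cohort fluxomics: neutral expression gives identical profiles", {
  spec <- SyntheticSpec(nIndividuals = 6, nPathways = 3, nAgeGenes = 10,
                        reactionsPerPathway = 2, nProbes = 40)
  mod <- makeToyModel(spec)
  genes <- unique(unlist(lapply(gprRules(mod), function(r)
    metaboAge:::gprGenes(parseGPR(r)))))
  vals <- matrix(1, length(genes), 4,
                 dimnames = list(paste0("pr_", genes), paste0("i", 1:4)))
  coh <- CohortExpression(vals,
                          probeGenes = setNames(as.list(genes),
                                                rownames(vals)),
                          age = c(20, 30, 40, 50))
  fp <- cohortFluxomics(mod, coh)
  fm <- fluxMatrix(fp)
  for (i in 2:4) expect_equal(unname(fm[i, ]), unname(fm[1, ]))
  # pathway fluxes are the means of member reaction fluxes
  pwys <- subsystems(mod)
  for (p in unique(pwys))
    expect_equal(unname(pathwayFluxMatrix(fp)[1, p]),
                 mean(fm[1, names(pwys)[pwys == p]]))
})

test_that("cohort fluxomics is independent across individuals", {
  spec <- SyntheticSpec(nIndividuals = 8, nPathways = 3, nAgeGenes = 10,
                        reactionsPerPathway = 2, nProbes = 40, seed = 3)
  mod <- makeToyModel(spec)
  coh <- makeCohort(spec, mod)
  norm <- normaliseProbes(coh$expr)
  fp <- cohortFluxomics(mod, norm)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  vals <- exprValues(norm)[, perm]
  normPerm <- CohortExpression(vals, probeGenes = probeGenes(norm),
                               age = ages(norm)[perm],
                               sex = sexes(norm)[perm])
  fpPerm <- cohortFluxomics(mod, normPerm)
  expect_equal(fluxMatrix(fpPerm), fluxMatrix(fp)[perm, ])
})

test_that("per-individual failures are collected, not silently dropped", {
  # demand reaction with a fixed positive lower bound, supplied through a
  # gene-gated reaction: shutting the gene makes the model infeasible
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("SUP", "CONV", "DEM")))
  mod <- MetabolicModel(c("SUP", "CONV", "DEM"), c("A", "B"), S,
                        c(0, 0, 5), c(10, 10, 1000),
                        gpr = c("", "g1", ""),
                        biomassIndex = 3, maintenanceIndex = 1)
  vals <- matrix(c(1, 1e-9), 1, 2, dimnames = list("pr_g1", c("ok", "bad")))
  coh <- CohortExpression(vals, probeGenes = list(pr_g1 = "g1"),
                          age = c(30, 40))
  expect_error(cohortFluxomics(mod, coh, strict = TRUE), "bad")
  expect_warning(fp <- cohortFluxomics(mod, coh, strict = FALSE), "bad")
  expect_identical(colnames(fluxMatrix(fp)), c("SUP", "CONV", "DEM"))
  expect_identical(rownames(fluxMatrix(fp)), "ok")
})
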