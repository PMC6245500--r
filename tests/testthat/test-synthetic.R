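test_that("toy model has the expected pathway structure", {
  spec <- SyntheticSpec(nPathways = 3, reactionsPerPathway = 2)
  mod <- makeToyModel(spec)
  subs <- unique(unname(subsystems(mod)))
  expect_setequal(subs, c("PWY_001", "PWY_002", "PWY_003", "Exchange/demand",
                          "Energy salvage", "Biomass", "Maintenance"))
  # 3 x (exchange + 2 internal + salvage) + biomass + maintenance
  expect_length(reactionIds(mod), 14)
  # every internal reaction is gene-gated, everything else is not
  internal <- grepl("^RXN", reactionIds(mod))
  expect_true(all(nzchar(gprRules(mod)[internal])))
  expect_false(any(nzchar(gprRules(mod)[!internal])))
  expect_true(validObject(mod))
})

test_that("construction is deterministic for a fixed spec", {
  spec <- SyntheticSpec(nPathways = 4, reactionsPerPathway = 3, seed = 9)
  expect_identical(makeToyModel(spec), makeToyModel(spec))
  modA <- makeToyModel(spec)
  cohA <- makeCohort(spec, modA)
  cohB <- makeCohort(spec, modA)
  expect_identical(exprValues(cohA$expr), exprValues(cohB$expr))
  expect_identical(cohA$effects, cohB$effects)
  expect_identical(unname(ages(cohA$expr)), unname(ages(cohB$expr)))
})

test_that("unconstrained toy model grows, confirmed by the LP oracle", {
  spec <- SyntheticSpec(nPathways = 2, reactionsPerPathway = 1)
  mod <- makeToyModel(spec)
  sol <- bilevelFBA(mod)
  expect_gt(sol$primary, 0)
  orc <- oracleLP(as.numeric(seq_along(reactionIds(mod)) ==
                               biomassReaction(mod)),
                  stoichiometry(mod), rep(0, length(metaboliteIds(mod))),
                  unname(lowerBounds(mod)), unname(upperBounds(mod)))
  expect_equal(sol$primary, orc$objective, tolerance = 1e-8)
})

test_that("noiseless age genes are exact linear functions of age", {
  spec <- SyntheticSpec(nIndividuals = 25, nProbes = 40, nAgeGenes = 10,
                        noiseSd = 0, fluxNoiseSd = 0, nPathways = 2,
                        reactionsPerPathway = 1, seed = 2)
  mod <- makeToyModel(spec)
  coh <- makeCohort(spec, mod)
  a <- unname(ages(coh$expr))
  for (k in 1:10) {
    x <- exprValues(coh$expr)[sprintf("pr_AGE_%03d", k), ]
    fitted <- 1 + coh$effects[[k]] * (a - mean(a))
    expect_equal(unname(x), pmax(fitted, 0), tolerance = 1e-12)
  }
})

test_that("effectScale = 0 yields a flat transcriptomic predictor", {
  spec <- SyntheticSpec(nIndividuals = 20, nProbes = 40, nAgeGenes = 10,
                        effectScale = 0, noiseSd = 0, nPathways = 2,
                        reactionsPerPathway = 1, seed = 4)
  mod <- makeToyModel(spec)
  coh <- makeCohort(spec, mod)
  norm <- normaliseProbes(coh$expr)
  b <- probeEffectSizes(probeGenes(norm), coh$effects)
  v <- exprValues(norm)[names(b), , drop = FALSE]
  z <- as.numeric(crossprod(v, b))
  expect_equal(var(z), 0)
  expect_error(transcriptomicAge(norm, b), "degenerate|zero variance")
})

test_that("planted transcriptomic signal is recovered on the default cohort", {
  spec <- SyntheticSpec(seed = 1)   # n = 200, 50 age genes, noise 0.05
  mod <- makeToyModel(spec)
  coh <- makeCohort(spec, mod)
  norm <- normaliseProbes(coh$expr)
  b <- probeEffectSizes(probeGenes(norm), coh$effects)
  pred <- transcriptomicAge(norm, b)
  expect_gt(cor(predictorValues(pred), unname(ages(norm))), 0.9)
})

test_that("spec validation rejects impossible configurations", {
  expect_error(SyntheticSpec(nAgeGenes = 50, nProbes = 10), "nAgeGenes")
  expect_error(SyntheticSpec(ageRange = c(50, 20)), "min < max")
  mod <- makeToyModel(SyntheticSpec(nPathways = 20, reactionsPerPathway = 3))
  expect_error(makeCohort(SyntheticSpec(nPathways = 20,
                                        reactionsPerPathway = 3,
                                        nProbes = 30, nAgeGenes = 5), mod),
               "cannot cover")
})

test_that("paired GPR mode emits parseable AND rules", {
  spec <- SyntheticSpec(nPathways = 2, reactionsPerPathway = 2,
                        gprMode = "paired")
  mod <- makeToyModel(spec)
  rules <- gprRules(mod)[grepl("^RXN", reactionIds(mod))]
  expect_true(all(grepl(" AND ", rules)))
  for (r in rules) expect_length(metaboAge:::gprGenes(parseGPR(r)), 2)
})

test_that("simulateInputs writes a consistent, reloadable input set", {
  dir <- withr::local_tempdir()
  spec <- SyntheticSpec(nIndividuals = 10, nProbes = 40, nAgeGenes = 5,
                        nPathways = 3, reactionsPerPathway = 1, seed = 6)
  simulateInputs(spec, dir)
  mod <- readMetabolicModel(file.path(dir, "model"))
  modX <- readMetabolicModel(file.path(dir, "model.xml"))
  expect_identical(reactionIds(mod), reactionIds(modX))
  coh <- readCohort(file.path(dir, "expression.tsv"),
                    file.path(dir, "metadata.tsv"),
                    file.path(dir, "probe_map.tsv"))
  expect_equal(ncol(exprValues(coh)), 10)
  eff <- readEffectSizes(file.path(dir, "effect_sizes.tsv"))
  expect_length(eff, 5)
})
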