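test_that("a hand-written tabular bundle loads with the right shape", {
  dir <- writeToyBundle(withr::local_tempdir())
  mod <- readMetabolicModel(dir)
  expect_s4_class(mod, "MetabolicModel")
  expect_length(reactionIds(mod), 3)
  expect_length(metaboliteIds(mod), 2)
  expect_identical(unname(gprRules(mod)), c("", "gA", ""))
  expect_identical(reactionIds(mod)[biomassReaction(mod)], "R3")
  expect_identical(reactionIds(mod)[maintenanceReaction(mod)], "R1")
})

test_that("missing bounds and subsystems fall back to documented defaults", {
  dir <- writeToyBundle(withr::local_tempdir(),
    reactions = c("reaction_id\tgpr\tsubsystem",
                  "R1\t\t", "R2\tgA\tcore", "R3\t\tcore"))
  mod <- readMetabolicModel(dir)
  expect_equal(unname(lowerBounds(mod)), rep(-1000, 3))
  expect_equal(unname(upperBounds(mod)), rep(1000, 3))
  expect_identical(unname(subsystems(mod))[1], "unassigned")
})

test_that("malformed bundles raise informative validation errors", {
  base <- withr::local_tempdir()
  dirDup <- writeToyBundle(file.path(base, "dup"),
    reactions = c("reaction_id\tlower_bound\tupper_bound",
                  "R1\t0\t10", "R1\t0\t10", "R3\t0\t10"))
  expect_error(readMetabolicModel(dirDup), "duplicate reaction id.*R1")

  dirBad <- writeToyBundle(file.path(base, "badstoich"),
    stoich = c("metabolite_id\treaction_id\tcoefficient",
               "M1\tRX\t1"))
  expect_error(readMetabolicModel(dirBad), "unknown reaction.*RX")

  expect_error(
    MetabolicModel(c("R1", "R2"), "M1", matrix(0, 1, 3), c(0, 0), c(1, 1),
                   biomassIndex = 1, maintenanceIndex = 2),
    "columns")
})

test_that("tabular write/read round trip preserves every field", {
  spec <- SyntheticSpec(nPathways = 4, reactionsPerPathway = 2,
                        gprMode = "paired")
  mod <- makeToyModel(spec)
  dir <- withr::local_tempdir()
  writeMetabolicModel(mod, dir)
  back <- readMetabolicModel(dir)
  expect_identical(reactionIds(back), reactionIds(mod))
  expect_identical(metaboliteIds(back), metaboliteIds(mod))
  expect_equal(stoichiometry(back), stoichiometry(mod))
  expect_equal(lowerBounds(back), lowerBounds(mod))
  expect_equal(upperBounds(back), upperBounds(mod))
  expect_identical(gprRules(back), gprRules(mod))
  expect_identical(subsystems(back), subsystems(mod))
  expect_identical(biomassReaction(back), biomassReaction(mod))
  expect_identical(maintenanceReaction(back), maintenanceReaction(mod))
})

test_that("SBML write/read round trip reproduces the model", {
  mod <- makeToyModel(SyntheticSpec(nPathways = 3, reactionsPerPathway = 2,
                                    gprMode = "paired"))
  f <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(mod, f)
  back <- readMetabolicModel(f, format = "sbml")
  expect_identical(reactionIds(back), reactionIds(mod))
  expect_equal(stoichiometry(back)[metaboliteIds(mod), ],
               stoichiometry(mod))
  expect_equal(lowerBounds(back), lowerBounds(mod))
  expect_equal(upperBounds(back), upperBounds(mod))
  expect_identical(subsystems(back), subsystems(mod))
  expect_identical(biomassReaction(back), biomassReaction(mod))
  # GPRs may gain redundant parentheses on the round trip; compare
  # evaluation on random expression profiles instead of the strings
  set.seed(1)
  genes <- unique(unlist(lapply(gprRules(mod), function(r)
    metaboAge:::gprGenes(parseGPR(r)))))
  for (rep in 1:3) {
    ge <- setNames(runif(length(genes), 0, 2), genes)
    for (i in seq_along(reactionIds(mod)))
      expect_equal(reactionExpression(gprRules(back)[i], ge),
                   reactionExpression(gprRules(mod)[i], ge))
  }
})

test_that("SBML reactions without explicit bounds default by reversibility", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="Rrev" reversible="true">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_biomass" reversible="false">',
    '<notes><p>SUBSYSTEM: growth</p></notes>',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R_atp_drain" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), f)
  mod <- readMetabolicModel(f, format = "sbml")
  expect_equal(unname(lowerBounds(mod)), c(-1000, 0, 0))
  expect_equal(unname(upperBounds(mod)), c(1000, 1000, 1000))
  expect_identical(unname(subsystems(mod)), c("unassigned", "growth",
                                              "unassigned"))
})

test_that("a 4-probe x 3-individual cohort loads aligned to the metadata", {
  p <- writeToyCohortFiles(withr::local_tempdir())
  coh <- readCohort(p$expr, p$meta, p$map)
  expect_s4_class(coh, "CohortExpression")
  expect_equal(dim(exprValues(coh)), c(4, 3))
  expect_identical(individualIds(coh), c("i1", "i2", "i3"))
  expect_equal(unname(ages(coh)), c(20, 30, 40))
  expect_identical(probeGenes(coh)$p3, c("gA", "gC"))
})

test_that("cohort loading enforces the documented mismatch policies", {
  base <- withr::local_tempdir()
  p <- writeToyCohortFiles(file.path(base, "a"),
    metaLines = c("individual_id\tage\tsex", "i1\t20\tF", "i2\t30\tM",
                  "i3\t40\tF", "i9\t50\tM"))
  expect_warning(coh <- readCohort(p$expr, p$meta, p$map),
                 "dropping individual.*i9")
  expect_equal(ncol(exprValues(coh)), 3)

  p2 <- writeToyCohortFiles(file.path(base, "b"),
    metaLines = c("individual_id\tage\tsex", "i1\t20\tF", "i2\t30\tM"))
  expect_error(readCohort(p2$expr, p2$meta, p2$map),
               "absent from metadata.*i3")

  p3 <- writeToyCohortFiles(file.path(base, "c"),
    metaLines = c("individual_id\tage\tsex", "i1\t20\tF", "i2\tNA\tM",
                  "i3\t40\tF"))
  expect_error(readCohort(p3$expr, p3$meta, p3$map), "age.*i2")

  p4 <- writeToyCohortFiles(file.path(base, "d"),
    exprLines = c("probe_id\ti1\ti2\ti3", "p1\t1\tx\t3"))
  expect_error(readCohort(p4$expr, p4$meta, p4$map),
               "non-numeric.*p1.*i2")
})

test_that("cohort loading is insensitive to input row order", {
  base <- withr::local_tempdir()
  p <- writeToyCohortFiles(file.path(base, "orig"))
  coh <- readCohort(p$expr, p$meta, p$map)
  pPerm <- writeToyCohortFiles(file.path(base, "perm"),
    exprLines = c("probe_id\ti2\ti3\ti1",
                  "p4\t5\t6\t4", "p2\t2\t2\t2",
                  "p1\t2\t3\t1", "p3\t1\t1.5\t0.5"),
    mapLines = c("probe_id\tgene_id",
                 "p3\tgC", "p4\tgD", "p1\tgA", "p3\tgA", "p2\tgB"))
  cohPerm <- readCohort(pPerm$expr, pPerm$meta, pPerm$map)
  ord <- rownames(exprValues(coh))
  expect_equal(exprValues(cohPerm)[ord, ], exprValues(coh))
  expect_identical(individualIds(cohPerm), individualIds(coh))
  expect_identical(lapply(probeGenes(cohPerm)[ord], sort),
                   lapply(probeGenes(coh)[ord], sort))
})

test_that("CSV input is auto-detected", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id,effect_size", "gA,0.2", "gB,-0.4"),
             file.path(dir, "eff.csv"))
  b <- readEffectSizes(file.path(dir, "eff.csv"))
  expect_equal(b, c(gA = 0.2, gB = -0.4))
})
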