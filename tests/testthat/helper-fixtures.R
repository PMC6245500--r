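# Fixture builders, all generated in code at test time.

# Linear chain: uptake -> (gene-gated conversion) -> biomass, plus an ATP
# branch so the two objectives are distinct.
#   EX:   -> A            [0, uptake]
#   CONV: A -> B          [0, 1000], gene g1
#   GROW: B ->            [0, 1000]   (biomass)
#   BURN: A -> atp        [0, burnCap]
#   ATPM: atp ->          [0, 1000]   (maintenance)
chainModel <- function(uptake = 5, burnCap = 1000) {
  mets <- c("A", "B", "atp")
  rid <- c("EX", "CONV", "GROW", "BURN", "ATPM")
  S <- matrix(0, 3, 5, dimnames = list(mets, rid))
  S["A", "EX"] <- 1
  S["A", "CONV"] <- -1; S["B", "CONV"] <- 1
  S["B", "GROW"] <- -1
  S["A", "BURN"] <- -1; S["atp", "BURN"] <- 1
  S["atp", "ATPM"] <- -1
  MetabolicModel(rid, mets, S,
                 lowerBounds = rep(0, 5),
                 upperBounds = c(uptake, 1000, 1000, burnCap, 1000),
                 gpr = c("", "g1", "", "", ""),
                 subsystem = c("Exchange", "Core", "Biomass", "Energy",
                               "Maintenance"),
                 biomassIndex = "GROW", maintenanceIndex = "ATPM")
}

# Random tiny network with finite bounds containing zero, so v = 0 is
# feasible and vertex enumeration applies.
randomTinyModel <- function(nMets, nRxns) {
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), nMets * nRxns, replace = TRUE),
                nMets, nRxns)
    if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0) &&
        qr(S)$rank == nMets) break   # full row rank so vertices exist
  }
  lb <- sample(c(0, 0, -2, -1), nRxns, replace = TRUE)
  ub <- sample(1:3, nRxns, replace = TRUE)
  dimnames(S) <- list(paste0("m", seq_len(nMets)), paste0("r", seq_len(nRxns)))
  MetabolicModel(colnames(S), rownames(S), S, lb, ub,
                 biomassIndex = 1L, maintenanceIndex = 2L)
}

# Write a hand-made tabular model bundle; fields overridable per file.
writeToyBundle <- function(dir,
                           reactions = c(
                             "reaction_id\tlower_bound\tupper_bound\tgpr\tsubsystem",
                             "R1\t0\t10\t\tuptake",
                             "R2\t0\t1000\tgA\tcore",
                             "R3\t0\t1000\t\tcore"),
                           metabolites = c("metabolite_id", "M1", "M2"),
                           stoich = c(
                             "metabolite_id\treaction_id\tcoefficient",
                             "M1\tR1\t1", "M1\tR2\t-1", "M2\tR2\t1",
                             "M2\tR3\t-1"),
                           objectives = c("role\treaction_id",
                                          "biomass\tR3",
                                          "maintenance\tR1")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(reactions, file.path(dir, "reactions.tsv"))
  writeLines(metabolites, file.path(dir, "metabolites.tsv"))
  writeLines(stoich, file.path(dir, "stoichiometry.tsv"))
  writeLines(objectives, file.path(dir, "objectives.tsv"))
  dir
}

# Write a small cohort (expression + metadata + probe map) as TSV files.
writeToyCohortFiles <- function(dir, exprLines = NULL, metaLines = NULL,
                                mapLines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(exprLines))
    exprLines <- c("probe_id\ti1\ti2\ti3",
                   "p1\t1\t2\t3", "p2\t2\t2\t2",
                   "p3\t0.5\t1\t1.5", "p4\t4\t5\t6")
  if (is.null(metaLines))
    metaLines <- c("individual_id\tage\tsex",
                   "i1\t20\tF", "i2\t30\tM", "i3\t40\tF")
  if (is.null(mapLines))
    mapLines <- c("probe_id\tgene_id",
                  "p1\tgA", "p2\tgB", "p3\tgA", "p3\tgC", "p4\tgD")
  writeLines(exprLines, file.path(dir, "expression.tsv"))
  writeLines(metaLines, file.path(dir, "metadata.tsv"))
  writeLines(mapLines, file.path(dir, "probe_map.tsv"))
  list(expr = file.path(dir, "expression.tsv"),
       meta = file.path(dir, "metadata.tsv"),
       map = file.path(dir, "probe_map.tsv"))
}

# A CohortExpression built directly in memory (already "normalised" unless
# stated otherwise).
inMemoryCohort <- function(values, age = NULL, genes = NULL) {
  if (is.null(age)) age <- seq(20, by = 10, length.out = ncol(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("i", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("p", seq_len(nrow(values)))
  if (is.null(genes))
    genes <- setNames(as.list(sub("^p", "g", rownames(values))),
                      rownames(values))
  CohortExpression(values, probeGenes = genes, age = age)
}
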