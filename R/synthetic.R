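## Synthetic study system: a toy genome-scale model made of parallel
## nutrient-uptake chains feeding one biomass reaction and an ATP drain, and
## an age-structured cohort with (a) planted transcriptomic age genes and
## (b) planted pathways whose gene expression, hence achievable flux, trends
## with age. Defaults emulate the shape of the real study system: 95
## metabolic pathways, a cohort spanning adolescence to old age with all
## three age groups (<=21, 22-49, >=50) populated, weak per-gene effect
## sizes and small residual expression noise.

#' SyntheticSpec: parameters of the synthetic study system
#'
#' @slot nIndividuals integer(1), cohort size.
#' @slot ageRange numeric(2), min/max chronological age (years).
#' @slot nProbes integer(1), total probes on the synthetic array; must cover
#'   the age genes and one probe per model gene.
#' @slot nAgeGenes integer(1), genes with a nonzero planted transcriptomic
#'   effect.
#' @slot effectScale numeric(1), SD of the planted per-gene effect sizes
#'   (expression units per year).
#' @slot noiseSd numeric(1), residual SD of age-gene and background probes.
#' @slot fluxNoiseSd numeric(1), residual SD of model-gene probes; 0 makes
#'   the planted flux signal a deterministic function of age.
#' @slot nPathways,reactionsPerPathway integer(1), toy network shape.
#' @slot plantedPathways character, pathway labels given an age trend in
#'   achievable flux.
#' @slot plantedAmplitude numeric(1), log-scale amplitude of the planted
#'   expression trend per age SD (signs alternate across planted pathways).
#' @slot gprMode character(1), \code{"single"} (one gene per reaction) or
#'   \code{"paired"} (two-gene AND rules, exercising the GPR grammar).
#' @slot seed integer(1), RNG seed.
#' @param nIndividuals,ageRange,nProbes,nAgeGenes,effectScale,noiseSd see slots.
#' @param fluxNoiseSd,nPathways,reactionsPerPathway,plantedPathways see slots.
#' @param plantedAmplitude,gprMode,seed see slots.
#' @return a validated \code{SyntheticSpec}.
#' @examples
#' SyntheticSpec(nPathways = 3, reactionsPerPathway = 2)
#' @name SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nIndividuals = "integer", ageRange = "numeric",
                 nProbes = "integer", nAgeGenes = "integer",
                 effectScale = "numeric", noiseSd = "numeric",
                 fluxNoiseSd = "numeric", nPathways = "integer",
                 reactionsPerPathway = "integer",
                 plantedPathways = "character",
                 plantedAmplitude = "numeric", gprMode = "character",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nIndividuals < 2) msg <- c(msg, "need at least 2 individuals")
  if (object@ageRange[1] >= object@ageRange[2])
    msg <- c(msg, "ageRange must satisfy min < max")
  if (object@ageRange[1] < 0) msg <- c(msg, "ages must be non-negative")
  if (object@nAgeGenes > object@nProbes)
    msg <- c(msg, "nAgeGenes must not exceed nProbes")
  if (object@nPathways < 1 || object@reactionsPerPathway < 1)
    msg <- c(msg, "network shape counts must be positive")
  if (object@effectScale < 0 || object@noiseSd < 0 || object@fluxNoiseSd < 0)
    msg <- c(msg, "scales must be non-negative")
  if (!object@gprMode %in% c("single", "paired"))
    msg <- c(msg, "gprMode must be 'single' or 'paired'")
  if (length(msg)) msg else TRUE
})

pathwayLabels <- function(n) sprintf("PWY_%03d", seq_len(n))

#' @rdname SyntheticSpec-class
#' @export
SyntheticSpec <- function(nIndividuals = 200, ageRange = c(18, 75),
                          nProbes = 500, nAgeGenes = 50, effectScale = 0.02,
                          noiseSd = 0.05, fluxNoiseSd = 0.05,
                          nPathways = 95, reactionsPerPathway = 2,
                          plantedPathways = NULL, plantedAmplitude = 0.25,
                          gprMode = "single", seed = 1) {
  if (is.null(plantedPathways))
    plantedPathways <- pathwayLabels(nPathways)[seq_len(min(3, nPathways))]
  new("SyntheticSpec", nIndividuals = as.integer(nIndividuals),
      ageRange = as.numeric(ageRange), nProbes = as.integer(nProbes),
      nAgeGenes = as.integer(nAgeGenes), effectScale = effectScale,
      noiseSd = noiseSd, fluxNoiseSd = fluxNoiseSd,
      nPathways = as.integer(nPathways),
      reactionsPerPathway = as.integer(reactionsPerPathway),
      plantedPathways = as.character(plantedPathways),
      plantedAmplitude = plantedAmplitude, gprMode = gprMode,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d individuals aged %g-%g, %d probes (%d age genes)\n",
    object@nIndividuals, object@ageRange[1], object@ageRange[2],
    object@nProbes, object@nAgeGenes))
  cat(sprintf("  network: %d pathways x %d reactions, planted: %s\n",
              object@nPathways, object@reactionsPerPathway,
              if (length(object@plantedPathways))
                paste(object@plantedPathways, collapse = ", ") else "none"))
})

toyGeneNames <- function(spec) {
  ## genes of internal reaction j of pathway p; paired mode uses two per rule
  per <- if (spec@gprMode == "paired") 2L else 1L
  array(sprintf("G_%03d_%d%s",
                rep(seq_len(spec@nPathways), each = spec@reactionsPerPathway * per),
                rep(rep(seq_len(spec@reactionsPerPathway), each = per),
                    spec@nPathways),
                rep(letters[seq_len(per)],
                    spec@nPathways * spec@reactionsPerPathway)),
        dim = c(per, spec@reactionsPerPathway, spec@nPathways))
}

#' Build the toy metabolic network
#'
#' One nutrient-uptake chain per pathway: an exchange reaction imports the
#' pathway's nutrient, a chain of gene-associated internal reactions converts
#' it to a terminal metabolite, the biomass reaction consumes one unit of
#' every pathway's terminal metabolite (primary objective), and a salvage
#' reaction per pathway burns surplus terminal metabolite into ATP, which the
#' ATP-maintenance drain (secondary objective) removes. Internal reaction
#' bounds sit near the operating flux, so expression-derived bound
#' coefficients bite; planted pathways get extra uptake headroom so their
#' flux follows their (age-trending) expression over the whole cohort.
#'
#' Construction is deterministic: the same spec always yields the identical
#' model.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{MetabolicModel} with subsystem labels
#'   \code{PWY_...} for internal reactions plus \code{"Exchange/demand"},
#'   \code{"Energy salvage"}, \code{"Biomass"} and \code{"Maintenance"}.
#' @export
makeToyModel <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  P <- spec@nPathways
  R <- spec@reactionsPerPathway
  labs <- pathwayLabels(P)
  planted <- labs %in% spec@plantedPathways
  gn <- toyGeneNames(spec)

  rid <- character(0); lb <- ub <- numeric(0)
  gpr <- character(0); sub <- character(0)
  mets <- c(sprintf("X_%03d_%d", rep(seq_len(P), each = R + 1),
                    rep(0:R, P)), "atp")
  S <- matrix(0, length(mets), 0, dimnames = list(mets, NULL))
  addRxn <- function(id, stoich, l, u, rule, subsys) {
    col <- numeric(length(mets)); names(col) <- mets
    col[names(stoich)] <- stoich
    S <<- cbind(S, col)
    rid <<- c(rid, id); lb <<- c(lb, l); ub <<- c(ub, u)
    gpr <<- c(gpr, rule); sub <<- c(sub, subsys)
  }
  met <- function(p, j) sprintf("X_%03d_%d", p, j)

  for (p in seq_len(P)) {
    uptake <- if (planted[p]) 20 else 12
    addRxn(sprintf("EX_%03d", p), setNames(1, met(p, 0)), 0, uptake, "",
           "Exchange/demand")
    for (j in seq_len(R)) {
      rule <- paste(gn[, j, p], collapse = " AND ")
      addRxn(sprintf("RXN_%03d_%d", p, j),
             setNames(c(-1, 1), c(met(p, j - 1), met(p, j))),
             0, 10, rule, labs[p])
    }
    addRxn(sprintf("BURN_%03d", p), setNames(c(-1, 1), c(met(p, R), "atp")),
           0, 1e4, "", "Energy salvage")
  }
  ## biomass demand saturates below any chain capacity (caps stay above ~6
  ## under the default expression amplitudes), so each pathway's flux tracks
  ## its own expression-derived capacity rather than the cohort-wide minimum
  addRxn("BIOMASS", setNames(rep(-1, P), vapply(seq_len(P), met, "", j = R)),
         0, 5, "", "Biomass")
  addRxn("ATPM", setNames(-1, "atp"), 0, 1e4, "", "Maintenance")
  colnames(S) <- rid
  MetabolicModel(rid, mets, S, lb, ub, gpr = gpr, subsystem = sub,
                 biomassIndex = match("BIOMASS", rid),
                 maintenanceIndex = match("ATPM", rid))
}

#' Generate an age-structured synthetic cohort
#'
#' Draws integer chronological ages uniformly over the spec's range, then
#' builds probe-level expression:
#' \itemize{
#'   \item age-gene probes follow \eqn{x = 1 + b (age - \bar a) + N(0,
#'     noiseSd)} with per-gene slopes \eqn{b \sim N(0, effectScale)};
#'   \item probes of genes governing planted-pathway reactions follow
#'     \eqn{x = \exp(s (age - \bar a)/\sigma_a) + N(0, fluxNoiseSd)}, the
#'     log-scale amplitude \eqn{|s|} = \code{plantedAmplitude} with signs
#'     alternating (+, -, +, ...) across planted pathways;
#'   \item remaining model-gene probes are \eqn{1 + N(0, fluxNoiseSd)} and
#'     background probes \eqn{1 + N(0, noiseSd)}.
#' }
#' Expression is truncated at zero. The returned effect-size table contains
#' the drawn age-gene slopes (the planted ground truth for the
#' transcriptomic predictor).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param model the matching toy model from \code{\link{makeToyModel}}.
#' @return list with elements \code{expr} (a raw, un-normalised
#'   \linkS4class{CohortExpression}), \code{effects} (named numeric,
#'   gene -> planted slope) and \code{pathwaySigns} (named numeric, planted
#'   pathway -> trend sign).
#' @export
makeCohort <- function(spec, model) {
  stopifnot(is(spec, "SyntheticSpec"), is(model, "MetabolicModel"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nIndividuals
  age <- sample(seq(spec@ageRange[1], spec@ageRange[2]), n, replace = TRUE)
  agec <- age - mean(age)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(294, 205) / 499)
  ids <- sprintf("ind_%03d", seq_len(n))

  modelGenes <- unique(unlist(lapply(gprRules(model), function(r)
    gprGenes(parseGPR(r)))))
  nFixed <- spec@nAgeGenes + length(modelGenes)
  if (spec@nProbes < nFixed)
    stop(sprintf("nProbes = %d cannot cover %d age genes + %d model genes",
                 spec@nProbes, spec@nAgeGenes, length(modelGenes)),
         call. = FALSE)
  nBg <- spec@nProbes - nFixed

  ageGenes <- sprintf("AGE_%03d", seq_len(spec@nAgeGenes))
  slopes <- rnorm(spec@nAgeGenes, 0, spec@effectScale)
  bgGenes <- if (nBg) sprintf("BG_%03d", seq_len(nBg)) else character(0)

  geneOfProbe <- c(ageGenes, modelGenes, bgGenes)
  probes <- paste0("pr_", geneOfProbe)
  vals <- matrix(NA_real_, length(probes), n,
                 dimnames = list(probes, ids))

  for (k in seq_len(spec@nAgeGenes))
    vals[k, ] <- 1 + slopes[k] * agec + rnorm(n, 0, spec@noiseSd)

  ## planted pathway trends: alternate sign so both directions are recoverable
  planted <- spec@plantedPathways
  pathwaySigns <- setNames(rep_len(c(1, -1), length(planted)), planted)
  sigmaAge <- cohortSD(age)
  subOfGene <- rep(subsystems(model), vapply(gprRules(model), function(r)
    length(gprGenes(parseGPR(r))), integer(1)))
  names(subOfGene) <- unlist(lapply(gprRules(model), function(r)
    gprGenes(parseGPR(r))))
  for (g in modelGenes) {
    row <- match(paste0("pr_", g), probes)
    ps <- subOfGene[[g]]
    if (!is.null(ps) && ps %in% planted) {
      s <- pathwaySigns[[ps]] * spec@plantedAmplitude
      vals[row, ] <- exp(s * agec / sigmaAge) + rnorm(n, 0, spec@fluxNoiseSd)
    } else {
      vals[row, ] <- 1 + rnorm(n, 0, spec@fluxNoiseSd)
    }
  }
  if (nBg)
    for (k in seq_len(nBg))
      vals[spec@nAgeGenes + length(modelGenes) + k, ] <-
        1 + rnorm(n, 0, spec@noiseSd)
  vals <- pmax(vals, 0)

  expr <- CohortExpression(vals,
                           probeGenes = setNames(as.list(geneOfProbe), probes),
                           age = age, sex = sex)
  list(expr = expr, effects = setNames(slopes, ageGenes),
       pathwaySigns = pathwaySigns)
}

#' Simulate a complete input set on disk
#'
#' Runs \code{\link{makeToyModel}} and \code{\link{makeCohort}} and writes
#' the standard pipeline inputs (tabular model bundle, SBML copy,
#' expression/metadata/probe-map TSVs, effect-size TSV) under \code{dir}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
simulateInputs <- function(spec, dir) {
  model <- makeToyModel(spec)
  coh <- makeCohort(spec, model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMetabolicModel(model, file.path(dir, "model"))
  writeModelSBML(model, file.path(dir, "model.xml"))
  writeCohort(coh$expr, dir)
  writeEffectSizes(coh$effects, file.path(dir, "effect_sizes.tsv"))
  invisible(dir)
}
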