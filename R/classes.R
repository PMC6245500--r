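## Central S4 containers shared by all pipeline stages.

#' MetabolicModel: a constraint-based metabolic network
#'
#' Holds the stoichiometric matrix, per-reaction flux bounds
#' (mmol/gDW/h), boolean gene-protein-reaction (GPR) rules, subsystem
#' (pathway) labels and the indices of the two objective reactions: the
#' primary (biomass) and the secondary (ATP maintenance) objective of the
#' lexicographic flux balance solve.
#'
#' @slot reactionIds character, unique reaction identifiers (columns of S).
#' @slot metaboliteIds character, unique metabolite identifiers (rows of S).
#' @slot S numeric matrix, metabolites x reactions stoichiometry.
#' @slot lowerBounds,upperBounds numeric, per-reaction flux bounds.
#' @slot gpr character, per-reaction boolean gene rule over AND/OR and
#'   parentheses; \code{""} means no gene association.
#' @slot subsystem character, per-reaction pathway label.
#' @slot biomassIndex,maintenanceIndex integer(1), objective reaction indices.
#'
#' @param x a \code{MetabolicModel}.
#' @return Accessors return the corresponding slot; \code{stoichiometry}
#'   returns the metabolites x reactions matrix with dimnames set.
#' @examples
#' mod <- makeToyModel(SyntheticSpec(nPathways = 3, reactionsPerPathway = 2))
#' length(reactionIds(mod))
#' table(subsystems(mod))
#' @aliases reactionIds metaboliteIds stoichiometry lowerBounds upperBounds
#'   gprRules subsystems biomassReaction maintenanceReaction
#' @name MetabolicModel-class
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    reactionIds = "character",
    metaboliteIds = "character",
    S = "matrix",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    gpr = "character",
    subsystem = "character",
    biomassIndex = "integer",
    maintenanceIndex = "integer"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  nr <- length(object@reactionIds)
  nm <- length(object@metaboliteIds)
  if (anyDuplicated(object@reactionIds))
    msg <- c(msg, "duplicate reaction ids")
  if (anyDuplicated(object@metaboliteIds))
    msg <- c(msg, "duplicate metabolite ids")
  if (ncol(object@S) != nr)
    msg <- c(msg, sprintf("S has %d columns but there are %d reaction ids",
                          ncol(object@S), nr))
  if (nrow(object@S) != nm)
    msg <- c(msg, sprintf("S has %d rows but there are %d metabolite ids",
                          nrow(object@S), nm))
  for (sl in c("lowerBounds", "upperBounds", "gpr", "subsystem"))
    if (length(slot(object, sl)) != nr)
      msg <- c(msg, sprintf("slot '%s' must have one entry per reaction", sl))
  if (length(object@lowerBounds) == nr &&
      any(object@lowerBounds > object@upperBounds + 1e-12))
    msg <- c(msg, "lower bound exceeds upper bound for some reaction")
  if (length(object@biomassIndex) != 1L || length(object@maintenanceIndex) != 1L)
    msg <- c(msg, "objective indices must be single integers")
  else {
    if (object@biomassIndex < 1L || object@biomassIndex > nr ||
        object@maintenanceIndex < 1L || object@maintenanceIndex > nr)
      msg <- c(msg, "objective index out of range")
    else if (object@biomassIndex == object@maintenanceIndex)
      msg <- c(msg, "primary and secondary objective must differ")
  }
  nonempty <- which(nzchar(object@gpr))
  for (i in nonempty) {
    ok <- tryCatch({ parseGPR(object@gpr[i]); TRUE }, error = function(e) FALSE)
    if (!ok) {
      msg <- c(msg, sprintf("GPR rule for reaction '%s' does not parse",
                            object@reactionIds[i]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicModel
#'
#' @param reactionIds,metaboliteIds unique identifier vectors.
#' @param S metabolites x reactions stoichiometric matrix.
#' @param lowerBounds,upperBounds per-reaction flux bounds (mmol/gDW/h).
#' @param gpr per-reaction GPR rule strings; empty string for none. Missing
#'   entries (\code{NA}) become the empty rule.
#' @param subsystem per-reaction pathway labels; missing entries become
#'   \code{"unassigned"}.
#' @param biomassIndex,maintenanceIndex indices (or reaction ids) of the
#'   primary and secondary objective reactions.
#' @return a validated \code{MetabolicModel}.
#' @export
MetabolicModel <- function(reactionIds, metaboliteIds, S, lowerBounds,
                           upperBounds, gpr = NULL, subsystem = NULL,
                           biomassIndex, maintenanceIndex) {
  nr <- length(reactionIds)
  if (is.null(gpr)) gpr <- rep("", nr)
  if (is.null(subsystem)) subsystem <- rep("unassigned", nr)
  gpr[is.na(gpr)] <- ""
  subsystem[is.na(subsystem) | !nzchar(subsystem)] <- "unassigned"
  asIndex <- function(i) {
    if (is.character(i)) i <- match(i, reactionIds)
    as.integer(i)
  }
  S <- as.matrix(S)
  if (nrow(S) == length(metaboliteIds) && ncol(S) == length(reactionIds))
    dimnames(S) <- list(metaboliteIds, reactionIds)  # else validity reports
  new("MetabolicModel",
      reactionIds = as.character(reactionIds),
      metaboliteIds = as.character(metaboliteIds),
      S = S,
      lowerBounds = as.numeric(lowerBounds),
      upperBounds = as.numeric(upperBounds),
      gpr = as.character(gpr),
      subsystem = as.character(subsystem),
      biomassIndex = asIndex(biomassIndex),
      maintenanceIndex = asIndex(maintenanceIndex))
}

#' @rdname MetabolicModel-class
setMethod("reactionIds", "MetabolicModel", function(x) x@reactionIds)
#' @rdname MetabolicModel-class
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metaboliteIds)
#' @rdname MetabolicModel-class
setMethod("stoichiometry", "MetabolicModel", function(x) x@S)
#' @rdname MetabolicModel-class
setMethod("lowerBounds", "MetabolicModel", function(x)
  setNames(x@lowerBounds, x@reactionIds))
#' @rdname MetabolicModel-class
setMethod("upperBounds", "MetabolicModel", function(x)
  setNames(x@upperBounds, x@reactionIds))
#' @rdname MetabolicModel-class
setMethod("gprRules", "MetabolicModel", function(x)
  setNames(x@gpr, x@reactionIds))
#' @rdname MetabolicModel-class
setMethod("subsystems", "MetabolicModel", function(x)
  setNames(x@subsystem, x@reactionIds))
#' @rdname MetabolicModel-class
setMethod("biomassReaction", "MetabolicModel", function(x) x@biomassIndex)
#' @rdname MetabolicModel-class
setMethod("maintenanceReaction", "MetabolicModel", function(x) x@maintenanceIndex)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel with", length(object@reactionIds), "reactions,",
      length(object@metaboliteIds), "metabolites\n")
  cat("  subsystems:", length(unique(object@subsystem)), "\n")
  cat("  primary objective:   ", object@reactionIds[object@biomassIndex], "\n")
  cat("  secondary objective: ", object@reactionIds[object@maintenanceIndex], "\n")
  ng <- sum(nzchar(object@gpr))
  cat("  reactions with GPR:  ", ng, "\n")
})

#' CohortExpression: probe-level expression for an age-annotated cohort
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"exprs"} assay is a
#' probe x individual matrix of non-negative expression values, the row data
#' carry the probe-to-gene mapping (a probe may map to several genes), and
#' the column data carry each individual's chronological age (years) and sex.
#'
#' @param values probe x individual numeric matrix with dimnames.
#' @param probeGenes named list (or CharacterList), probe id -> gene ids.
#' @param age numeric, chronological ages in years (one per individual).
#' @param sex character, per-individual labels.
#' @param x a \code{CohortExpression}.
#' @return \code{CohortExpression()} returns the validated object. Accessors:
#'   \code{exprValues} the matrix, \code{probeGenes} a named list,
#'   \code{ages}/\code{sexes} named vectors, \code{probeIds}/
#'   \code{individualIds} the dimnames.
#' @aliases probeIds individualIds probeGenes exprValues ages sexes
#' @name CohortExpression-class
#' @exportClass CohortExpression
setClass("CohortExpression", contains = "SummarizedExperiment")

setValidity("CohortExpression", function(object) {
  msg <- character()
  if (!"exprs" %in% names(SummarizedExperiment::assays(object)))
    return("assay 'exprs' is missing")
  v <- assay(object, "exprs")
  if (anyNA(v)) msg <- c(msg, "expression values contain missing entries")
  else if (any(v < 0)) msg <- c(msg, "expression values must be non-negative")
  if (!"genes" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'genes' (probe->gene mapping) is missing")
  cd <- colData(object)
  if (!all(c("age", "sex") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'age' and 'sex'")
  else {
    if (anyNA(cd$age)) msg <- c(msg, "missing ages")
    else if (any(cd$age < 0)) msg <- c(msg, "negative ages")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CohortExpression-class
#' @export
CohortExpression <- function(values, probeGenes, age, sex = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs probe rownames and individual colnames")
  if (is.null(sex)) sex <- rep(NA_character_, ncol(values))
  pg <- probeGenes[rownames(values)]
  pg[vapply(pg, is.null, logical(1))] <- list(character(0))
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(genes = CharacterList(pg), row.names = rownames(values)),
    colData = DataFrame(age = as.numeric(age), sex = as.character(sex),
                        row.names = colnames(values)))
  new("CohortExpression", se)
}

#' @rdname CohortExpression-class
setMethod("exprValues", "CohortExpression", function(x) assay(x, "exprs"))
#' @rdname CohortExpression-class
setMethod("probeIds", "CohortExpression", function(x) rownames(x))
#' @rdname CohortExpression-class
setMethod("individualIds", "CohortExpression", function(x) colnames(x))
#' @rdname CohortExpression-class
setMethod("probeGenes", "CohortExpression", function(x)
  setNames(as.list(rowData(x)$genes), rownames(x)))
#' @rdname CohortExpression-class
setMethod("ages", "CohortExpression", function(x)
  setNames(colData(x)$age, colnames(x)))
#' @rdname CohortExpression-class
setMethod("sexes", "CohortExpression", function(x)
  setNames(colData(x)$sex, colnames(x)))

setMethod("show", "CohortExpression", function(object) {
  cat("CohortExpression:", nrow(object), "probes x", ncol(object),
      "individuals\n")
  a <- colData(object)$age
  cat(sprintf("  age: %.1f-%.1f years (mean %.1f)\n",
              min(a), max(a), mean(a)))
  callNextMethod()
})

#' FluxProfileMatrix: per-individual flux distributions
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"flux"} assay is a
#' reaction x individual matrix of steady-state fluxes (mmol/gDW/h), row data
#' carry the subsystem label of each reaction, and the
#' \code{pathwayFluxes} slot holds the pathway x individual matrix of mean
#' member-reaction fluxes.
#'
#' @slot pathwayFluxes pathway x individual numeric matrix.
#' @param x a \code{FluxProfileMatrix}.
#' @return \code{fluxMatrix} returns the individual x reaction matrix (the
#'   orientation the statistics consume); \code{pathwayFluxMatrix} the
#'   individual x pathway matrix.
#' @aliases fluxMatrix pathwayFluxMatrix
#' @name FluxProfileMatrix-class
#' @exportClass FluxProfileMatrix
setClass("FluxProfileMatrix",
  contains = "SummarizedExperiment",
  representation(pathwayFluxes = "matrix"))

setValidity("FluxProfileMatrix", function(object) {
  msg <- character()
  if (!"flux" %in% names(SummarizedExperiment::assays(object)))
    return("assay 'flux' is missing")
  if (!"subsystem" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'subsystem' is missing")
  pf <- object@pathwayFluxes
  if (!identical(colnames(pf), colnames(object)))
    msg <- c(msg, "pathwayFluxes columns must match individuals")
  else if ("subsystem" %in% colnames(rowData(object))) {
    recomputed <- rowsumByGroup(assay(object, "flux"),
                                rowData(object)$subsystem)
    recomputed <- recomputed[rownames(pf), , drop = FALSE]
    if (max(abs(recomputed - pf)) > 1e-8)
      msg <- c(msg, "pathwayFluxes inconsistent with per-reaction fluxes")
  }
  if (length(msg)) msg else TRUE
})

# group means of rows of m by label (used for pathway aggregation)
rowsumByGroup <- function(m, labels) {
  g <- factor(labels)
  out <- rowsum(m, g) / as.vector(table(g))
  out[levels(g), , drop = FALSE]
}

newFluxProfileMatrix <- function(fluxes, subsystem, age = NULL, sex = NULL) {
  ## fluxes: reaction x individual
  cd <- DataFrame(row.names = colnames(fluxes))
  if (!is.null(age)) cd$age <- as.numeric(age)
  if (!is.null(sex)) cd$sex <- as.character(sex)
  se <- SummarizedExperiment(
    assays = list(flux = fluxes),
    rowData = DataFrame(subsystem = subsystem, row.names = rownames(fluxes)),
    colData = cd)
  new("FluxProfileMatrix", se,
      pathwayFluxes = rowsumByGroup(fluxes, subsystem))
}

#' @rdname FluxProfileMatrix-class
setMethod("fluxMatrix", "FluxProfileMatrix", function(x)
  t(assay(x, "flux")))
#' @rdname FluxProfileMatrix-class
setMethod("pathwayFluxMatrix", "FluxProfileMatrix", function(x)
  t(x@pathwayFluxes))
#' @rdname FluxProfileMatrix-class
setMethod("ages", "FluxProfileMatrix", function(x)
  setNames(colData(x)$age, colnames(x)))
#' @rdname FluxProfileMatrix-class
setMethod("subsystems", "FluxProfileMatrix", function(x)
  setNames(rowData(x)$subsystem, rownames(x)))

setMethod("show", "FluxProfileMatrix", function(object) {
  cat("FluxProfileMatrix:", ncol(object), "individuals x", nrow(object),
      "reactions (", nrow(object@pathwayFluxes), "pathways )\n")
  callNextMethod()
})

#' AgePrediction: a cohort-scaled age predictor
#'
#' Stores the raw per-individual predictor (the effect-size-weighted sum Z
#' over probes, or M over pathway fluxes) together with its affine rescaling
#' to the cohort's chronological-age mean and standard deviation, which
#' defines the transcriptomic age SZ or the metabolic age SM.
#'
#' @slot individualIds character.
#' @slot predictor numeric, raw Z or M values (dimensionless).
#' @slot scaledAge numeric, SZ or SM in years.
#' @slot muAge,sigmaAge numeric(1), cohort age mean/SD (years).
#' @slot muPred,sigmaPred numeric(1), predictor mean/SD.
#' @slot layer character(1), \code{"transcriptomic"} or \code{"metabolic"}.
#' @param x an \code{AgePrediction}.
#' @aliases predictorValues scaledAges
#' @name AgePrediction-class
#' @exportClass AgePrediction
setClass("AgePrediction",
  representation(
    individualIds = "character",
    predictor = "numeric",
    scaledAge = "numeric",
    muAge = "numeric", sigmaAge = "numeric",
    muPred = "numeric", sigmaPred = "numeric",
    layer = "character"))

setValidity("AgePrediction", function(object) {
  msg <- character()
  n <- length(object@individualIds)
  if (length(object@predictor) != n || length(object@scaledAge) != n)
    msg <- c(msg, "per-individual vectors must share length")
  if (object@sigmaPred <= 0)
    msg <- c(msg, "sigmaPred must be positive")
  if (n >= 2) {
    if (abs(mean(object@scaledAge) - object@muAge) > 1e-6)
      msg <- c(msg, "mean(scaled age) must equal the cohort age mean")
    if (abs(sd(object@scaledAge) - object@sigmaAge) > 1e-6)
      msg <- c(msg, "SD(scaled age) must equal the cohort age SD")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AgePrediction-class
setMethod("predictorValues", "AgePrediction", function(x)
  setNames(x@predictor, x@individualIds))
#' @rdname AgePrediction-class
setMethod("scaledAges", "AgePrediction", function(x)
  setNames(x@scaledAge, x@individualIds))
#' @rdname AgePrediction-class
setMethod("individualIds", "AgePrediction", function(x) x@individualIds)

setMethod("show", "AgePrediction", function(object) {
  cat(sprintf("AgePrediction (%s), %d individuals\n", object@layer,
              length(object@individualIds)))
  cat(sprintf("  predictor: mean %.4g, sd %.4g\n", object@muPred,
              object@sigmaPred))
  cat(sprintf("  scaled age: mean %.2f y, sd %.2f y\n", object@muAge,
              object@sigmaAge))
})

#' As a data.frame
#' @param x an AgePrediction
#' @param row.names,optional,... passed through (unused)
#' @export
#' @method as.data.frame AgePrediction
as.data.frame.AgePrediction <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(individual_id = x@individualIds,
             predictor = x@predictor,
             scaled_age = x@scaledAge,
             stringsAsFactors = FALSE)
}

#' SilhouetteCurve: mean age-based silhouette over a range of cluster counts
#'
#' @slot kValues integer, evaluated cluster counts (strictly increasing).
#' @slot meanSilhouette numeric in [-1, 1], cohort mean of the per-individual
#'   age-based silhouette at each k.
#' @slot method character(1), \code{"kmeans"} or \code{"hierarchical"}.
#' @slot layer character(1), data layer the clustering ran on.
#' @name SilhouetteCurve-class
#' @exportClass SilhouetteCurve
setClass("SilhouetteCurve",
  representation(kValues = "integer", meanSilhouette = "numeric",
                 method = "character", layer = "character"))

setValidity("SilhouetteCurve", function(object) {
  msg <- character()
  if (length(object@kValues) != length(object@meanSilhouette))
    msg <- c(msg, "kValues and meanSilhouette lengths differ")
  if (is.unsorted(object@kValues, strictly = TRUE))
    msg <- c(msg, "kValues must be strictly increasing")
  if (any(object@meanSilhouette < -1 - 1e-12 | object@meanSilhouette > 1 + 1e-12))
    msg <- c(msg, "mean silhouette values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SilhouetteCurve", function(object) {
  cat(sprintf("SilhouetteCurve (%s, %s): k = %d..%d, max %.3f at k = %d\n",
              object@method, object@layer, min(object@kValues),
              max(object@kValues), max(object@meanSilhouette),
              object@kValues[which.max(object@meanSilhouette)]))
})

#' PCAContribution: eigenvalues and variable contributions for one age group
#'
#' Standardised (correlation-based) PCA of an individual x variable flux
#' matrix for one age group. Contributions are percentages per component
#' (each column sums to 100); totals are the eigenvalue-weighted sums over
#' the retained components.
#'
#' @slot groupLabel character(1).
#' @slot nIndividuals integer(1).
#' @slot eigenvalues numeric, non-increasing.
#' @slot contributions variable x component matrix of percentages.
#' @slot nRetained integer(1), NA until \code{\link{retainComponents}} ran.
#' @slot totals named numeric, per-variable weighted totals (empty until
#'   \code{\link{totalContribution}} ran).
#' @slot dropped character, zero-variance variables removed before PCA.
#' @name PCAContribution-class
#' @exportClass PCAContribution
setClass("PCAContribution",
  representation(groupLabel = "character", nIndividuals = "integer",
                 eigenvalues = "numeric", contributions = "matrix",
                 nRetained = "integer", totals = "numeric",
                 dropped = "character"))

setValidity("PCAContribution", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) && any(diff(ev) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (ncol(object@contributions) != length(ev))
    msg <- c(msg, "one contribution column per eigenvalue required")
  cs <- colSums(object@contributions)
  if (length(cs) && max(abs(cs - 100)) > 1e-6)
    msg <- c(msg, "contribution columns must sum to 100")
  if (!is.na(object@nRetained) && object@nRetained < 1L)
    msg <- c(msg, "nRetained must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAContribution", function(object) {
  cat(sprintf("PCAContribution '%s': %d individuals, %d variables\n",
              object@groupLabel, object@nIndividuals,
              nrow(object@contributions)))
  if (!is.na(object@nRetained))
    cat(sprintf("  retained components: %d (%.2f%% of variance)\n",
                object@nRetained,
                100 * sum(object@eigenvalues[seq_len(object@nRetained)]) /
                  sum(object@eigenvalues)))
  if (length(object@dropped))
    cat("  dropped zero-variance variables:", length(object@dropped), "\n")
})

#' ElasticNetFit: an elastic-net regression path with tenfold CV
#'
#' @slot alpha numeric(1), L1/L2 mixing parameter.
#' @slot lambdaGrid numeric, 100 decreasing penalty values.
#' @slot cvMse numeric, per-lambda mean squared error from cross-validation.
#' @slot lambdaStar numeric(1), penalty with the lowest mean CV MSE.
#' @slot beta0 numeric(1), intercept (years).
#' @slot beta named numeric, coefficients at lambdaStar on the original
#'   predictor scale (years per flux unit).
#' @slot selected character, predictors with nonzero coefficient.
#' @slot dropped character, zero-variance predictors removed before fitting.
#' @slot betaPath predictor x lambda matrix of coefficients along the whole
#'   path (original scale).
#' @slot beta0Path per-lambda intercepts.
#' @param x an \code{ElasticNetFit}.
#' @aliases selectedPredictors effectSizes
#' @name ElasticNetFit-class
#' @exportClass ElasticNetFit
setClass("ElasticNetFit",
  representation(alpha = "numeric", lambdaGrid = "numeric", cvMse = "numeric",
                 lambdaStar = "numeric", beta0 = "numeric", beta = "numeric",
                 selected = "character", dropped = "character",
                 betaPath = "matrix", beta0Path = "numeric"))

setValidity("ElasticNetFit", function(object) {
  msg <- character()
  if (length(object@lambdaGrid) != 100L)
    msg <- c(msg, "lambda grid must contain 100 values")
  if (is.unsorted(rev(object@lambdaGrid), strictly = TRUE))
    msg <- c(msg, "lambda grid must be strictly decreasing")
  if (!object@lambdaStar %in% object@lambdaGrid)
    msg <- c(msg, "lambdaStar must be a grid value")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname ElasticNetFit-class
setMethod("selectedPredictors", "ElasticNetFit", function(x) x@selected)
#' @rdname ElasticNetFit-class
setMethod("effectSizes", "ElasticNetFit", function(x) x@beta)

setMethod("show", "ElasticNetFit", function(object) {
  cat(sprintf("ElasticNetFit: alpha = %.2f, lambda* = %.4g\n", object@alpha,
              object@lambdaStar))
  cat(sprintf("  %d of %d predictors selected\n", length(object@selected),
              length(object@beta)))
})

#' FluxSolverConfig: parameters of the expression-to-bounds map and LP solve
#'
#' @slot gamma numeric(1) > 0, sensitivity of the bound map phi.
#' @slot epsilonPrimary numeric(1) in [0, 1), fractional slack allowed on the
#'   primary optimum when maximising the secondary objective.
#' @slot lpTolerance numeric(1), solver feasibility tolerance.
#' @slot missingGeneValue numeric(1), expression assigned to GPR genes absent
#'   from the profile (1 = neutral).
#' @slot thetaFloor numeric(1), floor applied to reaction expression before
#'   taking the logarithm.
#' @param gamma,epsilonPrimary,lpTolerance,missingGeneValue,thetaFloor see slots.
#' @return a validated \code{FluxSolverConfig}.
#' @examples
#' FluxSolverConfig(gamma = 2)
#' @name FluxSolverConfig-class
#' @exportClass FluxSolverConfig
setClass("FluxSolverConfig",
  representation(gamma = "numeric", epsilonPrimary = "numeric",
                 lpTolerance = "numeric", missingGeneValue = "numeric",
                 thetaFloor = "numeric"))

setValidity("FluxSolverConfig", function(object) {
  msg <- character()
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@epsilonPrimary < 0 || object@epsilonPrimary >= 1)
    msg <- c(msg, "epsilonPrimary must lie in [0, 1)")
  if (object@lpTolerance <= 0) msg <- c(msg, "lpTolerance must be > 0")
  if (object@thetaFloor <= 0) msg <- c(msg, "thetaFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FluxSolverConfig-class
#' @export
FluxSolverConfig <- function(gamma = 1, epsilonPrimary = 0,
                             lpTolerance = 1e-9, missingGeneValue = 1,
                             thetaFloor = 1e-6) {
  new("FluxSolverConfig", gamma = gamma, epsilonPrimary = epsilonPrimary,
      lpTolerance = lpTolerance, missingGeneValue = missingGeneValue,
      thetaFloor = thetaFloor)
}

setMethod("show", "FluxSolverConfig", function(object) {
  cat(sprintf(
    "FluxSolverConfig: gamma = %g, epsilon = %g, lp tol = %g, missing = %g\n",
    object@gamma, object@epsilonPrimary, object@lpTolerance,
    object@missingGeneValue))
})
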