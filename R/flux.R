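## Expression-constrained flux modelling: the bound map phi, the per-reaction
## bound transformation, the lexicographic (bilevel) FBA solve, and the
## cohort-level driver producing one flux profile per individual.

#' Bound map phi: reaction expression to a bound coefficient
#'
#' Converts a reaction expression value Theta into a multiplicative
#' coefficient for the reaction's flux bounds:
#' \deqn{\varphi(\Theta) = (1 + \gamma |\ln \Theta|)^{\mathrm{sign}(\Theta - 1)}}
#' so that \eqn{\varphi(1) = 1} (neutral), over-expressed reactions widen
#' their bounds logarithmically and under-expressed reactions tighten them
#' symmetrically: \eqn{\varphi(\Theta)\,\varphi(1/\Theta) = 1}. Theta is
#' floored at \code{thetaFloor} before the logarithm so zero expression gives
#' a finite (very small) coefficient rather than shutting the solver down.
#'
#' @param theta non-negative reaction expression value(s).
#' @param gamma sensitivity parameter, > 0.
#' @param thetaFloor positive floor applied to theta.
#' @return coefficient(s) phi(theta) > 0.
#' @examples
#' boundCoefficient(1)             # 1
#' boundCoefficient(exp(1))        # 2
#' boundCoefficient(exp(-1))       # 0.5
#' @export
boundCoefficient <- function(theta, gamma = 1, thetaFloor = 1e-6) {
  stopifnot(all(theta >= 0), gamma > 0, thetaFloor > 0)
  th <- pmax(theta, thetaFloor)
  (1 + gamma * abs(log(th)))^sign(th - 1)
}

#' Apply expression-derived coefficients to flux bounds
#'
#' Multiplies both bounds of every reaction that has a gene association by
#' phi(Theta). Reactions with an empty GPR keep their bounds. Since phi > 0
#' the ordering lower <= upper is preserved; negative lower bounds of
#' reversible reactions are scaled by the same coefficient, so
#' over-expression widens the whole reversible range.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param theta per-reaction expression values (length = reactions).
#' @param config a \linkS4class{FluxSolverConfig}.
#' @return list with numeric vectors \code{lower} and \code{upper}.
#' @export
applyExpressionBounds <- function(model, theta, config = FluxSolverConfig()) {
  stopifnot(is(model, "MetabolicModel"),
            length(theta) == length(model@reactionIds))
  phi <- boundCoefficient(theta, gamma = config@gamma,
                          thetaFloor = config@thetaFloor)
  phi[!nzchar(model@gpr)] <- 1
  list(lower = model@lowerBounds * phi, upper = model@upperBounds * phi)
}

#' Lexicographic (bilevel) flux balance analysis
#'
#' Solves the two-objective flux balance problem: first maximise the primary
#' objective (biomass) subject to steady state \eqn{Sv = 0} and the
#' transformed bounds, giving optimum F*; then maximise the secondary
#' objective (ATP maintenance) over the near-optimal face
#' \eqn{f^\top v \ge (1 - \epsilon) F^*} (sign-aware when F* < 0). With the
#' default \eqn{\epsilon = 0} the secondary solve cannot degrade the primary
#' optimum.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param lower,upper transformed bounds; default the model's own bounds.
#' @param config a \linkS4class{FluxSolverConfig}.
#' @param individual optional id used in error messages.
#' @return list with \code{fluxes} (named per-reaction vector),
#'   \code{primary} (F*) and \code{secondary} (the attained g'v).
#' @examples
#' mod <- makeToyModel(SyntheticSpec(nPathways = 2, reactionsPerPathway = 1))
#' sol <- bilevelFBA(mod)
#' sol$primary
#' @export
bilevelFBA <- function(model, lower = NULL, upper = NULL,
                       config = FluxSolverConfig(), individual = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  if (is.null(lower)) lower <- model@lowerBounds
  if (is.null(upper)) upper <- model@upperBounds
  nr <- length(model@reactionIds)
  stopifnot(length(lower) == nr, length(upper) == nr)
  if (any(lower > upper + 1e-12))
    stop("transformed bounds are inconsistent (lower > upper)")
  who <- if (is.null(individual)) "" else sprintf(" for individual '%s'",
                                                  individual)

  f <- numeric(nr); f[model@biomassIndex] <- 1
  g <- numeric(nr); g[model@maintenanceIndex] <- 1

  lp1 <- solveLinearProgram(f, model@S, rep(0, nrow(model@S)), lower, upper,
                            tol = config@lpTolerance)
  if (lp1$status == "infeasible")
    stop("infeasible individual model", who, call. = FALSE)
  if (lp1$status != "optimal")
    stop("primary FBA solve ", lp1$status, who, call. = FALSE)
  Fstar <- lp1$objective

  eps <- config@epsilonPrimary
  thr <- if (Fstar >= 0) (1 - eps) * Fstar else (1 + eps) * Fstar
  ## slack variable turns f'v >= thr into an equality row
  A2 <- cbind(rbind(model@S, f), c(rep(0, nrow(model@S)), -1))
  lp2 <- solveLinearProgram(c(g, 0), A2, c(rep(0, nrow(model@S)), thr),
                            c(lower, 0), c(upper, Inf),
                            tol = config@lpTolerance)
  if (lp2$status != "optimal")
    stop("secondary FBA solve ", lp2$status, who, call. = FALSE)
  v <- lp2$solution[seq_len(nr)]
  names(v) <- model@reactionIds
  list(fluxes = v, primary = sum(f * v), secondary = lp2$objective)
}

## gene expression matrix (genes x individuals) from normalised probe values
geneExpressionMatrix <- function(expr, genes) {
  pg <- probeGenes(expr)
  vals <- exprValues(expr)
  long <- data.frame(
    probe = rep(names(pg), lengths(pg)),
    gene = unlist(pg, use.names = FALSE), stringsAsFactors = FALSE)
  long <- long[long$gene %in% genes, , drop = FALSE]
  out <- matrix(NA_real_, length(genes), ncol(vals),
                dimnames = list(genes, colnames(vals)))
  if (nrow(long)) {
    sp <- split(long$probe, long$gene)
    for (gn in names(sp)) {
      rows <- vals[sp[[gn]], , drop = FALSE]
      out[gn, ] <- colMeans(rows)
    }
  }
  out
}

#' Cohort-wide fluxomic profiles
#'
#' Runs one lexicographic FBA per individual: each individual's normalised
#' expression is aggregated probe-to-gene (mean over a gene's probes),
#' summarised per reaction through its GPR rule, converted to bound
#' coefficients by \code{\link{boundCoefficient}}, and the resulting
#' personalised model is solved by \code{\link{bilevelFBA}}. Pathway fluxes
#' are the per-individual means of member-reaction fluxes.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param expr a \linkS4class{CohortExpression} of normalised values (see
#'   \code{\link{normaliseProbes}}); the function does not re-normalise.
#' @param config a \linkS4class{FluxSolverConfig}.
#' @param strict if \code{TRUE} (default) any per-individual solver failure
#'   aborts after all individuals were attempted, reporting the failing ids;
#'   if \code{FALSE}, failed individuals are dropped with a warning.
#' @return a \linkS4class{FluxProfileMatrix}.
#' @export
cohortFluxomics <- function(model, expr, config = FluxSolverConfig(),
                            strict = TRUE) {
  stopifnot(is(model, "MetabolicModel"), is(expr, "CohortExpression"))
  asts <- lapply(gprRules(model), parseGPR)
  genes <- unique(unlist(lapply(asts, gprGenes)))
  gmat <- geneExpressionMatrix(expr, genes)
  gmat[is.na(gmat)] <- config@missingGeneValue

  inds <- individualIds(expr)
  nr <- length(model@reactionIds)
  withGenes <- which(!vapply(asts, is.null, logical(1)))
  fluxes <- matrix(NA_real_, nr, length(inds),
                   dimnames = list(model@reactionIds, inds))
  failed <- character(0)
  for (j in seq_along(inds)) {
    ge <- setNames(gmat[, j], rownames(gmat))  # [, j] drops names at 1 gene
    theta <- rep(1, nr)
    for (i in withGenes)
      theta[i] <- evalGPRAst(asts[[i]], ge, missing = config@missingGeneValue)
    b <- applyExpressionBounds(model, theta, config)
    sol <- tryCatch(
      bilevelFBA(model, b$lower, b$upper, config, individual = inds[j]),
      error = function(e) e)
    if (inherits(sol, "error")) failed <- c(failed, inds[j])
    else fluxes[, j] <- sol$fluxes
  }
  if (length(failed)) {
    msg <- sprintf("flux solve failed for %d individual(s): %s",
                   length(failed), paste(failed, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    fluxes <- fluxes[, !inds %in% failed, drop = FALSE]
    inds <- setdiff(inds, failed)
  }
  newFluxProfileMatrix(fluxes, subsystem = model@subsystem,
                       age = ages(expr)[inds], sex = sexes(expr)[inds])
}
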