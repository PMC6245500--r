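## Transcriptomic age: per-probe mean normalisation, probe-level effect
## sizes, the raw predictor Z and its affine rescaling to the cohort age
## distribution (the transcriptomic age SZ).
##
## All standard deviations in the package are sample SDs (n - 1 denominator),
## kept in one place so the convention is auditable; the mean/SD identity of
## the scaled ages holds under either convention.

cohortSD <- function(x) stats::sd(x)

#' Per-probe mean normalisation
#'
#' Divides every probe row by its own mean across individuals, so each
#' probe's cohort mean becomes exactly 1. This is the neutral point of the
#' flux bound map: an individual at the cohort average leaves the metabolic
#' model untouched.
#'
#' @param raw a \linkS4class{CohortExpression} of non-negative raw values.
#' @return a \linkS4class{CohortExpression} with row means 1.
#' @export
normaliseProbes <- function(raw) {
  stopifnot(is(raw, "CohortExpression"))
  v <- exprValues(raw)
  mu <- rowMeans(v)
  zero <- mu <= 0
  if (any(zero))
    stop("probe(s) with zero mean expression cannot be normalised: ",
         paste(rownames(v)[zero], collapse = ", "), call. = FALSE)
  CohortExpression(v / mu, probeGenes = probeGenes(raw), age = ages(raw),
                   sex = sexes(raw))
}

#' Probe-level effect sizes
#'
#' Maps gene effect sizes onto probes: a probe's effect size is the
#' arithmetic mean of the effect sizes of its mapped genes that appear in
#' the table. Mapped genes without a listed effect are ignored in the
#' average; probes with no listed gene at all are excluded from the
#' predictor.
#'
#' @param mapping named list, probe id -> gene ids (as returned by
#'   \code{\link{probeGenes}}).
#' @param effects named numeric vector, gene -> signed effect size.
#' @return named numeric vector, probe -> averaged effect size, containing
#'   only probes with at least one listed gene.
#' @examples
#' probeEffectSizes(list(p1 = c("gA", "gB")), c(gA = 0.2, gB = -0.4)) # -0.1
#' @export
probeEffectSizes <- function(mapping, effects) {
  b <- vapply(mapping, function(genes) {
    hit <- effects[genes[genes %in% names(effects)]]
    if (length(hit)) mean(hit) else NA_real_
  }, numeric(1))
  b[!is.na(b)]
}

scaleToCohortAge <- function(pred, age, ids, layer) {
  if (length(age) < 2) stop("need at least two individuals", call. = FALSE)
  sigmaAge <- cohortSD(age)
  if (sigmaAge <= 0) stop("chronological ages have zero variance",
                          call. = FALSE)
  muPred <- mean(pred)
  sigmaPred <- cohortSD(pred)
  if (sigmaPred <= 0)
    stop("degenerate predictor: zero variance across individuals",
         call. = FALSE)
  muAge <- mean(age)
  scaled <- muAge + (pred - muPred) * sigmaAge / sigmaPred
  new("AgePrediction", individualIds = ids, predictor = unname(pred),
      scaledAge = unname(scaled), muAge = muAge, sigmaAge = sigmaAge,
      muPred = muPred, sigmaPred = sigmaPred, layer = layer)
}

#' Transcriptomic age predictor
#'
#' Computes the raw transcriptomic predictor of each individual as the
#' effect-size-weighted sum of their normalised probe expression values,
#' \eqn{Z = \sum_i b_i x_i}, and rescales it to the cohort's chronological
#' age distribution:
#' \deqn{SZ = \mu_{age} + (Z - \mu_Z)\,\sigma_{age} / \sigma_Z}
#' so the scaled ages reproduce the cohort age mean and SD exactly.
#'
#' @param expr a \emph{normalised} \linkS4class{CohortExpression} (see
#'   \code{\link{normaliseProbes}}).
#' @param probeB named numeric vector of per-probe effect sizes (see
#'   \code{\link{probeEffectSizes}}); probes absent from the expression
#'   matrix are ignored.
#' @return an \linkS4class{AgePrediction} with layer
#'   \code{"transcriptomic"}.
#' @export
transcriptomicAge <- function(expr, probeB) {
  stopifnot(is(expr, "CohortExpression"))
  probeB <- probeB[names(probeB) %in% probeIds(expr)]
  if (!length(probeB))
    stop("no effect-size probe is present in the expression matrix",
         call. = FALSE)
  v <- exprValues(expr)[names(probeB), , drop = FALSE]
  z <- as.numeric(crossprod(v, probeB))
  scaleToCohortAge(z, unname(ages(expr)), individualIds(expr),
                   layer = "transcriptomic")
}
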