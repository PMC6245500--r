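## Elastic-net regression of chronological age on pathway (or reaction)
## fluxes, and the resulting metabolic age predictor. The penalised fit is
## delegated to glmnet, whose objective is exactly
##   1/(2N) sum (y - b0 - x'b)^2 + lambda * [ (1-a)/2 ||b||_2^2 + a ||b||_1 ].
## The lambda grid and the cross-validation loop live here so the grid size
## (100 values) and the age-stratified fold assignment are explicit.

elasticLambdaGrid <- function(X, y, alpha, nlambda = 100,
                              lambdaMinRatio = 1e-4) {
  ## analytic lambda_max: smallest penalty at which all coefficients vanish,
  ## computed on internally standardised predictors (population SD, as in
  ## glmnet); for alpha near 0 the lasso formula is damped the way glmnet
  ## does it (alpha floored at 0.001)
  n <- nrow(X)
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  Xs <- scale(X, center = TRUE, scale = sds)
  yc <- y - mean(y)
  a <- max(alpha, 0.001)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * a)
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nlambda))
}

## glmnet standardises the response internally, which leaves its L1 penalty
## on the documented scale but divides the quadratic penalty by the
## population SD of y. To fit the textbook objective
##   1/(2N) RSS + lambda * ( alpha ||b||_1 + (1-alpha)/2 ||b||_2^2 )
## exactly, reparameterise each call: matching the two penalty components
## gives lambda' = lambda (alpha + (1-alpha) sd(y)), alpha' = lambda alpha /
## lambda'. Identity when alpha = 1.
glmnetExact <- function(X, y, alpha, lambda, standardize) {
  sy <- sqrt(mean((y - mean(y))^2))
  scl <- alpha + (1 - alpha) * sy
  glmnet::glmnet(X, y, alpha = alpha / scl, lambda = lambda * scl,
                 standardize = standardize, thresh = 1e-12)
}

stratifiedFolds <- function(y, nFolds, seed) {
  ## fold ids stratified by age tertile so every fold spans the age range
  set.seed(seed)
  tert <- cut(y, breaks = quantile(y, probs = c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  fold <- integer(length(y))
  for (t in unique(tert)) {
    idx <- sample(which(tert == t))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Elastic-net regression path with tenfold cross-validation
#'
#' Fits the elastic-net path of chronological age on a flux matrix over a
#' log-spaced grid of 100 penalty values spanning four decades below the
#' analytic \eqn{\lambda_{max}}, estimates the per-penalty mean squared
#' error by k-fold cross-validation (folds stratified by age tertile), and
#' selects the penalty with the lowest mean CV MSE (ties resolved towards
#' the larger, sparser penalty). Predictors are standardised internally and
#' coefficients reported on the original flux scale.
#'
#' @param X individual x predictor flux matrix (pathways or reactions).
#' @param y chronological ages (years).
#' @param alpha L1/L2 mixing parameter (0 = ridge, 1 = lasso); 0.5 balances
#'   sparsity against the grouped selection of correlated pathways.
#' @param nFolds cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @param standardize standardise predictors before penalisation.
#' @param lambda optional explicit penalty grid (100 decreasing values).
#' @return an \linkS4class{ElasticNetFit}.
#' @export
elasticNetPath <- function(X, y, alpha = 0.5, nFolds = 10, seed = 1,
                           standardize = TRUE, lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < nFolds)
    stop("need at least as many individuals as folds", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in the regression inputs",
                                 call. = FALSE)
  if (var(y) == 0) stop("constant response: ages do not vary",
                        call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant predictors left", call. = FALSE)

  if (is.null(lambda)) lambda <- elasticLambdaGrid(X, y, alpha)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  ## glmnet requires >= 2 columns; pad single-predictor problems with an
  ## all-zero dummy that cannot enter the model
  pad <- ncol(X) == 1
  fitX <- if (pad) cbind(X, ".pad" = 0) else X

  fit <- glmnetExact(fitX, y, alpha, lambda, standardize)
  fold <- stratifiedFolds(y, nFolds, seed)
  sqerr <- matrix(NA_real_, nrow(X), length(lambda))
  for (f in seq_len(nFolds)) {
    test <- fold == f
    cvfit <- glmnetExact(fitX[!test, , drop = FALSE], y[!test],
                         alpha, lambda, standardize)
    pred <- predict(cvfit, fitX[test, , drop = FALSE])
    ## glmnet may stop the path early on a fold; carry the last fitted model
    if (ncol(pred) < length(lambda))
      pred <- cbind(pred, matrix(pred[, ncol(pred)], sum(test),
                                 length(lambda) - ncol(pred)))
    sqerr[test, ] <- (pred - y[test])^2
  }
  cvMse <- colMeans(sqerr)
  lambdaStar <- max(lambda[cvMse <= min(cvMse)])

  bp <- as.matrix(fit$beta)
  b0p <- as.numeric(fit$a0)
  if (ncol(bp) < length(lambda)) {        # early-stopped path: carry last fit
    extra <- length(lambda) - ncol(bp)
    bp <- cbind(bp, bp[, rep(ncol(bp), extra), drop = FALSE])
    b0p <- c(b0p, rep(b0p[length(b0p)], extra))
  }
  if (pad) bp <- bp[1, , drop = FALSE]
  dimnames(bp) <- list(colnames(X), NULL)
  jStar <- match(lambdaStar, lambda)
  beta <- setNames(bp[, jStar], colnames(X))
  new("ElasticNetFit", alpha = alpha, lambdaGrid = lambda, cvMse = cvMse,
      lambdaStar = lambdaStar, beta0 = b0p[jStar], beta = beta,
      selected = names(beta)[beta != 0], dropped = dropped,
      betaPath = bp, beta0Path = b0p)
}

#' Elastic-net penalty value
#'
#' The mixed penalty \eqn{P_\alpha(\beta) = \sum_j (1-\alpha)/2\,\beta_j^2 +
#' \alpha |\beta_j|} evaluated at a coefficient vector.
#'
#' @param beta coefficient vector.
#' @param alpha mixing parameter.
#' @return the penalty value.
#' @examples
#' elasticPenalty(c(1, -2), alpha = 0.5)  # 2.75
#' @export
elasticPenalty <- function(beta, alpha = 0.5) {
  sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

#' Elastic-net objective
#'
#' The penalised least-squares objective minimised by
#' \code{\link{elasticNetPath}} at one penalty value.
#'
#' @param X,y data.
#' @param beta0,beta intercept and coefficients.
#' @param lambda penalty strength.
#' @param alpha mixing parameter.
#' @return the objective value.
#' @export
elasticObjective <- function(X, y, beta0, beta, lambda, alpha = 0.5) {
  r <- y - beta0 - as.numeric(X %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * elasticPenalty(beta, alpha)
}

#' Metabolic age predictor
#'
#' Computes the metabolic predictor \eqn{M = \sum_i b_i f_i} over the
#' pathways with nonzero elastic-net effect size and rescales it to the
#' cohort's chronological-age mean and SD, giving the metabolic age SM (the
#' flux-layer analogue of the transcriptomic age).
#'
#' @param fluxes individual x pathway flux matrix (same flux scale the
#'   effect sizes were fitted on).
#' @param beta named numeric effect sizes (pathway -> years per flux unit);
#'   typically \code{effectSizes(fit)} from \code{\link{elasticNetPath}}.
#' @param ages chronological ages.
#' @return an \linkS4class{AgePrediction} with layer \code{"metabolic"}.
#' @export
metabolicAge <- function(fluxes, beta, ages) {
  fluxes <- as.matrix(fluxes)
  beta <- beta[beta != 0]
  if (!length(beta))
    stop("no predictor selected: all effect sizes are zero", call. = FALSE)
  miss <- setdiff(names(beta), colnames(fluxes))
  if (length(miss))
    stop("effect sizes refer to unknown pathway(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.numeric(fluxes[, names(beta), drop = FALSE] %*% beta)
  ids <- if (is.null(rownames(fluxes))) sprintf("ind_%03d", seq_along(m))
         else rownames(fluxes)
  scaleToCohortAge(m, as.numeric(ages), ids, layer = "metabolic")
}

#' Correlation of a scaled age with chronological age
#'
#' Pearson correlation with its two-sided p-value.
#'
#' @param sm scaled (metabolic or transcriptomic) ages, or an
#'   \linkS4class{AgePrediction}.
#' @param ages chronological ages.
#' @return list with \code{r} and \code{p.value}.
#' @export
ageCorrelation <- function(sm, ages) {
  if (is(sm, "AgePrediction")) sm <- scaledAges(sm)
  sm <- as.numeric(sm); ages <- as.numeric(ages)
  if (length(sm) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (sd(sm) == 0 || sd(ages) == 0)
    stop("zero variance in one of the inputs", call. = FALSE)
  ct <- cor.test(sm, ages, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}
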