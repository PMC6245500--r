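## Per-age-group PCA of flux matrices, with eigenvalue-weighted total
## contributions and between-group contribution differences.

#' Split a cohort into the three chronological age groups
#'
#' Boundaries: 21 and under, 22 to 49, 50 and over.
#'
#' @param ages numeric chronological ages (years).
#' @return factor with levels \code{"21-"}, \code{"22-49"}, \code{"50+"}.
#' @export
ageGroups <- function(ages) {
  cut(ages, breaks = c(-Inf, 21, 49, Inf),
      labels = c("21-", "22-49", "50+"))
}

#' Random-data variance threshold for component retention
#'
#' For an n x m data matrix with randomly distributed entries, each axis is
#' expected to carry 100/(n - 1) percent of the variance in terms of rows;
#' axes above this share are considered significant.
#'
#' @param n number of individuals (rows).
#' @return threshold percentage.
#' @examples
#' round(varianceThreshold(499), 2)  # 0.2
#' @export
varianceThreshold <- function(n) 100 / (n - 1)

#' Standardised PCA of one age group
#'
#' Variables are z-scored (zero mean, unit variance) before the
#' decomposition, so the eigenvalues are those of the correlation structure
#' and the Kaiser criterion (eigenvalue > 1) is meaningful. The contribution
#' of variable j to component i is the squared standardised loading as a
#' percentage, so every contribution column sums to 100. Zero-variance
#' columns are removed first and recorded.
#'
#' @param mat individual x variable numeric matrix (reaction or pathway
#'   fluxes).
#' @param groupLabel name stored on the result.
#' @return a \linkS4class{PCAContribution} without retention applied
#'   (\code{nRetained} is \code{NA} until \code{\link{retainComponents}}).
#' @export
fitGroupPCA <- function(mat, groupLabel = "all") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3)
    stop("PCA needs at least 3 individuals", call. = FALSE)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  vars <- apply(mat, 2, var)
  dropped <- colnames(mat)[vars <= 1e-12]
  keep <- mat[, vars > 1e-12, drop = FALSE]
  if (ncol(keep) == 0)
    stop("all variables are constant; nothing to decompose", call. = FALSE)
  pc <- prcomp(keep, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  contrib <- 100 * pc$rotation^2      # unit-norm loadings -> columns sum to 100
  colnames(contrib) <- paste0("PC", seq_along(ev))
  new("PCAContribution", groupLabel = groupLabel,
      nIndividuals = nrow(mat), eigenvalues = ev, contributions = contrib,
      nRetained = NA_integer_, totals = numeric(0), dropped = dropped)
}

#' Retain significant components
#'
#' Applies the three retention criteria: (i) Kaiser, eigenvalue > 1;
#' (iii) individual contribution to variance above the random-data threshold
#' \code{\link{varianceThreshold}}(n); and (ii) the retained set must carry
#' at least 50 percent of the total variance -- if the components passing
#' (i) and (iii) fall short, the count is extended down the eigenvalue
#' ranking until the cumulative share reaches 50 percent. Decisions use
#' unrounded shares; at least one component is always retained.
#'
#' @param pca a \linkS4class{PCAContribution} from \code{\link{fitGroupPCA}}.
#' @param nIndividuals group size; defaults to the one stored in \code{pca}.
#' @param minCumVariance cumulative variance floor (percent).
#' @return the \code{PCAContribution} with \code{nRetained} set.
#' @export
retainComponents <- function(pca, nIndividuals = NULL, minCumVariance = 50) {
  stopifnot(is(pca, "PCAContribution"))
  if (is.null(nIndividuals)) nIndividuals <- pca@nIndividuals
  ev <- pca@eigenvalues
  share <- 100 * ev / sum(ev)
  ok <- ev > 1 & share > varianceThreshold(nIndividuals)
  nk <- if (any(ok)) max(which(ok)) else 1L
  cum <- cumsum(share)
  while (cum[nk] < minCumVariance && nk < length(ev)) nk <- nk + 1L
  pca@nRetained <- as.integer(max(nk, 1L))
  validObject(pca)
  pca
}

#' Eigenvalue-weighted total contributions
#'
#' The total contribution of a variable (reaction) or subsystem (pathway)
#' across the retained components is the weighted sum
#' \eqn{T = \sum_{i=1}^{n} E_i V_i} with \eqn{E_i} the eigenvalue and
#' \eqn{V_i} the percentage contribution to component i.
#'
#' @param pca a \linkS4class{PCAContribution} with \code{nRetained} set (see
#'   \code{\link{retainComponents}}).
#' @return the \code{PCAContribution} with per-variable \code{totals} filled
#'   in (units: eigenvalue x percent).
#' @export
totalContribution <- function(pca) {
  stopifnot(is(pca, "PCAContribution"))
  if (is.na(pca@nRetained))
    stop("run retainComponents() first", call. = FALSE)
  idx <- seq_len(pca@nRetained)
  tot <- as.numeric(pca@contributions[, idx, drop = FALSE] %*%
                    pca@eigenvalues[idx])
  pca@totals <- setNames(tot, rownames(pca@contributions))
  pca
}

#' Rank between-group contribution differences
#'
#' For each ordered pair of age groups, computes difference = T(older) -
#' T(younger) per variable (restricted to the variables present in both
#' groups), sorted by absolute difference, and reports the top N.
#'
#' @param totalsByGroup named list, group label -> named totals vector, in
#'   increasing age order (e.g. \code{"21-"}, \code{"22-49"}, \code{"50+"}).
#' @param topN rows per pair (default 20).
#' @return named list of data frames, one per group pair
#'   (\code{"younger_vs_older"}), with columns \code{variable},
#'   \code{younger}, \code{older}, \code{difference}.
#' @export
groupDifferenceRanking <- function(totalsByGroup, topN = 20) {
  stopifnot(is.list(totalsByGroup), length(totalsByGroup) >= 2)
  groups <- names(totalsByGroup)
  out <- list()
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq(i + 1, length(groups))) {
      young <- totalsByGroup[[i]]; old <- totalsByGroup[[j]]
      common <- intersect(names(young), names(old))
      if (!length(common))
        stop("groups '", groups[i], "' and '", groups[j],
             "' share no variables", call. = FALSE)
      d <- old[common] - young[common]
      ord <- order(abs(d), decreasing = TRUE)
      df <- data.frame(variable = common[ord],
                       younger = unname(young[common][ord]),
                       older = unname(old[common][ord]),
                       difference = unname(d[ord]),
                       stringsAsFactors = FALSE)
      out[[paste0(groups[i], "_vs_", groups[j])]] <- head(df, topN)
    }
  }
  out
}

#' Per-age-group PCA contribution analysis of a flux matrix
#'
#' Convenience driver: splits individuals by \code{\link{ageGroups}}, fits
#' the standardised PCA per group, applies the retention criteria, computes
#' eigenvalue-weighted totals and the pairwise difference ranking.
#'
#' @param mat individual x variable flux matrix.
#' @param ages chronological ages, one per row.
#' @param topN rows per pairwise comparison.
#' @return list with \code{groups} (named list of
#'   \linkS4class{PCAContribution}) and \code{differences} (see
#'   \code{\link{groupDifferenceRanking}}).
#' @export
pcaByAgeGroup <- function(mat, ages, topN = 20) {
  mat <- as.matrix(mat)
  stopifnot(length(ages) == nrow(mat))
  grp <- ageGroups(ages)
  fits <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    if (sum(sel) < 3) {
      warning("age group '", g, "' has fewer than 3 individuals; skipped",
              call. = FALSE)
      next
    }
    fits[[g]] <- totalContribution(
      retainComponents(fitGroupPCA(mat[sel, , drop = FALSE], groupLabel = g)))
  }
  if (length(fits) < 2)
    stop("need at least two age groups with >= 3 individuals", call. = FALSE)
  list(groups = fits,
       differences = groupDifferenceRanking(lapply(fits, slot, "totals"),
                                            topN = topN))
}
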