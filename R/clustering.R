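## Age-based cluster validation: individuals are clustered on a data layer
## (transcriptomic or fluxomic), but silhouette cohesion/separation is
## measured on chronological-age dissimilarities, so the curve asks "how
## well does this layer's clustering organise the cohort by age?".

#' Age-based silhouette values
#'
#' For each individual with chronological age c, dissimilarity to another
#' individual is the absolute age difference. With a the mean dissimilarity
#' to the individual's own cluster and l the lowest mean dissimilarity to
#' any other cluster, the silhouette is \eqn{s = (l - a) / \max(a, l)}.
#' Members of singleton clusters score 0, as does the degenerate case
#' a = l = 0 (e.g. an equal-age cohort).
#'
#' @param ages numeric, chronological ages (years).
#' @param labels cluster assignment, same length; at least two non-empty
#'   clusters.
#' @return numeric vector of per-individual silhouette values in [-1, 1].
#' @examples
#' ageSilhouette(c(20, 20, 40), c(1, 1, 2))   # 1, 1, 1
#' @export
ageSilhouette <- function(ages, labels) {
  stopifnot(length(ages) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  n <- length(ages)
  D <- abs(outer(ages, ages, "-"))
  sizes <- table(labels)
  ## mean dissimilarity of each individual to each cluster
  M <- vapply(names(sizes), function(cl)
    rowMeans(D[, labels == cl, drop = FALSE]), numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    ni <- sizes[[cl]]
    if (ni == 1) { s[i] <- 0; next }
    a <- M[i, cl] * ni / (ni - 1)      # exclude self from the own-cluster mean
    l <- min(M[i, colnames(M) != cl])
    s[i] <- if (max(a, l) == 0) 0 else (l - a) / max(a, l)
  }
  s
}

kmeansPlusPlusCenters <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster individuals on one data layer
#'
#' k-means uses k-means++ seeding with 10 restarts (best total
#' within-cluster sum of squares kept); hierarchical clustering is
#' agglomerative with Ward linkage on Euclidean distances by default, cut at
#' k clusters. Both are deterministic for a fixed seed.
#'
#' @param mat individual x feature numeric matrix.
#' @param method \code{"kmeans"} or \code{"hierarchical"}.
#' @param k number of clusters, 2 <= k <= individuals.
#' @param seed RNG seed (k-means restarts).
#' @param nstart k-means restarts.
#' @param linkage hierarchical linkage (\code{"ward.D2"}, \code{"single"},
#'   \code{"complete"}, \code{"average"}).
#' @param standardise z-score columns first (off by default: the layers are
#'   already on meaningful common scales).
#' @return integer cluster labels (length = individuals).
#' @export
clusterLayer <- function(mat, method = c("kmeans", "hierarchical"), k,
                         seed = 1, nstart = 10, linkage = "ward.D2",
                         standardise = FALSE) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds the number of individuals",
                          call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  if (standardise) {
    sds <- apply(mat, 2, sd)
    mat <- scale(mat[, sds > 0, drop = FALSE])
  }
  if (k == nrow(mat)) return(seq_len(nrow(mat)))
  if (method == "kmeans") {
    set.seed(seed)
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- kmeansPlusPlusCenters(mat, k)
      km <- tryCatch(
        suppressWarnings(kmeans(mat, centers = centers, iter.max = 100)),
        error = function(e) NULL)   # duplicate centers on degenerate data
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
    }
    if (is.null(best))   # e.g. all rows identical: any k-partition is valid
      return(cutree(hclust(dist(mat), method = linkage), k = k))
    best$cluster
  } else {
    hc <- hclust(dist(mat), method = linkage)
    cutree(hc, k = k)
  }
}

#' Mean age-silhouette across a range of cluster counts
#'
#' For each k in \code{kRange}, clusters the layer and averages the
#' per-individual age-based silhouette values.
#'
#' @inheritParams clusterLayer
#' @param ages chronological ages, one per row of \code{mat}.
#' @param kRange integer vector of cluster counts (default 2..30).
#' @param layer label stored on the curve.
#' @param ... passed to \code{\link{clusterLayer}}.
#' @return a \linkS4class{SilhouetteCurve}.
#' @export
silhouetteCurve <- function(mat, ages, method = c("kmeans", "hierarchical"),
                            kRange = 2:30, seed = 1,
                            layer = "unspecified", ...) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  stopifnot(length(ages) == nrow(mat))
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2 || max(kRange) > nrow(mat) - 1)
    stop("kRange must lie within [2, individuals - 1]", call. = FALSE)
  ms <- vapply(kRange, function(k) {
    labels <- clusterLayer(mat, method = method, k = k, seed = seed, ...)
    mean(ageSilhouette(ages, labels))
  }, numeric(1))
  new("SilhouetteCurve", kValues = kRange, meanSilhouette = ms,
      method = method, layer = layer)
}

#' Compare two silhouette curves
#'
#' Two-sample Kolmogorov-Smirnov test on the per-k mean silhouette values of
#' the two curves (one value per cluster count).
#'
#' @param curveA,curveB \linkS4class{SilhouetteCurve}s over the same k range.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
compareCurves <- function(curveA, curveB) {
  stopifnot(is(curveA, "SilhouetteCurve"), is(curveB, "SilhouetteCurve"))
  if (!identical(curveA@kValues, curveB@kValues))
    stop("curves must cover the same cluster counts", call. = FALSE)
  kt <- suppressWarnings(ks.test(curveA@meanSilhouette,
                                 curveB@meanSilhouette))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Select a cluster count from a silhouette curve
#'
#' Automates the visual "elbow closest to 1" choice: among cluster counts
#' whose mean silhouette lies within \code{tolFrac} of the curve maximum,
#' returns the smallest k maximising the discrete curvature
#' \eqn{2 s_k - s_{k-1} - s_{k+1}} (endpoints padded), i.e. the point just
#' before the drop. A flat curve returns the smallest k in range; a manual
#' \code{override} wins unconditionally.
#'
#' @param curve a \linkS4class{SilhouetteCurve} with at least 3 points.
#' @param tolFrac fraction of the maximum defining the candidate set.
#' @param override optional manual choice.
#' @return the selected cluster count.
#' @export
selectK <- function(curve, tolFrac = 0.05, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(is(curve, "SilhouetteCurve"))
  s <- curve@meanSilhouette
  if (length(s) < 3) stop("curve needs at least 3 points", call. = FALSE)
  pad <- c(s[1], s, s[length(s)])
  curvature <- 2 * s - pad[seq_along(s)] - pad[seq_along(s) + 2]
  cand <- which(s >= max(s) - tolFrac * abs(max(s)))
  best <- cand[which.max(curvature[cand])]
  curve@kValues[best]
}
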