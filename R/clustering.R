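## Unsupervised assessment: PCA reduction, Ward hierarchical clustergram
## cut, elbow-based K choice and K-means cluster composition.

#' Reduce a feature table to leading principal components
#'
#' Centered (not re-scaled) PCA; each component's sign is fixed so that its
#' largest-magnitude loading is positive, making score signs reproducible.
#'
#' @param table a [FeatureTable-class] or numeric matrix.
#' @param nComponents number of leading components to keep.
#' @return numeric matrix of scores (rows preserved, columns `PC1..PCk`)
#'   with attribute `"explainedVariance"`.
#' @export
pcaReduce <- function(table, nComponents = 10L) {
  m <- if (is(table, "FeatureTable")) featureValues(table) else table
  m[!is.finite(m)] <- 0
  if (nComponents > min(nrow(m) - 1L, ncol(m)))
    stop("nComponents (", nComponents, ") exceeds min(rows - 1, cols) = ",
         min(nrow(m) - 1L, ncol(m)))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2, flip, "*")
  attr(scores, "explainedVariance") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)]
  scores
}

clusterReport <- function(method, k, assignments, labels, meta = list()) {
  labels <- factor(labels)
  tab <- table(cluster = assignments, class = labels)
  # order clusters by rebounder share, descending, for reporting stability
  shr <- if ("rebounder" %in% colnames(tab))
    tab[, "rebounder"] / rowSums(tab) else tab[, 1] / rowSums(tab)
  ord <- order(shr, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  relabel <- match(assignments, as.integer(rownames(tab)))
  composition <- sweep(tab, 1, rowSums(tab), "/") * 100   # rows sum to 100
  capture <- sweep(tab, 2, colSums(tab), "/") * 100       # % of class in cluster
  rownames(composition) <- rownames(capture) <-
    paste0("cluster", seq_len(nrow(tab)))
  structure(list(method = method, k = k, assignments = relabel,
                 composition = as.matrix(composition),
                 classCapture = as.matrix(capture), meta = meta),
            class = "ClusterReport")
}

#' @export
print.ClusterReport <- function(x, ...) {
  cat(sprintf("ClusterReport (%s, k = %d)\n", x$method, x$k))
  cat("within-cluster composition (%):\n")
  print(round(x$composition, 1))
  invisible(x)
}

#' Hierarchical clustergram cut
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) cut at
#' `nClusters`; cluster composition is tabulated against the class labels.
#' Clusters are ordered by rebounder share for stable reporting.
#'
#' @param reduced numeric matrix (e.g. PCA scores), rows = eyes.
#' @param nClusters number of clusters (default 2).
#' @param labels class labels per row.
#' @return a `ClusterReport` with per-cluster composition percentages (rows
#'   sum to 100 over classes) and class-capture percentages.
#' @export
hierarchicalCut <- function(reduced, nClusters = 2L, labels) {
  hc <- stats::hclust(stats::dist(reduced), method = "ward.D2")
  cl <- stats::cutree(hc, k = nClusters)
  clusterReport("hierarchical", nClusters, cl, labels,
                meta = list(linkage = "ward.D2", distance = "euclidean"))
}

#' Elbow-based choice of K for K-means
#'
#' Computes the within-cluster sum of squares for `k = 1..kMax` (seeded
#' K-means, 10 restarts) and picks the k of maximum discrete curvature
#' (second difference of the WCSS curve).  When the maximum curvature is
#' less than twice the median of the others, the elbow is weak and the
#' result carries attribute `weakElbow = TRUE`.
#'
#' @param reduced numeric matrix of scores.
#' @param kMax largest k to examine (lowered with a warning when there are
#'   fewer rows).
#' @param seed integer seed.
#' @return integer k, with attributes `wcss` and `weakElbow`.
#' @export
elbowK <- function(reduced, kMax = 6L, seed = 1L) {
  n <- nrow(reduced)
  if (kMax >= n) {
    warning("kMax lowered to ", n - 1L, " (only ", n, " rows)")
    kMax <- n - 1L
  }
  if (kMax < 2L) stop("kMax must be >= 2")
  wcss <- withRNG(seed, vapply(seq_len(kMax), function(k) {
    if (k == 1) sum(scale(reduced, scale = FALSE)^2)
    else stats::kmeans(reduced, centers = k, nstart = 10)$tot.withinss
  }, numeric(1)))
  if (kMax == 2L) {
    k <- 2L
    curv <- NA_real_
    weak <- FALSE
  } else {
    ks <- 2:(kMax - 1L)
    d2 <- wcss[ks - 1] - 2 * wcss[ks] + wcss[ks + 1]
    k <- ks[which.max(d2)]
    others <- d2[-which.max(d2)]
    weak <- length(others) > 0 &&
      max(d2) < 2 * stats::median(pmax(others, 0) + 1e-12)
  }
  structure(as.integer(k), wcss = wcss, weakElbow = weak)
}

#' K-means cluster composition
#'
#' Seeded K-means (10 restarts, best inertia) on the reduced scores,
#' typically the top two principal components; composition as in
#' [hierarchicalCut()].
#'
#' @param reduced numeric matrix of scores (rows = eyes).
#' @param k number of clusters.
#' @param labels class labels per row.
#' @param seed integer seed.
#' @return a `ClusterReport`.
#' @export
kmeansComposition <- function(reduced, k, labels, seed = 1L) {
  if (k > nrow(reduced)) stop("k exceeds number of rows")
  km <- withRNG(seed, stats::kmeans(reduced, centers = k, nstart = 10))
  clusterReport("kmeans", k, km$cluster, labels,
                meta = list(nstart = 10, seed = seed,
                            totWithinss = km$tot.withinss))
}
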