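# k-means morphology clustering and the control-versus-treated
# separability report (the machine twin of a best-performance table row).

#' k-means clustering of a feature matrix
#'
#' Best-inertia solution over random restarts; deterministic given the seed.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param k number of clusters (2 <= k < n).
#' @param seed RNG seed.
#' @param restarts number of random restarts (default 20).
#' @return a \linkS4class{ClusterReport} with labels, inertia and mean
#'   silhouette (group statistics empty; see
#'   \code{\link{clusterGroupReport}}).
#' @export
kmeansCluster <- function(fm, k, seed = 1, restarts = 20) {
  n <- nrow(fm@X)
  if (k < 2 || k >= n) stop("need 2 <= k < number of spines")
  km <- with_seed(seed,
    kmeans(fm@X, centers = k, nstart = restarts, iter.max = 200))
  sil <- mean(cluster::silhouette(km$cluster, dist(fm@X))[, 3])
  new("ClusterReport", k = as.integer(k),
      labels = as.integer(km$cluster), spineIds = fm@spineIds,
      reduction = "none",
      perCluster = data.frame(), chi2P = NA_real_,
      inertia = km$tot.withinss, silhouette = sil,
      seed = as.integer(seed))
}

#' Cluster-count diagnostics: elbow and silhouette
#'
#' Runs k-means for every k in the range and reports inertia and mean
#' silhouette. The elbow is the k with the largest second difference of
#' inertia; the recommended k is the silhouette argmax. Both are surfaced --
#' no silent tie-break.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param kRange integer vector of candidate k (within [2, n-1]).
#' @param seed RNG seed.
#' @param restarts k-means restarts per k.
#' @return list with \code{table} (k, inertia, silhouette), \code{elbowK}
#'   and \code{recommendedK} (silhouette argmax).
#' @export
chooseK <- function(fm, kRange = 2:8, seed = 1, restarts = 20) {
  kRange <- sort(unique(as.integer(kRange)))
  reps <- lapply(kRange, function(k)
    kmeansCluster(fm, k, seed = seed, restarts = restarts))
  tab <- data.frame(k = kRange,
                    inertia = vapply(reps, slot, 0, "inertia"),
                    silhouette = vapply(reps, slot, 0, "silhouette"))
  elbowK <- NA_integer_
  if (nrow(tab) >= 3) {
    d2 <- diff(diff(tab$inertia))  # second difference, length n-2
    elbowK <- tab$k[which.max(d2) + 1]
  }
  list(table = tab, elbowK = elbowK,
       recommendedK = tab$k[which.max(tab$silhouette)])
}

#' Cluster the spines and test control-versus-treated separability
#'
#' Reduces the feature space (optionally), k-means clusters it, then for
#' every cluster runs a one-versus-rest Agresti-Caffo test comparing the
#' cluster membership rate in the control group against the treated group,
#' plus one overall chi-squared test on the k x 2 cluster-by-group table.
#' Per-cluster p-values are reported raw (a Holm-adjusted column is added,
#' clearly labeled).
#'
#' @param fm a \linkS4class{FeatureMatrix} with group labels.
#' @param k number of clusters.
#' @param reduction "none", "pca", "tsne" or "umap".
#' @param seed RNG seed.
#' @param dim reduction target dimension.
#' @param restarts k-means restarts.
#' @return a \linkS4class{ClusterReport}; the reduced feature matrix is in
#'   attribute \code{reducedFM}.
#' @export
clusterGroupReport <- function(fm, k, reduction = "none", seed = 1,
                               dim = 3, restarts = 20) {
  if (!length(fm@group))
    stop("feature matrix carries no group labels")
  groups <- fm@group
  glev <- c("control", "treated")
  if (!all(groups %in% glev))
    stop("group labels must be 'control' or 'treated'")
  if (length(unique(groups)) < 2)
    stop("both groups must be represented")
  red <- reduceDim(fm, reduction, dim = dim, seed = seed)
  rep0 <- kmeansCluster(red, k, seed = seed, restarts = restarts)
  lab <- rep0@labels
  n1 <- sum(groups == "control"); n2 <- sum(groups == "treated")
  per <- do.call(rbind, lapply(seq_len(k), function(cl) {
    x1 <- sum(lab == cl & groups == "control")
    x2 <- sum(lab == cl & groups == "treated")
    ac <- agrestiCaffo(x1, n1, x2, n2)
    data.frame(cluster = cl, nControl = x1, nTreated = x2,
               pctControl = 100 * x1 / n1, pctTreated = 100 * x2 / n2,
               acP = ac$p)
  }))
  per$acPHolm <- stats::p.adjust(per$acP, method = "holm")
  counts <- cbind(per$nControl, per$nTreated)
  chi2p <- suppressWarnings(chiSquareGroups(counts))
  out <- new("ClusterReport", k = as.integer(k), labels = lab,
             spineIds = fm@spineIds, reduction = reduction,
             perCluster = per, chi2P = chi2p,
             inertia = rep0@inertia, silhouette = rep0@silhouette,
             seed = as.integer(seed))
  attr(out, "reducedFM") <- red
  out
}

#' Format a ClusterReport as one summary-table row
#'
#' Mirrors the columns of the best-performance clustering table: feature
#' space, reduction, k, number of clusters with Agresti-Caffo p < .05,
#' their p-values, and the overall chi-squared p-value.
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param dimension label of the feature space (e.g. "SphHarm + Volume").
#' @return one-row data.frame.
#' @export
table1Row <- function(report, dimension = "features") {
  sig <- report@perCluster$acP[report@perCluster$acP < 0.05]
  data.frame(
    dimension = dimension,
    reduction = report@reduction,
    n_clusters = report@k,
    n_significant = length(sig),
    ac_p_values = paste(signif(sig, 3), collapse = "; "),
    chi2_p = report@chi2P)
}

#' Representative spines per cluster
#'
#' The \code{top} spines nearest (Euclidean, in the clustering space) to
#' their cluster centroid, sorted by distance; clusters smaller than
#' \code{top} return all members.
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param fm the \linkS4class{FeatureMatrix} in the clustering space (e.g.
#'   \code{attr(report, "reducedFM")}).
#' @param top number of representatives per cluster (>= 1).
#' @return named list (cluster -> character vector of spine ids).
#' @export
representativeSpines <- function(report, fm, top = 3) {
  if (top < 1) stop("top must be >= 1")
  stopifnot(identical(report@spineIds, fm@spineIds))
  lab <- report@labels
  out <- lapply(seq_len(report@k), function(cl) {
    rows <- which(lab == cl)
    ctr <- colMeans(fm@X[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(fm@X[rows, , drop = FALSE], 2, ctr)^2))
    fm@spineIds[rows[order(d)][seq_len(min(top, length(rows)))]]
  })
  names(out) <- sprintf("cluster_%d", seq_len(report@k))
  out
}

#' Serialize a ClusterReport to JSON
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClusterReport <- function(report, path) {
  obj <- list(k = report@k, reduction = report@reduction,
              seed = report@seed, inertia = report@inertia,
              silhouette = report@silhouette, chi2_p = report@chi2P,
              per_cluster = report@perCluster,
              labels = data.frame(spine_id = report@spineIds,
                                  cluster = report@labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
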