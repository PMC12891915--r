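#' Assemble per-spine descriptor vectors into a feature matrix
#'
#' Stacks equal-length descriptor vectors into rows, optionally appends the
#' spine volume as an extra column (the one scalar size metric kept
#' alongside the size-invariant descriptors), and z-scores columns by
#' default. Spines whose descriptor is missing (NULL or containing NA) are
#' dropped and recorded.
#'
#' @param descriptors named list of numeric vectors (names are spine ids);
#'   failed spines may be NULL.
#' @param volumes optional named numeric vector of spine volumes.
#' @param scaling "zscore" (default) or "none".
#' @param group optional named character vector of group labels
#'   ("control"/"treated").
#' @return a \linkS4class{FeatureMatrix}.
#' @export
assembleFeatures <- function(descriptors, volumes = NULL,
                             scaling = c("zscore", "none"), group = NULL) {
  scaling <- match.arg(scaling)
  ids <- names(descriptors)
  if (is.null(ids)) stop("descriptors must be a named list")
  ok <- vapply(descriptors, function(d)
    !is.null(d) && all(is.finite(d)), TRUE)
  if (!is.null(volumes)) {
    ok <- ok & ids %in% names(volumes)[is.finite(volumes)]
  }
  dropped <- ids[!ok]
  ids <- ids[ok]
  if (!length(ids)) stop("no spine with a complete descriptor")
  lens <- vapply(descriptors[ids], length, 0L)
  if (length(unique(lens)) != 1)
    stop("descriptor vectors have differing lengths")
  X <- do.call(rbind, descriptors[ids])
  fnames <- names(descriptors[[ids[1]]])
  if (is.null(fnames)) fnames <- sprintf("f%03d", seq_len(ncol(X)))
  if (!is.null(volumes)) {
    X <- cbind(X, volume = as.numeric(volumes[ids]))
    fnames <- c(fnames, "volume")
  }
  if (scaling == "zscore") {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1  # constant columns pass through centered
    X <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  }
  grp <- character(0)
  if (!is.null(group)) {
    if (!all(ids %in% names(group)))
      stop("group labels missing for some spines")
    grp <- as.character(group[ids])
  }
  dimnames(X) <- NULL
  new("FeatureMatrix", spineIds = ids, X = X, featureNames = fnames,
      scaling = scaling, group = grp, dropped = dropped)
}

#' Reduce feature dimensionality
#'
#' PCA (prcomp), t-SNE (Rtsne, perplexity 30 capped at (n-1)/3) or UMAP
#' (uwot, 15 neighbours, min_dist 0.1), all seeded; "none" returns the
#' input unchanged.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param method "none", "pca", "tsne" or "umap".
#' @param dim target dimension (default 3).
#' @param seed RNG seed.
#' @return a \linkS4class{FeatureMatrix} in the embedded space.
#' @export
reduceDim <- function(fm, method = c("none", "pca", "tsne", "umap"),
                      dim = 3, seed = 1) {
  method <- match.arg(method)
  if (method == "none") return(fm)
  X <- fm@X
  if (dim >= ncol(X))
    stop("target dim must be smaller than the feature dimension")
  Y <- switch(method,
    pca = {
      p <- prcomp(X, center = TRUE, scale. = FALSE)
      p$x[, seq_len(dim), drop = FALSE]
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("t-SNE reduction needs the Rtsne package")
      perp <- min(30, floor((nrow(X) - 1) / 3))
      with_seed(seed,
        Rtsne::Rtsne(X, dims = dim, perplexity = perp,
                     check_duplicates = FALSE, pca = ncol(X) > 50,
                     verbose = FALSE)$Y)
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("UMAP reduction needs the uwot package")
      with_seed(seed,
        uwot::umap(X, n_components = dim,
                   n_neighbors = min(15, nrow(X) - 1), min_dist = 0.1,
                   n_threads = 1, n_sgd_threads = 1, batch = TRUE))
    })
  new("FeatureMatrix", spineIds = fm@spineIds, X = unname(as.matrix(Y)),
      featureNames = sprintf("%s%d", method, seq_len(dim)),
      scaling = fm@scaling, group = fm@group, dropped = fm@dropped)
}
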