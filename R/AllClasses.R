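#' TriangleMesh: a triangulated spine surface
#'
#' Holds the vertices and triangular faces of one segmented dendritic-spine
#' surface, plus (optionally) the indices of the junction-region vertices --
#' the rim where the spine attaches to its dendrite -- which drive canonical
#' orientation.
#'
#' @slot vertices numeric matrix, n x 3, finite coordinates (length units are
#'   whatever the meshes were segmented in, typically micrometres; no
#'   conversion is ever applied).
#' @slot faces integer matrix, m x 3, 1-based vertex indices; no degenerate
#'   faces.
#' @slot junctionRegion integer vector of vertex indices marking the
#'   dendrite-attachment rim (may be empty).
#'
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 junctionRegion = "integer"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            junctionRegion = integer(0)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (length(v) && !all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f)) {
    if (min(f) < 1 || max(f) > nrow(v))
      return("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate faces (repeated vertex index)")
  }
  jr <- object@junctionRegion
  if (length(jr) && (min(jr) < 1 || max(jr) > nrow(v)))
    return("junctionRegion indices out of range")
  TRUE
})

#' SphericalSample: the tabulated radial function of a star-shaped surface
#'
#' Maps sampled directions (zenith, azimuth) from a chosen interior center to
#' the radius at which a ray in that direction meets the surface, together
#' with ray-casting quality diagnostics.
#'
#' @slot center numeric length-3 interior point used as the origin of the
#'   spherical coordinate system.
#' @slot directions numeric k x 3 matrix of unit vectors.
#' @slot radii numeric vector of positive radii, aligned with directions.
#' @slot multiHitFraction fraction of kept rays that crossed the surface more
#'   than once (star-shape violation rate).
#' @slot missCount number of rays dropped because they hit nothing.
#'
#' @export
setClass("SphericalSample",
  representation(center = "numeric", directions = "matrix", radii = "numeric",
                 multiHitFraction = "numeric", missCount = "integer"))

setValidity("SphericalSample", function(object) {
  if (length(object@center) != 3) return("center must be length 3")
  if (nrow(object@directions) != length(object@radii))
    return("directions and radii must align")
  if (length(object@radii) &&
      (!all(is.finite(object@radii)) || any(object@radii <= 0)))
    return("radii must be strictly positive and finite")
  if (object@multiHitFraction < 0 || object@multiHitFraction > 1)
    return("multiHitFraction must lie in [0, 1]")
  TRUE
})

#' SphHarmDescriptor: packed real spherical-harmonics coefficients
#'
#' The coefficients a_lm of the truncated real spherical-harmonics expansion
#' of a spine's radial function, packed in (l, m) lexicographic order
#' l = 0..L-1, m = -l..l (length L^2), plus the geometry needed to place a
#' reconstruction back into the original frame.
#'
#' @slot degreeL truncation degree L (coefficients cover l < L).
#' @slot nSamples number of Monte-Carlo directions used for the projection.
#' @slot coefficients numeric vector of length L^2.
#' @slot center numeric length-3 encoding origin.
#' @slot scale normalization radius divided out before encoding (1 if none).
#'
#' @export
setClass("SphHarmDescriptor",
  representation(degreeL = "integer", nSamples = "integer",
                 coefficients = "numeric", center = "numeric",
                 scale = "numeric"))

setValidity("SphHarmDescriptor", function(object) {
  L <- object@degreeL
  if (L < 1) return("degreeL must be >= 1")
  if (length(object@coefficients) != L^2)
    return(sprintf("coefficients must have length L^2 = %d", L^2))
  if (!all(is.finite(object@coefficients)))
    return("coefficients must be finite")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' Silhouette: a binary orthographic projection of a mesh
#'
#' A square binary raster of the mesh silhouette seen from one observation
#' point, with the minimal-enclosing-circle parameters filled in by
#' \code{\link{inscribeUnitDisk}} (NA before inscription).
#'
#' @slot pixels integer matrix (rows = image y, columns = image x), values
#'   0/1.
#' @slot resolution pixels per length unit of the projected scene.
#' @slot diskCenter numeric length-2 center (x, y in pixel units) of the
#'   minimal enclosing circle of the foreground.
#' @slot diskRadius radius in pixels of that circle.
#'
#' @export
setClass("Silhouette",
  representation(pixels = "matrix", resolution = "numeric",
                 diskCenter = "numeric", diskRadius = "numeric"),
  prototype(diskCenter = c(NA_real_, NA_real_), diskRadius = NA_real_))

setValidity("Silhouette", function(object) {
  px <- object@pixels
  if (!all(px %in% c(0L, 1L))) return("pixels must be 0/1")
  TRUE
})

#' LightFieldDescriptor: Zernike moments of five mesh silhouettes
#'
#' Complex Zernike moments a_mn (radial order n <= M, azimuthal order
#' 0 <= m <= n, n - m even) of the five canonical-viewpoint silhouettes of
#' one spine. Moments for negative m are the conjugates and are not stored.
#'
#' @slot orderM maximum radial order M.
#' @slot viewpoints numeric 5 x 3 matrix with columns zenith, azimuth,
#'   distance.
#' @slot moments list of 5 complex vectors (one per viewpoint), aligned with
#'   \code{momentIndex}.
#' @slot momentIndex data.frame with integer columns n, m listing the stored
#'   (n, m) pairs.
#' @slot mode "complex" as produced; reduced representations are made by
#'   \code{\link{lfRealFeatures}}.
#'
#' @export
setClass("LightFieldDescriptor",
  representation(orderM = "integer", viewpoints = "matrix", moments = "list",
                 momentIndex = "data.frame", mode = "character"))

setValidity("LightFieldDescriptor", function(object) {
  if (nrow(object@viewpoints) != 5) return("exactly 5 viewpoints expected")
  nm <- nrow(object@momentIndex)
  if (!all(vapply(object@moments, length, 0L) == nm))
    return("each viewpoint must carry one moment per (n, m) pair")
  TRUE
})

#' FeatureMatrix: per-spine descriptor features ready for clustering
#'
#' @slot spineIds character vector of spine identifiers (row order).
#' @slot X numeric n x d matrix with no missing values.
#' @slot featureNames character vector of d column labels.
#' @slot scaling "none" or "zscore".
#' @slot group optional per-spine group label ("control"/"treated"); length 0
#'   when absent.
#' @slot dropped character vector of spine ids excluded because their
#'   descriptor could not be computed.
#'
#' @export
setClass("FeatureMatrix",
  representation(spineIds = "character", X = "matrix",
                 featureNames = "character", scaling = "character",
                 group = "character", dropped = "character"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@X) != length(object@spineIds))
    return("rows of X must align with spineIds")
  if (ncol(object@X) != length(object@featureNames))
    return("featureNames must align with columns of X")
  if (ncol(object@X) < 1) return("at least one feature required")
  if (any(!is.finite(object@X))) return("X must not contain missing values")
  if (length(object@group) && length(object@group) != length(object@spineIds))
    return("group must align with spineIds")
  TRUE
})

#' ClusterReport: k-means result with per-cluster group separability
#'
#' The machine-readable form of one clustering-result row: cluster labels,
#' quality scores, and per-cluster control-versus-treated membership
#' proportions with Agresti-Caffo tests plus the overall chi-squared test.
#'
#' @slot k number of clusters.
#' @slot labels integer cluster assignment per spine (1..k).
#' @slot spineIds character ids aligned with labels.
#' @slot reduction dimensionality reduction applied before clustering
#'   ("none", "pca", "tsne", "umap").
#' @slot perCluster data.frame with one row per cluster: cluster, nControl,
#'   nTreated, pctControl, pctTreated, acP, acPHolm.
#' @slot chi2P overall chi-squared p-value (NA when no groups given).
#' @slot inertia total within-cluster sum of squares.
#' @slot silhouette mean silhouette width.
#' @slot seed RNG seed the report was produced with.
#'
#' @export
setClass("ClusterReport",
  representation(k = "integer", labels = "integer", spineIds = "character",
                 reduction = "character", perCluster = "data.frame",
                 chi2P = "numeric", inertia = "numeric",
                 silhouette = "numeric", seed = "integer"))

setValidity("ClusterReport", function(object) {
  if (length(object@labels) != length(object@spineIds))
    return("labels must align with spineIds")
  if (length(object@labels) && max(object@labels) > object@k)
    return("labels exceed k")
  TRUE
})
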