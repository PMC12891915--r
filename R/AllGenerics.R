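#' Accessors for spinemorph classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("junctionRegion", function(x) standardGeneric("junctionRegion"))
#' @rdname accessors
#' @export
setGeneric("junctionRegion<-",
           function(x, value) standardGeneric("junctionRegion<-"))
#' @rdname accessors
#' @export
setGeneric("shCoefficients", function(x) standardGeneric("shCoefficients"))
#' @rdname accessors
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("junctionRegion", "TriangleMesh", function(x) x@junctionRegion)
#' @rdname accessors
#' @param value integer vertex indices
#' @export
setMethod("junctionRegion<-", "TriangleMesh", function(x, value) {
  x@junctionRegion <- as.integer(value)
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("shCoefficients", "SphHarmDescriptor", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("radii", "SphericalSample", function(x) x@radii)
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureMatrix", function(x) x@X)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterReport", function(x) x@labels)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces",
              nrow(object@vertices), nrow(object@faces)))
  if (length(object@junctionRegion))
    cat(sprintf(", junction region of %d vertices",
                length(object@junctionRegion)))
  cat("\n")
})

setMethod("show", "SphericalSample", function(object) {
  cat(sprintf(
    "SphericalSample: %d directions, multi-hit fraction %.3f, %d misses\n",
    length(object@radii), object@multiHitFraction, object@missCount))
})

setMethod("show", "SphHarmDescriptor", function(object) {
  cat(sprintf(
    "SphHarmDescriptor: L = %d (%d coefficients), N = %d, scale = %.4g\n",
    object@degreeL, length(object@coefficients), object@nSamples,
    object@scale))
})

setMethod("show", "Silhouette", function(object) {
  cat(sprintf("Silhouette: %d x %d, %d foreground px",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels)))
  if (!is.na(object@diskRadius))
    cat(sprintf(", inscribed (disk radius %.1f px)", object@diskRadius))
  cat("\n")
})

setMethod("show", "LightFieldDescriptor", function(object) {
  cat(sprintf(
    "LightFieldDescriptor: order M = %d, %d viewpoints x %d moments = %d\n",
    object@orderM, length(object@moments), nrow(object@momentIndex),
    length(object@moments) * nrow(object@momentIndex)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d spines x %d features (%s scaling)%s\n",
              nrow(object@X), ncol(object@X), object@scaling,
              if (length(object@group)) " with group labels" else ""))
  if (length(object@dropped))
    cat(sprintf("  dropped %d spines with failed descriptors\n",
                length(object@dropped)))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf(
    "ClusterReport: k = %d (%s reduction), inertia %.4g, mean silhouette %.3f\n",
    object@k, object@reduction, object@inertia, object@silhouette))
  if (nrow(object@perCluster)) {
    nsig <- sum(object@perCluster$acP < 0.05, na.rm = TRUE)
    cat(sprintf("  %d/%d clusters differ between groups (Agresti-Caffo p < .05); chi-squared p = %.3g\n",
                nsig, object@k, object@chi2P))
  }
})
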