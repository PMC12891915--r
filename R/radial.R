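#' Uniform random directions on the unit sphere
#'
#' Monte-Carlo direction set: independent 3D standard-normal draws,
#' normalized to unit length. Deterministic given the seed.
#'
#' @param n number of directions (>= 1).
#' @param seed integer RNG seed.
#' @return n x 3 matrix of unit vectors.
#' @export
sampleSphere <- function(n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    g <- matrix(rnorm(3 * n), ncol = 3)
    nz <- sqrt(rowSums(g^2))
    while (any(nz < 1e-12)) {  # essentially never
      bad <- nz < 1e-12
      g[bad, ] <- matrix(rnorm(3 * sum(bad)), ncol = 3)
      nz <- sqrt(rowSums(g^2))
    }
    g / nz
  })
}

# Cartesian unit vectors -> (zenith from +z, azimuth from +x in [0, 2pi)).
dirs_to_angles <- function(d) {
  theta <- acos(pmin(1, pmax(-1, d[, 3])))
  phi <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  cbind(theta = theta, phi = phi)
}

angles_to_dirs <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Tabulate the radial surface function by ray casting
#'
#' For each direction a ray is cast from the center; the radius recorded is
#' the distance to the farthest intersection with the surface (outer
#' envelope) or the first, by choice. Rays that miss are dropped and counted;
#' rays that cross the surface more than once feed the multi-hit fraction,
#' the star-shape quality diagnostic.
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @param center interior point, origin of the spherical system.
#' @param directions k x 3 matrix of unit vectors.
#' @param multiHit "farthest" (outer surface, default) or "first".
#' @return a \linkS4class{SphericalSample}.
#' @export
radialTabulation <- function(mesh, center, directions,
                             multiHit = c("farthest", "first")) {
  multiHit <- match.arg(multiHit)
  if (!pointInMesh(mesh, center))
    stop("center is not strictly inside the mesh")
  hits <- cpp_ray_mesh(as.numeric(center), directions, mesh@vertices,
                       mesh@faces - 1L)
  got <- hits[, 1] > 0
  if (mean(!got) > 0.5)
    stop("degenerate tabulation: more than 50% of rays miss the surface")
  r <- if (multiHit == "farthest") hits[got, 3] else hits[got, 2]
  new("SphericalSample",
      center = as.numeric(center),
      directions = directions[got, , drop = FALSE],
      radii = as.numeric(r),
      multiHitFraction = mean(hits[got, 1] > 1),
      missCount = as.integer(sum(!got)))
}

#' Symmetric Hausdorff distance between two meshes
#'
#' max(h(A, B), h(B, A)) where h is the maximum, over a sample of surface
#' points of one mesh, of the exact point-to-triangle distance to the other.
#' The sample always includes all mesh vertices, so the estimate can only
#' grow as \code{nSamples} increases at a fixed seed.
#'
#' @param a,b \linkS4class{TriangleMesh} objects.
#' @param nSamples extra area-weighted surface samples per mesh (>= 100).
#' @param seed RNG seed for the surface samples.
#' @return the distance estimate (length units).
#' @export
hausdorffDistance <- function(a, b, nSamples = 2000, seed = 1) {
  if (nrow(a@faces) == 0 || nrow(b@faces) == 0)
    stop("empty mesh")
  if (nSamples < 100) stop("nSamples must be >= 100")
  with_seed(seed, {
    pa <- rbind(a@vertices, sampleSurface(a, nSamples))
    pb <- rbind(b@vertices, sampleSurface(b, nSamples))
    hab <- max(cpp_points_mesh_dist(pa, b@vertices, b@faces - 1L))
    hba <- max(cpp_points_mesh_dist(pb, a@vertices, a@faces - 1L))
    max(hab, hba)
  })
}
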