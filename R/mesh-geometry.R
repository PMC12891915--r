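# Geometric primitives shared by both descriptors.

tri_arrays <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

signedVolume <- function(mesh) {
  t <- tri_arrays(mesh)
  cr <- cbind(t$b[, 2] * t$c[, 3] - t$b[, 3] * t$c[, 2],
              t$b[, 3] * t$c[, 1] - t$b[, 1] * t$c[, 3],
              t$b[, 1] * t$c[, 2] - t$b[, 2] * t$c[, 1])
  sum(rowSums(t$a * cr)) / 6
}

#' Test whether a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return logical.
#' @export
isWatertight <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes over faces (divergence theorem). The
#' mesh must be watertight; winding is assumed consistent (see
#' \code{\link{fixWinding}}).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return volume in cubic length units, positive.
#' @export
meshVolume <- function(mesh) {
  if (!isWatertight(mesh))
    stop("mesh is not watertight; volume undefined")
  abs(signedVolume(mesh))
}

#' Center of mass of a mesh
#'
#' Uniform-density volumetric centroid via signed-tetrahedron weighting for
#' closed meshes; for open meshes falls back to the area-weighted surface
#' centroid with a warning.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return numeric length-3 point.
#' @export
centerOfMass <- function(mesh) {
  t <- tri_arrays(mesh)
  if (isWatertight(mesh)) {
    cr <- cbind(t$b[, 2] * t$c[, 3] - t$b[, 3] * t$c[, 2],
                t$b[, 3] * t$c[, 1] - t$b[, 1] * t$c[, 3],
                t$b[, 1] * t$c[, 2] - t$b[, 2] * t$c[, 1])
    w <- rowSums(t$a * cr) / 6          # signed tetra volumes
    cent <- (t$a + t$b + t$c) / 4       # tetra centroid (4th vertex = origin)
    as.numeric(colSums(cent * w) / sum(w))
  } else {
    warning("open mesh: using area-weighted surface centroid")
    n <- cbind((t$b[, 2] - t$a[, 2]) * (t$c[, 3] - t$a[, 3]) -
               (t$b[, 3] - t$a[, 3]) * (t$c[, 2] - t$a[, 2]),
               (t$b[, 3] - t$a[, 3]) * (t$c[, 1] - t$a[, 1]) -
               (t$b[, 1] - t$a[, 1]) * (t$c[, 3] - t$a[, 3]),
               (t$b[, 1] - t$a[, 1]) * (t$c[, 2] - t$a[, 2]) -
               (t$b[, 2] - t$a[, 2]) * (t$c[, 1] - t$a[, 1]))
    area <- sqrt(rowSums(n^2)) / 2
    cent <- (t$a + t$b + t$c) / 3
    as.numeric(colSums(cent * area) / sum(area))
  }
}

faceAreas <- function(mesh) {
  t <- tri_arrays(mesh)
  n <- cbind((t$b[, 2] - t$a[, 2]) * (t$c[, 3] - t$a[, 3]) -
             (t$b[, 3] - t$a[, 3]) * (t$c[, 2] - t$a[, 2]),
             (t$b[, 3] - t$a[, 3]) * (t$c[, 1] - t$a[, 1]) -
             (t$b[, 1] - t$a[, 1]) * (t$c[, 3] - t$a[, 3]),
             (t$b[, 1] - t$a[, 1]) * (t$c[, 2] - t$a[, 2]) -
             (t$b[, 2] - t$a[, 2]) * (t$c[, 1] - t$a[, 1]))
  sqrt(rowSums(n^2)) / 2
}

# Area-weighted uniform surface samples (barycentric).
sampleSurface <- function(mesh, n) {
  areas <- faceAreas(mesh)
  fi <- sample.int(nrow(mesh@faces), n, replace = TRUE, prob = areas)
  u <- runif(n); v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  t <- tri_arrays(mesh)
  t$a[fi, , drop = FALSE] * (1 - u - v) +
    t$b[fi, , drop = FALSE] * u +
    t$c[fi, , drop = FALSE] * v
}

#' Point-in-mesh test by ray parity
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @param point numeric length-3 query point.
#' @return logical: TRUE when the point lies inside.
#' @export
pointInMesh <- function(mesh, point) {
  # three jittered directions, majority vote, to dodge edge-on degeneracy
  dirs <- rbind(c(0.577, 0.577, 0.578), c(-0.12, 0.93, 0.35),
                c(0.41, -0.2, 0.89))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hits <- cpp_ray_mesh(as.numeric(point), dirs, mesh@vertices,
                       mesh@faces - 1L)
  sum(hits[, 1] %% 2 == 1) >= 2
}

#' Voxelize the solid enclosed by a mesh
#'
#' Parity rasterization on a regular grid: a voxel is solid when its center
#' lies inside the closed surface.
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @param pitch voxel edge length; default bounding-box diagonal / 64.
#' @return list with \code{occupancy} (3D 0/1 array), \code{origin} (corner
#'   of voxel (1,1,1)) and \code{pitch}.
#' @export
voxelizeMesh <- function(mesh, pitch = NULL) {
  v <- mesh@vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  if (is.null(pitch)) pitch <- sqrt(sum((hi - lo)^2)) / 64
  lo <- lo - pitch; hi <- hi + pitch
  n <- pmax(2L, as.integer(ceiling((hi - lo) / pitch)))
  occ <- cpp_voxelize(v, mesh@faces - 1L, lo, pitch, n[1], n[2], n[3])
  dim(occ) <- n
  list(occupancy = occ, origin = lo, pitch = pitch)
}

#' Internal center of a closed mesh
#'
#' The point on the shape skeleton closest to the center of mass, used as the
#' origin of the spherical coordinate system so that the radial function is
#' as close to single-valued as possible. The skeleton is taken as the ridge
#' of the chamfer distance transform of the voxelized solid (voxels whose
#' distance to the surface is maximal within their 26-neighbourhood).
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @param pitch voxel pitch; default bounding-box diagonal / 64.
#' @return numeric length-3 point strictly inside the mesh.
#' @export
internalCenter <- function(mesh, pitch = NULL) {
  if (!isWatertight(mesh))
    stop("decomposition not possible: mesh is not watertight")
  vox <- voxelizeMesh(mesh, pitch)
  occ <- vox$occupancy
  n <- dim(occ)
  if (sum(occ) == 0)
    stop("solid rasterization empty: mesh thinner than voxel pitch; ",
         "halve the pitch")
  dt <- cpp_chamfer_dt(as.integer(occ), n[1], n[2], n[3])
  dim(dt) <- n
  # ridge: occupied voxels whose DT is a 26-neighbourhood maximum
  nmax <- array(-Inf, n)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src <- dt[pmin(pmax(seq_len(n[1]) + di, 1), n[1]),
              pmin(pmax(seq_len(n[2]) + dj, 1), n[2]),
              pmin(pmax(seq_len(n[3]) + dk, 1), n[3])]
    nmax <- pmax(nmax, src)
  }
  ridge <- which(occ == 1 & dt >= nmax, arr.ind = TRUE)
  if (nrow(ridge) == 0)
    stop("empty skeleton at this voxel pitch; halve the pitch")
  centers <- sweep((ridge - 0.5) * vox$pitch, 2, vox$origin, `+`)
  com <- centerOfMass(mesh)
  d2 <- rowSums(sweep(centers, 2, com)^2)
  pt <- as.numeric(centers[which.min(d2), ])
  if (!pointInMesh(mesh, pt)) {
    # fall back to the deepest voxel, which is interior by construction
    deepest <- which(dt == max(dt), arr.ind = TRUE)[1, , drop = FALSE]
    pt <- as.numeric(vox$origin + (deepest - 0.5) * vox$pitch)
  }
  pt
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere; the standard
#' initialization for spherical-harmonics mesh reconstruction.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @param radius sphere radius.
#' @return a \linkS4class{TriangleMesh}.
#' @export
icosphere <- function(subdivisions = 4, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4 * i - 3:0, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                   c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  TriangleMesh(v * radius, f)
}

boundingRadius <- function(mesh, center) {
  sqrt(max(rowSums(sweep(mesh@vertices, 2, center)^2)))
}
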