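# Light-Field descriptor: five fixed observation points on a sphere of
# radius 2r around the spine, orthographic binary silhouettes, unit-disk
# inscription and Zernike decomposition.

#' The five canonical observation points
#'
#' Returns the five viewpoints on the enclosing sphere of radius 2r, where r
#' is the maximum vertex radius about \code{center}: the three principal
#' orthogonal projections (+z, +x, +y) plus two diagonal positions in the
#' front quadrants. The mesh must already be in canonical pose (see
#' \code{\link{orientSpine}}); if a junction region is present its plane
#' normal is checked against the y-axis.
#'
#' @param mesh an oriented \linkS4class{TriangleMesh}.
#' @param center interior center (default: \code{\link{internalCenter}}).
#' @return 5 x 3 matrix with columns zenith, azimuth, distance and row names
#'   A..E.
#' @export
observationPoints <- function(mesh, center = NULL) {
  jr <- mesh@junctionRegion
  if (length(jr) >= 3) {
    J <- mesh@vertices[jr, , drop = FALSE]
    n <- eigen(cov(J), symmetric = TRUE)$vectors[, 3]
    if (abs(n[2]) < 0.99)
      stop("mesh does not appear to be in canonical pose; ",
           "apply orientSpine() first")
  }
  if (is.null(center)) center <- internalCenter(mesh)
  r <- boundingRadius(mesh, center)
  vp <- rbind(A = c(0,        0,        2 * r),
              B = c(pi / 2,   0,        2 * r),
              C = c(pi / 2,   pi / 2,   2 * r),
              D = c(pi / 3,   pi / 3,   2 * r),
              E = c(2 * pi / 3, pi / 3, 2 * r))
  colnames(vp) <- c("zenith", "azimuth", "distance")
  attr(vp, "center") <- center
  vp
}

viewpoint_cartesian <- function(vp, center = c(0, 0, 0)) {
  d <- angles_to_dirs(vp[, "zenith"], vp[, "azimuth"]) * vp[, "distance"]
  sweep(d, 2, center, `+`)
}

#' Orthographic silhouette of a mesh from one viewpoint
#'
#' Projects every face onto the image plane through the center,
#' perpendicular to the viewing direction, and rasterizes the union of the
#' filled triangles into a binary px-by-px image. In-plane camera roll is
#' fixed by taking the world z-axis projected into the view plane as image
#' "up" (the top viewpoint, which looks along z, uses world x instead), so
#' silhouettes are deterministic.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param viewpoint numeric length-3 (zenith, azimuth, distance) or one row
#'   of \code{\link{observationPoints}}.
#' @param px image side length in pixels (>= 32).
#' @param center projection center (default: mean vertex).
#' @param window half-width of the imaged square; default the max vertex
#'   radius about the center, so the whole mesh is always in frame.
#' @return a \linkS4class{Silhouette} (not yet inscribed).
#' @export
projectSilhouette <- function(mesh, viewpoint, px = 256, center = NULL,
                              window = NULL) {
  if (px < 32) stop("px must be >= 32")
  if (nrow(mesh@faces) == 0) stop("empty mesh")
  if (is.null(center)) center <- colMeans(mesh@vertices)
  w <- -as.numeric(angles_to_dirs(viewpoint[1], viewpoint[2]))  # view dir
  up <- c(0, 0, 1) - sum(c(0, 0, 1) * w) * w
  if (sqrt(sum(up^2)) < 1e-8)
    up <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w
  up <- up / sqrt(sum(up^2))
  right <- cross3(up, w)
  rel <- sweep(mesh@vertices, 2, center)
  u <- rel %*% right
  v <- rel %*% up
  if (is.null(window)) window <- sqrt(max(rowSums(rel^2)))
  # pixel coords in [0, px]
  P2 <- cbind((u + window) / (2 * window) * px,
              (v + window) / (2 * window) * px)
  img <- cpp_rasterize_tris(P2, mesh@faces - 1L, as.integer(px))
  if (sum(img) == 0) stop("silhouette projection is empty")
  new("Silhouette", pixels = img, resolution = px / (2 * window))
}

# Exact minimal enclosing circle (Welzl) of 2D points; returns c(cx, cy, r).
min_enclosing_circle <- function(pts) {
  circ2 <- function(p, q) c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: take the widest pair
      cands <- list(circ2(p, q), circ2(q, r), circ2(p, r))
      return(cands[[which.max(vapply(cands, `[`, 0, 3))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, p) {
    sqrt(sum((p - circ[1:2])^2)) <= circ[3] * (1 + 1e-10) + 1e-12
  }
  welzl <- function(P, R) {
    if (nrow(P) == 0 || nrow(R) == 3) {
      if (nrow(R) == 0) return(c(0, 0, 0))
      if (nrow(R) == 1) return(c(R[1, ], 0))
      if (nrow(R) == 2) return(circ2(R[1, ], R[2, ]))
      return(circ3(R[1, ], R[2, ], R[3, ]))
    }
    p <- P[nrow(P), ]
    D <- welzl(P[-nrow(P), , drop = FALSE], R)
    if (inside(D, p)) return(D)
    welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
  }
  # shrink to the convex hull first (the circle only touches hull points)
  if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
  welzl(pts, pts[0, , drop = FALSE])
}

#' Inscribe a silhouette into the unit disk
#'
#' Finds the minimal enclosing circle of the foreground pixels and stores
#' its center and radius, so that pixel coordinates normalized by them all
#' lie in the closed unit disk. This makes the descriptor translation and
#' scale invariant; no further scaling is needed before Zernike projection.
#'
#' @param sil a \linkS4class{Silhouette} with non-empty foreground.
#' @return the silhouette with \code{diskCenter}/\code{diskRadius} filled.
#' @export
inscribeUnitDisk <- function(sil) {
  fg <- which(sil@pixels == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty silhouette foreground")
  pts <- cbind(fg[, 2] - 0.5, fg[, 1] - 0.5)  # (x, y) pixel centers
  circ <- with_seed(7L, min_enclosing_circle(pts))
  sil@diskCenter <- circ[1:2]
  # half-pixel pad so pixel centers on the rim stay inside the closed disk
  sil@diskRadius <- max(circ[3], 0.5) + 1e-9
  sil
}

#' Encode a mesh with the Light-Field descriptor
#'
#' Runs orientation (optional), internal-center computation, the five
#' canonical viewpoints, and per viewpoint silhouette projection, unit-disk
#' inscription and Zernike decomposition up to order M. Defaults M = 10 and
#' 5 views (36 moments per view, 180 in total) are the grid-search optima.
#'
#' @param mesh a closed \linkS4class{TriangleMesh}.
#' @param M maximum Zernike order (default 10).
#' @param px silhouette raster size (default 256).
#' @param orient apply \code{\link{orientSpine}} first (default TRUE).
#' @param normalization Zernike normalization, see
#'   \code{\link{encodeZernike}}.
#' @return a \linkS4class{LightFieldDescriptor}.
#' @export
encodeLightField <- function(mesh, M = 10, px = 256, orient = TRUE,
                             normalization = "standard") {
  m <- if (orient) orientSpine(mesh) else mesh
  ctr <- internalCenter(m)
  vp <- observationPoints(m, ctr)
  moments <- lapply(seq_len(nrow(vp)), function(i) {
    sil <- projectSilhouette(m, vp[i, ], px = px, center = ctr,
                             window = vp[i, "distance"] / 2)
    sil <- inscribeUnitDisk(sil)
    mom <- encodeZernike(sil, M = M, normalization = normalization)
    attr(mom, "index") <- NULL
    mom
  })
  names(moments) <- rownames(vp)
  new("LightFieldDescriptor", orderM = as.integer(M),
      viewpoints = vp[, , drop = FALSE], moments = moments,
      momentIndex = zernikeIndex(M), mode = "complex")
}

#' Real-valued Light-Field feature vector
#'
#' Concatenates, over the five viewpoints, either the real parts or the
#' moduli of the complex Zernike moments. Moduli are invariant to in-plane
#' silhouette rotation and give the better clustering separability, so they
#' are the default.
#'
#' @param desc a \linkS4class{LightFieldDescriptor}.
#' @param mode "modulus" (default) or "real".
#' @return named numeric vector of length 5 x nrow(momentIndex).
#' @export
lfRealFeatures <- function(desc, mode = c("modulus", "real")) {
  mode <- match.arg(mode)
  idx <- desc@momentIndex
  out <- unlist(lapply(names(desc@moments), function(view) {
    v <- desc@moments[[view]]
    vals <- if (mode == "modulus") Mod(v) else Re(v)
    setNames(vals, sprintf("%s_n%d_m%d", view, idx$n, idx$m))
  }))
  out
}

#' Write Light-Field features to CSV
#'
#' Long format: \code{spine_id, view, n, m, re, im, modulus}; wide format
#' (for model input): \code{spine_id} plus one modulus column per
#' (view, n, m).
#'
#' @param descs named list of \linkS4class{LightFieldDescriptor}.
#' @param path output CSV path.
#' @param wide write the wide modulus table instead of the long one.
#' @return \code{path}, invisibly.
#' @export
writeLightFieldCSV <- function(descs, path, wide = FALSE) {
  stopifnot(length(descs) > 0)
  if (wide) {
    rows <- lapply(names(descs), function(id) {
      feat <- lfRealFeatures(descs[[id]], "modulus")
      cbind(data.frame(spine_id = id),
            as.data.frame(as.list(feat), check.names = FALSE))
    })
    df <- do.call(rbind, rows)
  } else {
    rows <- lapply(names(descs), function(id) {
      d <- descs[[id]]
      do.call(rbind, lapply(names(d@moments), function(view) {
        v <- d@moments[[view]]
        data.frame(spine_id = id, view = view,
                   n = d@momentIndex$n, m = d@momentIndex$m,
                   re = Re(v), im = Im(v), modulus = Mod(v))
      }))
    })
    df <- do.call(rbind, rows)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
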