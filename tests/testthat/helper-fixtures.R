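# Fixture builders and independent oracles, all generated in code.

# Axis-aligned cube [-s/2, s/2]^3 centered at `center`.
make_cube <- function(s = 1, center = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(-s / 2, s / 2), c(-s / 2, s / 2),
                             c(-s / 2, s / 2)))
  v <- sweep(v, 2, center, `+`)
  f <- rbind(c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
             c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8),
             c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7))
  fixWinding(TriangleMesh(v, f))
}

# Closed cylinder of radius r and height h along +y, base at y = 0.
make_cylinder <- function(r = 0.3, h = 2, nTheta = 32, nRings = 16) {
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  ys <- seq(0, h, length.out = nRings)
  rings <- do.call(rbind, lapply(ys, function(y)
    cbind(r * cos(theta), y, r * sin(theta))))
  v <- rbind(c(0, 0, 0), rings, c(0, h, 0))
  iR <- function(ring, j) 1L + (ring - 1L) * nTheta + ((j - 1L) %% nTheta) + 1L
  faces <- list()
  for (j in seq_len(nTheta)) {
    faces[[length(faces) + 1]] <- c(1L, iR(1, j + 1), iR(1, j))
    faces[[length(faces) + 1]] <- c(iR(nRings, j), iR(nRings, j + 1),
                                    nrow(v))
  }
  for (ring in seq_len(nRings - 1)) for (j in seq_len(nTheta)) {
    faces[[length(faces) + 1]] <- c(iR(ring, j), iR(ring, j + 1),
                                    iR(ring + 1, j))
    faces[[length(faces) + 1]] <- c(iR(ring, j + 1), iR(ring + 1, j + 1),
                                    iR(ring + 1, j))
  }
  m <- TriangleMesh(v, do.call(rbind, faces))
  if (spinemorph:::signedVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

# Torus with major radius R about the y-axis, tube radius r.
make_torus <- function(R = 1, r = 0.25, nu = 24, nv = 16) {
  iV <- function(i, j) ((i - 1L) %% nu) * nv + ((j - 1L) %% nv) + 1L
  v <- matrix(0, nu * nv, 3)
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    u <- 2 * pi * (i - 1) / nu; w <- 2 * pi * (j - 1) / nv
    v[iV(i, j), ] <- c((R + r * cos(w)) * cos(u), r * sin(w),
                       (R + r * cos(w)) * sin(u))
  }
  faces <- list()
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    faces[[length(faces) + 1]] <- c(iV(i, j), iV(i + 1, j), iV(i, j + 1))
    faces[[length(faces) + 1]] <- c(iV(i + 1, j), iV(i + 1, j + 1),
                                    iV(i, j + 1))
  }
  fixWinding(TriangleMesh(v, do.call(rbind, faces)))
}

# Bent tube ("banana"): circular cross-section swept along a circular arc
# in the xz-plane; strong bends put the center of mass outside the solid.
make_bent_tube <- function(Rc = 1, rt = 0.15, angle = 2 * pi / 3,
                           nu = 24, nv = 12) {
  us <- seq(-angle / 2, angle / 2, length.out = nu)
  rings <- lapply(us, function(u) {
    cdir <- c(cos(u), 0, sin(u))          # radial direction of the arc
    tdir <- c(-sin(u), 0, cos(u))         # tangent (unused)
    ndir <- c(0, 1, 0)
    ctr <- Rc * cdir
    w <- 2 * pi * (seq_len(nv) - 1) / nv
    t(sapply(w, function(a) ctr + rt * (cos(a) * cdir + sin(a) * ndir)))
  })
  v <- do.call(rbind, rings)
  iR <- function(ring, j) (ring - 1L) * nv + ((j - 1L) %% nv) + 1L
  capA <- nrow(v) + 1L; capB <- nrow(v) + 2L
  v <- rbind(v, Rc * c(cos(us[1]), 0, sin(us[1])),
             Rc * c(cos(us[nu]), 0, sin(us[nu])))
  faces <- list()
  for (ring in seq_len(nu - 1)) for (j in seq_len(nv)) {
    faces[[length(faces) + 1]] <- c(iR(ring, j), iR(ring, j + 1),
                                    iR(ring + 1, j))
    faces[[length(faces) + 1]] <- c(iR(ring, j + 1), iR(ring + 1, j + 1),
                                    iR(ring + 1, j))
  }
  for (j in seq_len(nv)) {
    faces[[length(faces) + 1]] <- c(capA, iR(1, j + 1), iR(1, j))
    faces[[length(faces) + 1]] <- c(capB, iR(nu, j), iR(nu, j + 1))
  }
  fixWinding(TriangleMesh(v, do.call(rbind, faces)))
}

# L-shaped prism: L polygon extruded along z. Analytic centroid available.
make_L_prism <- function(h = 0.5) {
  poly <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  n <- nrow(poly)
  v <- rbind(cbind(poly, 0), cbind(poly, h))
  # caps: fan from vertex 1 (the polygon is star-shaped from there)
  faces <- list()
  for (i in 2:(n - 1)) {
    faces[[length(faces) + 1]] <- c(1, i, i + 1)
    faces[[length(faces) + 1]] <- c(n + 1, n + i + 1, n + i)
  }
  for (i in seq_len(n)) {
    j <- i %% n + 1
    faces[[length(faces) + 1]] <- c(i, j, n + i)
    faces[[length(faces) + 1]] <- c(j, n + j, n + i)
  }
  fixWinding(TriangleMesh(v, do.call(rbind, faces)))
}

# Star-shaped mesh from a radial function r(theta, phi) sampled on an
# icosphere (used for band-limited round-trip fixtures).
make_radial_mesh <- function(radialFun, subdivisions = 3) {
  ico <- icosphere(subdivisions)
  ang <- spinemorph:::dirs_to_angles(vertices(ico))
  r <- radialFun(ang[, "theta"], ang[, "phi"])
  stopifnot(all(r > 0))
  TriangleMesh(vertices(ico) * r, faces(ico))
}

# Random band-limited positive radial function: r = c00*Y00 + sum c_lm Y_lm,
# degrees 1..4, coefficients scaled until positive everywhere.
random_bandlimited <- function(seed, lmax = 4, amp = 0.25) {
  set.seed(seed)
  L <- lmax + 1
  coef <- c(sqrt(4 * pi), rnorm(L^2 - 1, 0, amp))
  fun <- function(theta, phi) {
    as.numeric(sphHarmBasis(L, theta, phi) %*% coef)
  }
  # shrink the fluctuating part until the radius is safely positive
  probe <- spinemorph:::dirs_to_angles(sampleSphere(5000, seed + 1))
  while (min(fun(probe[, "theta"], probe[, "phi"])) < 0.3) {
    coef[-1] <- coef[-1] * 0.8
  }
  list(coef = coef, fun = fun, L = L)
}

# Independent R-level point-to-triangle distance (for Hausdorff oracle):
# plane projection tested by barycentric coordinates, else the minimum of
# the three exact point-to-segment distances. No shared code with the C++
# kernel (which uses the region decomposition).
oracle_point_tri <- function(p, a, b, c) {
  seg <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((u + t * d - p)^2))
  }
  n <- spinemorph:::cross3(b - a, c - a)
  n2 <- sum(n^2)
  if (n2 > 0) {
    # barycentric coordinates of the in-plane projection
    q <- p - n * sum((p - a) * n) / n2
    M <- cbind(b - a, c - a)
    st <- tryCatch(solve(crossprod(M), crossprod(M, q - a)),
                   error = function(e) NULL)
    if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
      return(sqrt(sum((q - p)^2)))
  }
  min(seg(p, a, b), seg(p, b, c), seg(p, c, a))
}

oracle_hausdorff <- function(A, B) {
  one_way <- function(P, M) {
    f <- faces(M); v <- vertices(M)
    max(apply(P, 1, function(p) {
      min(vapply(seq_len(nrow(f)), function(i)
        oracle_point_tri(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0))
    }))
  }
  max(one_way(vertices(A), B), one_way(vertices(B), A))
}

# Rotation matrix from a seed (uniform via QR of Gaussians).
random_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotate_mesh <- function(mesh, R, shift = c(0, 0, 0)) {
  TriangleMesh(sweep(vertices(mesh) %*% t(R), 2, shift, `+`),
               faces(mesh), junctionRegion(mesh))
}

# Draw an analytic 2D shape (function of x, y -> logical) into a Silhouette.
draw_silhouette <- function(fun, px = 256, halfwidth = 1.2) {
  cx <- ((seq_len(px) - 0.5) / px * 2 - 1) * halfwidth
  g <- expand.grid(x = cx, y = cx)
  img <- matrix(0L, px, px)
  img[cbind(match(g$y, cx), match(g$x, cx))] <- as.integer(fun(g$x, g$y))
  new("Silhouette", pixels = img, resolution = px / (2 * halfwidth))
}
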