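test_that("Zernike radial polynomials match closed forms and reject bad indices", {
  expect_equal(zernikeRadial(0, 0, c(0, 0.5, 1)), c(1, 1, 1))
  expect_equal(zernikeRadial(2, 0, 0.5), -0.5)
  expect_equal(zernikeRadial(2, 2, 0.7), 0.49)
  expect_error(zernikeRadial(3, 2, 0.5), "even")
  expect_error(zernikeBasis(2, 3, 0.5, 0), "exceed")
  expect_equal(zernikeBasis(2, -2, 0.7, 0.3),
               Conj(zernikeBasis(2, 2, 0.7, 0.3)))
})

test_that("the (n, m) index table counts 36 moments at order 10", {
  idx <- zernikeIndex(10)
  expect_equal(nrow(idx), 36L)
  expect_true(all((idx$n - idx$m) %% 2 == 0))
  expect_true(all(idx$m >= 0 & idx$m <= idx$n))
})

test_that("Zernike polynomials are orthogonal on the disk (quadrature oracle)", {
  nq <- 400
  r <- (seq_len(nq) - 0.5) / nq
  th <- 2 * pi * (seq_len(nq) - 1) / nq
  g <- expand.grid(r = r, th = th)
  w <- g$r * (1 / nq) * (2 * pi / nq)  # polar area element
  idx <- zernikeIndex(6)
  V <- sapply(seq_len(nrow(idx)), function(i)
    zernikeBasis(idx$n[i], idx$m[i], g$r, g$th))
  G <- Conj(t(V)) %*% (V * w)
  d <- Mod(diag(G))
  off <- Mod(G - diag(diag(G)))
  expect_lt(max(off) / min(d), 1e-3)
})

test_that("a full disk yields the monopole moment and nothing else", {
  disk <- draw_silhouette(function(x, y) x^2 + y^2 <= 1, px = 256)
  disk <- inscribeUnitDisk(disk)
  mom <- encodeZernike(disk, M = 4)
  expect_equal(Mod(mom[1]), 1, tolerance = 0.02)  # a00 = 1 standard-normalized
  expect_lt(max(Mod(mom[-1])) / Mod(mom[1]), 0.02)
})

test_that("moment moduli are invariant to in-plane rotation", {
  shape <- function(ang) {
    function(x, y) {
      xr <- cos(ang) * x + sin(ang) * y
      yr <- -sin(ang) * x + cos(ang) * y
      (xr^2 / 0.8^2 + yr^2 / 0.45^2 <= 1) |
        ((xr - 0.55)^2 + yr^2 <= 0.3^2)
    }
  }
  m0 <- encodeZernike(inscribeUnitDisk(draw_silhouette(shape(0), 400)), 10)
  m37 <- encodeZernike(inscribeUnitDisk(draw_silhouette(shape(37 * pi / 180),
                                                        400)), 10)
  keep <- Mod(m0) > 0.02 * max(Mod(m0))  # compare non-negligible moments
  drift <- abs(Mod(m37[keep]) - Mod(m0[keep])) / max(Mod(m0))
  expect_lt(max(drift), 0.02)
  # real parts are NOT rotation invariant (the property pair)
  expect_gt(max(abs(Re(m37) - Re(m0))) / max(Mod(m0)), 0.05)
})

test_that("unit-disk inscription is exact on known circles and scale free", {
  disk <- draw_silhouette(function(x, y) (x - 0.2)^2 + (y + 0.1)^2 <= 0.5^2,
                          px = 256, halfwidth = 1.2)
  insc <- inscribeUnitDisk(disk)
  px_per_unit <- 256 / 2.4
  expect_equal(insc@diskRadius, 0.5 * px_per_unit, tolerance = 1.5)
  expect_equal(insc@diskCenter,
               c((0.2 + 1.2) * px_per_unit, (-0.1 + 1.2) * px_per_unit),
               tolerance = 1.5)
  # normalized foreground never leaves the closed unit disk, and fills it
  fg <- which(insc@pixels == 1L, arr.ind = TRUE)
  rr <- sqrt((fg[, 2] - 0.5 - insc@diskCenter[1])^2 +
             (fg[, 1] - 0.5 - insc@diskCenter[2])^2) / insc@diskRadius
  expect_lte(max(rr), 1)
  expect_gt(max(rr), 1 - 1 / insc@diskRadius)  # within a pixel of the rim
})

test_that("inscription radius matches a brute-force minimal-circle oracle", {
  blob <- draw_silhouette(function(x, y)
    ((x - 0.3)^2 / 0.5^2 + (y - 0.2)^2 / 0.2^2 <= 1), px = 128)
  insc <- inscribeUnitDisk(blob)
  fg <- which(blob@pixels == 1L, arr.ind = TRUE)
  pts <- cbind(fg[, 2] - 0.5, fg[, 1] - 0.5)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  # oracle: smallest of all 2-point and 3-point circles covering the hull
  cover <- function(c2) all(sqrt((hull[, 1] - c2[1])^2 +
                                 (hull[, 2] - c2[2])^2) <= c2[3] + 1e-6)
  best <- Inf
  n <- nrow(hull)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cc <- c((hull[i, ] + hull[j, ]) / 2,
            sqrt(sum((hull[i, ] - hull[j, ])^2)) / 2)
    if (cc[3] < best && cover(cc)) best <- cc[3]
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n) {
      cc <- tryCatch(spinemorph:::min_enclosing_circle(hull[c(i, j, k), ]),
                     error = function(e) NULL)
      if (!is.null(cc) && cc[3] < best && cover(cc)) best <- cc[3]
    }
  expect_equal(insc@diskRadius, best, tolerance = 0.51)
})

test_that("silhouette reconstruction from moments round-trips simple shapes", {
  iou <- function(a, b) sum(a & b) / sum(a | b)
  disk <- inscribeUnitDisk(draw_silhouette(function(x, y) x^2 + y^2 <= 0.9^2,
                                           px = 128))
  rec <- reconstructSilhouette(encodeZernike(disk, 4), 4, px = 128)
  # compare in normalized disk coordinates via re-inscription
  norm_fg <- function(s) {
    fg <- which(s@pixels == 1L, arr.ind = TRUE)
    cbind((fg[, 2] - 0.5 - s@diskCenter[1]) / s@diskRadius,
          (fg[, 1] - 0.5 - s@diskCenter[2]) / s@diskRadius)
  }
  rec <- inscribeUnitDisk(rec)
  # rasterize both normalized point sets on a common grid
  rast <- function(pts, n = 64) {
    ij <- pmin(n, pmax(1, ceiling((pts + 1) / 2 * n)))
    m <- matrix(FALSE, n, n); m[ij] <- TRUE; m
  }
  expect_gt(iou(rast(norm_fg(disk)), rast(norm_fg(rec))), 0.95)

  square <- inscribeUnitDisk(draw_silhouette(function(x, y)
    pmax(abs(x), abs(y)) <= 0.55, px = 128))
  rec2 <- inscribeUnitDisk(reconstructSilhouette(encodeZernike(square, 10),
                                                 10, px = 128))
  expect_gt(iou(rast(norm_fg(square)), rast(norm_fg(rec2))), 0.85)

  empty <- reconstructSilhouette(complex(36), 10, px = 64)
  expect_equal(sum(empty@pixels), 0)
})
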