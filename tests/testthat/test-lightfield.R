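test_that("the five observation points sit on the 2r sphere as specified", {
  m <- orientSpine(makeSpine(spineShapeParams("mushroom"), seed = 1))
  ctr <- internalCenter(m)
  vp <- observationPoints(m, ctr)
  expect_equal(nrow(vp), 5L)
  r <- sqrt(max(rowSums(sweep(vertices(m), 2, ctr)^2)))
  expect_equal(unname(vp[, "distance"]), rep(2 * r, 5), tolerance = 1e-9)
  # A is the +z pole: cartesian (0, 0, 2r) relative to the center
  cart <- spinemorph:::viewpoint_cartesian(vp)
  expect_equal(unname(cart["A", ]), c(0, 0, 2 * r), tolerance = 1e-9)
  # B and C are the +x and +y principal directions
  expect_equal(unname(cart["B", ] / (2 * r)), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(unname(cart["C", ] / (2 * r)), c(0, 1, 0), tolerance = 1e-9)
  # scaling the mesh scales distances, not angles
  m3 <- TriangleMesh(vertices(m) * 3, faces(m), junctionRegion(m))
  vp3 <- observationPoints(m3, ctr * 3)
  expect_equal(vp3[, c("zenith", "azimuth")], vp[, c("zenith", "azimuth")],
               tolerance = 1e-9)
  expect_equal(unname(vp3[, "distance"]), unname(3 * vp[, "distance"]),
               tolerance = 1e-9)
})

test_that("unoriented meshes are rejected for observation points", {
  m <- makeSpine(spineShapeParams("mushroom"), seed = 2)
  tilted <- rotate_mesh(m, random_rotation(5))
  expect_error(observationPoints(tilted), "canonical pose")
})

test_that("silhouettes of canonical solids have the right area", {
  ico <- icosphere(3)
  vp <- c(0, 0, 4)
  sil <- projectSilhouette(ico, vp, px = 256, center = c(0, 0, 0),
                           window = 1.3)
  area <- sum(sil@pixels)
  rpix <- sil@resolution  # pixels per unit length, disk radius 1
  expect_equal(area / (pi * rpix^2), 1, tolerance = 0.02)
  # cube face-on: silhouette is its own bounding square
  cube <- make_cube()
  sc <- projectSilhouette(cube, c(0, 0, 2), px = 256, center = c(0, 0, 0),
                          window = 0.8)
  fg <- which(sc@pixels == 1L, arr.ind = TRUE)
  bbox_area <- diff(range(fg[, 1]) + c(-0, 1)) * diff(range(fg[, 2]) + c(0, 1))
  expect_equal(sum(sc@pixels) / bbox_area, 1, tolerance = 0.02)
})

test_that("silhouette area fraction converges with raster resolution", {
  m <- orientSpine(makeSpine(spineShapeParams("thin"), seed = 3))
  frac <- sapply(c(256, 512), function(px) {
    s <- projectSilhouette(m, c(pi / 2, 0, 4), px = px,
                           center = internalCenter(m))
    mean(s@pixels)
  })
  expect_equal(frac[1], frac[2], tolerance = 0.01)
})

test_that("the Light-Field descriptor has the contracted shape", {
  m <- makeSpine(spineShapeParams("mushroom"), seed = 4)
  lf <- encodeLightField(m, M = 10, px = 128)
  expect_equal(length(lf@moments), 5L)
  expect_equal(nrow(lf@momentIndex), 36L)
  expect_equal(length(lfRealFeatures(lf)), 180L)
  expect_equal(length(lfRealFeatures(lf, "real")), 180L)
})

test_that("a sphere looks identical from all five viewpoints", {
  ico <- icosphere(3)
  lf <- encodeLightField(ico, M = 6, px = 128, orient = FALSE)
  mods <- sapply(lf@moments, Mod)
  ref <- mods[, 1]
  for (v in 2:5)
    expect_lt(max(abs(mods[, v] - ref)) / max(ref), 0.02)
})

test_that("modulus features are scale invariant through inscription", {
  m <- makeSpine(spineShapeParams("stubby"), seed = 5)
  f1 <- lfRealFeatures(encodeLightField(m, M = 8, px = 128))
  m3 <- TriangleMesh(vertices(m) * 3, faces(m), junctionRegion(m))
  f3 <- lfRealFeatures(encodeLightField(m3, M = 8, px = 128))
  expect_lt(max(abs(f1 - f3)) / max(f1), 0.03)
})

test_that("real part and modulus reductions follow |3+4i| = 5", {
  idx <- zernikeIndex(0)
  lf <- new("LightFieldDescriptor", orderM = 0L,
            viewpoints = matrix(0, 5, 3,
                                dimnames = list(LETTERS[1:5],
                                                c("zenith", "azimuth",
                                                  "distance"))),
            moments = setNames(rep(list(complex(real = 3,
                                                imaginary = 4)), 5),
                               LETTERS[1:5]),
            momentIndex = idx, mode = "complex")
  expect_equal(unname(lfRealFeatures(lf, "modulus")), rep(5, 5))
  expect_equal(unname(lfRealFeatures(lf, "real")), rep(3, 5))
})

test_that("different morphological classes separate in feature space", {
  mush <- lapply(1:3, function(s)
    lfRealFeatures(encodeLightField(makeSpine(spineShapeParams("mushroom"),
                                              seed = s), M = 8, px = 128)))
  thin <- lapply(1:3, function(s)
    lfRealFeatures(encodeLightField(makeSpine(spineShapeParams("thin"),
                                              seed = s), M = 8, px = 128)))
  dmat <- function(a, b) sqrt(sum((a - b)^2))
  intra <- mean(c(dmat(mush[[1]], mush[[2]]), dmat(mush[[2]], mush[[3]]),
                  dmat(thin[[1]], thin[[2]]), dmat(thin[[2]], thin[[3]])))
  inter <- mean(outer(1:3, 1:3, Vectorize(function(i, j)
    dmat(mush[[i]], thin[[j]]))))
  expect_gt(inter, intra)
})

test_that("Light-Field CSV exports both long and wide schemas", {
  m <- makeSpine(spineShapeParams("thin"), seed = 6)
  lf <- encodeLightField(m, M = 4, px = 64)
  p1 <- file.path(tempdir(), "lf_long.csv")
  p2 <- file.path(tempdir(), "lf_wide.csv")
  writeLightFieldCSV(list(sp = lf), p1)
  writeLightFieldCSV(list(sp = lf), p2, wide = TRUE)
  long <- read.csv(p1)
  expect_equal(names(long),
               c("spine_id", "view", "n", "m", "re", "im", "modulus"))
  expect_equal(nrow(long), 5 * nrow(zernikeIndex(4)))
  wide <- read.csv(p2, check.names = FALSE)
  expect_equal(ncol(wide), 1 + 5 * nrow(zernikeIndex(4)))
})
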