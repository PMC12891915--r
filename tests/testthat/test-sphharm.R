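test_that("closed-form harmonic values and the packing contract hold", {
  expect_equal(realSphericalHarmonic(0, 0, 1.1, 2.2), 1 / sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(realSphericalHarmonic(1, 0, 0, 0), sqrt(3 / (4 * pi)),
               tolerance = 1e-12)
  expect_error(realSphericalHarmonic(1, 2, 0, 0), "exceed")
  B <- sphHarmBasis(10, c(0.3, 1.2), c(0.1, 4))
  expect_equal(ncol(B), 100L)
  expect_equal(colnames(B)[1:5],
               c("a_0_0", "a_1_-1", "a_1_0", "a_1_1", "a_2_-2"))
})

test_that("real harmonics are orthonormal under Gauss-Legendre quadrature", {
  gl <- pracma::gaussLegendre(200, -1, 1)
  phi <- 2 * pi * (seq_len(400) - 1) / 400
  grid <- expand.grid(x = gl$x, phi = phi)
  B <- sphHarmBasis(6, acos(grid$x), grid$phi)
  w <- rep(gl$w, times = 400) * (2 * pi / 400)
  G <- crossprod(B, B * w)
  expect_lt(max(abs(G - diag(36))), 1e-6)
})

test_that("encoding a constant radius recovers the monopole", {
  dirs <- sampleSphere(1e5, 11)
  samp <- new("SphericalSample", center = c(0, 0, 0), directions = dirs,
              radii = rep(2, nrow(dirs)), multiHitFraction = 0,
              missCount = 0L)
  d <- encodeSphHarm(samp, 10, normalize = FALSE)
  co <- shCoefficients(d)
  expect_equal(co[["a_0_0"]], 2 * sqrt(4 * pi), tolerance = 0.01)
  # Monte-Carlo noise: per-coefficient sd is 2*sqrt(4*pi/N) ~ 0.0224;
  # bound the max of the 99 zero-mean coefficients at 4.5 sigma
  expect_lt(max(abs(co[-1])), 4.5 * 2 * sqrt(4 * pi / 1e5))
  expect_equal(length(co), 100L)
})

test_that("a planted single harmonic is recovered within Monte-Carlo error", {
  dirs <- sampleSphere(1e5, 13)
  ang <- spinemorph:::dirs_to_angles(dirs)
  f <- 1 + 0.3 * realSphericalHarmonic(2, 0, ang[, "theta"], ang[, "phi"])
  samp <- new("SphericalSample", center = c(0, 0, 0), directions = dirs,
              radii = f, multiHitFraction = 0, missCount = 0L)
  d <- encodeSphHarm(samp, 5, normalize = FALSE)
  se <- sqrt(mean(f^2)) * sqrt(4 * pi / 1e5)
  expect_lt(abs(shCoefficients(d)[["a_2_0"]] - 0.3), 3 * se)
  expect_lt(abs(shCoefficients(d)[["a_0_0"]] - sqrt(4 * pi)), 3 * se)
})

test_that("Monte-Carlo projection agrees with product quadrature", {
  # deterministic quadrature oracle for the same radial functions
  gl <- pracma::gaussLegendre(120, -1, 1)
  phi <- 2 * pi * (seq_len(240) - 1) / 240
  grid <- expand.grid(x = gl$x, phi = phi)
  w <- rep(gl$w, times = 240) * (2 * pi / 240)
  Bq <- sphHarmBasis(5, acos(grid$x), grid$phi)
  dirs <- sampleSphere(1e5, 17)
  ang <- spinemorph:::dirs_to_angles(dirs)
  for (s in 1:5) {
    bl <- random_bandlimited(400 + s)
    fq <- bl$fun(acos(grid$x), grid$phi)
    exact <- as.numeric(crossprod(Bq, fq * w))
    f <- bl$fun(ang[, "theta"], ang[, "phi"])
    samp <- new("SphericalSample", center = c(0, 0, 0), directions = dirs,
                radii = f, multiHitFraction = 0, missCount = 0L)
    est <- shCoefficients(encodeSphHarm(samp, 5, normalize = FALSE))
    se <- sqrt(mean(f^2)) * sqrt(4 * pi / 1e5)
    expect_true(all(abs(est - exact) < 3.7 * se))
  }
})

test_that("reconstruction of a pure monopole is an exact sphere", {
  co <- numeric(100); co[1] <- sqrt(4 * pi)
  d <- new("SphHarmDescriptor", degreeL = 10L, nSamples = 1L,
           coefficients = co, center = c(0, 0, 0), scale = 1)
  rec <- reconstructSphHarm(d, 3)
  r <- sqrt(rowSums(vertices(rec)^2))
  expect_equal(r, rep(1, length(r)), tolerance = 1e-6)
  expect_equal(attr(rec, "clamped"), 0)
})

test_that("negative reconstructed radii are clamped and reported", {
  co <- numeric(4); co[3] <- 5  # dipole only: half the sphere negative
  d <- new("SphHarmDescriptor", degreeL = 2L, nSamples = 1L,
           coefficients = co, center = c(0, 0, 0), scale = 1)
  rec <- reconstructSphHarm(d, 2)
  expect_gt(attr(rec, "clamped"), 0)
  expect_true(all(sqrt(rowSums(vertices(rec)^2)) > 0))
})

test_that("band-limited shapes are recovered at dense sampling", {
  dirs <- sampleSphere(4e5, 19)
  ang <- spinemorph:::dirs_to_angles(dirs)
  for (s in 1:3) {
    bl <- random_bandlimited(500 + s)
    f <- bl$fun(ang[, "theta"], ang[, "phi"])
    samp <- new("SphericalSample", center = c(0, 0, 0), directions = dirs,
                radii = f, multiHitFraction = 0, missCount = 0L)
    est <- shCoefficients(encodeSphHarm(samp, 10, normalize = FALSE))
    truth <- c(bl$coef, numeric(100 - 25))
    relL2 <- sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
    expect_lt(relL2, 0.02)
  }
})

test_that("the full accuracy chain runs and flags failures", {
  m <- makeSpine(spineShapeParams("mushroom"), seed = 12)
  d <- sphHarmAccuracy(m, L = 10, N = 140, seed = 1)
  expect_true(is.finite(as.numeric(d)))
  expect_gte(attr(d, "multiHitFraction"), 0)
  open_m <- m
  open_m@faces <- open_m@faces[-1, ]
  expect_error(sphHarmAccuracy(open_m, seed = 1))
})

test_that("grid search degenerates to a single accuracy and finds plateaus", {
  m <- orientSpine(makeSpine(spineShapeParams("stubby"), seed = 3))
  gs <- gridSearchSphHarm(list(m), Lgrid = 6, Ngrid = 200, seed = 5,
                          orient = FALSE)
  expect_equal(nrow(gs$table), 1L)
  expect_equal(gs$table$mean,
               as.numeric(sphHarmAccuracy(m, L = 6, N = 200, seed = 6,
                                          orient = FALSE)),
               tolerance = 1e-12)
  expect_equal(unname(gs$optimal), c(6, 200))
})

test_that("descriptor CSV export honours the packing order", {
  m <- orientSpine(makeSpine(spineShapeParams("thin"), seed = 7))
  rt <- radialTabulation(m, internalCenter(m), sampleSphere(140, 3))
  d <- encodeSphHarm(rt, 4)
  p <- file.path(tempdir(), "desc.csv")
  writeSphHarmCSV(list(sp1 = d), p)
  df <- read.csv(p, check.names = FALSE)
  expect_equal(names(df)[1:5], c("spine_id", "L", "N", "a_0_0", "a_1_-1"))
  expect_equal(as.numeric(df[1, -(1:3)]), unname(shCoefficients(d)),
               tolerance = 1e-10)
})

test_that("least-squares encoding nails band-limited functions at small N", {
  dirs <- sampleSphere(150, 23)
  ang <- spinemorph:::dirs_to_angles(dirs)
  bl <- random_bandlimited(600)
  f <- bl$fun(ang[, "theta"], ang[, "phi"])
  samp <- new("SphericalSample", center = c(0, 0, 0), directions = dirs,
              radii = f, multiHitFraction = 0, missCount = 0L)
  est <- shCoefficients(encodeSphHarm(samp, 10, normalize = FALSE,
                                      method = "lsq"))
  truth <- c(bl$coef, numeric(75))
  expect_equal(est, truth, tolerance = 1e-8, ignore_attr = TRUE)
})
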