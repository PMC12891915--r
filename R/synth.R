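# Parametric spine-like meshes: an ellipsoidal head fused to a cylindrical
# neck capped by a flat junction disk, built as a surface of revolution
# about the spine axis (+y), watertight by construction. Serves as the
# package's entire fixture and demo-data surface: the real microscopy-derived
# meshes are not deposited anywhere.

#' Shape parameters for one synthetic spine
#'
#' Class defaults are chosen so the rendered archetypes match the classical
#' morphologies (lengths in micrometres): mushroom (head much wider than
#' neck), thin (long narrow neck, small head), stubby (neckless, wide
#' attachment), filopodia (headless elongated protrusion with a tapered
#' tip).
#'
#' @param class one of "mushroom", "thin", "stubby", "filopodia".
#' @param ... overrides for any of headRadius, neckRadius, neckLength,
#'   eccentricity (head elongation along the axis, >= 1), jitterSd
#'   (Gaussian vertex noise, length units), nTheta / nProfile (mesh
#'   resolution).
#' @return named list of parameters with element \code{className}.
#' @export
spineShapeParams <- function(class = c("mushroom", "thin", "stubby",
                                       "filopodia"), ...) {
  class <- match.arg(class)
  base <- switch(class,
    mushroom  = list(headRadius = 0.45, neckRadius = 0.12,
                     neckLength = 0.50, eccentricity = 1.1),
    thin      = list(headRadius = 0.18, neckRadius = 0.08,
                     neckLength = 1.00, eccentricity = 1.2),
    stubby    = list(headRadius = 0.40, neckRadius = 0.32,
                     neckLength = 0.05, eccentricity = 1.0),
    filopodia = list(headRadius = 0.08, neckRadius = 0.08,
                     neckLength = 1.20, eccentricity = 2.0))
  p <- modifyList(c(base, list(jitterSd = 0.01, nTheta = 24L,
                               nProfile = 22L, className = class)),
                  list(...))
  if (p$headRadius < p$neckRadius)
    stop("headRadius must be >= neckRadius (the head caps the neck)")
  if (p$neckLength < 0 || p$headRadius <= 0 || p$neckRadius <= 0)
    stop("lengths must be positive (neckLength may be 0)")
  if (p$jitterSd >= p$neckRadius / 2)
    stop("jitterSd must stay below neckRadius / 2")
  p
}

#' Analytic volume of the ideal (jitter-free) synthetic spine
#'
#' Cylinder plus ellipsoidal-cap closed form, the oracle for mesh-volume
#' checks.
#'
#' @param params output of \code{\link{spineShapeParams}}.
#' @return volume in cubic length units.
#' @export
spineAnalyticVolume <- function(params) {
  a <- params$headRadius; rn <- params$neckRadius
  b <- a * params$eccentricity
  s <- sqrt(max(0, 1 - (rn / a)^2))
  pi * rn^2 * params$neckLength + pi * a^2 * b * (2 / 3 + s - s^3 / 3)
}

#' Generate one synthetic spine mesh
#'
#' Surface of revolution about +y: flat junction disk at y = 0 (its rim is
#' the junction region), cylindrical neck, ellipsoidal head closed at an
#' apex. Gaussian jitter is applied along the local radial direction to all
#' vertices except the junction disk, which stays planar. Deterministic
#' given the seed.
#'
#' @param params output of \code{\link{spineShapeParams}}.
#' @param seed integer RNG seed.
#' @return a watertight \linkS4class{TriangleMesh} with junction region set.
#' @export
makeSpine <- function(params, seed = 1) {
  a <- params$headRadius; rn <- params$neckRadius
  Ln <- params$neckLength; b <- a * params$eccentricity
  nTheta <- as.integer(params$nTheta)
  s <- sqrt(max(0, 1 - (rn / a)^2))
  yc <- Ln + b * s
  # profile rings (y, rho), bottom rim first
  nHead <- max(4L, as.integer(round(params$nProfile * b / (Ln + b))))
  nNeck <- max(if (Ln > 0) 2L else 1L, params$nProfile - nHead)
  rings <- if (Ln > 0) {
    yN <- seq(0, Ln, length.out = nNeck)
    cbind(y = yN, rho = rep(rn, nNeck))
  } else cbind(y = 0, rho = rn)
  psi <- seq(asin(-s), pi / 2, length.out = nHead + 1)
  psi <- psi[-c(1, nHead + 1)]  # first ring duplicates the neck top; last is the apex
  rings <- rbind(rings, cbind(y = yc + b * sin(psi), rho = a * cos(psi)))
  nR <- nrow(rings)
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  ringV <- do.call(rbind, lapply(seq_len(nR), function(r)
    cbind(rings[r, "rho"] * cos(theta), rings[r, "y"],
          rings[r, "rho"] * sin(theta))))
  bottomCenter <- c(0, 0, 0)
  apex <- c(0, yc + b, 0)
  V <- rbind(bottomCenter, ringV, apex)
  iRing <- function(r, j) 1L + (r - 1L) * nTheta + ((j - 1L) %% nTheta) + 1L
  iCenter <- 1L; iApex <- nrow(V)
  faces <- list()
  for (j in seq_len(nTheta)) {   # bottom disk, facing -y
    faces[[length(faces) + 1]] <- c(iCenter, iRing(1, j + 1), iRing(1, j))
  }
  for (r in seq_len(nR - 1)) for (j in seq_len(nTheta)) {
    faces[[length(faces) + 1]] <- c(iRing(r, j), iRing(r, j + 1),
                                    iRing(r + 1, j))
    faces[[length(faces) + 1]] <- c(iRing(r, j + 1), iRing(r + 1, j + 1),
                                    iRing(r + 1, j))
  }
  for (j in seq_len(nTheta)) {   # apex fan
    faces[[length(faces) + 1]] <- c(iRing(nR, j), iRing(nR, j + 1), iApex)
  }
  F <- do.call(rbind, faces)
  if (params$jitterSd > 0) {
    V <- with_seed(seed, {
      for (r in 2:nR) for (j in seq_len(nTheta)) {   # skip junction rim (r=1)
        i <- iRing(r, j)
        radial <- c(cos(theta[j]), 0, sin(theta[j]))
        d <- rnorm(1, 0, params$jitterSd)
        rho0 <- rings[r, "rho"]
        d <- max(d, -0.8 * rho0)  # keep the surface off the axis
        V[i, ] <- V[i, ] + d * radial
      }
      V[iApex, 2] <- V[iApex, 2] + rnorm(1, 0, params$jitterSd)
      V
    })
  }
  m <- TriangleMesh(V, F, junctionRegion = iRing(1, seq_len(nTheta)))
  if (signedVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  validObject(m)
  m
}

#' Specification of a two-group synthetic spine population
#'
#' The treated group emulates amyloid-toxicity morphology: heads shrink
#' (headRadiusFactor <= 1) and necks elongate (neckLengthFactor >= 1), which
#' reduces volume by construction. Per-spine lognormal parameter jitter
#' provides within-class diversity.
#'
#' @param nPerGroup spines per group (default 100).
#' @param classMixture named class probabilities, applied to both groups
#'   (or a list with elements \code{control}/\code{treated}).
#' @param headRadiusFactor,neckLengthFactor multiplicative treated-group
#'   shifts (defaults 0.7 and 1.4).
#' @param paramJitterSd sd of the lognormal per-spine parameter jitter.
#' @param seed integer RNG seed.
#' @return named list (a population spec).
#' @export
populationSpec <- function(nPerGroup = 100,
                           classMixture = c(mushroom = 0.4, thin = 0.3,
                                            stubby = 0.2, filopodia = 0.1),
                           headRadiusFactor = 0.7, neckLengthFactor = 1.4,
                           paramJitterSd = 0.15, seed = 1) {
  if (!is.list(classMixture))
    classMixture <- list(control = classMixture, treated = classMixture)
  for (g in names(classMixture)) {
    if (abs(sum(classMixture[[g]]) - 1) > 1e-9)
      stop("class mixture must sum to 1")
  }
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  list(nPerGroup = as.integer(nPerGroup), classMixture = classMixture,
       headRadiusFactor = headRadiusFactor,
       neckLengthFactor = neckLengthFactor,
       paramJitterSd = paramJitterSd, seed = as.integer(seed))
}

#' Generate a two-group synthetic spine population
#'
#' Draws each spine's class from its group mixture, jitters the class
#' default parameters lognormally, applies the treated-group effect factors,
#' and builds the meshes. Deterministic given the spec seed; each spine gets
#' its own RNG stream derived from its id.
#'
#' @param spec output of \code{\link{populationSpec}}.
#' @return list with \code{meshes} (named list of
#'   \linkS4class{TriangleMesh}), \code{labels} (data.frame spine_id, group,
#'   class) and \code{params} (per-spine parameter list).
#' @export
generatePopulation <- function(spec) {
  groups <- c("control", "treated")
  labels <- list(); meshes <- list(); plist <- list()
  draws <- with_seed(spec$seed, {
    lapply(groups, function(g)
      sample(names(spec$classMixture[[g]]), spec$nPerGroup, replace = TRUE,
             prob = spec$classMixture[[g]]))
  })
  names(draws) <- groups
  for (g in groups) {
    for (i in seq_len(spec$nPerGroup)) {
      id <- sprintf("%s_%03d", g, i)
      cls <- draws[[g]][i]
      sd_i <- derive_seed(spec$seed, id)
      jit <- with_seed(sd_i, rlnorm(3, 0, spec$paramJitterSd))
      base <- spineShapeParams(cls)
      hr <- base$headRadius * jit[1]
      nr <- min(base$neckRadius * jit[2], hr)
      nl <- base$neckLength * jit[3]
      if (g == "treated") {
        hr <- hr * spec$headRadiusFactor
        nr <- min(nr, hr)
        nl <- nl * spec$neckLengthFactor
      }
      p <- spineShapeParams(cls, headRadius = hr, neckRadius = nr,
                            neckLength = nl,
                            jitterSd = min(0.01, nr / 4))
      meshes[[id]] <- makeSpine(p, seed = sd_i + 1L)
      plist[[id]] <- p
      labels[[length(labels) + 1]] <-
        data.frame(spine_id = id, group = g, class = cls)
    }
  }
  list(meshes = meshes, labels = do.call(rbind, labels), params = plist)
}

#' Write a population to disk
#'
#' One ASCII PLY per spine (junction region embedded as the \code{junction}
#' vertex property), \code{labels.csv}, \code{junctions.json} (0-based
#' vertex indices) and the generating spec as \code{spec.yaml}.
#'
#' @param pop output of \code{\link{generatePopulation}}.
#' @param dir output directory (created if needed).
#' @param spec optional spec to record alongside.
#' @return \code{dir}, invisibly.
#' @export
writePopulation <- function(pop, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(pop$meshes))
    writeMesh(pop$meshes[[id]], file.path(dir, paste0(id, ".ply")), "ply")
  write.csv(pop$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  junc <- lapply(pop$meshes, function(m) m@junctionRegion - 1L)
  jsonlite::write_json(junc, file.path(dir, "junctions.json"))
  if (!is.null(spec)) {
    spec$classMixture <- lapply(spec$classMixture, as.list)
    yaml::write_yaml(spec, file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}
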