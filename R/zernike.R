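# Zernike polynomials on the unit disk: the per-silhouette basis of the
# Light-Field descriptor.

#' Zernike radial polynomial R_n^m
#'
#' @param n radial order >= 0.
#' @param m azimuthal order, 0 <= m <= n, n - m even.
#' @param r radii in [0, 1] (vectorized).
#' @return numeric vector of R_n^m(r).
#' @export
zernikeRadial <- function(n, m, r) {
  if (m < 0 || m > n) stop("need 0 <= m <= n")
  if ((n - m) %% 2 != 0) stop("n - m must be even")
  out <- numeric(length(r))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    out <- out + coef * r^(n - 2 * k)
  }
  out
}

#' Zernike polynomial V_mn on the unit disk
#'
#' V_mn(r, theta) = R_n^|m|(r) * exp(i m theta).
#'
#' @param n radial order.
#' @param m azimuthal order, |m| <= n, n - |m| even.
#' @param r radii in [0, 1].
#' @param theta polar angles.
#' @return complex vector.
#' @export
zernikeBasis <- function(n, m, r, theta) {
  if (abs(m) > n) stop("|m| must not exceed n")
  if ((n - abs(m)) %% 2 != 0) stop("n - |m| must be even")
  zernikeRadial(n, abs(m), r) * exp(1i * m * theta)
}

#' Stored (n, m) index pairs up to order M
#'
#' All pairs with 0 <= n <= M, 0 <= m <= n and n - m even; negative-m
#' moments are conjugates and are not stored. For M = 10 there are 36 pairs.
#'
#' @param M maximum radial order.
#' @return data.frame with integer columns n, m.
#' @export
zernikeIndex <- function(M) {
  do.call(rbind, lapply(0:M, function(n)
    data.frame(n = n, m = seq(n %% 2, n, by = 2))))
}

#' Project an inscribed silhouette onto Zernike polynomials
#'
#' Computes a_mn = sum over foreground pixels of f(x, y) V*_mn(rho, theta),
#' with the pixel coordinates normalized by the inscribed unit disk. Under
#' the default \code{normalization = "standard"} the sum carries the
#' per-pixel area element and the (n+1)/pi factor, so a full unit disk gives
#' a_00 = 1; \code{"plain"} is the bare double sum.
#'
#' @param sil an inscribed \linkS4class{Silhouette} (see
#'   \code{\link{inscribeUnitDisk}}).
#' @param M maximum radial order (default 10).
#' @param normalization "standard" or "plain".
#' @return complex vector of moments, one per \code{\link{zernikeIndex}} row,
#'   with the index table in attribute \code{index}.
#' @export
encodeZernike <- function(sil, M = 10, normalization = c("standard", "plain")) {
  normalization <- match.arg(normalization)
  if (is.na(sil@diskRadius))
    stop("silhouette is not inscribed; call inscribeUnitDisk() first")
  fg <- which(sil@pixels == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty silhouette foreground")
  # pixel centers in image coordinates: x = column, y = row
  x <- (fg[, 2] - 0.5 - sil@diskCenter[1]) / sil@diskRadius
  y <- (fg[, 1] - 0.5 - sil@diskCenter[2]) / sil@diskRadius
  rho <- sqrt(x^2 + y^2)
  keep <- rho <= 1 + 0.5 / sil@diskRadius
  x <- x[keep]; y <- y[keep]
  rho <- pmin(rho[keep], 1)
  theta <- atan2(y, x)
  idx <- zernikeIndex(M)
  dA <- 1 / sil@diskRadius^2
  mom <- complex(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    n <- idx$n[i]; m <- idx$m[i]
    vals <- Conj(zernikeBasis(n, m, rho, theta))
    s <- sum(vals)
    mom[i] <- if (normalization == "standard")
      (n + 1) / pi * s * dA else s
  }
  attr(mom, "index") <- idx
  mom
}

#' Reconstruct a silhouette image from Zernike moments
#'
#' Evaluates the real part of the truncated Zernike expansion (conjugate
#' negative-m terms included implicitly) on a px-by-px unit-disk grid and
#' thresholds it into a binary image.
#'
#' @param moments complex moments as returned by \code{\link{encodeZernike}}
#'   (standard normalization).
#' @param M maximum radial order of the moments.
#' @param px output image side length.
#' @param threshold binarization level as a fraction of the maximum of the
#'   reconstructed function (default 0.5).
#' @return a \linkS4class{Silhouette} over the unit disk.
#' @export
reconstructSilhouette <- function(moments, M, px = 256, threshold = 0.5) {
  idx <- zernikeIndex(M)
  stopifnot(length(moments) == nrow(idx))
  cx <- (seq_len(px) - 0.5) / px * 2 - 1
  grid <- expand.grid(x = cx, y = cx)
  rho <- sqrt(grid$x^2 + grid$y^2)
  inside <- rho <= 1
  theta <- atan2(grid$y, grid$x)
  g <- numeric(nrow(grid))
  for (i in seq_len(nrow(idx))) {
    n <- idx$n[i]; m <- idx$m[i]
    term <- moments[i] * zernikeBasis(n, m, rho[inside], theta[inside])
    g[inside] <- g[inside] + if (m == 0) Re(term) else 2 * Re(term)
  }
  g[!inside] <- 0
  img <- matrix(0L, px, px)
  if (any(g > 0)) {
    lvl <- threshold * max(g)
    # grid row index = y, column = x
    img[cbind(match(grid$y, cx), match(grid$x, cx))] <-
      as.integer(g >= lvl & inside)
  }
  new("Silhouette", pixels = img, resolution = px / 2,
      diskCenter = c(px / 2, px / 2), diskRadius = px / 2)
}
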