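#' Agresti-Caffo two-proportion test
#'
#' Adjusted Wald comparison of two binomial proportions: one success and one
#' failure are added to each group, giving adjusted proportions
#' p~_i = (x_i + 1) / (n_i + 2); the z statistic uses the adjusted standard
#' error and the two-sided p-value comes from the normal distribution. The
#' 95\% CI is diff +- 1.96 * se.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with \code{diff} (p~1 - p~2), \code{ci95}, \code{z},
#'   \code{p}.
#' @export
agrestiCaffo <- function(x1, n1, x2, n2) {
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2 || n1 < 1 || n2 < 1)
    stop("need 0 <= x <= n and n >= 1 in both groups")
  p1 <- (x1 + 1) / (n1 + 2)
  p2 <- (x2 + 1) / (n2 + 2)
  se <- sqrt(p1 * (1 - p1) / (n1 + 2) + p2 * (1 - p2) / (n2 + 2))
  d <- p1 - p2
  z <- if (se == 0) 0 else d / se
  list(diff = d,
       ci95 = d + c(-1, 1) * qnorm(0.975) * se,
       z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Chi-squared test on a clusters-by-groups contingency table
#'
#' Pearson chi-squared (no continuity correction) with k - 1 degrees of
#' freedom testing whether the cluster distribution differs between the two
#' groups. Warns when any expected count falls below 5.
#'
#' @param counts k x 2 matrix of cluster-by-group counts.
#' @return two-sided p-value.
#' @export
chiSquareGroups <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("counts must have two group columns")
  if (any(colSums(counts) == 0)) stop("a group has zero total count")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("some expected counts are below 5; chi-squared approximation ",
            "may be poor")
  suppressWarnings(chisq.test(counts, correct = FALSE)$p.value)
}
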