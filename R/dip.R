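#' Hartigan's dip test for unimodality
#'
#' Computes the dip statistic (the smallest sup-norm distance between the
#' empirical cdf and any unimodal cdf) with a seeded Monte-Carlo p-value
#' from the uniform null, the calibration the test was defined against.
#' The statistic is computed in C via a greatest-convex-minorant /
#' least-concave-majorant band formulation with a binary search over the
#' modal interval.
#'
#' @param x numeric sample (n >= 4).
#' @param B Monte-Carlo draws for the null (default 10000).
#' @param seed RNG seed for the null draws.
#' @return list (class `dip_test`) with `statistic`, `p.value`, `n`, `B`.
#' @examples
#' d <- dip_unimodality(stats::runif(200), B = 500, seed = 1)
#' d$p.value > 0.05   # uniform data: no evidence against unimodality
#' @export
dip_unimodality <- function(x, B = 10000L, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("dip test needs at least 4 finite values")
  n <- length(x)
  set.seed(seed)
  res <- .Call(c_dip_pvalue, sort(as.numeric(x)), as.integer(B))
  structure(list(statistic = res[1],
                 p.value = (1 + res[2]) / (B + 1),
                 n = n, B = B),
            class = "dip_test")
}

#' Dip statistic of a sample
#' @param x numeric vector.
#' @return The dip statistic (scalar).
#' @export
dip_stat <- function(x) {
  .Call(c_dip, sort(as.numeric(x)))
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.5f, p = %.4g (n = %d, %d MC draws)\n",
              x$statistic, x$p.value, x$n, x$B))
  invisible(x)
}
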