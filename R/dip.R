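# Hartigan's dip test of unimodality.
#
# The statistic is computed in C++ (src/dip.cpp).  P-values come from the
# uniform null: either fresh Monte-Carlo draws, or (default) interpolation in
# a pre-computed quantile table shipped with the package
# (inst/extdata/dip_null_quantiles.csv, 50,000 replicates per tabulated
# sample size; see tools/make_dip_table.R).  sqrt(n) * dip is asymptotically
# pivotal, so interpolation across sample sizes is done on that scale.

#' Dip statistic of unimodality
#'
#' Maximum distance between the empirical cdf of `x` and the closest unimodal
#' cdf. Larger values indicate stronger bimodality.
#'
#' @param x numeric vector (n >= 2 for a non-trivial value).
#' @return the dip statistic (a value in `[0, 0.25]`).
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_oro("dip_stat: non-finite values in input")
  dip_stat_cpp(x)
}

dip_table <- function() {
  if (is.null(.oro_env$dip_table)) {
    path <- system.file("extdata", "dip_null_quantiles.csv",
                        package = "oroinvade")
    if (path == "") stop_oro("dip null quantile table not installed")
    tab <- read.csv(path, check.names = FALSE)
    .oro_env$dip_table <- tab
  }
  .oro_env$dip_table
}

#' P-value of the dip test against the uniform (unimodal) null
#'
#' @param stat observed dip statistic.
#' @param n sample size the statistic was computed from.
#' @param n_mc if not `NULL`, draw this many fresh Monte-Carlo null samples
#'   instead of using the shipped quantile table (slower, but exact-n).
#' @param seed RNG seed for the Monte-Carlo route.
#' @return a p-value in `(0, 1]`.
#' @export
dip_pvalue <- function(stat, n, n_mc = NULL, seed = NULL) {
  stopifnot(length(stat) == 1, n >= 2)
  if (!is.null(n_mc)) {
    if (!is.null(seed)) set.seed(seed)
    null <- dip_null_cpp(as.integer(n), as.integer(n_mc))
    return((1 + sum(null >= stat)) / (n_mc + 1))
  }
  tab <- dip_table()
  ns <- tab$n
  probs <- as.numeric(colnames(tab)[-1])
  z <- stat * sqrt(n)
  # upper-tail probability at one tabulated n, interpolating the quantile grid
  tail_p <- function(i) {
    qz <- as.numeric(tab[i, -1]) * sqrt(ns[i])
    if (z <= qz[1]) return(1)
    if (z >= qz[length(qz)]) return(1 - probs[length(probs)])
    1 - stats::approx(qz, probs, xout = z, ties = "ordered")$y
  }
  if (n <= min(ns)) return(tail_p(which.min(ns)))
  if (n >= max(ns)) return(tail_p(which.max(ns)))
  i_lo <- max(which(ns <= n)); i_hi <- min(which(ns >= n))
  if (i_lo == i_hi) return(tail_p(i_lo))
  w <- (log(n) - log(ns[i_lo])) / (log(ns[i_hi]) - log(ns[i_lo]))
  (1 - w) * tail_p(i_lo) + w * tail_p(i_hi)
}
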