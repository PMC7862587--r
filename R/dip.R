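# Hartigan-type dip test for unimodality.  The statistic is computed in
# C++ (src/dip.cpp) as the minimal sup-norm distance between the ECDF
# and the closest unimodal distribution function; the p value comes from
# a seeded uniform(0,1) bootstrap of the same sample size.

#' Dip statistic for unimodality
#'
#' Minimal sup-norm distance between the sample's empirical CDF and any
#' unimodal distribution function (convex left of the mode, concave
#' right of it; an atom is allowed at the mode).  Larger values mean the
#' sample is harder to reconcile with a single mode.  For an untied
#' sample the statistic is at least `1/(2n)`.
#'
#' @param x numeric sample.
#' @return The dip statistic (non-negative scalar).
#' @examples
#' dip_statistic(c(1, 2, 3, 4))         # equally spaced: 1/(2n) = 0.125
#' dip_statistic(c(rnorm(50), rnorm(50, 8)))  # bimodal: much larger
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 2) return(0)
  .dip_stat_cpp(x)
}

#' Dip test of unimodality with bootstrap p value
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution.  The null reference is the uniform(0,1) distribution --
#' the asymptotically least-favourable unimodal case -- from which
#' `n_boot` samples of the same size are drawn to form the null dip
#' distribution; the p value is the add-one bootstrap proportion of null
#' dips at least as large as the observed one.
#'
#' @param x numeric sample, `n >= 4`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer seed applied before the bootstrap draws.
#' @param null_dips optional pre-computed vector of null dip values for
#'   the same `n` (e.g. from [dip_null_distribution()]); overrides the
#'   bootstrap and makes repeated tests at one sample size cheap.
#' @return A [stat_result()] with statistic `dip`.
#' @export
hartigan_dip <- function(x, n_boot = 1000, seed = NULL,
                         null_dips = NULL) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 4) stop("dip test needs n >= 4")
  d <- dip_statistic(x)
  if (is.null(null_dips)) {
    if (!is.null(seed)) set.seed(seed)
    null_dips <- .dip_boot_cpp(n, as.integer(n_boot))
  }
  p <- (1 + sum(null_dips >= d)) / (length(null_dips) + 1)
  stat_result("hartigan_dip", c(dip = d), p_value = p, n = n,
              note = sprintf("uniform bootstrap, %d replicates",
                             length(null_dips)),
              seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Null dip distribution at a given sample size
#'
#' Draws `n_boot` uniform(0,1) samples of size `n` and returns their dip
#' statistics, for reuse across many [hartigan_dip()] calls at the same
#' sample size.
#'
#' @param n sample size.
#' @param n_boot replicates.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_boot`.
#' @export
dip_null_distribution <- function(n, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .dip_boot_cpp(as.integer(n), as.integer(n_boot))
}
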