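#' Beta-binomial log probability mass function
#'
#' Density of the beta-binomial distribution parameterized by a mean
#' proportion \code{p} and a concentration (dispersion) parameter \code{d},
#' so that the underlying beta has shape parameters \code{d*p} and
#' \code{d*(1-p)}.  Larger \code{d} means less overdispersion; as
#' \code{d} grows the distribution converges to binomial(\code{n},
#' \code{p}).  All arithmetic is carried out with log-gamma functions so
#' large counts do not overflow the beta function.
#'
#' @param x integer vector of successes, \code{0 <= x <= n}.
#' @param n integer vector of trials.
#' @param p mean proportion, strictly inside (0, 1).
#' @param d concentration parameter, \code{d > 0}.
#' @param log if \code{TRUE} (default) return log density.
#' @return numeric vector of (log) densities, recycled to the common
#'   length of the arguments.
#' @examples
#' dbetabin(3, 10, 0.6, 20)
#' sum(dbetabin(0:12, 12, 0.3, 15, log = FALSE))  # sums to 1
#' @export
dbetabin <- function(x, n, p, d, log = TRUE) {
  if (any(p <= 0 | p >= 1)) stop("'p' must be strictly inside (0, 1)")
  if (any(d <= 0)) stop("'d' must be positive")
  if (any(x < 0 | x > n)) stop("'x' must satisfy 0 <= x <= n")
  a <- d * p
  b <- d * (1 - p)
  ll <- lchoose(n, x) + lgamma(x + a) + lgamma(n - x + b) - lgamma(n + a + b) -
    (lgamma(a) + lgamma(b) - lgamma(a + b))
  if (log) ll else exp(ll)
}

#' Genotyping error rate from a Phred-scaled genotype quality
#'
#' Converts a GQ value (as emitted by standard genotype callers) to the
#' probability that the heterozygous genotype call is wrong:
#' \eqn{\epsilon_G = 10^{-GQ/10}}.
#'
#' @param gq non-negative numeric vector of Phred-scaled genotype
#'   qualities.
#' @return numeric vector of error probabilities in (0, 1].
#' @examples
#' genotyping_error_rate(20)  # 0.01
#' @export
genotyping_error_rate <- function(gq) {
  if (any(is.na(gq)) || any(gq < 0)) {
    stop("genotype quality must be non-negative and non-missing")
  }
  10^(-gq / 10)
}

## numerically stable log(sum(exp(x))) along rows of a matrix, or of a vector
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rowlogsumexp <- function(x) {
  m <- apply(x, 1L, max)
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}
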