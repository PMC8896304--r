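## Beta-binomial allelic-imbalance likelihoods.
##
## The reference allele count x at a heterozygous site with n overlapping
## reads is modelled as beta-binomial with mean proportion 0.5 + a and
## concentration d, where a in [-0.5, 0.5] is the allelic imbalance.  In
## the RNA context a three-component mixture guards against genotyping
## errors: with probability 1 - eps_G the site is truly heterozygous;
## with probability eps_G it is homozygous (ref or alt, equally likely)
## and reads from the absent allele arise from sequencing error at rate
## eps_S.

A_BOUND <- 0.5 - 1e-4    # keeps both beta shape parameters positive
D_RANGE <- c(1e-2, 1e8)  # dispersion optimized on log scale in this range
EPS_RANGE <- c(1e-6, 0.1)

#' Per-site log-likelihood of the allelic imbalance parameter
#'
#' Computes, for each site, the log-likelihood of imbalance \code{a}
#' under the beta-binomial model.  With \code{error_mixture = TRUE} the
#' genotyping-error mixture is used: the heterozygous component with mean
#' \code{0.5 + a} is weighted by \code{1 - eps_G}, and two homozygous
#' components with means \code{eps_S} and \code{1 - eps_S} each carry
#' weight \code{eps_G / 2}, where \code{eps_G} is derived from each
#' site's GQ.  The mixture is combined with log-sum-exp.
#'
#' @param sites het-site table (see [het_sites()]).
#' @param a allelic imbalance, strictly inside (-0.5, 0.5).
#' @param params a [model_params()] object.
#' @param error_mixture logical; defaults to \code{TRUE} for RNA-context
#'   parameters and \code{FALSE} for DNA.
#' @param flip if \code{TRUE}, evaluate at the flipped counts
#'   \code{n - ref_count} (the other phase of each site).
#' @return numeric vector of per-site log-likelihoods.
#' @export
site_loglik <- function(sites, a, params,
                        error_mixture = params$context == "RNA",
                        flip = FALSE) {
  if (a <= -0.5 || a >= 0.5) stop("'a' must be strictly inside (-0.5, 0.5)")
  sites <- with_n(sites)
  x <- if (flip) sites$n - sites$ref_count else sites$ref_count
  n <- sites$n
  d <- params$dispersion
  het <- dbetabin(x, n, 0.5 + a, d)
  if (!error_mixture) return(het)
  eps_s <- params$seq_error
  if (is.null(eps_s)) stop("error mixture requires 'seq_error' in params")
  eg <- genotyping_error_rate(sites$gq)
  comp <- cbind(log1p(-eg) + het,
                log(eg / 2) + dbetabin(x, n, eps_s, d),
                log(eg / 2) + dbetabin(x, n, 1 - eps_s, d))
  rowlogsumexp(comp)
}

#' Phase-marginalized log-likelihood of a bin of heterozygous sites
#'
#' All heterozygous sites in a bin (20-exon genomic bin for DNA, the
#' exons of one gene for RNA) share a single imbalance \code{a}, but the
#' phase of each site relative to the others is unknown.  The likelihood
#' averages over all \code{2^(m-1)} haplotype configurations, anchored so
#' that the reference allele of the first site defines "chromosome A".
#' A linear-time dynamic program computes the sum: the first site enters
#' unflipped and every later site contributes the sum of its likelihood
#' at the observed and at the flipped count.  All arithmetic is in log
#' space with log-sum-exp for the per-site flip sums.
#'
#' @inheritParams site_loglik
#' @return a single log-likelihood value.
#' @export
bin_loglik <- function(sites, a, params,
                       error_mixture = params$context == "RNA") {
  sites <- with_n(sites)
  m <- nrow(sites)
  if (m < 1L) stop("bin must contain at least one site")
  ll_obs <- site_loglik(sites, a, params, error_mixture)
  if (m == 1L) return(ll_obs)
  ll_flip <- site_loglik(sites, a, params, error_mixture, flip = TRUE)
  pair <- cbind(ll_obs[-1L], ll_flip[-1L])
  ll_obs[1L] + sum(rowlogsumexp(pair)) - (m - 1) * log(2)
}

#' Estimate the genome-wide dispersion from DNA allele counts
#'
#' Fixes \code{a = 0} and maximizes the total pure beta-binomial
#' likelihood across all heterozygous sites of one sample, optimizing the
#' concentration on the log scale.  One dispersion is shared genome-wide.
#'
#' @param sites het-site table for one sample.
#' @param min_sites minimum number of sites required (default 100).
#' @return a DNA-context [model_params()] with the fitted dispersion and
#'   an \code{n_sites} element.
#' @export
estimate_dispersion_dna <- function(sites, min_sites = 100L) {
  sites <- with_n(sites)
  sites <- sites[sites$n > 0L, , drop = FALSE]
  if (nrow(sites) < min_sites) {
    stop(sprintf("dispersion estimation needs >= %d usable sites, got %d",
                 min_sites, nrow(sites)))
  }
  x <- sites$ref_count
  n <- sites$n
  obj <- function(logd) -sum(dbetabin(x, n, 0.5, exp(logd)))
  opt <- stats::optimize(obj, log(D_RANGE), tol = 1e-6)
  d_hat <- exp(opt$minimum)
  ll <- -opt$objective
  ## binomial data leave the likelihood flat in d: report the bound
  if (obj(log(D_RANGE[2L])) <= opt$objective + 1e-4) {
    d_hat <- D_RANGE[2L]
    ll <- -obj(log(D_RANGE[2L]))
  }
  p <- model_params(d_hat, context = "DNA")
  p$n_sites <- nrow(sites)
  p$loglik <- ll
  p
}

#' Jointly estimate dispersion and sequencing error from RNA allele counts
#'
#' Fixes \code{a = 0} and maximizes the genotyping-error mixture
#' likelihood over all exonic heterozygous sites of one sample, jointly
#' in \code{(log d, eps_S)} with L-BFGS-B.
#'
#' @inheritParams estimate_dispersion_dna
#' @return an RNA-context [model_params()] with fitted \code{dispersion}
#'   and \code{seq_error}.
#' @export
estimate_dispersion_rna <- function(sites, min_sites = 100L) {
  sites <- with_n(sites)
  sites <- sites[sites$n > 0L, , drop = FALSE]
  if (nrow(sites) < min_sites) {
    stop(sprintf("dispersion estimation needs >= %d usable sites, got %d",
                 min_sites, nrow(sites)))
  }
  x <- sites$ref_count
  n <- sites$n
  leg <- log(genotyping_error_rate(sites$gq) / 2)
  l1meg <- log1p(-genotyping_error_rate(sites$gq))
  ## both parameters on log scale so finite-difference gradient steps
  ## stay proportionate near small eps_S
  obj <- function(par) {
    d <- exp(par[1L]); eps <- exp(par[2L])
    comp <- cbind(l1meg + dbetabin(x, n, 0.5, d),
                  leg + dbetabin(x, n, eps, d),
                  leg + dbetabin(x, n, 1 - eps, d))
    -sum(rowlogsumexp(comp))
  }
  opt <- stats::optim(c(log(50), log(0.01)), obj, method = "L-BFGS-B",
                      lower = log(c(D_RANGE[1L], EPS_RANGE[1L])),
                      upper = log(c(D_RANGE[2L], EPS_RANGE[2L])))
  if (opt$convergence != 0L) {
    stop("joint (d, eps_S) optimization failed to converge: ", opt$message)
  }
  p <- model_params(exp(opt$par[1L]), seq_error = exp(opt$par[2L]),
                    context = "RNA")
  p$n_sites <- nrow(sites)
  p$loglik <- -opt$value
  p
}

#' Maximum-likelihood allelic imbalance for a bin or gene
#'
#' One-dimensional bounded maximization of the phase-marginalized bin
#' likelihood over \code{a}.  A coarse grid locates the basin (guarding
#' against flat or multimodal likelihoods) and golden-section refinement
#' polishes the optimum to tolerance 1e-8.  The fitted \code{a} is
#' signed; its sign is anchored to the arbitrary choice of which
#' chromosome carries the first site's reference allele, so downstream
#' analyses use \code{abs(a)}.
#'
#' @inheritParams bin_loglik
#' @return an object of class \code{"imbalance_fit"} with elements
#'   \code{a}, \code{loglik_alt}, \code{loglik_null}, \code{lrt_stat},
#'   \code{p_value} and \code{n_sites}.
#' @export
fit_imbalance <- function(sites, params,
                          error_mixture = params$context == "RNA") {
  sites <- with_n(sites)
  dropped <- sum(sites$n == 0L)
  sites <- sites[sites$n > 0L, , drop = FALSE]
  if (nrow(sites) == 0L) stop("no sites with reads to fit")
  f <- function(a) bin_loglik(sites, a, params, error_mixture)
  grid <- seq(-A_BOUND, A_BOUND, length.out = 21L)
  vals <- vapply(grid, f, numeric(1L))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(a) -f(a), c(lo, hi), tol = 1e-8)
  a_hat <- opt$minimum
  ll_alt <- -opt$objective
  ll_null <- f(0)
  if (ll_null > ll_alt) {  # numerical guard: null is in the parameter space
    a_hat <- 0
    ll_alt <- ll_null
  }
  fit <- structure(list(a = a_hat, loglik_alt = ll_alt, loglik_null = ll_null,
                        lrt_stat = max(0, 2 * (ll_alt - ll_null)),
                        p_value = NA_real_, n_sites = nrow(sites),
                        n_dropped = dropped, context = params$context),
                   class = "imbalance_fit")
  fit$p_value <- ase_lrt(fit)
  fit
}

#' Likelihood-ratio test for allelic imbalance
#'
#' Compares the alternative model (free \code{a}) to the null of no
#' imbalance (\code{a = 0}).  The statistic \code{2 * (l_alt - l_null)}
#' is referred to a chi-squared distribution with one degree of freedom
#' (the null value is interior to the parameter space).
#'
#' @param fit an \code{"imbalance_fit"} object.
#' @return two-sided p-value.
#' @export
ase_lrt <- function(fit) {
  stat <- max(0, 2 * (fit$loglik_alt - fit$loglik_null))
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' @export
print.imbalance_fit <- function(x, ...) {
  cat("Allelic-imbalance fit (", x$context, " context)\n", sep = "")
  cat(sprintf("  a = %.4f  (|a| = %.4f, sign is phase-anchored)\n",
              x$a, abs(x$a)))
  cat(sprintf("  sites: %d   logLik(a-hat) = %.3f   logLik(0) = %.3f\n",
              x$n_sites, x$loglik_alt, x$loglik_null))
  cat(sprintf("  LRT = %.3f   p = %.3g\n", x$lrt_stat, x$p_value))
  invisible(x)
}

#' @export
coef.imbalance_fit <- function(object, ...) c(a = object$a)

#' @export
logLik.imbalance_fit <- function(object, ...) {
  structure(object$loglik_alt, df = 1L, nobs = object$n_sites,
            class = "logLik")
}

#' @export
summary.imbalance_fit <- function(object, ...) {
  out <- data.frame(a = object$a, abs_a = abs(object$a),
                    n_sites = object$n_sites, lrt = object$lrt_stat,
                    p_value = object$p_value)
  class(out) <- c("summary.imbalance_fit", "data.frame")
  out
}
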