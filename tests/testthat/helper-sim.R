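## Shared simulation helpers and independent oracles for the test suite.

## beta-binomial deviates around proportion p with concentration d
rbb <- function(n, p, d) {
  rbinom(length(n), n, rbeta(length(n), d * p, d * (1 - p)))
}

## random het-site table: m sites, per-haplotype proportion p (scalar or
## per-site), depths drawn around `depth`
sim_sites <- function(m, depth, p, d, gq = 99) {
  n <- rnbinom(m, mu = depth, size = 10) + 5L
  x <- rbb(n, rep_len(p, m), d)
  het_sites("chr1", seq_len(m) * 100L, x, n - x, gq = gq)
}

## sites drawn under unknown phase: each site's reference allele sits on
## haplotype A (proportion 0.5 + a) or B (0.5 - a) with equal chance
sim_phased_sites <- function(m, depth, a, d, gq = 99) {
  p <- ifelse(runif(m) < 0.5, 0.5 + a, 0.5 - a)
  sim_sites(m, depth, p, d, gq)
}

## independent oracle: bin likelihood by explicit enumeration of the
## 2^(m-1) haplotype configurations (first site anchored unflipped),
## averaged in linear space via log-sum-exp
brute_bin_loglik <- function(sites, a, params,
                             error_mixture = params$context == "RNA") {
  m <- nrow(sites)
  ll_obs <- site_loglik(sites, a, params, error_mixture)
  ll_flip <- site_loglik(sites, a, params, error_mixture, flip = TRUE)
  n_cfg <- 2^(m - 1)
  if (m == 1L) return(ll_obs)
  ## rows: configurations; columns: flip indicator for sites 2..m
  flips <- outer(0:(n_cfg - 1L), 2^(0:(m - 2L)),
                 function(mask, bit) bitwAnd(mask, bit) > 0)
  tot <- ll_obs[1L] + flips %*% ll_flip[-1L] + (!flips) %*% ll_obs[-1L]
  mx <- max(tot)
  mx + log(sum(exp(tot - mx))) - log(n_cfg)
}

## reference Benjamini-Hochberg step-up, written independently of
## p.adjust: q_(i) = min_{j >= i} p_(j) * m / j
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

## reference two-sided Fisher exact p by full hypergeometric enumeration
fisher_enum <- function(k1, n1, k2, n2) {
  tot_k <- k1 + k2
  lo <- max(0, tot_k - n2)
  hi <- min(n1, tot_k)
  probs <- dhyper(lo:hi, n1, n2, tot_k)
  obs <- dhyper(k1, n1, n2, tot_k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
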