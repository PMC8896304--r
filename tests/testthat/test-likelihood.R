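rna_params <- function(d = 40, eps = 0.01) {
  model_params(d, seq_error = eps, context = "RNA")
}

test_that("error mixture collapses to the pure beta-binomial at high GQ", {
  s <- het_sites("chr1", 100, 18, 22, gq = 200)
  p <- rna_params()
  expect_lt(abs(site_loglik(s, 0.1, p) -
                  site_loglik(s, 0.1, p, error_mixture = FALSE)), 1e-9)
})

test_that("mixture likelihood matches a linear-space three-component oracle", {
  ## frozen from summing the three weighted beta-binomial components in
  ## linear space at x=25, n=50, gq=50, a=0, d=40, eps_S=0.01
  s <- het_sites("chr1", 100, 25, 25, gq = 50)
  expect_equal(site_loglik(s, 0, rna_params()), -2.595749259158703,
               tolerance = 1e-9)
})

test_that("monoallelic counts at low GQ are explained by the homozygous component", {
  s <- het_sites("chr1", 100, 50, 0, gq = 3)
  p <- rna_params()
  expect_gt(site_loglik(s, 0, p),
            site_loglik(s, 0, p, error_mixture = FALSE))
})

test_that("bin likelihood base cases: single site and null imbalance", {
  p <- model_params(30, context = "DNA")
  s1 <- het_sites("chr1", 100, 12, 20)
  expect_equal(bin_loglik(s1, 0.15, p), site_loglik(s1, 0.15, p))
  set.seed(21)
  s <- sim_sites(6, 40, 0.5, 30)
  expect_equal(bin_loglik(s, 0, p), sum(site_loglik(s, 0, p)))
})

test_that("dynamic program equals exhaustive phasing enumeration", {
  p <- model_params(25, context = "DNA")
  pr <- rna_params(25)
  set.seed(31)
  for (m in c(1, 2, 3, 5, 8, 10)) {
    for (rep in 1:5) {
      s <- sim_phased_sites(m, 40, 0.2, 25, gq = sample(20:99, m, TRUE))
      a <- runif(1, -0.45, 0.45)
      expect_equal(bin_loglik(s, a, p), brute_bin_loglik(s, a, p),
                   tolerance = 1e-9)
      expect_equal(bin_loglik(s, a, pr), brute_bin_loglik(s, a, pr),
                   tolerance = 1e-9)
    }
  }
})

test_that("bin likelihood is symmetric under a global ref/alt swap with negated a", {
  ## the phase anchor on the first site means L(a; x) = L(-a; n - x):
  ## relabelling which allele is "reference" flips the sign of a
  p <- model_params(30, context = "DNA")
  set.seed(32)
  for (rep in 1:10) {
    s <- sim_phased_sites(sample(1:8, 1), 50, 0.25, 30)
    sw <- s
    sw$ref_count <- s$alt_count
    sw$alt_count <- s$ref_count
    a <- runif(1, -0.4, 0.4)
    expect_equal(bin_loglik(s, a, p), bin_loglik(sw, -a, p),
                 tolerance = 1e-10)
  }
})

test_that("bin likelihood normalizes over all joint outcomes of a tiny bin", {
  p <- model_params(12, context = "DNA")
  for (a in c(0, 0.2)) {
    tot <- 0
    for (x1 in 0:3) for (x2 in 0:3) {
      s <- het_sites("chr1", c(100, 200), c(x1, x2), c(3 - x1, 3 - x2))
      tot <- tot + exp(bin_loglik(s, a, p))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("DNA dispersion is recovered from overdispersed counts", {
  set.seed(41)
  s <- sim_sites(10000, 50, 0.5, 30)
  fit <- estimate_dispersion_dna(s)
  expect_lt(abs(fit$dispersion - 30) / 30, 0.10)
})

test_that("counts without overdispersion push the dispersion estimate to its upper bound", {
  ## perfectly balanced counts have zero extra-binomial variance, so the
  ## likelihood increases monotonically in d
  s <- het_sites("chr1", seq_len(500) * 10L, rep(25L, 500), rep(25L, 500))
  fit <- estimate_dispersion_dna(s)
  expect_gte(fit$dispersion, 1e8)
  ## binomial draws give a large (if not boundary) estimate
  set.seed(42)
  x <- rbinom(2000, 50, 0.5)
  s2 <- het_sites("chr1", seq_len(2000) * 10L, x, 50L - x)
  expect_gt(estimate_dispersion_dna(s2)$dispersion, 500)
})

test_that("dispersion estimates are invariant to site order and need enough sites", {
  set.seed(43)
  s <- sim_sites(500, 40, 0.5, 25)
  f1 <- estimate_dispersion_dna(s)
  f2 <- estimate_dispersion_dna(s[sample(nrow(s)), ])
  expect_equal(f1$dispersion, f2$dispersion)
  sg <- s
  sg$gq <- sample(30:99, nrow(s), TRUE)
  r1 <- estimate_dispersion_rna(sg)
  r2 <- estimate_dispersion_rna(sg[sample(nrow(sg)), ])
  expect_equal(r1$dispersion, r2$dispersion)
  expect_equal(r1$seq_error, r2$seq_error)
  expect_error(estimate_dispersion_dna(s[1:50, ]), ">= 100")
})

test_that("with no genotyping errors the RNA and DNA dispersion estimates agree", {
  set.seed(44)
  s <- sim_sites(4000, 50, 0.5, 25, gq = 99)
  d_rna <- estimate_dispersion_rna(s)$dispersion
  d_dna <- estimate_dispersion_dna(s)$dispersion
  expect_lt(abs(d_rna - d_dna) / d_dna, 0.02)
})

test_that("imbalance fits hit the boundary for monoallelic data and zero for balanced data", {
  p <- model_params(30, context = "DNA")
  mono <- het_sites("chr1", 1:10 * 100L, rep(100L, 10), rep(0L, 10))
  expect_gte(fit_imbalance(mono, p, error_mixture = FALSE)$a, 0.49)
  bal <- het_sites("chr1", 1:10 * 100L, rep(50L, 10), rep(50L, 10))
  expect_lt(abs(fit_imbalance(bal, p, error_mixture = FALSE)$a), 0.01)
})

test_that("imbalance magnitude is recovered across effect sizes", {
  p <- model_params(30, context = "DNA")
  set.seed(45)
  for (a_true in c(0.1, 0.4)) {
    ah <- replicate(60, {
      s <- sim_phased_sites(20, 60, a_true, 30)
      abs(fit_imbalance(s, p, error_mixture = FALSE)$a)
    })
    expect_lt(abs(mean(ah) - a_true), 0.05)
  }
})

test_that("zero-read sites are dropped with a recorded count", {
  p <- model_params(30, context = "DNA")
  s <- het_sites("chr1", c(100, 200, 300), c(20, 0, 25), c(20, 0, 30))
  fit <- fit_imbalance(s, p, error_mixture = FALSE)
  expect_equal(fit$n_sites, 2L)
  expect_equal(fit$n_dropped, 1L)
})

test_that("the LRT is non-negative, p = 1 at equal likelihoods, and invariant under a global allele swap", {
  fit <- structure(list(loglik_alt = -10, loglik_null = -10),
                   class = "imbalance_fit")
  expect_equal(ase_lrt(fit), 1)
  p <- model_params(30, context = "DNA")
  set.seed(46)
  s <- sim_phased_sites(8, 60, 0.3, 30)
  sw <- s
  sw$ref_count <- s$alt_count
  sw$alt_count <- s$ref_count
  f1 <- fit_imbalance(s, p, error_mixture = FALSE)
  f2 <- fit_imbalance(sw, p, error_mixture = FALSE)
  expect_gte(f1$lrt_stat, 0)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-6)
})

test_that("fit objects support the standard modelling accessors", {
  p <- model_params(30, context = "DNA")
  set.seed(47)
  fit <- fit_imbalance(sim_phased_sites(5, 50, 0.2, 30), p,
                       error_mixture = FALSE)
  expect_named(coef(fit), "a")
  expect_s3_class(summary(fit), "summary.imbalance_fit")
  expect_equal(as.numeric(logLik(fit)), fit$loglik_alt)
  expect_output(print(fit), "Allelic-imbalance fit")
})
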