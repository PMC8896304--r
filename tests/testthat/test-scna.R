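## small helper: gene models with a run of consecutive exons
toy_models <- function(n_exons, chrom = "chr1", gene_id = "g1",
                       start = 1000L, width = 100L, gap = 400L) {
  st <- start + (seq_len(n_exons) - 1L) * (width + gap)
  gene_models(data.frame(gene_id = gene_id, chrom = chrom, strand = "+",
                         start0 = st, end0 = st + width))
}

test_that("exons are grouped into bins of 20 with a trailing remainder", {
  bins <- make_exon_bins(toy_models(45))
  expect_equal(bins$n_exons, c(20L, 20L, 5L))
  expect_true(all(diff(bins$start0) > 0))
})

test_that("bins never mix chromosomes and duplicated exons collapse", {
  m1 <- toy_models(15, "chr1", "g1")
  m2 <- toy_models(15, "chr2", "g2")
  both <- gene_models(rbind(m1$exons, m2$exons))
  bins <- make_exon_bins(both)
  expect_equal(nrow(bins), 2L)
  expect_setequal(bins$chrom, c("chr1", "chr2"))
  ## same intervals under a second gene id: deduplicated before binning
  dup <- m1$exons
  dup$gene_id <- "g1b"
  with_dup <- gene_models(rbind(m1$exons, dup))
  expect_equal(make_exon_bins(with_dup)$n_exons, 15L)
  expect_error(make_exon_bins(gene_models(m1$exons[0, ])), "positive width|no exons")
})

test_that("site pairing honors the read and site-count thresholds", {
  models <- toy_models(20)
  bins <- make_exon_bins(models)
  ex <- models$exons
  pos <- ex$start0[1:10] + 50L  # one site in each of 10 exons
  mk <- function(n) het_sites("chr1", pos, rep(n %/% 2, 10), rep(n - n %/% 2, 10))
  ## exactly 10 reads in both samples at 10 sites: bin retained
  out <- assign_and_filter_sites(bins, mk(10L), mk(10L))
  expect_equal(nrow(out$sites), 10L)
  ## 9 reads: all sites fail the depth filter
  out9 <- assign_and_filter_sites(bins, mk(9L), mk(9L))
  expect_equal(nrow(out9$sites), 0L)
  ## only 9 qualifying sites: bin dropped
  nn <- mk(40L)[1:9, ]
  out_few <- assign_and_filter_sites(bins, nn, nn)
  expect_equal(nrow(out_few$bins), 0L)
  ## site present only in the tumor is never used
  tum <- mk(40L)
  extra <- het_sites("chr1", ex$start0[11] + 50L, 20L, 20L)
  out_t <- assign_and_filter_sites(bins, mk(40L), rbind(tum, extra))
  expect_false(any(out_t$sites$pos == extra$pos))
})

test_that("delta_a is zero for identical samples and approaches 0.5 for monoallelic tumors", {
  models <- toy_models(20)
  bins <- make_exon_bins(models)
  ex <- models$exons
  pos <- ex$start0[1:12] + 50L
  par_dna <- model_params(40, context = "DNA")
  bal <- het_sites("chr1", pos, rep(100L, 12), rep(100L, 12))
  same <- assign_and_filter_sites(bins, bal, bal)
  d0 <- compute_delta_a(same, par_dna, par_dna)
  expect_equal(d0$delta_a, 0, tolerance = 1e-6)
  mono <- het_sites("chr1", pos, rep(200L, 12), rep(0L, 12))
  pair <- assign_and_filter_sites(bins, bal, mono)
  d1 <- compute_delta_a(pair, par_dna, par_dna)
  expect_gt(d1$delta_a, 0.49)
})

test_that("hemizygous deletion at purity one-half gives delta_a near one-sixth", {
  ## retained-allele fraction (0.5*1 + 0.5*1) / (0.5*1 + 0.5*2) = 2/3
  set.seed(61)
  par_dna <- model_params(40, context = "DNA")
  deltas <- replicate(30, {
    m <- 20
    phase <- runif(m) < 0.5
    p_t <- ifelse(phase, 2 / 3, 1 / 3)
    nn <- rep(80L, m)
    xt <- rbb(nn, p_t, 40)
    xn <- rbb(nn, 0.5, 40)
    pos <- seq_len(m) * 50L
    ft <- fit_imbalance(het_sites("chr1", pos, xt, nn - xt), par_dna, FALSE)
    fn <- fit_imbalance(het_sites("chr1", pos, xn, nn - xn), par_dna, FALSE)
    abs(ft$a) - abs(fn$a)
  })
  expect_lt(abs(mean(deltas) - 1 / 6), 0.03)
})

test_that("segmentation returns one segment for constant input and finds a step change-point", {
  seg <- segment_cbs(rep(0.25, 50))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$score, 0.25)
  expect_equal(seg$n_bins, 50L)
  set.seed(62)
  x <- c(rnorm(50, 0, 0.05), rnorm(50, 0.4, 0.05))
  seg2 <- segment_cbs(x)
  expect_equal(nrow(seg2), 2L)
  expect_lte(abs(seg2$end_bin[1L] - 50L), 2L)
})

test_that("segment scores are exact bin means and segmentation is idempotent", {
  set.seed(63)
  x <- c(rnorm(40, 0.02, 0.05), rnorm(30, 0.35, 0.05))
  seg <- segment_cbs(x)
  for (k in seq_len(nrow(seg))) {
    expect_equal(seg$score[k], mean(x[seg$start_bin[k]:seg$end_bin[k]]))
  }
  flat <- rep(seg$score, seg$n_bins)
  expect_equal(nrow(segment_cbs(flat)), nrow(seg))
})

test_that("pure noise rarely splits", {
  set.seed(64)
  n_seg <- sapply(1:40, function(i) nrow(segment_cbs(rnorm(80, 0, 0.05))))
  expect_gte(mean(n_seg == 1L), 0.9)
})

test_that("genes take the score of the promoter-overlapping segment, TSS winning at breakpoints", {
  models <- gene_models(data.frame(
    gene_id = c("inside", "spanning", "orphan"),
    chrom = c("chr1", "chr1", "chr9"), strand = "+",
    start0 = c(20000L, 9500L, 100L), end0 = c(20400L, 9900L, 500L)))
  segments <- data.frame(chrom = "chr1", start0 = c(0L, 9000L),
                         end0 = c(9000L, 40000L), n_bins = c(5L, 12L),
                         score = c(0.30, 0.02))
  sc <- gene_scna_score(models, segments)
  expect_equal(unname(sc["inside"]), 0.02)
  ## promoter of "spanning" covers both segments; its TSS (9500) sits in
  ## the second
  expect_equal(unname(sc["spanning"]), 0.02)
  expect_true(is.na(sc["orphan"]))
})

test_that("the SCNA decision threshold is inclusive at 0.09 and keeps NA distinguishable", {
  expect_true(has_scna(0.09))
  expect_false(has_scna(0.0899))
  expect_true(is.na(has_scna(NA_real_)))
  expect_equal(has_scna(c(0.2, 0.05)), c(TRUE, FALSE))
})
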