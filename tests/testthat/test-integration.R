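test_that("Fisher frequency test reproduces known values and full enumeration", {
  expect_equal(round(fisher_ase_frequency(5, 68, 1, 139), 3), 0.015)
  expect_equal(fisher_ase_frequency(0, 50, 0, 100), 1.0)
  ## all-vs-none: only the two extreme tables are as or more extreme
  expect_equal(fisher_ase_frequency(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  set.seed(81)
  for (rep in 1:20) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_ase_frequency(k1, n1, k2, n2),
                 fisher_enum(k1, n1, k2, n2), tolerance = 1e-8)
  }
  expect_error(fisher_ase_frequency(5, 3, 0, 10), "0 <= k <= n")
})

test_that("ASE-SCNA correlation screen applies the variance and score filters", {
  a <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.05,
                0.1, 0.2, 0.3, 0.4, 0.05,
                0.1, 0.2, 0.3, 0.4, 0.05),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("mono", "flat_score", "low_score"),
                              paste0("s", 1:5)))
  sc <- rbind(mono = c(0.0, 0.1, 0.2, 0.3, 0.0),
              flat_score = rep(0.2, 5),
              low_score = c(0.0, 0.01, 0.03, 0.05, 0.0))
  colnames(sc) <- paste0("s", 1:5)
  out <- spearman_ase_scna(a, sc)
  ## only the gene with varying scores reaching 0.09 is tested
  expect_equal(out$gene_id, "mono")
  ## average-rank ties: correlation of the rank vectors computed directly
  rho_expect <- cor(rank(a["mono", ]), rank(sc["mono", ]))
  expect_equal(out$rho, rho_expect, tolerance = 1e-9)
})

test_that("perfectly monotone pairs give rho of one", {
  a <- matrix(seq(0.05, 0.45, length.out = 6), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  sc <- matrix(c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4), nrow = 1,
               dimnames = list("g", paste0("s", 1:6)))
  out <- spearman_ase_scna(a, sc)
  expect_equal(out$rho, 1)
})

test_that("promoter methylation correlation requires three probes and valid betas", {
  models <- gene_models(data.frame(
    gene_id = c("ok", "sparse"), chrom = "chr1", strand = "+",
    start0 = c(10000L, 50000L), end0 = c(10500L, 50500L)))
  probe_pos <- data.frame(chrom = "chr1",
                          pos = c(9000L, 9500L, 10200L, 49500L, 49800L))
  set.seed(82)
  beta <- matrix(runif(5 * 6), 5, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  ## monotone mean beta for "ok": overwrite with increasing columns
  beta[1:3, ] <- rep(seq(0.1, 0.6, by = 0.1), each = 3)
  a <- matrix(rep(seq(0.0, 0.5, by = 0.1), each = 2), nrow = 2,
              byrow = FALSE, dimnames = list(c("ok", "sparse"),
                                             paste0("s", 1:6)))
  a["ok", ] <- seq(0.0, 0.5, by = 0.1)
  out <- promoter_methylation_corr(beta, probe_pos, a, models)
  expect_equal(out$gene_id, "ok")   # "sparse" has only 2 promoter probes
  expect_equal(out$rho, 1)
  bad <- beta; bad[1, 1] <- 1.5
  expect_error(promoter_methylation_corr(bad, probe_pos, a, models),
               "\\[0, 1\\]")
})

test_that("gene-set sampling matches hypergeometric expectations and degenerate sets", {
  muts <- data.frame(gene = sprintf("g%03d", 1:40),
                     consequence = "stop_gained",
                     stringsAsFactors = FALSE)
  all_carry <- sprintf("g%03d", 1:40)
  none_carry <- sprintf("h%03d", 1:150)
  mixed <- sprintf("g%03d", 1:200)  # 40 of 200 carry
  set.seed(83)
  out <- stopgain_geneset_sampling(
    list(all = all_carry, none = none_carry, mixed = mixed),
    muts, n_iter = 500, k = 30)
  expect_true(all(out$all == 30))
  expect_true(all(out$none == 0))
  ## hypergeometric mean k * K/N = 30 * 40/200 = 6
  expect_lt(abs(mean(out$mixed) - 6), 0.5)
  expect_lt(abs(var(out$mixed) -
                  30 * (40 / 200) * (160 / 200) * (170 / 199)), 1)
  expect_error(stopgain_geneset_sampling(list(small = letters), muts,
                                         k = 100), "at least")
})

test_that("category permutation preserves per-gene structure and detects placed enrichment", {
  set.seed(84)
  genes <- sprintf("g%02d", 1:40)
  cells <- expand.grid(gene_id = genes, sample = sprintf("T%02d", 1:10),
                       stringsAsFactors = FALSE)
  cells$category <- factor(
    sample(c("non_ASE", "ASE_SCNA", "ASE_non_SCNA"), nrow(cells), TRUE,
           prob = c(0.7, 0.15, 0.15)),
    levels = c("non_ASE", "ASE_SCNA", "ASE_non_SCNA"))
  ## place every stop-gain in an ASE_non_SCNA cell
  hot <- cells[cells$category == "ASE_non_SCNA", ][1:25, ]
  muts <- data.frame(sample = hot$sample, gene = hot$gene_id,
                     consequence = "stop_gained", stringsAsFactors = FALSE)
  out <- stopgain_rate_permutation(cells, muts, n_perm = 300)
  expect_gt(out$log2_ratio[["ASE_non_SCNA"]], 0)
  expect_lt(out$p_value[["ASE_non_SCNA"]], 0.01)
  ## permutations redistribute but never lose mutations: recover each
  ## permutation's per-category counts from the reported ratios
  expect_equal(sum(out$observed$mutations), 25)
  obs <- out$observed$mutations
  perm_counts <- sweep(2^(-out$perm_log2_ratio), 2, obs + 0.5, "*") - 0.5
  expect_equal(unname(rowSums(perm_counts)), rep(25, 300), tolerance = 1e-8)
})

test_that("uniformly scattered mutations show no category enrichment on average", {
  set.seed(85)
  ratios <- replicate(10, {
    genes <- sprintf("g%02d", 1:50)
    cells <- expand.grid(gene_id = genes, sample = sprintf("T%02d", 1:12),
                         stringsAsFactors = FALSE)
    cells$category <- factor(
      sample(c("non_ASE", "ASE_SCNA", "ASE_non_SCNA"), nrow(cells), TRUE),
      levels = c("non_ASE", "ASE_SCNA", "ASE_non_SCNA"))
    pickd <- cells[sample(nrow(cells), 60), ]
    muts <- data.frame(sample = pickd$sample, gene = pickd$gene_id,
                       consequence = "stop_gained", stringsAsFactors = FALSE)
    stopgain_rate_permutation(cells, muts, n_perm = 100)$log2_ratio
  })
  expect_true(all(abs(rowMeans(ratios)) < 0.2))
})

test_that("quantile normalization matches the rank-mean worked example", {
  x <- cbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), cbind(c(4, 5, 6), c(4, 5, 6), c(4, 5, 6)))
  ## identical columns are unchanged
  y <- cbind(c(2, 9, 4), c(2, 9, 4))
  expect_equal(unname(quantile_normalize(y)), unname(y))
})

test_that("expression normalization yields z-scored rows and drops constant genes", {
  set.seed(86)
  x <- matrix(rexp(60, 0.1), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  z <- normalize_expression(x)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-8)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-8)
  expect_error(normalize_expression(-x), "non-negative")
})

test_that("stage-4 differential screen applies both thresholds", {
  set.seed(87)
  n4 <- 20L; nr <- 30L
  stage <- c(rep("4", n4), rep(c("1", "2", "3"), length.out = nr))
  base <- matrix(2^rnorm(50 * 5, 6, 0.3), 5, 50,
                 dimnames = list(c("down2x", "null", "small_fc",
                                   "big_fc_noisy", "flat"), NULL))
  x <- base
  x["down2x", stage == "4"] <- x["down2x", stage == "4"] / 2
  x["small_fc", stage == "4"] <- x["small_fc", stage == "4"] / 2^0.3
  out <- stage4_differential(x, stage)
  expect_true(out$hit[out$gene_id == "down2x"])
  expect_lt(out$log2fc[out$gene_id == "down2x"], 0)
  expect_false(out$hit[out$gene_id == "small_fc"])  # |lfc| below 0.5
  expect_false(out$hit[out$gene_id == "null"])
  expect_error(stage4_differential(x[, 1:3], stage[1:3]), "at least 2")
})
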