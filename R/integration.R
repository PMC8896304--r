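## Downstream integration statistics: correlations of ASE with SCNA
## score, promoter methylation and expression; stop-gain gene-set
## sampling; within-gene category-label permutation; Fisher frequency
## test; expression normalization; and the stage-4 differential filter.

## Spearman correlation with average-rank ties and BH correction over
## the tested genes.  x, y: matrices gene x sample.
spearman_by_gene <- function(x, y, min_samples = 3L, fdr = 0.10) {
  genes <- intersect(rownames(x), rownames(y))
  samples <- intersect(colnames(x), colnames(y))
  res <- lapply(genes, function(g) {
    xv <- x[g, samples]
    yv <- y[g, samples]
    ok <- !is.na(xv) & !is.na(yv)
    if (sum(ok) < min_samples) return(NULL)
    if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) return(NULL)
    ct <- suppressWarnings(stats::cor.test(xv[ok], yv[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(gene_id = g, n = sum(ok), rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n = integer(0),
                      rho = numeric(0), p_value = numeric(0))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr
  rownames(out) <- NULL
  out
}

#' Correlate per-gene ASE with SCNA score across tumor samples
#'
#' Spearman correlation between \code{a_rna} magnitudes and SCNA scores
#' per gene, restricted to genes with non-zero variance in both
#' quantities and an SCNA score of at least \code{scna_min} in at least
#' one sample.  BH correction across the tested genes; FDR 10% defines
#' "SCNA-associated".
#'
#' @param a_rna matrix gene x sample of fitted RNA imbalances (signed;
#'   absolute values are correlated).
#' @param scna_scores matrix gene x sample of SCNA scores.
#' @param min_samples minimum paired observations per gene (default 3).
#' @param scna_min required maximum SCNA score across samples (default
#'   0.09).
#' @param fdr FDR threshold (default 0.10).
#' @return data.frame per tested gene: \code{gene_id}, \code{n},
#'   \code{rho}, \code{p_value}, \code{q_value}, \code{significant}.
#' @export
spearman_ase_scna <- function(a_rna, scna_scores, min_samples = 3L,
                              scna_min = 0.09, fdr = 0.10) {
  keep <- apply(scna_scores, 1L, function(v) any(!is.na(v) & v >= scna_min))
  spearman_by_gene(abs(a_rna), scna_scores[keep, , drop = FALSE],
                   min_samples = min_samples, fdr = fdr)
}

#' Correlate per-gene ASE with mean promoter methylation
#'
#' Computes the mean beta of CpG probes within each gene's promoter
#' (TSS +/- 1500 bp) per sample; promoters with fewer than
#' \code{min_probes} probes are untestable.  Spearman + BH as in
#' [spearman_ase_scna()].
#'
#' @param beta matrix probe x sample of methylation beta values in
#'   [0, 1]; probe positions given by \code{probe_pos}.
#' @param probe_pos data.frame with \code{chrom} and 1-based \code{pos}
#'   per probe (rows aligned with \code{beta}).
#' @param a_rna matrix gene x sample of fitted RNA imbalances.
#' @param models a [gene_models()] object.
#' @param min_probes minimum probes per promoter (default 3).
#' @inheritParams spearman_ase_scna
#' @return data.frame per tested gene as in [spearman_ase_scna()].
#' @export
promoter_methylation_corr <- function(beta, probe_pos, a_rna, models,
                                      min_probes = 3L, min_samples = 3L,
                                      fdr = 0.10) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  pm <- promoter_mean_beta(beta, probe_pos, models, min_probes)
  spearman_by_gene(abs(a_rna), pm, min_samples = min_samples, fdr = fdr)
}

#' Mean promoter methylation per gene
#'
#' @inheritParams promoter_methylation_corr
#' @return matrix gene x sample of mean promoter beta values; genes with
#'   fewer than \code{min_probes} probes in the promoter are omitted.
#' @export
promoter_mean_beta <- function(beta, probe_pos, models, min_probes = 3L) {
  g <- models$genes
  rows <- lapply(seq_len(nrow(g)), function(k) {
    sel <- probe_pos$chrom == g$chrom[k] &
      probe_pos$pos - 1L >= g$promoter_start0[k] &
      probe_pos$pos - 1L < g$promoter_end0[k]
    if (sum(sel) < min_probes) return(NULL)
    colMeans(beta[sel, , drop = FALSE])
  })
  names(rows) <- g$gene_id
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(matrix(numeric(0), 0L, ncol(beta),
                  dimnames = list(NULL, colnames(beta))))
  }
  do.call(rbind, rows)
}

#' Gene-set sampling of stop-gain mutation burden
#'
#' For each gene set, draws \code{k} genes without replacement
#' \code{n_iter} times and counts, per draw, how many sampled genes carry
#' at least one stop-gain mutation.  Comparing the resulting
#' distributions across sets shows whether one set is enriched for
#' stop-gain-carrying genes.
#'
#' @param gene_sets named list of character vectors of gene ids.
#' @param mutations data.frame with \code{gene} and \code{consequence}
#'   columns; \code{"stop_gained"} marks stop-gain records.
#' @param n_iter sampling iterations (default 500).
#' @param k genes per draw (default 100).
#' @return named list of integer vectors (length \code{n_iter}) of
#'   per-draw counts.
#' @export
stopgain_geneset_sampling <- function(gene_sets, mutations, n_iter = 500L,
                                      k = 100L) {
  stopgain_genes <- unique(mutations$gene[mutations$consequence ==
                                            "stop_gained"])
  lapply(gene_sets, function(gs) {
    gs <- unique(gs)
    if (length(gs) < k) {
      stop(sprintf("gene set has %d genes, need at least %d", length(gs), k))
    }
    vapply(seq_len(n_iter), function(b) {
      sum(sample(gs, k) %in% stopgain_genes)
    }, integer(1L))
  })
}

#' Stop-gain mutation rate per sample category, with permutation null
#'
#' The observed rate per category is the number of stop-gain mutations
#' falling in (gene, sample) cells of that category divided by the
#' number of cells in it.  The expected rate is estimated by shuffling
#' the category labels within each gene \code{n_perm} times, which
#' preserves each gene's mutation burden and its category multiset and
#' thereby controls for gene length and mutation-rate heterogeneity.
#' A 0.5 pseudocount is added to observed and expected mutation counts
#' so ratios stay finite.
#'
#' @param categories table from [categorize_samples()] (\code{gene_id},
#'   \code{sample}, \code{category}).
#' @param mutations data.frame with \code{sample}, \code{gene},
#'   \code{consequence}.
#' @param n_perm number of within-gene label permutations (default
#'   1000).
#' @return list with \code{observed} (counts and rates per category),
#'   \code{log2_ratio} (log2 observed/expected per category, expected =
#'   permutation mean), \code{perm_log2_ratio} (matrix n_perm x
#'   category of per-permutation log2 observed/permuted ratios) and
#'   \code{p_value} (per category, fraction of permutations with a
#'   count at least the observed).
#' @export
stopgain_rate_permutation <- function(categories, mutations, n_perm = 1000L) {
  lev <- levels(categories$category)
  n_cells <- table(categories$category)
  if (any(n_cells == 0L)) {
    warning("categories with zero cells are excluded: ",
            paste(lev[n_cells == 0L], collapse = ", "))
  }
  sg <- mutations[mutations$consequence == "stop_gained", , drop = FALSE]
  cell_mut <- integer(nrow(categories))
  if (nrow(sg)) {
    key <- paste(categories$gene_id, categories$sample)
    cell_mut <- as.integer(table(factor(paste(sg$gene, sg$sample),
                                        levels = key))[key])
  }
  count_by_cat <- function(cat) {
    vapply(lev, function(l) sum(cell_mut[cat == l]), numeric(1L))
  }
  obs <- count_by_cat(categories$category)
  gene_idx <- split(seq_len(nrow(categories)), categories$gene_id)
  perm_counts <- matrix(0, n_perm, length(lev), dimnames = list(NULL, lev))
  cat_int <- as.integer(categories$category)
  for (b in seq_len(n_perm)) {
    perm <- cat_int
    for (idx in gene_idx) {
      if (length(idx) > 1L) perm[idx] <- perm[idx[sample.int(length(idx))]]
    }
    perm_counts[b, ] <- vapply(seq_along(lev), function(l) {
      sum(cell_mut[perm == l])
    }, numeric(1L))
  }
  expected <- colMeans(perm_counts)
  log2_ratio <- log2((obs + 0.5) / (expected + 0.5))
  perm_log2 <- log2(outer(rep(1, n_perm), obs + 0.5) / (perm_counts + 0.5))
  p_val <- (colSums(perm_counts >= rep(obs, each = n_perm)) + 1) /
    (n_perm + 1)
  list(observed = data.frame(category = lev, n_cells = as.integer(n_cells),
                             mutations = obs,
                             rate = obs / as.integer(n_cells)),
       expected = expected, log2_ratio = log2_ratio,
       perm_log2_ratio = perm_log2, p_value = p_val)
}

#' Fisher's exact test on ASE frequencies in two cohorts
#'
#' Tests whether the fraction of samples with detectable ASE differs
#' between two cohorts (e.g. tumors vs a normal tissue), via the
#' two-sided exact test on the 2x2 table.
#'
#' @param k1,n1 ASE-positive and testable sample counts in cohort 1.
#' @param k2,n2 same for cohort 2.
#' @return two-sided p-value.
#' @examples
#' fisher_ase_frequency(5, 68, 1, 139)  # ~0.015
#' @export
fisher_ase_frequency <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || min(k1, k2, n1, n2) < 0) {
    stop("need 0 <= k <= n in both cohorts")
  }
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L,
                            byrow = TRUE))$p.value
}

#' Quantile-normalize and z-score an expression matrix
#'
#' Columns (samples) are quantile normalized to a common distribution
#' (ties resolved by averaged quantiles), then each gene row is z-scored
#' to mean 0, sd 1.  Rows that are constant after normalization cannot
#' be z-scored and are dropped (recorded in the \code{"dropped"}
#' attribute).
#'
#' @param x non-negative numeric matrix, genes in rows, samples in
#'   columns.
#' @return the normalized matrix with attributes \code{"state"}
#'   (\code{"quantile+zscore"}) and \code{"dropped"} (row names of
#'   excluded constant genes).
#' @export
normalize_expression <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  qn <- quantile_normalize(x)
  sds <- apply(qn, 1L, stats::sd)
  const <- sds == 0 | is.na(sds)
  z <- (qn[!const, , drop = FALSE] -
          rowMeans(qn[!const, , drop = FALSE])) / sds[!const]
  attr(z, "state") <- "quantile+zscore"
  attr(z, "dropped") <- rownames(qn)[const]
  z
}

#' Quantile normalization of a matrix's columns
#'
#' Thin wrapper over \code{limma::normalizeQuantiles} (averaged
#' quantiles for ties), so every column shares a common distribution.
#'
#' @param x numeric matrix, samples in columns.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  limma::normalizeQuantiles(x)
}

#' Differential expression of stage-4 tumors versus all other stages
#'
#' Welch t-test per gene comparing stage-4 samples to all other stages,
#' with the fold change computed as the difference of group means on
#' log2-scale expression.  BH correction; hits require
#' \code{q <= fdr} and \code{|log2FC| >= lfc}.
#'
#' @param x expression matrix, genes in rows, samples in columns.  With
#'   \code{log_transform = TRUE} (default) raw non-negative values are
#'   transformed to \code{log2(1 + x)} first; set to \code{FALSE} if the
#'   matrix is already on a log scale.
#' @param stage vector of clinical stages per column; stage-4 samples
#'   are those equal to \code{stage4}.
#' @param stage4 value marking the stage-4 group (default \code{"4"}).
#' @param fdr FDR threshold for hits (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 0.5).
#' @param log_transform apply \code{log2(1 + x)} before testing.
#' @return data.frame per gene: \code{gene_id}, \code{log2fc} (stage-4
#'   minus rest), \code{p_value}, \code{q_value}, \code{hit}.
#' @export
stage4_differential <- function(x, stage, stage4 = "4", fdr = 0.05,
                                lfc = 0.5, log_transform = TRUE) {
  stage <- as.character(stage)
  g4 <- stage == as.character(stage4)
  if (sum(g4) < 2L || sum(!g4) < 2L) {
    stop("need at least 2 samples in each group")
  }
  if (log_transform) x <- log2(1 + x)
  res <- t(apply(x, 1L, function(v) {
    tt <- stats::t.test(v[g4], v[!g4])
    c(log2fc = unname(tt$estimate[1L] - tt$estimate[2L]), p = tt$p.value)
  }))
  out <- data.frame(gene_id = rownames(x), log2fc = res[, "log2fc"],
                    p_value = res[, "p"], stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$hit <- out$q_value <= fdr & abs(out$log2fc) >= lfc
  rownames(out) <- NULL
  out
}
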