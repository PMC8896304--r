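## Cohort-level ASE calling: per-gene RNA imbalance fits with BH
## correction within each sample, classification of tumor-specific
## (recurrent) ASE genes, and the three-way sample categorization used
## by the mutation-enrichment analyses.

#' Drop heterozygous sites with too many "other" reads
#'
#' Reads matching neither the reference nor the alternate allele suggest
#' sequencing or mapping artifacts; sites where more than \code{max_other}
#' such reads are observed are removed before ASE analysis.
#'
#' @param sites het-site table with an \code{other_count} column.
#' @param max_other maximum tolerated other-read count (default 2).
#' @return the filtered table.
#' @export
filter_other_reads <- function(sites, max_other = 2L) {
  sites[sites$other_count <= max_other, , drop = FALSE]
}

#' Call allele-specific expression per gene for one sample
#'
#' Exonic heterozygous sites (after the other-read filter and a minimum
#' read-depth filter) are grouped per gene; each gene's RNA imbalance is
#' fitted with the genotyping-error mixture and tested with the
#' likelihood-ratio test.  p-values are Benjamini-Hochberg corrected
#' across all testable genes of the sample; a gene is significant when
#' its q-value is below \code{fdr}.
#'
#' @param sites RNA het-site table for one sample.
#' @param models a [gene_models()] object.
#' @param params RNA-context [model_params()] for the sample.
#' @param min_reads minimum reads per site for testability (default 10).
#' @param max_other other-read filter threshold (default 2).
#' @param fdr FDR threshold for significance (default 0.10).
#' @return data.frame per testable gene: \code{gene_id}, \code{n_sites},
#'   \code{a_rna}, \code{lrt}, \code{p_value}, \code{q_value},
#'   \code{significant}.
#' @export
call_ase_sample <- function(sites, models, params, min_reads = 10L,
                            max_other = 2L, fdr = 0.10) {
  sites <- with_n(filter_other_reads(sites, max_other))
  sites <- sites[sites$n >= min_reads, , drop = FALSE]
  hits <- sites_in_gene_exons(sites, models)
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      a_rna = numeric(0), lrt = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  }
  res <- lapply(split(hits$site_row, hits$gene_id), function(rows) {
    fit <- fit_imbalance(sites[rows, , drop = FALSE], params,
                         error_mixture = TRUE)
    data.frame(n_sites = fit$n_sites, a_rna = fit$a, lrt = fit$lrt_stat,
               p_value = fit$p_value)
  })
  out <- do.call(rbind, res)
  out <- data.frame(gene_id = names(res), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr
  out
}

#' Call ASE across a cohort of samples
#'
#' Runs per-sample nuisance-parameter estimation
#' ([estimate_dispersion_rna()]) and per-gene ASE calls for every sample,
#' returning a long-format table with cohort labels.
#'
#' @param rna_sites named list of RNA het-site tables, one per sample.
#' @param cohorts named character vector mapping sample id to cohort
#'   label (e.g. \code{"tumor"}, \code{"normal_adrenal"},
#'   \code{"normal_blood"}).
#' @inheritParams call_ase_sample
#' @param min_param_sites floor on sites for nuisance estimation.
#' @return data.frame of class \code{"ase_calls"}: one row per testable
#'   (gene, sample) with \code{cohort}, fit columns and q-values.
#' @export
call_ase_cohort <- function(rna_sites, models, cohorts, min_reads = 10L,
                            max_other = 2L, fdr = 0.10,
                            min_param_sites = 100L) {
  stopifnot(all(names(rna_sites) %in% names(cohorts)))
  out <- lapply(names(rna_sites), function(sm) {
    params <- estimate_dispersion_rna(rna_sites[[sm]],
                                      min_sites = min_param_sites)
    calls <- call_ase_sample(rna_sites[[sm]], models, params, min_reads,
                             max_other, fdr)
    if (!nrow(calls)) return(NULL)
    data.frame(sample = sm, cohort = unname(cohorts[sm]), calls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ase_calls", class(out))
  out
}

#' Classify genes with tumor-specific recurrent ASE
#'
#' A gene is classified tumor-specific (\code{nb_ase}) when it is (a)
#' testable in at least \code{min_testable} tumor samples and
#' \code{min_testable} normal samples (normal cohorts combined), and (b)
#' significant in at least \code{min_sig_tumor} tumors and at most
#' \code{max_sig_normal} normal samples.
#'
#' @param ase long-format ASE call table from [call_ase_cohort()].
#' @param tumor_cohort cohort label identifying tumors (default
#'   \code{"tumor"}); all other cohorts count as normal.
#' @param min_testable,min_sig_tumor,max_sig_normal classification
#'   thresholds (defaults 10, 3, 1).
#' @return data.frame per gene: testable and significant counts in tumor
#'   (\code{N.tumor}, \code{r.tumor}) and normal (\code{N.normal},
#'   \code{r.normal}) samples, and the \code{nb_ase} flag.
#' @export
classify_nb_ase <- function(ase, tumor_cohort = "tumor", min_testable = 10L,
                            min_sig_tumor = 3L, max_sig_normal = 1L) {
  is_tumor <- ase$cohort == tumor_cohort
  genes <- sort(unique(ase$gene_id))
  agg <- function(sel) {
    n <- tapply(rep(1L, sum(sel)), ase$gene_id[sel], sum)
    r <- tapply(ase$significant[sel], ase$gene_id[sel], sum)
    cbind(N = as.integer(n[genes]), r = as.integer(r[genes]))
  }
  tu <- agg(is_tumor)
  no <- agg(!is_tumor)
  tu[is.na(tu)] <- 0L
  no[is.na(no)] <- 0L
  out <- data.frame(gene_id = genes, N.tumor = tu[, "N"], r.tumor = tu[, "r"],
                    N.normal = no[, "N"], r.normal = no[, "r"],
                    stringsAsFactors = FALSE)
  out$nb_ase <- out$N.tumor >= min_testable & out$N.normal >= min_testable &
    out$r.tumor >= min_sig_tumor & out$r.normal <= max_sig_normal
  rownames(out) <- NULL
  out
}

#' Categorize tumor samples per gene by ASE and SCNA status
#'
#' For each testable (gene, tumor sample) cell: samples with significant
#' ASE and an SCNA over the gene's promoter are \code{ASE_SCNA}, samples
#' with significant ASE but no SCNA are \code{ASE_non_SCNA}, and all
#' other testable samples are \code{non_ASE}.  Cells whose SCNA score is
#' missing are treated as having no SCNA evidence.
#'
#' @param ase long-format ASE call table (tumor samples only or mixed;
#'   non-tumor cohorts are dropped).
#' @param scna_scores matrix of gene x tumor-sample SCNA scores (NA
#'   allowed).
#' @param tumor_cohort cohort label identifying tumors.
#' @param threshold SCNA-score threshold (default 0.09).
#' @return data.frame: \code{gene_id}, \code{sample}, \code{category}
#'   (factor with levels non_ASE, ASE_SCNA, ASE_non_SCNA).
#' @export
categorize_samples <- function(ase, scna_scores, tumor_cohort = "tumor",
                               threshold = 0.09) {
  tu <- ase[ase$cohort == tumor_cohort, , drop = FALSE]
  tu <- tu[tu$gene_id %in% rownames(scna_scores) &
             tu$sample %in% colnames(scna_scores), , drop = FALSE]
  sc <- scna_scores[cbind(match(tu$gene_id, rownames(scna_scores)),
                          match(tu$sample, colnames(scna_scores)))]
  scna <- !is.na(sc) & has_scna(sc, threshold)
  cat <- ifelse(!tu$significant, "non_ASE",
                ifelse(scna, "ASE_SCNA", "ASE_non_SCNA"))
  data.frame(gene_id = tu$gene_id, sample = tu$sample,
             category = factor(cat, levels = c("non_ASE", "ASE_SCNA",
                                               "ASE_non_SCNA")),
             stringsAsFactors = FALSE)
}

#' Long ASE calls as a gene x sample matrix
#'
#' @param ase long-format ASE call table.
#' @param value column to spread (default \code{"a_rna"}).
#' @return numeric matrix, genes in rows, samples in columns, NA where
#'   untestable.
#' @export
ase_matrix <- function(ase, value = "a_rna") {
  genes <- sort(unique(ase$gene_id))
  samples <- unique(ase$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(ase$gene_id, genes), match(ase$sample, samples))] <-
    ase[[value]]
  m
}
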