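#' Run the full ASE/SCNA pipeline on a cohort
#'
#' Orchestrates every stage on an in-memory cohort (as produced by
#' [simulate_cohort()], or assembled from [read_allele_counts()] tables):
#' per-sample nuisance-parameter estimation, tumor/normal DNA imbalance
#' over exon bins, CBS segmentation into SCNA scores, per-gene RNA ASE
#' calls with BH correction, tumor-specific ASE classification, sample
#' categorization, the ASE-SCNA Spearman screen, and the stop-gain
#' category permutation test.
#'
#' @param cohort list with \code{models}, \code{dna} (per tumor patient:
#'   \code{normal}/\code{tumor} site tables), \code{rna} (named list of
#'   RNA site tables), \code{samples} (with \code{sample_id} and
#'   \code{cohort}), and optionally \code{mutations}.
#' @param config a [run_config()].
#' @return list of class \code{"tumorase_run"} with elements
#'   \code{bins}, \code{delta_a}, \code{segments}, \code{scna_scores}
#'   (gene x tumor matrix), \code{ase} (long table), \code{nb_ase},
#'   \code{categories}, \code{ase_scna_corr} and (when mutations are
#'   present) \code{stopgain_permutation}.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  models <- cohort$models
  bins <- make_exon_bins(models, config$bin_exons)
  tumor_ids <- names(cohort$dna)

  delta_list <- list()
  seg_list <- list()
  scores <- matrix(NA_real_, nrow(models$genes), length(tumor_ids),
                   dimnames = list(models$genes$gene_id, tumor_ids))
  for (id in tumor_ids) {
    pr <- cohort$dna[[id]]
    params_n <- estimate_dispersion_dna(pr$normal, config$min_param_sites)
    params_t <- estimate_dispersion_dna(pr$tumor, config$min_param_sites)
    paired <- assign_and_filter_sites(bins, pr$normal, pr$tumor,
                                      min_reads = config$min_site_reads,
                                      min_sites = config$min_bin_sites)
    if (!nrow(paired$sites)) next
    delta <- compute_delta_a(paired, params_t, params_n)
    segs <- score_scna(delta, paired$bins, alpha = config$cbs_alpha,
                       nperm = config$cbs_nperm)
    delta_list[[id]] <- data.frame(sample = id, delta,
                                   stringsAsFactors = FALSE)
    seg_list[[id]] <- data.frame(sample = id, segs, stringsAsFactors = FALSE)
    scores[, id] <- gene_scna_score(models, segs)
  }

  cohorts <- stats::setNames(cohort$samples$cohort, cohort$samples$sample_id)
  ase <- call_ase_cohort(cohort$rna, models, cohorts,
                         min_reads = config$min_site_reads,
                         max_other = config$other_max, fdr = config$ase_fdr,
                         min_param_sites = config$min_param_sites)
  nb <- classify_nb_ase(ase, min_testable = config$nb_min_testable,
                        min_sig_tumor = config$nb_min_sig_tumor,
                        max_sig_normal = config$nb_max_sig_normal)
  categories <- categorize_samples(ase, scores,
                                   threshold = config$scna_threshold)
  corr <- spearman_ase_scna(ase_matrix(ase), scores,
                            scna_min = config$scna_threshold,
                            fdr = config$ase_fdr)
  out <- list(bins = bins,
              delta_a = do.call(rbind, delta_list),
              segments = do.call(rbind, seg_list),
              scna_scores = scores, ase = ase, nb_ase = nb,
              categories = categories, ase_scna_corr = corr,
              config = config)
  if (!is.null(cohort$mutations) && nrow(cohort$mutations)) {
    out$stopgain_permutation <-
      stopgain_rate_permutation(categories, cohort$mutations,
                                n_perm = config$n_perm)
  }
  class(out) <- "tumorase_run"
  out
}

#' @export
print.tumorase_run <- function(x, ...) {
  cat("tumorASE pipeline run\n")
  cat(sprintf("  %d exon bins; %d delta_a bins fitted; %d segments\n",
              nrow(x$bins),
              if (is.null(x$delta_a)) 0L else nrow(x$delta_a),
              if (is.null(x$segments)) 0L else nrow(x$segments)))
  cat(sprintf("  ASE calls: %d (gene, sample) cells, %d significant\n",
              nrow(x$ase), sum(x$ase$significant)))
  cat(sprintf("  tumor-specific ASE genes: %d of %d classified\n",
              sum(x$nb_ase$nb_ase), nrow(x$nb_ase)))
  if (!is.null(x$stopgain_permutation)) {
    lr <- x$stopgain_permutation$log2_ratio
    cat("  stop-gain log2(obs/exp): ",
        paste(sprintf("%s=%.2f", names(lr), lr), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write the canonical synthetic fixture suite
#'
#' Generates the small canonical cohort (by default 200 genes, 12
#' tumors, 12 normals) and writes every interchange file: the gene
#' models (GTF), DNA and RNA allele-count tables, the genotype VCF,
#' somatic mutations, the methylation matrix with probe positions, the
#' expression matrix with stages, the sample sheet and the truth table.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()]; the default is the canonical fixture
#'   configuration.
#' @return (invisibly) the simulated cohort.
#' @export
write_fixture_suite <- function(outdir, config = sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  write_gtf(cohort$models, file.path(outdir, "genes.gtf"))

  long <- function(sites, sample_id, assay) {
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
               alt = sites$alt, ref_count = sites$ref_count,
               alt_count = sites$alt_count, other_count = sites$other_count,
               gq = sites$gq, sample_id = sample_id, assay = assay,
               stringsAsFactors = FALSE)
  }
  dna <- do.call(rbind, lapply(names(cohort$dna), function(id) {
    rbind(long(cohort$dna[[id]]$normal, paste0(id, "_normal"), "DNA"),
          long(cohort$dna[[id]]$tumor, id, "DNA"))
  }))
  rna <- do.call(rbind, lapply(names(cohort$rna), function(id) {
    long(cohort$rna[[id]], id, "RNA")
  }))
  write_allele_counts(dna, file.path(outdir, "dna_counts.tsv"))
  write_allele_counts(rna, file.path(outdir, "rna_counts.tsv"))

  gq <- do.call(cbind, lapply(names(cohort$rna), function(id) {
    cohort$rna[[id]]$gq
  }))
  colnames(gq) <- names(cohort$rna)
  write_vcf(cohort$het, gq, file.path(outdir, "genotypes.vcf"))

  utils::write.table(cohort$mutations, file.path(outdir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$methylation$probe_pos,
                     file.path(outdir, "probe_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probe_id = rownames(cohort$methylation$beta),
                                cohort$methylation$beta,
                                check.names = FALSE),
                     file.path(outdir, "methylation_beta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(cohort$expression),
                                cohort$expression, check.names = FALSE),
                     file.path(outdir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
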