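## Synthetic tumor/normal cohort generator with known ground truth.
##
## Emulates the data-generating assumptions of the pipeline: reference
## allele counts are beta-binomially overdispersed around haplotype
## proportions; SCNAs (hemizygous deletions / single-copy duplications)
## shift DNA and RNA proportions diluted by tumor purity; stop-gain
## mutations degrade the mutated haplotype's transcripts (NMD);
## imprinted genes are monoallelic in tumor and normal alike; a small
## fraction of "heterozygous" sites are genotyping errors: truly
## homozygous sites with low GQ whose minor-allele reads are sequencing
## errors.

#' Configuration for the synthetic cohort generator
#'
#' All defaults are chosen once to resemble a bulk exome/RNA tumor
#' cohort; see the package vignette for the rationale of each value.
#'
#' @param n_genes number of genes.
#' @param n_chroms chromosomes; genes are laid out in contiguous blocks.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_length,intron_length,gene_gap layout in bp.
#' @param het_per_exon Poisson mean of heterozygous sites per exon.
#' @param dna_depth,rna_depth negative-binomial read-depth parameters
#'   \code{c(mean, size)}.
#' @param dispersion_dna,dispersion_rna true beta-binomial concentration
#'   for DNA and RNA counts.
#' @param seq_error true sequencing error rate at homozygous sites.
#' @param n_tumors,n_normals samples per cohort; normals are split into
#'   adrenal and blood sub-cohorts.
#' @param scna_events list of events, each a list with \code{chrom},
#'   \code{span} (gene-index fractions c(lo, hi) on that chromosome),
#'   \code{type} (\code{"hemizygous_del"} or \code{"duplication"}) and
#'   \code{carrier_frac}.
#' @param purity_shape Beta shape parameters for per-tumor purity.
#' @param nmd_gene_frac fraction of genes eligible for somatic stop-gain
#'   mutations; \code{nmd_carrier_frac} is the per-tumor carrier
#'   probability and \code{nmd_efficiency} the fraction of the mutated
#'   haplotype's transcripts degraded.
#' @param imprinted_frac fraction of genes imprinted (monoallelic in all
#'   samples).
#' @param regulatory_frac,regulatory_effect fraction of genes with a
#'   tumor-acquired cis-regulatory lesion, and the fraction of the
#'   affected haplotype's output lost.
#' @param geno_error_rate per-individual probability that a listed
#'   heterozygous site is actually homozygous (a genotyping error);
#'   \code{gq_real}/\code{gq_error} give GQ ranges for correct and
#'   erroneous calls.
#' @param meth_silenced_frac fraction of genes silenced by promoter
#'   hypermethylation in a random half of the tumors.
#' @param probes_per_promoter Poisson mean of CpG probes per promoter.
#' @param background_mutation_rate,passenger_stopgain_rate per
#'   (gene, tumor) rates of non-stop-gain and passenger stop-gain
#'   somatic mutations.
#' @param stage4_frac fraction of tumors labelled clinical stage 4;
#'   \code{stage4_effect_frac} of genes are down-regulated two-fold in
#'   stage-4 tumors.
#' @param seed master seed; all streams derive from it so adding samples
#'   never perturbs earlier ones.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 200L, n_chroms = 2L,
                       exons_per_gene = c(4L, 12L), exon_length = 150L,
                       intron_length = 2000L, gene_gap = 10000L,
                       het_per_exon = 2,
                       dna_depth = c(mean = 80, size = 8),
                       rna_depth = c(mean = 60, size = 5),
                       dispersion_dna = 40, dispersion_rna = 25,
                       seq_error = 0.005,
                       n_tumors = 12L, n_normals = 12L,
                       scna_events = list(
                         list(chrom = "chr1", span = c(0, 0.4),
                              type = "hemizygous_del", carrier_frac = 0.5),
                         list(chrom = "chr2", span = c(0.3, 0.6),
                              type = "duplication", carrier_frac = 0.25)),
                       purity_shape = c(8, 2),
                       nmd_gene_frac = 0.10, nmd_carrier_frac = 0.30,
                       nmd_efficiency = 0.8,
                       imprinted_frac = 0.05,
                       regulatory_frac = 0.05, regulatory_effect = 0.7,
                       geno_error_rate = 0.03,
                       gq_real = c(30L, 99L), gq_error = c(3L, 20L),
                       meth_silenced_frac = 0.05, probes_per_promoter = 6,
                       background_mutation_rate = 0.02,
                       passenger_stopgain_rate = 0.002,
                       stage4_frac = 0.4, stage4_effect_frac = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(nmd_gene_frac, imprinted_frac, regulatory_frac,
             meth_silenced_frac, geno_error_rate, stage4_frac,
             stage4_effect_frac, nmd_carrier_frac,
             background_mutation_rate, passenger_stopgain_rate)
  if (any(fracs < 0 | fracs > 1)) stop("rates must lie in [0, 1]")
  if (nmd_efficiency < 0 || nmd_efficiency > 1) {
    stop("nmd_efficiency must lie in [0, 1]")
  }
  if (n_genes < 0 || n_tumors < 0 || n_normals < 0) {
    stop("counts must be non-negative")
  }
  if (any(c(dna_depth, rna_depth) <= 0)) stop("depth parameters must be positive")
  for (ev in scna_events) {
    if (!ev$type %in% c("hemizygous_del", "duplication")) {
      stop("unknown SCNA type: ", ev$type)
    }
    if (ev$span[1L] < 0 || ev$span[2L] > 1 || ev$span[1L] >= ev$span[2L]) {
      stop("SCNA span must be an increasing pair of fractions in [0, 1]")
    }
  }
  structure(cfg, class = "sim_config")
}

## sample k values uniformly from lo:hi, safe for lo == hi (avoids
## sample()'s scalar expansion)
sample_range <- function(lo, hi, k) {
  lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
}

## beta-binomial deviates around proportion p with concentration d
rbetabinom_counts <- function(n, p, d) {
  p <- pmin(pmax(p, 0.002), 0.998)
  stats::rbinom(length(n), n, stats::rbeta(length(n), d * p, d * (1 - p)))
}

rnbinom_depth <- function(k, par) {
  stats::rnbinom(k, mu = par[["mean"]], size = par[["size"]])
}

#' Simulate the genome: gene models, heterozygous sites, gene effects
#'
#' Deterministic given the config's seed.  Genes are laid out in
#' contiguous blocks per chromosome, exons are disjoint, heterozygous
#' site positions are uniform within exons, and each gene is assigned
#' its ground-truth effect class (SCNA membership comes from the event
#' spans; NMD / imprinting / regulatory / methylation-silencing classes
#' are sampled disjointly among genes outside the SCNA spans).
#'
#' @param config a [sim_config()].
#' @return list with \code{models} ([gene_models()]), \code{het}
#'   (site table with \code{gene_id}), and \code{gene_truth} (per-gene
#'   effect flags and SCNA event membership).
#' @export
simulate_genome <- function(config) {
  seeds <- derive_seeds(config$seed, 1L)
  set.seed(seeds[1L])
  ng <- config$n_genes
  if (ng == 0L) {
    empty <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start0 = integer(0),
                        end0 = integer(0))
    return(list(models = NULL, het = data.frame(), gene_truth = empty))
  }
  chrom_of <- paste0("chr", rep(seq_len(config$n_chroms), length.out = ng,
                                each = ceiling(ng / config$n_chroms)))[seq_len(ng)]
  n_ex <- sample_range(config$exons_per_gene[1L], config$exons_per_gene[2L],
                       ng)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(ng))
  exon_rows <- vector("list", ng)
  het_rows <- vector("list", ng)
  cursor <- stats::setNames(rep(0L, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  for (g in seq_len(ng)) {
    cc <- chrom_of[g]
    start <- cursor[[cc]] + config$gene_gap
    st <- start + (seq_len(n_ex[g]) - 1L) *
      (config$exon_length + config$intron_length)
    en <- st + config$exon_length
    exon_rows[[g]] <- data.frame(gene_id = gene_id[g], chrom = cc,
                                 strand = strand[g], start0 = st, end0 = en,
                                 stringsAsFactors = FALSE)
    cursor[[cc]] <- max(en)
    k <- stats::rpois(n_ex[g], config$het_per_exon)
    if (sum(k) > 0L) {
      pos0 <- unlist(lapply(seq_len(n_ex[g]), function(e) {
        if (k[e] == 0L) return(integer(0))
        sort(sample(st[e]:(en[e] - 1L), k[e]))
      }))
      het_rows[[g]] <- data.frame(gene_id = gene_id[g], chrom = cc,
                                  pos = pos0 + 1L, stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, exon_rows)
  het <- do.call(rbind, het_rows)
  if (is.null(het)) het <- data.frame(gene_id = character(0),
                                      chrom = character(0), pos = integer(0))
  het$ref <- sample(c("A", "C", "G", "T"), nrow(het), replace = TRUE)
  het$alt <- vapply(het$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1L))
  models <- gene_models(exons)

  ## SCNA membership by gene-index fraction within each chromosome
  scna_event <- rep(0L, ng)
  for (k in seq_along(config$scna_events)) {
    ev <- config$scna_events[[k]]
    on_c <- which(chrom_of == ev$chrom)
    if (!length(on_c)) next
    frac <- (seq_along(on_c) - 1L) / length(on_c)
    inside <- on_c[frac >= ev$span[1L] & frac < ev$span[2L]]
    scna_event[inside] <- k
  }
  free <- which(scna_event == 0L)
  pick <- function(frac, pool) {
    n <- min(length(pool), round(frac * ng))
    if (n == 0L) return(integer(0))
    sort(pool[sample.int(length(pool), n)])
  }
  imprinted <- pick(config$imprinted_frac, free)
  free <- setdiff(free, imprinted)
  nmd <- pick(config$nmd_gene_frac, free)
  free <- setdiff(free, nmd)
  regulatory <- pick(config$regulatory_frac, free)
  free <- setdiff(free, regulatory)
  meth <- pick(config$meth_silenced_frac, free)
  gene_truth <- data.frame(gene_id = gene_id, chrom = chrom_of,
                           scna_event = scna_event,
                           imprinted = seq_len(ng) %in% imprinted,
                           nmd_gene = seq_len(ng) %in% nmd,
                           regulatory = seq_len(ng) %in% regulatory,
                           meth_silenced = seq_len(ng) %in% meth,
                           stringsAsFactors = FALSE)
  list(models = models, het = het, gene_truth = gene_truth)
}

## deterministic per-stream seeds from the master seed: drawing k seeds
## is a prefix of drawing k + 1, so adding samples never perturbs
## earlier streams
derive_seeds <- function(master, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, k, replace = TRUE)
}

#' Simulate a full tumor/normal cohort with ground truth
#'
#' Generates, per tumor patient, matched normal and tumor DNA allele
#' counts at the genome's heterozygous sites, and RNA allele counts for
#' tumors and for a separate cohort of normal individuals (split into
#' adrenal and blood sub-cohorts).  Also emits a somatic mutation table,
#' a promoter CpG methylation matrix, a tumor expression matrix with
#' clinical stages, and a truth table per (gene, tumor).
#'
#' @param config a [sim_config()].
#' @return list with \code{models}, \code{gene_truth}, \code{het},
#'   \code{samples}, \code{dna} (per tumor patient: \code{normal} and
#'   \code{tumor} site tables), \code{rna} (named list of site tables),
#'   \code{mutations}, \code{methylation} (\code{beta}, \code{probe_pos}),
#'   \code{expression} (matrix with \code{stage} attribute) and
#'   \code{truth}.
#' @export
simulate_cohort <- function(config) {
  genome <- simulate_genome(config)
  het <- genome$het
  gt <- genome$gene_truth
  ns <- config$n_tumors + config$n_normals
  seeds <- derive_seeds(config$seed, 2L + ns)
  n_sites <- nrow(het)
  gene_of_site <- match(het$gene_id, gt$gene_id)

  tumor_ids <- sprintf("T%02d", seq_len(config$n_tumors))
  n_adrenal <- ceiling(config$n_normals / 2)
  normal_ids <- sprintf("N%02d", seq_len(config$n_normals))
  cohort <- c(rep("tumor", config$n_tumors),
              rep(c("normal_adrenal", "normal_blood"),
                  c(n_adrenal, config$n_normals - n_adrenal)))
  sample_ids <- c(tumor_ids, normal_ids)

  dna <- list()
  rna <- list()
  truth_rows <- list()
  mut_rows <- list()
  purity <- rep(NA_real_, ns)
  stage <- rep(NA_character_, ns)
  meth_silenced_cells <- matrix(FALSE, nrow(gt), config$n_tumors,
                                dimnames = list(gt$gene_id, tumor_ids))

  for (s in seq_len(ns)) {
    set.seed(seeds[2L + s])
    id <- sample_ids[s]
    is_tumor <- cohort[s] == "tumor"
    ## germline state of this individual
    phase_A <- stats::runif(n_sites) < 0.5    # ref allele on haplotype A?
    geno_err <- stats::runif(n_sites) < config$geno_error_rate
    hom_ref <- stats::runif(n_sites) < 0.5    # if error: hom ref vs hom alt
    gq <- ifelse(geno_err,
                 sample_range(config$gq_error[1L], config$gq_error[2L],
                              n_sites),
                 sample_range(config$gq_real[1L], config$gq_real[2L],
                              n_sites))
    imp_sil_A <- stats::runif(nrow(gt)) < 0.5 # imprinting silences hap A?

    ## per-gene haplotype output/copy weights
    cnA_t <- rep(1, nrow(gt)); cnB_t <- rep(1, nrow(gt))  # tumor-cell DNA
    exA_t <- rep(1, nrow(gt)); exB_t <- rep(1, nrow(gt))  # tumor-cell RNA
    exA_n <- rep(1, nrow(gt)); exB_n <- rep(1, nrow(gt))  # normal-cell RNA
    imp <- gt$imprinted
    exA_t[imp & imp_sil_A] <- 0.02; exB_t[imp & !imp_sil_A] <- 0.02
    exA_n[imp & imp_sil_A] <- 0.02; exB_n[imp & !imp_sil_A] <- 0.02

    rho <- 1
    nmd_carrier <- rep(FALSE, nrow(gt))
    if (is_tumor) {
      rho <- stats::rbeta(1L, config$purity_shape[1L], config$purity_shape[2L])
      purity[s] <- rho
      stage[s] <- if (stats::runif(1L) < config$stage4_frac) "4" else
        sample(c("1", "2", "3"), 1L)
      ## SCNA events
      for (k in seq_along(config$scna_events)) {
        ev <- config$scna_events[[k]]
        if (stats::runif(1L) >= ev$carrier_frac) next
        lose_A <- stats::runif(1L) < 0.5
        in_ev <- gt$scna_event == k
        if (ev$type == "hemizygous_del") {
          if (lose_A) { cnA_t[in_ev] <- 0; exA_t[in_ev] <- 0 }
          else { cnB_t[in_ev] <- 0; exB_t[in_ev] <- 0 }
        } else {
          if (lose_A) { cnA_t[in_ev] <- 2; exA_t[in_ev] <- 2 * exA_t[in_ev] }
          else { cnB_t[in_ev] <- 2; exB_t[in_ev] <- 2 * exB_t[in_ev] }
        }
      }
      ## somatic stop-gains triggering NMD
      nmd_carrier <- gt$nmd_gene & stats::runif(nrow(gt)) < config$nmd_carrier_frac
      mut_on_A <- stats::runif(nrow(gt)) < 0.5
      keep <- 1 - config$nmd_efficiency
      exA_t[nmd_carrier & mut_on_A] <- exA_t[nmd_carrier & mut_on_A] * keep
      exB_t[nmd_carrier & !mut_on_A] <- exB_t[nmd_carrier & !mut_on_A] * keep
      ## tumor-acquired regulatory silencing
      reg_on_A <- stats::runif(nrow(gt)) < 0.5
      rkeep <- 1 - config$regulatory_effect
      reg <- gt$regulatory
      exA_t[reg & reg_on_A] <- exA_t[reg & reg_on_A] * rkeep
      exB_t[reg & !reg_on_A] <- exB_t[reg & !reg_on_A] * rkeep
      ## promoter-methylation silencing in a random half of tumors
      msil <- gt$meth_silenced & stats::runif(nrow(gt)) < 0.5
      meth_silenced_cells[msil, id] <- TRUE
      m_on_A <- stats::runif(nrow(gt)) < 0.5
      exA_t[msil & m_on_A] <- exA_t[msil & m_on_A] * rkeep
      exB_t[msil & !m_on_A] <- exB_t[msil & !m_on_A] * rkeep

      ## mutation records
      for (g in which(nmd_carrier)) {
        site_pool <- which(gene_of_site == g)
        pos <- if (length(site_pool))
          het$pos[site_pool[sample.int(length(site_pool), 1L)]] else NA
        mut_rows[[length(mut_rows) + 1L]] <-
          data.frame(sample = id, gene = gt$gene_id[g], chrom = gt$chrom[g],
                     pos = pos, consequence = "stop_gained",
                     stringsAsFactors = FALSE)
      }
      n_bg <- stats::rbinom(1L, nrow(gt), config$background_mutation_rate)
      if (n_bg > 0L) {
        bg <- sample(nrow(gt), n_bg)
        mut_rows[[length(mut_rows) + 1L]] <-
          data.frame(sample = id, gene = gt$gene_id[bg], chrom = gt$chrom[bg],
                     pos = stats::rpois(n_bg, 1e4),
                     consequence = sample(c("missense_high_impact",
                                            "frameshift", "other"),
                                          n_bg, replace = TRUE),
                     stringsAsFactors = FALSE)
      }
      n_pass <- stats::rbinom(1L, nrow(gt), config$passenger_stopgain_rate)
      if (n_pass > 0L) {
        pg <- sample(nrow(gt), n_pass)
        mut_rows[[length(mut_rows) + 1L]] <-
          data.frame(sample = id, gene = gt$gene_id[pg], chrom = gt$chrom[pg],
                     pos = stats::rpois(n_pass, 1e4),
                     consequence = "stop_gained", stringsAsFactors = FALSE)
      }
    }

    ## site-level proportions: mix tumor and contaminating normal cells
    mix <- function(wA_t, wB_t, wA_n, wB_n) {
      pA_gene <- (rho * wA_t + (1 - rho) * wA_n) /
        pmax(rho * (wA_t + wB_t) + (1 - rho) * (wA_n + wB_n), 1e-12)
      pA <- pA_gene[gene_of_site]
      ifelse(phase_A, pA, 1 - pA)
    }
    p_dna_t <- mix(cnA_t, cnB_t, 1, 1)
    p_rna <- mix(exA_t, exB_t, exA_n, exB_n)
    ## genotyping errors: the site is homozygous; minor reads are
    ## sequencing errors (affects DNA and RNA alike)
    hom_p <- ifelse(hom_ref, 1 - config$seq_error, config$seq_error)
    p_rna[geno_err] <- hom_p[geno_err]
    p_dna_t[geno_err] <- hom_p[geno_err]

    make_sites <- function(p, depth_par, d) {
      n <- rnbinom_depth(n_sites, depth_par)
      x <- rbetabinom_counts(n, p, d)
      oc <- stats::rpois(n_sites, 0.1)
      high <- stats::runif(n_sites) < 0.01
      oc[high] <- 3L + stats::rpois(sum(high), 1)
      data.frame(chrom = het$chrom, pos = het$pos, ref = het$ref,
                 alt = het$alt, ref_count = x, alt_count = n - x,
                 other_count = oc, gq = gq, n = n,
                 stringsAsFactors = FALSE)
    }

    if (is_tumor) {
      p_dna_n <- ifelse(geno_err, hom_p, 0.5)
      dna[[id]] <- list(
        normal = make_sites(p_dna_n, config$dna_depth, config$dispersion_dna),
        tumor = make_sites(p_dna_t, config$dna_depth, config$dispersion_dna))
    }
    rna[[id]] <- make_sites(p_rna, config$rna_depth, config$dispersion_rna)

    ## ground truth per gene for this sample
    pA_gene_rna <- (rho * exA_t + (1 - rho) * exA_n) /
      pmax(rho * (exA_t + exB_t) + (1 - rho) * (exA_n + exB_n), 1e-12)
    pA_gene_dna <- (rho * cnA_t + (1 - rho) * 1) /
      pmax(rho * (cnA_t + cnB_t) + (1 - rho) * 2, 1e-12)
    event <- ifelse(gt$scna_event > 0L,
                    vapply(gt$scna_event, function(k) {
                      if (k == 0L) "none" else config$scna_events[[k]]$type
                    }, character(1L)), "none")
    scna_here <- gt$scna_event > 0L & abs(pA_gene_dna - 0.5) > 1e-9
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(gene_id = gt$gene_id, sample = id, cohort = cohort[s],
                 a_true = pA_gene_rna - 0.5,
                 abs_a_true = abs(pA_gene_rna - 0.5),
                 scna_type = ifelse(scna_here, event, "none"),
                 expected_delta_a = abs(pA_gene_dna - 0.5),
                 nmd_mutation = nmd_carrier,
                 imprinted = gt$imprinted,
                 stringsAsFactors = FALSE)
  }

  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample = character(0), gene = character(0),
               chrom = character(0), pos = integer(0),
               consequence = character(0))
  truth <- do.call(rbind, truth_rows)
  truth$category_truth <- with(truth, ifelse(
    cohort != "tumor", NA_character_,
    ifelse(abs_a_true < 0.1, "non_ASE",
           ifelse(scna_type != "none", "ASE_SCNA", "ASE_non_SCNA"))))
  rownames(truth) <- NULL

  ## methylation: probes per promoter; silenced (gene, tumor) cells get
  ## high beta
  set.seed(seeds[1L])
  g <- genome$models$genes
  probe_rows <- lapply(seq_len(nrow(g)), function(k) {
    np <- max(stats::rpois(1L, config$probes_per_promoter), 0L)
    if (np == 0L) return(NULL)
    data.frame(probe_id = sprintf("%s_cg%02d", g$gene_id[k], seq_len(np)),
               gene_id = g$gene_id[k], chrom = g$chrom[k],
               pos = sort(sample(g$promoter_start0[k]:(g$promoter_end0[k] - 1L),
                                 np, replace = FALSE)) + 1L,
               stringsAsFactors = FALSE)
  })
  probe_pos <- do.call(rbind, probe_rows)
  beta <- matrix(stats::rbeta(nrow(probe_pos) * config$n_tumors, 1, 9),
                 nrow(probe_pos), config$n_tumors,
                 dimnames = list(probe_pos$probe_id, tumor_ids))
  for (id in tumor_ids) {
    sil <- rownames(meth_silenced_cells)[meth_silenced_cells[, id]]
    rows <- probe_pos$gene_id %in% sil
    beta[rows, id] <- stats::rbeta(sum(rows), 8, 2)
  }

  ## expression: proportional to total haplotype output, log-normal noise
  set.seed(seeds[2L])
  base <- stats::rlnorm(nrow(gt), meanlog = 3, sdlog = 1)
  ## total output relative to diploid two-allele expression: genes with
  ## a silenced or deleted haplotype have lower totals (monoallelic
  ## loss halves output, mirrored by abs_a_true)
  tot_out <- matrix(NA_real_, nrow(gt), config$n_tumors,
                    dimnames = list(gt$gene_id, tumor_ids))
  for (s in seq_len(config$n_tumors)) {
    tr <- truth[truth$sample == tumor_ids[s], ]
    tr <- tr[match(gt$gene_id, tr$gene_id), ]
    tot_out[, s] <- 1 - tr$abs_a_true
  }
  stage4_genes <- character(0)
  if (config$stage4_effect_frac > 0 && nrow(gt) > 0L) {
    stage4_genes <- sample(gt$gene_id,
                           round(config$stage4_effect_frac * nrow(gt)))
  }
  expr <- base * tot_out * matrix(stats::rlnorm(length(tot_out), 0, 0.15),
                                  nrow(tot_out))
  s4 <- which(stage[seq_len(config$n_tumors)] == "4")
  expr[rownames(expr) %in% stage4_genes, s4] <-
    expr[rownames(expr) %in% stage4_genes, s4] * 0.5
  samples <- data.frame(sample_id = sample_ids, cohort = cohort,
                        purity = purity, stage = stage,
                        stringsAsFactors = FALSE)
  attr(expr, "stage") <- stats::setNames(stage[seq_len(config$n_tumors)],
                                         tumor_ids)
  list(models = genome$models, gene_truth = gt, het = het,
       samples = samples, dna = dna, rna = rna, mutations = mutations,
       methylation = list(beta = beta, probe_pos = probe_pos),
       expression = expr, truth = truth,
       stage4_genes = stage4_genes, config = config)
}
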