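## Tabular interchange: allele-count tables (TSV, 1-based, VCF-like
## conventions), gene models (GTF or BED12), and the run configuration.
## Readers are gzip-transparent (R connections decompress .gz).

ALLELE_COLS <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
                 "other_count", "gq", "sample_id", "assay")

#' Read an allele-count table
#'
#' Expects a TSV with header columns \code{chrom, pos, ref, alt,
#' ref_count, alt_count, other_count, gq, sample_id, assay} (positions
#' 1-based; assay \code{DNA} or \code{RNA}).  Validates types, sorting
#' within chromosome, non-negative counts, and biallelic records;
#' multiallelic rows (comma in the alternate allele) are rejected.
#'
#' @param path file path (plain or gzip).
#' @return validated data.frame with an added \code{n} column.
#' @export
read_allele_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(ALLELE_COLS, names(x))
  if (length(miss)) {
    stop("allele-count table lacks columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(x$ref_count < 0 | x$alt_count < 0 | x$other_count < 0 |
                 is.na(x$ref_count) | is.na(x$alt_count))
  if (length(bad)) {
    stop("negative or missing count at line ", bad[1L] + 1L)
  }
  multi <- which(grepl(",", x$alt) | grepl(",", x$ref))
  if (length(multi)) {
    stop("multiallelic record at line ", multi[1L] + 1L,
         " (multiallelic sites are excluded)")
  }
  if (any(x$gq < 0, na.rm = TRUE)) stop("negative genotype quality")
  for (grp in split(seq_len(nrow(x)), paste(x$sample_id, x$assay, x$chrom))) {
    p <- x$pos[grp]
    if (is.unsorted(p)) {
      stop("positions not sorted within chromosome, first violation near line ",
           grp[which(diff(p) < 0)[1L] + 1L] + 1L)
    }
  }
  if (!all(x$assay %in% c("DNA", "RNA"))) {
    stop("assay must be 'DNA' or 'RNA'")
  }
  x$n <- x$ref_count + x$alt_count
  x
}

#' Write an allele-count table
#'
#' @param x data.frame with the allele-count columns.
#' @param path output path (gzip if it ends in \code{.gz}).
#' @export
write_allele_counts <- function(x, path) {
  miss <- setdiff(ALLELE_COLS, names(x))
  if (length(miss)) {
    stop("allele-count table lacks columns: ", paste(miss, collapse = ", "))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(x[, ALLELE_COLS], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF exon records (1-based, inclusive) or BED12 blocks (0-based,
#' half-open) are converted to the internal 0-based half-open exon
#' representation and assembled into [gene_models()].  The gene
#' identifier is the GTF \code{gene_id} attribute or the BED name field.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"gtf"} or
#'   \code{"bed12"}.
#' @param promoter_flank promoter half-width in bp (default 1500).
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12"),
                             promoter_flank = 1500L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  gr <- rtracklayer::import(path,
                            format = if (format == "gtf") "gtf" else "bed")
  df <- as.data.frame(gr)
  if (format == "gtf") {
    if ("type" %in% names(df)) df <- df[df$type == "exon", , drop = FALSE]
    if (!nrow(df)) stop("no exon records in GTF")
    exons <- data.frame(gene_id = as.character(df$gene_id),
                        chrom = as.character(df$seqnames),
                        strand = as.character(df$strand),
                        start0 = df$start - 1L, end0 = df$end,
                        stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      blk <- as.data.frame(df$blocks[[i]])
      data.frame(gene_id = df$name[i],
                 chrom = as.character(df$seqnames[i]),
                 strand = as.character(df$strand[i]),
                 start0 = df$start[i] - 1L + blk$start - 1L,
                 end0 = df$start[i] - 1L + blk$end,
                 stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, rows)
  }
  if (any(!exons$strand %in% c("+", "-"))) {
    stop("unknown strand in gene models")
  }
  exons <- unique(exons)
  gene_models(exons, promoter_flank = promoter_flank)
}

#' Write gene models as GTF
#'
#' @param models a [gene_models()] object.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  e <- models$exons
  lines <- sprintf(
    '%s\ttumorASE\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    e$chrom, e$start0 + 1L, e$end0, e$strand, e$gene_id, e$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write per-individual genotypes as a minimal VCF
#'
#' Emits the heterozygous site list with GT and GQ fields, one sample
#' column per individual (VCF 4.2, 1-based).
#'
#' @param het site table with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param gq matrix sites x samples of genotype qualities.
#' @param path output path.
#' @export
write_vcf <- function(het, gq, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gq)), collapse = "\t"))
  geno <- apply(gq, 2L, function(q) sprintf("0/1:%d", as.integer(q)))
  body <- cbind(het$chrom, het$pos, ".", het$ref, het$alt, ".", "PASS", ".",
                "GT:GQ", geno)
  writeLines(c(hdr, apply(body, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Pipeline thresholds and defaults
#'
#' Collects every tunable threshold of the pipeline with its default:
#' minimum reads per site (10), minimum sites per bin (10), exons per
#' bin (20), other-read maximum (2), ASE FDR (0.10), SCNA-score
#' threshold (0.09), promoter flank (1500 bp), tumor-specific ASE
#' classification counts (10 testable, >= 3 significant tumors, <= 1
#' significant normal), differential-expression FDR (0.05) and log2
#' fold-change (0.5), gene-set sampling (500 x 100), and permutation
#' count (1000).
#'
#' @param ... overrides of the defaults (unknown names are errors).
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  defaults <- list(min_site_reads = 10L, min_bin_sites = 10L,
                   bin_exons = 20L, other_max = 2L, ase_fdr = 0.10,
                   scna_threshold = 0.09, promoter_flank = 1500L,
                   nb_min_testable = 10L, nb_min_sig_tumor = 3L,
                   nb_max_sig_normal = 1L, de_fdr = 0.05, de_lfc = 0.5,
                   sampling_n_iter = 500L, sampling_k = 100L,
                   n_perm = 1000L, cbs_alpha = 0.01, cbs_nperm = 1000L,
                   min_param_sites = 100L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (nm in c("ase_fdr", "de_fdr", "cbs_alpha")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop(nm, " must lie strictly inside (0, 1)")
    }
  }
  if (cfg$scna_threshold < 0) stop("scna_threshold must be non-negative")
  if (any(unlist(cfg[c("min_site_reads", "min_bin_sites", "bin_exons",
                       "sampling_n_iter", "sampling_k", "n_perm")]) < 1)) {
    stop("count thresholds must be at least 1")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' The YAML document may set any subset of the [run_config()] keys;
#' unknown keys are errors (guarding against silent threshold typos).
#'
#' @param path YAML file path.
#' @return list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package")
  }
  do.call(run_config, yaml::read_yaml(path))
}
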