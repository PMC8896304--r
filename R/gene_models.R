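#' Build gene models from an exon table
#'
#' Internal coordinates are 0-based half-open (\code{start0}, \code{end0});
#' the readers in [read_gene_models()] convert from GTF (1-based
#' inclusive) or BED12 (already 0-based half-open).  The TSS is
#' strand-aware (leftmost base for \code{+}, rightmost for \code{-}) and
#' the promoter is TSS +/- 1500 bp, clipped at the chromosome start.
#'
#' @param exons data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"} or \code{"-"}), \code{start0}, \code{end0}.
#' @param promoter_flank half-width of the promoter window in bp
#'   (default 1500).
#' @return an object of class \code{"gene_models"}: a list with a
#'   \code{genes} table (gene_id, chrom, strand, tss0, promoter_start0,
#'   promoter_end0) and the sorted \code{exons} table.
#' @export
gene_models <- function(exons, promoter_flank = 1500L) {
  req <- c("gene_id", "chrom", "strand", "start0", "end0")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("missing exon columns: ", paste(miss, collapse = ", "))
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("unknown strand value; must be '+' or '-'")
  }
  if (any(exons$end0 <= exons$start0)) stop("exons must have positive width")
  exons <- exons[order(exons$gene_id, exons$start0), , drop = FALSE]
  split_idx <- split(seq_len(nrow(exons)), exons$gene_id)
  genes <- do.call(rbind, lapply(split_idx, function(i) {
    e <- exons[i, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L) {
      stop("gene ", e$gene_id[1L], " spans multiple chromosomes or strands")
    }
    if (nrow(e) > 1L && any(e$start0[-1L] < e$end0[-nrow(e)])) {
      stop("overlapping exons within gene ", e$gene_id[1L])
    }
    tss0 <- if (e$strand[1L] == "+") min(e$start0) else max(e$end0) - 1L
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], tss0 = tss0,
               promoter_start0 = max(0L, tss0 - promoter_flank),
               promoter_end0 = tss0 + promoter_flank + 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, promoter_flank = promoter_flank),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("Gene models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  cat(sprintf("  promoter window: TSS +/- %d bp\n", x$promoter_flank))
  invisible(x)
}

## which gene's exons contain each 1-based site position (list of gene ids
## per site would be overkill: returns a data.frame of site-row/gene pairs)
sites_in_gene_exons <- function(sites, models) {
  out <- vector("list", nrow(models$genes))
  for (g in seq_len(nrow(models$genes))) {
    gid <- models$genes$gene_id[g]
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    on_chr <- which(sites$chrom == models$genes$chrom[g])
    if (!length(on_chr)) next
    p0 <- sites$pos[on_chr] - 1L
    idx <- findInterval(p0, ex$start0)
    hit <- idx >= 1L & p0 < ex$end0[pmax(idx, 1L)]
    if (any(hit)) {
      out[[g]] <- data.frame(site_row = on_chr[hit], gene_id = gid,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(site_row = integer(0), gene_id = character(0))
  }
  out
}
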