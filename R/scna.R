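## Tumor-vs-normal DNA allelic imbalance and SCNA scoring.
##
## Exons are pooled across genes, sorted, and grouped into bins of 20
## consecutive exons.  Heterozygous sites (defined in the normal sample)
## with >= 10 reads in both tumor and normal are assigned to bins; bins
## with >= 10 such sites get tumor and normal imbalance fits, and
## delta_a = |a_tumor| - |a_normal| per bin is segmented with circular
## binary segmentation.  The segmented mean of delta_a is the SCNA score.

#' Group the pooled exome into bins of consecutive exons
#'
#' Per chromosome, the union of exons across genes (exact duplicate
#' intervals removed) is sorted and chunked into consecutive groups of
#' \code{bin_exons}; a trailing remainder group is kept.
#'
#' @param models a [gene_models()] object.
#' @param bin_exons exons per bin (default 20).
#' @return data.frame of bins: \code{bin_id}, \code{chrom},
#'   \code{start0}, \code{end0} (span of the bin's exons), \code{n_exons}.
#' @export
make_exon_bins <- function(models, bin_exons = 20L) {
  ex <- models$exons
  if (nrow(ex) == 0L) stop("no exons in gene models")
  ex <- unique(ex[, c("chrom", "start0", "end0")])
  ex <- ex[order(ex$chrom, ex$start0, ex$end0), , drop = FALSE]
  out <- lapply(split(ex, ex$chrom), function(e) {
    k <- ceiling(nrow(e) / bin_exons)
    grp <- rep(seq_len(k), each = bin_exons, length.out = nrow(e))
    data.frame(chrom = e$chrom[1L],
               start0 = tapply(e$start0, grp, min),
               end0 = tapply(e$end0, grp, max),
               n_exons = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  bins <- bins[order(bins$chrom, bins$start0), , drop = FALSE]
  bins$bin_id <- sprintf("%s_bin%04d", bins$chrom,
                         stats::ave(seq_len(nrow(bins)), bins$chrom,
                                    FUN = seq_along))
  rownames(bins) <- NULL
  bins[, c("bin_id", "chrom", "start0", "end0", "n_exons")]
}

## assign 1-based positions to bins on one chromosome (spans sorted);
## returns bin row index or NA
assign_to_bins <- function(chrom, pos, bins) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    b <- which(bins$chrom == cc)
    if (!length(b)) next
    sel <- which(chrom == cc)
    p0 <- pos[sel] - 1L
    idx <- findInterval(p0, bins$start0[b])
    ok <- idx >= 1L & p0 < bins$end0[b][pmax(idx, 1L)]
    out[sel[ok]] <- b[idx[ok]]
  }
  out
}

#' Pair tumor and normal allele counts and filter bins
#'
#' Heterozygous sites are defined from the normal sample; counts at the
#' shared positions are taken from the matched tumor.  Sites need at
#' least \code{min_reads} reads in both samples, and bins keep at least
#' \code{min_sites} qualifying sites.
#'
#' @param bins bin table from [make_exon_bins()].
#' @param sites_normal,sites_tumor het-site tables for the matched pair.
#' @param min_reads minimum reads per site in each sample (default 10).
#' @param min_sites minimum qualifying sites per bin (default 10).
#' @return list with \code{sites} (paired counts with a \code{bin_id}
#'   column) and \code{bins} (the retained bins).
#' @export
assign_and_filter_sites <- function(bins, sites_normal, sites_tumor,
                                    min_reads = 10L, min_sites = 10L) {
  sites_normal <- with_n(sites_normal)
  sites_tumor <- with_n(sites_tumor)
  key_n <- paste(sites_normal$chrom, sites_normal$pos)
  key_t <- paste(sites_tumor$chrom, sites_tumor$pos)
  shared <- match(key_n, key_t)
  keep <- !is.na(shared)
  nn <- sites_normal[keep, , drop = FALSE]
  tt <- sites_tumor[shared[keep], , drop = FALSE]
  ok <- nn$n >= min_reads & tt$n >= min_reads
  nn <- nn[ok, , drop = FALSE]
  tt <- tt[ok, , drop = FALSE]
  bin_row <- assign_to_bins(nn$chrom, nn$pos, bins)
  use <- !is.na(bin_row)
  paired <- data.frame(bin_id = bins$bin_id[bin_row[use]],
                       chrom = nn$chrom[use], pos = nn$pos[use],
                       ref_normal = nn$ref_count[use], n_normal = nn$n[use],
                       ref_tumor = tt$ref_count[use], n_tumor = tt$n[use],
                       stringsAsFactors = FALSE)
  counts <- table(paired$bin_id)
  keep_bins <- names(counts)[counts >= min_sites]
  paired <- paired[paired$bin_id %in% keep_bins, , drop = FALSE]
  list(sites = paired,
       bins = bins[bins$bin_id %in% keep_bins, , drop = FALSE])
}

#' Tumor-minus-normal DNA allelic imbalance per bin
#'
#' Fits the imbalance separately on tumor and normal counts of each bin
#' (pure beta-binomial, no error mixture) and returns
#' \code{delta_a = |a_tumor| - |a_normal|}.
#'
#' @param paired output of [assign_and_filter_sites()].
#' @param params_tumor,params_normal DNA-context [model_params()] for the
#'   two samples.
#' @return data.frame with one row per bin: \code{bin_id}, \code{chrom},
#'   \code{n_sites}, \code{a_tumor}, \code{a_normal}, \code{delta_a}.
#' @export
compute_delta_a <- function(paired, params_tumor, params_normal) {
  res <- lapply(split(paired$sites, paired$sites$bin_id), function(s) {
    st <- data.frame(chrom = s$chrom, pos = s$pos, ref_count = s$ref_tumor,
                     alt_count = s$n_tumor - s$ref_tumor,
                     other_count = 0L, gq = 99, n = s$n_tumor)
    sn <- data.frame(chrom = s$chrom, pos = s$pos, ref_count = s$ref_normal,
                     alt_count = s$n_normal - s$ref_normal,
                     other_count = 0L, gq = 99, n = s$n_normal)
    ft <- fit_imbalance(st, params_tumor, error_mixture = FALSE)
    fn <- fit_imbalance(sn, params_normal, error_mixture = FALSE)
    data.frame(bin_id = s$bin_id[1L], chrom = s$chrom[1L],
               n_sites = nrow(s), a_tumor = ft$a, a_normal = fn$a,
               delta_a = abs(ft$a) - abs(fn$a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ## restore genome order
  out <- out[match(intersect(paired$bins$bin_id, out$bin_id), out$bin_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- circular binary segmentation ------------------------------------

## precompute arc boundary pairs (i, j], 0 <= i < j <= N, with both the
## arc and its complement at least min_width long
cbs_pairs <- function(N, min_width) {
  i <- rep.int(0:(N - 1L), N:1L)
  j <- sequence(N:1L) + i
  k <- j - i
  keep <- k >= min_width & (N - k) >= min_width
  list(i = i[keep], j = j[keep], k = k[keep])
}

## max two-sample t statistic over all circular arcs of x
cbs_max_stat <- function(x, pairs) {
  N <- length(x)
  if (!length(pairs$i)) return(list(stat = 0, i = 0L, j = N))
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  i <- pairs$i; j <- pairs$j; k <- pairs$k
  Sarc <- S[j + 1L] - S[i + 1L]
  Qarc <- Q[j + 1L] - Q[i + 1L]
  mu1 <- Sarc / k
  mu2 <- (S[N + 1L] - Sarc) / (N - k)
  ss <- (Qarc - k * mu1^2) + (Q[N + 1L] - Qarc - (N - k) * mu2^2)
  s2 <- pmax(ss, 0) / max(N - 2L, 1L)  # guard fp cancellation at ss ~ 0
  tt <- abs(mu1 - mu2) / sqrt(s2 * (1 / k + 1 / (N - k)))
  tt[is.nan(tt)] <- 0            # zero variance, equal means
  tt[is.infinite(tt)] <- .Machine$double.xmax
  b <- which.max(tt)
  list(stat = tt[b], i = i[b], j = j[b])
}

## permutation p-value with early stopping: once the exceedance count
## guarantees p > alpha the remaining permutations cannot change the
## split decision
cbs_perm_signif <- function(x, stat, alpha, nperm, min_width, pairs) {
  limit <- floor(alpha * (nperm + 1L)) # significant iff exceedances < limit
  count <- 0L
  for (b in seq_len(nperm)) {
    ps <- cbs_max_stat(sample(x), pairs)$stat
    if (ps >= stat) {
      count <- count + 1L
      if (count >= limit) return(FALSE)
    }
  }
  (count + 1L) / (nperm + 1L) <= alpha
}

#' Circular binary segmentation of per-bin delta_a values
#'
#' Recursive change-point detection in the style of Olshen et al.:
#' within each current segment, the maximal absolute two-sample
#' t-statistic over all circular arcs is found, its significance is
#' assessed by permutation, and accepted splits are recursed into.  Each
#' final segment's score is the mean of its bin values.
#'
#' @param values numeric vector of delta_a values in genome order along
#'   one chromosome.
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param nperm permutations per test (default 1000).
#' @param min_width minimum arc width in bins (default 2).
#' @return data.frame of segments: \code{start_bin}, \code{end_bin}
#'   (1-based, inclusive), \code{n_bins}, \code{score}.
#' @export
segment_cbs <- function(values, alpha = 0.01, nperm = 1000L, min_width = 2L) {
  N <- length(values)
  if (N < 1L) stop("need at least one value to segment")
  boundaries <- c(0L, N)
  stack <- list(c(1L, N))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    x <- values[lo:hi]
    if (length(x) < 2L * min_width) next
    pairs <- cbs_pairs(length(x), min_width)
    ms <- cbs_max_stat(x, pairs)
    if (ms$stat <= 0) next
    if (!cbs_perm_signif(x, ms$stat, alpha, nperm, min_width, pairs)) next
    cuts <- c(ms$i, ms$j)
    cuts <- cuts[cuts > 0L & cuts < length(x)]
    if (!length(cuts)) next
    pieces <- c(lo - 1L, lo - 1L + cuts, hi)
    boundaries <- union(boundaries, lo - 1L + cuts)
    for (p in seq_len(length(pieces) - 1L)) {
      stack[[length(stack) + 1L]] <- c(pieces[p] + 1L, pieces[p + 1L])
    }
  }
  boundaries <- sort(boundaries)
  starts <- boundaries[-length(boundaries)] + 1L
  ends <- boundaries[-1L]
  data.frame(start_bin = starts, end_bin = ends,
             n_bins = ends - starts + 1L,
             score = vapply(seq_along(starts), function(s) {
               mean(values[starts[s]:ends[s]])
             }, numeric(1L)))
}

#' Segment delta_a genome-wide into SCNA scores
#'
#' Runs [segment_cbs()] per chromosome on the per-bin delta_a table and
#' attaches genomic coordinates from the bin spans.
#'
#' @param delta per-bin table from [compute_delta_a()].
#' @param bins the retained bin table (same order as \code{delta}).
#' @inheritParams segment_cbs
#' @return data.frame of segments: \code{chrom}, \code{start0},
#'   \code{end0}, \code{n_bins}, \code{score}.
#' @export
score_scna <- function(delta, bins, alpha = 0.01, nperm = 1000L,
                       min_width = 2L) {
  bins <- bins[match(delta$bin_id, bins$bin_id), , drop = FALSE]
  out <- lapply(unique(delta$chrom), function(cc) {
    sel <- delta$chrom == cc
    segs <- segment_cbs(delta$delta_a[sel], alpha, nperm, min_width)
    b <- bins[sel, , drop = FALSE]
    data.frame(chrom = cc, start0 = b$start0[segs$start_bin],
               end0 = b$end0[segs$end_bin], n_bins = segs$n_bins,
               score = segs$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' SCNA score of the segment overlapping a gene's promoter
#'
#' A gene is assigned to the segment overlapping its promoter
#' (TSS +/- 1500 bp).  If the promoter spans a breakpoint, the segment
#' containing the TSS wins.  Genes whose promoter overlaps no segment
#' get \code{NA} (untested).
#'
#' @param models a [gene_models()] object.
#' @param segments segment table from [score_scna()] (one sample).
#' @return named numeric vector of SCNA scores per gene (NA = no
#'   overlapping segment).
#' @export
gene_scna_score <- function(models, segments) {
  g <- models$genes
  out <- rep(NA_real_, nrow(g))
  names(out) <- g$gene_id
  for (k in seq_len(nrow(g))) {
    seg <- segments[segments$chrom == g$chrom[k], , drop = FALSE]
    if (!nrow(seg)) next
    ov <- seg$start0 < g$promoter_end0[k] & seg$end0 > g$promoter_start0[k]
    if (!any(ov)) next
    hit <- which(ov)
    if (length(hit) > 1L) {
      with_tss <- hit[seg$start0[hit] <= g$tss0[k] & g$tss0[k] < seg$end0[hit]]
      if (length(with_tss)) hit <- with_tss[1L]
      else hit <- hit[which.max(pmin(seg$end0[hit], g$promoter_end0[k]) -
                                  pmax(seg$start0[hit], g$promoter_start0[k]))]
    }
    out[k] <- seg$score[hit[1L]]
  }
  out
}

#' Does an SCNA score indicate a copy-number alteration?
#'
#' Applies the SCNA-score threshold (default 0.09).  Missing scores
#' (gene untested, no overlapping segment) propagate as \code{NA} so
#' callers can distinguish "no SCNA" from "not testable".
#'
#' @param score numeric vector of SCNA scores (NA allowed).
#' @param threshold decision threshold (default 0.09).
#' @return logical vector (NA where the score is missing).
#' @export
has_scna <- function(score, threshold = 0.09) {
  score >= threshold
}
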