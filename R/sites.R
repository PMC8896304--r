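#' Construct a table of heterozygous sites
#'
#' The atomic observation of the model: allele-specific read counts at a
#' heterozygous site, together with the Phred-scaled genotype quality used
#' to derive the genotyping error rate.  Positions are 1-based (VCF
#' convention).
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based integer positions.
#' @param ref_count,alt_count,other_count non-negative integer read counts
#'   matching the reference allele, the alternate allele, and neither.
#' @param gq Phred-scaled genotype quality (non-negative).
#' @return a \code{data.frame} with one row per site and an \code{n}
#'   column (\code{ref_count + alt_count}).
#' @export
het_sites <- function(chrom, pos, ref_count, alt_count,
                      other_count = 0L, gq = 99) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref_count = as.integer(ref_count),
                  alt_count = as.integer(alt_count),
                  other_count = as.integer(rep_len(other_count, length(pos))),
                  gq = as.numeric(rep_len(gq, length(pos))),
                  stringsAsFactors = FALSE)
  validate_het_sites(x)
  x$n <- x$ref_count + x$alt_count
  x
}

validate_het_sites <- function(x) {
  req <- c("chrom", "pos", "ref_count", "alt_count", "other_count", "gq")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing het-site columns: ", paste(miss, collapse = ", "))
  counts <- c(x$ref_count, x$alt_count, x$other_count)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("read counts must be non-negative and non-missing")
  }
  if (any(x$gq < 0)) stop("genotype quality must be non-negative")
  invisible(x)
}

## ensure an 'n' column exists
with_n <- function(sites) {
  if (is.null(sites$n)) sites$n <- sites$ref_count + sites$alt_count
  sites
}

#' Model parameters for the allelic-imbalance likelihood
#'
#' Bundles the genome-wide nuisance parameters: the beta-binomial
#' concentration \code{dispersion} and, in the RNA context, the
#' sequencing error rate \code{seq_error} used by the genotyping-error
#' mixture.  DNA-context parameters carry no sequencing error and the
#' likelihood uses the pure beta-binomial form.
#'
#' @param dispersion positive beta-binomial concentration.
#' @param seq_error sequencing error rate in (0, 0.5); required for the
#'   RNA context, ignored for DNA.
#' @param context \code{"DNA"} or \code{"RNA"}.
#' @return an object of class \code{"model_params"}.
#' @export
model_params <- function(dispersion, seq_error = NULL,
                         context = c("DNA", "RNA")) {
  context <- match.arg(context)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0) {
    stop("'dispersion' must be a single positive number")
  }
  if (context == "RNA") {
    if (is.null(seq_error)) stop("RNA context requires 'seq_error'")
    if (seq_error <= 0 || seq_error >= 0.5) {
      stop("'seq_error' must be in (0, 0.5)")
    }
  }
  structure(list(dispersion = dispersion, seq_error = seq_error,
                 context = context),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Allelic-imbalance model parameters (%s context)\n", x$context))
  cat(sprintf("  dispersion d = %.4g\n", x$dispersion))
  if (!is.null(x$seq_error)) {
    cat(sprintf("  sequencing error rate = %.3g\n", x$seq_error))
  }
  if (!is.null(x$n_sites)) cat(sprintf("  estimated from %d sites\n", x$n_sites))
  invisible(x)
}
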