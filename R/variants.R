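#' Site filter thresholds
#'
#' Defaults reproduce the hard filter applied to GATK short-variant
#' calls in this analysis: depth > 40, QD > 2, FS < 60, MQ > 40, all
#' comparisons strict.
#'
#' @param min_depth Exclusive lower bound on site depth (reads).
#' @param min_qd Exclusive lower bound on quality-by-depth.
#' @param max_fs Exclusive upper bound on the strand-bias phred score.
#' @param min_mq Exclusive lower bound on mapping quality.
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(min_depth = 40, min_qd = 2,
                              max_fs = 60, min_mq = 40) {
  vals <- c(min_depth, min_qd, max_fs, min_mq)
  if (!all(is.finite(vals))) stop_param("thresholds must be finite")
  structure(list(min_depth = min_depth, min_qd = min_qd,
                 max_fs = max_fs, min_mq = min_mq),
            class = "filter_thresholds")
}

#' Filter variant sites on depth and call-quality annotations
#'
#' Retains exactly the sites with `DP > min_depth`, `QD > min_qd`,
#' `FS < max_fs` and `MQ > min_mq` (strict inequalities). Sites missing
#' an annotation are removed under the default `"strict"` policy
#' (fail-closed) and retained under `"permissive"` provided no present
#' annotation fails. Order-preserving and idempotent.
#'
#' @param sites Data frame from [read_vcf()].
#' @param thresholds A [filter_thresholds()].
#' @param missing Annotation policy: `"strict"` or `"permissive"`.
#' @param quiet Suppress the removed-site count message.
#' @return The retained subset of `sites`.
#' @export
filter_variants <- function(sites, thresholds = filter_thresholds(),
                            missing = c("strict", "permissive"),
                            quiet = TRUE) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  missing <- match.arg(missing)
  if (nrow(sites) == 0) return(sites)
  cmp <- cbind(sites$dp > thresholds$min_depth,
               sites$qd > thresholds$min_qd,
               sites$fs < thresholds$max_fs,
               sites$mq > thresholds$min_mq)
  if (missing == "strict") cmp[is.na(cmp)] <- FALSE else
    cmp[is.na(cmp)] <- TRUE
  keep <- rowSums(cmp) == 4L
  if (!quiet)
    message(sum(!keep), " of ", length(keep), " sites removed by filter")
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most-abundant-alternate allele frequency of a site
#'
#' The per-site allele frequency used throughout: the read fraction of
#' the most abundant non-reference allele, `max(AD[alts]) / sum(AD)`.
#' Ties between alternates are broken toward the lowest allele index.
#' A frequency of 0.5 is the signature of one alternate allele in two
#' copies (diploid heterozygote); 1/3 or 2/3 indicate a triploid region;
#' 1/4, 1/2, 3/4 a tetraploid one; ~1 a homozygous or single-copy region.
#'
#' @param ad Integer vector of allele depths (reference first), or a
#'   data frame from [read_vcf()] (vectorized over rows).
#' @return Numeric frequency in `[0, 1]` (vector for data-frame input).
#' @export
alt_allele_frequency <- function(ad) {
  if (is.data.frame(ad))
    return(vapply(ad$ad, alt_allele_frequency, 1))
  ad <- as.numeric(ad)
  if (length(ad) < 2) stop_param("AD must hold a reference and >= 1 alternate")
  tot <- sum(ad)
  if (tot <= 0) stop_param("undefined allele frequency: sum(AD) = 0")
  max(ad[-1]) / tot  # max() takes the first (lowest-index) maximum
}
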