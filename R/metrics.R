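#' Covered proportion of a subgenome
#'
#' Length-weighted fraction of a subgenome's nuclear positions lying in
#' depth bins with mean depth at or above `min_depth`. This is the
#' "proportion of nucleotides covered" statistic used to establish which
#' subgenomes a strain carries; the covered length (Mb) stands in for an
#' assembly-based genome length.
#'
#' @param bins Depth-track data frame (see [read_bedgraph()]).
#' @param subgenome `"Sc"` or `"Se"`.
#' @param min_depth Minimum mean bin depth (reads) to count as covered.
#' @return List with `proportion` (fraction in `[0, 1]`) and
#'   `covered_mb` (covered length, Mb).
#' @export
covered_proportion <- function(bins, subgenome, min_depth = 1) {
  if (min_depth < 0) stop_param("min_depth must be >= 0")
  b <- bins[bins$subgenome == subgenome & !is_mito_contig(bins$chrom), ,
            drop = FALSE]
  if (nrow(b) == 0)
    stop_param("no depth bins for subgenome ", subgenome)
  w <- b$end - b$start
  covered <- sum(w[b$depth >= min_depth])
  list(proportion = covered / sum(w), covered_mb = covered / 1e6)
}

#' Se/Sc mapping ratio
#'
#' Ratio of the Se covered proportion to the Sc covered proportion.
#' Near-zero ratios indicate a pure Sc strain, very large or infinite
#' ratios a pure Se strain, and ratios near 1 a hybrid carrying both
#' subgenomes.
#'
#' @param prop_se,prop_sc Covered proportions in `[0, 1]`.
#' @return Numeric ratio; `Inf` when only Se signal exists.
#' @export
mapping_ratio <- function(prop_se, prop_sc) {
  stopifnot(prop_se >= 0, prop_se <= 1, prop_sc >= 0, prop_sc <= 1)
  if (prop_sc == 0 && prop_se == 0)
    stop_param("no coverage signal on either subgenome")
  if (prop_sc == 0) return(Inf)
  prop_se / prop_sc
}

#' Call the mitotype from mitochondrial coverage dominance
#'
#' Mitochondria are uniparentally inherited, so one mitochondrial contig
#' should dominate coverage overwhelmingly. The call requires
#' `fold_threshold`-fold dominance; anything less is `"ambiguous"`.
#'
#' @param cov_sc,cov_se Mean coverage of each subgenome's mitochondrial
#'   contig (reads).
#' @param fold_threshold Required coverage dominance (> 1).
#' @return `"Sc"`, `"Se"`, or `"ambiguous"`.
#' @export
call_mitotype <- function(cov_sc, cov_se, fold_threshold = 5) {
  if (cov_sc < 0 || cov_se < 0) stop_param("coverages must be >= 0")
  if (fold_threshold <= 1) stop_param("fold_threshold must be > 1")
  if (cov_sc == 0 && cov_se == 0) {
    warning("no mitochondrial coverage on either subgenome", call. = FALSE)
    return("ambiguous")
  }
  if (cov_sc >= fold_threshold * cov_se) return("Sc")
  if (cov_se >= fold_threshold * cov_sc) return("Se")
  "ambiguous"
}

#' Per-subgenome coverage summary for one strain
#'
#' Combines covered proportions, the Se/Sc mapping ratio, mitochondrial
#' coverages, and the mitotype call into one summary row.
#'
#' @param bins Depth-track data frame including the mitochondrial
#'   contigs.
#' @param sample Sample name.
#' @param min_depth Covered-position depth cutoff (reads).
#' @param fold_threshold Mitotype dominance threshold.
#' @return A `subgenome_summary`: list with `sample`, `prop_sc`,
#'   `prop_se`, `ratio`, `covered_sc_mb`, `covered_se_mb`,
#'   `mito_cov_sc`, `mito_cov_se`, `mitotype`.
#' @export
subgenome_summary <- function(bins, sample = "sample", min_depth = 1,
                              fold_threshold = 5) {
  sc <- covered_proportion(bins, "Sc", min_depth)
  se <- covered_proportion(bins, "Se", min_depth)
  mito <- bins[is_mito_contig(bins$chrom), , drop = FALSE]
  mito_cov <- vapply(c(Sc = "Sc", Se = "Se"), function(sg) {
    m <- mito[mito$subgenome == sg, , drop = FALSE]
    if (nrow(m) == 0) 0 else
      sum(m$depth * (m$end - m$start)) / sum(m$end - m$start)
  }, 1)
  ratio <- if (sc$proportion == 0 && se$proportion == 0) NA_real_ else
    mapping_ratio(se$proportion, sc$proportion)
  structure(list(
    sample = sample,
    prop_sc = sc$proportion, prop_se = se$proportion, ratio = ratio,
    covered_sc_mb = sc$covered_mb, covered_se_mb = se$covered_mb,
    mito_cov_sc = unname(mito_cov["Sc"]),
    mito_cov_se = unname(mito_cov["Se"]),
    mitotype = call_mitotype(mito_cov[["Sc"]], mito_cov[["Se"]],
                             fold_threshold)
  ), class = "subgenome_summary")
}

#' @export
print.subgenome_summary <- function(x, ...) {
  cat(sprintf(
    "Subgenome summary for %s\n  covered: Sc %.3f (%.2f Mb), Se %.3f (%.2f Mb)\n  Se/Sc mapping ratio: %s\n  mito coverage: Sc %.1f, Se %.1f -> mitotype %s\n",
    x$sample, x$prop_sc, x$covered_sc_mb, x$prop_se, x$covered_se_mb,
    format(x$ratio, digits = 3), x$mito_cov_sc, x$mito_cov_se,
    x$mitotype))
  invisible(x)
}

#' @rdname subgenome_summary
#' @param x A `subgenome_summary`.
#' @param ... Unused.
#' @export
as.data.frame.subgenome_summary <- function(x, ...) {
  data.frame(sample = x$sample, prop_sc = x$prop_sc, prop_se = x$prop_se,
             ratio = x$ratio, covered_sc_mb = x$covered_sc_mb,
             covered_se_mb = x$covered_se_mb,
             mito_cov_sc = x$mito_cov_sc, mito_cov_se = x$mito_cov_se,
             mitotype = x$mitotype, stringsAsFactors = FALSE)
}
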