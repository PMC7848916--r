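#' Simulate observed variant sites for one allele-copy configuration
#'
#' Minimal generator for allele-frequency modality experiments: `n`
#' variant sites on a region of known copy number where `alt_copies` of
#' the `copy` chromosome copies carry the alternate allele. Depths are
#' `DP ~ Poisson(mean_dp)` and alternate depths binomial with success
#' probability `alt_copies / copy` perturbed by a symmetric error
#' leakage, the same observation model as [simulate_observed()].
#'
#' @param n Number of sites.
#' @param copy Chromosome copy number (>= 1).
#' @param alt_copies Copies carrying the alternate allele (1..copy).
#' @param mean_dp Mean site depth in reads.
#' @param error_rate Symmetric base-error leakage.
#' @param seed Integer seed.
#' @param chrom Contig name for the emitted records.
#' @return VCF-shaped data frame (as from [read_vcf()]); sites drawn
#'   with depth 0 are dropped, so it can hold slightly fewer than `n`
#'   rows.
#' @export
simulate_af_sites <- function(n, copy, alt_copies, mean_dp = 100,
                              error_rate = 0.002, seed = 1L,
                              chrom = "Sc_chrI") {
  stopifnot(n >= 1, copy >= 1, alt_copies >= 1, alt_copies <= copy,
            mean_dp > 0)
  set.seed(derive_seed(seed, "afsites", copy, alt_copies))
  f <- alt_copies / copy
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  dp <- rpois(n, mean_dp)
  x <- rbinom(n, dp, p)
  keep <- dp > 0
  dp <- dp[keep]; x <- x[keep]
  out <- data.frame(
    subgenome = contig_subgenome(chrom), chrom = chrom,
    pos = seq_along(dp) * 100L, ref = "A", alt = "T",
    gt = if (alt_copies == copy) "1/1" else "0/1",
    dp = dp, qd = 25, fs = 1, mq = 60, stringsAsFactors = FALSE
  )
  out$ad <- I(lapply(seq_along(dp), function(j) c(dp[j] - x[j], x[j])))
  out
}
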