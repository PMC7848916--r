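#' Simulate the observable data for a hybrid: VCF records and depth track
#'
#' Produces the two observables the downstream inference consumes, at the
#' variant/pileup level (alignment is upstream and not modeled):
#' \itemize{
#'   \item variant records for every truth site the hybrid inherited at
#'     least one alternate copy of: total depth `DP ~ Poisson(u * c)`
#'     where `u` is the per-copy depth and `c` the chromosome copy
#'     number; allele depths binomial in `DP` with success probability
#'     equal to the true allele-copy fraction perturbed by a symmetric
#'     base-error leakage `error_rate`;
#'   \item a binned depth track (bedGraph semantics: 0-based half-open):
#'     per bin, depth normal with mean `u * c` and standard deviation
#'     `sqrt(u * c) / sqrt(bin_width / read_scale)`, truncated at zero.
#'     Deleted chromosomes and the non-inherited mitochondrial contig
#'     receive only error-rate leakage; the inherited mitochondrial
#'     contig gets `u * mito_depth_multiplier`.
#' }
#'
#' @param truth A `truth_set` from [mate()].
#' @param refs The `reference_pair` (chromosome lengths).
#' @param per_copy_depth Mean reads contributed by one chromosome copy.
#' @param mito_depth_multiplier Mitochondrial depth relative to one
#'   nuclear copy (mitochondria are high-copy organelles).
#' @param bin_width Depth bin width in bp (>= 1000).
#' @param error_rate Symmetric base-error leakage fraction.
#' @param seed Integer seed.
#' @param exact If `TRUE`, suppress all noise: `DP = u * c` exactly,
#'   `AD = round(f * DP)`, bin depth exactly `u * c`. Used for oracle
#'   tests of the inference layer.
#' @param read_scale Effective read length used to scale bin-level noise.
#' @param sample Sample name recorded in outputs.
#' @param dir Optional directory; when given, `"<sample>.vcf"` and
#'   `"<sample>.bedGraph"` are written there.
#' @return An `observed_hybrid`: list with `sites` (VCF-shaped data
#'   frame), `bins` (depth track data frame: `subgenome`, `chrom`,
#'   `start`, `end`, `depth`), `mito_coverage` (named numeric, mean depth
#'   of each subgenome's mitochondrial contig), `sample`, and (if `dir`
#'   was given) `vcf` / `bedgraph` paths.
#' @export
simulate_observed <- function(truth, refs, per_copy_depth = 50,
                              mito_depth_multiplier = 20,
                              bin_width = 10000, error_rate = 0.002,
                              seed = 1L, exact = FALSE,
                              read_scale = 150, sample = "hybrid",
                              dir = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(refs, "reference_pair"))
  if (per_copy_depth <= 0) stop_param("per_copy_depth must be > 0")
  if (bin_width < 1000) stop_param("bin_width must be >= 1 kb")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_param("error_rate must lie in [0, 0.5)")
  set.seed(derive_seed(seed, "observe", sample))
  u <- per_copy_depth
  leak <- u * error_rate

  ## variant records
  ts <- truth$sites[truth$sites$alt_copies >= 1 & truth$sites$copy >= 1, ,
                    drop = FALSE]
  n <- nrow(ts)
  if (n > 0) {
    f <- ts$alt_copies / ts$copy
    p <- f * (1 - error_rate) + (1 - f) * error_rate
    if (exact) {
      dp <- as.integer(round(u * ts$copy))
      x <- as.integer(round(f * dp))
    } else {
      dp <- rpois(n, u * ts$copy)
      x <- rbinom(n, dp, p)
    }
    keep <- dp > 0
    ts <- ts[keep, , drop = FALSE]
    dp <- dp[keep]; x <- x[keep]
    sites <- data.frame(
      subgenome = ts$subgenome, chrom = ts$chrom, pos = ts$pos,
      ref = ts$ref, alt = ts$alt,
      gt = ifelse(ts$alt_copies == ts$copy, "1/1", "0/1"),
      dp = dp,
      qd = if (exact) rep(25, length(dp)) else round(runif(length(dp), 15, 30), 2),
      fs = if (exact) rep(1, length(dp)) else round(runif(length(dp), 0, 5), 3),
      mq = if (exact) rep(60, length(dp)) else round(runif(length(dp), 50, 60), 2),
      stringsAsFactors = FALSE
    )
    sites$ad <- I(lapply(seq_along(dp), function(j)
      c(dp[j] - x[j], x[j])))
  } else {
    sites <- data.frame(subgenome = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), gt = character(),
                        dp = integer(), qd = numeric(), fs = numeric(),
                        mq = numeric(), ad = I(list()))
  }

  ## depth track
  copy_of <- setNames(truth$copy_number$copy, truth$copy_number$chrom)
  bin_rows <- list()
  for (i in seq_len(nrow(refs$chromosomes))) {
    chrom <- refs$chromosomes$chrom[i]
    sg <- refs$chromosomes$subgenome[i]
    L <- refs$chromosomes$length[i]
    mito <- refs$chromosomes$is_mito[i]
    starts <- seq(0L, L - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, L)
    nb <- length(starts)
    mean_d <- if (mito) {
      if (sg == truth$mitotype) u * mito_depth_multiplier else leak
    } else {
      cc <- unname(copy_of[chrom])
      if (is.na(cc) || cc == 0) leak else u * cc
    }
    if (exact) {
      depth <- rep(mean_d, nb)
    } else if (mean_d <= leak + 1e-12) {
      depth <- pmax(0, rnorm(nb, leak, sqrt(leak + 1e-9)))
    } else {
      sd_bin <- sqrt(mean_d) / sqrt(bin_width / read_scale)
      depth <- pmax(0, rnorm(nb, mean_d, sd_bin))
    }
    bin_rows[[length(bin_rows) + 1L]] <- data.frame(
      subgenome = sg, chrom = chrom, start = starts, end = ends,
      depth = round(depth, 3), stringsAsFactors = FALSE
    )
  }
  bins <- do.call(rbind, bin_rows)
  rownames(bins) <- NULL

  mito_bins <- bins[is_mito_contig(bins$chrom), ]
  mito_coverage <- vapply(c(Sc = "Sc", Se = "Se"), function(sg)
    mean(mito_bins$depth[mito_bins$subgenome == sg]), 1)

  out <- structure(
    list(sites = sites, bins = bins, mito_coverage = mito_coverage,
         sample = sample, seed = seed,
         params = list(per_copy_depth = per_copy_depth,
                       mito_depth_multiplier = mito_depth_multiplier,
                       bin_width = bin_width, error_rate = error_rate,
                       exact = exact)),
    class = "observed_hybrid"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$vcf <- file.path(dir, paste0(sample, ".vcf"))
    out$bedgraph <- file.path(dir, paste0(sample, ".bedGraph"))
    write_vcf(sites, out$vcf, sample = sample, refs = refs)
    write_bedgraph(bins, out$bedgraph)
  }
  out
}
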