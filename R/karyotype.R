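#' Estimate the per-copy sequencing depth unit
#'
#' A chromosome carried in `c` copies sequences to a mean bin depth of
#' `c * u`, where `u` is the depth contributed by one copy (a haploid
#' region shows half the depth of a diploid one, a tetraploid region
#' double). `u` is estimated by grid search over candidates in
#' `[max(depth)/8, max(depth)]`, maximizing a quantization score: the
#' mean over nonzero bins of `exp(-(d/u - round(d/u))^2 / (2 sigma^2))`
#' with `round(d/u)` restricted to `[1, max_copy]`. Ties are broken
#' toward the largest `u` (fewest copies), so a genome with a single
#' depth level is read as single-copy.
#'
#' @param bins Depth-track data frame, or a numeric vector of bin
#'   depths. Mitochondrial bins are excluded automatically.
#' @param sigma Width (in copy units) of the quantization kernel.
#' @param max_copy Copy-number ceiling (guards against degenerate small
#'   `u`).
#' @param n_grid Number of grid candidates (exact divisors of the
#'   maximum depth are always included).
#' @return Estimated per-copy depth `u` (> 0).
#' @export
estimate_per_copy_depth <- function(bins, sigma = 0.15, max_copy = 8,
                                    n_grid = 512) {
  d <- if (is.data.frame(bins))
    bins$depth[!is_mito_contig(bins$chrom)] else as.numeric(bins)
  d <- d[d > 0]
  if (length(d) == 0) stop_param("no nonzero depth bins: no signal")
  if (length(d) < 20)
    warning("fewer than 20 nonzero bins; per-copy depth estimate is weak",
            call. = FALSE)
  hi <- max(d)
  lo <- hi / max_copy
  cand <- sort(unique(c(seq(lo, hi, length.out = n_grid),
                        hi / seq_len(max_copy))))
  cand <- cand[cand >= lo - 1e-9]
  score <- vapply(cand, function(u) {
    k <- pmin(pmax(round(d / u), 1), max_copy)
    mean(exp(-(d / u - k)^2 / (2 * sigma^2)))
  }, 1)
  best <- max(score)
  # tie-break toward larger u among (numerically) maximal scores
  max(cand[score >= best - 1e-9])
}

#' Scale a depth track to \[0, 1\] for display
#'
#' Divides bin depths by a robust maximum (the 99.5th percentile) and
#' clips to 1, the scaling used for depth panels in karyotype plots.
#' For reporting only; inference uses raw depths.
#'
#' @param bins Depth-track data frame or numeric depth vector.
#' @return Numeric vector of scaled depths in `[0, 1]`.
#' @export
scaled_depth <- function(bins) {
  d <- if (is.data.frame(bins)) bins$depth else as.numeric(bins)
  if (length(d) == 0) stop_param("empty depth track")
  m <- quantile(d, 0.995, names = FALSE, type = 7)
  if (m <= 0) return(rep(0, length(d)))
  pmin(d / m, 1)
}

# canonical allele-frequency peak sets by implied allele count
canonical_af_sets <- list(
  "1" = 1,
  "2" = 1 / 2,
  "3" = c(1 / 3, 2 / 3),
  "4" = c(1 / 4, 1 / 2, 3 / 4)
)

#' Allele-frequency peak profile of a region
#'
#' Histograms the per-site most-abundant-alternate allele frequencies of
#' a region (bin width 0.02 on (0, 1]), smooths with a 3-bin moving
#' average, and keeps local maxima whose 3-bin mass is at least 10% of
#' the region's sites. Detected peaks are then matched against the
#' canonical sets `{1}`, `{1/2}`, `{1/3, 2/3}`, `{1/4, 1/2, 3/4}` —
#' the uni-, bi- and trimodal signatures of copy number 2, 3 and 4 and
#' the near-1 signature of homozygous or single-copy regions — choosing
#' the set that minimizes total matching distance with every peak and
#' every set member matched within ±0.05. A near-1 peak can coexist with
#' a heterozygous set (homozygous sites occur at any copy number) and
#' does not veto the match.
#'
#' @param af Numeric vector of allele frequencies (see
#'   [alt_allele_frequency()]), or a sites data frame.
#' @param min_sites Minimum informative sites; below it the profile is
#'   `none`.
#' @param binwidth Histogram bin width.
#' @param peak_mass Minimum fraction of sites in a peak's 3-bin window.
#' @param tolerance Peak-to-canonical matching tolerance.
#' @return An `af_peak_profile`: list with `peaks` (detected positions),
#'   `canonical` (matched set or `NULL`), `label` (`"1"`, `"1/2"`,
#'   `"1/3,2/3"`, `"1/4,1/2,3/4"` or `"none"`), and `n_sites`.
#' @export
af_peak_profile <- function(af, min_sites = 20, binwidth = 0.02,
                            peak_mass = 0.10, tolerance = 0.05) {
  if (is.data.frame(af)) af <- alt_allele_frequency(af)
  af <- af[!is.na(af) & af > 0 & af <= 1]
  n <- length(af)
  none <- structure(list(peaks = numeric(0), canonical = NULL,
                         label = "none", n_sites = n),
                    class = "af_peak_profile")
  if (n < min_sites) return(none)

  breaks <- seq(0, 1, by = binwidth)
  counts <- tabulate(pmin(ceiling(af / binwidth), length(breaks) - 1),
                     nbins = length(breaks) - 1)
  centers <- breaks[-1] - binwidth / 2
  nb <- length(counts)
  # 3-bin moving average; edge bins average over the available window
  sm <- vapply(seq_len(nb), function(i) {
    w <- max(1, i - 1):min(nb, i + 1)
    mean(counts[w])
  }, 1)
  peaks <- numeric(0)
  i <- 1
  while (i <= nb) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < nb) sm[i + 1] else -Inf
    w <- max(1, i - 1):min(nb, i + 1)
    mass <- sum(counts[w])
    if (sm[i] >= left && sm[i] >= right && counts[i] > 0 &&
        mass >= peak_mass * n) {
      peaks <- c(peaks, sum(centers[w] * counts[w]) / mass)
      i <- i + 2  # skip the right neighbour: one peak per plateau
    } else {
      i <- i + 1
    }
  }
  if (length(peaks) == 0) return(none)

  hom <- any(peaks >= 0.95)
  het <- peaks[peaks < 0.95]
  if (length(het) == 0) {
    if (!hom) return(none)
    return(structure(list(peaks = peaks, canonical = 1, label = "1",
                          n_sites = n), class = "af_peak_profile"))
  }
  # a set is eligible when every detected heterozygous peak matches one
  # of its members within tolerance; unmatched members are allowed (a
  # triploid region may show only its 1/3 peak when every site carries a
  # single alternate copy). Ties go to the set with fewest alleles.
  best <- NULL
  for (lbl in c("2", "3", "4")) {
    set <- canonical_af_sets[[lbl]]
    d_peak <- vapply(het, function(p) min(abs(p - set)), 1)
    if (any(d_peak > tolerance)) next
    total <- sum(d_peak)
    if (is.null(best) || total < best$total - 1e-12)
      best <- list(set = set, label = lbl, total = total)
  }
  if (is.null(best)) return(structure(
    list(peaks = peaks, canonical = NULL, label = "none", n_sites = n),
    class = "af_peak_profile"))
  label <- paste(c("2" = "1/2", "3" = "1/3,2/3",
                   "4" = "1/4,1/2,3/4")[best$label])
  structure(list(peaks = peaks, canonical = best$set, label = label,
                 n_sites = n), class = "af_peak_profile")
}

#' @export
print.af_peak_profile <- function(x, ...) {
  cat(sprintf("AF peak profile: %d sites, peaks at %s, canonical set %s\n",
              x$n_sites,
              if (length(x$peaks)) paste(round(x$peaks, 3), collapse = ", ")
              else "-", x$label))
  invisible(x)
}

# copy numbers compatible with a matched canonical AF set; NULL = any
af_implied_copies <- function(label) {
  switch(label,
         "1" = NULL,            # homozygous regions occur at any copy number
         "1/2" = c(2L, 4L),
         "1/3,2/3" = c(3L, 6L),
         "1/4,1/2,3/4" = 4L,
         "none" = NULL)
}

#' Infer a chromosome's integer copy number
#'
#' Combines the depth evidence (modal bin depth quantized by the
#' per-copy unit `u`) with the allele-frequency peak profile. Depth
#' takes precedence: the ambiguity of AF signatures (0.5 fits diploid or
#' tetraploid; AF ~ 1 fits homozygous or haploid) is resolved by depth,
#' and the call is `round(modal_depth / u)` clipped to `[0, 8]`. The
#' agreement flag records whether the AF profile is consistent with that
#' call; disagreement lowers confidence but never changes the call.
#'
#' @param profile An [af_peak_profile()] for the chromosome.
#' @param modal_depth Typical (modal) bin depth of the chromosome; `NA`
#'   or near zero means a whole-chromosome deletion.
#' @param u Per-copy depth unit from [estimate_per_copy_depth()].
#' @param max_copy Copy ceiling.
#' @param deletion_frac Depths below `deletion_frac * u` are deletions.
#' @return A `copy_number_call`: list with `copy`, `modal_depth`, `u`,
#'   `af_label`, `agreement`, `confidence`.
#' @export
infer_copy_number <- function(profile, modal_depth, u, max_copy = 8,
                              deletion_frac = 0.25) {
  stopifnot(u > 0)
  lab <- if (inherits(profile, "af_peak_profile")) profile$label else "none"
  if (is.na(modal_depth) || modal_depth < deletion_frac * u) {
    return(structure(list(copy = 0L, modal_depth = modal_depth, u = u,
                          af_label = lab, agreement = TRUE,
                          confidence = "high"),
                     class = "copy_number_call"))
  }
  c_d <- min(max(round(modal_depth / u), 0L), max_copy)
  c_af <- af_implied_copies(lab)
  agreement <- is.null(c_af) || c_d %in% c_af
  structure(list(copy = as.integer(c_d), modal_depth = modal_depth,
                 u = u, af_label = lab, agreement = agreement,
                 confidence = if (agreement) "high" else "low"),
            class = "copy_number_call")
}

# typical bin depth of one chromosome: median over its bins (robust to a
# minority of CNV bins; chromosomes are called at whole-chromosome level)
modal_bin_depth <- function(depths) {
  if (length(depths) == 0) return(NA_real_)
  median(depths)
}

#' Summarize per-chromosome calls into a karyotype
#'
#' Computes the modal copy number of each subgenome (mode over its
#' chromosomes, ties toward the smaller value), the karyotype ratio
#' string `"Sc:Se"`, the ploidy (modal Sc + modal Se, reported as e.g.
#' `"4N"`), and the duplication/deletion lists relative to each
#' subgenome's modal copy number.
#'
#' @param calls Data frame with one row per chromosome: `subgenome`,
#'   `chrom`, `copy` (plus any evidence columns, carried through).
#' @param u Per-copy depth used (recorded).
#' @return A `karyotype_result`: list with `calls`, `modal_sc`,
#'   `modal_se`, `ratio`, `ploidy`, `duplications`, `deletions`, `u`.
#' @export
call_karyotype <- function(calls, u = NA_real_) {
  stopifnot(all(c("subgenome", "chrom", "copy") %in% names(calls)))
  if (anyDuplicated(calls$chrom))
    stop_param("each chromosome must appear exactly once")
  modal <- vapply(c(Sc = "Sc", Se = "Se"), function(sg) {
    cc <- calls$copy[calls$subgenome == sg]
    if (length(cc) == 0) return(0L)
    tab <- table(cc)
    as.integer(min(as.integer(names(tab)[tab == max(tab)])))
  }, 1L)
  calls$modal <- modal[calls$subgenome]
  dup <- calls[calls$copy > calls$modal, c("subgenome", "chrom", "copy")]
  del <- calls[calls$copy < calls$modal, c("subgenome", "chrom", "copy")]
  del$full_deletion <- del$copy == 0L
  rownames(dup) <- rownames(del) <- NULL
  structure(list(
    calls = calls,
    modal_sc = unname(modal["Sc"]), modal_se = unname(modal["Se"]),
    ratio = sprintf("%d:%d", modal["Sc"], modal["Se"]),
    ploidy = sprintf("%dN", modal["Sc"] + modal["Se"]),
    duplications = dup, deletions = del, u = u
  ), class = "karyotype_result")
}

#' @export
print.karyotype_result <- function(x, ...) {
  cat(sprintf("Karyotype: %s (ploidy %s), per-copy depth %s\n",
              x$ratio, x$ploidy, format(x$u, digits = 4)))
  if (nrow(x$duplications))
    cat("  duplications:",
        paste(x$duplications$chrom, collapse = ", "), "\n")
  if (nrow(x$deletions))
    cat("  deletions:", paste(x$deletions$chrom, collapse = ", "), "\n")
  if (!nrow(x$duplications) && !nrow(x$deletions))
    cat("  no aneuploidies\n")
  invisible(x)
}

#' Infer the full karyotype of a strain
#'
#' End-to-end chromosome copy-number inference: estimates the per-copy
#' depth unit from the whole nuclear depth track, then for every nuclear
#' chromosome combines its AF peak profile (from the filtered variant
#' sites) with its modal bin depth via [infer_copy_number()], and
#' summarizes with [call_karyotype()].
#'
#' Depth quantization fixes copy numbers only up to a global integer
#' factor: a genome whose chromosomes all sit at one depth level is read
#' as single-copy by the depth unit alone, yet its heterozygous AF peaks
#' at 0.5 reveal it is diploid. The absolute scale is therefore anchored
#' by the AF modality: among depth units `u, u/2, u/3, u/4` the one
#' whose per-chromosome depth-implied copies agree with the most AF
#' profiles is used (ties toward the larger unit, i.e. fewer copies).
#' Given the scale, depth still decides every chromosome; disagreements
#' are flagged, never averaged.
#'
#' @param sites Filtered variant data frame (see [filter_variants()]).
#' @param bins Depth-track data frame (mitochondrial bins ignored).
#' @param min_sites Minimum sites for an informative AF profile.
#' @param max_copy Copy-number ceiling.
#' @param ... Passed to [estimate_per_copy_depth()].
#' @return A `karyotype_result`; its `calls` component carries per-
#'   chromosome evidence (`modal_depth`, `u`, `af_label`, `agreement`,
#'   `confidence`, `n_sites`).
#' @export
infer_karyotype <- function(sites, bins, min_sites = 20, max_copy = 8,
                            ...) {
  nuc <- bins[!is_mito_contig(bins$chrom), , drop = FALSE]
  if (nrow(nuc) == 0) stop_param("no nuclear depth bins")
  u0 <- estimate_per_copy_depth(nuc, ...)
  chroms <- unique(nuc$chrom)
  chroms <- chroms[order_chroms(chroms)]
  profiles <- lapply(chroms, function(chrom)
    af_peak_profile(sites[sites$chrom == chrom, , drop = FALSE],
                    min_sites = min_sites))
  modal <- vapply(chroms, function(chrom)
    modal_bin_depth(nuc$depth[nuc$chrom == chrom]), 1)

  # anchor the global scale on AF agreement (heterozygous profiles only)
  af_votes <- function(u) {
    sum(vapply(seq_along(chroms), function(i) {
      c_af <- af_implied_copies(profiles[[i]]$label)
      if (is.null(c_af) || is.na(modal[i])) return(FALSE)
      min(max(round(modal[i] / u), 0), max_copy) %in% c_af
    }, TRUE))
  }
  ks <- Filter(function(k)
    round(max(modal, na.rm = TRUE) / (u0 / k)) <= max_copy, 1:4)
  votes <- vapply(ks, function(k) af_votes(u0 / k), 1)
  u <- u0 / ks[which.max(votes)]  # which.max: first (smallest k) on ties

  rows <- lapply(seq_along(chroms), function(i) {
    chrom <- chroms[i]
    prof <- profiles[[i]]
    cl <- infer_copy_number(prof, modal[i], u)
    data.frame(subgenome = contig_subgenome(chrom), chrom = chrom,
               copy = cl$copy, modal_depth = cl$modal_depth, u = u,
               af_label = cl$af_label, agreement = cl$agreement,
               confidence = cl$confidence, n_sites = prof$n_sites,
               stringsAsFactors = FALSE)
  })
  call_karyotype(do.call(rbind, rows), u = u)
}
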