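#' Private homozygous SNP markers of a parent pair
#'
#' A marker is a site at which one parent is homozygous for an alternate
#' allele (GT 1/1) while the other parent carries only the reference
#' (GT 0/0 or no call at the position). Heterozygous sites in either
#' parent and positions homozygous-alternate in both are excluded.
#' Because each parent is monoallelic at its markers, the marker allele
#' can be traced unambiguously into the hybrid.
#'
#' @param parent_a,parent_b Variant data frames from [read_vcf()] (one
#'   per parent, called against the same chimeric reference).
#' @param name_a,name_b Parent names; default to the VCF sample names.
#' @return Data frame of markers: `subgenome`, `chrom`, `pos`, `parent`
#'   (owner), `allele` (the owner's homozygous alternate base),
#'   `other_allele` (reference base carried by the other parent).
#' @export
private_homozygous_snps <- function(parent_a, parent_b,
                                    name_a = NULL, name_b = NULL) {
  name_a <- name_a %||% attr(parent_a, "sample") %||% "parentA"
  name_b <- name_b %||% attr(parent_b, "sample") %||% "parentB"
  is_hom_alt <- function(gt) gt %in% c("1/1", "1|1")
  is_het <- function(gt) gt %in% c("0/1", "0|1", "1/0", "1|0")
  key <- function(x) paste(x$chrom, x$pos)

  pick <- function(owner, other, owner_name) {
    hom <- owner[is_hom_alt(owner$gt), , drop = FALSE]
    if (nrow(hom) == 0) return(NULL)
    k_hom_other <- key(other[is_hom_alt(other$gt), , drop = FALSE])
    k_het_other <- key(other[is_het(other$gt), , drop = FALSE])
    k <- key(hom)
    keep <- !(k %in% k_hom_other) & !(k %in% k_het_other)
    hom <- hom[keep, , drop = FALSE]
    if (nrow(hom) == 0) return(NULL)
    # first alternate: parents are clean homozygous calls
    allele <- vapply(strsplit(hom$alt, ",", fixed = TRUE), `[`, "", 1)
    data.frame(subgenome = hom$subgenome, chrom = hom$chrom,
               pos = hom$pos, parent = owner_name, allele = allele,
               other_allele = hom$ref, stringsAsFactors = FALSE)
  }
  het_a <- key(parent_a[is_het(parent_a$gt), , drop = FALSE])
  het_b <- key(parent_b[is_het(parent_b$gt), , drop = FALSE])
  out <- rbind(pick(parent_a, parent_b, name_a),
               pick(parent_b, parent_a, name_b))
  if (is.null(out))
    return(data.frame(subgenome = character(), chrom = character(),
                      pos = integer(), parent = character(),
                      allele = character(), other_allele = character()))
  # a site heterozygous in the *owner* was already excluded by is_hom_alt;
  # exclude owner-homozygous sites that are heterozygous in the other
  out <- out[!(paste(out$chrom, out$pos) %in% c(het_a, het_b)), ,
             drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)[
    order_chroms(unique(out$chrom))]), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Parental-allele frequency of markers in a hybrid
#'
#' For each private marker found among the hybrid's variant sites, the
#' frequency is the proportion of reads carrying the parental allele,
#' `AD(parental allele) / sum(AD)`. A marker position absent from the
#' hybrid's variants is evidence of non-inheritance when the position is
#' sequenced: it contributes frequency 0 for the owning parent if its
#' depth bin is covered (depth >= `min_depth`), and is dropped
#' otherwise (e.g. inside a deleted chromosome).
#'
#' @param markers Marker data frame from [private_homozygous_snps()].
#' @param hybrid_sites Filtered hybrid variant data frame.
#' @param bins Hybrid depth track (for coverage of absent positions).
#' @param min_depth Minimum bin depth for an absent marker to count as
#'   covered.
#' @return Data frame: `subgenome`, `chrom`, `pos`, `parent`, `freq`.
#' @export
parental_allele_frequency <- function(markers, hybrid_sites, bins,
                                      min_depth = 1) {
  if (nrow(markers) == 0)
    return(data.frame(subgenome = character(), chrom = character(),
                      pos = integer(), parent = character(),
                      freq = numeric()))
  hk <- paste(hybrid_sites$chrom, hybrid_sites$pos)
  idx <- match(paste(markers$chrom, markers$pos), hk)

  freq <- rep(NA_real_, nrow(markers))
  hit <- !is.na(idx)
  if (any(hit)) {
    freq[hit] <- vapply(which(hit), function(j) {
      i <- idx[j]
      ad <- hybrid_sites$ad[[i]]
      tot <- sum(ad)
      if (tot <= 0) return(NA_real_)
      alts <- strsplit(hybrid_sites$alt[i], ",", fixed = TRUE)[[1]]
      a <- match(markers$allele[j], alts)
      if (is.na(a)) 0 else ad[1 + a] / tot
    }, 1)
  }
  if (any(!hit)) {
    covered <- vapply(which(!hit), function(j) {
      b <- bins[bins$chrom == markers$chrom[j] &
                  bins$start < markers$pos[j] &
                  bins$end >= markers$pos[j], , drop = FALSE]
      nrow(b) > 0 && any(b$depth >= min_depth)
    }, TRUE)
    freq[which(!hit)[covered]] <- 0
  }
  out <- cbind(markers[, c("subgenome", "chrom", "pos", "parent")],
               freq = freq)
  out <- out[!is.na(out$freq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromosome-wide median parental allele frequency
#'
#' The chromosome-level summary used to read off contributed copies: a
#' parent that contributed one of three copies shows a median near 0.33,
#' two of three near 0.66. Chromosomes with fewer than `min_sites`
#' informative markers for a parent are reported `undetermined`.
#'
#' @param freqs Per-site frequencies from [parental_allele_frequency()].
#' @param min_sites Minimum informative markers per chromosome per
#'   parent.
#' @return Data frame: `subgenome`, `chrom`, `parent`, `median_af`,
#'   `n_sites`, `status` (`"determined"` / `"undetermined"`).
#' @export
chromosome_median_frequency <- function(freqs, min_sites = 20) {
  if (nrow(freqs) == 0)
    return(data.frame(subgenome = character(), chrom = character(),
                      parent = character(), median_af = numeric(),
                      n_sites = integer(), status = character()))
  grp <- interaction(freqs$chrom, freqs$parent, drop = TRUE)
  out <- do.call(rbind, lapply(split(freqs, grp), function(g) {
    data.frame(subgenome = g$subgenome[1], chrom = g$chrom[1],
               parent = g$parent[1], median_af = median(g$freq),
               n_sites = nrow(g),
               status = if (nrow(g) >= min_sites) "determined"
                        else "undetermined",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$chrom, unique(out$chrom)[
    order_chroms(unique(out$chrom))]), out$parent), ]
  rownames(out) <- NULL
  out
}

#' Convert parental medians into contributed copy counts
#'
#' Given the chromosome copy number `c` and the two parents'
#' chromosome-wide medians, assigns integer contributions `k_a + k_b =
#' c`. When both medians are determined, `k_a` minimizes the joint
#' inconsistency `|k_a - m_a c| + |(c - k_a) - m_b c|` (independent
#' rounding could violate the sum constraint); ties favour the parent
#' with more informative markers. With one determined median, `k_a =
#' round(m_a c)` clipped to `[0, c]`. Medians deviating more than 0.15
#' from the nearest `k/c` lower confidence to `"low"`.
#'
#' @param median_a,median_b Chromosome-wide medians (`NA` when
#'   undetermined).
#' @param copy Chromosome copy number `c >= 0`.
#' @param n_a,n_b Informative marker counts (tie-breaking).
#' @param max_deviation Median deviation beyond which confidence drops.
#' @return List with `k_a`, `k_b`, `confidence` (`"high"`/`"low"`).
#' @export
assign_contributions <- function(median_a, median_b, copy,
                                 n_a = 0, n_b = 0,
                                 max_deviation = 0.15) {
  if (copy < 0) stop_param("copy number must be >= 0")
  if (is.na(median_a) && is.na(median_b))
    stop_param("at least one parent needs a determined median")
  if (copy == 0) {
    if (max(median_a, median_b, 0, na.rm = TRUE) > 0)
      warning("nonzero parental medians on a deleted chromosome",
              call. = FALSE)
    return(list(k_a = 0L, k_b = 0L, confidence = "low"))
  }
  if (is.na(median_b)) {
    k_a <- min(max(round(median_a * copy), 0L), copy)
  } else if (is.na(median_a)) {
    k_a <- copy - min(max(round(median_b * copy), 0L), copy)
  } else {
    k <- 0:copy
    loss <- abs(k - median_a * copy) + abs((copy - k) - median_b * copy)
    ties <- k[loss <= min(loss) + 1e-9]
    k_a <- if (n_a >= n_b) max(ties) else min(ties)
  }
  k_a <- as.integer(k_a)
  k_b <- as.integer(copy - k_a)
  dev <- max(abs(median_a - k_a / copy), abs(median_b - k_b / copy),
             na.rm = TRUE)
  list(k_a = k_a, k_b = k_b,
       confidence = if (dev > max_deviation) "low" else "high")
}

#' Trace the parental origin of every chromosome of a hybrid
#'
#' Full tracing pipeline: selects private homozygous markers from the
#' two parents, computes their allele frequencies in the hybrid,
#' summarizes chromosome-wide medians, and converts them to contributed
#' copies using the inferred chromosome copy numbers.
#'
#' @param parent_a,parent_b Parent variant data frames ([read_vcf()]).
#' @param hybrid_sites Filtered hybrid variant data frame.
#' @param bins Hybrid depth track.
#' @param copy_calls Data frame with `chrom` and `copy` (e.g. the
#'   `calls` component of [infer_karyotype()]).
#' @param min_sites Minimum informative markers per chromosome.
#' @param min_depth Coverage cutoff for absent-marker evidence.
#' @param name_a,name_b Parent names.
#' @return Data frame with one row per chromosome per parent:
#'   `subgenome`, `chrom`, `parent`, `median_af`, `n_sites`, `copy`,
#'   `copies` (contributed), `status`, `confidence`.
#' @export
trace_parents <- function(parent_a, parent_b, hybrid_sites, bins,
                          copy_calls, min_sites = 20, min_depth = 1,
                          name_a = NULL, name_b = NULL) {
  name_a <- name_a %||% attr(parent_a, "sample") %||% "parentA"
  name_b <- name_b %||% attr(parent_b, "sample") %||% "parentB"
  markers <- private_homozygous_snps(parent_a, parent_b, name_a, name_b)
  freqs <- parental_allele_frequency(markers, hybrid_sites, bins,
                                     min_depth = min_depth)
  med <- chromosome_median_frequency(freqs, min_sites = min_sites)

  chroms <- copy_calls$chrom[order_chroms(copy_calls$chrom)]
  rows <- lapply(chroms, function(chrom) {
    cc <- copy_calls$copy[copy_calls$chrom == chrom]
    g <- med[med$chrom == chrom, , drop = FALSE]
    get <- function(p, col) {
      r <- g[g$parent == p, , drop = FALSE]
      if (nrow(r) == 0) NA else r[[col]][1]
    }
    m_a <- get(name_a, "median_af"); m_b <- get(name_b, "median_af")
    s_a <- get(name_a, "status"); s_b <- get(name_b, "status")
    n_a <- get(name_a, "n_sites") %||% 0; n_b <- get(name_b, "n_sites") %||% 0
    if (isTRUE(s_a != "determined")) m_a <- NA_real_
    if (isTRUE(s_b != "determined")) m_b <- NA_real_
    base <- data.frame(
      subgenome = contig_subgenome(chrom), chrom = chrom,
      parent = c(name_a, name_b),
      median_af = c(m_a, m_b),
      n_sites = c(ifelse(is.na(n_a), 0L, as.integer(n_a)),
                  ifelse(is.na(n_b), 0L, as.integer(n_b))),
      copy = cc, stringsAsFactors = FALSE
    )
    if (is.na(m_a) && is.na(m_b)) {
      base$copies <- NA_integer_
      base$status <- "undetermined"
      base$confidence <- NA_character_
    } else {
      k <- assign_contributions(m_a, m_b, cc,
                                n_a = base$n_sites[1], n_b = base$n_sites[2])
      base$copies <- c(k$k_a, k$k_b)
      base$status <- "determined"
      base$confidence <- k$confidence
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
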