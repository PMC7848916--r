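#' Specify a parental strain for simulation
#'
#' A parent is described by how many copies of each subgenome it carries
#' (e.g. a diploid ale strain is `c(Sc = 2, Se = 0)`; an allodiploid lager
#' meiotic segregant is `c(Sc = 1, Se = 1)`), by its within-subgenome
#' heterozygous-site density, by its density of homozygous private SNPs
#' (the markers used to trace inheritance), and by its mitotype.
#'
#' @param name Parent name (no "." allowed; used in haplotype labels).
#' @param copies Named integer vector `c(Sc =, Se =)` of subgenome copies.
#' @param het_density Heterozygous sites per kb within each subgenome
#'   carried in >= 2 copies.
#' @param private_density Homozygous private SNPs per kb on each carried
#'   subgenome.
#' @param mitotype `"Sc"` or `"Se"`.
#' @return An object of class `parent_spec`.
#' @export
parent_spec <- function(name, copies, het_density = 1,
                        private_density = 1, mitotype = "Sc") {
  if (grepl("\\.", name)) stop_param("parent name must not contain '.'")
  full <- setNames(integer(2), c("Sc", "Se"))
  full[names(copies)] <- as.integer(copies)
  if (sum(full) < 1) stop_param("parent must carry at least one copy")
  if (het_density < 0 || private_density < 0)
    stop_param("densities must be >= 0")
  if (!mitotype %in% c("Sc", "Se"))
    stop_param("mitotype must be 'Sc' or 'Se'")
  structure(list(name = name, copies = full, het_density = het_density,
                 private_density = private_density, mitotype = mitotype),
            class = "parent_spec")
}

#' All haplotype labels of a simulated parent
#'
#' Labels have the form `"<parent>.<subgenome>.<index>"`.
#'
#' @param parent A `sim_parent` from [simulate_parent()] or a
#'   `parent_spec`.
#' @param subgenome Optional subgenome to restrict to.
#' @return Character vector of haplotype labels.
#' @export
haplotype_labels <- function(parent, subgenome = NULL) {
  spec <- if (inherits(parent, "sim_parent")) parent$spec else parent
  sgs <- if (is.null(subgenome)) c("Sc", "Se") else subgenome
  unlist(lapply(sgs, function(sg) {
    k <- spec$copies[[sg]]
    if (k == 0) character(0)
    else paste(spec$name, sg, seq_len(k), sep = ".")
  }))
}

#' Simulate genotypes of one parental strain
#'
#' Plants heterozygous sites (GT 0/1, the alternate allele on exactly one
#' haplotype) at `het_density` per kb on subgenomes carried in >= 2
#' copies, and homozygous private SNPs (GT 1/1, alternate on every
#' haplotype) at `private_density` per kb on every carried subgenome.
#' Per-chromosome site counts are Poisson with the corresponding mean.
#' Positions listed in `exclude` (e.g. fixed inter-subgenome divergence
#' positions, or positions already used by another parent so that private
#' SNPs stay private) are never used.
#'
#' @param spec A [parent_spec()].
#' @param refs A `reference_pair` from [build_references()].
#' @param seed Integer seed.
#' @param exclude Named list (by contig) of 1-based positions to avoid.
#' @return A `sim_parent`: list with `spec` and `sites`, a data frame with
#'   one row per variant site (`parent`, `subgenome`, `chrom`, `pos`,
#'   `ref`, `alt`, `gt`, `alt_haps` list-column of haplotype indices
#'   carrying the alternate allele, plus clean `ad`/`dp`/`qd`/`fs`/`mq`
#'   fields for VCF export).
#' @export
simulate_parent <- function(spec, refs, seed, exclude = NULL) {
  stopifnot(inherits(spec, "parent_spec"), inherits(refs, "reference_pair"))
  set.seed(derive_seed(seed, "parent", spec$name))
  bases <- c("A", "C", "G", "T")
  chroms <- refs$chromosomes[!refs$chromosomes$is_mito, ]
  rows <- list()
  for (i in seq_len(nrow(chroms))) {
    sg <- chroms$subgenome[i]
    chrom <- chroms$chrom[i]
    L <- chroms$length[i]
    k <- spec$copies[[sg]]
    if (k == 0) next
    excl <- exclude[[chrom]] %||% integer(0)
    n_het <- if (k >= 2 && spec$het_density > 0)
      rpois(1, spec$het_density * L / 1000) else 0L
    n_priv <- if (spec$private_density > 0)
      rpois(1, spec$private_density * L / 1000) else 0L
    n <- n_het + n_priv
    if (n == 0) next
    avail <- setdiff(seq_len(L), excl)
    if (length(avail) < n)
      stop_param("site density too high for chromosome ", chrom,
                 ": not enough free positions")
    pos <- sort(sample(avail, n))
    is_het <- rep(FALSE, n)
    if (n_het > 0) is_het[sample.int(n, n_het)] <- TRUE
    ref <- ref_base_at(refs, chrom, pos)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    alt_haps <- lapply(is_het, function(h)
      if (h) sample.int(k, 1) else seq_len(k))
    rows[[length(rows) + 1L]] <- data.frame(
      parent = spec$name, subgenome = sg, chrom = chrom, pos = pos,
      ref = ref, alt = alt,
      gt = ifelse(is_het, "0/1", "1/1"),
      stringsAsFactors = FALSE
    ) |> transform(alt_haps = I(alt_haps))
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = character(), subgenome = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), gt = character(),
               alt_haps = I(list()))
  rownames(sites) <- NULL
  # clean, filter-passing evidence fields for parent VCF export: parents
  # are deeply sequenced reference material, their calls are not under test
  n <- nrow(sites)
  sites$dp <- rep(100L, n)
  sites$ad <- I(lapply(seq_len(n), function(j)
    if (sites$gt[j] == "0/1") c(50L, 50L) else c(0L, 100L)))
  sites$qd <- rep(25, n)
  sites$fs <- rep(1, n)
  sites$mq <- rep(60, n)
  structure(list(spec = spec, sites = sites, seed = seed),
            class = "sim_parent")
}

#' Simulate a set of parents with mutually private SNPs
#'
#' Coordinates [simulate_parent()] calls so that no two parents reuse a
#' position: every homozygous-alternate site of one parent is guaranteed
#' absent from all others, making it a private marker by construction.
#' Fixed inter-subgenome divergence positions are excluded for everyone.
#'
#' @param specs List of [parent_spec()] objects (unique names).
#' @param refs A `reference_pair`.
#' @param seed Integer seed.
#' @return Named list of `sim_parent` objects.
#' @export
simulate_parents <- function(specs, refs, seed) {
  nms <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nms)) stop_param("parent names must be unique")
  # divergence positions apply to the Se contig and its Sc partner alike
  used <- list()
  nuc <- refs$chromosomes[!refs$chromosomes$is_mito, ]
  sc <- nuc$chrom[nuc$subgenome == "Sc"]
  se <- nuc$chrom[nuc$subgenome == "Se"]
  for (j in seq_along(se)) {
    dp <- refs$div_positions[[se[j]]] %||% integer(0)
    used[[se[j]]] <- dp
    used[[sc[j]]] <- dp
  }
  out <- list()
  for (spec in specs) {
    p <- simulate_parent(spec, refs, seed, exclude = used)
    for (chrom in unique(p$sites$chrom)) {
      used[[chrom]] <- c(used[[chrom]] %||% integer(0),
                         p$sites$pos[p$sites$chrom == chrom])
    }
    out[[spec$name]] <- p
  }
  out
}

#' Write a simulated parent's calls as a VCF
#'
#' @param parent A `sim_parent`.
#' @param path Output VCF path.
#' @param refs The `reference_pair` (for contig headers).
#' @return `path`, invisibly.
#' @export
write_parent_vcf <- function(parent, path, refs) {
  write_vcf(parent$sites, path, sample = parent$spec$name, refs = refs)
}
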