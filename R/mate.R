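#' Define a hybrid karyotype as parental haplotype lists
#'
#' Each chromosome of the hybrid is described by the ordered list of
#' parental haplotype labels it carries; the list length is the copy
#' number (an empty list is a whole-chromosome deletion). Labels take the
#' form `"<parent>.<subgenome>.<index>"` (see [haplotype_labels()]).
#'
#' @param haplotypes Named list: contig name -> character vector of
#'   haplotype labels (possibly empty).
#' @param mitotype `"Sc"` or `"Se"`: the inherited mitochondrial genome.
#' @return An object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(haplotypes, mitotype) {
  stopifnot(is.list(haplotypes), !is.null(names(haplotypes)))
  if (!mitotype %in% c("Sc", "Se"))
    stop_param("mitotype must be 'Sc' or 'Se'")
  copy <- vapply(haplotypes, length, 1L)
  if (all(copy == 0)) stop_param("at least one chromosome must have copy >= 1")
  structure(list(haplotypes = haplotypes, mitotype = mitotype),
            class = "karyotype_spec")
}

#' Karyotype of a rare-mating event: union of both parents' genomes
#'
#' Rare mating fuses whole genomes, so the hybrid inherits every
#' haplotype of every parent on every chromosome (an allodiploid
#' `{Sc:1, Se:1}` segregant mated to a diploid `{Sc:2}` ale strain gives
#' Sc copy 3, Se copy 1). `drop` removes chromosomes afterwards (e.g. the
#' Se Chr3 loss that restores fertility through MAT-locus hemizygosity),
#' `duplicate` adds one extra copy of a named haplotype.
#'
#' @param parents Named list of `sim_parent` objects.
#' @param refs The `reference_pair`.
#' @param mitotype Inherited mitotype (`"Sc"` or `"Se"`).
#' @param drop Character vector of contigs to delete entirely.
#' @param duplicate Named character vector: contig -> haplotype label to
#'   add one more copy of.
#' @return A `karyotype_spec`.
#' @export
union_karyotype <- function(parents, refs, mitotype,
                            drop = character(0), duplicate = NULL) {
  nuc <- refs$chromosomes[!refs$chromosomes$is_mito, ]
  haps <- list()
  for (i in seq_len(nrow(nuc))) {
    chrom <- nuc$chrom[i]
    sg <- nuc$subgenome[i]
    h <- unlist(lapply(parents, haplotype_labels, subgenome = sg),
                use.names = FALSE)
    if (chrom %in% drop) h <- character(0)
    if (!is.null(duplicate) && chrom %in% names(duplicate))
      h <- c(h, duplicate[[chrom]])
    haps[[chrom]] <- h
  }
  karyotype_spec(haps, mitotype)
}

#' Mate simulated parents into a hybrid truth set
#'
#' Computes, for every parental variant site on every retained
#' chromosome, the number of hybrid copies carrying the alternate allele:
#' the sum over the chromosome's haplotype list of the allele carried by
#' each haplotype. Also tallies the parental contribution (haplotypes per
#' parent) of every chromosome.
#'
#' @param parents Named list of `sim_parent` objects (from
#'   [simulate_parents()]).
#' @param karyotype A [karyotype_spec()] whose labels all reference
#'   existing parental haplotypes.
#' @param seed Integer seed recorded in the truth set.
#' @return A `truth_set`: list with `karyotype`, `copy_number` (data
#'   frame `subgenome`/`chrom`/`copy`), `sites` (per-site true alternate
#'   copies, including sites the hybrid did not inherit, `alt_copies`
#'   0..copy), `contributions` (per chromosome per parent), `mitotype`,
#'   and `seed`.
#' @export
mate <- function(parents, karyotype, seed) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  all_labels <- unlist(lapply(parents, haplotype_labels), use.names = FALSE)
  asked <- unique(unlist(karyotype$haplotypes, use.names = FALSE))
  missing <- setdiff(asked, all_labels)
  if (length(missing))
    stop_param("karyotype references unknown haplotypes: ",
               paste(missing, collapse = ", "))

  chroms <- names(karyotype$haplotypes)
  copy_number <- data.frame(
    subgenome = contig_subgenome(chroms), chrom = chroms,
    copy = vapply(karyotype$haplotypes, length, 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )

  parent_names <- vapply(parents, function(p) p$spec$name, "")
  contrib <- do.call(rbind, lapply(chroms, function(chrom) {
    labs <- karyotype$haplotypes[[chrom]]
    from <- vapply(strsplit(labs, ".", fixed = TRUE), `[`, "", 1)
    data.frame(subgenome = contig_subgenome(chrom), chrom = chrom,
               parent = parent_names,
               copies = vapply(parent_names,
                               function(p) sum(from == p), 1L),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  site_rows <- list()
  for (chrom in chroms) {
    labs <- karyotype$haplotypes[[chrom]]
    if (length(labs) == 0) next
    parts <- strsplit(labs, ".", fixed = TRUE)
    hap_parent <- vapply(parts, `[`, "", 1)
    hap_idx <- as.integer(vapply(parts, `[`, "", 3))
    for (p in parents) {
      s <- p$sites[p$sites$chrom == chrom, , drop = FALSE]
      if (nrow(s) == 0) next
      # one element of hap_parent/hap_idx per list entry, so repeated
      # labels (duplicated haplotypes) are counted with multiplicity
      alt_copies <- vapply(seq_len(nrow(s)), function(j) {
        sum(hap_parent == s$parent[j] & hap_idx %in% s$alt_haps[[j]])
      }, 1L)
      s$alt_copies <- alt_copies
      s$copy <- length(labs)
      site_rows[[length(site_rows) + 1L]] <-
        s[, c("subgenome", "chrom", "pos", "ref", "alt", "parent",
              "alt_copies", "copy")]
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(subgenome = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               parent = character(), alt_copies = integer(),
               copy = integer())
  sites <- sites[order(match(sites$chrom, chroms[order_chroms(chroms)]),
                       sites$pos), ]
  rownames(sites) <- NULL

  structure(list(karyotype = karyotype, copy_number = copy_number,
                 sites = sites, contributions = contrib,
                 mitotype = karyotype$mitotype, seed = seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Hybrid truth set\n")
  for (sg in c("Sc", "Se")) {
    cc <- x$copy_number$copy[x$copy_number$subgenome == sg]
    cat(sprintf("  %s copies: %s\n", sg, paste(cc, collapse = " ")))
  }
  cat(sprintf("  mitotype: %s; %d variant sites\n",
              x$mitotype, nrow(x$sites)))
  invisible(x)
}
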