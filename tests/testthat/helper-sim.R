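# shared fixtures, all generated in code

# small two-subgenome reference for fast tests
tiny_refs <- function(seed = 11, n_chroms = 4, chrom_length = 10000,
                      divergence = 0.1, mito_length = 2000) {
  build_references(n_chroms, chrom_length, divergence, seed,
                   mito_length = mito_length)
}

# hand-built truth set: one nuclear chromosome with `copy` copies and n
# sites all carrying `alt_copies` alternate copies; every other
# chromosome of the reference gets copy 1 so the depth unit is anchored
manual_truth <- function(refs, chrom, copy, alt_copies, n,
                         mitotype = "Sc", other_copy = 1L) {
  chroms <- refs$chromosomes$chrom[!refs$chromosomes$is_mito]
  haps <- lapply(chroms, function(cc) {
    k <- if (cc == chrom) copy else other_copy
    if (k == 0) character(0) else paste("P", contig_subgenome(cc),
                                        seq_len(k), sep = ".")
  })
  names(haps) <- chroms
  L <- refs$chromosomes$length[refs$chromosomes$chrom == chrom]
  pos <- if (n > 0) unique(round(seq(100, L - 100, length.out = n)))
         else integer(0)
  n <- length(pos)
  sites <- data.frame(
    subgenome = rep(contig_subgenome(chrom), n), chrom = rep(chrom, n),
    pos = pos, ref = rep("A", n), alt = rep("T", n),
    parent = rep("P", n), alt_copies = rep(alt_copies, n),
    copy = rep(copy, n), stringsAsFactors = FALSE
  )
  copy_number <- data.frame(
    subgenome = contig_subgenome(chroms), chrom = chroms,
    copy = vapply(haps, length, 1L), stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(
    karyotype = structure(list(haplotypes = haps, mitotype = mitotype),
                          class = "karyotype_spec"),
    copy_number = copy_number, sites = sites,
    contributions = data.frame(subgenome = copy_number$subgenome,
                               chrom = chroms, parent = "P",
                               copies = copy_number$copy,
                               stringsAsFactors = FALSE),
    mitotype = mitotype, seed = NA_integer_
  ), class = "truth_set")
}

# standard group3-like cross on a reduced geometry
small_group3 <- function(seed, n_chroms = 6, chrom_length = 20000,
                         ...) {
  simulate_scenario("group3_like", seed = seed, n_chroms = n_chroms,
                    chrom_length = chrom_length, bin_width = 2000,
                    het_density = 2, private_density = 2, ...)
}
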