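#' Build a chimeric two-subgenome reference
#'
#' Generates a pair of divergent subgenomes ("Sc"-like and "Se"-like) plus
#' one mitochondrial contig each, mimicking a chimeric reference built by
#' concatenating two species' assemblies for competitive read mapping.
#' Each Se chromosome is a copy of its Sc partner with substitutions at
#' exactly `round(divergence * length)` positions; the substituted
#' positions are recorded so that downstream simulation can avoid planting
#' SNPs on top of fixed inter-species differences.
#'
#' Sc chromosomes are named with Roman numerals (`Sc_chrI`, ...) and Se
#' chromosomes with Arabic numerals (`Se_chr1`, ...); the mitochondrial
#' contigs are `Sc_mito` and `Se_mito`.
#'
#' @param n_chroms Number of chromosomes per subgenome (>= 1).
#' @param chrom_length Chromosome length in bp (>= 10000).
#' @param divergence Fraction of positions at which the subgenomes differ,
#'   in (0, 0.5].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param mito_length Mitochondrial contig length in bp.
#' @param fasta Optional path; when non-`NULL` the merged reference is
#'   written there as a single FASTA.
#' @return An object of class `reference_pair`: list with `chromosomes`
#'   (data frame: `subgenome`, `chrom`, `length`, `is_mito`), `sequences`
#'   (a [Biostrings::DNAStringSet]), `divergence`, `div_positions` (named
#'   list of substituted positions per Se contig), and `seed`.
#' @export
build_references <- function(n_chroms, chrom_length, divergence, seed,
                             mito_length = 10000, fasta = NULL) {
  if (n_chroms < 1) stop_param("n_chroms must be >= 1")
  if (chrom_length < 10000) stop_param("chrom_length must be >= 10 kb")
  if (mito_length < 1000) stop_param("mito_length must be >= 1 kb")
  if (!is.numeric(divergence) || divergence <= 0 || divergence > 0.5)
    stop_param("divergence must lie in (0, 0.5]")

  sc_names <- c(paste0("Sc_chr", as.roman(seq_len(n_chroms))), "Sc_mito")
  se_names <- c(paste0("Se_chr", seq_len(n_chroms)), "Se_mito")
  lengths <- c(rep(chrom_length, n_chroms), mito_length)

  set.seed(derive_seed(seed, "refs"))
  bases <- c("A", "C", "G", "T")
  sc_seqs <- lapply(lengths, function(L) sample(bases, L, replace = TRUE))

  div_positions <- vector("list", length(se_names))
  names(div_positions) <- se_names
  se_seqs <- vector("list", length(se_names))
  for (i in seq_along(se_names)) {
    L <- lengths[i]
    n_sub <- round(divergence * L)
    pos <- sort(sample.int(L, n_sub))
    s <- sc_seqs[[i]]
    # substitute with a uniformly chosen different base
    s[pos] <- vapply(s[pos],
                     function(b) sample(setdiff(bases, b), 1), "")
    se_seqs[[i]] <- s
    div_positions[[i]] <- pos
  }

  seqs <- Biostrings::DNAStringSet(c(
    setNames(vapply(sc_seqs, paste, "", collapse = ""), sc_names),
    setNames(vapply(se_seqs, paste, "", collapse = ""), se_names)
  ))

  chromosomes <- data.frame(
    subgenome = rep(c("Sc", "Se"), each = n_chroms + 1L),
    chrom = c(sc_names, se_names),
    length = rep(lengths, 2),
    is_mito = rep(c(rep(FALSE, n_chroms), TRUE), 2),
    stringsAsFactors = FALSE
  )

  refs <- structure(
    list(chromosomes = chromosomes, sequences = seqs,
         divergence = divergence, div_positions = div_positions,
         seed = seed),
    class = "reference_pair"
  )
  if (!is.null(fasta)) write_reference_fasta(refs, fasta)
  refs
}

#' Write a reference pair as a merged FASTA
#'
#' @param refs A `reference_pair` from [build_references()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_pair"))
  Biostrings::writeXStringSet(refs$sequences, path, width = 80L)
  invisible(path)
}

#' @export
print.reference_pair <- function(x, ...) {
  nuc <- x$chromosomes[!x$chromosomes$is_mito, ]
  cat("Chimeric reference pair\n")
  for (sg in c("Sc", "Se")) {
    n <- sum(nuc$subgenome == sg)
    mb <- sum(nuc$length[nuc$subgenome == sg]) / 1e6
    cat(sprintf("  %s: %d chromosomes, %.2f Mb (+ mito)\n", sg, n, mb))
  }
  cat(sprintf("  divergence: %.3f\n", x$divergence))
  invisible(x)
}

# reference base at 1-based positions of a contig
ref_base_at <- function(refs, chrom, pos) {
  seq <- refs$sequences[[chrom]]
  vapply(pos, function(p) as.character(Biostrings::subseq(seq, p, p)), "")
}
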