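#' Per-chromosome allele-frequency / scaled-depth karyotype plot
#'
#' One panel per chromosome: per-site most-abundant-alternate allele
#' frequencies as points and the scaled (0-1) depth track as a step
#' line, the standard visual for reading copy number along a hybrid
#' genome. Requires \pkg{ggplot2}.
#'
#' @param sites Filtered variant data frame.
#' @param bins Depth-track data frame.
#' @param subgenome Optional subgenome to restrict to.
#' @return A ggplot object.
#' @export
plot_karyotype <- function(sites, bins, subgenome = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("plot_karyotype() requires ggplot2")
  nuc <- bins[!is_mito_contig(bins$chrom), , drop = FALSE]
  if (!is.null(subgenome)) {
    nuc <- nuc[nuc$subgenome == subgenome, , drop = FALSE]
    sites <- sites[sites$subgenome == subgenome, , drop = FALSE]
  }
  nuc$scaled <- scaled_depth(nuc)
  sites$af <- alt_allele_frequency(sites)
  lev <- unique(nuc$chrom)[order_chroms(unique(nuc$chrom))]
  nuc$chrom <- factor(nuc$chrom, levels = lev)
  sites$chrom <- factor(sites$chrom, levels = lev)
  ggplot2::ggplot() +
    ggplot2::geom_step(data = nuc,
                       ggplot2::aes(x = .data$start, y = .data$scaled),
                       colour = "steelblue") +
    ggplot2::geom_point(data = sites,
                        ggplot2::aes(x = .data$pos, y = .data$af),
                        colour = "firebrick", size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = "allele frequency / scaled depth") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Parental allele-frequency plot with canonical guide lines
#'
#' Per-chromosome distribution of parental-allele frequencies with
#' guides at 0.25, 0.33, 0.5, 0.66 and 0.75 — the expected medians for
#' the possible contributed-copy fractions in tri- and tetraploid
#' chromosomes. Requires \pkg{ggplot2}.
#'
#' @param freqs Data frame from [parental_allele_frequency()].
#' @return A ggplot object.
#' @export
plot_parental_af <- function(freqs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("plot_parental_af() requires ggplot2")
  lev <- unique(freqs$chrom)[order_chroms(unique(freqs$chrom))]
  freqs$chrom <- factor(freqs$chrom, levels = lev)
  guides <- data.frame(x = c(1/4, 1/3, 1/2, 2/3, 3/4),
                       kind = c("2/4N", "3N", "2/4N", "3N", "2/4N"))
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_histogram(binwidth = 0.02, fill = "grey40") +
    ggplot2::geom_vline(data = guides,
                        ggplot2::aes(xintercept = .data$x,
                                     colour = .data$kind),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c("2/4N" = "darkgreen",
                                            "3N" = "steelblue")) +
    ggplot2::facet_grid(chrom ~ parent) +
    ggplot2::labs(x = "parental allele frequency", y = "markers",
                  colour = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}
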