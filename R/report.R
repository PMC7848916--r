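#' Assemble a per-strain report
#'
#' Combines the subgenome coverage summary, the karyotype result, and
#' the parental contribution table into one report shaped like a
#' strain-summary table row: ploidy, karyotype ratio, mitotype, covered
#' lengths, duplications, deletions, parental contributions, plus full
#' provenance.
#'
#' @param summary A [subgenome_summary()].
#' @param karyotype A `karyotype_result` from [infer_karyotype()].
#' @param contributions Contribution table from [trace_parents()] (may
#'   be `NULL` when no parents are available).
#' @param sample Sample name; must match `summary$sample`.
#' @param provenance Optional list (config hash, seed, thresholds);
#'   package version is always added.
#' @return A `strain_report` object.
#' @export
build_strain_report <- function(summary, karyotype, contributions = NULL,
                                sample = summary$sample,
                                provenance = list()) {
  stopifnot(inherits(summary, "subgenome_summary"),
            inherits(karyotype, "karyotype_result"))
  if (!identical(sample, summary$sample))
    stop_param("sample name mismatch: report '", sample,
               "' vs summary '", summary$sample, "'")
  provenance$tool_version <-
    as.character(utils::packageVersion("allokaryo"))
  dup <- karyotype$duplications
  del <- karyotype$deletions
  fmt_events <- function(ev, sg)
    paste(chrom_label(ev$chrom[ev$subgenome == sg]), collapse = ", ")
  structure(list(
    sample = sample,
    ploidy = karyotype$ploidy,
    ratio = karyotype$ratio,
    mitotype = summary$mitotype,
    covered_sc_mb = summary$covered_sc_mb,
    covered_se_mb = summary$covered_se_mb,
    mapping_ratio = summary$ratio,
    duplications = list(Sc = fmt_events(dup, "Sc"),
                        Se = fmt_events(dup, "Se")),
    deletions = list(Sc = fmt_events(del, "Sc"),
                     Se = fmt_events(del, "Se")),
    karyotype = karyotype,
    summary = summary,
    contributions = contributions,
    provenance = provenance
  ), class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf("Strain report: %s\n", x$sample))
  cat(sprintf("  ploidy %s, karyotype %s (Sc:Se), mitotype %s\n",
              x$ploidy, x$ratio, x$mitotype))
  cat(sprintf("  covered: Sc %.2f Mb, Se %.2f Mb (Se/Sc ratio %s)\n",
              x$covered_sc_mb, x$covered_se_mb,
              format(x$mapping_ratio, digits = 3)))
  cat(sprintf("  duplications: Sc [%s]  Se [%s]\n",
              x$duplications$Sc, x$duplications$Se))
  cat(sprintf("  deletions:    Sc [%s]  Se [%s]\n",
              x$deletions$Sc, x$deletions$Se))
  if (!is.null(x$contributions)) {
    det <- x$contributions[x$contributions$status == "determined", ,
                           drop = FALSE]
    for (p in unique(det$parent))
      cat(sprintf("  %s contributed %d chromosome copies\n",
                  p, sum(det$copies[det$parent == p])))
  }
  invisible(x)
}

#' Write a strain report as JSON
#'
#' @param report A `strain_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    sample = report$sample, ploidy = report$ploidy,
    karyotype_ratio = report$ratio, mitotype = report$mitotype,
    covered_length_mb = list(Sc = report$covered_sc_mb,
                             Se = report$covered_se_mb),
    mapping_ratio_se_sc = report$mapping_ratio,
    per_copy_depth = report$karyotype$u,
    duplications = report$duplications,
    deletions = report$deletions,
    copy_number = report$karyotype$calls,
    contributions = report$contributions,
    provenance = report$provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Analyze one strain from in-memory inputs
#'
#' The core analysis sequence behind [run_pipeline()]: filter the hybrid
#' variants, summarize subgenome coverage and mitotype, infer the
#' karyotype, trace parental origin (when parents are given), and build
#' the report.
#'
#' @param hybrid_sites Hybrid variant data frame ([read_vcf()]).
#' @param bins Hybrid depth track ([read_bedgraph()]).
#' @param parent_a,parent_b Optional parent variant data frames.
#' @param sample Sample name.
#' @param thresholds A [filter_thresholds()].
#' @param min_sites Minimum informative sites (AF profile, tracing).
#' @param min_depth Covered-position depth cutoff (reads).
#' @param fold_threshold Mitotype dominance threshold.
#' @param provenance Passed to [build_strain_report()].
#' @return List: `report`, `summary`, `karyotype`, `contributions`,
#'   `filtered_sites`.
#' @export
analyze_strain <- function(hybrid_sites, bins, parent_a = NULL,
                           parent_b = NULL, sample = "sample",
                           thresholds = filter_thresholds(),
                           min_sites = 20, min_depth = 1,
                           fold_threshold = 5, provenance = list()) {
  filtered <- filter_variants(hybrid_sites, thresholds)
  summary <- subgenome_summary(bins, sample = sample,
                               min_depth = min_depth,
                               fold_threshold = fold_threshold)
  karyotype <- infer_karyotype(filtered, bins, min_sites = min_sites)
  contributions <- NULL
  if (!is.null(parent_a) && !is.null(parent_b)) {
    contributions <- trace_parents(parent_a, parent_b, filtered, bins,
                                   karyotype$calls,
                                   min_sites = min_sites,
                                   min_depth = min_depth)
  }
  report <- build_strain_report(summary, karyotype, contributions,
                                sample = sample,
                                provenance = provenance)
  list(report = report, summary = summary, karyotype = karyotype,
       contributions = contributions, filtered_sites = filtered)
}
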