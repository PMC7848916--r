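#' Simulate a complete hybrid scenario
#'
#' One-call simulation of a named cross design with known truth:
#' \describe{
#'   \item{`"group3_like"`}{an allodiploid lager meiotic segregant
#'     (`{Sc:1, Se:1}`, Se mitotype) rare-mated to a diploid Sc ale
#'     strain (`{Sc:2}`): Sc copy 3, Se copy 1, with the Se partner of
#'     chromosome 3 deleted — the 3:1 "group III" pattern.}
#'   \item{`"group2_like"`}{diploid Sc mated to diploid Se: the 2:2
#'     allotetraploid pattern of group II lager strains.}
#' }
#'
#' @param scenario `"group3_like"` or `"group2_like"`.
#' @param seed Integer seed (mandatory; drives every stage).
#' @param n_chroms,chrom_length,divergence Reference geometry (see
#'   [build_references()]).
#' @param het_density,private_density Parent site densities (sites/kb).
#' @param per_copy_depth,mito_depth_multiplier,bin_width,error_rate
#'   Observation-model parameters (see [simulate_observed()]).
#' @param sample Hybrid sample name.
#' @param dir Optional directory to write FASTA/VCF/bedGraph files into.
#' @return List: `refs`, `parents`, `truth`, `observed`, and (when `dir`
#'   is given) file paths `hybrid_vcf`, `bedgraph`, `parent_vcfs`,
#'   `fasta`.
#' @export
simulate_scenario <- function(scenario = c("group3_like", "group2_like"),
                              seed,
                              n_chroms = 16, chrom_length = 50000,
                              divergence = 0.2,
                              het_density = 1, private_density = 1,
                              per_copy_depth = 50,
                              mito_depth_multiplier = 20,
                              bin_width = 10000, error_rate = 0.002,
                              sample = "hybrid", dir = NULL) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop_param("a seed is mandatory in simulation mode")
  refs <- build_references(n_chroms, chrom_length, divergence, seed)
  if (scenario == "group3_like") {
    specs <- list(
      parent_spec("Plager", c(Sc = 1, Se = 1), het_density = het_density,
                  private_density = private_density, mitotype = "Se"),
      parent_spec("Pale", c(Sc = 2), het_density = het_density,
                  private_density = private_density, mitotype = "Sc")
    )
    parents <- simulate_parents(specs, refs, seed)
    kar <- union_karyotype(parents, refs, mitotype = "Se",
                           drop = "Se_chr3")
  } else {
    specs <- list(
      parent_spec("Psc", c(Sc = 2), het_density = het_density,
                  private_density = private_density, mitotype = "Sc"),
      parent_spec("Pse", c(Se = 2), het_density = het_density,
                  private_density = private_density, mitotype = "Se")
    )
    parents <- simulate_parents(specs, refs, seed)
    kar <- union_karyotype(parents, refs, mitotype = "Se")
  }
  truth <- mate(parents, kar, seed)
  observed <- simulate_observed(
    truth, refs, per_copy_depth = per_copy_depth,
    mito_depth_multiplier = mito_depth_multiplier,
    bin_width = bin_width, error_rate = error_rate, seed = seed,
    sample = sample, dir = dir)
  out <- list(refs = refs, parents = parents, truth = truth,
              observed = observed)
  if (!is.null(dir)) {
    out$hybrid_vcf <- observed$vcf
    out$bedgraph <- observed$bedgraph
    out$parent_vcfs <- vapply(parents, function(p) {
      path <- file.path(dir, paste0(p$spec$name, ".vcf"))
      write_parent_vcf(p, path, refs)
      path
    }, "")
    out$fasta <- file.path(dir, "reference.fasta")
    write_reference_fasta(refs, out$fasta)
  }
  out
}

#' Compare inferred calls with a simulation truth set
#'
#' @param truth A `truth_set`.
#' @param karyotype A `karyotype_result`.
#' @param contributions Optional [trace_parents()] table.
#' @return List with `copy_table` (per-chromosome truth vs inferred and
#'   match flag), `copy_match_rate`, and (when contributions are given)
#'   `contribution_table` and `contribution_match_rate`.
#' @export
compare_to_truth <- function(truth, karyotype, contributions = NULL) {
  tt <- truth$copy_number
  calls <- karyotype$calls
  copy_table <- merge(tt, calls[, c("chrom", "copy")], by = "chrom",
                      suffixes = c("_true", "_inferred"))
  copy_table <- copy_table[order_chroms(copy_table$chrom), ]
  copy_table$match <- copy_table$copy_true == copy_table$copy_inferred
  rownames(copy_table) <- NULL
  out <- list(copy_table = copy_table,
              copy_match_rate = mean(copy_table$match))
  if (!is.null(contributions)) {
    tc <- truth$contributions
    ct <- merge(tc, contributions[, c("chrom", "parent", "copies")],
                by = c("chrom", "parent"),
                suffixes = c("_true", "_inferred"))
    ct$match <- ct$copies_true == ct$copies_inferred
    out$contribution_table <- ct
    out$contribution_match_rate <- mean(ct$match, na.rm = TRUE)
  }
  out
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_param("no such config file: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_param("config must be a list or a file path")
  config
}

#' Run the full pipeline from a configuration
#'
#' Executes (optionally) simulate, then filter, coverage metrics,
#' karyotype inference, parental tracing, and report assembly, writing
#' all tabular artifacts to `out_dir`. The configuration is a list or a
#' YAML/JSON file with fields:
#' \preformatted{
#' sample: my_hybrid
#' mode: simulate            # or "analyze"
#' seed: 42                  # mandatory in simulate mode
#' simulate:                 # simulate mode only
#'   scenario: group3_like   # or group2_like
#'   per_copy_depth: 50      # ... any simulate_scenario() parameter
#' analyze:                  # analyze mode only
#'   hybrid_vcf: hybrid.vcf
#'   bedgraph: hybrid.bedGraph
#'   parent_vcfs: [Plager.vcf, Pale.vcf]
#' thresholds: {min_depth: 40, min_qd: 2, max_fs: 60, min_mq: 40}
#' options: {min_sites: 20, min_depth: 1, fold_threshold: 5}
#' }
#' Explicit function arguments win over config values. In simulate mode
#' the simulated files are written to `out_dir` and then re-read through
#' the standard VCF/bedGraph readers, and a truth-vs-inferred comparison
#' table is produced.
#'
#' @param config List or path to a YAML/JSON configuration.
#' @param out_dir Output directory (default: `out_dir` from the config,
#'   else a temporary directory).
#' @param seed Optional seed overriding the config.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `report`, `summary`, `karyotype`,
#'   `contributions`, `truth_comparison` (simulate mode), and `files`
#'   (paths of everything written).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  config <- read_config(config)
  mode <- config$mode %||% "analyze"
  sample <- config$sample %||% "sample"
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), paste0("allokaryo-", sample))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  say <- function(...) if (!quiet) message(...)

  thr <- do.call(filter_thresholds, config$thresholds %||% list())
  opts <- modifyList(list(min_sites = 20, min_depth = 1,
                          fold_threshold = 5),
                     config$options %||% list())
  provenance <- list(config_hash = object_hash(config), seed = seed,
                     thresholds = unclass(thr), mode = mode)

  sim <- NULL
  if (mode == "simulate") {
    if (is.null(seed)) stop_param("a seed is mandatory in simulation mode")
    sim_args <- config$simulate %||% list()
    sim_args$scenario <- sim_args$scenario %||% "group3_like"
    sim_args$seed <- seed
    sim_args$sample <- sample
    sim_args$dir <- file.path(out_dir, "simulated")
    sim <- do.call(simulate_scenario, sim_args)
    say("simulated scenario '", sim_args$scenario, "' -> ", sim_args$dir)
    hybrid_vcf <- sim$hybrid_vcf
    bedgraph <- sim$bedgraph
    parent_vcfs <- sim$parent_vcfs
  } else {
    a <- config$analyze %||% list()
    hybrid_vcf <- a$hybrid_vcf
    bedgraph <- a$bedgraph
    parent_vcfs <- a$parent_vcfs
    if (is.null(hybrid_vcf) || !file.exists(hybrid_vcf))
      stop_param("analyze mode requires an existing hybrid_vcf")
    if (is.null(bedgraph) || !file.exists(bedgraph))
      stop_param("analyze mode requires an existing bedgraph")
    if (!is.null(parent_vcfs) && !all(file.exists(unlist(parent_vcfs))))
      stop_param("missing parent VCF(s): ",
                 paste(unlist(parent_vcfs)[!file.exists(unlist(parent_vcfs))],
                       collapse = ", "))
  }

  hybrid_sites <- read_vcf(hybrid_vcf)
  bins <- read_bedgraph(bedgraph)
  say("read ", nrow(hybrid_sites), " variant records and ",
      nrow(bins), " depth bins")
  parent_a <- parent_b <- NULL
  if (!is.null(parent_vcfs) && length(parent_vcfs) >= 2) {
    parent_a <- read_vcf(unlist(parent_vcfs)[1])
    parent_b <- read_vcf(unlist(parent_vcfs)[2])
  }

  res <- analyze_strain(hybrid_sites, bins, parent_a, parent_b,
                        sample = sample, thresholds = thr,
                        min_sites = opts$min_sites,
                        min_depth = opts$min_depth,
                        fold_threshold = opts$fold_threshold,
                        provenance = provenance)
  say("filtered sites: ", nrow(res$filtered_sites), " of ",
      nrow(hybrid_sites), "; karyotype ", res$karyotype$ratio,
      " (", res$karyotype$ploidy, "), mitotype ", res$summary$mitotype)

  files <- list()
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
  }
  w(as.data.frame(res$summary), "subgenome_summary.tsv")
  w(res$karyotype$calls, "copy_number_calls.tsv")
  w(data.frame(sample = sample, ratio = res$karyotype$ratio,
               ploidy = res$karyotype$ploidy, u = res$karyotype$u),
    "karyotype_summary.tsv")
  if (!is.null(res$contributions))
    w(res$contributions, "parental_contributions.tsv")
  files$report <- file.path(out_dir, "strain_report.json")
  write_report_json(res$report, files$report)

  truth_comparison <- NULL
  if (!is.null(sim)) {
    truth_comparison <- compare_to_truth(sim$truth, res$karyotype,
                                         res$contributions)
    w(truth_comparison$copy_table, "truth_comparison.tsv")
    say(sprintf("truth comparison: %.0f%% of chromosome copy calls match",
                100 * truth_comparison$copy_match_rate))
  }
  invisible(list(report = res$report, summary = res$summary,
                 karyotype = res$karyotype,
                 contributions = res$contributions,
                 truth_comparison = truth_comparison,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 files = files, out_dir = out_dir))
}
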