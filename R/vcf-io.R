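#' Write variant sites as a VCF v4.2 file
#'
#' Emits one record per site with `INFO DP;QD;FS;MQ` and
#' `FORMAT GT:AD:DP` for a single sample. Output is byte-deterministic
#' for a given input.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gt`, `ad` (list-column, ref depth first), `dp`, `qd`, `fs`, `mq`.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @param refs Optional `reference_pair` for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, sample = "sample", refs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=allokaryo",
    if (!is.null(refs))
      sprintf("##contig=<ID=%s,length=%d>",
              refs$chromosomes$chrom, refs$chromosomes$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Strand-bias phred score\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample), collapse = "\t")
  )
  body <- character(0)
  if (nrow(sites) > 0) {
    ord <- order_chroms(sites$chrom)
    # order_chroms returns a chromosome-level ordering permutation; apply
    # it then sort by position within chromosome
    sites <- sites[ord, , drop = FALSE]
    sites <- sites[order(match(sites$chrom, unique(sites$chrom)),
                         sites$pos), , drop = FALSE]
    ad_str <- vapply(sites$ad, paste, "", collapse = ",")
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;QD=%s;FS=%s;MQ=%s\tGT:AD:DP\t%s:%s:%d",
      sites$chrom, sites$pos, sites$ref, sites$alt, sites$dp,
      format(sites$qd, trim = TRUE, scientific = FALSE),
      format(sites$fs, trim = TRUE, scientific = FALSE),
      format(sites$mq, trim = TRUE, scientific = FALSE),
      sites$gt, ad_str, sites$dp
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a per-site data frame
#'
#' Parses a VCF v4.2 (via \pkg{vcfR}) into one row per record carrying
#' the fields the pipeline uses: sample `GT`/`AD`/`DP` and site
#' `QD`/`FS`/`MQ` annotations. The subgenome is derived from the contig
#' name prefix (`Sc_` / `Se_`); records on unknown contigs are dropped
#' with a warning, as are records whose sample lacks `AD`.
#'
#' @param path VCF path.
#' @param sample Sample to extract; defaults to the first sample column.
#' @return Data frame with columns `subgenome`, `chrom`, `pos`, `ref`,
#'   `alt` (comma-separated when multi-allelic), `gt`, `ad`
#'   (list-column: ref depth then alternate depths), `dp`, `qd`, `fs`,
#'   `mq`. Attribute `"sample"` records the sample name.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop_param("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(subgenome = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), gt = character(),
                      ad = I(list()), dp = integer(), qd = numeric(),
                      fs = numeric(), mq = numeric())
  if (nrow(v@fix) == 0) return(structure(empty, sample = sample %||% NA))
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples)
    stop_param("sample '", sample, "' not present in ", path)

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, "GT")[, sample]
  ad_raw <- vcfR::extract.gt(v, "AD")[, sample]
  dp_fmt <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, "DP")[, sample]))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(v, "FS")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  dp_info <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))

  sg <- contig_subgenome(fix$CHROM)
  if (anyNA(sg)) {
    bad <- unique(fix$CHROM[is.na(sg)])
    warning("dropping ", sum(is.na(sg)), " record(s) on unknown contig(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  no_ad <- is.na(ad_raw)
  if (any(no_ad & !is.na(sg)))
    warning("skipping ", sum(no_ad & !is.na(sg)),
            " record(s) lacking AD", call. = FALSE)
  keep <- !is.na(sg) & !no_ad
  if (!any(keep)) return(structure(empty, sample = sample))

  ad <- lapply(strsplit(unname(ad_raw[keep]), ",", fixed = TRUE),
               as.integer)
  dp <- ifelse(is.na(dp_fmt[keep]), dp_info[keep], dp_fmt[keep])
  dp <- ifelse(is.na(dp), vapply(ad, sum, 1L), dp)

  out <- data.frame(
    subgenome = sg[keep], chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]), ref = fix$REF[keep],
    alt = fix$ALT[keep], gt = unname(gt[keep]),
    dp = as.integer(dp), qd = qd[keep], fs = fs[keep], mq = mq[keep],
    stringsAsFactors = FALSE
  )
  out$ad <- I(ad)
  rownames(out) <- NULL
  structure(out, sample = sample)
}

#' Write a binned depth track as bedGraph
#'
#' Four-column bedGraph, 0-based half-open intervals.
#'
#' @param bins Data frame with `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", bins$chrom, as.integer(bins$start),
                   as.integer(bins$end),
                   format(bins$depth, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph depth track
#'
#' Parsed with \pkg{rtracklayer}; intervals are returned in bedGraph
#' coordinates (0-based half-open) with the subgenome derived from the
#' contig prefix.
#'
#' @param path bedGraph path.
#' @return Data frame with `subgenome`, `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_param("no such bedGraph: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    subgenome = contig_subgenome(as.character(GenomicRanges::seqnames(gr))),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
    end = GenomicRanges::end(gr),
    depth = gr$score,
    stringsAsFactors = FALSE
  )
}
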