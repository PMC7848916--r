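#' Derive a reproducible sub-seed from a global seed and a stream label
#'
#' All stochastic stages draw their own seed from the single user-supplied
#' seed plus a stage label, so that adding or reordering stages never
#' perturbs the random stream of another stage.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric labels identifying the stream.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# subgenome of a contig name ("Sc_chrI" -> "Sc"); NA when no known prefix
contig_subgenome <- function(chrom) {
  out <- rep(NA_character_, length(chrom))
  out[startsWith(chrom, "Sc_")] <- "Sc"
  out[startsWith(chrom, "Se_")] <- "Se"
  out
}

is_mito_contig <- function(chrom) grepl("_mito$", chrom)

# "Sc_chrIX" -> "IX"; "Se_chr3" -> "3"
chrom_label <- function(chrom) sub("^S[ce]_chr", "", chrom)

# deterministic ordering: Sc chromosomes in Roman-numeral order, then Se
# in numeric order, mitochondria last
order_chroms <- function(chrom) {
  sg <- contig_subgenome(chrom)
  mito <- is_mito_contig(chrom)
  lab <- chrom_label(chrom)
  num <- suppressWarnings(ifelse(sg == "Sc" & !mito,
                                 as.integer(as.roman(lab)),
                                 as.integer(lab)))
  num[mito] <- 1e6L
  order(match(sg, c("Sc", "Se")), num, chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

# deterministic hash of an R object (base tools only)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
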