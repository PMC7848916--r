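mk_parent <- function(name, chrom, pos, gt, alt = "T") {
  n <- length(pos)
  out <- data.frame(subgenome = contig_subgenome(chrom), chrom = chrom,
                    pos = as.integer(pos), ref = "A",
                    alt = rep_len(alt, n), gt = rep_len(gt, n),
                    dp = 100L, qd = 25, fs = 1, mq = 60,
                    stringsAsFactors = FALSE)
  out$ad <- I(lapply(out$gt, function(g)
    if (g == "0/1") c(50L, 50L) else c(0L, 100L)))
  structure(out, sample = name)
}

test_that("private marker selection follows the homozygosity rules", {
  a <- mk_parent("A", "Sc_chrI", c(100, 200, 300, 400),
                 c("1/1", "0/1", "1/1", "1/1"))
  b <- mk_parent("B", "Sc_chrI", c(300, 400, 500),
                 c("1/1", "0/1", "1/1"))
  m <- private_homozygous_snps(a, b)
  # 100: 1/1 in A, absent in B -> owned by A
  # 200: heterozygous in A -> excluded
  # 300: 1/1 in both -> excluded; 400: 1/1 in A but het in B -> excluded
  # 500: 1/1 in B, absent in A -> owned by B
  expect_identical(m$pos, c(100L, 500L))
  expect_identical(m$parent, c("A", "B"))
  expect_identical(m$allele, c("T", "T"))
  expect_identical(m$other_allele, c("A", "A"))
})

test_that("parental allele frequencies read the hybrid's allele depths", {
  markers <- data.frame(subgenome = "Sc", chrom = "Sc_chrI",
                        pos = c(100L, 200L, 300L, 400L),
                        parent = "A", allele = "T", other_allele = "A")
  hyb <- mk_parent("H", "Sc_chrI", c(100, 200), c("0/1", "1/1"))
  hyb$ad <- I(list(c(66L, 33L), c(0L, 100L)))
  hyb$dp <- c(99L, 100L)
  bins <- data.frame(subgenome = "Sc", chrom = "Sc_chrI",
                     start = c(0L, 250L), end = c(250L, 350L),
                     depth = c(100, 80))
  f <- parental_allele_frequency(markers, hyb, bins)
  # 33 of 99 reads carry the parental allele -> 1/3 (one of three copies)
  expect_equal(f$freq[f$pos == 100], 1 / 3)
  expect_equal(f$freq[f$pos == 200], 1.0)
  # absent but covered -> 0; absent and uncovered -> dropped
  expect_equal(f$freq[f$pos == 300], 0)
  expect_false(400 %in% f$pos)
})

test_that("chromosome medians honor the informative-site minimum", {
  f <- data.frame(subgenome = "Sc", chrom = "Sc_chrI",
                  pos = 1:3 * 100L, parent = "A",
                  freq = c(0.3, 0.33, 0.35))
  med <- chromosome_median_frequency(f, min_sites = 3)
  expect_equal(med$median_af, 0.33)
  expect_identical(med$status, "determined")
  med5 <- chromosome_median_frequency(
    transform(f[c(1, 1, 2, 2, 3), ], pos = 1:5 * 100L), min_sites = 20)
  expect_identical(med5$status, "undetermined")
})

test_that("contribution assignment rounds jointly and consistently", {
  k <- assign_contributions(0.33, 0.66, 3)
  expect_identical(c(k$k_a, k$k_b), c(1L, 2L))
  expect_identical(k$confidence, "high")

  k2 <- assign_contributions(0.5, NA, 2)
  expect_identical(c(k2$k_a, k2$k_b), c(1L, 1L))

  # uniparental single-copy chromosome
  k1 <- assign_contributions(1.0, 0.0, 1)
  expect_identical(c(k1$k_a, k1$k_b), c(1L, 0L))

  expect_warning(k0 <- assign_contributions(0.4, 0.1, 0), "deleted")
  expect_identical(c(k0$k_a, k0$k_b), c(0L, 0L))

  # deviant medians lower confidence but still sum to c
  kd <- assign_contributions(0.5, 0.5, 3, n_a = 10, n_b = 5)
  expect_identical(kd$k_a + kd$k_b, 3L)
  expect_identical(kd$confidence, "low")

  # symmetry: swapping parents swaps the assignment
  set.seed(11)
  for (i in 1:50) {
    cc <- sample(1:5, 1)
    ka <- sample(0:cc, 1)
    ma <- ka / cc + runif(1, -0.05, 0.05)
    mb <- (cc - ka) / cc + runif(1, -0.05, 0.05)
    r1 <- assign_contributions(ma, mb, cc, n_a = 30, n_b = 30)
    r2 <- assign_contributions(mb, ma, cc, n_a = 30, n_b = 30)
    expect_identical(r1$k_a, r2$k_b)
    expect_identical(r1$k_b, r2$k_a)
    expect_identical(r1$k_a + r1$k_b, as.integer(cc))
  }
})

test_that("noiseless tracing reproduces the truth contributions exactly", {
  sc <- simulate_scenario("group3_like", seed = 17, n_chroms = 4,
                          chrom_length = 20000, bin_width = 2000,
                          het_density = 2, private_density = 2)
  obs <- simulate_observed(sc$truth, sc$refs, bin_width = 2000,
                           error_rate = 0, exact = TRUE, seed = 17)
  k <- infer_karyotype(obs$sites, obs$bins)
  pa <- sc$parents[[1]]$sites; attr(pa, "sample") <- "Plager"
  pb <- sc$parents[[2]]$sites; attr(pb, "sample") <- "Pale"
  tr <- trace_parents(pa, pb, obs$sites, obs$bins, k$calls,
                      min_sites = 10)
  cmp <- merge(sc$truth$contributions, tr[, c("chrom", "parent", "copies")],
               by = c("chrom", "parent"))
  det <- !is.na(cmp$copies.y)
  expect_true(all(cmp$copies.x[det] == cmp$copies.y[det]))
  # every non-deleted chromosome is determined
  live <- cmp$chrom %in%
    sc$truth$copy_number$chrom[sc$truth$copy_number$copy > 0]
  expect_true(all(det[live]))
})

test_that("contributions of noisy simulated hybrids are recovered", {
  refs <- tiny_refs(seed = 45, n_chroms = 2, chrom_length = 20000)
  specs <- list(parent_spec("A", c(Sc = 2), private_density = 3),
                parent_spec("B", c(Sc = 2), private_density = 3))
  parents <- simulate_parents(specs, refs, seed = 7)
  n_match <- 0; n_total <- 0
  for (h in 1:20) {
    set.seed(2000 + h)
    # a real hybrid carries both parents somewhere: keep one chromosome
    # with a mixed contribution, the other unconstrained
    split_a <- c(sample(1:2, 1), sample(0:3, 1))
    haps <- list()
    for (i in 1:2) {
      chrom <- paste0("Sc_chr", as.roman(i))
      ka <- split_a[i]
      haps[[chrom]] <- c(rep(paste0("A.Sc.", 1:2), length.out = ka),
                         rep(paste0("B.Sc.", 1:2), length.out = 3 - ka))
    }
    for (cc in paste0("Se_chr", 1:2)) haps[[cc]] <- character(0)
    truth <- mate(parents, karyotype_spec(haps, "Sc"), seed = h)
    obs <- simulate_observed(truth, refs, per_copy_depth = 34,
                             bin_width = 2000, seed = 2000 + h)
    k <- infer_karyotype(filter_variants(obs$sites, filter_thresholds(
      min_depth = 40)), obs$bins)
    pa <- parents$A$sites; attr(pa, "sample") <- "A"
    pb <- parents$B$sites; attr(pb, "sample") <- "B"
    tr <- trace_parents(pa, pb, filter_variants(obs$sites), obs$bins,
                        k$calls, min_sites = 20)
    cmp <- merge(truth$contributions,
                 tr[, c("chrom", "parent", "copies")],
                 by = c("chrom", "parent"))
    live <- cmp$chrom %in%
      truth$copy_number$chrom[truth$copy_number$copy > 0]
    n_total <- n_total + sum(live)
    n_match <- n_match + sum(live & !is.na(cmp$copies.y) &
                               cmp$copies.x == cmp$copies.y)
  }
  expect_gte(n_match / n_total, 0.95)
})
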