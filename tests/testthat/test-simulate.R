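refs1 <- tiny_refs(seed = 21, n_chroms = 1, chrom_length = 100000)

test_that("parent simulation honors densities and ploidy", {
  # zero private density -> no homozygous-alternate records
  p <- simulate_parent(parent_spec("A", c(Sc = 2), het_density = 1,
                                   private_density = 0),
                       refs1, seed = 2)
  expect_false(any(p$sites$gt == "1/1"))

  # het density 1/kb on a 100 kb diploid chromosome: Poisson(100) count
  n_het <- sum(p$sites$gt == "0/1" & p$sites$subgenome == "Sc")
  expect_gt(n_het, 100 - 1.96 * 10)
  expect_lt(n_het, 100 + 1.96 * 10)

  # one haplotype per subgenome cannot be heterozygous
  allo <- simulate_parent(parent_spec("L", c(Sc = 1, Se = 1),
                                      het_density = 2,
                                      private_density = 1),
                          refs1, seed = 2)
  expect_false(any(allo$sites$gt == "0/1"))
  expect_true(all(allo$sites$gt == "1/1"))
})

test_that("coordinated parents never share positions", {
  refs <- tiny_refs(seed = 22)
  parents <- simulate_parents(
    list(parent_spec("A", c(Sc = 2), private_density = 2),
         parent_spec("B", c(Sc = 2), private_density = 2)),
    refs, seed = 9)
  ka <- paste(parents$A$sites$chrom, parents$A$sites$pos)
  kb <- paste(parents$B$sites$chrom, parents$B$sites$pos)
  expect_length(intersect(ka, kb), 0)
  # and nobody sits on a fixed divergence position
  for (p in parents) {
    for (chrom in unique(p$sites$chrom)) {
      partner <- sub("Sc_chr", "", chrom)
      div <- refs$div_positions[[paste0("Se_chr",
                                        as.integer(as.roman(partner)))]]
      expect_length(intersect(p$sites$pos[p$sites$chrom == chrom], div), 0)
    }
  }
})

test_that("mating counts allele copies and parental contributions", {
  refs <- tiny_refs(seed = 23)
  parents <- simulate_parents(
    list(parent_spec("A", c(Sc = 2), het_density = 1, private_density = 1),
         parent_spec("B", c(Sc = 2), het_density = 1, private_density = 1)),
    refs, seed = 4)

  # 2 haplotypes from B, 1 from A on Sc_chrI; Sc_chrII deleted
  haps <- list(Sc_chrI = c("A.Sc.1", "B.Sc.1", "B.Sc.2"),
               Sc_chrII = character(0))
  for (cc in c("Sc_chrIII", "Sc_chrIV", paste0("Se_chr", 1:4)))
    haps[[cc]] <- character(0)
  haps$Sc_chrIII <- c("A.Sc.1", "A.Sc.2")
  truth <- mate(parents, karyotype_spec(haps, "Sc"), seed = 4)

  ctb <- truth$contributions
  i <- ctb$chrom == "Sc_chrI"
  expect_identical(ctb$copies[i & ctb$parent == "A"], 1L)
  expect_identical(ctb$copies[i & ctb$parent == "B"], 2L)

  # deleted chromosome: copy 0, no sites emitted
  expect_identical(
    truth$copy_number$copy[truth$copy_number$chrom == "Sc_chrII"], 0L)
  expect_false(any(truth$sites$chrom == "Sc_chrII"))

  # contributions always sum to the copy number
  sums <- tapply(ctb$copies, ctb$chrom, sum)
  expect_identical(as.integer(sums[truth$copy_number$chrom]),
                   as.integer(truth$copy_number$copy))

  # B-private homozygous sites on Sc_chrI are carried by 2 of 3 copies
  b_hom_1 <- parents$B$sites$pos[parents$B$sites$gt == "1/1" &
                                   parents$B$sites$chrom == "Sc_chrI"]
  bpriv <- truth$sites$chrom == "Sc_chrI" & truth$sites$parent == "B" &
    truth$sites$pos %in% b_hom_1
  expect_true(all(truth$sites$alt_copies[bpriv] == 2L))

  # unknown haplotype label is a configuration error
  bad <- haps; bad$Sc_chrI <- c("A.Sc.1", "C.Sc.1")
  expect_error(mate(parents, karyotype_spec(bad, "Sc"), seed = 1),
               "unknown haplotype")
})

test_that("observed data conserve depths and match expectations", {
  refs <- tiny_refs(seed = 24, n_chroms = 2, chrom_length = 50000)
  truth <- manual_truth(refs, "Sc_chrI", copy = 3, alt_copies = 1,
                        n = 600)
  obs <- simulate_observed(truth, refs, per_copy_depth = 40,
                           bin_width = 5000, seed = 8)

  # conservation: sum(AD) = DP for every emitted site
  expect_true(all(vapply(obs$sites$ad, sum, 1L) == obs$sites$dp))

  # moment check at f = 1/3, E[DP] = 120
  s <- obs$sites[obs$sites$chrom == "Sc_chrI", ]
  af <- alt_allele_frequency(s)
  f <- 1 / 3
  tol <- 3 * sqrt(f * (1 - f) / 120) / sqrt(nrow(s))
  expect_lt(abs(mean(af) - f), tol + 0.001)

  # deleted chromosome: bins near zero, no variant records
  truth0 <- manual_truth(refs, "Sc_chrII", copy = 0, alt_copies = 1,
                         n = 0)
  obs0 <- simulate_observed(truth0, refs, per_copy_depth = 40,
                            bin_width = 5000, seed = 8)
  del_bins <- obs0$bins[obs0$bins$chrom == "Sc_chrII", ]
  expect_true(all(del_bins$depth < 1))
  expect_false(any(obs0$sites$chrom == "Sc_chrII"))

  # mitochondrial dominance follows the truth mitotype
  expect_gt(obs$mito_coverage[["Sc"]], 10 * obs$mito_coverage[["Se"]])
})

test_that("simulation is byte-deterministic under a fixed seed", {
  refs <- tiny_refs(seed = 25, n_chroms = 2)
  truth <- manual_truth(refs, "Sc_chrI", copy = 2, alt_copies = 1,
                        n = 100)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  o1 <- simulate_observed(truth, refs, seed = 3, bin_width = 2000,
                          dir = d1)
  o2 <- simulate_observed(truth, refs, seed = 3, bin_width = 2000,
                          dir = d2)
  expect_identical(readLines(o1$vcf), readLines(o2$vcf))
  expect_identical(readLines(o1$bedgraph), readLines(o2$bedgraph))
  o3 <- simulate_observed(truth, refs, seed = 4, bin_width = 2000)
  expect_false(identical(o1$sites$dp, o3$sites$dp))
})
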