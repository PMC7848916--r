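# independent brute-force quantization score for the per-copy estimator
oracle_u <- function(depths, sigma = 0.15) {
  d <- depths[depths > 0]
  grid <- seq(max(d) / 8, max(d), length.out = 20000)
  score <- vapply(grid, function(u) {
    k <- pmin(pmax(round(d / u), 1), 8)
    mean(exp(-(d / u - k)^2 / (2 * sigma^2)))
  }, 1)
  max(grid[score >= max(score) - 1e-9])
}

test_that("per-copy depth estimation matches a brute-force oracle", {
  # single depth level: copy-1 reading preferred by the larger-u tie-break
  expect_equal(estimate_per_copy_depth(rep(100, 30)), 100)

  # three noiseless levels 50/100/150 in 1:2:1 proportions -> u = 50
  d <- rep(c(50, 100, 150), times = c(25, 50, 25))
  got <- estimate_per_copy_depth(d)
  expect_equal(got, 50, tolerance = 0.01)
  expect_equal(got, oracle_u(d), tolerance = 0.01)

  # noisy simulation with known truth u = 50
  set.seed(19)
  copies <- sample(1:4, 500, replace = TRUE)
  noisy <- rnorm(500, 50 * copies, sqrt(50 * copies) / 2)
  u_hat <- estimate_per_copy_depth(noisy)
  expect_gt(u_hat, 45)
  expect_lt(u_hat, 55)

  expect_error(estimate_per_copy_depth(rep(0, 30)), "no signal")
})

test_that("scaled depth is a clipped robust rescaling", {
  expect_equal(scaled_depth(rep(7, 10)), rep(1, 10))
  expect_equal(scaled_depth(c(0, 50, 100)), c(0, 0.5, 1), tolerance = 0.01)
  d <- c(rep(50, 400), 500)  # one 10x outlier
  s <- scaled_depth(d)
  expect_equal(s[401], 1)
  expect_gt(s[1], 0.95)
})

test_that("AF peak profiles recover the canonical modality signatures", {
  prof2 <- af_peak_profile(simulate_af_sites(500, 2, 1, seed = 1))
  expect_identical(prof2$label, "1/2")
  expect_lt(abs(prof2$peaks[which.min(abs(prof2$peaks - 0.5))] - 0.5),
            0.05)

  prof3 <- af_peak_profile(c(
    alt_allele_frequency(simulate_af_sites(250, 3, 1, seed = 2)),
    alt_allele_frequency(simulate_af_sites(250, 3, 2, seed = 3))))
  expect_identical(prof3$label, "1/3,2/3")

  prof1 <- af_peak_profile(simulate_af_sites(300, 2, 2, seed = 4))
  expect_identical(prof1$label, "1")

  # a homozygous peak coexisting with heterozygous peaks is tolerated
  mix <- c(alt_allele_frequency(simulate_af_sites(300, 2, 1, seed = 5)),
           alt_allele_frequency(simulate_af_sites(150, 2, 2, seed = 6)))
  expect_identical(af_peak_profile(mix)$label, "1/2")

  expect_identical(
    af_peak_profile(simulate_af_sites(10, 2, 1, seed = 7))$label, "none")
})

test_that("depth resolves AF ambiguity in copy-number calls", {
  p_half <- af_peak_profile(simulate_af_sites(400, 2, 1, seed = 8))
  c2 <- infer_copy_number(p_half, modal_depth = 100, u = 50)
  expect_identical(c2$copy, 2L)
  expect_true(c2$agreement)

  # 0.5 peak is also consistent with tetraploid 2+2: depth decides
  c4 <- infer_copy_number(p_half, modal_depth = 200, u = 50)
  expect_identical(c4$copy, 4L)
  expect_true(c4$agreement)

  # AF ~ 1 fits homozygous or haploid; depth reads it as single copy
  p_one <- af_peak_profile(simulate_af_sites(400, 1, 1, seed = 9))
  c1 <- infer_copy_number(p_one, modal_depth = 50, u = 50)
  expect_identical(c1$copy, 1L)
  expect_true(c1$agreement)

  # triploid AF against diploid depth disagrees and lowers confidence
  p_tri <- af_peak_profile(c(
    alt_allele_frequency(simulate_af_sites(200, 3, 1, seed = 10)),
    alt_allele_frequency(simulate_af_sites(200, 3, 2, seed = 11))))
  cx <- infer_copy_number(p_tri, modal_depth = 100, u = 50)
  expect_identical(cx$copy, 2L)
  expect_false(cx$agreement)
  expect_identical(cx$confidence, "low")

  # all-zero chromosome is a deletion
  c0 <- infer_copy_number(p_half, modal_depth = 0, u = 50)
  expect_identical(c0$copy, 0L)
})

test_that("karyotype summary computes modal copies, events and ploidy", {
  calls <- data.frame(
    subgenome = rep(c("Sc", "Se"), each = 4),
    chrom = c(paste0("Sc_chr", as.roman(1:4)), paste0("Se_chr", 1:4)),
    copy = c(3L, 3L, 3L, 3L, 1L, 1L, 0L, 1L))
  k <- call_karyotype(calls)
  expect_identical(k$ratio, "3:1")
  expect_identical(k$ploidy, "4N")
  expect_identical(k$deletions$chrom, "Se_chr3")
  expect_true(k$deletions$full_deletion)
  expect_identical(nrow(k$duplications), 0L)

  flat <- transform(calls, copy = 2L)
  k2 <- call_karyotype(flat)
  expect_identical(k2$ratio, "2:2")
  expect_identical(k2$ploidy, "4N")
  expect_identical(nrow(k2$duplications) + nrow(k2$deletions), 0L)

  dup <- calls; dup$copy[2] <- 4L
  k3 <- call_karyotype(dup)
  expect_identical(k3$duplications$chrom, "Sc_chrII")

  # ploidy is always the sum of the modal copies
  for (i in 1:20) {
    set.seed(i)
    cc <- transform(calls, copy = sample(0:4, 8, replace = TRUE))
    kk <- call_karyotype(cc)
    expect_identical(kk$ploidy, sprintf("%dN", kk$modal_sc + kk$modal_se))
  }
})

test_that("noiseless inputs give exact copy recovery for c in 0..6", {
  refs <- tiny_refs(seed = 43, n_chroms = 7, chrom_length = 10000)
  chroms <- paste0("Sc_chr", as.roman(1:7))
  haps <- lapply(0:6, function(k)
    if (k == 0) character(0) else paste("P.Sc.", 1:k, sep = ""))
  names(haps) <- chroms
  for (cc in paste0("Se_chr", 1:7)) haps[[cc]] <- "P.Se.1"
  sites <- do.call(rbind, lapply(1:6, function(k) {
    do.call(rbind, lapply(seq_len(k), function(a)
      data.frame(subgenome = "Sc", chrom = chroms[k + 1],
                 pos = a * 50L + seq(200, 9000, by = 180L), ref = "A",
                 alt = "T", parent = "P", alt_copies = a, copy = k)))
  }))
  truth <- structure(list(
    karyotype = structure(list(haplotypes = haps, mitotype = "Sc"),
                          class = "karyotype_spec"),
    copy_number = data.frame(
      subgenome = rep(c("Sc", "Se"), each = 7),
      chrom = c(chroms, paste0("Se_chr", 1:7)),
      copy = c(0:6, rep(1L, 7))),
    sites = sites,
    contributions = NULL, mitotype = "Sc", seed = 1L
  ), class = "truth_set")

  obs <- simulate_observed(truth, refs, per_copy_depth = 50,
                           bin_width = 1000, exact = TRUE, seed = 1)
  k <- infer_karyotype(obs$sites, obs$bins)
  got <- setNames(k$calls$copy, k$calls$chrom)
  want <- setNames(truth$copy_number$copy, truth$copy_number$chrom)
  expect_identical(got[names(want)], want)
})

test_that("copy calls are invariant to a global depth rescaling", {
  sc <- small_group3(seed = 31)
  k1 <- infer_karyotype(filter_variants(sc$observed$sites),
                        sc$observed$bins)
  doubled <- transform(sc$observed$bins, depth = depth * 2)
  k2 <- infer_karyotype(filter_variants(sc$observed$sites), doubled)
  expect_equal(k2$u, 2 * k1$u, tolerance = 0.02)
  expect_identical(k2$calls$copy, k1$calls$copy)
})

test_that("copy numbers of simulated hybrids are recovered with deletions", {
  refs <- tiny_refs(seed = 44, n_chroms = 6, chrom_length = 20000)
  nuc <- refs$chromosomes$chrom[!refs$chromosomes$is_mito]
  n_total <- 0; n_match <- 0; deletions_found <- TRUE
  for (h in 1:20) {
    set.seed(1000 + h)
    copies <- sample(c(0L, 1L, 2L, 3L, 4L), length(nuc), replace = TRUE,
                     prob = c(0.1, 0.3, 0.3, 0.2, 0.1))
    truth_sites <- do.call(rbind, lapply(which(copies > 0), function(i) {
      a <- sample.int(copies[i], 40, replace = TRUE)
      data.frame(subgenome = contig_subgenome(nuc[i]), chrom = nuc[i],
                 pos = seq(100, 19900, length.out = 40) + i,
                 ref = "A", alt = "T", parent = "P", alt_copies = a,
                 copy = copies[i])
    }))
    haps <- lapply(seq_along(nuc), function(i)
      if (copies[i] == 0) character(0)
      else paste("P", contig_subgenome(nuc[i]), seq_len(copies[i]),
                 sep = "."))
    names(haps) <- nuc
    if (all(copies == 0)) next
    truth <- structure(list(
      karyotype = structure(list(haplotypes = haps, mitotype = "Sc"),
                            class = "karyotype_spec"),
      copy_number = data.frame(subgenome = contig_subgenome(nuc),
                               chrom = nuc, copy = copies),
      sites = truth_sites, contributions = NULL, mitotype = "Sc",
      seed = h), class = "truth_set")
    obs <- simulate_observed(truth, refs, per_copy_depth = 50,
                             bin_width = 2000, seed = 1000 + h)
    k <- infer_karyotype(filter_variants(obs$sites), obs$bins)
    got <- setNames(k$calls$copy, k$calls$chrom)[nuc]
    n_total <- n_total + length(nuc)
    n_match <- n_match + sum(got == copies)
    if (any(copies == 0 & got != 0)) deletions_found <- FALSE
  }
  expect_gte(n_match / n_total, 0.95)
  expect_true(deletions_found)
})
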