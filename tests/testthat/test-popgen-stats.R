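# Heterozygosity, Weir-Cockerham F and theta, private alleles, null-allele
# diagnostics.

test_that("allele counts pool genes by ploidy and exclude missing genotypes", {
  ds <- genotype_dataset(make_females(list(L1 = table3_like_locus(10L, 20L))))
  ac <- allele_counts(ds, "L1", "P")
  expect_equal(unname(ac$counts[c("10", "20")]), c(14L, 4L))
  expect_equal(ac$n_diploid, 9)

  mixed <- genotype_dataset(tibble::tibble(
    id = c("M1", "F1"), population = "P", sex = c("male", "female"),
    locus = "L1", a1 = c(10L, 10L), a2 = c(NA, 20L)))
  ac <- allele_counts(mixed, "L1", "P", sexes = c("male", "female"))
  expect_equal(unname(ac$counts), c(2L, 1L))
  expect_equal(c(ac$n_diploid, ac$n_haploid), c(1, 1))

  all_missing <- genotype_dataset(tibble::tibble(
    id = "F1", population = "P", sex = "female", locus = "L1",
    a1 = 0L, a2 = 0L))
  expect_error(allele_counts(all_missing, "L1", "P"), "no non-missing")
})

test_that("observed heterozygosity is the diploid heterozygote fraction", {
  g12 <- rbind(matrix(rep(c(10L, 20L), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(10L, 10L), 7), ncol = 2, byrow = TRUE))
  ds <- genotype_dataset(make_females(list(L1 = g12)))
  expect_equal(round_half_up(observed_heterozygosity(ds, "L1", "P"), 3), 0.417)

  g9 <- rbind(c(10L, 20L), matrix(rep(10L, 16), ncol = 2))
  ds9 <- genotype_dataset(make_females(list(L1 = g9)))
  expect_equal(round_half_up(observed_heterozygosity(ds9, "L1", "P"), 3), 0.111)

  homo <- genotype_dataset(make_females(list(L1 = table3_like_locus())))
  expect_equal(observed_heterozygosity(homo, "L1", "P"), 0)
})

test_that("Levene-unbiased gene diversity matches closed form and hand values", {
  expect_equal(expected_heterozygosity_unbiased(c(A = 14, B = 4)),
               (18 / 17) * (1 - (196 + 16) / 324))
  # biallelic closed form (2n/(2n-1)) * 2pq
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    x <- sample(seq_len(2 * n - 1), 1)
    counts <- c(A = x, B = 2 * n - x)
    p <- x / (2 * n)
    expect_equal(expected_heterozygosity_unbiased(counts),
                 (2 * n / (2 * n - 1)) * 2 * p * (1 - p))
    # relabeling invariance
    expect_equal(expected_heterozygosity_unbiased(rev(counts)),
                 expected_heterozygosity_unbiased(counts))
  }
  expect_equal(expected_heterozygosity_unbiased(c(A = 18)), 0)
  expect_true(is.na(expected_heterozygosity_unbiased(c(A = 2))))
})

test_that("Weir-Cockerham F is exactly 1 for polymorphic loci without heterozygotes", {
  ds <- genotype_dataset(make_females(list(L1 = table3_like_locus())))
  expect_identical(fis_weir_cockerham(ds, "L1", "P"), 1)
  # three alleles, still all homozygous
  g <- cbind(c(rep(1L, 4), rep(2L, 3), rep(3L, 2)),
             c(rep(1L, 4), rep(2L, 3), rep(3L, 2)))
  ds3 <- genotype_dataset(make_females(list(L1 = g)))
  expect_identical(fis_weir_cockerham(ds3, "L1", "P"), 1)
  # monomorphic: undefined, not 0
  mono <- genotype_dataset(make_females(list(L1 = cbind(rep(1L, 9), rep(1L, 9)))))
  expect_true(is.na(fis_weir_cockerham(mono, "L1", "P")))
})

test_that("Weir-Cockerham F matches a hand plug-in at n = 2", {
  ds <- genotype_dataset(make_females(list(L1 = rbind(c(1L, 2L), c(1L, 2L)))))
  # by hand: p = 1/2, hbar = 1 for both alleles; c_u = 1/2;
  # b_u = 2 * (1/4 - 3/8) = -1/4; F = 1 - 1 / (2 * (1/2 - 1/4)) = -1
  expect_equal(fis_weir_cockerham(ds, "L1", "P"), -1)
})

test_that("F estimators are near 0 under random mating and agree in the limit", {
  ds <- genotype_dataset(hw_females(10000, c(0.5, 0.3, 0.2), seed = 314))
  f_wc <- fis_weir_cockerham(ds, "L1", "P")
  expect_lt(abs(f_wc), 0.05)
  expect_lt(abs(f_wc - fis_simple(ds, "L1", "P")), 0.02)
})

test_that("multilocus F is a ratio of sums over loci", {
  # single locus: reduces to the per-locus estimator
  ds1 <- genotype_dataset(hw_females(30, c(0.6, 0.4), seed = 9))
  expect_equal(as.numeric(fis_multilocus(ds1, "P")),
               fis_weir_cockerham(ds1, "L1", "P"))
  # all loci without heterozygotes: F = 1
  ds2 <- genotype_dataset(make_females(list(
    L1 = table3_like_locus(), L2 = table3_like_locus(30L, 40L))))
  expect_equal(as.numeric(fis_multilocus(ds2, "P")), 1)
  # ratio of sums, not mean of per-locus ratios
  set.seed(21)
  g1 <- hw_females(12, c(0.7, 0.3), locus = "L1")
  both <- genotype_dataset(dplyr::bind_rows(
    dplyr::mutate(g1, id = paste0("A", id)),
    dplyr::mutate(g1[g1$locus == "L1", ] |>
                    dplyr::mutate(locus = "L2"), id = paste0("A", id))
  ))
  comp1 <- hapmsat:::wc_within_components(both, "L1", "P")
  comp2 <- hapmsat:::wc_within_components(both, "L2", "P")
  expect_equal(as.numeric(fis_multilocus(both, "P")),
               1 - (comp1$c + comp2$c) / (comp1$b + comp1$c + comp2$b + comp2$c))
  # monomorphic loci are skipped and reported
  ds3 <- genotype_dataset(make_females(list(
    L1 = table3_like_locus(), L2 = cbind(rep(5L, 9), rep(5L, 9)))))
  f <- fis_multilocus(ds3, "P")
  expect_equal(attr(f, "skipped"), "L2")
  expect_error(fis_multilocus(genotype_dataset(make_females(list(
    L1 = cbind(rep(5L, 9), rep(5L, 9))))), "P"), "no informative locus")
})

test_that("Weir-Cockerham theta hits the analytic endpoints", {
  fixed <- genotype_dataset(dplyr::bind_rows(
    make_females(list(L1 = cbind(rep(1L, 8), rep(1L, 8))), population = "A",
                 id_prefix = "A"),
    make_females(list(L1 = cbind(rep(2L, 8), rep(2L, 8))), population = "B",
                 id_prefix = "B")))
  expect_equal(fst_weir_cockerham(fixed, c("A", "B"))$multilocus[1], 1)

  set.seed(8)
  g <- hw_females(15, c(0.5, 0.3, 0.2))
  dup <- genotype_dataset(dplyr::bind_rows(
    dplyr::mutate(g, population = "A", id = paste0("A", id)),
    dplyr::mutate(g, population = "B", id = paste0("B", id))))
  expect_lt(abs(fst_weir_cockerham(dup, c("A", "B"))$multilocus[1]), 0.02)
})

test_that("theta agrees with an independent component plug-in to 1e-12", {
  set.seed(12)
  for (i in 1:5) {
    gA <- matrix(sample(1:4, 2 * 12, TRUE, prob = c(.4, .3, .2, .1)), ncol = 2)
    gB <- matrix(sample(1:4, 2 * 9, TRUE, prob = c(.1, .2, .3, .4)), ncol = 2)
    ds <- genotype_dataset(dplyr::bind_rows(
      make_females(list(L1 = gA), population = "A", id_prefix = "A"),
      make_females(list(L1 = gB), population = "B", id_prefix = "B")))
    got <- fst_weir_cockerham(ds, c("A", "B"))$multilocus[1]
    want <- bf_theta(list(
      cbind(pmin(gA[, 1], gA[, 2]), pmax(gA[, 1], gA[, 2])),
      cbind(pmin(gB[, 1], gB[, 2]), pmax(gB[, 1], gB[, 2]))))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("private allele proportions follow set logic", {
  mk <- function(pop, prefix, col1, col2) {
    make_females(list(L1 = cbind(col1, col2)), population = pop,
                 id_prefix = prefix)
  }
  ds <- genotype_dataset(dplyr::bind_rows(
    mk("p1", "A", c(1L, 2L, 3L), c(1L, 2L, 3L)),
    mk("p2", "B", c(2L, 2L, 2L), c(2L, 2L, 2L))))
  expect_equal(private_allele_proportion(ds, "p1"), 2 / 3)
  expect_equal(private_allele_proportion(ds, "p2"), 0)

  disj <- genotype_dataset(dplyr::bind_rows(
    mk("p1", "A", c(1L, 2L), c(1L, 2L)), mk("p2", "B", c(3L, 4L), c(3L, 4L))))
  expect_equal(private_allele_proportion(disj, "p1"), 1)
  expect_equal(private_allele_proportion(disj, "p2"), 1)

  same <- genotype_dataset(dplyr::bind_rows(
    mk("p1", "A", c(1L, 2L), c(1L, 2L)), mk("p2", "B", c(1L, 2L), c(1L, 2L))))
  expect_equal(private_allele_proportion(same, "p1"), 0)
  expect_equal(private_allele_proportion(same, "p2"), 0)
})

test_that("haploid males expose null-allele signatures", {
  females <- make_females(list(L1 = table3_like_locus(128L, 140L)))
  males <- tibble::tibble(
    id = sprintf("M%02d", 1:12), population = "P", sex = "male", locus = "L1",
    a1 = c(rep(128L, 9), 162L, 0L, 0L), a2 = NA_integer_)
  ds <- genotype_dataset(dplyr::bind_rows(females, males))
  diag <- null_allele_diagnostics(ds)
  expect_equal(diag$haploid_dropout, 1 / 6)  # 2 of 12 males missing
  expect_true(diag$suspicious)
  expect_equal(diag$suspicious_alleles[[1]], 162L)
  expect_equal(diag$suspicious_carriers[[1]], "M10")

  clean_males <- dplyr::mutate(males, a1 = rep(c(128L, 140L), 6))
  clean <- genotype_dataset(dplyr::bind_rows(females, clean_males))
  diag2 <- null_allele_diagnostics(clean)
  expect_false(diag2$suspicious)
  expect_equal(diag2$haploid_dropout, 0)

  expect_warning(null_allele_diagnostics(genotype_dataset(females)),
                 "no haploid males")
})
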