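# Hardy-Weinberg exact/Markov-chain tests, LD permutation test, FDR.

test_that("Levene probabilities sum to 1 over every enumerated configuration", {
  set.seed(17)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    a <- as.integer(rmultinom(1, 2 * sample(4:10, 1), rep(1, k)))
    a <- a[a > 0]
    if (length(a) < 2) next
    arrays <- hapmsat:::enumerate_genotype_arrays(a)
    lp <- vapply(arrays, hapmsat:::levene_log_prob, numeric(1))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
  }
})

test_that("the two-diploid worked example gives p = 1/3 in both modes", {
  # alleles {A:2, B:2}: P({AB,AB}) = 2/3, P({AA,BB}) = 1/3
  arr <- as_genotype_array(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(hwe_exact_test(arr, "probability")$p_value, 1 / 3)
  expect_equal(hwe_exact_test(arr, "deficit")$p_value, 1 / 3)
  het <- as_genotype_array(matrix(c(0L, 2L, 0L, 0L), 2, 2, byrow = FALSE))
  expect_equal(hwe_exact_test(het, "probability")$p_value, 1)
  expect_equal(hwe_exact_test(het, "deficit")$p_value, 1)
})

test_that("enumeration matches an independent gene-pairing oracle", {
  set.seed(23)
  for (i in 1:8) {
    k <- sample(2:3, 1)
    n <- sample(3:5, 1)
    genes <- sort(sample(seq_len(k), 2 * n, replace = TRUE))
    if (length(unique(genes)) < 2) next
    a <- as.integer(table(genes))
    arrays <- hapmsat:::enumerate_genotype_arrays(a)
    lp <- vapply(arrays, hapmsat:::levene_log_prob, numeric(1))
    oracle <- pairing_oracle(genes)
    expect_equal(length(lp), length(oracle))
    key_of <- function(m) {
      alle <- sort(unique(genes))
      pairs <- character(0)
      for (u in seq_along(alle)) for (v in u:length(alle)) {
        if (m[u, v] > 0) {
          pairs <- c(pairs, rep(paste(alle[u], alle[v], sep = "/"), m[u, v]))
        }
      }
      paste(sort(pairs), collapse = ";")
    }
    got <- setNames(exp(lp), vapply(arrays, key_of, character(1)))
    expect_equal(sort(names(got)), sort(names(oracle)))
    expect_equal(unname(got[names(oracle)]), unname(oracle),
                 tolerance = 1e-10)
    # probability-mode p agrees with the oracle tail for each observed array
    for (j in seq_along(arrays)) {
      p_pkg <- hwe_exact_test(as_genotype_array(arrays[[j]]),
                              "probability")$p_value
      p_orc <- sum(oracle[oracle <= oracle[[key_of(arrays[[j]])]] + 1e-12])
      expect_equal(p_pkg, p_orc, tolerance = 1e-10)
    }
  }
})

test_that("the Markov chain reproduces enumerated p-values within MC error", {
  set.seed(31)
  for (i in 1:5) {
    genes <- sample(1:3, 20, replace = TRUE)
    if (length(unique(genes)) < 2) next
    perm <- sample(genes)
    m <- matrix(0L, 3, 3)
    for (r in seq(1, 19, 2)) {
      a <- min(perm[r], perm[r + 1]); b <- max(perm[r], perm[r + 1])
      m[a, b] <- m[a, b] + 1L
    }
    keep <- (rowSums(m) + colSums(m)) > 0
    arr <- as_genotype_array(m[keep, keep, drop = FALSE])
    if (length(arr$alleles) < 2) next
    for (mode in c("probability", "deficit")) {
      p_ex <- hwe_exact_test(arr, mode)$p_value
      t_mc <- hwe_exact_test(arr, mode, mc = mc_config(), method = "markov_chain")
      expect_lt(abs(t_mc$p_value - p_ex),
                3 * max(t_mc$std_error, 2e-3))
      expect_equal(t_mc$method, "markov_chain")
      expect_false(is.na(t_mc$std_error))
    }
  }
})

test_that("monomorphic or capped inputs raise instructive errors", {
  mono <- as_genotype_array(matrix(9L, 1, 1))
  expect_error(hwe_exact_test(mono), "monomorphic")
  big <- as_genotype_array(diag(rep(30L, 8)))
  expect_error(hwe_exact_test(big, enumeration_cap = 10), "mc")
})

test_that("perfectly associated haploid loci give a tiny LD p-value", {
  tbl <- dplyr::bind_rows(
    tibble::tibble(id = sprintf("M%02d", 1:20), population = "P",
                   sex = "male", locus = "L1",
                   a1 = rep(c(1L, 2L), each = 10), a2 = NA_integer_),
    tibble::tibble(id = sprintf("M%02d", 1:20), population = "P",
                   sex = "male", locus = "L2",
                   a1 = rep(c(7L, 9L), each = 10), a2 = NA_integer_))
  ds <- genotype_dataset(dplyr::bind_rows(tbl))
  set.seed(1)
  res <- ld_test(ds, c("L1", "L2"), "male",
                 mc = mc_config(batches = 20, iterations_per_batch = 500))
  expect_lte(res$p_value, 0.001)
  expect_gt(res$statistic, 0)
})

test_that("LD permutation p matches Fisher's exact test on 2x2 haploid tables", {
  set.seed(4)
  for (i in 1:3) {
    n <- 30
    x <- sample(1:2, n, TRUE)
    y <- ifelse(runif(n) < 0.6, x, sample(1:2, n, TRUE))  # moderate association
    tbl <- dplyr::bind_rows(
      tibble::tibble(id = sprintf("M%02d", 1:n), population = "P",
                     sex = "male", locus = "L1", a1 = x, a2 = NA_integer_),
      tibble::tibble(id = sprintf("M%02d", 1:n), population = "P",
                     sex = "male", locus = "L2", a1 = y, a2 = NA_integer_))
    ds <- genotype_dataset(tbl)
    res <- ld_test(ds, c("L1", "L2"), "male",
                   mc = mc_config(batches = 20, iterations_per_batch = 500))
    fis <- fisher.test(table(x, y))$p.value
    expect_lt(abs(res$p_value - fis), 3 * max(res$std_error, 0.01) + 0.02)
  }
})

test_that("LD test needs two categories per locus in the stratum", {
  tbl <- dplyr::bind_rows(
    tibble::tibble(id = c("M1", "M2"), population = "P", sex = "male",
                   locus = "L1", a1 = c(1L, 1L), a2 = NA_integer_),
    tibble::tibble(id = c("M1", "M2"), population = "P", sex = "male",
                   locus = "L2", a1 = c(1L, 2L), a2 = NA_integer_))
  expect_error(ld_test(genotype_dataset(tbl), c("L1", "L2"), "male"),
               ">= 2")
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.07, 6)), rep(0.07, 6))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(1:25, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bf_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance report bands q-values and counts significant loci", {
  res <- tibble::tibble(locus = paste0("L", 1:4),
                        p_value = c(1e-5, 0.004, 0.02, 0.9))
  rep1 <- significance_report(res)
  # BH q-values: 4e-5, 0.008, 0.0267, 0.9
  expect_equal(rep1$label, c("<0.001", "<0.01", "<0.05", "N.S."))
  # 12 of 20 loci below threshold, as a constructed summary
  p <- c(rep(1e-4, 12), seq(0.5, 0.9, length.out = 8))
  rep2 <- significance_report(tibble::tibble(locus = paste0("L", 1:20),
                                             p_value = p))
  expect_equal(attr(rep2, "n_significant"), 12)
})
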