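# Exact and Monte-Carlo tests: Hardy-Weinberg (Levene conditional
# distribution; full enumeration or the Guo-Thompson switch chain) and
# genotypic/allelic linkage disequilibrium by permutation, with
# Benjamini-Hochberg FDR correction.

#' Monte-Carlo configuration
#'
#' Markov-chain / permutation parameters, following the customary defaults
#' of GENEPOP-style Markov-chain tests: a dememorization (burn-in) phase,
#' then batches whose means give the Monte-Carlo standard error.
#'
#' @param dememorization Burn-in steps discarded (default 10000).
#' @param batches Number of batches (default 20).
#' @param iterations_per_batch Recorded steps per batch (default 5000).
#' @param seed Optional integer seed applied before sampling.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(dememorization = 10000, batches = 20,
                      iterations_per_batch = 5000, seed = NULL) {
  for (nm in c("dememorization", "batches", "iterations_per_batch")) {
    check_number(get(nm), nm, lower = 1)
  }
  structure(list(dememorization = as.integer(dememorization),
                 batches = as.integer(batches),
                 iterations_per_batch = as.integer(iterations_per_batch),
                 seed = seed),
            class = "mc_config")
}

#' Genotype array at one locus
#'
#' The sufficient statistics of the Hardy-Weinberg exact test: diploid
#' genotype counts `n_uv` (u <= v) at one locus in one population, with the
#' derived allele counts, sample size `n` and heterozygote count `h`.
#'
#' @param dataset A `geno_tbl`.
#' @param locus,population Names selecting one locus in one population.
#' @return List of class `genotype_array`: `counts` (upper-triangular k x k
#'   matrix, allele codes as dimnames), `alleles`, `allele_counts`, `n`, `h`.
#' @export
genotype_array <- function(dataset, locus, population) {
  d <- subset_genotypes(dataset, populations = population, sexes = "female",
                        loci = locus)
  d <- d[d$a1 != 0L, , drop = FALSE]
  if (nrow(d) < 2) abort("need at least two typed diploids.")
  alleles <- sort(unique(c(d$a1, d$a2)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i <- match(d$a1, alleles)
  j <- match(d$a2, alleles)
  for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1L
  as_genotype_array(m)
}

#' @rdname genotype_array
#' @param counts Upper-triangular matrix of genotype counts (`counts[i, j]`,
#'   `i <= j`).
#' @export
as_genotype_array <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k != ncol(counts)) abort("genotype counts must be a square matrix.")
  if (any(counts[lower.tri(counts)] != 0)) {
    counts[upper.tri(counts)] <- counts[upper.tri(counts)] +
      t(counts)[upper.tri(counts)]
    counts[lower.tri(counts)] <- 0L
  }
  storage.mode(counts) <- "integer"
  a <- vapply(seq_len(k), function(u) {
    2L * counts[u, u] + sum(counts[u, -u][seq_len(k)[-u] > u]) +
      sum(counts[-u, u][seq_len(k)[-u] < u])
  }, integer(1))
  structure(list(counts = counts,
                 alleles = rownames(counts) %||% as.character(seq_len(k)),
                 allele_counts = a,
                 n = sum(counts),
                 h = sum(counts[upper.tri(counts)])),
            class = "genotype_array")
}

# log Levene probability of a genotype array given its allele counts:
# P = n! 2^h prod(a_u!) / ((2n)! prod(n_uv!))
levene_log_prob <- function(counts) {
  n <- sum(counts)
  h <- sum(counts[upper.tri(counts)])
  # upper-triangular storage: row + column sums count homozygotes twice
  a <- colSums(counts) + rowSums(counts)
  lfactorial(n) + h * log(2) + sum(lfactorial(a)) -
    lfactorial(2 * n) - sum(lfactorial(counts[upper.tri(counts, diag = TRUE)]))
}

# Enumerate all genotype arrays with the given allele (gene) counts.
# Cells are filled in row order (1,1), (1,2), ..., (k,k); after the last
# cell of allele i, its remaining gene count must be zero. Returns a list
# of upper-triangular matrices, or NULL if `cap` is exceeded.
enumerate_genotype_arrays <- function(allele_counts, cap = 1e6) {
  k <- length(allele_counts)
  out <- vector("list", 256L)
  n_out <- 0L
  overflow <- FALSE
  m <- matrix(0L, k, k)
  rec <- function(i, j, rem) {
    if (overflow) return()
    if (i > k) {
      if (all(rem == 0L)) {
        n_out <<- n_out + 1L
        if (n_out > cap) {
          overflow <<- TRUE
          return()
        }
        if (n_out > length(out)) length(out) <<- 2L * length(out)
        out[[n_out]] <<- m
      }
      return()
    }
    if (j > k) {
      if (rem[i] != 0L) return()  # allele i fully allocated after its row
      rec(i + 1L, i + 1L, rem)
      return()
    }
    max_c <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (cnt in 0:max_c) {
      m[i, j] <<- cnt
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * cnt else {
        rem2[i] <- rem2[i] - cnt
        rem2[j] <- rem2[j] - cnt
      }
      rec(i, j + 1L, rem2)
      if (overflow) break
    }
    m[i, j] <<- 0L
  }
  rec(1L, 1L, as.integer(allele_counts))
  if (overflow) return(NULL)
  out[seq_len(n_out)]
}

#' Hardy-Weinberg exact test
#'
#' Conditional exact test of Hardy-Weinberg proportions using the Levene
#' distribution of genotype arrays given allele counts:
#' `P(array) = n! 2^h prod(a_u!) / ((2n)! prod(n_uv!))`.
#' In `"probability"` mode the p-value sums `P(array')` over arrays no more
#' probable than the observed one (ties included); in `"deficit"` mode it
#' is the one-sided heterozygote-deficiency tail, summing over arrays with
#' `h(array') <= h(observed)` — the alternative expected under inbreeding.
#' Arrays are fully enumerated when their number is at most
#' `enumeration_cap`; beyond that a Guo-Thompson switch Markov chain is run
#' with `mc`, returning the p-value with a batch-means standard error.
#'
#' @param array A [genotype_array()].
#' @param mode `"probability"` or `"deficit"`.
#' @param mc An [mc_config()], required when enumeration is infeasible.
#' @param enumeration_cap Maximum number of arrays enumerated (default 1e6).
#' @param method `"auto"` (enumerate if possible), `"enumeration"`, or
#'   `"markov_chain"`.
#' @return List of class `hwe_test`: `p_value`, `std_error` (`NA` for
#'   enumeration), `method`, `n_resamples`, `mode`, `statistic` (observed
#'   heterozygote count).
#' @export
hwe_exact_test <- function(array, mode = c("probability", "deficit"),
                           mc = NULL, enumeration_cap = 1e6,
                           method = c("auto", "enumeration", "markov_chain")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!inherits(array, "genotype_array")) abort("`array` must be a genotype_array.")
  if (length(array$alleles) < 2) {
    abort("monomorphic locus: Hardy-Weinberg test undefined.")
  }
  if (method != "markov_chain") {
    res <- hwe_exact_tail(array$allele_counts, array$counts,
                          if (mode == "deficit") 1L else 0L,
                          as.double(enumeration_cap))
    if (!res$feasible && method == "enumeration") {
      abort(paste0("more than `enumeration_cap` arrays; use method = ",
                   "\"markov_chain\" with an mc_config."))
    }
    if (res$feasible) {
      return(structure(list(p_value = min(1, res$p), std_error = NA_real_,
                            method = "enumeration",
                            n_resamples = res$n_arrays, mode = mode,
                            statistic = array$h),
                       class = "hwe_test"))
    }
  }
  if (is.null(mc)) {
    abort("enumeration infeasible (or markov_chain requested): supply `mc`.")
  }
  if (!is.null(mc$seed)) set.seed(mc$seed)
  bm <- gt_chain_batches(array$counts, mc$dememorization, mc$batches,
                         mc$iterations_per_batch,
                         if (mode == "deficit") 1L else 0L)
  structure(list(p_value = mean(bm),
                 std_error = stats::sd(bm) / sqrt(length(bm)),
                 method = "markov_chain",
                 n_resamples = mc$batches * mc$iterations_per_batch,
                 mode = mode, statistic = array$h),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg exact test (%s mode, %s)\n", x$mode, x$method))
  cat(sprintf("  p = %.5g%s\n", x$p_value,
              if (is.na(x$std_error)) "" else
                sprintf(" +/- %.2g (MC s.e.)", x$std_error)))
  invisible(x)
}

# ---- linkage disequilibrium ------------------------------------------------

g_statistic <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  terms <- tab * log(tab / e)
  2 * sum(terms[tab > 0])
}

#' Permutation test of linkage disequilibrium
#'
#' Sex-stratified genotypic LD test between two loci. In the haploid (male)
#' stratum the contingency table crosses alleles; in the diploid (female)
#' stratum it crosses unordered genotypes, so no phasing is required. The
#' statistic is the log-likelihood-ratio G; significance comes from random
#' permutation of the second locus' categories, with the add-one estimator
#' `p = (#{G_perm >= G_obs} + 1) / (N + 1)` (never exactly zero) and a
#' batch-means standard error.
#'
#' @param dataset A `geno_tbl`.
#' @param locus_pair Character vector of two locus names.
#' @param sex_stratum `"male"` or `"female"`.
#' @param mc An [mc_config()]; permutations = `batches *
#'   iterations_per_batch` (default here 20 x 500).
#' @param population Optional population restriction.
#' @return List of class `ld_test`: `statistic` (G), `p_value`,
#'   `std_error`, `method = "permutation"`, `n_resamples`.
#' @export
ld_test <- function(dataset, locus_pair, sex_stratum = c("female", "male"),
                    mc = mc_config(batches = 20, iterations_per_batch = 500),
                    population = NULL) {
  sex_stratum <- match.arg(sex_stratum)
  if (length(locus_pair) != 2L) abort("`locus_pair` must name two loci.")
  d <- subset_genotypes(dataset, populations = population,
                        sexes = sex_stratum, loci = locus_pair)
  wide <- tidyr::pivot_wider(
    tibble::tibble(id = d$id, locus = d$locus,
                   cat = ifelse(d$a1 == 0L, NA_character_,
                                ifelse(is.na(d$a2), as.character(d$a1),
                                       paste0(d$a1, "/", d$a2)))),
    names_from = "locus", values_from = "cat")
  x <- wide[[locus_pair[1]]]
  y <- wide[[locus_pair[2]]]
  keep <- !is.na(x) & !is.na(y)
  x <- factor(x[keep])
  y <- factor(y[keep])
  if (length(x) < 2 || nlevels(x) < 2 || nlevels(y) < 2) {
    abort("stratum needs >= 2 individuals and >= 2 categories at each locus.")
  }
  if (!is.null(mc$seed)) set.seed(mc$seed)
  xi <- as.integer(x)
  yi <- as.integer(y)
  K <- nlevels(x)
  L <- nlevels(y)
  g_from_codes <- function(yy) {
    tab <- matrix(tabulate(xi + K * (yy - 1L), K * L), K, L)
    g_statistic(tab)
  }
  g_obs <- g_from_codes(yi)
  n_perm <- mc$batches * mc$iterations_per_batch
  hits <- logical(n_perm)
  for (b in seq_len(n_perm)) {
    hits[b] <- g_from_codes(sample(yi)) >= g_obs - 1e-12
  }
  batch_id <- rep(seq_len(mc$batches), each = mc$iterations_per_batch)
  structure(list(statistic = g_obs,
                 p_value = (sum(hits) + 1) / (n_perm + 1),
                 std_error = stats::sd(tapply(hits, batch_id, mean)) /
                   sqrt(mc$batches),
                 method = "permutation",
                 n_resamples = n_perm),
            class = "ld_test")
}

# ---- multiple testing ------------------------------------------------------

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} m p_(j) / j`, capped at
#' 1 and returned in input order (a thin validated wrapper around
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must be numbers in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Significance report with banded labels
#'
#' FDR-adjusts a set of per-locus p-values and renders the banded labels
#' used in characterization tables: `"<0.001"`, `"<0.01"`, `"<0.05"`, or
#' `"N.S."`.
#'
#' @param results Data frame with columns `locus` and `p_value`.
#' @param alpha_level Significance threshold on the q-values (default 0.05).
#' @return Tibble with `locus`, `p_value`, `q_value`, `significant`,
#'   `label`; the number of significant loci is in the `"n_significant"`
#'   attribute.
#' @export
significance_report <- function(results, alpha_level = 0.05) {
  q <- fdr_adjust(results$p_value)
  label <- dplyr::case_when(
    q < 0.001 ~ "<0.001",
    q < 0.01 ~ "<0.01",
    q < alpha_level ~ paste0("<", format(alpha_level)),
    TRUE ~ "N.S."
  )
  out <- tibble::tibble(locus = results$locus, p_value = results$p_value,
                        q_value = q, significant = q < alpha_level,
                        label = label)
  attr(out, "n_significant") <- sum(out$significant)
  out
}
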