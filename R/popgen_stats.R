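# Per-locus and multilocus population-genetic statistics, sex-aware.
#
# Heterozygosity, inbreeding and Hardy-Weinberg statistics are computed from
# diploid females only (haploid males carry no heterozygosity information);
# allele pooling across sexes is used for private-allele and null-allele
# diagnostics. Undefined statistics are reported as NA, never as 0.

#' Allele counts at one locus
#'
#' Gene counts by allele for one locus/population: haploids contribute one
#' gene, diploids two; missing genotypes are excluded from the sample sizes.
#'
#' @param dataset A `geno_tbl`.
#' @param locus,population Names selecting one locus in one population.
#' @param sexes Sexes to pool (default `"female"`, the convention for
#'   heterozygosity and inbreeding work in haplodiploids).
#' @return List with `locus`, `population`, `counts` (named integer vector,
#'   allele code -> gene count), `n_diploid`, `n_haploid`.
#' @export
allele_counts <- function(dataset, locus, population, sexes = "female") {
  d <- subset_genotypes(dataset, populations = population, sexes = sexes,
                        loci = locus)
  d <- d[d$a1 != 0L, , drop = FALSE]
  if (!nrow(d)) {
    abort(sprintf("no non-missing genotypes at locus %s in population %s",
                  locus, population))
  }
  genes <- c(d$a1, d$a2[!is.na(d$a2)])
  counts <- table(genes)
  list(locus = locus, population = population,
       counts = setNames(as.integer(counts), names(counts)),
       n_diploid = sum(d$sex == "female"),
       n_haploid = sum(d$sex == "male"))
}

#' Observed heterozygosity
#'
#' Fraction of heterozygous individuals among the non-missing diploids.
#' Haploids are excluded by definition.
#'
#' @param dataset A `geno_tbl`.
#' @param locus,population Names selecting one locus in one population.
#' @return Proportion in `[0, 1]`, or `NA` if no diploid is typed.
#' @export
observed_heterozygosity <- function(dataset, locus, population) {
  d <- subset_genotypes(dataset, populations = population, sexes = "female",
                        loci = locus)
  d <- d[d$a1 != 0L, , drop = FALSE]
  if (!nrow(d)) return(NA_real_)
  mean(d$a1 != d$a2)
}

#' Unbiased expected heterozygosity (gene diversity)
#'
#' Levene/Nei small-sample-corrected gene diversity from diploid gene
#' counts: `(2n/(2n-1)) * (1 - sum(p_u^2))` with `n` diploids and allele
#' frequencies `p_u` taken over the `2n` genes.
#'
#' @param counts Named gene-count vector, or the list from
#'   [allele_counts()].
#' @return Gene diversity in `[0, 1]`; `NA` when fewer than 2 diploids.
#' @examples
#' expected_heterozygosity_unbiased(c(A = 14, B = 4))  # 0.366 at n = 9
#' @export
expected_heterozygosity_unbiased <- function(counts) {
  if (is.list(counts)) counts <- counts$counts
  genes <- sum(counts)
  if (genes %% 2 != 0) {
    abort("gene count must be even (diploid genes only) for unbiased H_E.")
  }
  n <- genes / 2
  if (n < 2) return(NA_real_)
  p <- counts / genes
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

# Weir & Cockerham (1984) within-population components for one locus.
# For each allele u: c_u = hbar_u / 2 and
# b_u = (n/(n-1)) * (p_u (1-p_u) - (2n-1)/(4n) * hbar_u),
# where hbar_u is the observed frequency of heterozygotes carrying u.
# Returns the summed components; F = 1 - sum(c)/sum(b + c).
wc_within_components <- function(dataset, locus, population) {
  d <- subset_genotypes(dataset, populations = population, sexes = "female",
                        loci = locus)
  d <- d[d$a1 != 0L, , drop = FALSE]
  n <- nrow(d)
  if (n < 2) return(NULL)
  genes <- c(d$a1, d$a2)
  alleles <- sort(unique(genes))
  if (length(alleles) < 2) return(NULL)
  comp <- vapply(alleles, function(u) {
    p_u <- mean(genes == u)
    hbar <- mean(d$a1 != d$a2 & (d$a1 == u | d$a2 == u))
    c_u <- hbar / 2
    b_u <- (n / (n - 1)) * (p_u * (1 - p_u) - (2 * n - 1) / (4 * n) * hbar)
    c(b = b_u, c = c_u)
  }, c(b = 0, c = 0))
  list(b = sum(comp["b", ]), c = sum(comp["c", ]), n = n)
}

#' Weir-Cockerham inbreeding coefficient (single locus)
#'
#' The Weir & Cockerham (1984) within-population inbreeding estimator
#' (little-f / F_IS), `1 - sum(c_u) / sum(b_u + c_u)` over alleles, computed
#' from diploid females. This is the estimator behind the `F` column of
#' standard GENEPOP-style characterization tables; it equals exactly 1 at
#' any polymorphic locus with zero observed heterozygosity. The naive
#' plug-in `1 - H_O/H_E` is available via `fis_simple()` for comparison.
#'
#' @inheritParams observed_heterozygosity
#' @return Estimate of F, or `NA` when the locus is monomorphic, fewer than
#'   two diploids are typed, or the denominator is non-positive.
#' @export
fis_weir_cockerham <- function(dataset, locus, population) {
  comp <- wc_within_components(dataset, locus, population)
  if (is.null(comp)) return(NA_real_)
  denom <- comp$b + comp$c
  if (denom <= 0) return(NA_real_)
  1 - comp$c / denom
}

#' @rdname fis_weir_cockerham
#' @export
fis_simple <- function(dataset, locus, population) {
  ho <- observed_heterozygosity(dataset, locus, population)
  he <- expected_heterozygosity_unbiased(
    allele_counts(dataset, locus, population, sexes = "female"))
  if (is.na(ho) || is.na(he) || he == 0) return(NA_real_)
  1 - ho / he
}

#' Multilocus inbreeding coefficient
#'
#' Ratio-of-sums combination of the Weir-Cockerham within-population
#' components over loci: `F = 1 - sum_l sum_u c / sum_l sum_u (b + c)`.
#' Loci with undefined components (monomorphic, too few diploids) are
#' skipped and recorded in the `"skipped"` attribute. A ratio of sums —
#' never a mean of per-locus ratios — so informative loci are weighted by
#' their information content.
#'
#' @param dataset A `geno_tbl`.
#' @param population Population name.
#' @param loci Loci to use (default all).
#' @return Multilocus F (attribute `"skipped"` lists excluded loci).
#' @export
fis_multilocus <- function(dataset, population, loci = NULL) {
  loci <- loci %||% gd_loci(dataset)
  comps <- lapply(loci, function(l) wc_within_components(dataset, l, population))
  ok <- !vapply(comps, is.null, logical(1))
  if (!any(ok)) {
    abort(sprintf("no informative locus in population %s", population))
  }
  b <- sum(vapply(comps[ok], `[[`, numeric(1), "b"))
  cc <- sum(vapply(comps[ok], `[[`, numeric(1), "c"))
  if (b + cc <= 0) {
    abort(sprintf("non-positive multilocus denominator in population %s",
                  population))
  }
  structure(1 - cc / (b + cc), skipped = loci[!ok])
}

#' Weir-Cockerham F_ST between two populations
#'
#' The Weir & Cockerham (1984) theta estimator from variance components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), computed from diploid females: per-locus
#' `theta = sum_u a_u / sum_u (a_u + b_u + c_u)` and a multilocus ratio of
#' sums over loci. Loci not typed in both populations are skipped (listed
#' in the `"skipped"` attribute of the result).
#'
#' @param dataset A `geno_tbl`.
#' @param pop_pair Character vector of the two population names.
#' @param loci Loci to use (default all).
#' @return List with `per_locus` (tibble: locus, theta) and `multilocus`.
#' @export
fst_weir_cockerham <- function(dataset, pop_pair, loci = NULL) {
  if (length(pop_pair) != 2L) abort("`pop_pair` must name two populations.")
  loci <- loci %||% gd_loci(dataset)
  per <- list()
  sums <- c(a = 0, den = 0)
  skipped <- character(0)
  for (l in loci) {
    comp <- wc_theta_components(dataset, l, pop_pair)
    if (is.null(comp)) {
      skipped <- c(skipped, l)
      next
    }
    theta_l <- if (comp["den"] > 0) comp["a"] / comp["den"] else NA_real_
    per[[length(per) + 1L]] <- tibble::tibble(locus = l,
                                              theta = unname(theta_l))
    sums <- sums + comp
  }
  if (!length(per)) abort("no locus typed in both populations.")
  list(per_locus = dplyr::bind_rows(per),
       multilocus = structure(unname(sums["a"] / sums["den"]),
                              skipped = skipped))
}

# W&C 1984 variance components a, b, c for one locus over r = 2 populations
# (diploid females). Returns c(a = sum_a, den = sum_(a+b+c)) over alleles.
wc_theta_components <- function(dataset, locus, pops) {
  per_pop <- lapply(pops, function(p) {
    d <- subset_genotypes(dataset, populations = p, sexes = "female",
                          loci = locus)
    d <- d[d$a1 != 0L, , drop = FALSE]
    d
  })
  ns <- vapply(per_pop, nrow, integer(1))
  if (any(ns < 2)) return(NULL)
  genes <- lapply(per_pop, function(d) c(d$a1, d$a2))
  alleles <- sort(unique(unlist(genes)))
  if (length(alleles) < 2) return(c(a = 0, den = 0))
  r <- 2
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  a_sum <- 0
  den_sum <- 0
  for (u in alleles) {
    p_i <- vapply(genes, function(g) mean(g == u), numeric(1))
    h_i <- vapply(per_pop, function(d) {
      mean(d$a1 != d$a2 & (d$a1 == u | d$a2 == u))
    }, numeric(1))
    pbar <- sum(ns * p_i) / (r * nbar)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    den_sum <- den_sum + a + b + cc
  }
  c(a = a_sum, den = den_sum)
}

#' Private-allele proportion
#'
#' Fraction of the focal population's observed alleles (pooled over loci,
#' both sexes by default) seen in no reference population. Alleles are
#' counted as locus/allele pairs.
#'
#' @param dataset A `geno_tbl`.
#' @param population Focal population.
#' @param reference_pops Reference populations (default: all others).
#' @param sexes Sexes contributing observations (default both).
#' @return Proportion in `[0, 1]`.
#' @export
private_allele_proportion <- function(dataset, population,
                                      reference_pops = NULL,
                                      sexes = c("male", "female")) {
  reference_pops <- reference_pops %||%
    setdiff(gd_populations(dataset), population)
  if (!length(reference_pops)) abort("needs at least one reference population.")
  observed_pairs <- function(pops) {
    d <- subset_genotypes(dataset, populations = pops, sexes = sexes)
    d <- d[d$a1 != 0L, , drop = FALSE]
    unique(c(paste(d$locus, d$a1), paste(d$locus[!is.na(d$a2)],
                                         d$a2[!is.na(d$a2)])))
  }
  focal <- observed_pairs(population)
  if (!length(focal)) {
    abort(sprintf("population %s has no observed alleles", population))
  }
  ref <- observed_pairs(reference_pops)
  mean(!focal %in% ref)
}

#' Null-allele diagnostics from haploid males
#'
#' In a haplodiploid system the haploid males are a built-in null-allele
#' probe: a non-amplifying allele shows up as a missing male genotype
#' (`haploid_dropout`), and an allele amplified only in males — never in
#' any female — is flagged `suspicious` with its carriers listed, since a
#' male-only allele could reflect differential amplification in
#' heterozygous females.
#'
#' @param dataset A `geno_tbl` containing haploid males.
#' @param population Optional population restriction.
#' @return Tibble: `locus`, `haploid_dropout` (proportion of males with a
#'   missing genotype), `suspicious_alleles` (list column of allele codes),
#'   `suspicious_carriers` (list column of male ids), `suspicious` flag.
#' @export
null_allele_diagnostics <- function(dataset, population = NULL) {
  d <- if (is.null(population)) dataset else {
    subset_genotypes(dataset, populations = population)
  }
  if (!any(d$sex == "male")) {
    warn("no haploid males in dataset; null-allele diagnostics undefined.")
    return(tibble::tibble(locus = character(), haploid_dropout = numeric(),
                          suspicious_alleles = list(),
                          suspicious_carriers = list(),
                          suspicious = logical()))
  }
  out <- lapply(gd_loci(d), function(l) {
    males <- d[d$sex == "male" & d$locus == l, , drop = FALSE]
    females <- d[d$sex == "female" & d$locus == l, , drop = FALSE]
    dropout <- mean(males$a1 == 0L)
    female_alleles <- unique(c(females$a1, females$a2))
    female_alleles <- female_alleles[!is.na(female_alleles) &
                                       female_alleles != 0L]
    male_typed <- males[males$a1 != 0L, , drop = FALSE]
    only_male <- setdiff(unique(male_typed$a1), female_alleles)
    carriers <- male_typed$id[male_typed$a1 %in% only_male]
    tibble::tibble(locus = l, haploid_dropout = dropout,
                   suspicious_alleles = list(as.integer(only_male)),
                   suspicious_carriers = list(carriers),
                   suspicious = length(only_male) > 0)
  })
  dplyr::bind_rows(out)
}
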