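# Per-locus characterization tables in the layout of classic
# microsatellite development papers: size range, allele number, H_O, H_E,
# F and the FDR-corrected Hardy-Weinberg p-value per locus.

#' Per-locus statistics for one population
#'
#' Computes, from diploid females, the standard characterization columns
#' per locus: allele number and size range (both sexes), observed
#' heterozygosity, Levene/Nei unbiased expected heterozygosity,
#' Weir-Cockerham inbreeding coefficient, and the Hardy-Weinberg exact
#' test p-value with its FDR-adjusted q-value and banded label.
#' Monomorphic loci report `H_O = H_E = 0` with `F` and the test undefined
#' (`NA`), flagged in the `monomorphic` column.
#'
#' @param dataset A `geno_tbl`.
#' @param population Population name.
#' @param hwe_mode `"probability"` or `"deficit"` (see [hwe_exact_test()]).
#' @param mc An [mc_config()] used when a locus needs the Markov chain.
#' @param alpha_level FDR threshold for the significance labels.
#' @param enumeration_cap Enumeration limit handed to [hwe_exact_test()].
#' @return Tibble of class `locus_stats`: `locus`, `size_range`,
#'   `n_alleles`, `H_O`, `H_E`, `F`, `p_hwe`, `q_hwe`, `hwe_label`,
#'   `monomorphic`.
#' @export
locus_stats <- function(dataset, population,
                        hwe_mode = c("probability", "deficit"),
                        mc = mc_config(), alpha_level = 0.05,
                        enumeration_cap = 1e6) {
  hwe_mode <- match.arg(hwe_mode)
  loci <- gd_loci(dataset)
  rows <- lapply(loci, function(l) {
    both <- subset_genotypes(dataset, populations = population, loci = l)
    typed <- both[both$a1 != 0L, , drop = FALSE]
    alleles <- sort(unique(c(typed$a1, typed$a2[!is.na(typed$a2)])))
    fem <- typed[typed$sex == "female", , drop = FALSE]
    fem_alleles <- unique(c(fem$a1, fem$a2))
    mono <- length(fem_alleles) < 2
    ho <- observed_heterozygosity(dataset, l, population)
    he <- if (mono) {
      if (nrow(fem)) 0 else NA_real_
    } else {
      expected_heterozygosity_unbiased(
        allele_counts(dataset, l, population, sexes = "female"))
    }
    if (mono && !is.na(he)) ho <- 0
    f <- if (mono) NA_real_ else fis_weir_cockerham(dataset, l, population)
    p <- if (mono || nrow(fem) < 2) NA_real_ else {
      arr <- genotype_array(dataset, l, population)
      hwe_exact_test(arr, mode = hwe_mode, mc = mc,
                     enumeration_cap = enumeration_cap)$p_value
    }
    tibble::tibble(
      locus = l,
      size_range = if (length(alleles)) {
        paste0(min(alleles), "-", max(alleles))
      } else NA_character_,
      n_alleles = length(alleles),
      H_O = ho, H_E = he, F = f, p_hwe = p,
      monomorphic = mono)
  })
  out <- dplyr::bind_rows(rows)
  testable <- !is.na(out$p_hwe)
  out$q_hwe <- NA_real_
  out$hwe_label <- NA_character_
  if (any(testable)) {
    rep_tab <- significance_report(
      tibble::tibble(locus = out$locus[testable],
                     p_value = out$p_hwe[testable]),
      alpha_level = alpha_level)
    out$q_hwe[testable] <- rep_tab$q_value
    out$hwe_label[testable] <- rep_tab$label
  }
  out <- out[c("locus", "size_range", "n_alleles", "H_O", "H_E", "F",
               "p_hwe", "q_hwe", "hwe_label", "monomorphic")]
  class(out) <- c("locus_stats", class(out))
  attr(out, "population") <- population
  out
}

#' Render a per-locus table for reporting
#'
#' Formats a [locus_stats()] tibble the way characterization tables are
#' printed: statistics rounded half-up to 3 decimals, undefined entries as
#' an em dash, and the banded HWE label.
#'
#' @param stats A `locus_stats` tibble.
#' @return Character tibble ready for `readr::write_tsv()`.
#' @export
format_locus_stats <- function(stats) {
  fmt <- function(x) {
    ifelse(is.na(x), "—", sprintf("%.3f", round_half_up(x, 3)))
  }
  tibble::tibble(
    Locus = stats$locus,
    `Size range (bp)` = ifelse(is.na(stats$size_range), "—",
                               stats$size_range),
    N_a = stats$n_alleles,
    H_O = fmt(stats$H_O), H_E = fmt(stats$H_E), F = fmt(stats$F),
    `P of HWE` = ifelse(is.na(stats$hwe_label), "—", stats$hwe_label))
}
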