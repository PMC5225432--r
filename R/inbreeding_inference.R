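# Sib-mating frequency and foundress number from the multilocus inbreeding
# coefficient under haplodiploid inheritance.
#
# At equilibrium with a fraction alpha of brother-sister matings,
# F = alpha / (4 - 3 alpha), hence alpha = 4F / (3F + 1) and, assuming the
# foundresses on a host are unrelated and lay equal clutches,
# n = 1/alpha = (3F + 1) / (4F), interpretable as a harmonic mean number of
# ovipositing females.

#' Sib-mating frequency from the inbreeding coefficient
#'
#' `alpha = 4F / (3F + 1)` for haplodiploid inheritance; strictly
#' increasing in F, with `alpha(0) = 0` and `alpha(1) = 1`.
#'
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @return Sib-mating frequency in `[0, 1]`.
#' @examples
#' sibmating_from_F(0.632)  # ~0.873
#' @export
sibmating_from_F <- function(F) {
  vapply(F, check_number, numeric(1), name = "F", lower = 0, upper = 1)
  4 * F / (3 * F + 1)
}

#' Effective foundress number from the inbreeding coefficient
#'
#' `n = (3F + 1) / (4F) = 1/alpha`: the number of females ovipositing on a
#' host patch consistent with the observed inbreeding, under the
#' assumptions that foundresses are unrelated and contribute equal
#' clutches. Strictly decreasing in F, with `n = 1` exactly at `F = 1`;
#' `F = 0` means no inbreeding and an unbounded foundress number
#' (returned as `Inf`, not an error).
#'
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @return Effective foundress number, `>= 1` (`Inf` at `F = 0`).
#' @examples
#' foundress_from_F(0.632)  # ~1.15
#' @export
foundress_from_F <- function(F) {
  vapply(F, check_number, numeric(1), name = "F", lower = 0, upper = 1)
  ifelse(F == 0, Inf, (3 * F + 1) / (4 * F))
}

#' Equilibrium inbreeding coefficient from the sib-mating frequency
#'
#' Algebraic inverse of [sibmating_from_F()]: `F = alpha / (4 - 3 alpha)`.
#' Used to set simulation targets.
#'
#' @param alpha Sib-mating frequency in `[0, 1]`.
#' @return Inbreeding coefficient in `[0, 1]`.
#' @examples
#' F_from_sibmating(0.873)  # ~0.632
#' @export
F_from_sibmating <- function(alpha) {
  vapply(alpha, check_number, numeric(1), name = "alpha", lower = 0, upper = 1)
  alpha / (4 - 3 * alpha)
}

#' Harmonic mean
#'
#' `k / sum(1/x)`, the mean under which the foundress-number estimate is
#' interpreted (foundresses contributing unequally pull the effective
#' number below the arithmetic mean). Requires strictly positive values.
#'
#' @param values Positive numeric vector.
#' @return The harmonic mean, always `<=` the arithmetic mean.
#' @export
harmonic_mean <- function(values) {
  if (!length(values) || !is.numeric(values) || anyNA(values) ||
      any(values <= 0)) {
    abort("harmonic mean needs a non-empty vector of positive values.")
  }
  length(values) / sum(1 / values)
}

#' Infer sib-mating frequency and foundress number from genotypes
#'
#' For each population: multilocus Weir-Cockerham inbreeding coefficient
#' (females only, ratio of sums over loci), converted to the sib-mating
#' frequency `alpha = 4F/(3F+1)` and effective foundress number
#' `n = 1/alpha`. An exclusion list re-runs the estimate without chosen
#' loci (a robustness check when individual loci look suspect). The
#' estimator assumes unrelated, equal-clutch foundresses; both assumptions
#' bias `n` downward when violated, and the returned object carries that
#' warning.
#'
#' @param dataset A `geno_tbl`.
#' @param populations Populations to analyse (default all).
#' @param exclude_loci Optional character vector of loci to drop.
#' @return Object of class `sibmating_fit` with per-population estimates;
#'   see [tidy.sibmating_fit()] and [glance.sibmating_fit()].
#' @export
infer_sibmating <- function(dataset, populations = NULL, exclude_loci = NULL) {
  populations <- populations %||% gd_populations(dataset)
  loci <- setdiff(gd_loci(dataset), exclude_loci)
  if (!length(loci)) abort("exclusion list covers all loci.")
  rows <- lapply(populations, function(pop) {
    Fm <- fis_multilocus(dataset, pop, loci = loci)
    skipped <- attr(Fm, "skipped")
    Fv <- min(max(as.numeric(Fm), 0), 1)  # estimator noise can leave [0,1]
    tibble::tibble(population = pop,
                   F_multilocus = as.numeric(Fm),
                   alpha = sibmating_from_F(Fv),
                   n_foundress = foundress_from_F(Fv),
                   loci_used = length(loci) - length(skipped),
                   loci_skipped = list(skipped))
  })
  structure(list(
    estimates = dplyr::bind_rows(rows),
    loci = loci,
    warnings = c(
      "alpha/n assume unrelated foundresses laying equal clutches;",
      "related or unequally contributing foundresses inflate alpha and",
      "deflate n relative to the true number of ovipositing females."
    )),
    class = "sibmating_fit")
}

#' @export
print.sibmating_fit <- function(x, ...) {
  cat("Sib-mating inference from multilocus inbreeding (haplodiploid)\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %s: F = %.3f, alpha = %.3f, n = %s (%d loci)\n",
                est$population[i], est$F_multilocus[i],
                round_half_up(est$alpha[i], 3),
                ifelse(is.finite(est$n_foundress[i]),
                       sprintf("%.2f", round_half_up(est$n_foundress[i], 2)),
                       "unbounded"),
                est$loci_used[i]))
  }
  cat("Caveat:", paste(x$warnings, collapse = " "), "\n")
  invisible(x)
}

#' Tidy a sib-mating fit
#'
#' @param x A `sibmating_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per population with `F_multilocus`, `alpha`,
#'   `n_foundress`, `loci_used`. `glance()`: a one-row summary (population
#'   count, locus count).
#' @export
tidy.sibmating_fit <- function(x, ...) {
  dplyr::select(x$estimates, "population", "F_multilocus", "alpha",
                "n_foundress", "loci_used")
}

#' @rdname tidy.sibmating_fit
#' @export
glance.sibmating_fit <- function(x, ...) {
  tibble::tibble(n_populations = nrow(x$estimates),
                 n_loci = length(x$loci),
                 mean_alpha = mean(x$estimates$alpha))
}
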