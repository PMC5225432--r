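# Forward simulation of patch-structured haplodiploid populations with a
# controllable sib-mating rate, emulating the survey design in which one
# male and one female are collected per host patch.
#
# Transmission is haplodiploid: daughters receive one maternal gamete plus
# the father's single gene; sons develop from unfertilized eggs and carry a
# maternal gamete only. Each generation a fraction alpha of females mate
# with a brother, the rest with a random male drawn from the whole
# population. Under this model the equilibrium inbreeding coefficient is
# F = alpha / (4 - 3 alpha), the relation inverted by the estimator.

#' Simulation configuration
#'
#' Defaults describe a Melittobia-like system: strongly female-biased
#' broods (5% males — the genus range is about 1-5% — with every brood
#' containing at least one male, as expected for large gregarious broods),
#' single-foundress patches, multiallelic microsatellite loci starting from
#' equifrequent alleles, stepwise mutation, and a fixed 20-generation
#' burn-in, which brings the inbreeding recursion within ~0.005 of its
#' equilibrium even at `sib_mating_rate = 1` (geometric approach at rate
#' `3*alpha/4`).
#'
#' @param n_patches Host patches per generation.
#' @param foundresses_per_patch Mated females founding each patch.
#' @param offspring_per_foundress Brood size per foundress in the final
#'   emergence cohort.
#' @param sex_ratio Proportion of sons in a brood (default 0.05).
#' @param sib_mating_rate Probability that a female mates with a brother
#'   (otherwise a random male from the population).
#' @param n_loci,n_alleles_init Number of microsatellite loci and of
#'   initial equifrequent alleles per locus.
#' @param mutation_rate Per-gamete stepwise (+/-1) mutation rate (default
#'   1e-4; set 0 for drift-only runs).
#' @param generations Burn-in generations before the emergence cohort.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patches = 100, foundresses_per_patch = 1,
                       offspring_per_foundress = 20, sex_ratio = 0.05,
                       sib_mating_rate = 0.5, n_loci = 5,
                       n_alleles_init = 8, mutation_rate = 1e-4,
                       generations = 20, seed = 1) {
  check_number(n_patches, "n_patches", lower = 1)
  check_number(foundresses_per_patch, "foundresses_per_patch", lower = 1)
  check_number(offspring_per_foundress, "offspring_per_foundress", lower = 2)
  check_number(sex_ratio, "sex_ratio", lower = 0, upper = 1)
  check_number(sib_mating_rate, "sib_mating_rate", lower = 0, upper = 1)
  check_number(n_loci, "n_loci", lower = 1)
  check_number(n_alleles_init, "n_alleles_init", lower = 1)
  check_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  check_number(generations, "generations", lower = 0)
  check_number(seed, "seed")
  structure(as.list(environment()), class = "sim_config")
}

# one gamete per (female, locus) from diploid mothers; stepwise mutation
draw_gametes <- function(A1, A2, rows, mu) {
  pick <- matrix(runif(length(rows) * ncol(A1)) < 0.5,
                 nrow = length(rows))
  g <- ifelse(pick, A1[rows, , drop = FALSE], A2[rows, , drop = FALSE])
  if (mu > 0) {
    hit <- matrix(runif(length(g)) < mu, nrow = nrow(g))
    step <- ifelse(runif(length(g)) < 0.5, -1L, 1L)
    g[hit] <- pmax(1L, g[hit] + step[hit])
  }
  g
}

#' Forward-simulate a haplodiploid population
#'
#' Runs the sib-mating model for `generations` generations of
#' `n_patches * foundresses_per_patch` mated females, then instantiates a
#' final emergence cohort patch by patch (each foundress contributes
#' `offspring_per_foundress` offspring; sons are drawn binomially at
#' `sex_ratio` with at least one son per brood). Mated females never
#' leave descendants through sons alone, so a generation without daughters
#' is an extinction error.
#'
#' @param config A [sim_config()].
#' @param population Population label on the output dataset.
#' @return List with `dataset` (a `geno_tbl` of the emergence cohort; the
#'   patch of each individual is in the `"patches"` attribute) and `truth`
#'   (list: `realized_sib_mating`, `expected_F`, `allele_freqs`, `config`).
#' @export
simulate_population <- function(config = sim_config(), population = "Sim") {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  set.seed(config$seed)
  n_f <- config$n_patches * config$foundresses_per_patch
  L <- config$n_loci
  mu <- config$mutation_rate
  init <- function() {
    matrix(sample.int(config$n_alleles_init, n_f * L, replace = TRUE),
           nrow = n_f)
  }
  A1 <- init(); A2 <- init(); M <- init()
  sib_events <- 0; mate_events <- 0
  for (g in seq_len(config$generations)) {
    mi <- sample.int(n_f, n_f, replace = TRUE)
    D1 <- draw_gametes(A1, A2, mi, mu)
    D2 <- M[mi, , drop = FALSE]
    sib <- runif(n_f) < config$sib_mating_rate
    father_mother <- ifelse(sib, mi, sample.int(n_f, n_f, replace = TRUE))
    DM <- draw_gametes(A1, A2, father_mother, mu)
    sib_events <- sib_events + sum(father_mother == mi)
    mate_events <- mate_events + n_f
    A1 <- D1; A2 <- D2; M <- DM
  }

  # emergence cohort, patch by patch
  o <- config$offspring_per_foundress
  foundress_patch <- rep(seq_len(config$n_patches),
                         each = config$foundresses_per_patch)
  n_sons <- pmax(1L, rbinom(n_f, o, config$sex_ratio))
  n_daughters <- o - n_sons
  if (sum(n_daughters) == 0) {
    abort(paste0("extinction: no daughters in the emergence cohort; ",
                 "increase offspring_per_foundress or lower sex_ratio."))
  }
  d_mother <- rep(seq_len(n_f), n_daughters)
  s_mother <- rep(seq_len(n_f), n_sons)
  F1 <- draw_gametes(A1, A2, d_mother, mu)
  F2 <- M[d_mother, , drop = FALSE]
  MG <- draw_gametes(A1, A2, s_mother, mu)

  f_ids <- sprintf("F%05d", seq_along(d_mother))
  m_ids <- sprintf("M%05d", seq_along(s_mother))
  loci <- sprintf("L%02d", seq_len(L))
  long <- function(ids, g1, g2, sex) {
    tibble::tibble(
      id = rep(ids, times = L),
      population = population, sex = sex,
      locus = rep(loci, each = length(ids)),
      a1 = as.integer(g1),
      a2 = if (is.null(g2)) NA_integer_ else as.integer(g2))
  }
  tbl <- dplyr::bind_rows(long(f_ids, F1, F2, "female"),
                          long(m_ids, MG, NULL, "male"))
  ds <- genotype_dataset(tbl, loci = loci)
  attr(ds, "patches") <- tibble::tibble(
    id = c(f_ids, m_ids),
    patch = c(foundress_patch[d_mother], foundress_patch[s_mother]))
  genes <- rbind(A1, A2)
  truth <- list(
    realized_sib_mating = if (mate_events > 0) sib_events / mate_events
                          else NA_real_,
    expected_F = F_from_sibmating(config$sib_mating_rate),
    allele_freqs = lapply(seq_len(L), function(l) {
      tab <- table(genes[, l])
      setNames(as.numeric(tab) / sum(tab), names(tab))
    }),
    config = config)
  list(dataset = ds, truth = truth)
}

#' Survey sampling: one male and one female per patch
#'
#' Emulates the field scheme that guards against sampling relatives of the
#' same sex: exactly one female and one male are drawn from each of
#' `n_patches_sampled` distinct patches (patches sampled without
#' replacement among those holding at least one adult of each sex).
#'
#' @param dataset A simulated `geno_tbl` carrying the `"patches"`
#'   attribute (from [simulate_population()]).
#' @param n_patches_sampled Number of patches to sample.
#' @param seed Optional integer seed.
#' @param population Label written on the sampled individuals (default:
#'   kept from the input).
#' @return A `geno_tbl` with `2 * n_patches_sampled` individuals; the
#'   sampled patch of each individual is kept in the `"patches"` attribute.
#' @export
sample_survey <- function(dataset, n_patches_sampled, seed = NULL,
                          population = NULL) {
  patches <- attr(dataset, "patches")
  if (is.null(patches)) abort("`dataset` carries no patch assignment.")
  if (!is.null(seed)) set.seed(seed)
  ind <- dplyr::left_join(gd_individuals(dataset), patches, by = "id")
  eligible <- ind %>%
    dplyr::group_by(.data$patch) %>%
    dplyr::summarise(both = any(.data$sex == "male") &
                       any(.data$sex == "female")) %>%
    dplyr::filter(.data$both) %>%
    dplyr::pull(.data$patch)
  if (n_patches_sampled > length(eligible)) {
    abort(sprintf("requested %d patches but only %d hold both sexes",
                  n_patches_sampled, length(eligible)))
  }
  chosen <- sample(eligible, n_patches_sampled)
  pick <- function(p, sx) {
    ids <- ind$id[ind$patch == p & ind$sex == sx]
    ids[sample.int(length(ids), 1L)]
  }
  ids <- unlist(lapply(chosen, function(p) {
    c(pick(p, "female"), pick(p, "male"))
  }))
  out <- tibble::as_tibble(dataset)[dataset$id %in% ids, , drop = FALSE]
  if (!is.null(population)) out$population <- population
  out <- new_geno_tbl(out, gd_loci(dataset))
  attr(out, "patches") <- patches[patches$id %in% ids, , drop = FALSE]
  out
}

#' Inject null (non-amplifying) alleles at a locus
#'
#' Marks a random subset of the locus' alleles, of total frequency close to
#' `null_freq`, as non-amplifying: haploid carriers and diploid homozygous
#' carriers become missing genotypes, and heterozygous carriers appear
#' homozygous for their visible allele. Downstream this produces the
#' classic null-allele signature — an apparent heterozygote deficit in
#' females and dropout in haploid males.
#'
#' @param dataset A `geno_tbl`.
#' @param locus Locus name.
#' @param null_freq Target total frequency of null alleles, in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return The transformed `geno_tbl`; the chosen null alleles are in the
#'   `"null_alleles"` attribute.
#' @export
inject_null_alleles <- function(dataset, locus, null_freq, seed = NULL) {
  check_number(null_freq, "null_freq", lower = 0, upper = 1)
  if (null_freq <= 0 || null_freq >= 1) {
    abort("`null_freq` must be strictly between 0 and 1.")
  }
  if (!locus %in% gd_loci(dataset)) abort(sprintf("unknown locus %s", locus))
  if (!is.null(seed)) set.seed(seed)
  at <- dataset$locus == locus & dataset$a1 != 0L
  genes <- c(dataset$a1[at], dataset$a2[at][!is.na(dataset$a2[at])])
  freqs <- table(genes) / length(genes)
  ord <- sample(names(freqs))
  cum <- cumsum(as.numeric(freqs[ord]))
  take <- max(1L, which.min(abs(cum - null_freq)))
  nulls <- as.integer(ord[seq_len(take)])

  a1 <- dataset$a1
  a2 <- dataset$a2
  rows <- which(dataset$locus == locus)
  for (r in rows) {
    n1 <- a1[r] %in% nulls
    if (is.na(a2[r])) {              # haploid
      if (n1) a1[r] <- 0L
    } else if (a1[r] != 0L) {        # diploid, typed
      n2 <- a2[r] %in% nulls
      if (n1 && n2) {
        a1[r] <- 0L; a2[r] <- 0L
      } else if (n1) {
        a1[r] <- a2[r]
      } else if (n2) {
        a2[r] <- a1[r]
      }
    }
  }
  out <- dataset
  out$a1 <- a1
  out$a2 <- a2
  attr(out, "null_alleles") <- nulls
  out
}
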