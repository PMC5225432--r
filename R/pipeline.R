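# Pipeline orchestration: mine / stats / infer / simulate / run as
# reproducible steps that write reports plus a run manifest (effective
# configuration, seed, package version, input digests), so a run can be
# reproduced bit-identically from its manifest.

write_manifest <- function(out_dir, command, params, seed, inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    command = command,
    package = "hapmsat",
    version = as.character(utils::packageVersion("hapmsat")),
    seed = seed,
    params = params,
    input_md5 = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Pipeline step: mine microsatellites from reads
#'
#' Runs the mining funnel on a FASTA/FASTQ file (or a read tibble) and
#' writes `hits.tsv`, `hits.bed`, `composition.tsv` and a manifest that
#' records the stage counts (total reads, after deduplication, after the
#' length filter, reads with at least one hit).
#'
#' @param reads Path to a FASTA/FASTQ file, or a tibble with `id`,
#'   `sequence`.
#' @param out_dir Output directory (created if needed).
#' @param config A [mining_config()].
#' @return The hit tibble, invisibly.
#' @export
pipeline_mine <- function(reads, out_dir, config = mining_config()) {
  ensure_dir(out_dir)
  input_path <- character()
  if (is.character(reads)) {
    input_path <- reads
    reads <- read_dna_reads(reads)
  }
  hits <- mine_ssr(reads, config)
  funnel <- attr(hits, "funnel")
  write_ssr_tsv(hits, file.path(out_dir, "hits.tsv"))
  write_ssr_bed(hits, file.path(out_dir, "hits.bed"))
  readr::write_tsv(composition_summary(hits),
                   file.path(out_dir, "composition.tsv"), progress = FALSE)
  write_manifest(out_dir, "mine",
                 params = c(unclass(config), list(funnel = as.list(funnel))),
                 seed = NA, inputs = input_path)
  message(sprintf("mine: %d reads -> %d unique -> %d >= %d bp -> %d with SSR",
                  funnel["total"], funnel["deduplicated"],
                  funnel["length_passed"], config$min_read_length,
                  funnel["with_ssr"]))
  invisible(hits)
}

#' Pipeline step: per-locus statistics
#'
#' Per-population characterization tables (written as
#' `stats_<population>.tsv` in formatted form and
#' `stats_<population>_raw.tsv` at full precision), pairwise
#' Weir-Cockerham F_ST when exactly two populations are present, and a
#' JSON summary.
#'
#' @param dataset A `geno_tbl`, or a path to a tabular genotype file.
#' @param out_dir Output directory.
#' @param hwe_mode,mc,alpha_level Passed to [locus_stats()].
#' @param seed Seed set before any Markov-chain test.
#' @return Named list of `locus_stats` tibbles, invisibly.
#' @export
pipeline_stats <- function(dataset, out_dir,
                           hwe_mode = c("probability", "deficit"),
                           mc = mc_config(), alpha_level = 0.05, seed = 1) {
  hwe_mode <- match.arg(hwe_mode)
  ensure_dir(out_dir)
  input_path <- character()
  if (is.character(dataset)) {
    input_path <- dataset
    dataset <- read_geno_table(dataset)
  }
  if (nrow(gd_individuals(dataset)) < 2) {
    abort("need at least two individuals for population statistics.")
  }
  set.seed(seed)
  pops <- gd_populations(dataset)
  tables <- lapply(pops, function(p) {
    locus_stats(dataset, p, hwe_mode = hwe_mode, mc = mc,
                alpha_level = alpha_level)
  })
  names(tables) <- pops
  summary <- list()
  for (p in pops) {
    readr::write_tsv(format_locus_stats(tables[[p]]),
                     file.path(out_dir, paste0("stats_", p, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(tables[[p]]),
                     file.path(out_dir, paste0("stats_", p, "_raw.tsv")),
                     progress = FALSE)
    summary[[p]] <- list(
      n_loci = nrow(tables[[p]]),
      n_hwe_significant = sum(tables[[p]]$q_hwe < alpha_level, na.rm = TRUE))
  }
  if (length(pops) == 2) {
    fst <- fst_weir_cockerham(dataset, pops)
    readr::write_tsv(fst$per_locus, file.path(out_dir, "fst_per_locus.tsv"),
                     progress = FALSE)
    summary$fst_multilocus <- as.numeric(fst$multilocus)
  }
  jsonlite::write_json(summary, file.path(out_dir, "stats_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "stats",
                 params = list(hwe_mode = hwe_mode, mc = unclass(mc),
                               alpha_level = alpha_level),
                 seed = seed, inputs = input_path)
  invisible(tables)
}

#' Pipeline step: sib-mating inference
#'
#' Multilocus inbreeding coefficient per population, converted to the
#' sib-mating frequency and effective foundress number; written as
#' `inference.tsv` and `inference.json` (alpha rounded to 3 decimals, n to
#' 2, the presentation convention for these quantities).
#'
#' @param dataset A `geno_tbl` or path to a tabular genotype file.
#' @param out_dir Output directory.
#' @param exclude_loci Optional loci to drop (robustness re-run).
#' @return The `sibmating_fit`, invisibly.
#' @export
pipeline_infer <- function(dataset, out_dir, exclude_loci = NULL) {
  ensure_dir(out_dir)
  input_path <- character()
  if (is.character(dataset)) {
    input_path <- dataset
    dataset <- read_geno_table(dataset)
  }
  fit <- infer_sibmating(dataset, exclude_loci = exclude_loci)
  est <- tidy(fit)
  report <- dplyr::mutate(
    est,
    alpha = round_half_up(.data$alpha, 3),
    n_foundress = ifelse(is.finite(.data$n_foundress),
                         round_half_up(.data$n_foundress, 2), Inf))
  readr::write_tsv(report, file.path(out_dir, "inference.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(estimates = report, warnings = fit$warnings),
    file.path(out_dir, "inference.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "infer",
                 params = list(exclude_loci = exclude_loci),
                 seed = NA, inputs = input_path)
  invisible(fit)
}

#' Pipeline step: simulate a haplodiploid population
#'
#' Writes the emergence cohort as the tabular dialect
#' (`genotypes.csv`), a GENEPOP export (`genotypes.gen`, males as
#' homozygotes with an id suffix), and the simulation truth
#' (`truth.json`). Reproducible bit-identically from the manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param population Population label.
#' @return The `simulate_population()` result, invisibly.
#' @export
pipeline_simulate <- function(config = sim_config(), out_dir,
                              population = "Sim") {
  ensure_dir(out_dir)
  sim <- simulate_population(config, population = population)
  write_geno_table(sim$dataset, file.path(out_dir, "genotypes.csv"))
  write_genepop(sim$dataset, file.path(out_dir, "genotypes.gen"),
                male_policy = "as_homozygote")
  jsonlite::write_json(
    list(realized_sib_mating = sim$truth$realized_sib_mating,
         expected_F = sim$truth$expected_F,
         allele_freqs = sim$truth$allele_freqs),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate", params = unclass(config),
                 seed = config$seed)
  invisible(sim)
}

#' Full pipeline: statistics plus inference
#'
#' @inheritParams pipeline_stats
#' @param exclude_loci Passed to [pipeline_infer()].
#' @return List with the stats tables and the sib-mating fit, invisibly.
#' @export
pipeline_run <- function(dataset, out_dir,
                         hwe_mode = c("probability", "deficit"),
                         mc = mc_config(), alpha_level = 0.05, seed = 1,
                         exclude_loci = NULL) {
  if (is.character(dataset)) dataset <- read_geno_table(dataset)
  tables <- pipeline_stats(dataset, out_dir, hwe_mode = hwe_mode, mc = mc,
                           alpha_level = alpha_level, seed = seed)
  fit <- pipeline_infer(dataset, out_dir, exclude_loci = exclude_loci)
  invisible(list(stats = tables, inference = fit))
}
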