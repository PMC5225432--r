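# Genotype data model: a long tibble, one row per individual x locus.
#
# Columns: id, population, sex ("male"/"female"), locus, a1, a2.
# Allele codes are opaque positive integers (by convention fragment sizes in
# bp); 0 marks a missing genotype. Males are haploid: a2 is NA. Diploid
# genotypes are unordered; rows are canonicalised to a1 <= a2. A genotype is
# missing iff every slot is 0 — a half-missing diploid call is invalid.

GENO_COLS <- c("id", "population", "sex", "locus", "a1", "a2")

#' Build a validated genotype dataset
#'
#' Validates and canonicalises a long genotype table for a haplodiploid
#' population: males carry exactly one allele per locus (`a2` is `NA`),
#' females two; allele code 0 is reserved for missing genotypes. Every
#' individual must have a row (possibly missing) for every locus.
#'
#' @param tbl Data frame with columns `id`, `population`, `sex`
#'   (`"male"`/`"female"`), `locus`, `a1`, and optionally `a2`.
#' @param loci Optional character vector fixing the locus order; defaults to
#'   order of first appearance.
#' @return A tibble of class `geno_tbl` with the locus order stored in the
#'   `"loci"` attribute.
#' @examples
#' genotype_dataset(tibble::tibble(
#'   id = c("F01", "M01"), population = "A",
#'   sex = c("female", "male"), locus = "L1",
#'   a1 = c(228L, 228L), a2 = c(244L, NA)
#' ))
#' @export
genotype_dataset <- function(tbl, loci = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (!"a2" %in% names(tbl)) tbl$a2 <- NA_integer_
  missing_cols <- setdiff(GENO_COLS, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[GENO_COLS]
  tbl$a1 <- as.integer(tbl$a1)
  tbl$a2 <- as.integer(tbl$a2)
  loci <- loci %||% unique(tbl$locus)
  validate_genotypes(tbl, loci)
  # canonical storage: unordered diploid genotype kept as (min, max)
  fem <- tbl$sex == "female"
  lo <- pmin(tbl$a1, tbl$a2)
  hi <- pmax(tbl$a1, tbl$a2)
  tbl$a1[fem] <- lo[fem]
  tbl$a2[fem] <- hi[fem]
  new_geno_tbl(tbl, loci)
}

new_geno_tbl <- function(tbl, loci) {
  attr(tbl, "loci") <- loci
  class(tbl) <- unique(c("geno_tbl", class(tbl)))
  tbl
}

validate_genotypes <- function(tbl, loci) {
  if (!all(tbl$sex %in% c("male", "female"))) {
    abort("sex must be \"male\" or \"female\".")
  }
  if (anyNA(tbl$a1) || any(tbl$a1 < 0L)) {
    abort("a1 must be a non-negative integer (0 = missing).")
  }
  male <- tbl$sex == "male"
  if (any(!is.na(tbl$a2[male]))) {
    abort("haploid males must have a single allele slot (a2 must be NA).")
  }
  fem <- !male
  if (anyNA(tbl$a2[fem]) || any(tbl$a2[fem] < 0L, na.rm = TRUE)) {
    abort("diploid females must have two allele slots (a2 missing).")
  }
  half <- fem & (xor(tbl$a1 == 0L, tbl$a2 == 0L))
  if (any(half)) {
    abort(paste0("partially missing diploid genotype for individual(s): ",
                 paste(unique(tbl$id[half]), collapse = ", ")))
  }
  if (anyDuplicated(tbl[c("id", "locus")])) {
    abort("duplicate individual/locus rows.")
  }
  ind <- unique(tbl[c("id", "population", "sex")])
  if (anyDuplicated(ind$id)) {
    abort(paste0("duplicate individual_id: ",
                 paste(ind$id[duplicated(ind$id)], collapse = ", ")))
  }
  per_ind <- table(tbl$id)
  if (length(unique(per_ind)) > 1L || any(per_ind != length(loci))) {
    abort("every individual needs one row per locus.")
  }
  if (!setequal(unique(tbl$locus), loci)) {
    abort("locus set does not match the declared loci.")
  }
  invisible(tbl)
}

#' Locus and population accessors
#'
#' @param dataset A `geno_tbl`.
#' @return `gd_loci()`: ordered locus names; `gd_populations()`: population
#'   names; `gd_individuals()`: one-row-per-individual tibble.
#' @export
gd_loci <- function(dataset) {
  attr(dataset, "loci") %||% unique(dataset$locus)
}

#' @rdname gd_loci
#' @export
gd_populations <- function(dataset) unique(dataset$population)

#' @rdname gd_loci
#' @export
gd_individuals <- function(dataset) {
  dplyr::distinct(tibble::as_tibble(dataset)[c("id", "population", "sex")])
}

#' Subset a genotype dataset
#'
#' Filtered copy by population, sex and/or locus; preserves locus order.
#' The analyses of heterozygosity, inbreeding and Hardy-Weinberg
#' deviation operate on females only, so `subset_genotypes(d, sexes =
#' "female")` is the usual first step.
#'
#' @param dataset A `geno_tbl`.
#' @param populations,sexes,loci Optional character vectors; `NULL` keeps all.
#'   Unknown names raise an error.
#' @return A `geno_tbl`.
#' @export
subset_genotypes <- function(dataset, populations = NULL, sexes = NULL,
                             loci = NULL) {
  check_known <- function(x, have, what) {
    bad <- setdiff(x, have)
    if (length(bad)) {
      abort(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")))
    }
  }
  keep <- rep(TRUE, nrow(dataset))
  if (!is.null(populations)) {
    check_known(populations, gd_populations(dataset), "population(s)")
    keep <- keep & dataset$population %in% populations
  }
  if (!is.null(sexes)) {
    check_known(sexes, c("male", "female"), "sex(es)")
    keep <- keep & dataset$sex %in% sexes
  }
  locus_order <- gd_loci(dataset)
  if (!is.null(loci)) {
    check_known(loci, locus_order, "locus/loci")
    keep <- keep & dataset$locus %in% loci
    locus_order <- locus_order[locus_order %in% loci]
  }
  out <- tibble::as_tibble(dataset)[keep, , drop = FALSE]
  new_geno_tbl(out, locus_order)
}

# ---- tabular dialect -------------------------------------------------------

#' Read/write the sex-aware tabular genotype dialect
#'
#' Canonical storage format: a delimited text file with header columns
#' `individual_id`, `population`, `sex`, then one column per locus. Diploid
#' cells are `"a/b"`, haploid cells `"a"`, missing genotypes `"."`. The
#' round trip is lossless, including sex and ploidy — unlike GENEPOP, which
#' has no native sex field.
#'
#' @param path File path.
#' @param delim Field delimiter (default `","`).
#' @return `read_geno_table()`: a `geno_tbl`. `write_geno_table()`: `path`,
#'   invisibly.
#' @export
read_geno_table <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), trim_ws = TRUE, progress = FALSE)
  need <- c("individual_id", "population", "sex")
  if (!all(need %in% names(raw)[1:3])) {
    abort("tabular genotype file must start with individual_id, population, sex.")
  }
  loci <- setdiff(names(raw), need)
  if (!length(loci)) abort("no locus columns found.")
  long <- tidyr::pivot_longer(raw, dplyr::all_of(loci),
                              names_to = "locus", values_to = "cell")
  parse_cell <- function(cell, sex, id, locus) {
    if (is.na(cell) || cell == ".") {
      return(if (sex == "male") c(0L, NA_integer_) else c(0L, 0L))
    }
    parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
    if (sex == "female" && length(parts) != 2L) {
      abort(sprintf(
        "female %s at locus %s: diploid cell must be \"a/b\", got \"%s\"",
        id, locus, cell))
    }
    if (sex == "male" && length(parts) != 1L) {
      abort(sprintf(
        "male %s at locus %s: haploid cell must be a single allele, got \"%s\"",
        id, locus, cell))
    }
    vals <- suppressWarnings(as.integer(parts))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric allele in cell \"%s\" (%s, %s)", cell, id, locus))
    }
    if (sex == "male") c(vals, NA_integer_) else vals
  }
  parsed <- purrr::pmap(
    list(long$cell, long$sex, long$individual_id, long$locus), parse_cell)
  genotype_dataset(tibble::tibble(
    id = long$individual_id, population = long$population, sex = long$sex,
    locus = long$locus,
    a1 = purrr::map_int(parsed, 1), a2 = purrr::map_int(parsed, 2)
  ), loci = loci)
}

#' @rdname read_geno_table
#' @param dataset A `geno_tbl`.
#' @export
write_geno_table <- function(dataset, path, delim = ",") {
  cell <- ifelse(
    dataset$a1 == 0L, ".",
    ifelse(dataset$sex == "male", as.character(dataset$a1),
           paste0(dataset$a1, "/", dataset$a2)))
  wide <- tidyr::pivot_wider(
    tibble::tibble(individual_id = dataset$id, population = dataset$population,
                   sex = dataset$sex, locus = dataset$locus, cell = cell),
    names_from = "locus", values_from = "cell")
  wide <- wide[c("individual_id", "population", "sex", gd_loci(dataset))]
  readr::write_delim(wide, path, delim = delim, progress = FALSE)
  invisible(path)
}

# ---- GENEPOP interchange ---------------------------------------------------

#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP layout (title line, locus names, `Pop`
#' separators, `name , g1 g2 ...` rows with 2- or 3-digit-per-allele codes;
#' `00`/`000` = missing). GENEPOP carries no sex, so ploidy is assigned by
#' policy: `"all_diploid"` treats every individual as a diploid female;
#' `"sex_from_id_suffix"` reads sex from an id suffix and collapses male
#' diploid-coded homozygotes to a single haploid allele (a male coded
#' heterozygous is a validation error).
#'
#' @param path File path.
#' @param ploidy_policy `"all_diploid"` or `"sex_from_id_suffix"`.
#' @param male_suffix,female_suffix Id suffixes used by
#'   `"sex_from_id_suffix"`.
#' @return A `geno_tbl`.
#' @export
read_genepop <- function(path, ploidy_policy = c("all_diploid", "sex_from_id_suffix"),
                         male_suffix = "_m", female_suffix = "_f") {
  ploidy_policy <- match.arg(ploidy_policy)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("[\r[:space:]]+$", "", lines)
  if (length(lines) < 3L) abort("not a GENEPOP file: too few lines.")
  is_pop <- function(x) grepl("^\\s*pop\\s*$", x, ignore.case = TRUE)
  first_pop <- which(vapply(lines, is_pop, logical(1)))[1]
  if (is.na(first_pop)) abort("not a GENEPOP file: no Pop separator.")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) abort("duplicate locus names in GENEPOP header.")

  rows <- list()
  pop_idx <- 0L
  for (k in seq(first_pop, length(lines))) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    if (is_pop(line)) {
      pop_idx <- pop_idx + 1L
      next
    }
    halves <- strsplit(line, ",")[[1]]
    if (length(halves) < 2L) {
      abort(sprintf("line %d: expected \"name , genotypes\"", k))
    }
    id <- trimws(halves[1])
    toks <- strsplit(trimws(paste(halves[-1], collapse = ",")), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci)) {
      abort(sprintf("line %d (%s): %d genotype(s) for %d loci",
                    k, id, length(toks), length(loci)))
    }
    widths <- nchar(toks)
    if (!all(widths %in% c(4L, 6L)) || length(unique(widths)) != 1L ||
        !all(grepl("^[0-9]+$", toks))) {
      abort(sprintf("line %d (%s): malformed genotype width", k, id))
    }
    d <- widths[1] / 2L
    a1 <- as.integer(substr(toks, 1L, d))
    a2 <- as.integer(substr(toks, d + 1L, 2L * d))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = id, population = paste0("Pop", pop_idx), locus = loci,
      a1 = a1, a2 = a2)
  }
  if (!length(rows)) abort("GENEPOP file contains no individuals.")
  tbl <- dplyr::bind_rows(rows)

  if (ploidy_policy == "all_diploid") {
    tbl$sex <- "female"
  } else {
    ends_with <- function(x, suf) {
      nchar(x) >= nchar(suf) &
        substr(x, nchar(x) - nchar(suf) + 1L, nchar(x)) == suf
    }
    is_m <- ends_with(tbl$id, male_suffix)
    is_f <- ends_with(tbl$id, female_suffix)
    unknown <- !(is_m | is_f)
    if (any(unknown)) {
      abort(sprintf("id(s) without a sex suffix (\"%s\"/\"%s\"): %s",
                    male_suffix, female_suffix,
                    paste(unique(tbl$id[unknown]), collapse = ", ")))
    }
    tbl$sex <- ifelse(is_m, "male", "female")
    bad_male <- is_m & tbl$a1 != tbl$a2
    if (any(bad_male)) {
      abort(sprintf(
        "male(s) coded heterozygous under sex_from_id_suffix: %s",
        paste(unique(tbl$id[bad_male]), collapse = ", ")))
    }
    tbl$a2[is_m] <- NA_integer_
  }
  # missing genotype: both slots 0 (all_diploid) or single 0 (males)
  genotype_dataset(tbl[c("id", "population", "sex", "locus", "a1", "a2")],
                   loci = loci)
}

#' Write a GENEPOP file
#'
#' GENEPOP has no sex field, so haploid males are handled by policy:
#' `"exclude"` drops them; `"as_homozygote"` duplicates each male's single
#' allele into a diploid-coded homozygote and appends `male_suffix` to the
#' id (if absent), so `read_genepop(..., "sex_from_id_suffix")` restores the
#' original ploidy.
#'
#' @inheritParams write_geno_table
#' @param male_policy `"exclude"` or `"as_homozygote"`.
#' @param digits Digits per allele code (3, or 2 on request). Codes must fit:
#'   an allele of 1024 cannot be encoded at 3 digits.
#' @param male_suffix,female_suffix Id suffixes appended under
#'   `"as_homozygote"` so the sexes survive the round trip.
#' @param title Title line for the file.
#' @export
write_genepop <- function(dataset, path, male_policy = c("exclude", "as_homozygote"),
                          digits = 3, male_suffix = "_m", female_suffix = "_f",
                          title = "hapmsat export") {
  male_policy <- match.arg(male_policy)
  if (!digits %in% c(2, 3)) abort("`digits` must be 2 or 3.")
  d <- dataset
  if (male_policy == "exclude") {
    d <- d[d$sex == "female", , drop = FALSE]
    if (!nrow(d)) abort("no females to export under male_policy = \"exclude\".")
  }
  max_code <- max(c(d$a1, d$a2), na.rm = TRUE)
  if (max_code > 10^digits - 1) {
    abort(sprintf("allele code %d does not fit %d-digit GENEPOP encoding",
                  max_code, digits))
  }
  suffix_for <- function(id, sex) {
    suf <- ifelse(sex == "male", male_suffix, female_suffix)
    has <- substr(id, pmax(1L, nchar(id) - nchar(suf) + 1L), nchar(id)) == suf
    ifelse(has, id, paste0(id, suf))
  }
  enc <- function(x) formatC(x, width = digits, flag = "0")
  d$out_id <- if (male_policy == "as_homozygote") {
    suffix_for(d$id, d$sex)
  } else d$id
  d$tok <- paste0(enc(d$a1), enc(ifelse(is.na(d$a2), d$a1, d$a2)))
  loci <- gd_loci(dataset)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(d)[c("out_id", "population", "locus", "tok")],
    names_from = "locus", values_from = "tok")
  out <- c(title, loci)
  for (pop in unique(wide$population)) {
    out <- c(out, "Pop")
    block <- wide[wide$population == pop, , drop = FALSE]
    out <- c(out, paste0(block$out_id, " , ",
                         apply(block[loci], 1, paste, collapse = " ")))
  }
  readr::write_lines(out, path)
  invisible(path)
}
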