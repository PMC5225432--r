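# Microsatellite (SSR) mining from sequencing reads.
#
# Perfect tandem repeats of 2-6 bp motifs, one per-motif-length minimum
# repeat count. A run is reported once, under its shortest period, and a
# position belongs to at most one hit (longest run wins, ties to the
# smaller start). Homopolymers are never reported.

#' Mining configuration
#'
#' Defaults follow the standard SSR-development workflow for read data:
#' reads shorter than 150 bp are excluded (too short to fit a repeat plus
#' primer-design flanks), exact duplicate reads are removed, and minimum
#' repeat numbers are 8 for dinucleotides and 5 for tri- through
#' hexanucleotides.
#'
#' @param min_read_length Minimum read length in bp kept by
#'   [filter_reads_by_length()]; a read of exactly this length is kept.
#' @param min_repeats Named integer vector mapping motif length (`"2"`..`"6"`)
#'   to the minimum repeat count.
#' @param dedup Whether [mine_ssr()] removes duplicate reads first.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(min_read_length = 150,
                          min_repeats = c("2" = 8, "3" = 5, "4" = 5,
                                          "5" = 5, "6" = 5),
                          dedup = TRUE) {
  check_number(min_read_length, "min_read_length", lower = 1)
  if (!all(as.character(2:6) %in% names(min_repeats))) {
    abort("`min_repeats` must be defined for every motif length 2..6.")
  }
  if (any(min_repeats < 2)) abort("minimum repeat counts must be >= 2.")
  structure(list(min_read_length = min_read_length,
                 min_repeats = min_repeats[as.character(2:6)],
                 dedup = isTRUE(dedup)),
            class = "mining_config")
}

#' Read sequencing reads into a tibble
#'
#' FASTA or FASTQ (gzip-transparent), via Biostrings. The format is taken
#' from the file extension (`.fq`/`.fastq` with optional `.gz` read as
#' FASTQ, anything else as FASTA).
#'
#' @param path File path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_dna_reads <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA/FASTQ requires the Biostrings package.")
  }
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(id = sub("\\s.*$", "", names(seqs)),
                 sequence = as.character(seqs))
}

#' Read filtering
#'
#' `deduplicate_reads()` drops exact-sequence duplicates, keeping the first
#' occurrence in input order. `filter_reads_by_length()` keeps reads whose
#' length is at least `min_read_length` ("shorter than" the threshold are
#' excluded, so a 150 bp read survives the 150 bp default).
#'
#' @param reads Tibble with columns `id`, `sequence`.
#' @param min_read_length Minimum length in bp.
#' @return Filtered tibble, input order preserved.
#' @export
deduplicate_reads <- function(reads) {
  reads[!duplicated(reads$sequence), , drop = FALSE]
}

#' @rdname deduplicate_reads
#' @export
filter_reads_by_length <- function(reads, min_read_length = 150) {
  check_number(min_read_length, "min_read_length", lower = 1)
  reads[nchar(reads$sequence) >= min_read_length, , drop = FALSE]
}

#' Canonical motif class
#'
#' The class representative of an SSR motif: the lexicographically smallest
#' string among all cyclic rotations of the motif and of its reverse
#' complement (the standard SSR-class convention, so e.g. `"GA"`, `"AG"`,
#' `"TC"` and `"CT"` all report as `"AG"`). Idempotent. The motif must be
#' primitive: a period-reducible motif such as `"ATAT"` is an error, since a
#' tandem of it is really a tandem of the shorter unit.
#'
#' @param motif Character vector of motifs over ACGT, each of length 2-6.
#' @return Character vector of canonical motifs.
#' @examples
#' canonical_motif("GA")
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (!grepl("^[ACGT]{2,6}$", m)) {
      abort(sprintf("motif must be 2-6 bp over ACGT, got \"%s\"", m))
    }
    if (is_period_reducible(m)) {
      abort(sprintf("motif \"%s\" is period-reducible; pass the primitive unit", m))
    }
    rc <- revcomp(m)
    min(c(rotations(m), rotations(rc)))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1, i - 1))
  }, character(1))
}

revcomp <- function(m) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(m, "")[[1]]), collapse = ""))
}

is_period_reducible <- function(m) {
  k <- nchar(m)
  for (p in seq_len(k - 1)) {
    if (k %% p == 0 &&
        m == strrep(substr(m, 1, p), k / p)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Scan one read for perfect microsatellites
#'
#' Finds maximal perfect tandem runs of 2-6 bp motifs that meet the
#' per-motif-length repeat thresholds. Each run is reported once, under its
#' shortest period; homopolymer runs are never reported; `N` never matches
#' inside a repeat. Overlaps are resolved so that a position belongs to at
#' most one hit: the longer tandem wins, ties go to the smaller start.
#' Coordinates are 0-based half-open.
#'
#' @param sequence A single DNA string over `ACGTN`.
#' @param config A [mining_config()].
#' @param read_id Id recorded on the hits.
#' @return Tibble with columns `read_id`, `motif`, `canonical_motif`,
#'   `motif_length`, `repeat_count`, `start`, `end`.
#' @examples
#' scan_read(paste0("TT", strrep("AC", 8), "GG"))
#' @export
scan_read <- function(sequence, config = mining_config(), read_id = "read") {
  if (length(sequence) != 1L || !grepl("^[ACGTN]*$", sequence)) {
    abort("`sequence` must be a single string over ACGTN.")
  }
  s <- strsplit(sequence, "")[[1]]
  L <- length(s)
  cand <- list()
  for (k in 2:6) {
    if (L < 2L * k) next
    eq <- s[seq_len(L - k)] == s[seq_len(L - k) + k] &
      s[seq_len(L - k)] != "N"
    r <- rle(eq)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      start <- starts_idx[j]              # 1-based position in s
      m_len <- r$lengths[j]               # matched comparisons
      reps <- (m_len + k) %/% k
      if (reps < config$min_repeats[[as.character(k)]]) next
      motif <- paste(s[start:(start + k - 1L)], collapse = "")
      if (is_period_reducible(motif)) next
      cand[[length(cand) + 1L]] <- list(
        motif = motif, motif_length = k, repeat_count = reps,
        start = start - 1L, end = start - 1L + k * reps)
    }
  }
  if (!length(cand)) return(empty_hits())
  hits <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  # shortest-period rule: a run detected at period k may also surface at a
  # multiple of k with the same span; keep the smaller period when spans
  # overlap entirely. Then resolve partial overlaps: longest run first,
  # ties to the smaller start.
  hits <- hits[order(-(hits$end - hits$start), hits$start, hits$motif_length), ]
  kept <- logical(0)
  kept_start <- integer(0)
  kept_end <- integer(0)
  sel <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- any(hits$start[i] < kept_end & hits$end[i] > kept_start)
    if (!ov) {
      sel[i] <- TRUE
      kept_start <- c(kept_start, hits$start[i])
      kept_end <- c(kept_end, hits$end[i])
    }
  }
  hits <- hits[sel, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  tibble::tibble(read_id = read_id,
                 motif = hits$motif,
                 canonical_motif = canonical_motif(hits$motif),
                 motif_length = hits$motif_length,
                 repeat_count = hits$repeat_count,
                 start = hits$start, end = hits$end)
}

empty_hits <- function() {
  tibble::tibble(read_id = character(), motif = character(),
                 canonical_motif = character(), motif_length = integer(),
                 repeat_count = integer(), start = integer(), end = integer())
}

#' Mine microsatellites from a read set
#'
#' Full mining funnel: optional exact-duplicate removal, length filtering,
#' then per-read scanning with [scan_read()]. Stage counts (total, after
#' dedup, after the length filter, reads with at least one hit) are attached
#' as the `"funnel"` attribute.
#'
#' @param reads Tibble with columns `id`, `sequence`.
#' @param config A [mining_config()].
#' @return Tibble of hits (see [scan_read()]) with a `"funnel"` attribute.
#' @export
mine_ssr <- function(reads, config = mining_config()) {
  n_total <- nrow(reads)
  if (config$dedup) reads <- deduplicate_reads(reads)
  n_dedup <- nrow(reads)
  reads <- filter_reads_by_length(reads, config$min_read_length)
  n_len <- nrow(reads)
  hits <- purrr::map2(reads$sequence, reads$id,
                      function(s, id) scan_read(s, config, read_id = id))
  hits <- dplyr::bind_rows(hits)
  if (!nrow(hits)) hits <- empty_hits()
  attr(hits, "funnel") <- c(total = n_total, deduplicated = n_dedup,
                            length_passed = n_len,
                            with_ssr = length(unique(hits$read_id)))
  hits
}

#' Motif-length composition of a hit set
#'
#' Counts and frequencies of detected microsatellites by motif length
#' (di- through hexanucleotide), the usual first summary of a mining run.
#'
#' @param hits Hit tibble from [mine_ssr()] or [scan_read()].
#' @return Tibble of class `ssr_composition` with columns `motif_type`,
#'   `motif_length`, `n`, `frequency`. Frequencies sum to 1 (all zero on an
#'   empty hit set).
#' @export
composition_summary <- function(hits) {
  types <- c("2" = "Dinucleotide", "3" = "Trinucleotide",
             "4" = "Tetranucleotide", "5" = "Pentanucleotide",
             "6" = "Hexanucleotide")
  n <- vapply(2:6, function(k) sum(hits$motif_length == k), numeric(1))
  total <- sum(n)
  out <- tibble::tibble(
    motif_type = unname(types), motif_length = 2:6, n = n,
    frequency = if (total > 0) n / total else rep(0, 5))
  class(out) <- c("ssr_composition", class(out))
  out
}

#' Export SSR hits
#'
#' `write_ssr_tsv()` writes the hit table (0-based half-open coordinates);
#' `write_ssr_bed()` writes BED-like intervals (`read_id start end
#' motif xrepeat_count`); `write_ssr_flanks_fasta()` writes each hit with
#' its flanking sequence for external primer design.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @param reads Read tibble (for flanks).
#' @param flank Flank width in bp.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(hits, path) {
  readr::write_tsv(tibble::as_tibble(hits)[c(
    "read_id", "motif", "canonical_motif", "repeat_count", "start", "end")],
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ssr_tsv
#' @export
write_ssr_bed <- function(hits, path) {
  bed <- tibble::tibble(chrom = hits$read_id, start = hits$start,
                        end = hits$end,
                        name = paste0(hits$motif, "x", hits$repeat_count))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_ssr_tsv
#' @export
write_ssr_flanks_fasta <- function(hits, reads, path, flank = 50) {
  seqs <- setNames(reads$sequence, reads$id)
  lines <- character(0)
  for (i in seq_len(nrow(hits))) {
    s <- seqs[[hits$read_id[i]]]
    from <- max(1L, hits$start[i] + 1L - flank)
    to <- min(nchar(s), hits$end[i] + flank)
    lines <- c(lines,
               sprintf(">%s_%d_%d %sx%d", hits$read_id[i], hits$start[i],
                       hits$end[i], hits$motif[i], hits$repeat_count[i]),
               substr(s, from, to))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
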