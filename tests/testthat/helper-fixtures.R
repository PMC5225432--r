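# Fixture builders and independent oracles shared across the suite.

# long genotype tibble for one population of females, from a list of
# genotype rows c(a1, a2) per locus: genos[[locus]] is a 2-column matrix
make_females <- function(genos, population = "P", id_prefix = "F") {
  loci <- names(genos)
  n <- nrow(genos[[1]])
  rows <- lapply(loci, function(l) {
    tibble::tibble(id = sprintf("%s%02d", id_prefix, seq_len(n)),
                   population = population, sex = "female", locus = l,
                   a1 = as.integer(genos[[l]][, 1]),
                   a2 = as.integer(genos[[l]][, 2]))
  })
  dplyr::bind_rows(rows)
}

# 9 all-homozygous females, allele counts 14:4 (7 AA + 2 BB) at one locus
table3_like_locus <- function(a = 128L, b = 162L) {
  cbind(c(rep(a, 7), rep(b, 2)), c(rep(a, 7), rep(b, 2)))
}

# random valid dataset for round-trip property tests
random_dataset <- function(seed, n_pops = 2, n_loci = 3, n_per_sex = 4,
                           miss_rate = 0.15, max_code = 400L) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_pops)) {
    for (i in seq_len(n_per_sex)) {
      for (sx in c("female", "male")) {
        id <- sprintf("P%d_%s%02d", p, ifelse(sx == "male", "M", "F"), i)
        for (l in seq_len(n_loci)) {
          if (runif(1) < miss_rate) {
            a1 <- 0L
            a2 <- if (sx == "female") 0L else NA_integer_
          } else {
            a1 <- sample.int(max_code, 1)
            a2 <- if (sx == "female") sample.int(max_code, 1) else NA_integer_
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = id, population = paste0("pop", p), sex = sx,
            locus = paste0("L", l), a1 = a1, a2 = a2)
        }
      }
    }
  }
  genotype_dataset(dplyr::bind_rows(rows), loci = paste0("L", seq_len(n_loci)))
}

# order-insensitive dataset comparison
expect_same_dataset <- function(a, b) {
  norm <- function(d) {
    d <- tibble::as_tibble(d)[order(d$id, d$locus),
                              c("id", "population", "sex", "locus", "a1", "a2")]
    rownames(d) <- NULL
    d
  }
  expect_equal(norm(a), norm(b))
}

# ---- independent oracles ---------------------------------------------------

# brute-force SSR scanner: for every period and every run start, extend the
# tandem by direct substring comparison; then apply the same reporting rules
# (primitive motif, per-length threshold, overlap resolution).
bf_scan <- function(seq, config = mining_config()) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  primitive <- function(m) {
    k <- nchar(m)
    for (p in seq_len(k - 1)) {
      if (k %% p == 0 && m == strrep(substr(m, 1, p), k / p)) return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (k in 2:6) {
    for (i in seq_len(max(0, n - 2 * k + 1))) {
      # run start: position i-1 must not continue the same period-k match
      if (i > 1 && ch[i - 1] == ch[i - 1 + k] && ch[i - 1] != "N") next
      reps <- 1L
      motif <- substr(seq, i, i + k - 1)
      if (grepl("N", motif)) next
      while (i + (reps + 1) * k - 1 <= n &&
             substr(seq, i + reps * k, i + (reps + 1) * k - 1) == motif) {
        reps <- reps + 1L
      }
      if (reps >= config$min_repeats[[as.character(k)]] && primitive(motif)) {
        cand[[length(cand) + 1L]] <- data.frame(
          motif = motif, motif_length = k, repeat_count = reps,
          start = i - 1L, end = i - 1L + k * reps)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(motif = character(), motif_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$motif_length), ]
  kept <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prev <- which(kept)
    kept[i] <- !any(cand$start[i] < cand$end[prev] &
                      cand$end[i] > cand$start[prev])
  }
  out <- cand[kept, ]
  out[order(out$start), ]
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j>=i} m p_(j)/j
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q[ord] <- q_sorted
  q
}

# exact Levene probabilities of all genotype arrays by enumerating every
# perfect pairing of the gene multiset (feasible for n <= 5 diploids)
pairing_oracle <- function(genes) {
  stopifnot(length(genes) %% 2 == 0)
  arrays <- new.env()
  rec <- function(rem, pairs) {
    if (!length(rem)) {
      key <- paste(sort(vapply(pairs, function(pr) {
        paste(sort(pr), collapse = "/")
      }, character(1))), collapse = ";")
      arrays[[key]] <- (arrays[[key]] %||% 0) + 1
      return(invisible())
    }
    first <- rem[1]
    rest <- rem[-1]
    for (j in seq_along(rest)) {
      rec(rest[-j], c(pairs, list(c(first, rest[j]))))
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  rec(genes, list())
  counts <- unlist(as.list(arrays))
  counts / sum(counts)
}

# direct Weir & Cockerham (1984) theta plug-in, coded independently from the
# package: per-allele variance components from the published formulas.
bf_theta <- function(pop_genotypes) {
  # pop_genotypes: list of 2 matrices (n_i x 2 alleles) per population
  r <- length(pop_genotypes)
  ns <- vapply(pop_genotypes, nrow, integer(1))
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  alleles <- sort(unique(unlist(pop_genotypes)))
  A <- 0; D <- 0
  for (u in alleles) {
    p_i <- vapply(pop_genotypes, function(g) mean(g == u), numeric(1))
    h_i <- vapply(pop_genotypes, function(g) {
      mean(g[, 1] != g[, 2] & (g[, 1] == u | g[, 2] == u))
    }, numeric(1))
    pbar <- sum(ns * p_i) / sum(ns)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / sum(ns)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
    cc <- hbar / 2
    A <- A + a
    D <- D + a + b + cc
  }
  A / D
}

# random-mating diploid sample: 2n genes drawn iid, paired at random
hw_females <- function(n, freqs, locus = "L1", population = "P", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sample(seq_along(freqs) * 10L, 2 * n, replace = TRUE, prob = freqs)
  g <- matrix(sample(genes), ncol = 2)
  make_females(setNames(list(g), locus), population = population)
}
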