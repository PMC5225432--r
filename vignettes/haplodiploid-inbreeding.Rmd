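---
title: "Inferring sib-mating from microsatellites in haplodiploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sib-mating from microsatellites in haplodiploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapmsat)
```

## The biological problem

In haplodiploid insects, males develop from unfertilized eggs and carry a
single allele per locus; females are diploid. In gregarious parasitoids
such as *Melittobia*, mating happens inside the natal patch (a host cocoon
or brood cell) before females disperse, so a large fraction of matings are
between siblings. Two consequences matter for microsatellite data:

1. Diploid females show a strong deficit of heterozygotes relative to
   Hardy–Weinberg expectation, summarized by the inbreeding coefficient
   $F$ ($F_{IS}$).
2. Haploid males are an unusually clean diagnostic for null alleles: a
   non-amplifying allele appears in a male as a missing genotype, not as a
   fake homozygote.

`hapmsat` covers the whole chain from raw reads (SSR discovery) through
per-locus statistics and exact tests to the demographic quantity of
interest: the sib-mating frequency and the effective number of foundresses
per patch.

## Estimators

**Gene diversity.** Expected heterozygosity uses the Levene/Nei
small-sample correction computed from the $2n$ genes of $n$ typed diploid
females,
$$ H_E = \frac{2n}{2n-1}\Bigl(1 - \sum_u p_u^2\Bigr), $$
which for a biallelic locus reduces to $(2n/(2n-1))\,2pq$. Observed
heterozygosity is the heterozygote fraction among typed females. All
female-only conventions follow from haplodiploidy: males carry no
heterozygosity information, so $H_O$, $H_E$, $F$ and the Hardy–Weinberg
tests are computed from females, while allele pooling across sexes is used
only for private-allele and null-allele reports.

**Inbreeding.** The default $F$ is the Weir & Cockerham (1984)
within-population estimator. Per allele $u$, with $\bar h_u$ the observed
frequency of heterozygotes carrying $u$ and $p_u$ its frequency,
$$ \hat c_u = \bar h_u / 2, \qquad
   \hat b_u = \frac{n}{n-1}\Bigl(p_u(1-p_u) - \frac{2n-1}{4n}\bar h_u\Bigr),
   \qquad
   \hat F = 1 - \frac{\sum_u \hat c_u}{\sum_u (\hat b_u + \hat c_u)}. $$
It equals exactly 1 at any polymorphic locus with $H_O = 0$, which is why
heavily inbred samples print an $F$ column of `1.000`. The naive plug-in
$1 - H_O/H_E$ is available as `fis_simple()` for comparison; the two
converge for large $n$ but differ noticeably at survey sizes of 9–12
females, and the Weir–Cockerham form is what GENEPOP-style software
reports. Multilocus $F$ (and multilocus $\theta$ for $F_{ST}$) is always a
ratio of summed components over loci, never a mean of per-locus ratios,
so uninformative loci do not dilute the estimate.

**Sib mating and foundresses.** For haplodiploids at equilibrium with a
fraction $\alpha$ of brother–sister matings, the inbreeding recursion has
the fixed point $F = \alpha/(4 - 3\alpha)$. Inverting,
$$ \alpha = \frac{4F}{3F + 1}, \qquad n = \frac{1}{\alpha} = \frac{3F+1}{4F}, $$
where $n$ is the effective (harmonic-mean) number of foundresses laying on
a patch, under the assumptions that foundresses are unrelated and
contribute equal clutches. Both assumptions are optimistic for real
gregarious parasitoids — sequentially arriving females lay unequal
clutches, and co-foundresses are often relatives — and both violations
bias $\alpha$ upward and $n$ downward. The `sibmating_fit` object carries
this caveat, and reports round $\alpha$ to 3 decimals and $n$ to 2, the
convention for these quantities. $F = 0$ is reported as an unbounded
foundress number rather than an error.

## Exact tests

Hardy–Weinberg tests condition on allele counts, giving the Levene
distribution of genotype arrays,
$$ P(\{n_{uv}\}) = \frac{n!\, 2^h \prod_u a_u!}{(2n)! \prod_{u \le v} n_{uv}!}. $$
Two modes are provided: the *probability* test (tail = arrays no more
probable than the observed, ties included) and the one-sided *deficit*
test (tail = arrays with no more heterozygotes than observed), which is
the natural alternative under inbreeding. The report defaults to the
probability test. When the number of arrays is at most the enumeration cap
(10^6^, computed in C++ by a streaming recursion that never stores
arrays), the tail is exact; beyond it a Guo–Thompson switch Markov chain
is used. The chain draws an index 4-tuple $(i_1, j_1, i_2, j_2)$ with
$i_1 \ne i_2$, $j_1 \ne j_2$ uniformly and switches one gene between
genotypes $\{i_1,j_1\}$ and $\{i_2,j_2\}$; the map
$(i_1,j_1,i_2,j_2) \mapsto (i_1,j_2,i_2,j_1)$ is a bijection between
tuples proposing a move and its reverse, so the kernel is symmetric and
plain Metropolis with the exact Levene ratio is correct. Defaults follow
the customary Markov-chain settings of GENEPOP-type software
(10,000 dememorization steps, 20 batches of 5,000), with batch means
giving the standard error; the log kernel is recomputed at each batch
boundary to stop incremental drift from corrupting tie detection.

A practical calibration note: at survey sizes like $n = 12$ with three
alleles, the exact deficit test is conservative by construction — the
attainable tail probabilities of the discrete heterozygote-count
distribution jump past the nominal level, so the attained size at nominal
5% falls well short of it (the calibration check in the test suite, 2,000
random-mating loci with three equifrequent alleles, measures roughly half
the nominal rate). Users should read "non-significant" at these sample
sizes accordingly.

Linkage disequilibrium uses genotypic contingency tables (alleles for the
haploid stratum, unordered genotypes for the diploid stratum, so no
phasing is ever required), the log-likelihood-ratio $G$, and a permutation
p-value with the add-one estimator $p = (\#\{G^* \ge G\} + 1)/(N + 1)$,
which is never exactly zero. Multiple testing across loci or locus pairs
is handled by Benjamini–Hochberg adjustment (`stats::p.adjust`), with the
banded labels (`<0.001`, `<0.01`, `<0.05`, `N.S.`) used in
characterization tables.

## SSR mining

The scanner reports maximal perfect tandem runs of 2–6 bp motifs meeting
per-length minimum repeat counts (defaults 8, 5, 5, 5, 5 for di- through
hexanucleotides). Three conventions disambiguate the output:

- a run is reported once under its shortest period — `(AT)₁₀` is a
  dinucleotide hit, never `(ATAT)₅` — and homopolymers are never reported;
- a position belongs to at most one hit; when candidate runs overlap, the
  longer tandem wins, ties going to the smaller start;
- repeats are perfect: `N` never matches, and no mismatches or
  interruptions are tolerated (compound repeats appear as separate hits).

Reads shorter than 150 bp are excluded (a read of exactly 150 bp is kept —
the filter drops reads *shorter than* the threshold) and exact duplicate
reads are removed first; the funnel counts at each stage are recorded on
the result. Motif classes aggregate by the canonical motif: the
lexicographic minimum over all cyclic rotations of the motif and of its
reverse complement. The scanner is validated against a brute-force oracle
(every start, every period, maximal extension) on random reads.

## The simulator

`simulate_population()` is a forward model of the survey system, not a
generic coalescent. Mated females are the state: each carries her two
alleles (maternal gamete, paternal gene) and her mate's single gene. A
daughter receives a maternal gamete plus her mother's stored sperm; with
probability $\alpha$ she mates a brother — implemented as an independent
gamete of her own mother, which leaves the inbreeding recursion of the
estimator exactly intact — and otherwise a random male of the population.
Writing the recursion for this model and setting it stationary gives
$F = \alpha/(4-3\alpha)$, i.e. the simulator and the estimator agree by
construction, which is what makes parameter recovery a meaningful
end-to-end test rather than a tautology about one formula.

Defaults describe a *Melittobia*-like system: 5% sons per brood (the genus
range is about 1–5%), with every brood containing at least one son — the
natural situation for large gregarious broods, and a requirement for a
sib mate to exist under the direct model; single-foundress patches; eight
equifrequent alleles per locus initially; stepwise (±1) mutation at
10⁻⁴ per gamete (recovery tests run mutation-free over short horizons); and
a fixed 20-generation burn-in rather than convergence detection — the
recursion approaches equilibrium geometrically at rate $3\alpha/4$, so 20
generations leave a residual below 0.005 even at $\alpha = 1$. The final
emergence cohort is instantiated patch by patch, and `sample_survey()`
draws exactly one female and one male per patch without replacement,
mirroring the field scheme that prevents sampling same-sex relatives.
`inject_null_alleles()` adds the classic null-allele pathology for
diagnostic testing.

Recovery tests use 500 single-foundress patches (≈2,850 cohort females),
five loci and 20 seeds per sib-mating rate; at
$\alpha \in \{0, 0.25, 0.5, 0.873, 1\}$ the median recovered $\alpha$ sits
within ±0.05 of truth and the median multilocus $\hat F$ at
$\alpha = 0.873$ within ±0.03 of 0.632. What the simulator does *not*
emulate: allele-size homoplasy and binning artefacts, genotyping error,
amplification failure (except when injected), related or
unequally-contributing foundresses, and any evolution of the sex ratio.
Passing recovery therefore validates the estimator chain under the
model's own assumptions, not robustness to those real-data complications.

## Numerical and design choices

- Allele codes are opaque positive integers (conventionally fragment
  sizes in bp); 0 is reserved for missing. Diploid genotypes are
  unordered; writers emit min/max order for determinism. A half-missing
  diploid call is invalid rather than silently repaired.
- The tabular dialect with an explicit sex column is the canonical
  format; GENEPOP (which has no sex field) is interchange, with haploid
  males either excluded or written as diploid-coded homozygotes with an
  id suffix that the reader uses to restore ploidy.
- Undefined statistics (monomorphic loci, too few diploids, non-positive
  denominators) are `NA` and render as an em dash — never 0.
- Report rounding is half-up at 3 decimals (2 for foundress numbers);
  `base::round()`'s round-half-even would disagree with printed tables.
- All stochastic procedures take explicit seeds; pipeline steps write a
  manifest (effective configuration, seed, package version, input MD5s)
  from which a run reproduces bit-identically.
- Private-allele proportions pool alleles over loci (each locus/allele
  pair counted once); a per-locus-averaged definition would weight loci
  equally regardless of allele richness, and the pooled form is the
  documented choice.

## Limitations

Null-allele frequency estimation (Brookfield/ML-style), relatedness and
kinship coefficients, multi-locus combined Hardy–Weinberg tests, imperfect
or compound SSR models, and sex-ratio (local mate competition)
optimization are out of scope. The foundress-number estimate is an
effective number under strong assumptions and should be compared with
direct field counts where available; discrepancies are informative about
foundress relatedness and clutch inequality rather than errors in either
number.
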