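#include <Rcpp.h>
using namespace Rcpp;

// Guo-Thompson switch-based Markov chain over diploid genotype arrays with
// fixed allele counts. Target measure is the Levene conditional
// distribution, pi(M) proportional to 2^h / prod(n_uv!).
//
// Proposal: draw an ordered tuple (i1, j1, i2, j2) uniformly with i1 != i2
// and j1 != j2, and switch one gene between genotypes {i1,j1} and {i2,j2}:
// counts at cells (i1,j1) and (i2,j2) decrease by one, (i1,j2) and (i2,j1)
// increase by one. The map (i1,j1,i2,j2) -> (i1,j2,i2,j1) is a bijection
// between the tuples proposing a move and those proposing its reverse, so
// the kernel is symmetric and plain Metropolis applies. Invalid draws
// (empty source cell) count as a step with no move, keeping the kernel
// well-defined.

static inline int cell(const IntegerMatrix &m, int a, int b) {
  return a <= b ? m(a, b) : m(b, a);
}
static inline void bump(IntegerMatrix &m, int a, int b, int d) {
  if (a <= b) m(a, b) += d; else m(b, a) += d;
}
static inline bool is_het(int a, int b) { return a != b; }

// log pi up to a constant shared by all arrays with the same margins
static double log_levene_kernel(const IntegerMatrix &m) {
  const int k = m.nrow();
  double lp = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      lp -= lgamma((double)m(i, j) + 1.0);
      if (i != j) lp += m(i, j) * std::log(2.0);
    }
  return lp;
}

static int het_count(const IntegerMatrix &m) {
  const int k = m.nrow();
  int h = 0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) h += m(i, j);
  return h;
}

// mode 0: probability test  (indicator: logP(M) <= logP(obs) + eps)
// mode 1: deficit test      (indicator: h(M) <= h(obs))
// Returns per-batch means of the tail indicator.
// [[Rcpp::export]]
NumericVector gt_chain_batches(IntegerMatrix observed, int dememorization,
                               int batches, int iter_per_batch, int mode) {
  const int k = observed.nrow();
  if (k < 2) stop("need at least two alleles");
  IntegerMatrix m = clone(observed);
  double lp = log_levene_kernel(m);
  const double lp_obs = lp;
  const int h_obs = het_count(m);
  int h = h_obs;
  const double eps = 1e-9;

  RNGScope scope;
  NumericVector batch_means(batches);
  long total_steps = (long)dememorization + (long)batches * iter_per_batch;
  long step = 0;
  int batch = -1;
  long in_batch = 0;
  double acc = 0.0;

  while (step < total_steps) {
    // propose
    int i1 = (int)(unif_rand() * k);
    int i2 = (int)(unif_rand() * k);
    int j1 = (int)(unif_rand() * k);
    int j2 = (int)(unif_rand() * k);
    if (i1 >= k) i1 = k - 1;
    if (i2 >= k) i2 = k - 1;
    if (j1 >= k) j1 = k - 1;
    if (j2 >= k) j2 = k - 1;
    bool valid = (i1 != i2) && (j1 != j2);
    if (valid) {
      int c1 = cell(m, i1, j1);
      int c2 = cell(m, i2, j2);
      bool same_src = (std::min(i1, j1) == std::min(i2, j2)) &&
                      (std::max(i1, j1) == std::max(i2, j2));
      if (c1 < 1 || c2 < 1 || (same_src && c1 < 2)) valid = false;
      if (valid) {
        // apply tentatively, compute delta log pi from the 4 cells
        int dh = 0;
        dh -= is_het(i1, j1) ? 1 : 0;
        dh -= is_het(i2, j2) ? 1 : 0;
        dh += is_het(i1, j2) ? 1 : 0;
        dh += is_het(i2, j1) ? 1 : 0;
        double dlp = dh * std::log(2.0);
        // decrement of a cell at count c: -log((c-1)!) + log(c!) = +log(c)
        dlp += std::log((double)cell(m, i1, j1));
        bump(m, i1, j1, -1);
        dlp += std::log((double)cell(m, i2, j2));
        bump(m, i2, j2, -1);
        // increment of a cell at count c: -log((c+1)!) + log(c!) = -log(c+1)
        dlp -= std::log((double)cell(m, i1, j2) + 1.0);
        bump(m, i1, j2, +1);
        dlp -= std::log((double)cell(m, i2, j1) + 1.0);
        bump(m, i2, j1, +1);
        double new_lp = lp + dlp;
        if (std::log(unif_rand()) <= dlp) {
          lp = new_lp;
          h += dh;
        } else {
          // undo
          bump(m, i2, j1, -1);
          bump(m, i1, j2, -1);
          bump(m, i2, j2, +1);
          bump(m, i1, j1, +1);
        }
      }
    }
    // record
    if (step >= dememorization) {
      long post = step - dememorization;
      int b = (int)(post / iter_per_batch);
      if (b != batch) {
        if (batch >= 0) batch_means[batch] = acc / in_batch;
        batch = b;
        acc = 0.0;
        in_batch = 0;
        lp = log_levene_kernel(m);  // resync against incremental drift
      }
      bool in_tail = (mode == 1) ? (h <= h_obs) : (lp <= lp_obs + eps);
      acc += in_tail ? 1.0 : 0.0;
      in_batch++;
    }
    step++;
  }
  if (batch >= 0) batch_means[batch] = acc / in_batch;
  return batch_means;
}
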