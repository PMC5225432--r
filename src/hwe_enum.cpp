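#include <Rcpp.h>
using namespace Rcpp;

// Streaming enumeration of all diploid genotype arrays with fixed allele
// counts, accumulating the Levene-conditional tail probability without
// storing arrays. Cells (i,j), i <= j, are filled in row order; once the
// last cell of row i is set, allele i must be fully allocated, which
// prunes hard. Aborts once more than `cap` arrays have been visited.

namespace {

struct EnumState {
  int k;
  std::vector<int> rem;
  std::vector<std::vector<int>> m;
  const std::vector<double> *lfact;
  double lp_obs;      // observed log kernel (2^h / prod n!)
  int h_obs;
  int mode;           // 0 = probability, 1 = deficit
  double tail;
  double total;
  long long count;
  long long cap;
  bool overflow;
};

double log_kernel(const EnumState &st) {
  double lp = 0.0;
  for (int i = 0; i < st.k; ++i)
    for (int j = i; j < st.k; ++j) {
      lp -= (*st.lfact)[st.m[i][j]];
      if (i != j) lp += st.m[i][j] * std::log(2.0);
    }
  return lp;
}

void rec(EnumState &st, int i, int j) {
  if (st.overflow) return;
  if (i >= st.k) {
    bool ok = true;
    for (int u = 0; u < st.k; ++u) {
      if (st.rem[u] != 0) { ok = false; break; }
    }
    if (!ok) return;
    if (++st.count > st.cap) { st.overflow = true; return; }
    double lp = log_kernel(st);
    double pr = std::exp(lp);  // un-normalized
    st.total += pr;
    bool in_tail;
    if (st.mode == 1) {
      int h = 0;
      for (int a = 0; a < st.k; ++a)
        for (int b = a + 1; b < st.k; ++b) h += st.m[a][b];
      in_tail = h <= st.h_obs;
    } else {
      in_tail = lp <= st.lp_obs + 1e-9;
    }
    if (in_tail) st.tail += pr;
    return;
  }
  if (j >= st.k) {
    if (st.rem[i] != 0) return;  // allele i must be used up after its row
    rec(st, i + 1, i + 1);
    return;
  }
  int max_c = (i == j) ? st.rem[i] / 2 : std::min(st.rem[i], st.rem[j]);
  for (int c = 0; c <= max_c; ++c) {
    st.m[i][j] = c;
    if (i == j) st.rem[i] -= 2 * c;
    else { st.rem[i] -= c; st.rem[j] -= c; }
    rec(st, i, j + 1);
    if (i == j) st.rem[i] += 2 * c;
    else { st.rem[i] += c; st.rem[j] += c; }
    st.m[i][j] = 0;
    if (st.overflow) return;
  }
}

} // namespace

// [[Rcpp::export]]
List hwe_exact_tail(IntegerVector allele_counts, IntegerMatrix observed,
                    int mode, double cap) {
  EnumState st;
  st.k = allele_counts.size();
  st.rem.assign(allele_counts.begin(), allele_counts.end());
  st.m.assign(st.k, std::vector<int>(st.k, 0));
  int genes = 0;
  for (int u = 0; u < st.k; ++u) genes += allele_counts[u];
  std::vector<double> lfact(genes + 1, 0.0);
  for (int t = 2; t <= genes; ++t) lfact[t] = lfact[t - 1] + std::log((double)t);
  st.lfact = &lfact;
  st.mode = mode;
  st.cap = (long long)cap;
  st.tail = 0.0;
  st.total = 0.0;
  st.count = 0;
  st.overflow = false;

  // observed kernel and heterozygote count
  EnumState obs = st;
  for (int i = 0; i < st.k; ++i)
    for (int j = i; j < st.k; ++j) obs.m[i][j] = observed(i, j);
  st.lp_obs = log_kernel(obs);
  st.h_obs = 0;
  for (int i = 0; i < st.k; ++i)
    for (int j = i + 1; j < st.k; ++j) st.h_obs += observed(i, j);

  rec(st, 0, 0);
  if (st.overflow) {
    return List::create(Named("feasible") = false,
                        Named("p") = NA_REAL,
                        Named("n_arrays") = NA_REAL);
  }
  return List::create(Named("feasible") = true,
                      Named("p") = st.tail / st.total,
                      Named("n_arrays") = (double)st.count);
}
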