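#include <Rcpp.h>
using namespace Rcpp;

// e is a full L x L x q x q array with e(i,j,a,b) = e(j,i,b,a) and zero
// diagonal blocks; index helper below assumes column-major R layout.
static inline double E(const NumericVector &e, int L, int q,
                       int i, int j, int a, int b) {
  return e[i + L * (j + L * (a + q * b))];
}

// [[Rcpp::export]]
NumericVector hamiltonian_batch_cpp(IntegerMatrix idx, NumericMatrix h,
                                    NumericVector e) {
  const int n = idx.nrow(), L = idx.ncol(), q = h.ncol();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    double acc = 0.0;
    for (int i = 0; i < L; ++i) {
      const int a = idx(s, i) - 1;
      acc += h(i, a);
      for (int j = i + 1; j < L; ++j)
        acc += E(e, L, q, i, j, a, idx(s, j) - 1);
    }
    out[s] = -acc;
  }
  return out;
}

// Single-chain Gibbs sampler over the Potts distribution
// P(S) = exp(sum_i h_i(s_i) + sum_{i<j} e_ij(s_i,s_j)) / Z.
// Uses R's RNG: the caller seeds with set.seed() for reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_potts_cpp(NumericMatrix h, NumericVector e,
                                     int n, int burn_in, int thin) {
  const int L = h.nrow(), q = h.ncol();
  IntegerVector state(L);
  // random initial state
  for (int i = 0; i < L; ++i)
    state[i] = (int)(unif_rand() * q);
  IntegerMatrix out(n, L);
  std::vector<double> logp(q), p(q);
  const int total_sweeps = burn_in + n * thin;
  int kept = 0;
  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int i = 0; i < L; ++i) {
      double mx = R_NegInf;
      for (int a = 0; a < q; ++a) {
        double lp = h(i, a);
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          // use e(i,j,a,s_j); symmetry makes orientation irrelevant
          lp += E(e, L, q, i, j, a, state[j]);
        }
        logp[a] = lp;
        if (lp > mx) mx = lp;
      }
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(logp[a] - mx); Z += p[a]; }
      double u = unif_rand() * Z, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { c += p[a]; if (u <= c) { pick = a; break; } }
      state[i] = pick;
    }
    if (sweep > burn_in && (sweep - burn_in) % thin == 0 && kept < n) {
      for (int i = 0; i < L; ++i) out(kept, i) = state[i] + 1;
      ++kept;
    }
  }
  return out;
}

static inline double pair_identity(const IntegerMatrix &idx, int gap,
                                   int r1, int r2) {
  const int L = idx.ncol();
  int match = 0, n1 = 0, n2 = 0;
  for (int k = 0; k < L; ++k) {
    const int a = idx(r1, k), b = idx(r2, k);
    if (a != gap) ++n1;
    if (b != gap) ++n2;
    if (a != gap && b != gap && a == b) ++match;
  }
  const int denom = n1 < n2 ? n1 : n2;
  return denom == 0 ? 0.0 : (double)match / denom;
}

// Greedy scan in the order `ord` (1-based): keep a record iff identity to
// every previously kept record is < threshold. Returns kept flags per
// position of `ord`.
// [[Rcpp::export]]
LogicalVector identity_greedy_cpp(IntegerMatrix idx, IntegerVector ord,
                                  int gap_idx, double threshold) {
  const int n = ord.size();
  LogicalVector keep(n);
  std::vector<int> kept_rows;
  for (int t = 0; t < n; ++t) {
    const int r = ord[t] - 1;
    bool ok = true;
    for (size_t k = 0; k < kept_rows.size(); ++k) {
      if (pair_identity(idx, gap_idx, r, kept_rows[k]) >= threshold) {
        ok = false; break;
      }
    }
    keep[t] = ok;
    if (ok) kept_rows.push_back(r);
  }
  return keep;
}

// Neighborhood sizes for DCA reweighting: for each record, the number of
// records (self included) with identity >= threshold.
// [[Rcpp::export]]
IntegerVector identity_neighbors_cpp(IntegerMatrix idx, int gap_idx,
                                     double threshold) {
  const int n = idx.nrow();
  IntegerVector cnt(n, 1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pair_identity(idx, gap_idx, i, j) >= threshold) { ++cnt[i]; ++cnt[j]; }
  return cnt;
}

// Max identity of one query row (1-based index into idx2) against all rows
// of idx; returns c(best identity, best row).
// [[Rcpp::export]]
NumericVector max_identity_cpp(IntegerMatrix idx, IntegerVector query,
                               int gap_idx) {
  const int n = idx.nrow(), L = idx.ncol();
  double best = -1.0; int best_row = 0;
  for (int i = 0; i < n; ++i) {
    int match = 0, n1 = 0, n2 = 0;
    for (int k = 0; k < L; ++k) {
      const int a = idx(i, k), b = query[k];
      if (a != gap_idx) ++n1;
      if (b != gap_idx) ++n2;
      if (a != gap_idx && b != gap_idx && a == b) ++match;
    }
    const int denom = n1 < n2 ? n1 : n2;
    const double id = denom == 0 ? 0.0 : (double)match / denom;
    if (id > best) { best = id; best_row = i + 1; }
  }
  return NumericVector::create(best, (double)best_row);
}
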