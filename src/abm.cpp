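#include <Rcpp.h>
using namespace Rcpp;

// Exit-entry (death-birth) event loop on a k-regular graph.
//
// neighbors: N x k integer matrix of 0-based vertex ids.
// types:     length-N integer vector, 1 = type A, 0 = type C.
//
// Per event, exactly two draws from R's RNG in fixed order:
//   (1) exiting vertex  v = floor(u1 * N)
//   (2) replacement     enter A iff u2 < F_A / (F_A + F_C)
// so trajectories are bit-reproducible given set.seed() and match the
// pure-R reference step.
//
// The link from a neighbor back to the vacated vertex counts toward that
// neighbor's payoff tally with the exiting cell's (old) type when
// count_vacated is true; it is skipped entirely when false.

// [[Rcpp::export]]
List run_abm_cpp(IntegerMatrix neighbors, IntegerVector types0,
                 double a, double b, double c, double d,
                 double omega, double max_events, double record_every,
                 bool count_vacated) {
  const long long max_ev = (long long)max_events;
  const long long rec_ev = (long long)record_every;
  if (rec_ev < 1) stop("record_every must be >= 1 event");
  const int N = neighbors.nrow();
  const int k = neighbors.ncol();
  if (types0.size() != N) stop("types must have length N");

  std::vector<int> types(types0.begin(), types0.end());

  // population and undirected edge counts by type pair
  long nA = 0;
  for (int i = 0; i < N; ++i) nA += types[i];
  double eAA = 0.0, eAC = 0.0, eCC = 0.0;  // undirected
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < k; ++j) {
      int u = neighbors(i, j);
      if (u > i) {
        int s = types[i] + types[u];
        if (s == 2) eAA += 1.0; else if (s == 1) eAC += 1.0; else eCC += 1.0;
      }
    }
  }

  R_xlen_t n_rec_max = (R_xlen_t)(max_ev / rec_ev) + 3;
  NumericMatrix rec(n_rec_max, 5);  // event, n_A, eAA, eAC, eCC
  R_xlen_t ri = 0;
  rec(ri, 0) = 0; rec(ri, 1) = (double)nA;
  rec(ri, 2) = eAA; rec(ri, 3) = eAC; rec(ri, 4) = eCC;
  ++ri;

  bool absorbed = (nA == 0 || nA == N);
  double absorption_event = absorbed ? 0.0 : NA_REAL;
  long long e = 0;

  while (!absorbed && e < max_ev) {
    // draw 1: exiting vertex
    double u1 = unif_rand();
    int v = (int)(u1 * N);
    if (v >= N) v = N - 1;
    const int tv = types[v];

    // neighbor tallies
    int KA = 0, KC = 0;
    double eA_A = 0.0, eA_C = 0.0, eC_A = 0.0, eC_C = 0.0;
    for (int j = 0; j < k; ++j) {
      int u = neighbors(v, j);
      int tu = types[u];
      int linksA = 0, linksC = 0;
      for (int m = 0; m < k; ++m) {
        int w = neighbors(u, m);
        if (!count_vacated && w == v) continue;
        if (types[w] == 1) ++linksA; else ++linksC;
      }
      if (tu == 1) { ++KA; eA_A += linksA; eA_C += linksC; }
      else         { ++KC; eC_A += linksA; eC_C += linksC; }
    }

    double FA = KA * (1.0 - omega) + omega * (eA_A * a + eA_C * b);
    double FC = KC * (1.0 - omega) + omega * (eC_A * c + eC_C * d);
    double tot = FA + FC;
    if (!(tot > 0.0))
      stop("degenerate fitness configuration (F_A + F_C <= 0) at event %lld", e + 1);

    // draw 2: replacement type
    double u2 = unif_rand();
    int tnew = (u2 < FA / tot) ? 1 : 0;

    if (tnew != tv) {
      for (int j = 0; j < k; ++j) {
        int tu = types[neighbors(v, j)];
        // remove edge (tv, tu), add edge (tnew, tu)
        if (tv == 1) { if (tu == 1) eAA -= 1.0; else eAC -= 1.0; }
        else         { if (tu == 1) eAC -= 1.0; else eCC -= 1.0; }
        if (tnew == 1) { if (tu == 1) eAA += 1.0; else eAC += 1.0; }
        else           { if (tu == 1) eAC += 1.0; else eCC += 1.0; }
      }
      types[v] = tnew;
      nA += (tnew - tv);
    }
    e += 1;

    bool hit = (nA == 0 || nA == N);
    if (e % rec_ev == 0 || hit) {
      rec(ri, 0) = (double)e; rec(ri, 1) = (double)nA;
      rec(ri, 2) = eAA; rec(ri, 3) = eAC; rec(ri, 4) = eCC;
      ++ri;
    }
    if (hit) { absorbed = true; absorption_event = (double)e; }
  }

  NumericMatrix out(ri, 5);
  for (R_xlen_t i = 0; i < ri; ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = rec(i, j);

  return List::create(
    _["records"] = out,
    _["absorbed"] = absorbed,
    _["absorption_event"] = absorption_event,
    _["n_events"] = (double)e,
    _["final_types"] = IntegerVector(types.begin(), types.end()));
}
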