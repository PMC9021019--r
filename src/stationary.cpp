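#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// LAPACK banded solver (R ships a full LAPACK).
extern "C" void dgbsv_(const int *n, const int *kl, const int *ku,
                       const int *nrhs, double *ab, const int *ldab,
                       int *ipiv, double *b, const int *ldb, int *info);

// Banded storage for A = t(Q) with kl sub- and ku super-diagonals.
// Column-major LAPACK band layout: A(i, j) lives at ab[kl + ku + i - j + j*ldab].
struct BandMat {
  int n, kl, ku, ldab;
  std::vector<double> ab;
  BandMat(int n_, int kl_, int ku_)
    : n(n_), kl(kl_), ku(ku_), ldab(2 * kl_ + ku_ + 1),
      ab((size_t)(2 * kl_ + ku_ + 1) * n_, 0.0) {}
  inline void add(int i, int j, double v) {
    ab[(size_t)(kl + ku + i - j) + (size_t)j * ldab] += v;
  }
  inline void set(int i, int j, double v) {
    ab[(size_t)(kl + ku + i - j) + (size_t)j * ldab] = v;
  }
};

// Add one CTMC transition from state `from` to state `to` with rate r
// into A = t(Q): A[to, from] += r, A[from, from] -= r.
static inline void add_rate(BandMat &A, int from, int to, double r) {
  if (r <= 0.0) return;
  A.add(to, from, r);
  A.add(from, from, -r);
}

// Solve t(Q) pi = 0, sum(pi) = 1 by replacing the balance equation of a
// reference recurrent state `ref` with pi[ref] = 1, then renormalizing.
static std::vector<double> solve_stationary(BandMat &A, int ref) {
  const int n = A.n, kl = A.kl, ku = A.ku, ldab = A.ldab;
  // zero out row `ref` within the band, then set A[ref, ref] = 1
  int jlo = std::max(0, ref - ku), jhi = std::min(n - 1, ref + kl);
  for (int j = jlo; j <= jhi; ++j) A.set(ref, j, 0.0);
  A.set(ref, ref, 1.0);
  std::vector<double> b(n, 0.0);
  b[ref] = 1.0;
  std::vector<int> ipiv(n);
  int nrhs = 1, info = 0;
  dgbsv_(&n, &kl, &ku, &nrhs, A.ab.data(), &ldab, ipiv.data(), b.data(), &n,
         &info);
  if (info != 0)
    stop("banded stationary solve failed (LAPACK dgbsv info = %d)", info);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (b[i] < 0.0) b[i] = 0.0;  // clamp tiny negative round-off
    s += b[i];
  }
  if (!(s > 0.0)) stop("stationary solve returned a zero vector");
  for (int i = 0; i < n; ++i) b[i] /= s;
  return b;
}

// Stationary distribution of the truncated telegraph-model master equation.
// States (m, s), s = 0 (OFF) / 1 (ON), m = 0..M, index = 2*m + s.
// Reflecting truncation at m = M. Requires kon, koff, mu, delta > 0.
// ref_m anchors the normalization at a high-probability state (usually the
// mode): anchoring at m = 0 underflows when the stationary mass sits far
// from zero.
// [[Rcpp::export(name = ".telegraph_stationary_cpp")]]
List telegraph_stationary_cpp(double kon, double koff, double mu, double delta,
                              int M, int ref_m) {
  if (M < 0) stop("M must be >= 0");
  if (ref_m < 0 || ref_m > M) stop("ref_m out of range");
  const int N = 2 * (M + 1);
  BandMat A(N, 2, 2);
  for (int m = 0; m <= M; ++m) {
    int off = 2 * m, on = 2 * m + 1;
    add_rate(A, off, on, kon);
    add_rate(A, on, off, koff);
    if (m < M) add_rate(A, on, on + 2, mu);      // birth (ON only)
    if (m > 0) {
      add_rate(A, off, off - 2, m * delta);      // death
      add_rate(A, on, on - 2, m * delta);
    }
  }
  std::vector<double> pi = solve_stationary(A, 2 * ref_m);
  NumericVector pmf(M + 1);
  double pon = 0.0;
  for (int m = 0; m <= M; ++m) {
    pmf[m] = pi[2 * m] + pi[2 * m + 1];
    pon += pi[2 * m + 1];
  }
  return List::create(_["pmf"] = pmf, _["p_on"] = pon);
}

// Stationary distribution of the mechanistic enhancer-promoter CTMC.
// State (contact, step, promoter, m) with inner index
//   inner = promoter + 2*contact + 4*step  (contact: 0 far / 1 close),
// K = 4*(n+1) inner states, global index = m*K + inner, m = 0..M.
// Transitions:
//   contact far->close at k_close, close->far at k_far;
//   step+1 at k_forward only when close and step < n;
//   step-1 at k_back in either contact state;
//   promoter OFF->ON at kon_enh if step == n else kon_basal; ON->OFF at k_off;
//   mRNA birth at mu when ON; death at m*delta.
// [[Rcpp::export(name = ".mechanistic_stationary_cpp")]]
List mechanistic_stationary_cpp(double k_close, double k_far, double k_forward,
                                double k_back, int n, double kon_basal,
                                double kon_enh, double k_off, double mu,
                                double delta, int M, int ref_m) {
  if (n < 1) stop("n must be >= 1");
  if (M < 0) stop("M must be >= 0");
  if (ref_m < 0 || ref_m > M) stop("ref_m out of range");
  const int K = 4 * (n + 1);
  const int N = K * (M + 1);
  BandMat A(N, K, K);
  for (int m = 0; m <= M; ++m) {
    for (int step = 0; step <= n; ++step) {
      for (int contact = 0; contact <= 1; ++contact) {
        for (int prom = 0; prom <= 1; ++prom) {
          int idx = m * K + prom + 2 * contact + 4 * step;
          // contact toggling
          add_rate(A, idx, idx + (contact ? -2 : 2), contact ? k_far : k_close);
          // regulatory steps
          if (contact == 1 && step < n) add_rate(A, idx, idx + 4, k_forward);
          if (step > 0) add_rate(A, idx, idx - 4, k_back);
          // promoter switching
          if (prom == 0)
            add_rate(A, idx, idx + 1, step == n ? kon_enh : kon_basal);
          else
            add_rate(A, idx, idx - 1, k_off);
          // mRNA birth/death
          if (prom == 1 && m < M) add_rate(A, idx, idx + K, mu);
          if (m > 0) add_rate(A, idx, idx - K, m * delta);
        }
      }
    }
  }
  // reference state: (close, step 0, OFF, m = ref_m) -- recurrent when
  // k_close > 0
  std::vector<double> pi = solve_stationary(A, ref_m * K + 2);
  NumericVector pmf(M + 1);
  NumericVector step_occ(n + 1);
  NumericMatrix joint_cp(2, 2);  // [contact, promoter]
  for (int m = 0; m <= M; ++m) {
    double acc = 0.0;
    for (int step = 0; step <= n; ++step)
      for (int contact = 0; contact <= 1; ++contact)
        for (int prom = 0; prom <= 1; ++prom) {
          double v = pi[(size_t)m * K + prom + 2 * contact + 4 * step];
          acc += v;
          step_occ[step] += v;
          joint_cp(contact, prom) += v;
        }
    pmf[m] = acc;
  }
  return List::create(_["pmf"] = pmf, _["step_occ"] = step_occ,
                      _["joint_cp"] = joint_cp);
}

// Exact (Gillespie) stochastic simulation of the mechanistic CTMC.
// Uses R's RNG so that set.seed() in R makes runs reproducible.
// Samples the mRNA count on the deterministic grid
//   t = burn_in + k * sample_spacing, k = 0 .. n_samples-1 (if n_samples > 0).
// When `record` is true the full event trajectory is returned (up to
// max_events events; the simulation stops with truncated = TRUE beyond that).
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(double k_close, double k_far, double k_forward,
                   double k_back, int n, double kon_basal, double kon_enh,
                   double k_off, double mu, double delta, double t_end,
                   double burn_in, double sample_spacing, int n_samples,
                   bool record, int max_events, int contact0, int step0,
                   int prom0, int m0) {
  if (n < 1) stop("n must be >= 1");
  if (t_end <= burn_in && n_samples > 0)
    stop("t_end must exceed burn_in when sampling");
  int contact = contact0, step = step0, prom = prom0, m = m0;
  double t = 0.0;
  std::vector<double> tt;
  std::vector<int> cc, ss, pp, mm;
  if (record) {
    tt.push_back(t); cc.push_back(contact); ss.push_back(step);
    pp.push_back(prom); mm.push_back(m);
  }
  IntegerVector samples(n_samples > 0 ? n_samples : 0);
  int k = 0;
  bool absorbed = false, truncated = false;
  long events = 0;
  while (t < t_end) {
    double a1 = contact ? k_far : k_close;
    double a2 = (contact == 1 && step < n) ? k_forward : 0.0;
    double a3 = (step > 0) ? k_back : 0.0;
    double a4 = prom ? k_off : (step == n ? kon_enh : kon_basal);
    double a5 = prom ? mu : 0.0;
    double a6 = m * delta;
    double total = a1 + a2 + a3 + a4 + a5 + a6;
    double t_next;
    if (total <= 0.0) {
      absorbed = true;
      t_next = t_end;
    } else {
      t_next = t + R::exp_rand() / total;
    }
    // emit samples due strictly before the next event
    while (k < n_samples) {
      double ts = burn_in + (double)k * sample_spacing;
      if (ts >= t_next || ts > t_end) break;
      samples[k++] = m;
    }
    if (absorbed || t_next > t_end) { t = t_end; break; }
    t = t_next;
    double u = unif_rand() * total;
    if (u < a1) contact = 1 - contact;
    else if (u < a1 + a2) step += 1;
    else if (u < a1 + a2 + a3) step -= 1;
    else if (u < a1 + a2 + a3 + a4) prom = 1 - prom;
    else if (u < a1 + a2 + a3 + a4 + a5) m += 1;
    else m -= 1;
    ++events;
    if (record) {
      if ((long)tt.size() < (long)max_events) {
        tt.push_back(t); cc.push_back(contact); ss.push_back(step);
        pp.push_back(prom); mm.push_back(m);
      } else {
        truncated = true;
        if (n_samples == 0) break;  // nothing else to collect
      }
    }
  }
  // any remaining samples take the final state
  while (k < n_samples) {
    double ts = burn_in + (double)k * sample_spacing;
    if (ts > t_end) break;
    samples[k++] = m;
  }
  if (k < n_samples) samples = head(samples, k);
  List out = List::create(
      _["samples"] = samples, _["absorbed"] = absorbed,
      _["truncated"] = truncated, _["t_final"] = t, _["events"] = (double)events);
  if (record) {
    out["time"] = wrap(tt);
    out["contact"] = wrap(cc);
    out["step"] = wrap(ss);
    out["promoter"] = wrap(pp);
    out["m"] = wrap(mm);
  }
  return out;
}
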