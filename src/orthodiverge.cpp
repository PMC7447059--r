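#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=T. A substitution is a transition
// exactly when old^new == 2 (A<->G, C<->T). Codons are 16*b1 + 4*b2 + b3.

namespace {

inline bool is_transition_int(int a, int b) { return (a ^ b) == 2; }

struct EvolveCtx {
  std::vector<int> seq;      // nucleotide states
  int L;                     // nucleotides
  double kappa, omega, cpg_mult;
  const double *pi64;       // codon frequency, 0 for stops
  const int *aa64;          // amino-acid index per codon, -1 for stops
  std::vector<double> rate;  // 3 proposal rates per site
  std::vector<int> altb;     // the 3 alternative bases per site
  double total;

  bool cpg_context(int p) const {
    if (p > 0 && seq[p - 1] == 1 && seq[p] == 2) return true;       // ..C[G]..
    if (seq[p] == 1 && p + 1 < L && seq[p + 1] == 2) return true;   // ..[C]G..
    return false;
  }

  int codon_int(int c0) const {
    return seq[3 * c0] * 16 + seq[3 * c0 + 1] * 4 + seq[3 * c0 + 2];
  }

  // recompute the 3 proposal rates of nucleotide site p; returns their sum
  double site_rates(int p) {
    if (p < 3) {  // the initiation codon is held invariant
      rate[3 * p] = rate[3 * p + 1] = rate[3 * p + 2] = 0.0;
      int b = seq[p], j = 0;
      for (int nb = 0; nb < 4; ++nb) if (nb != b) altb[3 * p + j++] = nb;
      return 0.0;
    }
    int c0 = p / 3, w = p % 3;
    int oc = codon_int(c0);
    int oaa = aa64[oc];
    int b = seq[p];
    bool cpg = cpg_context(p);
    static const int shift[3] = {16, 4, 1};
    double s = 0.0;
    int j = 0;
    for (int nb = 0; nb < 4; ++nb) {
      if (nb == b) continue;
      int nc = oc + (nb - b) * shift[w];
      double r;
      if (aa64[nc] < 0) {
        r = 0.0;  // proposals creating stop codons are forbidden
      } else {
        r = pi64[nc];
        if (is_transition_int(b, nb)) {
          r *= kappa;
          if (cpg) r *= cpg_mult;
        }
        if (aa64[nc] != oaa) r *= omega;
      }
      rate[3 * p + j] = r;
      altb[3 * p + j] = nb;
      s += r;
      ++j;
    }
    return s;
  }

  void init_rates() {
    total = 0.0;
    for (int p = 0; p < L; ++p) total += site_rates(p);
  }

  double sum_all() const {
    double s = 0.0;
    for (size_t k = 0; k < rate.size(); ++k) s += rate[k];
    return s;
  }
};

}  // namespace

// Evolve one lineage of a sense-codon sequence for `t_branch` expected
// substitutions per codon (expectation taken at the starting sequence),
// under a GY94-style model: proposal rate to codon j is
// pi_j * kappa^[transition] * omega^[nonsynonymous] * cpg_mult^[transition
// at a site currently in CpG context]; stop-creating proposals get rate 0.
// Exact (Gillespie) simulation; uses R's RNG.
// [[Rcpp::export(name = ".evolve_lineage_cpp")]]
IntegerVector evolve_lineage_cpp(IntegerVector seq0, double t_branch,
                                 double kappa, double omega, double cpg_mult,
                                 NumericVector pi64, IntegerVector aa64) {
  EvolveCtx ctx;
  ctx.seq.assign(seq0.begin(), seq0.end());
  ctx.L = ctx.seq.size();
  if (ctx.L % 3 != 0) stop("sequence length not a multiple of 3");
  ctx.kappa = kappa;
  ctx.omega = omega;
  ctx.cpg_mult = cpg_mult;
  ctx.pi64 = REAL(pi64);
  ctx.aa64 = INTEGER(aa64);
  ctx.rate.assign(3 * ctx.L, 0.0);
  ctx.altb.assign(3 * ctx.L, 0);
  ctx.init_rates();

  int n_codons = ctx.L / 3;
  double r0 = ctx.total;  // raw total rate at the start
  if (r0 <= 0.0) return IntegerVector(ctx.seq.begin(), ctx.seq.end());
  // raw-time horizon giving t_branch expected substitutions per codon
  double T = t_branch * n_codons / r0;

  double t = 0.0;
  long n_events = 0;
  while (true) {
    if (ctx.total <= 0.0) break;
    t += exp_rand() / ctx.total;
    if (t > T) break;
    // pick proposal proportional to rate
    double u = unif_rand() * ctx.total;
    double acc = 0.0;
    int kpick = -1;
    int nk = 3 * ctx.L;
    for (int k = 0; k < nk; ++k) {
      acc += ctx.rate[k];
      if (u <= acc) { kpick = k; break; }
    }
    if (kpick < 0) kpick = nk - 1;
    int p = kpick / 3;
    int nb = ctx.altb[kpick];
    ctx.seq[p] = nb;
    // update rates of every site whose proposal rates can change: the
    // mutated codon (syn/nonsyn/stop structure) and the two flanking
    // nucleotides (CpG context)
    int c0 = p / 3;
    int lo = std::max(0, 3 * c0 - 1), hi = std::min(ctx.L - 1, 3 * c0 + 3);
    if (p - 1 >= 0 && p - 1 < lo) lo = p - 1;
    if (p + 1 <= ctx.L - 1 && p + 1 > hi) hi = p + 1;
    for (int q = lo; q <= hi; ++q) {
      double old_s = ctx.rate[3 * q] + ctx.rate[3 * q + 1] + ctx.rate[3 * q + 2];
      double new_s = ctx.site_rates(q);
      ctx.total += new_s - old_s;
    }
    // periodic exact resummation to keep the incremental total honest
    if ((++n_events & 0xFFF) == 0) ctx.total = ctx.sum_all();
  }
  return IntegerVector(ctx.seq.begin(), ctx.seq.end());
}

// Global (Needleman-Wunsch) alignment with affine gaps. A gap run of
// length k costs gap_open + k * gap_extend. States: M (substitution),
// X (gap in b, consumes a), Y (gap in a, consumes b); ties are broken
// deterministically with preference M > X > Y everywhere, which realises
// the "diagonal > up > left" traceback rule.
// With fit = true the alignment is semi-global ("fit" a inside b): gaps in
// the a-row before the first and after the last aligned position of a are
// free, so a is located within b without penalising b's overhangs.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix score,
                  double gap_open, double gap_extend, bool fit = false) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  const double go = gap_open, ge = gap_extend;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
      Y((m + 1) * W, NEG);
  // traceback: predecessor state (0=M,1=X,2=Y) for each cell/state
  std::vector<unsigned char> pm((m + 1) * W), px((m + 1) * W), py((m + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[i * W] = -(go + ge * i);
    px[i * W] = 1;
  }
  px[W] = 0;  // first gap opens from M at origin
  for (int j = 1; j <= n; ++j) {
    Y[j] = fit ? 0.0 : -(go + ge * j);
    py[j] = 2;
  }
  if (n >= 1) py[1] = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
                lf = i * W + (j - 1);
      // M from diagonal, preference M > X > Y
      double best = M[d];
      unsigned char bs = 0;
      if (X[d] > best) { best = X[d]; bs = 1; }
      if (Y[d] > best) { best = Y[d]; bs = 2; }
      M[c] = best + score(a[i - 1], b[j - 1]);
      pm[c] = bs;
      // X: consume a[i-1] (gap in b)
      double open = std::max(M[up], Y[up]) - (go + ge);
      unsigned char xo = (M[up] >= Y[up]) ? 0 : 2;
      double ext = X[up] - ge;
      if (open >= ext) { X[c] = open; px[c] = xo; }
      else             { X[c] = ext;  px[c] = 1; }
      // Y: consume b[j-1] (gap in a)
      double open2 = std::max(M[lf], X[lf]) - (go + ge);
      unsigned char yo = (M[lf] >= X[lf]) ? 0 : 1;
      double ext2 = Y[lf] - ge;
      if (open2 >= ext2) { Y[c] = open2; py[c] = yo; }
      else               { Y[c] = ext2;  py[c] = 2; }
    }
  }

  int jend = n;
  double best;
  int st;
  if (fit) {
    // end anywhere on the last row; b's trailing overhang is free
    best = -1e300;
    st = 0;
    for (int j = 0; j <= n; ++j) {
      const int c = m * W + j;
      if (M[c] > best) { best = M[c]; st = 0; jend = j; }
      if (X[c] > best) { best = X[c]; st = 1; jend = j; }
    }
  } else {
    const int end = m * W + n;
    best = M[end];
    st = 0;
    if (X[end] > best) { best = X[end]; st = 1; }
    if (Y[end] > best) { best = Y[end]; st = 2; }
  }

  std::vector<int> ai, bi;
  int i = m, j = jend;
  while (i > 0 || j > 0) {
    if (st == 0) {
      ai.push_back(i - 1); bi.push_back(j - 1);
      st = pm[i * W + j]; --i; --j;
    } else if (st == 1) {
      ai.push_back(i - 1); bi.push_back(-1);
      st = px[i * W + j]; --i;
    } else {
      ai.push_back(-1); bi.push_back(j - 1);
      st = py[i * W + j]; --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bi.begin(), bi.end()),
                      _["score"] = best);
}
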