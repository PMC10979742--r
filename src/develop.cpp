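#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// Sparse triplet matrix-vector products drive the developmental recursion.
// Entries arrive in column-major order (from dgCMatrix), one combined set of
// parallel vectors (m, i, j, x) over the six genome matrices with
// m: 1=E, 2=F, 3=G, 4=H, 5=J, 6=P.

namespace {

struct Tri {
  std::vector<int> i, j;      // 0-based
  std::vector<double> x;
};

// y += M v
inline void spmv(const Tri &M, const double *v, double *y) {
  const size_t nnz = M.x.size();
  for (size_t k = 0; k < nnz; ++k) y[M.i[k]] += M.x[k] * v[M.j[k]];
}

inline double act_atan(double x, double gain) {
  return (2.0 / M_PI) * std::atan(gain * x);
}

struct DevResult {
  std::vector<double> adult;
  int nSteps;
  bool converged;
};

void splitTriplets(const IntegerVector &m, const IntegerVector &i,
                   const IntegerVector &j, const NumericVector &x,
                   Tri mats[6]) {
  const int nnz = m.size();
  for (int t = 0; t < 6; ++t) {
    mats[t].i.clear(); mats[t].j.clear(); mats[t].x.clear();
  }
  for (int k = 0; k < nnz; ++k) {
    Tri &M = mats[m[k] - 1];
    M.i.push_back(i[k] - 1);
    M.j.push_back(j[k] - 1);
    M.x.push_back(x[k]);
  }
}

// One full developmental run.  mats order: E F G H J P.
DevResult developCore(const Tri mats[6], int n, const double *cue, bool useCue,
                      int maxSteps, double convTol, double alpha,
                      const double *gains /* f g h p */) {
  const Tri &E = mats[0], &F = mats[1], &G = mats[2],
            &H = mats[3], &J = mats[4], &P = mats[5];
  std::vector<double> f(n, 0.0), g(n, 1.0), h(n, 0.0), p(n, 0.0);
  std::vector<double> pt(n, 0.0), v(n, 1.0);
  std::vector<double> arg(n), cvec(n), hnew(n);

  DevResult res;
  res.nSteps = maxSteps;
  res.converged = false;

  for (int s = 1; s <= maxSteps; ++s) {
    // f(s) = act_f(G g(s-1) + E (c - pt(s-1))), c = cue (Full) or 0 (NoCue)
    for (int q = 0; q < n; ++q)
      cvec[q] = (useCue ? cue[q] : 0.0) - pt[q];
    std::fill(arg.begin(), arg.end(), 0.0);
    spmv(G, g.data(), arg.data());
    spmv(E, cvec.data(), arg.data());
    for (int q = 0; q < n; ++q) f[q] = act_atan(arg[q], gains[0]);

    // g(s) = act_g(F f(s))
    std::fill(arg.begin(), arg.end(), 0.0);
    spmv(F, f.data(), arg.data());
    for (int q = 0; q < n; ++q) g[q] = act_atan(arg[q], gains[1]);

    // h(s) = act_h(H g(s) + J h(s-1))
    std::fill(arg.begin(), arg.end(), 0.0);
    spmv(H, g.data(), arg.data());
    spmv(J, h.data(), arg.data());
    for (int q = 0; q < n; ++q) hnew[q] = act_atan(arg[q], gains[2]);
    h.swap(hnew);

    // p(s) = act_p(P h(s))
    std::fill(arg.begin(), arg.end(), 0.0);
    spmv(P, h.data(), arg.data());
    for (int q = 0; q < n; ++q) p[q] = std::tanh(gains[3] * arg[q]);

    // v then the phenotype moving average, both against pt(s-1)
    double sumv = 0.0;
    for (int q = 0; q < n; ++q) {
      const double d = pt[q] - p[q];
      v[q] = (1.0 - alpha) * (v[q] + alpha * d * d);
      sumv += v[q];
      pt[q] = alpha * p[q] + (1.0 - alpha) * pt[q];
    }
    if (sumv < convTol) {
      res.nSteps = s;
      res.converged = true;
      break;
    }
  }
  res.adult = pt;
  return res;
}

} // namespace

// [[Rcpp::export]]
List cppDevelop(IntegerVector m, IntegerVector i, IntegerVector j,
                NumericVector x, int n, NumericVector cue, bool useCue,
                int maxSteps, double convTol, double alpha,
                NumericVector gains) {
  Tri mats[6];
  splitTriplets(m, i, j, x, mats);
  DevResult r = developCore(mats, n, useCue ? cue.begin() : (double *)nullptr,
                            useCue, maxSteps, convTol, alpha, gains.begin());
  return List::create(_["adult"] = NumericVector(r.adult.begin(), r.adult.end()),
                      _["nSteps"] = r.nSteps, _["converged"] = r.converged);
}

// Develop a whole population in one call.  pop: list of list(m, i, j, x);
// cues: n x N matrix (ignored when useCue is false).
// [[Rcpp::export]]
List cppDevelopPopulation(List pop, int n, NumericMatrix cues, bool useCue,
                          int maxSteps, double convTol, double alpha,
                          NumericVector gains) {
  const int N = pop.size();
  NumericMatrix adults(n, N);
  IntegerVector steps(N);
  LogicalVector conv(N);
  Tri mats[6];
  for (int k = 0; k < N; ++k) {
    List gnm = pop[k];
    IntegerVector m = gnm["m"], i = gnm["i"], j = gnm["j"];
    NumericVector x = gnm["x"];
    splitTriplets(m, i, j, x, mats);
    const double *cue = nullptr;
    if (useCue) cue = &cues(0, k);
    DevResult r = developCore(mats, n, cue, useCue, maxSteps, convTol, alpha,
                              gains.begin());
    std::copy(r.adult.begin(), r.adult.end(), adults.column(k).begin());
    steps[k] = r.nSteps;
    conv[k] = r.converged;
  }
  return List::create(_["adults"] = adults, _["nSteps"] = steps,
                      _["converged"] = conv);
}

// Whole-generation reproduction: row-block crossover of each parent pair
// followed by density-preserving per-element mutation of both offspring.
// Uses R's RNG (unif_rand) so runs stay reproducible under set.seed().
// [[Rcpp::export]]
List cppReproduce(List pop, IntegerMatrix pairs, int n, double rate,
                  double density, bool gaussian) {
  const int nPairs = pairs.nrow();
  const double nsq = (double)n * n;
  const double tot = 6.0 * nsq;
  List offspring(2 * nPairs);
  std::vector<int> swap(n);

  for (int r = 0; r < nPairs; ++r) {
    List fa = pop[pairs(r, 0) - 1];
    List fb = pop[pairs(r, 1) - 1];
    for (int q = 0; q < n; ++q) swap[q] = unif_rand() < 0.5;

    for (int which = 0; which < 2; ++which) {
      // offspring 0 keeps parent-a rows where !swap, takes b rows where swap;
      // offspring 1 holds the complement
      List keepP = which == 0 ? fa : fb;
      List takeP = which == 0 ? fb : fa;
      IntegerVector km = keepP["m"], ki = keepP["i"], kj = keepP["j"];
      NumericVector kx = keepP["x"];
      IntegerVector tm = takeP["m"], ti = takeP["i"], tj = takeP["j"];
      NumericVector tx = takeP["x"];

      std::vector<int> om, oi, oj;
      std::vector<double> ox;
      om.reserve(km.size() + tm.size());
      oi.reserve(km.size() + tm.size());
      oj.reserve(km.size() + tm.size());
      ox.reserve(km.size() + tm.size());
      for (int k = 0; k < km.size(); ++k)
        if (!swap[ki[k] - 1]) {
          om.push_back(km[k]); oi.push_back(ki[k]);
          oj.push_back(kj[k]); ox.push_back(kx[k]);
        }
      for (int k = 0; k < tm.size(); ++k)
        if (swap[ti[k] - 1]) {
          om.push_back(tm[k]); oi.push_back(ti[k]);
          oj.push_back(tj[k]); ox.push_back(tx[k]);
        }

      // mutation: Binomial(6 n^2, rate) distinct positions resampled from
      // the marginal element distribution
      if (rate > 0) {
        const int nSel = (int)R::rbinom(tot, rate);
        std::unordered_set<long long> sel;
        sel.reserve(2 * nSel);
        while ((int)sel.size() < nSel)
          sel.insert((long long)(unif_rand() * tot));
        if (!sel.empty()) {
          size_t w = 0;
          for (size_t k = 0; k < om.size(); ++k) {
            const long long key = (long long)(om[k] - 1) * (long long)nsq +
                                  (long long)(oi[k] - 1) * n + (oj[k] - 1);
            if (sel.count(key)) continue;
            om[w] = om[k]; oi[w] = oi[k]; oj[w] = oj[k]; ox[w] = ox[k];
            ++w;
          }
          om.resize(w); oi.resize(w); oj.resize(w); ox.resize(w);
          for (long long pos : sel) {
            if (unif_rand() >= density) continue;
            const double val = gaussian ? norm_rand()
                                        : (unif_rand() < 0.5 ? -1.0 : 1.0);
            const int mm = (int)(pos / (long long)nsq);
            const long long rr = pos % (long long)nsq;
            om.push_back(mm + 1);
            oi.push_back((int)(rr / n) + 1);
            oj.push_back((int)(rr % n) + 1);
            ox.push_back(val);
          }
        }
      }
      offspring[2 * r + which] = List::create(
          _["m"] = IntegerVector(om.begin(), om.end()),
          _["i"] = IntegerVector(oi.begin(), oi.end()),
          _["j"] = IntegerVector(oj.begin(), oj.end()),
          _["x"] = NumericVector(ox.begin(), ox.end()),
          _["n"] = n);
    }
  }
  return offspring;
}
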