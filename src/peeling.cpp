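#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iterative peeling on a pedigree for a single biallelic locus.
//
// State space: 4 ordered genotypes per individual (paternal allele first):
// 0 = aa, 1 = aA, 2 = Aa, 3 = AA. Messages are passed between nuclear
// families (sire, dam, full-sib offspring set):
//   anterior a_i   : information flowing down from i's parents' family
//   postS/postD[f] : information flowing up from family f to its sire/dam
// Each sweep processes every family forward then backward in topological
// order; on looped pedigrees this iterates the messages to a fixed point.
//
// pen(i, g): phenotype likelihood P(y_i | genotype g), 1 for missing.
// prior: ordered Hardy-Weinberg founder distribution.
// A normalisation sum of zero means the phenotype data contradict the
// penetrance model; the offending individual index is returned.

static inline double pA(int g) {
  return (g == 0) ? 0.0 : ((g == 3) ? 1.0 : 0.5);
}

// [[Rcpp::export]]
List peel_cpp(NumericMatrix pen, NumericVector prior,
              IntegerVector fs, IntegerVector fd, List off,
              List parfams, IntegerVector natal, IntegerVector fam_order,
              double tol, int max_sweeps) {
  const int n = pen.nrow(), F = fs.size();

  // transmission tensor T[go + 4*gs + 16*gd] = P(go | gs, gd)
  double T[64];
  for (int gd = 0; gd < 4; ++gd)
    for (int gs = 0; gs < 4; ++gs) {
      double ps = pA(gs), pd = pA(gd);
      T[0 + 4 * gs + 16 * gd] = (1 - ps) * (1 - pd);
      T[1 + 4 * gs + 16 * gd] = (1 - ps) * pd;
      T[2 + 4 * gs + 16 * gd] = ps * (1 - pd);
      T[3 + 4 * gs + 16 * gd] = ps * pd;
    }

  NumericMatrix a(n, 4), p(n, 4), postS(F, 4), postD(F, 4);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < 4; ++g) {
      a(i, g) = (natal[i] < 0) ? prior[g] : 0.25;
      p(i, g) = 0.25;
    }
  for (int f = 0; f < F; ++f)
    for (int g = 0; g < 4; ++g) { postS(f, g) = 0.25; postD(f, g) = 0.25; }

  // a_i * pen_i * prod of messages to i from parent-families != fexcl
  auto excl = [&](int i, int fexcl, double *out) -> bool {
    for (int g = 0; g < 4; ++g) out[g] = a(i, g) * pen(i, g);
    IntegerVector pf = parfams[i];
    for (int k = 0; k < pf.size(); ++k) {
      int f2 = pf[k];
      if (f2 == fexcl) continue;
      if (fs[f2] == i)
        for (int g = 0; g < 4; ++g) out[g] *= postS(f2, g);
      else
        for (int g = 0; g < 4; ++g) out[g] *= postD(f2, g);
    }
    double s = 0;
    for (int g = 0; g < 4; ++g) s += out[g];
    if (s <= 0) return false;
    for (int g = 0; g < 4; ++g) out[g] /= s;
    return true;
  };

  int err_ind = -1, sweeps_done = 0;
  bool converged = false;
  std::vector<double> Lbuf, pre, suf;

  for (int sweep = 1; sweep <= max_sweeps && !converged; ++sweep) {
    sweeps_done = sweep;
    for (int dir = 0; dir < 2; ++dir) {
      for (int fi = 0; fi < F; ++fi) {
        int f = (dir == 0) ? fam_order[fi] : fam_order[F - 1 - fi];
        int s = fs[f], d = fd[f];
        IntegerVector O = off[f];
        int m = O.size();
        double sstar[4], dstar[4];
        if (!excl(s, f, sstar)) { err_ind = s; goto done; }
        if (!excl(d, f, dstar)) { err_ind = d; goto done; }

        // offspring likelihood surfaces L_o(gs, gd)
        Lbuf.assign((size_t)16 * m, 0.0);
        for (int j = 0; j < m; ++j) {
          int o = O[j];
          double b[4];
          for (int g = 0; g < 4; ++g) b[g] = pen(o, g);
          IntegerVector pf = parfams[o];
          for (int k = 0; k < pf.size(); ++k) {
            int f2 = pf[k];
            if (fs[f2] == o)
              for (int g = 0; g < 4; ++g) b[g] *= postS(f2, g);
            else
              for (int g = 0; g < 4; ++g) b[g] *= postD(f2, g);
          }
          double *L = &Lbuf[(size_t)16 * j], mx = 0;
          for (int gd = 0; gd < 4; ++gd)
            for (int gs = 0; gs < 4; ++gs) {
              double v = 0;
              for (int go = 0; go < 4; ++go) v += T[go + 4 * gs + 16 * gd] * b[go];
              L[gs + 4 * gd] = v;
              if (v > mx) mx = v;
            }
          if (mx <= 0) { err_ind = o; goto done; }
          for (int t = 0; t < 16; ++t) L[t] /= mx;  // underflow guard
        }

        // prefix/suffix products for leave-one-out surfaces
        pre.assign((size_t)16 * (m + 1), 0.0);
        suf.assign((size_t)16 * (m + 1), 0.0);
        for (int t = 0; t < 16; ++t) { pre[t] = 1.0; suf[(size_t)16 * m + t] = 1.0; }
        for (int j = 0; j < m; ++j)
          for (int t = 0; t < 16; ++t)
            pre[(size_t)16 * (j + 1) + t] =
              pre[(size_t)16 * j + t] * Lbuf[(size_t)16 * j + t];
        for (int j = m - 1; j >= 0; --j)
          for (int t = 0; t < 16; ++t)
            suf[(size_t)16 * j + t] =
              suf[(size_t)16 * (j + 1) + t] * Lbuf[(size_t)16 * j + t];
        double *Mall = &pre[(size_t)16 * m];

        // messages up to the parents
        double newS[4], newD[4], ns = 0, nd = 0;
        for (int gs = 0; gs < 4; ++gs) {
          double v = 0;
          for (int gd = 0; gd < 4; ++gd) v += dstar[gd] * Mall[gs + 4 * gd];
          newS[gs] = v; ns += v;
        }
        for (int gd = 0; gd < 4; ++gd) {
          double v = 0;
          for (int gs = 0; gs < 4; ++gs) v += sstar[gs] * Mall[gs + 4 * gd];
          newD[gd] = v; nd += v;
        }
        if (ns <= 0) { err_ind = s; goto done; }
        if (nd <= 0) { err_ind = d; goto done; }
        for (int g = 0; g < 4; ++g) {
          postS(f, g) = newS[g] / ns;
          postD(f, g) = newD[g] / nd;
        }

        // anteriors down to each offspring (siblings' surfaces included)
        for (int j = 0; j < m; ++j) {
          int o = O[j];
          double an[4] = {0, 0, 0, 0};
          for (int gd = 0; gd < 4; ++gd)
            for (int gs = 0; gs < 4; ++gs) {
              double w = sstar[gs] * dstar[gd] *
                pre[(size_t)16 * j + gs + 4 * gd] *
                suf[(size_t)16 * (j + 1) + gs + 4 * gd];
              if (w == 0) continue;
              for (int go = 0; go < 4; ++go) an[go] += w * T[go + 4 * gs + 16 * gd];
            }
          double sa = 0;
          for (int g = 0; g < 4; ++g) sa += an[g];
          if (sa <= 0) { err_ind = o; goto done; }
          for (int g = 0; g < 4; ++g) a(o, g) = an[g] / sa;
        }
      }
    }

    // individual posteriors and convergence check
    {
      double maxdiff = 0;
      for (int i = 0; i < n; ++i) {
        double v[4];
        for (int g = 0; g < 4; ++g) v[g] = a(i, g) * pen(i, g);
        IntegerVector pf = parfams[i];
        for (int k = 0; k < pf.size(); ++k) {
          int f2 = pf[k];
          if (fs[f2] == i)
            for (int g = 0; g < 4; ++g) v[g] *= postS(f2, g);
          else
            for (int g = 0; g < 4; ++g) v[g] *= postD(f2, g);
        }
        double sv = 0;
        for (int g = 0; g < 4; ++g) sv += v[g];
        if (sv <= 0) { err_ind = i; goto done; }
        for (int g = 0; g < 4; ++g) {
          v[g] /= sv;
          double dff = std::fabs(v[g] - p(i, g));
          if (dff > maxdiff) maxdiff = dff;
          p(i, g) = v[g];
        }
      }
      if (maxdiff < tol) converged = true;
    }
  }

done:
  return List::create(_["p"] = p, _["sweeps"] = sweeps_done,
                      _["converged"] = converged,
                      _["err_ind"] = err_ind + 1);  // 1-based, 0 = ok
}
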