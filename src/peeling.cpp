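// Single-locus iterative peeling (segregation analysis) over a pedigree.
//
// Genotypes are counts (0/1/2) of the allele whose frequency is `freq`.
// Messages per individual i and genotype g:
//   anterior ant[i][g]  - information from ancestors and sibs
//   posterior post[m][role][g] - contribution of mating m to parent `role`
// Observed genotypes enter as indicator penetrances. Founders carry a
// Hardy-Weinberg prior. On loop-free pedigrees the fixpoint equals exact
// marginals; on looped pedigrees the iteration is the standard
// approximation. Every individual has either two parents or none (the R
// wrapper inserts phantom founder parents beforehand); individuals are in
// topological order (parents first).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline void normalize3(double* v, bool& ok) {
  double s = v[0] + v[1] + v[2];
  if (s <= 0.0 || !R_finite(s)) {
    v[0] = v[1] = v[2] = 1.0 / 3.0;
    ok = false;
  } else {
    v[0] /= s; v[1] /= s; v[2] /= s;
  }
}

// [[Rcpp::export(name = ".peel_all_cpp")]]
List peel_all_cpp(IntegerMatrix obs, IntegerVector sire, IntegerVector dam,
                  NumericVector freq, double tol, int max_rounds) {
  const int n = obs.nrow();
  const int n_snp = obs.ncol();

  // Mendelian transmission T[go][gs][gd]
  double T[3][3][3];
  for (int gs = 0; gs < 3; ++gs) {
    for (int gd = 0; gd < 3; ++gd) {
      double ps = gs / 2.0, pd = gd / 2.0; // P(parent transmits allele 1)
      T[0][gs][gd] = (1 - ps) * (1 - pd);
      T[1][gs][gd] = ps * (1 - pd) + (1 - ps) * pd;
      T[2][gs][gd] = ps * pd;
    }
  }

  // mating structure: one mating per (sire, dam) pair
  std::vector<int> mate_s, mate_d;              // parents of each mating
  std::vector<std::vector<int>> mate_off;       // offspring of each mating
  std::vector<int> own_mating(n, -1);           // mating an individual is born from
  std::vector<std::vector<int>> par_matings(n); // matings in which i is a parent
  std::vector<std::vector<int>> par_role(n);    // 0 = sire, 1 = dam
  {
    std::vector<long long> keys;
    for (int i = 0; i < n; ++i) {
      if (sire[i] < 0 && dam[i] < 0) continue;
      if (sire[i] < 0 || dam[i] < 0)
        stop("internal error: individual with exactly one known parent");
      long long key = (long long)sire[i] * n + dam[i];
      int m = -1;
      for (size_t k = 0; k < keys.size(); ++k) {
        if (keys[k] == key) { m = (int)k; break; }
      }
      if (m < 0) {
        m = (int)keys.size();
        keys.push_back(key);
        mate_s.push_back(sire[i]);
        mate_d.push_back(dam[i]);
        mate_off.push_back(std::vector<int>());
        par_matings[sire[i]].push_back(m);
        par_role[sire[i]].push_back(0);
        par_matings[dam[i]].push_back(m);
        par_role[dam[i]].push_back(1);
      }
      mate_off[m].push_back(i);
      own_mating[i] = m;
    }
  }
  const int n_mat = (int)mate_s.size();

  NumericVector out((R_xlen_t)n * 3 * n_snp);
  IntegerVector rounds_used(n_snp);
  LogicalVector converged(n_snp);

  std::vector<double> ant(n * 3), pen(n * 3), q(n * 3), qold(n * 3);
  std::vector<double> post(n_mat * 6); // [m][role][g]

  // product over all matings of i of post towards i
  auto w_of = [&](int i, int g) {
    double w = pen[i * 3 + g];
    for (size_t k = 0; k < par_matings[i].size(); ++k) {
      w *= post[par_matings[i][k] * 6 + par_role[i][k] * 3 + g];
    }
    return w;
  };
  // ant * pen * posterior product excluding mating `excl`
  auto u_excl = [&](int i, int excl, double* u) {
    for (int g = 0; g < 3; ++g) {
      double v = ant[i * 3 + g] * pen[i * 3 + g];
      for (size_t k = 0; k < par_matings[i].size(); ++k) {
        if (par_matings[i][k] == excl) continue;
        v *= post[par_matings[i][k] * 6 + par_role[i][k] * 3 + g];
      }
      u[g] = v;
    }
    bool ok = true;
    normalize3(u, ok);
  };

  bool ok = true;
  for (int s = 0; s < n_snp; ++s) {
    const double p = freq[s];
    const double hwe[3] = {(1 - p) * (1 - p), 2 * p * (1 - p), p * p};
    for (int i = 0; i < n; ++i) {
      int g_obs = obs(i, s);
      for (int g = 0; g < 3; ++g) {
        pen[i * 3 + g] = (g_obs < 0 || g_obs == g) ? 1.0 : 0.0;
        ant[i * 3 + g] = hwe[g];
      }
    }
    std::fill(post.begin(), post.end(), 1.0 / 3.0);
    for (int i = 0; i < n * 3; ++i) qold[i] = -1.0;

    int r = 0;
    bool conv = false;
    for (r = 1; r <= max_rounds; ++r) {
      // anterior pass, parents before offspring
      for (int i = 0; i < n; ++i) {
        int m = own_mating[i];
        if (m < 0) continue;
        double us[3], ud[3];
        u_excl(mate_s[m], m, us);
        u_excl(mate_d[m], m, ud);
        double a[3] = {0.0, 0.0, 0.0};
        for (int gs = 0; gs < 3; ++gs) {
          if (us[gs] == 0.0) continue;
          for (int gd = 0; gd < 3; ++gd) {
            double wpair = us[gs] * ud[gd];
            if (wpair == 0.0) continue;
            // full sibs of i in the same mating
            for (size_t k = 0; k < mate_off[m].size(); ++k) {
              int o = mate_off[m][k];
              if (o == i) continue;
              double b = 0.0;
              for (int go = 0; go < 3; ++go) {
                double t = T[go][gs][gd];
                if (t > 0.0) b += t * w_of(o, go);
              }
              wpair *= b;
            }
            if (wpair == 0.0) continue;
            for (int g = 0; g < 3; ++g) a[g] += wpair * T[g][gs][gd];
          }
        }
        normalize3(a, ok);
        for (int g = 0; g < 3; ++g) ant[i * 3 + g] = a[g];
      }

      // posterior pass, youngest matings first
      for (int m = n_mat - 1; m >= 0; --m) {
        for (int role = 0; role < 2; ++role) {
          int other = role == 0 ? mate_d[m] : mate_s[m];
          double uo[3];
          u_excl(other, m, uo);
          double np[3] = {0.0, 0.0, 0.0};
          for (int gself = 0; gself < 3; ++gself) {
            for (int go2 = 0; go2 < 3; ++go2) {
              if (uo[go2] == 0.0) continue;
              int gs = role == 0 ? gself : go2;
              int gd = role == 0 ? go2 : gself;
              double term = uo[go2];
              for (size_t k = 0; k < mate_off[m].size(); ++k) {
                int o = mate_off[m][k];
                double b = 0.0;
                for (int go = 0; go < 3; ++go) {
                  double t = T[go][gs][gd];
                  if (t > 0.0) b += t * w_of(o, go);
                }
                term *= b;
                if (term == 0.0) break;
              }
              np[gself] += term;
            }
          }
          normalize3(np, ok);
          for (int g = 0; g < 3; ++g) post[m * 6 + role * 3 + g] = np[g];
        }
      }

      // final triplets and convergence check
      double delta = 0.0;
      for (int i = 0; i < n; ++i) {
        double v[3];
        for (int g = 0; g < 3; ++g) v[g] = ant[i * 3 + g] * w_of(i, g);
        normalize3(v, ok);
        for (int g = 0; g < 3; ++g) {
          double d = std::abs(v[g] - qold[i * 3 + g]);
          if (d > delta) delta = d;
          q[i * 3 + g] = v[g];
          qold[i * 3 + g] = v[g];
        }
      }
      if (delta < tol) { conv = true; break; }
    }
    rounds_used[s] = std::min(r, max_rounds);
    converged[s] = conv;
    for (int i = 0; i < n; ++i) {
      for (int g = 0; g < 3; ++g) {
        out[(R_xlen_t)s * n * 3 + (R_xlen_t)g * n + i] = q[i * 3 + g];
      }
    }
  }

  return List::create(_["prob"] = out,
                      _["rounds"] = rounds_used,
                      _["converged"] = converged);
}
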