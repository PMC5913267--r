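// Compiled phase loop: iterates the community exactly like the R reference
// implementation in step_community(), with an identical random-draw order
// (effort error; Bernoulli deaths bottom-up; Poisson births, mutations and
// phenotype noise bottom-up), so that for a given seed the compiled and
// reference engines produce identical trajectories. Accumulations use long
// double to match R's internal summation.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Pop {
  std::vector<double> G, attack, vuln, death, birth, pbirth;
  size_t size() const { return G.size(); }
};

inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

} // namespace

// [[Rcpp::export(name = ".run_phase_loop")]]
List run_phase_loop(List pops_in, NumericMatrix par, double resource,
                    double R_max, double r, double graze_scale,
                    NumericVector frozen, double mut_prob, double mut_sd,
                    int harvest_level, double f, double f_error_cv,
                    double onset, int t0, int iters) {
  const int nl = pops_in.size();
  // par columns: a0 v0 b h d0 A V M noise_cv
  std::vector<Pop> pops(nl);
  for (int i = 0; i < nl; ++i) {
    List p = pops_in[i];
    NumericVector G = p["G"], a = p["attack"], v = p["vuln"],
                  d = p["death"], b = p["birth"], pb = p["parent_birth"];
    pops[i].G.assign(G.begin(), G.end());
    pops[i].attack.assign(a.begin(), a.end());
    pops[i].vuln.assign(v.begin(), v.end());
    pops[i].death.assign(d.begin(), d.end());
    pops[i].birth.assign(b.begin(), b.end());
    pops[i].pbirth.assign(pb.begin(), pb.end());
  }

  NumericMatrix rec_ab(iters, nl), rec_bi(iters, nl), rec_de(iters, nl),
      rec_ne(iters, nl), rec_yi(iters, nl), rec_mg(iters, nl),
      rec_sg(iters, nl), rec_gs(iters, nl), rec_gn(iters, nl);
  NumericVector rec_res(iters);
  IntegerVector rec_it(iters);

  std::vector<std::vector<double>> fr(nl), dP(nl), Dtot(nl);
  std::vector<std::vector<int>> dead(nl);
  double R = resource;
  int t = t0;

  for (int k = 0; k < iters; ++k) {
    std::vector<int> Ns(nl);
    for (int i = 0; i < nl; ++i) Ns[i] = (int)pops[i].size();

    const double R_avail = R + r * (R_max - R);

    // functional responses of each level on its prey pool
    std::vector<double> mfr(nl, 0.0);
    for (int i = 0; i < nl; ++i) {
      fr[i].assign(Ns[i], 0.0);
      if (Ns[i] == 0) continue;
      const double n_prey = (i == 0) ? R_avail : (double)Ns[i - 1];
      const double hn = par(i, 3) * n_prey;
      // producers encounter resource units at graze_scale * attack
      const double ascale = (i == 0) ? graze_scale : 1.0;
      long double acc = 0.0;
      for (int j = 0; j < Ns[i]; ++j) {
        const double a = ascale * pops[i].attack[j];
        const double v = a / (1.0 + hn * a);
        fr[i][j] = v;
        acc += v;
      }
      mfr[i] = (double)(acc / Ns[i]);
    }

    // realized harvest effort
    double eff = 0.0;
    int hl = 0; // 1-based level, 0 = none
    if (harvest_level > 0 && t >= onset) {
      hl = harvest_level;
      // R's rnorm consumes no draw when sd == 0; mirror that
      const double s_f = f_error_cv * f;
      const double eps_f = s_f > 0 ? norm_rand() * s_f : 0.0;
      eff = clamp01(f + eps_f);
    }

    // deaths, predation accounting, yield (Bernoulli per individual)
    std::vector<int> deaths(nl, 0);
    std::vector<double> n_eaten(nl, 0.0), yield(nl, 0.0);
    for (int i = 0; i < nl; ++i) {
      dead[i].assign(Ns[i], 0);
      if (Ns[i] == 0) continue;
      const bool has_pred = (i + 1 < nl) && (Ns[i + 1] > 0);
      const double pred_pressure =
          has_pred ? mfr[i + 1] * (double)Ns[i + 1] : 0.0;
      dP[i].assign(Ns[i], 0.0);
      Dtot[i].assign(Ns[i], 0.0);
      const double hfac = (i + 1 == hl) ? (1.0 - eff) : 1.0;
      long double acc_ne = 0.0, acc_y = 0.0;
      for (int j = 0; j < Ns[i]; ++j) {
        double dp = has_pred ? pred_pressure * pops[i].vuln[j] : 0.0;
        if (dp > 1.0) dp = 1.0;
        dP[i][j] = dp;
        const double D = 1.0 - (1.0 - pops[i].death[j]) * (1.0 - dp) * hfac;
        Dtot[i][j] = D;
        const bool die = unif_rand() < D;
        if (die) {
          dead[i][j] = 1;
          ++deaths[i];
          if (has_pred) acc_ne += dp / D;
          if (i + 1 == hl && eff > 0) acc_y += eff / D;
        }
      }
      n_eaten[i] = (double)acc_ne;
      yield[i] = (double)acc_y;
    }

    // producers graze the replenished pool
    double consumed = 0.0;
    if (Ns[0] > 0) {
      double g = mfr[0] * (double)Ns[0];
      if (g > 1.0) g = 1.0;
      consumed = g * R_avail;
    }

    // births, inheritance with mutation, phenotype noise, population update
    std::vector<int> births(nl, 0);
    std::vector<double> gen_sum(nl, 0.0);
    std::vector<int> gen_n(nl, 0);
    std::vector<double> mean_G(nl, NA_REAL), sd_G(nl, NA_REAL);
    for (int i = 0; i < nl; ++i) {
      if (Ns[i] == 0) continue;
      const double prey_eaten = (i == 0) ? consumed : n_eaten[i - 1];
      std::vector<int> counts(Ns[i], 0);
      int nb = 0;
      if (prey_eaten > 0) {
        if (mfr[i] == 0)
          stop("inconsistent state: prey eaten but mean functional response is 0");
        const double scale = par(i, 2) * prey_eaten / (mfr[i] * Ns[i]);
        for (int j = 0; j < Ns[i]; ++j) {
          counts[j] = (int)R::rpois(fr[i][j] * scale);
          nb += counts[j];
        }
      }

      Pop off;
      if (nb > 0) {
        off.G.reserve(nb);
        off.pbirth.reserve(nb);
        std::vector<double> pG(nb);
        long double acc_pb = 0.0;
        int m = 0;
        for (int j = 0; j < Ns[i]; ++j) {
          for (int c = 0; c < counts[j]; ++c) {
            pG[m] = pops[i].G[j];
            off.pbirth.push_back(pops[i].birth[j]);
            acc_pb += pops[i].birth[j];
            ++m;
          }
        }
        if (ISNA(frozen[i])) {
          // mutation: all uniforms first, then normals for mutants only
          std::vector<int> mut(nb, 0);
          for (int j = 0; j < nb; ++j) mut[j] = unif_rand() < mut_prob;
          if (mut_sd > 0) {
            for (int j = 0; j < nb; ++j) {
              if (mut[j]) pG[j] += norm_rand() * mut_sd;
            }
          }
          off.G = pG;
        } else {
          off.G.assign(nb, frozen[i]);
        }
        // phenotypes with fresh environmental noise, trait by trait
        const double cv = par(i, 8);
        const double a0 = par(i, 0), v0 = par(i, 1), d0 = par(i, 4);
        const double A = par(i, 5), V = par(i, 6), M = par(i, 7);
        std::vector<double> ea(nb, 0.0), ev(nb, 0.0), ed(nb, 0.0);
        if (cv * a0 > 0)
          for (int j = 0; j < nb; ++j) ea[j] = norm_rand() * (cv * a0);
        if (cv * v0 > 0)
          for (int j = 0; j < nb; ++j) ev[j] = norm_rand() * (cv * v0);
        if (cv * d0 > 0)
          for (int j = 0; j < nb; ++j) ed[j] = norm_rand() * (cv * d0);
        off.attack.resize(nb);
        off.vuln.resize(nb);
        off.death.resize(nb);
        off.birth.assign(nb, (double)(t + 1));
        for (int j = 0; j < nb; ++j) {
          const double G = off.G[j];
          double a = (a0 + ea[j]) * (1.0 + A * G / 100.0);
          double v = (v0 + ev[j]) * (1.0 + V * G / 100.0);
          double d = (d0 + ed[j]) * (1.0 + M * G * G / 100.0);
          off.attack[j] = a < 0 ? 0 : a;
          off.vuln[j] = v < 0 ? 0 : v;
          off.death[j] = clamp01(d);
        }
        gen_sum[i] = (double)((long double)nb * t - acc_pb);
        gen_n[i] = nb;
      }
      births[i] = nb;

      // survivors then offspring
      Pop np;
      const int nsurv = Ns[i] - deaths[i];
      const int ntot = nsurv + nb;
      np.G.reserve(ntot);
      np.attack.reserve(ntot);
      np.vuln.reserve(ntot);
      np.death.reserve(ntot);
      np.birth.reserve(ntot);
      np.pbirth.reserve(ntot);
      for (int j = 0; j < Ns[i]; ++j) {
        if (!dead[i][j]) {
          np.G.push_back(pops[i].G[j]);
          np.attack.push_back(pops[i].attack[j]);
          np.vuln.push_back(pops[i].vuln[j]);
          np.death.push_back(pops[i].death[j]);
          np.birth.push_back(pops[i].birth[j]);
          np.pbirth.push_back(pops[i].pbirth[j]);
        }
      }
      for (int j = 0; j < nb; ++j) {
        np.G.push_back(off.G[j]);
        np.attack.push_back(off.attack[j]);
        np.vuln.push_back(off.vuln[j]);
        np.death.push_back(off.death[j]);
        np.birth.push_back(off.birth[j]);
        np.pbirth.push_back(off.pbirth[j]);
      }
      pops[i] = std::move(np);

      const int ni = (int)pops[i].size();
      if (ni > 0) {
        long double s = 0.0;
        for (int j = 0; j < ni; ++j) s += pops[i].G[j];
        const double m = (double)(s / ni);
        mean_G[i] = m;
        if (ni > 1) {
          long double ss = 0.0;
          for (int j = 0; j < ni; ++j) {
            const double dG = pops[i].G[j] - m;
            ss += dG * dG;
          }
          sd_G[i] = std::sqrt((double)(ss / (ni - 1)));
        } else {
          sd_G[i] = 0.0;
        }
      }
    }

    R = R_avail - consumed;
    if (R < 0) R = 0;
    if (R > R_max) R = R_max;
    ++t;

    for (int i = 0; i < nl; ++i) {
      rec_ab(k, i) = Ns[i] + births[i] - deaths[i];
      rec_bi(k, i) = births[i];
      rec_de(k, i) = deaths[i];
      rec_ne(k, i) = n_eaten[i];
      rec_yi(k, i) = yield[i];
      rec_mg(k, i) = mean_G[i];
      rec_sg(k, i) = sd_G[i];
      rec_gs(k, i) = gen_sum[i];
      rec_gn(k, i) = gen_n[i];
    }
    rec_res[k] = R;
    rec_it[k] = t;

    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List pops_out(nl);
  for (int i = 0; i < nl; ++i) {
    pops_out[i] = List::create(
        _["G"] = NumericVector(pops[i].G.begin(), pops[i].G.end()),
        _["attack"] = NumericVector(pops[i].attack.begin(), pops[i].attack.end()),
        _["vuln"] = NumericVector(pops[i].vuln.begin(), pops[i].vuln.end()),
        _["death"] = NumericVector(pops[i].death.begin(), pops[i].death.end()),
        _["birth"] = NumericVector(pops[i].birth.begin(), pops[i].birth.end()),
        _["parent_birth"] =
            NumericVector(pops[i].pbirth.begin(), pops[i].pbirth.end()));
  }
  return List::create(
      _["pops"] = pops_out, _["resource"] = R, _["t"] = t,
      _["abundance"] = rec_ab, _["births"] = rec_bi, _["deaths"] = rec_de,
      _["n_eaten"] = rec_ne, _["yield"] = rec_yi, _["mean_G"] = rec_mg,
      _["sd_G"] = rec_sg, _["gen_sum"] = rec_gs, _["gen_n"] = rec_gn,
      _["res_vec"] = rec_res, _["it_vec"] = rec_it);
}
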