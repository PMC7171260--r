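#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo over protonation microstates, one independent
// chain per pH value. Uses R's RNG so set.seed() on the R side makes runs
// reproducible. One sweep = n single-site flip attempts plus n/2 pair-flip
// attempts over the supplied strongly coupled pairs.
//
// Energy: E(x) = ln10 * RT * sum_i x_i (pH - pKa_i)
//               + sum_{i<j} W(i,j) q_i q_j,  q_i = qd_i + x_i.

static inline int rand_int(int n) {
  int k;
  do { k = (int)(unif_rand() * n); } while (k >= n);
  return k;
}

// [[Rcpp::export]]
List mc_titrate_cpp(NumericVector pka, NumericVector qd, NumericMatrix W,
                    NumericVector ph_grid, int sweeps, int burn_in,
                    double rt, IntegerMatrix pairs) {
  const int n = pka.size();
  const int np = ph_grid.size();
  const int npair = pairs.nrow();
  const double ln10rt = M_LN10 * rt;

  NumericMatrix mean_prot(n, np);
  NumericVector mean_charge(np), mean_eint(np);

  std::vector<double> q(n), field(n);
  std::vector<int> x(n);

  GetRNGstate();
  for (int p = 0; p < np; ++p) {
    const double ph = ph_grid[p];

    // deterministic start: protonated below the model pKa
    for (int i = 0; i < n; ++i) {
      x[i] = (ph < pka[i]) ? 1 : 0;
      q[i] = qd[i] + x[i];
    }
    // field[i] = sum_{j != i} W(i,j) q_j ; eint = interaction energy
    double eint = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      for (int j = 0; j < n; ++j) if (j != i) f += W(i, j) * q[j];
      field[i] = f;
      eint += 0.5 * f * q[i];
    }

    std::vector<double> sum_x(n, 0.0);
    double sum_q = 0.0, sum_e = 0.0;

    const int total = burn_in + sweeps;
    const int npair_att = n / 2;
    for (int sw = 0; sw < total; ++sw) {
      for (int a = 0; a < n; ++a) {
        const int i = rand_int(n);
        const double s = x[i] ? -1.0 : 1.0;  // change in x_i (and q_i)
        const double dE = s * (ln10rt * (ph - pka[i]) + field[i]);
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) {
          x[i] += (int)s;
          q[i] += s;
          eint += s * field[i];
          for (int j = 0; j < n; ++j) if (j != i) field[j] += s * W(i, j);
        }
      }
      if (npair > 0) {
        for (int a = 0; a < npair_att; ++a) {
          const int k = rand_int(npair);
          const int i = pairs(k, 0), j = pairs(k, 1);
          const double si = x[i] ? -1.0 : 1.0;
          const double sj = x[j] ? -1.0 : 1.0;
          const double dE = si * (ln10rt * (ph - pka[i]) + field[i]) +
                            sj * (ln10rt * (ph - pka[j]) + field[j]) +
                            si * sj * W(i, j);
          if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) {
            x[i] += (int)si; q[i] += si;
            x[j] += (int)sj; q[j] += sj;
            eint += si * field[i] + sj * field[j] + si * sj * W(i, j);
            for (int m = 0; m < n; ++m) {
              if (m != i) field[m] += si * W(i, m);
              if (m != j) field[m] += sj * W(j, m);
            }
          }
        }
      }
      if (sw >= burn_in) {
        for (int i = 0; i < n; ++i) sum_x[i] += x[i];
        double qt = 0.0;
        for (int i = 0; i < n; ++i) qt += q[i];
        sum_q += qt;
        sum_e += eint;
      }
    }
    for (int i = 0; i < n; ++i) mean_prot(i, p) = sum_x[i] / sweeps;
    mean_charge[p] = sum_q / sweeps;
    mean_eint[p] = sum_e / sweeps;
  }
  PutRNGstate();

  return List::create(_["mean_protonation"] = mean_prot,
                      _["mean_charge"] = mean_charge,
                      _["mean_interaction_energy"] = mean_eint);
}
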