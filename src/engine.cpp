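// Compiled core of the coevolution simulator: forward-Euler integration of
// the within-host signaling ODEs and the full generational loop. All
// randomness flows through R's RNG so runs are reproducible from set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Species order in the state vector: 0=P, 1=R, 2=A, 3=I, 4=U, 5=D.
// Edge order (target, source), matching edge_names() on the R side:
//   0 (R,P)  1 (A,R)  2 (I,A)  3 (U,A)  4 (D,A)  5 (R,U)  6 (I,D)  7 (P,I)
// phi is indexed by host protein: 0=R, 1=A, 2=I, 3=U, 4=D.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Euler-integrate one individual; accumulate lifetime sums of P and I over
// the stored grid (t = 0 included). traj, when non-null, receives the state
// at every grid point in column-major (steps+1) x 6 layout.
static void integrate_one(const double* mu, const double* phi, double pi_rate,
                          double P0, int steps, double dt, bool force_inh,
                          double* P_bar, double* I_bar, double* traj) {
  double mp[8], mn[8];
  for (int e = 0; e < 8; ++e) {
    mp[e] = mu[e] > 0.0 ? mu[e] : 0.0;
    mn[e] = mu[e] < 0.0 ? mu[e] : 0.0;
  }
  const double muPI = force_inh ? std::fabs(mu[7]) : mu[7];
  double y0 = P0, y1 = 0.0, y2 = 0.0, y3 = 0.0, y4 = 0.0, y5 = 0.0;
  long double sp = y0, si = y3;
  const int rows = steps + 1;
  if (traj) {
    traj[0] = y0; traj[rows] = y1; traj[2 * rows] = y2;
    traj[3 * rows] = y3; traj[4 * rows] = y4; traj[5 * rows] = y5;
  }
  for (int t = 1; t <= steps; ++t) {
    const double d0 = -muPI * y3 * y0 + pi_rate * y0 * (1.0 - y0);
    const double d1 = -phi[0] * y1 + mp[0] * y0 * (1.0 - y1) + mn[0] * y0 * y1
                                   + mp[5] * y4 * (1.0 - y1) + mn[5] * y4 * y1;
    const double d2 = -phi[1] * y2 + mp[1] * y1 * (1.0 - y2) + mn[1] * y1 * y2;
    const double d3 = -phi[2] * y3 + mp[2] * y2 * (1.0 - y3) + mn[2] * y2 * y3
                                   + mp[6] * y5 * (1.0 - y3) + mn[6] * y5 * y3;
    const double d4 = -phi[3] * y4 + mp[3] * y2 * (1.0 - y4) + mn[3] * y2 * y4;
    const double d5 = -phi[4] * y5 + mp[4] * y2 * (1.0 - y5) + mn[4] * y2 * y5;
    y0 = clamp01(y0 + dt * d0);
    y1 = clamp01(y1 + dt * d1);
    y2 = clamp01(y2 + dt * d2);
    y3 = clamp01(y3 + dt * d3);
    y4 = clamp01(y4 + dt * d4);
    y5 = clamp01(y5 + dt * d5);
    sp += y0; si += y3;
    if (traj) {
      traj[t] = y0; traj[rows + t] = y1; traj[2 * rows + t] = y2;
      traj[3 * rows + t] = y3; traj[4 * rows + t] = y4; traj[5 * rows + t] = y5;
    }
  }
  // lifetime average: dt * (grid sum) / T = (grid sum) / steps
  *P_bar = (double)(sp / (long double)steps);
  *I_bar = (double)(si / (long double)steps);
}

// [[Rcpp::export]]
List cpp_integrate_batch(NumericMatrix mu, NumericVector phi, double pi_rate,
                         double P0, int steps, double dt, bool infected,
                         bool force_inh, bool store) {
  const int m = mu.nrow();
  if (mu.ncol() != 8) stop("mu matrix must have 8 columns");
  NumericVector P_bar(m), I_bar(m);
  List trajs(store ? m : 0);
  std::vector<double> mui(8);
  for (int i = 0; i < m; ++i) {
    for (int e = 0; e < 8; ++e) mui[e] = mu(i, e);
    if (!infected) {
      P_bar[i] = 0.0; I_bar[i] = 0.0;
      if (store) trajs[i] = NumericMatrix(steps + 1, 6);
      continue;
    }
    if (store) {
      NumericMatrix Y(steps + 1, 6);
      integrate_one(mui.data(), phi.begin(), pi_rate, P0, steps, dt,
                    force_inh, &P_bar[i], &I_bar[i], Y.begin());
      trajs[i] = Y;
    } else {
      integrate_one(mui.data(), phi.begin(), pi_rate, P0, steps, dt,
                    force_inh, &P_bar[i], &I_bar[i], nullptr);
    }
  }
  List out = List::create(_["P_bar"] = P_bar, _["I_bar"] = I_bar);
  if (store) out["trajectories"] = trajs;
  return out;
}

static inline int rand_int(int k) {
  int j = (int)(k * R::unif_rand());
  return j >= k ? k - 1 : j;
}

// Fitness-proportional draw from a prepared cumulative-sum vector.
static inline int draw_cum(const std::vector<double>& cum) {
  const double u = cum.back() * R::unif_rand();
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// mu = 1 - 2H/L between a sender slice and a receiver slice of two bit rows.
static inline double mu_from_bits(const int* send, int send_stride,
                                  const int* recv, int recv_stride,
                                  int L) {
  int H = 0;
  for (int s = 0; s < L; ++s) {
    H += (send[(size_t)s * send_stride] != recv[(size_t)s * recv_stride]);
  }
  return 1.0 - 2.0 * (double)H / (double)L;
}

// [[Rcpp::export]]
List cpp_run_engine(IntegerMatrix hosts0, IntegerMatrix paths0, int L,
                    int generations, double theta, double alpha, double beta,
                    double MH, double MP, NumericVector phi, double pi_rate,
                    double P0, int steps, double dt, bool force_inh,
                    NumericVector overrides, int sample_interval) {
  const int n = hosts0.nrow();
  const int hcols = 15 * L, pcols = 3 * L;
  if (paths0.nrow() != n) stop("host and pathogen populations must have equal size");
  if (hosts0.ncol() != hcols || paths0.ncol() != pcols) stop("bit layout mismatch");

  // column offsets (0-based): host protein p, domain d -> (p*3 + d) * L
  // host proteins 0=R,1=A,2=I,3=U,4=D; domains 0=receiver,1=neutral,2=sender
  const int edge_src_prot[8] = {-1, 0, 1, 1, 1, 3, 4, 2}; // -1 = pathogen
  const int edge_tgt_prot[8] = {0, 1, 2, 3, 4, 0, 2, -1};

  std::vector<int> H(hosts0.begin(), hosts0.end());   // column-major, stride n
  std::vector<int> P(paths0.begin(), paths0.end());
  std::vector<int> Hnew(H.size()), Pnew(P.size());

  const int n_samples = 1 + (sample_interval > 0 ? generations / sample_interval : 0);
  NumericMatrix records(generations, 13);
  NumericMatrix host_cons(n_samples, hcols), path_cons(n_samples, pcols);
  IntegerVector sample_gens(n_samples);

  auto take_consensus = [&](int row, int gen) {
    for (int c = 0; c < hcols; ++c) {
      long double s = 0;
      const int* col = &H[(size_t)c * n];
      for (int i = 0; i < n; ++i) s += col[i];
      host_cons(row, c) = (double)(s / n);
    }
    for (int c = 0; c < pcols; ++c) {
      long double s = 0;
      const int* col = &P[(size_t)c * n];
      for (int i = 0; i < n; ++i) s += col[i];
      path_cons(row, c) = (double)(s / n);
    }
    sample_gens[row] = gen;
  };
  take_consensus(0, 0);
  int srow = 0;

  std::vector<int> perm(n);
  std::vector<char> infected(n);
  std::vector<double> mu(8 * (size_t)n);      // per-host coefficients, row i at mu[8i]
  std::vector<double> Pb(n), Ib(n), fit_h(n), fit_p(n), cum(n);
  std::vector<double> phiv(phi.begin(), phi.end());
  bool has_ov[8];
  double ov[8];
  for (int e = 0; e < 8; ++e) {
    has_ov[e] = !NumericVector::is_na(overrides[e]);
    ov[e] = has_ov[e] ? overrides[e] : 0.0;
  }

  for (int g = 1; g <= generations; ++g) {
    // random one-to-one pairing, then thin by theta
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rand_int(i + 1)]);
    int n_inf = 0;
    for (int i = 0; i < n; ++i) {
      infected[i] = theta >= 1.0 ? 1 : (theta <= 0.0 ? 0 : (R::unif_rand() < theta));
      n_inf += infected[i];
    }

    // interaction coefficients per host (pairing edges use the partner)
    for (int i = 0; i < n; ++i) {
      const int pj = perm[i];
      double* mui = &mu[8 * (size_t)i];
      for (int e = 0; e < 8; ++e) {
        if (has_ov[e]) { mui[e] = ov[e]; continue; }
        const int sp = edge_src_prot[e], tp = edge_tgt_prot[e];
        const int* send = (sp < 0)
          ? &P[(size_t)(2 * L) * n + pj]                      // pathogen sender
          : &H[(size_t)((sp * 3 + 2) * L) * n + i];           // host sender
        const int* recv = (tp < 0)
          ? &P[(size_t)(0 * L) * n + pj]                      // pathogen receiver
          : &H[(size_t)((tp * 3 + 0) * L) * n + i];           // host receiver
        mui[e] = mu_from_bits(send, n, recv, n, L);
      }
    }

    // within-host dynamics and fitnesses
    for (int i = 0; i < n; ++i) {
      if (infected[i]) {
        integrate_one(&mu[8 * (size_t)i], phiv.data(), pi_rate, P0, steps, dt,
                      force_inh, &Pb[i], &Ib[i], nullptr);
        fit_h[i] = std::exp(-(alpha * Pb[i] + beta * Ib[i]));
      } else {
        Pb[i] = 0.0; Ib[i] = 0.0; fit_h[i] = 1.0;
      }
    }
    std::fill(fit_p.begin(), fit_p.end(), 0.0);
    for (int i = 0; i < n; ++i) if (infected[i]) fit_p[perm[i]] = Pb[i];

    // per-generation record
    {
      long double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      long double fh = 0, fp = 0, pb = 0, ib = 0;
      for (int i = 0; i < n; ++i) {
        const double* mui = &mu[8 * (size_t)i];
        for (int e = 0; e < 8; ++e) {
          const bool pairing = (e == 0 || e == 7);
          if (!pairing) acc[e] += mui[e];
          else if (infected[i]) acc[e] += mui[e];
        }
        fh += fit_h[i]; fp += fit_p[i]; pb += Pb[i]; ib += Ib[i];
      }
      for (int e = 0; e < 8; ++e) {
        const bool pairing = (e == 0 || e == 7);
        const int denom = pairing ? n_inf : n;
        records(g - 1, e) = denom > 0 ? (double)(acc[e] / denom) : NA_REAL;
      }
      records(g - 1, 8) = (double)(fh / n);
      records(g - 1, 9) = (double)(fp / n);
      records(g - 1, 10) = (double)n_inf / n;
      records(g - 1, 11) = (double)(pb / n);
      records(g - 1, 12) = (double)(ib / n);
    }

    // host reproduction: sexual, two distinct fitness-proportional parents
    {
      double total = 0.0;
      int n_pos = 0;
      for (int i = 0; i < n; ++i) {
        total += fit_h[i];
        cum[i] = total;
        if (fit_h[i] > 0.0) ++n_pos;
      }
      if (n_pos < 2)
        stop("degenerate host population at generation %d: fewer than two viable parents", g);
      for (int i = 0; i < n; ++i) {
        const int pa = draw_cum(cum);
        int pb2 = draw_cum(cum), tries = 0;
        while (pb2 == pa) {
          if (++tries > 10000) stop("could not draw two distinct host parents");
          pb2 = draw_cum(cum);
        }
        // one crossover per protein: domain rd, cut in 1..L-1 (1-based);
        // sites < cut from parent1, >= cut from parent2; the two other
        // domains each come whole from a random parent
        for (int p = 0; p < 5; ++p) {
          const int rd = rand_int(3);
          for (int d = 0; d < 3; ++d) {
            const size_t base = (size_t)((p * 3 + d) * L) * n;
            if (d == rd) {
              const int cut = 1 + rand_int(L - 1);
              for (int s = 0; s < L; ++s) {
                const int from = (s + 1) < cut ? pa : pb2;
                Hnew[base + (size_t)s * n + i] = H[base + (size_t)s * n + from];
              }
            } else {
              const int from = rand_int(2) ? pb2 : pa;
              for (int s = 0; s < L; ++s)
                Hnew[base + (size_t)s * n + i] = H[base + (size_t)s * n + from];
            }
          }
        }
        if (MH > 0.0 && R::unif_rand() < MH) {
          const int c = rand_int(hcols);
          int& b = Hnew[(size_t)c * n + i];
          b = 1 - b;
        }
      }
    }

    // pathogen reproduction: asexual, fitness-proportional; if nothing
    // infected this generation every fitness is 0 and parents are drawn
    // uniformly (neutral drift)
    {
      double total = 0.0;
      for (int i = 0; i < n; ++i) { total += fit_p[i]; cum[i] = total; }
      for (int i = 0; i < n; ++i) {
        const int pa = total > 0.0 ? draw_cum(cum) : rand_int(n);
        for (int c = 0; c < pcols; ++c)
          Pnew[(size_t)c * n + i] = P[(size_t)c * n + pa];
        if (MP > 0.0 && R::unif_rand() < MP) {
          const int c = rand_int(pcols);
          int& b = Pnew[(size_t)c * n + i];
          b = 1 - b;
        }
      }
    }

    H.swap(Hnew);
    P.swap(Pnew);

    if (sample_interval > 0 && g % sample_interval == 0) take_consensus(++srow, g);
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix hosts_out(n, hcols), paths_out(n, pcols);
  std::copy(H.begin(), H.end(), hosts_out.begin());
  std::copy(P.begin(), P.end(), paths_out.begin());

  return List::create(
    _["records"] = records,
    _["host_consensus"] = host_cons,
    _["path_consensus"] = path_cons,
    _["sample_generations"] = sample_gens,
    _["hosts"] = hosts_out,
    _["pathogens"] = paths_out
  );
}
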