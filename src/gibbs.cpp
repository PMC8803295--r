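#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the genotype-frequency-class mixture model.
//
// Latent structure: per-individual class z_i (mixing proportions pi with a
// symmetric Dirichlet prior), per individual-locus ancestry state
// w_il in {2,1,0} A-copies with P(w | z) = phi_z, per-gene-copy pool-origin
// indicators, and per-pool per-locus allele frequencies thetaA/thetaB with
// symmetric Dirichlet priors. z is updated with w collapsed. Missing calls
// (a1 == 0) are skipped in every likelihood.
//
// Alleles are recoded 1..K[l] per locus; matrices are ragged over a Kmax
// width. All randomness flows through R's RNG so set.seed() governs runs.

static inline double genolik(int w, int a, int b, int l,
                             const NumericMatrix &thA,
                             const NumericMatrix &thB) {
  const double fa_A = thA(l, a - 1), fb_A = thA(l, b - 1);
  const double fa_B = thB(l, a - 1), fb_B = thB(l, b - 1);
  if (w == 2) return (a == b) ? fa_A * fa_A : 2.0 * fa_A * fb_A;
  if (w == 0) return (a == b) ? fa_B * fa_B : 2.0 * fa_B * fb_B;
  return (a == b) ? fa_A * fa_B : fa_A * fb_B + fb_A * fa_B;
}

static int sample_index(const std::vector<double> &p) {
  double tot = 0.0;
  for (double v : p) tot += v;
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t k = 0; k < p.size(); ++k) {
    acc += p[k];
    if (u <= acc) return (int)k;
  }
  return (int)p.size() - 1;
}

// [[Rcpp::export(name = ".gibbs_classify")]]
List gibbs_classify(IntegerMatrix A1, IntegerMatrix A2, IntegerVector K,
                    NumericMatrix phi, IntegerVector zfix,
                    NumericMatrix thetaA0, NumericMatrix thetaB0,
                    int iterations, int burnin, int thin,
                    double theta_prior, double pi_prior) {
  const int N = A1.nrow(), L = A1.ncol(), C = phi.nrow();
  const int Kmax = thetaA0.ncol();

  NumericMatrix thA = clone(thetaA0), thB = clone(thetaB0);
  std::vector<double> pi(C, 1.0 / C);
  std::vector<int> z(N);
  for (int i = 0; i < N; ++i)
    z[i] = zfix[i] > 0 ? zfix[i] - 1 : (int)(unif_rand() * C) % C;

  NumericMatrix post(N, C);
  NumericMatrix thA_mean(L, Kmax), thB_mean(L, Kmax);
  std::vector<double> ll_trace;
  // per (i,l) state likelihoods for the current theta: w = 2, 1, 0
  std::vector<double> p2(N * L), p1(N * L), p0(N * L);
  NumericMatrix cntA(L, Kmax), cntB(L, Kmax);
  std::vector<double> clsw(C), nz(C);
  int kept = 0;

  for (int it = 0; it < iterations; ++it) {
    // cache genotype likelihoods under each ancestry state
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l) {
        int a = A1(i, l), b = A2(i, l);
        if (a == 0) continue;
        p2[i * L + l] = genolik(2, a, b, l, thA, thB);
        p1[i * L + l] = genolik(1, a, b, l, thA, thB);
        p0[i * L + l] = genolik(0, a, b, l, thA, thB);
      }

    // z | theta, pi (w collapsed)
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      double mx = -1e308;
      for (int c = 0; c < C; ++c) {
        double lp = std::log(pi[c]);
        for (int l = 0; l < L; ++l) {
          if (A1(i, l) == 0) continue;
          double m = phi(c, 0) * p2[i * L + l] + phi(c, 1) * p1[i * L + l] +
                     phi(c, 2) * p0[i * L + l];
          lp += std::log(m > 1e-300 ? m : 1e-300);
        }
        clsw[c] = lp;
        if (lp > mx) mx = lp;
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { clsw[c] = std::exp(clsw[c] - mx); tot += clsw[c]; }
      ll += mx + std::log(tot);
      if (zfix[i] == 0) z[i] = sample_index(clsw);
      else z[i] = zfix[i] - 1;
      if (it >= burnin) post(i, z[i]) += 1.0;
    }

    // w and pool-origin indicators | z, theta -> allele counts per pool
    std::fill(cntA.begin(), cntA.end(), 0.0);
    std::fill(cntB.begin(), cntB.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const int c = z[i];
      for (int l = 0; l < L; ++l) {
        int a = A1(i, l), b = A2(i, l);
        if (a == 0) continue;
        std::vector<double> pw = {phi(c, 0) * p2[i * L + l],
                                  phi(c, 1) * p1[i * L + l],
                                  phi(c, 2) * p0[i * L + l]};
        int w = 2 - sample_index(pw);  // index 0 -> w=2, 1 -> w=1, 2 -> w=0
        if (w == 2) { cntA(l, a - 1) += 1; cntA(l, b - 1) += 1; }
        else if (w == 0) { cntB(l, a - 1) += 1; cntB(l, b - 1) += 1; }
        else if (a == b) { cntA(l, a - 1) += 1; cntB(l, a - 1) += 1; }
        else {
          double pa = thA(l, a - 1) * thB(l, b - 1);
          double pb = thA(l, b - 1) * thB(l, a - 1);
          if (unif_rand() * (pa + pb) <= pa) { cntA(l, a - 1) += 1; cntB(l, b - 1) += 1; }
          else { cntA(l, b - 1) += 1; cntB(l, a - 1) += 1; }
        }
      }
    }

    // theta | counts : Dirichlet(theta_prior + count) via gamma draws
    for (int l = 0; l < L; ++l) {
      double sa = 0.0, sb = 0.0;
      for (int k = 0; k < K[l]; ++k) {
        thA(l, k) = R::rgamma(theta_prior + cntA(l, k), 1.0);
        thB(l, k) = R::rgamma(theta_prior + cntB(l, k), 1.0);
        sa += thA(l, k); sb += thB(l, k);
      }
      for (int k = 0; k < K[l]; ++k) { thA(l, k) /= sa; thB(l, k) /= sb; }
    }

    // pi | z over free individuals
    std::fill(nz.begin(), nz.end(), 0.0);
    for (int i = 0; i < N; ++i) if (zfix[i] == 0) nz[z[i]] += 1.0;
    double sp = 0.0;
    for (int c = 0; c < C; ++c) { pi[c] = R::rgamma(pi_prior + nz[c], 1.0); sp += pi[c]; }
    for (int c = 0; c < C; ++c) pi[c] /= sp;

    if (it % thin == 0) ll_trace.push_back(ll);
    if (it >= burnin) {
      ++kept;
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < Kmax; ++k) {
          thA_mean(l, k) += thA(l, k);
          thB_mean(l, k) += thB(l, k);
        }
    }
  }

  const double denom = kept > 0 ? (double)kept : 1.0;
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) post(i, c) /= denom;
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < Kmax; ++k) {
      thA_mean(l, k) /= denom;
      thB_mean(l, k) /= denom;
    }

  return List::create(_["posterior"] = post,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["theta_A"] = thA_mean, _["theta_B"] = thB_mean,
                      _["kept"] = kept);
}
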