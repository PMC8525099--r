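// Multistate CJS hidden-Markov computations.
//
// Latent state space per bear-year: 1..5 alive (spatial states, 5 =
// "Elsewhere"), 6 dead (absorbing).  Everything conditions on the first
// observation.  Observation model: a bear alive in state n in year t is
// detected with probability rho(n, t) for n in 1..4 and never for n = 5 or
// dead.  Survival phi depends on sex, age class, and year; transitions tau
// on origin/destination state only.

#include <Rcpp.h>
using namespace Rcpp;

static inline double phi_at(const NumericVector& phi, int s, int c, int t) {
  // phi dims: 2 (sex, 0=M) x 7 (age class) x (K-1) (year index)
  return phi[s + 2 * c + 14 * t];
}

// One transition + observation step for bear b from occasion t-1 to t.
// a[0..5] is the (scaled) forward vector at t-1; writes the updated vector
// into anew.  Returns the observation weight application only; scaling is
// handled by the caller.
static void forward_step(const IntegerMatrix& enc, const IntegerMatrix& acl,
                         const NumericVector& phi, const NumericMatrix& tau,
                         const NumericMatrix& rho, int b, int sex, int t,
                         const double* a, double* anew) {
  int c = acl(b, t - 1) - 1;
  double ph = phi_at(phi, sex, c, t - 1);
  for (int n = 0; n < 5; ++n) {
    double acc = 0.0;
    for (int m = 0; m < 5; ++m) acc += a[m] * tau(m, n);
    anew[n] = ph * acc;
  }
  double dead = a[5];
  for (int m = 0; m < 5; ++m) dead += a[m] * (1.0 - ph);
  anew[5] = dead;
  int o = enc(b, t);
  if (o >= 1) {            // observed in spatial state o
    double keep = anew[o - 1] * rho(o - 1, t);
    for (int n = 0; n < 6; ++n) anew[n] = 0.0;
    anew[o - 1] = keep;
  } else {                 // not observed
    for (int n = 0; n < 4; ++n) anew[n] *= (1.0 - rho(n, t));
    // state 5 and dead: unobserved with probability 1
  }
}

// [[Rcpp::export]]
NumericVector cpp_cjs_loglik(IntegerMatrix enc, IntegerVector first,
                             IntegerVector sexi, IntegerMatrix acl,
                             NumericVector phi, NumericMatrix tau,
                             NumericMatrix rho) {
  int n_bear = enc.nrow(), K = enc.ncol();
  NumericVector out(n_bear);
  double a[6], anew[6];
  for (int b = 0; b < n_bear; ++b) {
    int f = first[b] - 1;
    int sex = sexi[b] - 1;
    for (int s = 0; s < 6; ++s) a[s] = 0.0;
    a[enc(b, f) - 1] = 1.0;   // condition on the first observation
    double ll = 0.0;
    for (int t = f + 1; t < K; ++t) {
      forward_step(enc, acl, phi, tau, rho, b, sex, t, a, anew);
      double tot = 0.0;
      for (int s = 0; s < 6; ++s) tot += anew[s];
      if (tot <= 0.0) { ll = R_NegInf; break; }
      for (int s = 0; s < 6; ++s) a[s] = anew[s] / tot;
      ll += std::log(tot);
    }
    out[b] = ll;
  }
  return out;
}

// Weighted total log-likelihood over deduplicated bear profiles.  Matrices
// are transposed (K x n) so each profile's sweep reads contiguous memory;
// weight[b] counts the bears sharing profile b.
// [[Rcpp::export]]
double cpp_cjs_loglik_wt(IntegerMatrix enc_t, IntegerVector first,
                         IntegerVector sexi, IntegerMatrix acl_t,
                         NumericVector phi, NumericMatrix tau,
                         NumericMatrix rho, NumericVector weight) {
  int K = enc_t.nrow(), n_prof = enc_t.ncol();
  const int* encp = INTEGER(enc_t);
  const int* aclp = INTEGER(acl_t);
  const double* phip = REAL(phi);
  const double* taup = REAL(tau);   // 5 x 5 column-major
  const double* rhop = REAL(rho);   // 4 x K column-major
  double total = 0.0;
  double a[6], anew[6];
  for (int b = 0; b < n_prof; ++b) {
    const int* e = encp + (size_t)K * b;
    const int* ac = aclp + (size_t)K * b;
    int f = first[b] - 1;
    int sex = sexi[b] - 1;
    for (int s = 0; s < 6; ++s) a[s] = 0.0;
    a[e[f] - 1] = 1.0;
    double ll = 0.0;
    for (int t = f + 1; t < K; ++t) {
      double ph = phip[sex + 2 * (ac[t - 1] - 1) + 14 * (t - 1)];
      for (int n = 0; n < 5; ++n) {
        double acc = 0.0;
        const double* tcol = taup + 5 * n;
        for (int m = 0; m < 5; ++m) acc += a[m] * tcol[m];
        anew[n] = ph * acc;
      }
      double dead = a[5];
      for (int m = 0; m < 5; ++m) dead += a[m] * (1.0 - ph);
      anew[5] = dead;
      const double* rcol = rhop + 4 * t;
      int o = e[t];
      if (o >= 1) {
        double keep = anew[o - 1] * rcol[o - 1];
        for (int s = 0; s < 6; ++s) anew[s] = 0.0;
        anew[o - 1] = keep;
      } else {
        for (int n = 0; n < 4; ++n) anew[n] *= (1.0 - rcol[n]);
      }
      double tot = 0.0;
      for (int s = 0; s < 6; ++s) tot += anew[s];
      if (tot <= 0.0) { ll = R_NegInf; break; }
      double inv = 1.0 / tot;
      for (int s = 0; s < 6; ++s) a[s] = anew[s] * inv;
      ll += std::log(tot);
    }
    total += weight[b] * ll;
  }
  return total;
}

// Forward-filter backward-sampling of latent states, one realization per
// bear.  Returns n x K integer matrix: 0 before first observation,
// 1..5 alive states, 6 dead.  Uses the R RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_cjs_ffbs(IntegerMatrix enc, IntegerVector first,
                           IntegerVector sexi, IntegerMatrix acl,
                           NumericVector phi, NumericMatrix tau,
                           NumericMatrix rho) {
  int n_bear = enc.nrow(), K = enc.ncol();
  IntegerMatrix out(n_bear, K);
  std::vector<double> alpha(6 * K);
  double anew[6];
  for (int b = 0; b < n_bear; ++b) {
    int f = first[b] - 1;
    int sex = sexi[b] - 1;
    for (int s = 0; s < 6; ++s) alpha[6 * f + s] = 0.0;
    alpha[6 * f + (enc(b, f) - 1)] = 1.0;
    for (int t = f + 1; t < K; ++t) {
      forward_step(enc, acl, phi, tau, rho, b, sex, t, &alpha[6 * (t - 1)],
                   anew);
      double tot = 0.0;
      for (int s = 0; s < 6; ++s) tot += anew[s];
      if (tot <= 0.0) stop("zero-probability history in backward sampling");
      for (int s = 0; s < 6; ++s) alpha[6 * t + s] = anew[s] / tot;
    }
    // sample s_K from the filtered distribution, then walk backwards
    double p[6];
    int cur = -1;
    {
      double u = unif_rand(), acc = 0.0;
      for (int s = 0; s < 6; ++s) {
        acc += alpha[6 * (K - 1) + s];
        if (u <= acc) { cur = s; break; }
      }
      if (cur < 0) cur = 5;
    }
    out(b, K - 1) = cur + 1;
    for (int t = K - 2; t >= f; --t) {
      int c = acl(b, t) - 1;
      double ph = phi_at(phi, sex, c, t);
      double tot = 0.0;
      for (int m = 0; m < 5; ++m) {
        double tr = (cur < 5) ? ph * tau(m, cur) : (1.0 - ph);
        p[m] = alpha[6 * t + m] * tr;
        tot += p[m];
      }
      p[5] = (cur == 5) ? alpha[6 * t + 5] : 0.0;  // dead stays dead
      tot += p[5];
      if (tot <= 0.0) stop("degenerate backward kernel");
      double u = unif_rand() * tot, acc = 0.0;
      int nxt = 5;
      for (int s = 0; s < 6; ++s) {
        acc += p[s];
        if (u <= acc) { nxt = s; break; }
      }
      out(b, t) = nxt + 1;
      cur = nxt;
    }
    for (int t = 0; t < f; ++t) out(b, t) = 0;
  }
  return out;
}

// Expected number of detections by spatial state (rows 1..4) and occasion,
// propagating each bear's latent chain forward from its first observation
// without conditioning on later detections (detection does not alter the
// latent process, so E[detections in (m,t)] = sum_b P(alive, state m at t)
// * rho(m,t)).
// [[Rcpp::export]]
NumericMatrix cpp_expected_counts(IntegerMatrix enc, IntegerVector first,
                                  IntegerVector sexi, IntegerMatrix acl,
                                  NumericVector phi, NumericMatrix tau,
                                  NumericMatrix rho) {
  int n_bear = enc.nrow(), K = enc.ncol();
  NumericMatrix out(4, K);
  double a[6], anew[6];
  for (int b = 0; b < n_bear; ++b) {
    int f = first[b] - 1;
    int sex = sexi[b] - 1;
    for (int s = 0; s < 6; ++s) a[s] = 0.0;
    a[enc(b, f) - 1] = 1.0;
    for (int t = f + 1; t < K; ++t) {
      int c = acl(b, t - 1) - 1;
      double ph = phi_at(phi, sex, c, t - 1);
      for (int n = 0; n < 5; ++n) {
        double acc = 0.0;
        for (int m = 0; m < 5; ++m) acc += a[m] * tau(m, n);
        anew[n] = ph * acc;
      }
      double dead = a[5];
      for (int m = 0; m < 5; ++m) dead += a[m] * (1.0 - ph);
      anew[5] = dead;
      for (int s = 0; s < 6; ++s) a[s] = anew[s];
      for (int m = 0; m < 4; ++m) out(m, t) += a[m] * rho(m, t);
    }
  }
  return out;
}

// Simulate one replicate data set conditional on each bear's first
// observation and the supplied parameters; returns detection counts by
// state (rows 1..4) and occasion.  Uses the R RNG.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_counts(IntegerMatrix enc, IntegerVector first,
                                  IntegerVector sexi, IntegerMatrix acl,
                                  NumericVector phi, NumericMatrix tau,
                                  NumericMatrix rho) {
  int n_bear = enc.nrow(), K = enc.ncol();
  NumericMatrix out(4, K);
  for (int b = 0; b < n_bear; ++b) {
    int f = first[b] - 1;
    int sex = sexi[b] - 1;
    int cur = enc(b, f) - 1;  // 0..4 alive, 5 dead
    for (int t = f + 1; t < K; ++t) {
      if (cur == 5) break;
      int c = acl(b, t - 1) - 1;
      double ph = phi_at(phi, sex, c, t - 1);
      if (unif_rand() > ph) { cur = 5; break; }
      double u = unif_rand(), acc = 0.0;
      int nxt = 4;
      for (int n = 0; n < 5; ++n) {
        acc += tau(cur, n);
        if (u <= acc) { nxt = n; break; }
      }
      cur = nxt;
      if (cur < 4 && unif_rand() <= rho(cur, t)) out(cur, t) += 1.0;
    }
  }
  return out;
}
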