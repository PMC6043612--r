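// Core numerics: birth-death master equation with absorbing detection
// threshold, and the hidden-tree dynamic-programming likelihood over a
// forest of genealogies. Kept in C++ because model fitting evaluates the
// forest likelihood thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// generator of the birth-death process on sub-threshold states 0..xstar-1;
// birth alpha (zeroth order), death gamma*x; flux from xstar-1 upward is
// absorbed (detection), so rows need not sum to zero here.
static arma::mat bd_generator(double alpha, double gamma, int xstar) {
  arma::mat Q(xstar, xstar, arma::fill::zeros);
  for (int x = 0; x < xstar; ++x) {
    double out = alpha + gamma * x;
    Q(x, x) -= out;
    if (x + 1 < xstar) Q(x, x + 1) += alpha;
    if (x > 0) Q(x, x - 1) += gamma * x;
  }
  return Q;
}

// sub-threshold propagator P_{x->x'}(t) = [expm(Q t)]_{x,x'}
// [[Rcpp::export]]
arma::mat bd_propagator_cpp(double alpha, double gamma, int xstar, double t) {
  if (alpha < 0 || gamma < 0) stop("rates must be nonnegative");
  if (xstar < 1) stop("x_star must be >= 1");
  if (t < 0) stop("t must be >= 0");
  return arma::expmat(bd_generator(alpha, gamma, xstar) * t);
}

// propagators on the uniform grid k*h, k = 0..K, as cumulative powers of
// expm(Q h); returns cube with slice k = P(k*h)
// [[Rcpp::export]]
arma::cube bd_grid_cpp(double alpha, double gamma, int xstar, double h, int K) {
  if (alpha < 0 || gamma < 0) stop("rates must be nonnegative");
  if (xstar < 1) stop("x_star must be >= 1");
  arma::mat E = arma::expmat(bd_generator(alpha, gamma, xstar) * h);
  arma::cube P(xstar, xstar, K + 1);
  P.slice(0).eye();
  for (int k = 1; k <= K; ++k) P.slice(k) = P.slice(k - 1) * E;
  return P;
}

// integrated clipped linear hazard over [t1, t2]
static double cumhaz(double t1, double t2, double a0, double a1) {
  if (a1 >= 0) return a0 * (t2 - t1) + 0.5 * a1 * (t2 * t2 - t1 * t1);
  double tz = a0 / (-a1);
  double u1 = std::min(t1, tz), u2 = std::min(t2, tz);
  return a0 * (u2 - u1) + 0.5 * a1 * (u2 * u2 - u1 * u1);
}

static double hazard_at(double t, double a0, double a1) {
  double v = a0 + a1 * t;
  return v > 0 ? v : 0.0;
}

static double logsumexp2(double la, double lb) {
  if (la == R_NegInf) return lb;
  if (lb == R_NegInf) return la;
  double m = std::max(la, lb);
  return m + std::log(std::exp(la - m) + std::exp(lb - m));
}

// Hidden-tree likelihood of a forest by post-order dynamic programming.
//
// Cells must be supplied in post-order (children before parents), with
// 0-based child indices (-1 for none) and event times as indices into the
// grid of the propagator cube P (step h). ionset = -1 when no onset;
// descendants of onset cells must already be pruned. Per cell the DP carries
//   A(x): data likelihood of the subtree given "already decided, expression
//         state x at birth" (sum-product message over states), and
//   B:    data likelihood of the subtree given "undecided at birth",
//         summing the scenarios "this cell decides at t' in its lifetime"
//         (trapezoidal quadrature on the grid) and "it does not decide".
// B at the root is the hidden-tree sum L(T | theta, eta) of the whole tree.
//
// inherit_mode: 0 = both daughters copy the mother's state, 1 = binomial
// partition of the state between daughters.
// [[Rcpp::export]]
List forest_dp_cpp(IntegerVector ibirth, IntegerVector iend,
                   IntegerVector ionset, IntegerVector child1,
                   IntegerVector child2, LogicalVector is_root,
                   double a0, double a1, const arma::cube& P,
                   double h, double alpha, int inherit_mode,
                   bool want_messages) {
  const int n = ibirth.size();
  const int S = P.n_rows;
  const int K = P.n_slices - 1;
  arma::mat A(S, n, arma::fill::zeros);
  arma::vec la(n, arma::fill::zeros);          // log scale of A columns
  arma::vec lb(n);                             // log of B
  arma::vec lopt1(n);                          // log of decide-here branch
  lb.fill(R_NegInf);
  lopt1.fill(R_NegInf);

  // binomial partition kernel W[y] = sum_k C(y,k) 2^-y A1[k] A2[y-k]
  arma::mat binp;
  if (inherit_mode == 1) {
    binp.zeros(S, S);
    for (int y = 0; y < S; ++y)
      for (int k = 0; k <= y; ++k)
        binp(y, k) = R::dbinom(k, y, 0.5, 0);
  }

  // from-state-0 rows of all grid propagators, contiguous per grid index:
  // R0(y, k) = P_{0 -> y}(k h); csum0(k) = total sub-threshold mass from 0
  arma::mat R0(S, K + 1);
  for (int k = 0; k <= K; ++k) R0.col(k) = P.slice(k).row(0).t();
  arma::rowvec csum0 = arma::sum(R0, 0);

  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int ib = ibirth[i], ie = iend[i], ion = ionset[i];
    const int c1 = child1[i], c2 = child2[i];
    if (ib < 0 || ie > K || ie <= ib || (ion >= 0 && (ion < ib || ion > ie)))
      stop("grid index out of range");
    const bool has_onset = ion >= 0;
    const bool divides = c1 >= 0;
    const double tb = ib * h;

    // W: combined daughters' A-message as a function of the mother's
    // division-time state (copy: pointwise product; binomial: convolution)
    arma::vec W;
    double lw = 0.0;
    if (divides) {
      arma::vec prod1 = A.col(c1), prod2 = A.col(c2);
      if (inherit_mode == 1) {
        arma::vec conv(S, arma::fill::zeros);
        for (int y = 0; y < S; ++y) {
          double s = 0.0;
          for (int k = 0; k <= y; ++k) s += binp(y, k) * prod1[k] * prod2[y - k];
          conv[y] = s;
        }
        W = conv;
      } else {
        W = prod1 % prod2;
      }
      lw = la[c1] + la[c2];
    }

    // A-message of this cell (entry already decided, state x at birth)
    arma::vec Av(S, arma::fill::zeros);
    double lav = 0.0;
    if (has_onset) {
      // first-passage flux at the observed onset
      Av = alpha * P.slice(ion - ib).col(S - 1);
    } else if (divides) {
      Av = P.slice(ie - ib) * W;
      lav = lw;
    } else {
      Av = arma::sum(P.slice(ie - ib), 1);    // censored: sub-threshold mass
    }
    double m = Av.max();
    if (m > 0) { Av /= m; la[i] = lav + std::log(m); }
    else { la[i] = R_NegInf; }
    A.col(i) = Av;

    // B: scenario sum for "undecided at birth"
    // option 1: decide at grid time j in [ib, iu]
    const int iu = has_onset ? ion : ie;
    double val1 = 0.0, lsc1;
    if (has_onset) lsc1 = 0.0; else if (divides) lsc1 = lw; else lsc1 = 0.0;
    if (iu > ib) {
      const int L = iu - ib + 1;
      const int kref = has_onset ? ion : ie;
      arma::vec g(L);
      if (divides && !has_onset) {
        // g[j - ib] = <P_{0->.}(kref - j), W>, batched as one mat-vec
        arma::vec gv = R0.cols(kref - iu, kref - ib).t() * W;
        g = arma::reverse(gv);
      } else if (has_onset) {
        for (int j = 0; j < L; ++j) g[j] = alpha * R0(S - 1, kref - ib - j);
      } else {
        for (int j = 0; j < L; ++j) g[j] = csum0(kref - ib - j);
      }
      // exact per-interval decision mass (S_j - S_{j+1}) times the
      // trapezoid-averaged delay factor: robust for hazards of any scale
      double Sprev = 1.0;  // exp(-cumhaz(tb, tb))
      for (int j = 1; j < L; ++j) {
        double Snext = std::exp(-cumhaz(tb, (ib + j) * h, a0, a1));
        val1 += (Sprev - Snext) * 0.5 * (g[j - 1] + g[j]);
        Sprev = Snext;
      }
    }
    double l1 = val1 > 0 ? lsc1 + std::log(val1) : R_NegInf;
    lopt1[i] = l1;

    // option 2: no decision during this cell (impossible if it has an onset)
    double l2 = R_NegInf;
    if (!has_onset) {
      double lsurv = -cumhaz(tb, ie * h, a0, a1);
      l2 = divides ? lsurv + lb[c1] + lb[c2] : lsurv;
    }
    lb[i] = logsumexp2(l1, l2);
    if (is_root[i]) total += lb[i];
  }

  if (!want_messages) return List::create(_["loglik"] = total);
  return List::create(_["loglik"] = total, _["logB"] = lb,
                      _["logA_scale"] = la, _["A"] = A,
                      _["log_decide_here"] = lopt1);
}

// convenience wrapper used inside optimisation (no message export)
// [[Rcpp::export]]
double forest_loglik_cpp(IntegerVector ibirth, IntegerVector iend,
                         IntegerVector ionset, IntegerVector child1,
                         IntegerVector child2, LogicalVector is_root,
                         double a0, double a1, const arma::cube& P,
                         double h, double alpha, int inherit_mode) {
  List r = forest_dp_cpp(ibirth, iend, ionset, child1, child2, is_root,
                         a0, a1, P, h, alpha, inherit_mode, false);
  return as<double>(r["loglik"]);
}

// Gillespie sample of the birth-death expression process from state x0 over
// [0, t_max]; returns the first time x reaches xstar (crossing) or the state
// at t_max. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List ssa_birth_death_cpp(double alpha, double gamma, int x0, int xstar,
                         double t_max) {
  double t = 0.0;
  int x = x0;
  while (true) {
    if (x >= xstar) return List::create(_["crossed"] = true, _["t_cross"] = t,
                                        _["x_end"] = x);
    double rate = alpha + gamma * x;
    if (rate <= 0) break;
    t += R::rexp(1.0 / rate);
    if (t > t_max) break;
    if (R::unif_rand() * rate < alpha) ++x; else --x;
  }
  return List::create(_["crossed"] = false, _["t_cross"] = NA_REAL,
                      _["x_end"] = x);
}

// toggle-switch propensities: two species with self-activation and mutual
// repression (Hill kinetics) and linear degradation
static inline double toggle_prod(double self, double other, double act,
                                 double rep, double K, double nh) {
  double sn = std::pow(self, nh), Kn = std::pow(K, nh);
  double on = std::pow(other, nh);
  return act * sn / (Kn + sn) + rep * Kn / (Kn + on);
}

// Gillespie simulation of the toggle switch from (A0, B0) over [0, t_max],
// recorded at multiples of record_dt; returns matrix [time, A, B].
// [[Rcpp::export]]
NumericMatrix ssa_toggle_cpp(double act, double rep, double K, double nh,
                             double deg, int A0, int B0, double t_max,
                             double record_dt) {
  int nrec = (int)std::floor(t_max / record_dt) + 1;
  NumericMatrix out(nrec, 3);
  double t = 0.0;
  int A = A0, B = B0, irec = 0;
  while (irec < nrec) {
    double a1r = toggle_prod(A, B, act, rep, K, nh);
    double a2r = toggle_prod(B, A, act, rep, K, nh);
    double a3r = deg * A, a4r = deg * B;
    double rate = a1r + a2r + a3r + a4r;
    double tnext = rate > 0 ? t + R::rexp(1.0 / rate) : R_PosInf;
    while (irec < nrec && irec * record_dt <= tnext) {
      if (irec * record_dt < t) { ++irec; continue; } // shouldn't happen
      out(irec, 0) = irec * record_dt; out(irec, 1) = A; out(irec, 2) = B;
      ++irec;
    }
    if (tnext > t_max || !std::isfinite(tnext)) break;
    t = tnext;
    double u = R::unif_rand() * rate;
    if (u < a1r) ++A;
    else if (u < a1r + a2r) ++B;
    else if (u < a1r + a2r + a3r) --A;
    else --B;
  }
  return out;
}

// long-run occupancy histogram of the toggle switch (for the quasi-potential)
// [[Rcpp::export]]
NumericMatrix toggle_occupancy_cpp(double act, double rep, double K, double nh,
                                   double deg, int A0, int B0,
                                   double burnin, double t_total,
                                   int amax, int bmax) {
  NumericMatrix occ(amax + 1, bmax + 1);
  double t = 0.0;
  int A = A0, B = B0;
  while (t < t_total) {
    double a1r = toggle_prod(A, B, act, rep, K, nh);
    double a2r = toggle_prod(B, A, act, rep, K, nh);
    double a3r = deg * A, a4r = deg * B;
    double rate = a1r + a2r + a3r + a4r;
    if (rate <= 0) break;
    double dwell = R::rexp(1.0 / rate);
    double t2 = std::min(t + dwell, t_total);
    double w = std::max(0.0, t2 - std::max(t, burnin));
    if (w > 0 && A <= amax && B <= bmax) occ(A, B) += w;
    t += dwell;
    double u = R::unif_rand() * rate;
    if (u < a1r) ++A;
    else if (u < a1r + a2r) ++B;
    else if (u < a1r + a2r + a3r) --A;
    else --B;
  }
  return occ;
}
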