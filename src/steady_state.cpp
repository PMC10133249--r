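// Direct steady-state solver for the chemostat consumer-resource model with
// species-specific death rates.  Enumerates candidate survivor subsets and
// returns the unique feasible, uninvadable steady state.
//
// Feasibility of a subset A (|A| = k):
//   * steady-state availabilities c_mu = s_mu / T_mu with T_mu the total
//     consumption of resource mu by A;
//   * every member grows at exactly its loss rate: sum_mu R_imu c_mu = delta_i
//     (delta_i = d + d_i), with strictly positive abundances;
//   * no outsider can invade: sum_mu R_jmu c_mu <= delta_j + tol.
// For k equal to the number of supplied resources the member equations fix c
// by a linear solve; for smaller k the abundances are the interior minimum of
// the strictly convex potential
//   G(n) = sum_i n_i delta_i - sum_mu s_mu log T_mu(n),
// found by a damped Newton iteration (the gradient of G is exactly the
// steady-state residual).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double COND2_TOL = 1e-9;   // hull-boundary / invasion tolerance
static const double POS_TOL   = 1e-12;  // strict positivity tolerance

// Solve the interior minimisation of G over abundances of the subset.
// Returns true on convergence to an interior point; fills n (length k).
static bool newton_subset(const mat& RA, const vec& sc, const vec& deltaA,
                          vec& n) {
  const uword k = RA.n_rows;
  const double Scons = accu(sc);
  if (Scons <= 0) return false;
  n.set_size(k);
  n.fill(Scons / accu(deltaA));
  vec T, g;
  mat H(k, k);
  for (int iter = 0; iter < 100; ++iter) {
    T = RA.t() * n;                      // consumption totals, length pc
    if (T.min() <= 0) return false;
    vec w = sc / T;                      // s_mu / T_mu
    g = deltaA - RA * w;                 // gradient of G
    double gscale = std::max(1.0, deltaA.max());
    if (norm(g, "inf") < 1e-11 * gscale) return true;
    vec w2 = sc / (T % T);
    H = RA * diagmat(w2) * RA.t();
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx)) return false;
    // backtracking line search keeping n strictly positive
    double t = 1.0;
    for (uword i = 0; i < k; ++i)
      if (step(i) > 0 && t * step(i) > 0.95 * n(i))
        t = 0.95 * n(i) / step(i);
    double G0 = dot(n, deltaA) - dot(sc, log(T));
    for (int ls = 0; ls < 40; ++ls) {
      vec ntry = n - t * step;
      vec Ttry = RA.t() * ntry;
      if (ntry.min() > 0 && Ttry.min() > 0) {
        double G1 = dot(ntry, deltaA) - dot(sc, log(Ttry));
        if (G1 <= G0 + 1e-12 * std::abs(G0)) { n = ntry; break; }
      }
      t *= 0.5;
      if (ls == 39) return false;       // stalled: interior optimum absent
    }
    if (n.min() < POS_TOL * Scons) return false;
  }
  return false;
}

// Evaluate one candidate subset; on success fills nA and cstar (length p,
// Inf marks supplied-but-unconsumed resources) and returns true.
static bool eval_subset(const mat& R, const vec& s, const vec& delta,
                        const uvec& A, const uvec& others,
                        vec& nA, vec& cstar) {
  const uword p = R.n_cols;
  mat RA = R.rows(A);
  vec deltaA = delta(A);

  // supplied resources consumed by at least one member
  uvec cons = find((sum(RA, 0).t() > 0) % (s > 0));
  const uword k = A.n_elem, pc = cons.n_elem;
  if (pc < k) return false;             // rank-deficient: no interior state

  vec ccons;                            // availabilities on consumed resources
  if (k == pc) {
    // member equations determine c directly (square linear system)
    mat RAc = RA.cols(cons);
    if (!solve(ccons, RAc, deltaA, solve_opts::no_approx)) return false;
    if (!ccons.is_finite() || ccons.min() <= 0) return false;   // condition 1
    vec T = s(cons) / ccons;
    if (!solve(nA, RAc.t(), T, solve_opts::no_approx)) return false;
    // condition 3 (supply inside the member hull): all abundances positive;
    // exact-boundary supplies fall through to the smaller subset
    if (nA.min() <= 0) return false;
  } else {
    mat RAc = RA.cols(cons);
    if (!newton_subset(RAc, s(cons), deltaA, nA)) return false;
    vec T = RAc.t() * nA;
    ccons = s(cons) / T;
  }

  // members consuming only unsupplied resources cannot balance their losses
  cstar.set_size(p);
  for (uword m = 0; m < p; ++m) {
    if (s(m) <= 0) { cstar(m) = 0.0; continue; }
    cstar(m) = datum::inf;              // supplied, unconsumed
  }
  cstar(cons) = ccons;

  // condition 2: outsiders must not be able to invade
  for (uword oi = 0; oi < others.n_elem; ++oi) {
    uword j = others(oi);
    double growth = 0.0;
    for (uword m = 0; m < p; ++m) {
      if (R(j, m) <= 0) continue;
      if (!std::isfinite(cstar(m))) return false;   // free resource: invades
      growth += R(j, m) * cstar(m);
    }
    if (growth > delta(j) + COND2_TOL) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".cr_solve_cpp")]]
Rcpp::List cr_solve_cpp(const arma::mat& R, const arma::vec& s,
                        const arma::vec& delta,
                        const arma::uvec& present1) {
  const uword m = R.n_rows, p = R.n_cols;
  uvec present = present1 - 1;          // to 0-based
  const uword np = present.n_elem;
  const uword peff = accu(s > 0);
  const uword kmax = std::min<uword>(np, peff);

  vec n_best; vec c_best; uvec A_best;
  int n_feasible = 0;
  uword best_k = 0;

  if (np > 0 && kmax > 0) {
    const unsigned long nmask = (1UL << np);
    for (unsigned long mask = 1; mask < nmask; ++mask) {
      uword k = __builtin_popcountl(mask);
      if (k > kmax) continue;
      uvec A(k), others(np - k);
      uword a = 0, o = 0;
      for (uword i = 0; i < np; ++i) {
        if (mask & (1UL << i)) A(a++) = present(i);
        else others(o++) = present(i);
      }
      vec nA, cstar;
      if (eval_subset(R, s, delta, A, others, nA, cstar)) {
        ++n_feasible;
        if (k > best_k) {
          best_k = k; A_best = A; n_best = nA; c_best = cstar;
        }
      }
    }
  }

  vec n_full(m, fill::zeros);
  if (best_k > 0) n_full(A_best) = n_best;
  return Rcpp::List::create(
    Rcpp::Named("found") = (best_k > 0),
    Rcpp::Named("survivors") = Rcpp::wrap(conv_to<std::vector<int>>::from(
        conv_to<ivec>::from(A_best + 1))),
    Rcpp::Named("abundances") = n_full,
    Rcpp::Named("c_star") = (best_k > 0) ? Rcpp::wrap(c_best)
                                         : Rcpp::wrap(vec(p, fill::value(datum::nan))),
    Rcpp::Named("n_feasible") = n_feasible);
}
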