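#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Kinetic Monte Carlo core for the l-TASEP with extended particles,
// open boundaries and optional per-ribosome drop-off.
//
// Conventions (documented in ?runSteadyState):
//  * a ribosome is labelled by its A-site = 5'-most covered codon i,
//    footprint covers i .. i+ell-1;
//  * initiation enabled iff codons 1..ell are all vacant, i.e. the most
//    5' ribosome has position > ell (or the lattice is empty);
//  * ribosome k may hop i -> i+1 iff i < L and the next ribosome
//    downstream has position >= i + ell + 1;
//  * a ribosome with A-site at codon L terminates at rate beta (its
//    footprint conceptually overhangs the 3' end);
//  * every bound ribosome detaches at rate delta.
//
// Uses R's RNG (seed via set.seed() before calling). Sampling is
// time-weighted; the sampling window is split into n_batch equal-time
// batches for Monte Carlo standard errors.

// [[Rcpp::export(name = ".tasep_kmc")]]
List tasep_kmc(int L, int ell, double alpha, double p, double beta,
               double delta, double t_burn, double min_init,
               double t_sample, int n_batch) {
  if (L < ell || ell < 1)
    stop("invalid lattice: need L >= ell >= 1");
  if (alpha < 0 || p < 0 || beta < 0 || delta < 0)
    stop("rates must be non-negative");

  std::vector<int> pos;            // ascending A-site positions
  pos.reserve(L / ell + 1);

  // A-sites live on 1..L with spacing >= ell, so up to
  // floor((L-1)/ell) + 1 ribosomes fit (the 3'-most footprint may
  // overhang the transcript end)
  const int cap = (L - 1) / ell + 1;
  NumericVector hist(cap + 1);     // time spent with N ribosomes
  NumericVector batch_N(n_batch);  // integral of N dt per batch
  NumericVector batch_term(n_batch);
  const double batch_len = t_sample / n_batch;

  double t = 0.0;                  // global clock (burn-in phase)
  double ts = 0.0;                 // clock within sampling window
  double burn_inits = 0.0;
  long c_init = 0, c_step = 0, c_term = 0, c_drop = 0;
  bool burning = true, absorbed = false;
  long iter = 0;

  // accumulate a dwell of length `dur` at occupancy N, starting at
  // window time `from`; splits across batch boundaries
  auto accum = [&](double from, double dur, int N) {
    hist[N] += dur;
    double a = from, rem = dur;
    while (rem > 0.0) {
      int b = (int)(a / batch_len);
      if (b >= n_batch) b = n_batch - 1;
      double take = std::min(rem, (b + 1) * batch_len - a);
      if (take <= 0.0) take = rem;   // guard against fp round-off
      batch_N[b] += take * N;
      a += take;
      rem -= take;
    }
  };

  while (true) {
    if (++iter % 1048576 == 0) Rcpp::checkUserInterrupt();
    const int n = (int)pos.size();

    // enabled-event rates
    const double r_init = (alpha > 0.0 && (n == 0 || pos[0] > ell)) ? alpha : 0.0;
    int n_mov = 0;
    for (int k = 0; k < n; ++k)
      if (pos[k] < L && (k == n - 1 || pos[k + 1] - pos[k] > ell)) ++n_mov;
    const double r_move = p * n_mov;
    const double r_term = (n > 0 && pos[n - 1] == L) ? beta : 0.0;
    const double r_drop = delta * n;
    const double total = r_init + r_move + r_term + r_drop;

    if (total <= 0.0) {
      // absorbing configuration (e.g. alpha = 0 and lattice empty)
      if (burning) { burning = false; ts = 0.0; }
      if (ts < t_sample) accum(ts, t_sample - ts, n);
      absorbed = true;
      break;
    }

    const double dt = R::exp_rand() / total;

    if (burning) {
      t += dt;
    } else {
      if (ts + dt >= t_sample) {       // window closes before next event
        accum(ts, t_sample - ts, n);
        break;
      }
      accum(ts, dt, n);
      ts += dt;
    }

    // pick one event with probability proportional to its rate
    const double u = R::unif_rand() * total;
    if (u < r_init) {
      pos.insert(pos.begin(), 1);
      if (burning) burn_inits += 1.0; else ++c_init;
    } else if (u < r_init + r_move) {
      int m = (int)((u - r_init) / p);
      if (m >= n_mov) m = n_mov - 1;
      int seen = -1;
      for (int k = 0; k < n; ++k) {
        if (pos[k] < L && (k == n - 1 || pos[k + 1] - pos[k] > ell)) {
          if (++seen == m) { ++pos[k]; break; }
        }
      }
      if (!burning) ++c_step;
    } else if (u < r_init + r_move + r_term) {
      pos.pop_back();
      if (!burning) {
        ++c_term;
        int b = (int)(ts / batch_len);
        if (b >= n_batch) b = n_batch - 1;
        batch_term[b] += 1.0;
      }
    } else {
      int m = (int)((u - r_init - r_move - r_term) / delta);
      if (m >= n) m = n - 1;
      pos.erase(pos.begin() + m);
      if (!burning) ++c_drop;
    }

    if (burning && t >= t_burn && burn_inits >= min_init) {
      burning = false;
      ts = 0.0;
    }
  }

  return List::create(
    _["hist"] = hist,
    _["batch_N"] = batch_N,
    _["batch_term"] = batch_term,
    _["n_events"] = NumericVector::create(
      _["init"] = (double)c_init, _["step"] = (double)c_step,
      _["term"] = (double)c_term, _["drop"] = (double)c_drop),
    _["t_burn_actual"] = t,
    _["absorbed"] = absorbed,
    _["final_positions"] = IntegerVector(pos.begin(), pos.end()));
}
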