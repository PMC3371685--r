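#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Right-hand side of the seven-population melanoma-immune system.
// y / yd: state and tau-delayed state in the order E, Ab, Es, As, N, C, A.
// Only the delayed E and Ab enter the equations; the full delayed state is
// passed for generality.
static inline void rhs(const double *y, const double *yd, const double *a,
                       double *dy) {
  // a: alpha1..alpha11 (0..10), h (11), k1 (12), k2 (13), k3 (14), M (15)
  const double E = y[0], Ab = y[1], Es = y[2], As = y[3];
  const double N = y[4], C = y[5], A = y[6];
  const double holl = As / (As + a[12]);
  const double km = (As + a[13]) / (As + a[14]);
  const double growth = (C >= 1.0) ? (a[0] - a[1] * std::log(C)) * C : 0.0;
  const double kill = a[2] * km * Es * C;
  const double na = a[5] * N * A;
  dy[0] = -(a[10] + a[7]) * E;
  dy[1] = -(a[10] + a[9]) * Ab;
  dy[2] = a[6] * holl * Es + a[10] * yd[0] + na - a[7] * Es;
  dy[3] = a[10] * yd[1] - a[8] * As * Es - a[9] * As;
  dy[4] = a[11] * (a[15] - N) - na;
  dy[5] = growth - kill;
  dy[6] = a[3] * kill - a[4] * A - na;
}

// Fixed-step classical RK4 with the method of steps. The grid step divides
// the delay, so delayed values at stage endpoints are stored ring-buffer
// nodes; half-stage values are linearly interpolated between the two
// bracketing nodes. Impulses are instantaneous jumps applied to a node's
// state before the step departing that node. Components are floored at
// zero after every step.
//
// [[Rcpp::export]]
List integrate_rk4_core(NumericVector y0, NumericVector avec, double hstep,
                        int n_steps, int tau_steps, int thin,
                        IntegerVector ev_steps, NumericVector ev_dE,
                        NumericVector ev_dAb) {
  const int nv = 7;
  const double *a = avec.begin();
  double yinit[nv], cur[nv];
  for (int v = 0; v < nv; ++v) yinit[v] = cur[v] = y0[v];

  const int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, nv);

  // ring buffer over the last tau (plus the node being written)
  const int L = tau_steps + 2;
  std::vector<double> buf((size_t)L * nv, 0.0);
  auto buf_row = [&](int node) { return &buf[(size_t)(node % L) * nv]; };
  // delayed state at integer node index (may be negative: pre-history)
  auto node_state = [&](int node) -> const double * {
    return (node < 0) ? yinit : buf_row(node);
  };
  // An impulse makes the stored state at an event node the post-jump
  // (right-limit) value. Delayed lookups that treat a node as the *right*
  // endpoint of a half-open step interval must instead see the pre-jump
  // left limit of E and Ab, kept here per event node.
  std::map<int, std::pair<double, double> > prejump;
  auto node_state_left = [&](int node, double *dest) {
    const double *s = (node < 0) ? yinit : buf_row(node);
    for (int v = 0; v < nv; ++v) dest[v] = s[v];
    if (node >= 0) {
      std::map<int, std::pair<double, double> >::const_iterator it =
          prejump.find(node);
      if (it != prejump.end()) {
        dest[0] = it->second.first;
        dest[1] = it->second.second;
      }
    }
  };

  const int nev = ev_steps.size();
  int ev = 0;

  double k1[nv], k2[nv], k3[nv], k4[nv], tmp[nv], dmid[nv];
  const double half = hstep / 2.0, sixth = hstep / 6.0;
  long clamp_count = 0;

  for (int j = 0; j <= n_steps; ++j) {
    if (ev < nev && ev_steps[ev] == j) {
      prejump[j] = std::make_pair(cur[0], cur[1]);
      while (ev < nev && ev_steps[ev] == j) {
        cur[0] += ev_dE[ev];
        cur[1] += ev_dAb[ev];
        ++ev;
      }
    }
    double *node = buf_row(j);
    for (int v = 0; v < nv; ++v) node[v] = cur[v];
    if (j % thin == 0) {
      const int r = j / thin;
      for (int v = 0; v < nv; ++v) out(r, v) = cur[v];
    }
    if (j == n_steps) break;

    if (tau_steps == 0) {
      rhs(cur, cur, a, k1);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + half * k1[v];
      rhs(tmp, tmp, a, k2);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + half * k2[v];
      rhs(tmp, tmp, a, k3);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + hstep * k3[v];
      rhs(tmp, tmp, a, k4);
    } else {
      // left endpoint: post-jump node value; right endpoint and the
      // interior half-stage: left-limit (pre-jump) values
      const double *d0 = node_state(j - tau_steps);
      double d1[nv], dn[nv];
      node_state_left(j + 1 - tau_steps, d1);
      if (j - tau_steps < 0) {
        // the half-stage delayed time is still in pre-history
        for (int v = 0; v < nv; ++v) dmid[v] = yinit[v];
      } else {
        node_state_left(j - tau_steps + 1, dn);
        for (int v = 0; v < nv; ++v) dmid[v] = 0.5 * (d0[v] + dn[v]);
      }
      rhs(cur, d0, a, k1);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + half * k1[v];
      rhs(tmp, dmid, a, k2);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + half * k2[v];
      rhs(tmp, dmid, a, k3);
      for (int v = 0; v < nv; ++v) tmp[v] = cur[v] + hstep * k3[v];
      rhs(tmp, d1, a, k4);
    }

    bool bad = false;
    for (int v = 0; v < nv; ++v) {
      double ynew =
          cur[v] + sixth * (k1[v] + 2.0 * k2[v] + 2.0 * k3[v] + k4[v]);
      if (!std::isfinite(ynew)) bad = true;
      if (ynew < 0.0) {
        ++clamp_count;
        ynew = 0.0;
      }
      cur[v] = ynew;
    }
    if (bad) {
      stop("integration failure: non-finite state at t = %f dt (step %d)",
           (j + 1) * hstep, j + 1);
    }
  }

  return List::create(Named("states") = out,
                      Named("clamp_count") = (double)clamp_count);
}
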