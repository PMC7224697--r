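// Core time-stepped integration of the recurrent rate network with
// per-neuron Hebbian learning rates, synaptic scaling, homeostatic
// inhibitory plasticity and Ornstein-Uhlenbeck input noise.
//
// Layout conventions (match the R level):
//   - neurons 0..NE-1 excitatory, NE..N-1 inhibitory
//   - W(i, j) is the signed weight from presynaptic j to postsynaptic i
//   - E->E in [0, wmax], I->E in [-wmax_inh, 0], E->I static, no I->I,
//     no autapses
// Learning rates are in Hz, internal time in ms, so weight updates scale
// by dt/1000.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double transfer(double x, double r0, double rmax,
                              bool baseline_shift) {
  if (x < 0.0) return 0.0;
  double span = rmax - r0;
  double r = span * std::tanh(x / span);
  return baseline_shift ? r + r0 : r;
}

// [[Rcpp::export]]
List cpp_run_network(arma::vec y, arma::mat W, int n_exc,
                     const arma::mat& drive,
                     const IntegerVector& schedule,
                     const IntegerVector& assoc,
                     double h_assoc,
                     int epoch_steps,
                     double dt, double tau_m,
                     double r0, double rmax, bool baseline_shift,
                     double tau_ou, double sigma_ou,
                     bool plastic, bool plast_linear,
                     const arma::vec& alpha, double zeta, double eta,
                     double w_total_ee, double y0,
                     double wmax, double wmax_inh,
                     int rec_rate_every, int rec_w_every,
                     const IntegerVector& groups, int rec_group_every,
                     int seed) {
  const int n = y.n_elem;
  const int ni = n - n_exc;
  const int n_epochs = schedule.size();
  const long n_steps = (long)n_epochs * epoch_steps;
  const double dts = dt / 1000.0;          // step in seconds for Hz rates
  const double euler = dt / tau_m;

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double ou_decay = std::exp(-dt / tau_ou);
  const double ou_amp = sigma_ou * std::sqrt(1.0 - ou_decay * ou_decay);
  arma::vec ou(n_exc, arma::fill::zeros);

  // row sums of the E->E block, maintained incrementally
  arma::vec rs(n_exc, arma::fill::zeros);
  for (int i = 0; i < n_exc; ++i)
    rs(i) = arma::accu(W.submat(i, 0, i, n_exc - 1));

  const int n_rate = rec_rate_every > 0 ? (int)(n_steps / rec_rate_every) : 0;
  arma::mat rates(n, std::max(n_rate, 0));
  arma::vec rate_times(std::max(n_rate, 0));
  const int n_snap = rec_w_every > 0 ? (int)(n_steps / rec_w_every) : 0;
  arma::cube snaps(n, n, std::max(n_snap, 0));
  arma::vec snap_times(std::max(n_snap, 0));
  const int n_grp = rec_group_every > 0 ? (int)(n_steps / rec_group_every) : 0;
  arma::mat spec_mean(n_exc, std::max(n_grp, 0));
  arma::mat nonspec_mean(n_exc, std::max(n_grp, 0));
  arma::vec grp_times(std::max(n_grp, 0));

  // same-group counts for the group-weight channel
  arma::ivec grp(n_exc);
  for (int i = 0; i < n_exc; ++i) grp(i) = groups[i];

  arma::vec r(n), rl(n), H(n), wr(n);
  arma::vec a_pre(n_exc), common(n_exc), new_rs(n_exc);
  double* const rp = r.memptr();
  double* const rlp = rl.memptr();
  double* const wrp = wr.memptr();
  double* const ap = a_pre.memptr();
  double* const cp = common.memptr();
  double* const np = new_rs.memptr();
  int i_rate = 0, i_snap = 0, i_grp = 0;

  for (long step = 0; step < n_steps; ++step) {
    const int epoch = (int)(step / epoch_steps);
    const int stim = schedule[epoch];
    const int asc = assoc[epoch];

    // OU noise (exact discretization), then external input
    for (int i = 0; i < n_exc; ++i) ou(i) = ou(i) * ou_decay + ou_amp * gauss(rng);
    H.zeros();
    const bool assoc_on = (asc >= 0 && asc == stim);
    for (int i = 0; i < n_exc; ++i) {
      H(i) = drive(i, stim) + ou(i);
      if (assoc_on) H(i) += h_assoc;
    }

    for (int i = 0; i < n; ++i) rp[i] = transfer(y(i), r0, rmax, baseline_shift);
    if (plastic) {
      if (plast_linear)
        for (int i = 0; i < n; ++i) rlp[i] = std::max(y(i), 0.0);
      else
        for (int i = 0; i < n; ++i) rlp[i] = rp[i];
    }

    // Recurrent drive W r (using this step's weights), fused with the
    // plastic E->E update: one column-major pass reads each weight for the
    // matvec and writes its Hebbian/scaling/clip update in place, tracking
    // E->E row sums incrementally. The dynamics see the pre-update weights.
    std::fill(wrp, wrp + n, 0.0);
    if (plastic) {
      for (int i = 0; i < n_exc; ++i) {
        ap[i] = dts * alpha(i) * rlp[i];
        cp[i] = -dts * zeta * (rs(i) - w_total_ee);
      }
      std::fill(np, np + n_exc, 0.0);
      for (int j = 0; j < n_exc; ++j) {
        const double rj = rp[j];
        const double rlj = rlp[j];
        double* wj = W.colptr(j);
        for (int i = 0; i < n_exc; ++i) {
          const double wold = wj[i];
          wrp[i] += wold * rj;
          double w = wold + ap[i] * rlj + cp[i];
          w = std::max(0.0, std::min(w, wmax));
          wj[i] = w;
          np[i] += w;
        }
        // undo the diagonal write: no autapses
        np[j] -= wj[j];
        wj[j] = 0.0;
        // E->I rows of column j are static: matvec only
        for (int k = 0; k < ni; ++k) wrp[n_exc + k] += W(n_exc + k, j) * rj;
      }
      rs = new_rs;
      // I columns: matvec plus the homeostatic I->E magnitude update
      for (int k = 0; k < ni; ++k) {
        const double rk = rp[n_exc + k];
        const double ek = dts * eta * rlp[n_exc + k];
        double* wk = W.colptr(n_exc + k);
        for (int i = 0; i < n_exc; ++i) {
          wrp[i] += wk[i] * rk;
          double w = wk[i] - ek * (rlp[i] - y0);
          wk[i] = std::min(0.0, std::max(w, -wmax_inh));
        }
        // I->I stays zero; no autapse handling needed (entries are 0)
      }
    } else {
      for (int j = 0; j < n; ++j) {
        const double rj = rp[j];
        if (rj == 0.0) continue;
        const double* wj = W.colptr(j);
        for (int i = 0; i < n; ++i) wrp[i] += wj[i] * rj;
      }
    }

    for (int i = 0; i < n; ++i) y(i) += euler * (-y(i) + wrp[i] + H(i));

    // recording
    if (rec_rate_every > 0 && (step + 1) % rec_rate_every == 0 && i_rate < n_rate) {
      for (int i = 0; i < n; ++i) rates(i, i_rate) = transfer(y(i), r0, rmax, baseline_shift);
      rate_times(i_rate) = (step + 1) * dt;
      ++i_rate;
    }
    if (rec_w_every > 0 && (step + 1) % rec_w_every == 0 && i_snap < n_snap) {
      snaps.slice(i_snap) = W;
      snap_times(i_snap) = (step + 1) * dt;
      ++i_snap;
    }
    if (rec_group_every > 0 && (step + 1) % rec_group_every == 0 && i_grp < n_grp) {
      for (int i = 0; i < n_exc; ++i) {
        double s = 0.0, nsp = 0.0; int cs = 0, cn = 0;
        for (int j = 0; j < n_exc; ++j) {
          if (j == i) continue;
          if (grp(j) == grp(i)) { s += W(i, j); ++cs; }
          else { nsp += W(i, j); ++cn; }
        }
        spec_mean(i, i_grp) = cs ? s / cs : NA_REAL;
        nonspec_mean(i, i_grp) = cn ? nsp / cn : NA_REAL;
      }
      grp_times(i_grp) = (step + 1) * dt;
      ++i_grp;
    }
  }

  return List::create(
    _["rates"] = rates, _["rate_times"] = rate_times,
    _["W"] = W,
    _["snapshots"] = snaps, _["snapshot_times"] = snap_times,
    _["spec_mean"] = spec_mean, _["nonspec_mean"] = nonspec_mean,
    _["group_times"] = grp_times,
    _["y"] = y, _["ou"] = ou);
}

// Embedded-plastic-neuron model: a recurrent population with fixed weights,
// plus static and plastic readout neurons whose population input is scaled
// by a coupling factor (pc_static / pc_plastic). The static-to-plastic
// weights are functionally silent: updated Hebbian-with-scaling each step
// but never fed back into activity.
// [[Rcpp::export]]
List cpp_run_embedded(arma::vec y_pop, const arma::mat& W_pop,
                      const arma::mat& drive_pop,
                      arma::vec y_static, const arma::mat& drive_static,
                      double y_plastic, const arma::rowvec& drive_plastic,
                      const arma::vec& w_pop_row,
                      double pc_static, double pc_plastic,
                      arma::vec w_plastic,
                      double alpha, double zeta, double w_total, double wmax,
                      const IntegerVector& schedule,
                      const IntegerVector& assoc, double h_assoc,
                      bool assoc_to_readouts,
                      int epoch_steps,
                      double dt, double tau_m,
                      double r0, double rmax, bool baseline_shift,
                      double tau_ou, double sigma_ou,
                      int rec_every, int seed) {
  const int npop = y_pop.n_elem;
  const int nst = y_static.n_elem;
  const int n_epochs = schedule.size();
  const long n_steps = (long)n_epochs * epoch_steps;
  const double dts = dt / 1000.0;
  const double euler = dt / tau_m;

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double ou_decay = std::exp(-dt / tau_ou);
  const double ou_amp = sigma_ou * std::sqrt(1.0 - ou_decay * ou_decay);
  arma::vec ou_pop(npop, arma::fill::zeros), ou_st(nst, arma::fill::zeros);
  double ou_pl = 0.0;

  const int n_rec = rec_every > 0 ? (int)(n_steps / rec_every) : 0;
  arma::mat w_rec(nst, std::max(n_rec, 0));
  arma::vec rec_times(std::max(n_rec, 0));
  int i_rec = 0;

  arma::vec r_pop(npop), r_st(nst);
  for (long step = 0; step < n_steps; ++step) {
    const int epoch = (int)(step / epoch_steps);
    const int stim = schedule[epoch];
    const int asc = assoc[epoch];
    const bool assoc_on = (asc >= 0 && asc == stim);
    const double add = assoc_on ? h_assoc : 0.0;       // population drive
    const double add_ro = assoc_to_readouts ? add : 0; // static/plastic drive

    for (int i = 0; i < npop; ++i) ou_pop(i) = ou_pop(i) * ou_decay + ou_amp * gauss(rng);
    for (int i = 0; i < nst; ++i) ou_st(i) = ou_st(i) * ou_decay + ou_amp * gauss(rng);
    ou_pl = ou_pl * ou_decay + ou_amp * gauss(rng);

    for (int i = 0; i < npop; ++i) r_pop(i) = transfer(y_pop(i), r0, rmax, baseline_shift);
    for (int i = 0; i < nst; ++i) r_st(i) = transfer(y_static(i), r0, rmax, baseline_shift);
    const double r_pl = transfer(y_plastic, r0, rmax, baseline_shift);
    const double rl_pl = std::max(y_plastic, 0.0);

    const double pop_in = arma::dot(w_pop_row, r_pop);  // shared population drive
    arma::vec wr = W_pop * r_pop;
    for (int i = 0; i < npop; ++i)
      y_pop(i) += euler * (-y_pop(i) + wr(i) + drive_pop(i, stim) + add + ou_pop(i));
    for (int i = 0; i < nst; ++i)
      y_static(i) += euler * (-y_static(i) + pc_static * pop_in +
                              drive_static(i, stim) + add_ro + ou_st(i));
    y_plastic += euler * (-y_plastic + pc_plastic * pop_in +
                          drive_plastic(stim) + add_ro + ou_pl);

    // silent static->plastic weights, Hebbian + scaling over the plastic
    // neuron's inputs, clipped
    const double common = -dts * zeta * (arma::accu(w_plastic) - w_total);
    for (int s = 0; s < nst; ++s) {
      double w = w_plastic(s) + dts * alpha * std::max(y_static(s), 0.0) * rl_pl + common;
      if (w < 0.0) w = 0.0; else if (w > wmax) w = wmax;
      w_plastic(s) = w;
    }

    if (rec_every > 0 && (step + 1) % rec_every == 0 && i_rec < n_rec) {
      w_rec.col(i_rec) = w_plastic;
      rec_times(i_rec) = (step + 1) * dt;
      ++i_rec;
    }
  }

  return List::create(_["w_plastic"] = w_plastic,
                      _["w_record"] = w_rec, _["record_times"] = rec_times);
}
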