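// Recurrent network core: time-averaged net-input dynamics, logistic units,
// hard/soft clamping of external inputs, cross-entropy error with a
// zero-error radius, and backpropagation through time over the unrolled
// dynamics. Layers: retinotopic (r), visual image (v), verbal (l) peripheral
// layers, each bidirectionally connected to one hidden layer (h). Only
// connected (across-item-varying) peripheral units are represented.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

struct Params {
  double eps;        // integration rate of the net input (0.1)
  double gain;       // soft-clamp gain (0.5)
  int    cycles;     // cycles per phase (10)
  double stop_thr;   // early-stop |output - target| threshold (0.5)
  double radius;     // zero-error radius (0.1)
  double lr;         // learning rate (0.05)
  double decay;      // weight decay (1e-8)
  double noise_sd;   // hidden net-input Gaussian noise SD (0.2)
  double guard;      // epsilon guard inside logarithms (1e-7)
  int    err_start;  // first cycle of a target phase that injects error
  bool   err_mean;   // average (rather than sum) error over error cycles
};

static Params read_params(const List& p) {
  Params q;
  q.eps      = as<double>(p["integration_rate"]);
  q.gain     = as<double>(p["clamp_gain"]);
  q.cycles   = as<int>(p["cycles_per_phase"]);
  q.stop_thr = as<double>(p["early_stop_threshold"]);
  q.radius   = as<double>(p["zero_error_radius"]);
  q.lr       = as<double>(p["learning_rate"]);
  q.decay    = as<double>(p["weight_decay"]);
  q.noise_sd = as<double>(p["hidden_input_noise_sd"]);
  q.guard    = as<double>(p["epsilon_guard"]);
  q.err_start = as<int>(p["error_start_cycle"]);
  q.err_mean = as<std::string>(p["error_aggregation"]) == "mean";
  return q;
}

struct Net {
  mat W_rh, W_vh, W_lh;  // peripheral -> hidden (n_x  x nh)
  mat W_hr, W_hv, W_hl;  // hidden -> peripheral (nh x n_x)
  vec b_h, b_r, b_v, b_l;
  int nr, nv, nl, nh;
};

static Net read_net(const List& w) {
  Net n;
  n.W_rh = as<mat>(w["W_rh"]); n.W_vh = as<mat>(w["W_vh"]); n.W_lh = as<mat>(w["W_lh"]);
  n.W_hr = as<mat>(w["W_hr"]); n.W_hv = as<mat>(w["W_hv"]); n.W_hl = as<mat>(w["W_hl"]);
  n.b_h = as<vec>(w["b_h"]); n.b_r = as<vec>(w["b_r"]);
  n.b_v = as<vec>(w["b_v"]); n.b_l = as<vec>(w["b_l"]);
  n.nr = n.W_rh.n_rows; n.nv = n.W_vh.n_rows; n.nl = n.W_lh.n_rows;
  n.nh = n.W_rh.n_cols;
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(
    _["W_rh"] = n.W_rh, _["W_vh"] = n.W_vh, _["W_lh"] = n.W_lh,
    _["W_hr"] = n.W_hr, _["W_hv"] = n.W_hv, _["W_hl"] = n.W_hl,
    _["b_h"] = n.b_h, _["b_r"] = n.b_r, _["b_v"] = n.b_v, _["b_l"] = n.b_l);
}

struct Phase {
  int n_cycles;
  bool has_ret;  vec ret_ext;    // hard clamp on the whole retinotopic layer
  bool has_verb; vec verb_mask;  // 0/1 per verbal unit
  vec verb_ext;                  // external value for masked verbal units
  int target_layer;              // 0 none, 1 visual image, 2 verbal
  vec target;
  int stop_cycle;                // filled by forward()
};

static std::vector<Phase> read_phases(const List& phases, const Net& net) {
  std::vector<Phase> out;
  for (int i = 0; i < phases.size(); ++i) {
    List p = phases[i];
    Phase ph;
    ph.n_cycles = as<int>(p["n_cycles"]);
    ph.has_ret = p.containsElementNamed("ret_ext") && !Rf_isNull(p["ret_ext"]);
    if (ph.has_ret) {
      ph.ret_ext = as<vec>(p["ret_ext"]);
      if ((int)ph.ret_ext.n_elem != net.nr)
        stop("retinotopic external input has wrong length");
    }
    ph.has_verb = p.containsElementNamed("verb_mask") && !Rf_isNull(p["verb_mask"]);
    if (ph.has_verb) {
      ph.verb_mask = as<vec>(p["verb_mask"]);
      ph.verb_ext = as<vec>(p["verb_ext"]);
      if ((int)ph.verb_mask.n_elem != net.nl)
        stop("verbal clamp mask has wrong length");
    }
    ph.target_layer = as<int>(p["target_layer"]);
    if (ph.target_layer > 0) ph.target = as<vec>(p["target"]);
    ph.stop_cycle = 0;
    out.push_back(ph);
  }
  return out;
}

static inline vec sigmoid(const vec& s) { return 1.0 / (1.0 + arma::exp(-s)); }

// Forward pass. S and A get one column per cycle plus the initial state in
// column 0; activations are post-clamp. Returns total cross-entropy error
// (guarded logs) summed over target units and error cycles; fills
// stop_cycle per phase and phase_of_cycle (1-based phase index per stored
// cycle column, 0 for the initial state).
struct Trace {
  mat S, A;
  std::vector<int> phase_of_cycle;
  std::vector<int> cycle_in_phase;
  int n_cycles_total;
  int n_error_cycles;
  double error;
};

static void forward(const Net& net, std::vector<Phase>& phases,
                    const Params& par, bool use_noise, Trace& tr) {
  const int nr = net.nr, nv = net.nv, nl = net.nl, nh = net.nh;
  const int ntot = nr + nv + nl + nh;
  const int r0 = 0, v0 = nr, l0 = nr + nv, h0 = nr + nv + nl;
  int max_cycles = 0;
  for (auto& ph : phases) max_cycles += ph.n_cycles;

  if ((int)tr.S.n_rows != ntot || (int)tr.S.n_cols < max_cycles + 1) {
    tr.S.set_size(ntot, max_cycles + 1);
    tr.A.set_size(ntot, max_cycles + 1);
  }
  tr.S.col(0).zeros();
  tr.A.col(0).fill(0.5);
  tr.phase_of_cycle.assign(max_cycles + 1, 0);
  tr.cycle_in_phase.assign(max_cycles + 1, 0);
  tr.n_error_cycles = 0;
  tr.error = 0.0;

  vec s = arma::zeros<vec>(ntot);
  vec a = tr.A.col(0);
  int t = 0;  // stored column index of the current state

  for (size_t pi = 0; pi < phases.size(); ++pi) {
    Phase& ph = phases[pi];
    ph.stop_cycle = ph.n_cycles;
    // External inputs apply from the start of their window: the hard
    // retinotopic clamp overwrites the window-start state (stimulus onset),
    // and at trial start the verbal soft clamp blends the initial output.
    // Window-start states are externally fixed, so no gradient flows
    // through them (two-phase trials are evaluation-only).
    if (ph.has_ret) {
      a.subvec(r0, r0 + nr - 1) = ph.ret_ext;
      tr.A.col(t).subvec(r0, r0 + nr - 1) = ph.ret_ext;
    }
    if (pi == 0 && ph.has_verb) {
      for (int i = 0; i < nl; ++i)
        if (ph.verb_mask[i] > 0.5)
          a[l0 + i] += par.gain * (ph.verb_ext[i] - a[l0 + i]);
      tr.A.col(t).subvec(l0, l0 + nl - 1) = a.subvec(l0, l0 + nl - 1);
    }
    for (int c = 1; c <= ph.n_cycles; ++c) {
      // One synchronous update: every layer's summed input uses the
      // previous cycle's activations, then s_t = s_{t-1} + eps *
      // (net_t - s_{t-1}) and a = logistic(s).
      vec net_h = net.b_h;
      net_h += net.W_rh.t() * a.subvec(r0, r0 + nr - 1);
      net_h += net.W_vh.t() * a.subvec(v0, v0 + nv - 1);
      net_h += net.W_lh.t() * a.subvec(l0, l0 + nl - 1);
      if (use_noise && par.noise_sd > 0)
        for (int i = 0; i < nh; ++i) net_h[i] += R::rnorm(0.0, par.noise_sd);
      vec net_v = net.b_v; net_v += net.W_hv.t() * a.subvec(h0, h0 + nh - 1);
      vec net_l = net.b_l; net_l += net.W_hl.t() * a.subvec(h0, h0 + nh - 1);

      for (int i = 0; i < nh; ++i)
        s[h0 + i] += par.eps * (net_h[i] - s[h0 + i]);
      for (int i = 0; i < nv; ++i)
        s[v0 + i] += par.eps * (net_v[i] - s[v0 + i]);
      for (int i = 0; i < nl; ++i)
        s[l0 + i] += par.eps * (net_l[i] - s[l0 + i]);
      a.subvec(h0, h0 + nh - 1) =
        1.0 / (1.0 + arma::exp(-s.subvec(h0, h0 + nh - 1)));
      a.subvec(v0, v0 + nv - 1) =
        1.0 / (1.0 + arma::exp(-s.subvec(v0, v0 + nv - 1)));
      a.subvec(l0, l0 + nl - 1) =
        1.0 / (1.0 + arma::exp(-s.subvec(l0, l0 + nl - 1)));

      // clamping: retinotopic hard (its net input is then irrelevant and
      // skipped), verbal soft (convex blend toward ext)
      if (ph.has_ret) {
        a.subvec(r0, r0 + nr - 1) = ph.ret_ext;
      } else {
        vec net_r = net.b_r; net_r += net.W_hr.t() * a.subvec(h0, h0 + nh - 1);
        for (int i = 0; i < nr; ++i)
          s[r0 + i] += par.eps * (net_r[i] - s[r0 + i]);
        a.subvec(r0, r0 + nr - 1) =
          1.0 / (1.0 + arma::exp(-s.subvec(r0, r0 + nr - 1)));
      }
      if (ph.has_verb)
        for (int i = 0; i < nl; ++i)
          if (ph.verb_mask[i] > 0.5)
            a[l0 + i] += par.gain * (ph.verb_ext[i] - a[l0 + i]);

      if (!a.is_finite() || !s.is_finite())
        stop("non-finite network state at cycle %d", t + 1);

      ++t;
      tr.S.col(t) = s;
      tr.A.col(t) = a;
      tr.phase_of_cycle[t] = (int)pi + 1;
      tr.cycle_in_phase[t] = c;

      if (ph.target_layer > 0) {
        int o0 = (ph.target_layer == 1) ? v0 : l0;
        int no = (ph.target_layer == 1) ? nv : nl;
        bool within = true;
        double e = 0.0;
        for (int i = 0; i < no; ++i) {
          double av = a[o0 + i];
          double T = ph.target[i];
          if (std::abs(av - T) >= par.stop_thr) within = false;
          double ag = std::min(std::max(av, par.guard), 1.0 - par.guard);
          e += -T * std::log(ag) - (1.0 - T) * std::log(1.0 - ag);
        }
        if (c >= par.err_start) {
          tr.error += e;
          ++tr.n_error_cycles;
        }
        if (within) {
          ph.stop_cycle = c;
          break;
        }
      }
    }
  }
  if (par.err_mean && tr.n_error_cycles > 0)
    tr.error /= tr.n_error_cycles;
  tr.n_cycles_total = t;
  tr.phase_of_cycle.resize(t + 1);
  tr.cycle_in_phase.resize(t + 1);
}

// rank-1 accumulation G += eps * x * y' without forming the outer product
static inline void add_outer(mat& G, const double* x, int nx,
                             const double* y, int ny, double eps) {
  for (int j = 0; j < ny; ++j) {
    double d = eps * y[j];
    if (d == 0.0) continue;
    double* col = G.colptr(j);
    for (int i = 0; i < nx; ++i) col[i] += d * x[i];
  }
}

// BPTT over the stored trajectory: gradients of the summed per-cycle
// cross-entropy (error injected every cycle of a target phase through its
// stop cycle) with the zero-error radius masking per unit and cycle.
static void zero_like(const Net& net, Net& g) {
  g.W_rh.zeros(net.nr, net.nh); g.W_vh.zeros(net.nv, net.nh);
  g.W_lh.zeros(net.nl, net.nh);
  g.W_hr.zeros(net.nh, net.nr); g.W_hv.zeros(net.nh, net.nv);
  g.W_hl.zeros(net.nh, net.nl);
  g.b_h.zeros(net.nh); g.b_r.zeros(net.nr); g.b_v.zeros(net.nv);
  g.b_l.zeros(net.nl);
  g.nr = net.nr; g.nv = net.nv; g.nl = net.nl; g.nh = net.nh;
}

static void backward(const Net& net, const std::vector<Phase>& phases,
                     const Params& par, const Trace& tr, Net& g) {
  const int nr = net.nr, nv = net.nv, nl = net.nl, nh = net.nh;
  const int r0 = 0, v0 = nr, l0 = nr + nv, h0 = nr + nv + nl;
  zero_like(net, g);

  vec ds_next = arma::zeros<vec>(nr + nv + nl + nh);
  vec da(nr + nv + nl + nh), ds(nr + nv + nl + nh);

  for (int t = tr.n_cycles_total; t >= 1; --t) {
    const Phase& ph = phases[tr.phase_of_cycle[t] - 1];
    da.zeros();

    if (ph.target_layer > 0 && tr.cycle_in_phase[t] >= par.err_start) {
      int o0 = (ph.target_layer == 1) ? v0 : l0;
      int no = (ph.target_layer == 1) ? nv : nl;
      double escale = (par.err_mean && tr.n_error_cycles > 0)
                        ? 1.0 / tr.n_error_cycles : 1.0;
      for (int i = 0; i < no; ++i) {
        double a = tr.A(o0 + i, t);
        double T = ph.target[i];
        if (std::abs(a - T) > par.radius) {
          double ag = std::min(std::max(a, par.guard), 1.0 - par.guard);
          da[o0 + i] += escale * (ag - T) / (ag * (1.0 - ag));
        }
      }
    }

    // activations at t feed the net inputs at t+1; the hard-clamped
    // retinotopic layer has zero ds, so its paths are skipped
    if (t < tr.n_cycles_total) {
      vec dsn_h = ds_next.subvec(h0, h0 + nh - 1);
      if (!ph.has_ret)
        da.subvec(r0, r0 + nr - 1) += par.eps * (net.W_rh * dsn_h);
      da.subvec(v0, v0 + nv - 1) += par.eps * (net.W_vh * dsn_h);
      da.subvec(l0, l0 + nl - 1) += par.eps * (net.W_lh * dsn_h);
      vec dah = net.W_hv * ds_next.subvec(v0, v0 + nv - 1) +
                net.W_hl * ds_next.subvec(l0, l0 + nl - 1);
      if (!ph.has_ret)
        dah += net.W_hr * ds_next.subvec(r0, r0 + nr - 1);
      da.subvec(h0, h0 + nh - 1) += par.eps * dah;
    }

    // d a / d s: logistic slope times the clamp attenuation factor,
    // then ds_t = da * f * slope + (1 - eps) * ds_{t+1}
    const double* sc = tr.S.colptr(t);
    const int ntot = nr + nv + nl + nh;
    for (int i = 0; i < ntot; ++i) {
      double ai = 1.0 / (1.0 + std::exp(-sc[i]));
      double f = 1.0;
      if (ph.has_ret && i >= r0 && i < r0 + nr) f = 0.0;
      if (ph.has_verb && i >= l0 && i < l0 + nl &&
          ph.verb_mask[i - l0] > 0.5) f = 1.0 - par.gain;
      ds[i] = da[i] * f * ai * (1.0 - ai) + (1.0 - par.eps) * ds_next[i];
    }

    const double* a_prev = tr.A.colptr(t - 1);
    const double* dsp = ds.memptr();
    add_outer(g.W_rh, a_prev + r0, nr, dsp + h0, nh, par.eps);
    add_outer(g.W_vh, a_prev + v0, nv, dsp + h0, nh, par.eps);
    add_outer(g.W_lh, a_prev + l0, nl, dsp + h0, nh, par.eps);
    if (!ph.has_ret) {
      add_outer(g.W_hr, a_prev + h0, nh, dsp + r0, nr, par.eps);
      g.b_r += par.eps * ds.subvec(r0, r0 + nr - 1);
    }
    add_outer(g.W_hv, a_prev + h0, nh, dsp + v0, nv, par.eps);
    add_outer(g.W_hl, a_prev + h0, nh, dsp + l0, nl, par.eps);
    g.b_h += par.eps * ds.subvec(h0, h0 + nh - 1);
    g.b_v += par.eps * ds.subvec(v0, v0 + nv - 1);
    g.b_l += par.eps * ds.subvec(l0, l0 + nl - 1);

    ds_next = ds;
  }

  if (!g.W_rh.is_finite() || !g.W_vh.is_finite() || !g.W_lh.is_finite() ||
      !g.W_hr.is_finite() || !g.W_hv.is_finite() || !g.W_hl.is_finite())
    stop("non-finite BPTT gradient");
}

// w <- w - lr * grad - decay * w, fused in one pass without temporaries
static inline void axpy_update(double* w, const double* g, int n,
                               double lr, double decay) {
  double keep = 1.0 - decay;
  for (int i = 0; i < n; ++i) w[i] = keep * w[i] - lr * g[i];
}

static void apply_update(Net& net, const Net& g, const Params& par) {
  axpy_update(net.W_rh.memptr(), g.W_rh.memptr(), net.W_rh.n_elem, par.lr, par.decay);
  axpy_update(net.W_vh.memptr(), g.W_vh.memptr(), net.W_vh.n_elem, par.lr, par.decay);
  axpy_update(net.W_lh.memptr(), g.W_lh.memptr(), net.W_lh.n_elem, par.lr, par.decay);
  axpy_update(net.W_hr.memptr(), g.W_hr.memptr(), net.W_hr.n_elem, par.lr, par.decay);
  axpy_update(net.W_hv.memptr(), g.W_hv.memptr(), net.W_hv.n_elem, par.lr, par.decay);
  axpy_update(net.W_hl.memptr(), g.W_hl.memptr(), net.W_hl.n_elem, par.lr, par.decay);
  axpy_update(net.b_h.memptr(), g.b_h.memptr(), net.b_h.n_elem, par.lr, par.decay);
  axpy_update(net.b_r.memptr(), g.b_r.memptr(), net.b_r.n_elem, par.lr, par.decay);
  axpy_update(net.b_v.memptr(), g.b_v.memptr(), net.b_v.n_elem, par.lr, par.decay);
  axpy_update(net.b_l.memptr(), g.b_l.memptr(), net.b_l.n_elem, par.lr, par.decay);
}

// [[Rcpp::export]]
List run_trial_cpp(List weights, List phases, List params,
                   bool use_noise = false, bool want_gradient = false) {
  Net net = read_net(weights);
  Params par = read_params(params);
  std::vector<Phase> phs = read_phases(phases, net);
  Trace tr;
  forward(net, phs, par, use_noise, tr);
  tr.S.resize(tr.S.n_rows, tr.n_cycles_total + 1);
  tr.A.resize(tr.A.n_rows, tr.n_cycles_total + 1);

  IntegerVector stop_cycles(phs.size());
  for (size_t i = 0; i < phs.size(); ++i) stop_cycles[i] = phs[i].stop_cycle;

  List out = List::create(
    _["S"] = tr.S, _["A"] = tr.A,
    _["phase_of_cycle"] = IntegerVector(tr.phase_of_cycle.begin(),
                                        tr.phase_of_cycle.end()),
    _["stop_cycles"] = stop_cycles,
    _["n_cycles"] = tr.n_cycles_total,
    _["error"] = tr.error);
  if (want_gradient) {
    Net g;
    backward(net, phs, par, tr, g);
    out["gradient"] = net_to_list(g);
  }
  return out;
}

// Build the single training phase for one (item, task) trial.
// task: 1 = visual recognition, 2 = verbalization, 3 = mental imagery.
static Phase task_phase(int task, int item0, const mat& RET, const mat& VIS,
                        const mat& VERB, const Params& par) {
  Phase ph;
  ph.n_cycles = par.cycles;
  ph.has_ret = (task == 1 || task == 2);
  if (ph.has_ret) ph.ret_ext = RET.col(item0);
  ph.has_verb = (task == 3);
  if (ph.has_verb) {
    // only the item's active label units receive external input (of 1.0),
    // exactly as in the verbalization conditions; inactive partners float
    ph.verb_mask = vec(VERB.col(item0));
    ph.verb_ext = arma::ones<vec>(VERB.n_rows);
  }
  ph.target_layer = (task == 2) ? 2 : 1;
  ph.target = (task == 2) ? vec(VERB.col(item0)) : vec(VIS.col(item0));
  ph.stop_cycle = 0;
  return ph;
}

// Run a whole schedule of training trials with per-trial weight updates.
// items is 1-based; RET/VIS/VERB hold one item per column (connected units
// only). Hidden-layer input noise is drawn from R's RNG.
// [[Rcpp::export]]
List train_schedule_cpp(List weights, arma::mat RET, arma::mat VIS,
                        arma::mat VERB, IntegerVector items,
                        IntegerVector tasks, List params,
                        bool use_noise = true) {
  Net net = read_net(weights);
  Params par = read_params(params);
  int n = items.size();
  NumericVector err(n);
  IntegerVector stop(n);
  Trace tr;
  Net g;
  for (int k = 0; k < n; ++k) {
    std::vector<Phase> phs(1, task_phase(tasks[k], items[k] - 1, RET, VIS,
                                         VERB, par));
    forward(net, phs, par, use_noise, tr);
    backward(net, phs, par, tr, g);
    apply_update(net, g, par);
    err[k] = tr.error;
    stop[k] = phs[0].stop_cycle;
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(net), _["error"] = err,
                      _["stop_cycle"] = stop);
}

// Final-cycle visual-image activations for a batch of evaluation trials
// (noise off, no target, full cycle count). Each column of the result is
// the visual layer state at the last cycle for one item. Used for
// nearest-neighbour scoring and polarity measurement. verb_sel: per item a
// 0/1 column marking which verbal units are externally activated (value
// 1.0, soft clamp); pre_cycles > 0 inserts a verbalization-only phase
// before retinotopic onset; maintain keeps the verbal clamp during the
// recognition phase.
// [[Rcpp::export]]
arma::mat eval_visual_cpp(List weights, arma::mat RET, IntegerVector items,
                          List params, Nullable<NumericMatrix> verb_sel_,
                          int pre_cycles = 0, bool maintain = true,
                          bool with_ret = true) {
  Net net = read_net(weights);
  Params par = read_params(params);
  mat out(net.nv, items.size());
  Trace tr;
  bool has_verb = verb_sel_.isNotNull();
  mat verb_sel;
  if (has_verb) verb_sel = as<mat>(NumericMatrix(verb_sel_));
  for (int k = 0; k < items.size(); ++k) {
    std::vector<Phase> phs;
    if (pre_cycles > 0) {
      Phase ph0;
      ph0.n_cycles = pre_cycles;
      ph0.has_ret = false;
      ph0.has_verb = has_verb;
      if (has_verb) {
        ph0.verb_mask = verb_sel.col(k);
        ph0.verb_ext = arma::ones<vec>(net.nl);
      }
      ph0.target_layer = 0;
      ph0.stop_cycle = 0;
      phs.push_back(ph0);
    }
    Phase ph;
    ph.n_cycles = par.cycles;
    ph.has_ret = with_ret;
    if (with_ret) ph.ret_ext = RET.col(items[k] - 1);
    ph.has_verb = has_verb && (pre_cycles == 0 || maintain);
    if (ph.has_verb) {
      ph.verb_mask = verb_sel.col(k);
      ph.verb_ext = arma::ones<vec>(net.nl);
    }
    ph.target_layer = 0;
    ph.stop_cycle = 0;
    phs.push_back(ph);
    forward(net, phs, par, false, tr);
    out.col(k) = tr.A.submat(net.nr, tr.n_cycles_total,
                             net.nr + net.nv - 1, tr.n_cycles_total);
  }
  return out;
}
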