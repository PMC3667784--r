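#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
using namespace Rcpp;

// Mass-action / insertion right-hand side.
// Reaction types: 0 = mass action (rate k*[r1] or k*[r1][r2]; r1==r2 gives
// k*[r1]^2 under the collision-counting convention, the statistical factor
// being carried by the stoichiometry), 1 = saturating insertion with rate
// k * max(MF0 - sum(o_w * y[o_idx]), 0).
static inline void rhs_eval(const double *y, double *dy, int ns,
                            const double *k, const int *r1, const int *r2,
                            const int *type,
                            const int *s_off, const int *s_idx, const double *s_del,
                            const int *o_off, const int *o_idx, const double *o_w,
                            const double *mf0,
                            const int *ridx, int nr) {
  for (int s = 0; s < ns; ++s) dy[s] = 0.0;
  for (int jj = 0; jj < nr; ++jj) {
    const int j = ridx[jj];
    double v;
    if (type[j] == 1) {
      double occ = 0.0;
      for (int q = o_off[j]; q < o_off[j + 1]; ++q) occ += o_w[q] * y[o_idx[q]];
      double freeSites = mf0[j] - occ;
      v = freeSites > 0.0 ? k[j] * freeSites : 0.0;
    } else {
      v = k[j];
      if (r1[j] >= 0) v *= y[r1[j]];
      if (r2[j] >= 0) v *= y[r2[j]];
    }
    for (int q = s_off[j]; q < s_off[j + 1]; ++q) dy[s_idx[q]] += s_del[q] * v;
  }
}

struct CNet {
  int ns, nr;
  std::vector<double> k, s_del, o_w, mf0;
  std::vector<int> r1, r2, type, embed, s_off, s_idx, o_off, o_idx;
  std::vector<int> all_idx, everywhere_idx;
  CNet(List cn) {
    ns = as<int>(cn["n_species"]);
    k = as<std::vector<double> >(cn["k"]);
    r1 = as<std::vector<int> >(cn["r1"]);
    r2 = as<std::vector<int> >(cn["r2"]);
    type = as<std::vector<int> >(cn["type"]);
    embed = as<std::vector<int> >(cn["embed"]);
    s_off = as<std::vector<int> >(cn["s_off"]);
    s_idx = as<std::vector<int> >(cn["s_idx"]);
    s_del = as<std::vector<double> >(cn["s_del"]);
    o_off = as<std::vector<int> >(cn["o_off"]);
    o_idx = as<std::vector<int> >(cn["o_idx"]);
    o_w = as<std::vector<double> >(cn["o_w"]);
    mf0 = as<std::vector<double> >(cn["mf0"]);
    nr = (int) k.size();
    for (int j = 0; j < nr; ++j) {
      all_idx.push_back(j);
      if (embed[j] == 0) everywhere_idx.push_back(j);
    }
  }
};

static inline void rk4_step(std::vector<double> &y, double dt, const CNet &net,
                            const int *ridx, int nr,
                            std::vector<double> &k1, std::vector<double> &k2,
                            std::vector<double> &k3, std::vector<double> &k4,
                            std::vector<double> &tmp) {
  const int ns = net.ns;
  rhs_eval(y.data(), k1.data(), ns, net.k.data(), net.r1.data(), net.r2.data(),
           net.type.data(), net.s_off.data(), net.s_idx.data(), net.s_del.data(),
           net.o_off.data(), net.o_idx.data(), net.o_w.data(), net.mf0.data(), ridx, nr);
  for (int s = 0; s < ns; ++s) tmp[s] = y[s] + 0.5 * dt * k1[s];
  rhs_eval(tmp.data(), k2.data(), ns, net.k.data(), net.r1.data(), net.r2.data(),
           net.type.data(), net.s_off.data(), net.s_idx.data(), net.s_del.data(),
           net.o_off.data(), net.o_idx.data(), net.o_w.data(), net.mf0.data(), ridx, nr);
  for (int s = 0; s < ns; ++s) tmp[s] = y[s] + 0.5 * dt * k2[s];
  rhs_eval(tmp.data(), k3.data(), ns, net.k.data(), net.r1.data(), net.r2.data(),
           net.type.data(), net.s_off.data(), net.s_idx.data(), net.s_del.data(),
           net.o_off.data(), net.o_idx.data(), net.o_w.data(), net.mf0.data(), ridx, nr);
  for (int s = 0; s < ns; ++s) tmp[s] = y[s] + dt * k3[s];
  rhs_eval(tmp.data(), k4.data(), ns, net.k.data(), net.r1.data(), net.r2.data(),
           net.type.data(), net.s_off.data(), net.s_idx.data(), net.s_del.data(),
           net.o_off.data(), net.o_idx.data(), net.o_w.data(), net.mf0.data(), ridx, nr);
  for (int s = 0; s < ns; ++s)
    y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
}

static void check_finite(const std::vector<double> &y, double t, CharacterVector nm) {
  for (size_t s = 0; s < y.size(); ++s) {
    if (!std::isfinite(y[s])) {
      std::ostringstream msg;
      msg << "integration blow-up at t = " << t << " s in species '"
          << as<std::string>(nm[s]) << "' (non-finite state); reduce dt";
      stop(msg.str());
    }
  }
}

// [[Rcpp::export(name = ".rk4_core")]]
List rk4_core(NumericVector y0, double t0, double t_end, double dt, int out_stride,
              List cnet, CharacterVector species_names,
              NumericVector e_time, NumericVector e_amount, NumericVector e_mf0,
              IntegerVector e_ooff, IntegerVector e_oidx, NumericVector e_ow,
              IntegerVector e_doff, IntegerVector e_didx, NumericVector e_ddel,
              IntegerVector clamp_idx, NumericVector clamp_val) {
  CNet net(cnet);
  const int ns = net.ns;
  std::vector<double> y = as<std::vector<double> >(y0);
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  const int nE = e_time.size();
  NumericVector applied(nE);

  std::vector<double> out_t;
  std::vector<double> out_y;
  long step_count = 0;

  const double eps = 1e-9;
  double t = t0;
  int ie = 0;

  // apply any events scheduled at or before t0, clamp, then record start
  for (int ci = 0; ci < clamp_idx.size(); ++ci) y[clamp_idx[ci]] = clamp_val[ci];
  while (ie < nE && e_time[ie] <= t0 + eps) {
    double amt = e_amount[ie];
    if (e_mf0[ie] > 0) {
      double occ = 0.0;
      for (int q = e_ooff[ie]; q < e_ooff[ie + 1]; ++q) occ += e_ow[q] * y[e_oidx[q]];
      double freeSites = e_mf0[ie] - occ;
      if (freeSites < 0) freeSites = 0;
      if (amt > freeSites) amt = freeSites;
    }
    applied[ie] = amt;
    for (int q = e_doff[ie]; q < e_doff[ie + 1]; ++q) y[e_didx[q]] += amt * e_ddel[q];
    for (int ci = 0; ci < clamp_idx.size(); ++ci) y[clamp_idx[ci]] = clamp_val[ci];
    ++ie;
  }
  out_t.push_back(t);
  for (int s = 0; s < ns; ++s) out_y.push_back(y[s]);

  while (t < t_end - eps) {
    double seg_end = (ie < nE && e_time[ie] < t_end) ? e_time[ie] : t_end;
    long n_full = (long) std::floor((seg_end - t) / dt + eps);
    for (long i = 0; i < n_full; ++i) {
      rk4_step(y, dt, net, net.all_idx.data(), net.nr, k1, k2, k3, k4, tmp);
      t += dt;
      for (int ci = 0; ci < clamp_idx.size(); ++ci) y[clamp_idx[ci]] = clamp_val[ci];
      ++step_count;
      if ((step_count & 255) == 0) check_finite(y, t, species_names);
      if (step_count % out_stride == 0) {
        out_t.push_back(t);
        for (int s = 0; s < ns; ++s) out_y.push_back(y[s]);
      }
    }
    double rem = seg_end - t;
    if (rem > eps) {
      rk4_step(y, rem, net, net.all_idx.data(), net.nr, k1, k2, k3, k4, tmp);
      t = seg_end;
      for (int ci = 0; ci < clamp_idx.size(); ++ci) y[clamp_idx[ci]] = clamp_val[ci];
      ++step_count;
      if (step_count % out_stride == 0) {
        out_t.push_back(t);
        for (int s = 0; s < ns; ++s) out_y.push_back(y[s]);
      }
    } else {
      t = seg_end;
    }

    // events due at the segment boundary
    while (ie < nE && e_time[ie] <= t + eps) {
      double amt = e_amount[ie];
      if (e_mf0[ie] > 0) {
        double occ = 0.0;
        for (int q = e_ooff[ie]; q < e_ooff[ie + 1]; ++q) occ += e_ow[q] * y[e_oidx[q]];
        double freeSites = e_mf0[ie] - occ;
        if (freeSites < 0) freeSites = 0;
        if (amt > freeSites) amt = freeSites;
      }
      applied[ie] = amt;
      for (int q = e_doff[ie]; q < e_doff[ie + 1]; ++q) y[e_didx[q]] += amt * e_ddel[q];
      for (int ci = 0; ci < clamp_idx.size(); ++ci) y[clamp_idx[ci]] = clamp_val[ci];
      ++ie;
    }
    if (t >= t_end - eps && out_t.back() < t - eps) {
      out_t.push_back(t);
      for (int s = 0; s < ns; ++s) out_y.push_back(y[s]);
    }
  }

  check_finite(y, t, species_names);
  const int nt = (int) out_t.size();
  NumericMatrix states(nt, ns);
  for (int i = 0; i < nt; ++i)
    for (int s = 0; s < ns; ++s) {
      double v = out_y[(size_t) i * ns + s];
      if (v < 0 && v > -1e-6) v = 0.0;  // integrator-tolerance clamp on output
      states(i, s) = v;
    }
  return List::create(_["times"] = wrap(out_t), _["states"] = states,
                      _["applied"] = applied);
}

// Reaction-diffusion stepper: operator-split RK4 chemistry per compartment,
// explicit FTCS diffusion substeps with zero-flux (closed) boundaries on a
// nx x ny x 1 lattice. State layout: matrix ns x ncomp (species fastest).
// [[Rcpp::export(name = ".spatial_core")]]
List spatial_core(NumericMatrix y0, int nx, int ny, IntegerVector mask,
                  List cnet, CharacterVector species_names,
                  IntegerVector diff_idx, NumericVector Dcoef, double h,
                  double dt, int nsub, double t_end,
                  int trace_stride, IntegerVector snap_steps,
                  NumericVector e_time, NumericVector e_amount, NumericVector e_mf0,
                  IntegerVector e_ooff, IntegerVector e_oidx, NumericVector e_ow,
                  IntegerVector e_doff, IntegerVector e_didx, NumericVector e_ddel) {
  CNet net(cnet);
  const int ns = net.ns;
  const int ncomp = nx * ny;
  if (y0.nrow() != ns || y0.ncol() != ncomp) stop("field dimensions do not match network/grid");
  std::vector<double> Y(y0.begin(), y0.end());
  std::vector<char> in_mask(ncomp, 0);
  for (int i = 0; i < mask.size(); ++i) in_mask[mask[i]] = 1;

  const int nd = diff_idx.size();
  std::vector<double> alpha(nd);
  const double dt_sub = dt / nsub;
  for (int d = 0; d < nd; ++d) alpha[d] = Dcoef[d] * dt_sub / (h * h);

  std::vector<double> yloc(ns), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  std::vector<double> buf(ncomp);

  const long nsteps = (long) std::llround(t_end / dt);
  std::vector<double> trace_t;
  std::vector<double> trace_v;       // ns values per record: mask mean
  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_t;
  int ie = 0;
  const int nE = e_time.size();
  NumericVector applied(nE);
  const int nmask = mask.size();

  auto record_trace = [&](double t) {
    trace_t.push_back(t);
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      for (int m = 0; m < nmask; ++m) acc += Y[(size_t) mask[m] * ns + s];
      trace_v.push_back(acc / nmask);
    }
  };
  auto apply_events = [&](double t) {
    while (ie < nE && e_time[ie] <= t + 1e-9) {
      double tot = 0.0;
      for (int m = 0; m < nmask; ++m) {
        double *yc = &Y[(size_t) mask[m] * ns];
        double amt = e_amount[ie];
        if (e_mf0[ie] > 0) {
          double occ = 0.0;
          for (int q = e_ooff[ie]; q < e_ooff[ie + 1]; ++q) occ += e_ow[q] * yc[e_oidx[q]];
          double freeSites = e_mf0[ie] - occ;
          if (freeSites < 0) freeSites = 0;
          if (amt > freeSites) amt = freeSites;
        }
        for (int q = e_doff[ie]; q < e_doff[ie + 1]; ++q) yc[e_didx[q]] += amt * e_ddel[q];
        tot += amt;
      }
      applied[ie] = tot / nmask;
      ++ie;
    }
  };

  apply_events(0.0);
  record_trace(0.0);
  size_t next_snap = 0;
  std::vector<int> snap_sorted(snap_steps.begin(), snap_steps.end());
  if (next_snap < snap_sorted.size() && snap_sorted[next_snap] == 0) {
    NumericMatrix sn(ns, ncomp);
    std::copy(Y.begin(), Y.end(), sn.begin());
    snaps.push_back(sn); snap_t.push_back(0.0); ++next_snap;
  }

  for (long step = 1; step <= nsteps; ++step) {
    // chemistry
    for (int c = 0; c < ncomp; ++c) {
      const int *ridx = in_mask[c] ? net.all_idx.data() : net.everywhere_idx.data();
      const int nr = in_mask[c] ? (int) net.all_idx.size() : (int) net.everywhere_idx.size();
      if (nr == 0) continue;
      double *yc = &Y[(size_t) c * ns];
      std::copy(yc, yc + ns, yloc.begin());
      rk4_step(yloc, dt, net, ridx, nr, k1, k2, k3, k4, tmp);
      std::copy(yloc.begin(), yloc.end(), yc);
    }
    // diffusion substeps
    for (int sub = 0; sub < nsub; ++sub) {
      for (int d = 0; d < nd; ++d) {
        if (alpha[d] == 0.0) continue;
        const int s = diff_idx[d];
        for (int c = 0; c < ncomp; ++c) buf[c] = Y[(size_t) c * ns + s];
        for (int iy = 0; iy < ny; ++iy) {
          for (int ix = 0; ix < nx; ++ix) {
            const int c = iy * nx + ix;
            double lap = 0.0;
            const double yc = buf[c];
            if (ix > 0)      lap += buf[c - 1] - yc;
            if (ix < nx - 1) lap += buf[c + 1] - yc;
            if (iy > 0)      lap += buf[c - nx] - yc;
            if (iy < ny - 1) lap += buf[c + nx] - yc;
            Y[(size_t) c * ns + s] = yc + alpha[d] * lap;
          }
        }
      }
    }
    double t = step * dt;
    apply_events(t);
    if (step % trace_stride == 0 || step == nsteps) record_trace(t);
    if (next_snap < snap_sorted.size() && snap_sorted[next_snap] == step) {
      NumericMatrix sn(ns, ncomp);
      for (size_t q = 0; q < Y.size(); ++q) {
        double v = Y[q];
        sn[q] = (v < 0 && v > -1e-6) ? 0.0 : v;
      }
      snaps.push_back(sn); snap_t.push_back(t); ++next_snap;
    }
    if (step % 256 == 0) {
      for (int c = 0; c < ncomp; c += 97)
        if (!std::isfinite(Y[(size_t) c * ns])) {
          std::ostringstream msg;
          msg << "reaction-diffusion blow-up at t = " << t << " s (compartment " << c << ")";
          stop(msg.str());
        }
    }
  }

  const int ntr = (int) trace_t.size();
  NumericMatrix trace(ntr, ns);
  for (int i = 0; i < ntr; ++i)
    for (int s = 0; s < ns; ++s) {
      double v = trace_v[(size_t) i * ns + s];
      trace(i, s) = (v < 0 && v > -1e-6) ? 0.0 : v;
    }
  List snl(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snl[i] = snaps[i];
  return List::create(_["trace_times"] = wrap(trace_t), _["trace"] = trace,
                      _["snap_times"] = wrap(snap_t), _["snaps"] = snl,
                      _["applied"] = applied);
}
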