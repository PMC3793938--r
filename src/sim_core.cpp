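// Compiled daily-step core of the grass growth simulator.
//
// This mirrors, operation for operation, the reference R implementation
// in R/simulate.R (step_day) and the process functions it composes; a
// test asserts numerical agreement between the two engines on multi-year
// runs.  Keep the arithmetic in the same order as the R code.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double ldmc, l0, phyllochron, td0;
  double leaf_thickness, leaf_width, leaf_form, sheath_ratio;
  double height_shape, height_dens_exp, t_expand;
  double c_struct, n_struct, n_protein;
  double amax_protein, eps_light, k_ext, theta_colim;
  double umax, km, sra, root_max_length, root_lin_density, root_lifespan;
  double tiller_app_rate, tiller_sen_rate, lai_crit, td_min, plant_density;
  double r_maint, q10, temp_ref, t_base, y_growth, g_max, kc, kn;
  double p_ref, p_min, p_max, tau_p, tau_q, q_min;
  double protein_turnover, remob_frac, store_frac, res_remob_rate;
  double exud_frac, cn_target;
  double c_inh, n_inh, inh_hill;
  double mineralization, leach_rate;
};

Params unpack(const List& p) {
  Params q;
  q.ldmc = p["ldmc"]; q.l0 = p["l0"]; q.phyllochron = p["phyllochron"];
  q.td0 = p["td0"];
  q.leaf_thickness = p["leaf_thickness"]; q.leaf_width = p["leaf_width"];
  q.leaf_form = p["leaf_form"]; q.sheath_ratio = p["sheath_ratio"];
  q.height_shape = p["height_shape"]; q.height_dens_exp = p["height_dens_exp"];
  q.t_expand = p["t_expand"];
  q.c_struct = p["c_struct"]; q.n_struct = p["n_struct"]; q.n_protein = p["n_protein"];
  q.amax_protein = p["amax_protein"]; q.eps_light = p["eps_light"];
  q.k_ext = p["k_ext"]; q.theta_colim = p["theta_colim"];
  q.umax = p["umax"]; q.km = p["km"]; q.sra = p["sra"];
  q.root_max_length = p["root_max_length"]; q.root_lin_density = p["root_lin_density"];
  q.root_lifespan = p["root_lifespan"];
  q.tiller_app_rate = p["tiller_app_rate"]; q.tiller_sen_rate = p["tiller_sen_rate"];
  q.lai_crit = p["lai_crit"]; q.td_min = p["td_min"]; q.plant_density = p["plant_density"];
  q.r_maint = p["r_maint"]; q.q10 = p["q10"]; q.temp_ref = p["temp_ref"];
  q.t_base = p["t_base"]; q.y_growth = p["y_growth"]; q.g_max = p["g_max"];
  q.kc = p["kc"]; q.kn = p["kn"];
  q.p_ref = p["p_ref"]; q.p_min = p["p_min"]; q.p_max = p["p_max"];
  q.tau_p = p["tau_p"]; q.tau_q = p["tau_q"]; q.q_min = p["q_min"];
  q.protein_turnover = p["protein_turnover"]; q.remob_frac = p["remob_frac"];
  q.store_frac = p["store_frac"]; q.res_remob_rate = p["res_remob_rate"];
  q.exud_frac = p["exud_frac"];
  q.cn_target = p["cn_target"];
  q.c_inh = p["c_inh"]; q.n_inh = p["n_inh"]; q.inh_hill = p["inh_hill"];
  q.mineralization = p["mineralization"]; q.leach_rate = p["leach_rate"];
  return q;
}

struct State {
  double wc, wn, res_c, res_n, w_root, w_protein;
  std::vector<double> leaf_len, leaf_age;
  double td, p, q, soil_n, tt, tt_leaf;
};

inline double lamina_mass_per_cm(const Params& pm) {
  return pm.leaf_form * pm.leaf_width * pm.leaf_thickness * pm.ldmc;
}

inline double leaf_area_sum(const State& s, const Params& pm) {
  long double a = 0.0L;
  for (double len : s.leaf_len) a += pm.leaf_form * pm.leaf_width * len;
  return (double)a;
}

inline double shoot_mass(const State& s, const Params& pm) {
  return (1.0 + pm.sheath_ratio) * leaf_area_sum(s, pm) * pm.leaf_thickness * pm.ldmc;
}

inline double smooth_min(double a, double b, double theta) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  double ssum = a + b;
  double disc = ssum * ssum - 4.0 * theta * a * b;
  if (disc < 0.0) disc = 0.0;
  return (ssum - std::sqrt(disc)) / (2.0 * theta);
}

inline double erectness(double td, const Params& pm) {
  return pm.height_shape * std::pow(td / pm.td0, pm.height_dens_exp);
}

inline double plant_height(const State& s, const Params& pm) {
  if (s.leaf_len.empty()) return 0.0;
  double h_pot = pm.height_shape * pm.l0;
  double mx = 0.0;
  for (double len : s.leaf_len) if (len > mx) mx = len;
  double h = erectness(s.td, pm) * mx;
  return h < h_pot ? h : h_pot;
}

} // namespace

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List params, List state0, NumericVector par_v,
                  NumericVector temp_v, NumericVector fert_doy,
                  NumericVector cut_doy, int ndays) {
  Params pm = unpack(params);
  State s;
  s.wc = state0["wc"]; s.wn = state0["wn"];
  s.res_c = state0["res_c"]; s.res_n = state0["res_n"];
  s.w_root = state0["w_root"]; s.w_protein = state0["w_protein"];
  {
    NumericVector ll = state0["leaf_len"], la = state0["leaf_age"];
    s.leaf_len.assign(ll.begin(), ll.end());
    s.leaf_age.assign(la.begin(), la.end());
  }
  s.td = state0["td"]; s.p = state0["p"]; s.q = state0["q"];
  s.soil_n = state0["soil_n"]; s.tt = state0["tt"]; s.tt_leaf = state0["tt_leaf"];

  const int ncol = 37;
  NumericMatrix daily(ndays, ncol);
  const int ndrv = par_v.size();
  const double mpc = lamina_mass_per_cm(pm);

  for (int d = 0; d < ndays; ++d) {
    const int i = d % ndrv;
    const int doy = d % 365;
    const double par = par_v[i], temp = temp_v[i];
    if (!std::isfinite(par) || !std::isfinite(temp) || par < 0.0)
      stop("simulation failure on day %d: invalid driver", d + 1);

    // -- management (normalised order: cut, then fertilize) ----------
    double harvest_mass = 0.0, harvest_c = 0.0, harvest_n = 0.0;
    if (cut_doy[doy] >= 0.0) {
      double residual = cut_doy[doy];
      if (!s.leaf_len.empty()) {
        double er = erectness(s.td, pm);
        double area_before = leaf_area_sum(s, pm);
        long double removed_len = 0.0L;
        for (size_t k = 0; k < s.leaf_len.size(); ++k) {
          double tip = er * s.leaf_len[k];
          double frac = 0.0;
          if (tip > 0.0) {
            frac = (tip - residual) / tip;
            if (frac < 0.0) frac = 0.0;
            if (frac > 1.0) frac = 1.0;
          }
          removed_len += s.leaf_len[k] * frac;
          s.leaf_len[k] *= (1.0 - frac);
        }
        double removed_lam = (double)removed_len * mpc;
        double area_after = leaf_area_sum(s, pm);
        double area_removed = area_before - area_after;
        double removed_struct = removed_lam * (1.0 + pm.sheath_ratio);
        double prot_removed = area_before > 0.0
          ? s.w_protein * area_removed / area_before : 0.0;
        s.w_protein -= prot_removed;
        harvest_mass += removed_struct + prot_removed;
        harvest_c += (removed_struct + prot_removed) * pm.c_struct;
        harvest_n += removed_struct * pm.n_struct + prot_removed * pm.n_protein;
      }
    }
    if (fert_doy[doy] > 0.0) s.soil_n += fert_doy[doy];

    double d_tt = temp - pm.t_base; if (d_tt < 0.0) d_tt = 0.0;

    // -- canopy and resource capture ---------------------------------
    double area_ax = leaf_area_sum(s, pm);
    double lai = area_ax * 1e-4 * s.td;
    double f_int = 1.0 - std::exp(-pm.k_ext * lai);
    double par_int = s.td > 0.0 ? par * f_int / s.td : 0.0;
    double a_light = pm.eps_light * par_int;
    double f_pt = (temp > 0.0 ? temp : 0.0) / pm.temp_ref;
    if (f_pt > 1.25) f_pt = 1.25;
    double a_cap = pm.amax_protein * s.w_protein * f_pt;
    double w_shoot = shoot_mass(s, pm);
    double W0 = w_shoot + s.w_root + s.w_protein;
    double inh_c = 1.0, inh_n = 1.0;
    if (W0 > 0.0) {
      inh_c = 1.0 / (1.0 + std::pow(s.wc / (pm.c_inh * W0), pm.inh_hill));
      inh_n = 1.0 / (1.0 + std::pow(s.wn / (pm.n_inh * W0), pm.inh_hill));
    }
    double photo = smooth_min(a_light, a_cap, pm.theta_colim) * inh_c;
    double su = pm.umax * pm.sra * s.w_root * s.soil_n / (pm.km + s.soil_n);
    if (s.td > 0.0 && su > s.soil_n / s.td) su = s.soil_n / s.td;
    su *= inh_n;

    // -- reserve storage / remobilisation ----------------------------
    double wc_mid = s.wc + photo, wn_mid = s.wn + su;
    double store_c = 0.0, store_n = 0.0, remob_res_c = 0.0, remob_res_n = 0.0;
    double excess_c = wc_mid - pm.cn_target * wn_mid;
    if (excess_c > 0.0) store_c = pm.store_frac * excess_c;
    double excess_n = wn_mid - wc_mid / pm.cn_target;
    if (excess_n > 0.0) store_n = pm.store_frac * excess_n;
    remob_res_c = pm.res_remob_rate * s.res_c;
    remob_res_n = pm.res_remob_rate * s.res_n;
    double exud_c = pm.exud_frac * (excess_c > 0.0 ? excess_c : 0.0);
    double exud_n = pm.exud_frac * (excess_n > 0.0 ? excess_n : 0.0);

    // -- growth under substrate and sink control ---------------------
    double expand_tt = pm.t_expand * pm.phyllochron;
    double dlen_max = pm.l0 * d_tt / expand_tt;
    std::vector<double> cap_coh(s.leaf_len.size(), 0.0);
    long double cap_tot_l = 0.0L;
    for (size_t k = 0; k < s.leaf_len.size(); ++k) {
      if (s.leaf_age[k] < expand_tt && s.leaf_len[k] < pm.l0) {
        double c = pm.l0 - s.leaf_len[k];
        if (dlen_max < c) c = dlen_max;
        cap_coh[k] = c * mpc;
        cap_tot_l += cap_coh[k];
      }
    }
    double cap_total = (double)cap_tot_l;
    double cap_shoot = cap_total * (1.0 + pm.sheath_ratio);
    double cap_root_room = pm.root_max_length * pm.root_lin_density - s.w_root;
    if (cap_root_room < 0.0) cap_root_room = 0.0;
    double cap_root = cap_root_room + s.w_root * d_tt / pm.root_lifespan;
    double pool_c = wc_mid + remob_res_c - store_c - exud_c;
    double pool_n = wn_mid + remob_res_n - store_n - exud_n;

    const double W = W0;
    double f_t = std::pow(pm.q10, (temp - pm.temp_ref) / 10.0);
    double resp_maint = pm.r_maint * W * f_t;
    if (resp_maint > pool_c) resp_maint = pool_c;
    double wc_avail = pool_c - resp_maint;
    double fc = W > 0.0 ? pool_c / (pool_c + pm.kc * W) : 0.0;
    double fn = W > 0.0 ? pool_n / (pool_n + pm.kn * W) : 0.0;
    double g_pot = pm.g_max * d_tt * W * fc * fn;
    double g_shoot = (1.0 - s.p) * (1.0 - s.q) * g_pot;
    if (g_shoot > cap_shoot) g_shoot = cap_shoot;
    double g_protein = (1.0 - s.p) * s.q * g_pot;
    double g_root = s.p * g_pot;
    if (g_root > cap_root) g_root = cap_root;
    double g_tot = g_shoot + g_protein + g_root;
    if (g_tot > 0.0) {
      double c_need = g_tot * pm.c_struct / pm.y_growth;
      double n_need = (g_shoot + g_root) * pm.n_struct + g_protein * pm.n_protein;
      double scale = 1.0;
      if (c_need > 0.0 && wc_avail / c_need < scale) scale = wc_avail / c_need;
      if (n_need > 0.0 && pool_n / n_need < scale) scale = pool_n / n_need;
      if (scale < 0.0) scale = 0.0;
      g_shoot *= scale; g_protein *= scale; g_root *= scale; g_tot *= scale;
    }
    double part_c = g_tot * pm.c_struct;
    double resp_growth = g_tot * pm.c_struct * (1.0 - pm.y_growth) / pm.y_growth;
    double part_n = (g_shoot + g_root) * pm.n_struct + g_protein * pm.n_protein;

    // -- tissue turnover ---------------------------------------------
    double prot_sen = pm.protein_turnover * s.w_protein;
    double root_sen = s.w_root * d_tt / pm.root_lifespan;
    double remob_prot_n = pm.remob_frac * prot_sen * pm.n_protein;
    double remob_root_n = pm.remob_frac * root_sen * pm.n_struct;

    // -- leaf demography ---------------------------------------------
    double g_lamina = g_shoot / (1.0 + pm.sheath_ratio);
    if (g_lamina > 0.0 && !s.leaf_len.empty() && cap_total > 0.0) {
      for (size_t k = 0; k < s.leaf_len.size(); ++k)
        s.leaf_len[k] += g_lamina * cap_coh[k] / cap_total / mpc;
    }
    double litter_mass_leaf = 0.0, litter_c_leaf = 0.0, litter_n_leaf = 0.0,
           remob_n_leaf = 0.0;
    {
      const double lls = params["lls"];
      long double dead_len = 0.0L;
      std::vector<double> kl, ka;
      kl.reserve(s.leaf_len.size()); ka.reserve(s.leaf_age.size());
      for (size_t k = 0; k < s.leaf_len.size(); ++k) {
        double age = s.leaf_age[k] + d_tt;
        if (age >= lls) dead_len += s.leaf_len[k];
        else { kl.push_back(s.leaf_len[k]); ka.push_back(age); }
      }
      if (dead_len > 0.0L) {
        double m_lam = (double)dead_len * mpc;
        double m = m_lam * (1.0 + pm.sheath_ratio);
        double n_tot = m * pm.n_struct;
        remob_n_leaf = pm.remob_frac * n_tot;
        litter_mass_leaf = m;
        litter_c_leaf = m * pm.c_struct;
        litter_n_leaf = n_tot - remob_n_leaf;
      }
      s.leaf_len.swap(kl); s.leaf_age.swap(ka);
    }
    s.tt_leaf += d_tt;
    while (s.tt_leaf >= pm.phyllochron) {
      s.tt_leaf -= pm.phyllochron;
      s.leaf_len.push_back(0.0);
      s.leaf_age.push_back(s.tt_leaf);
    }
    s.tt += d_tt;

    // -- substrate mass balance --------------------------------------
    double src_c = photo + remob_res_c;
    double snk_c = (resp_maint + resp_growth) + part_c + store_c + exud_c;
    if (snk_c > s.wc + src_c + 1e-9 * snk_c && snk_c > 0.0)
      stop("simulation failure on day %d: substrate sinks exceeded supply", d + 1);
    double remob_n_all = remob_n_leaf + remob_prot_n + remob_root_n + remob_res_n;
    double src_n = su + remob_n_all;
    double snk_n = part_n + store_n + exud_n;
    if (snk_n > s.wn + src_n + 1e-9 * snk_n && snk_n > 0.0)
      stop("simulation failure on day %d: substrate sinks exceeded supply", d + 1);
    double wc_new = s.wc + src_c - snk_c; if (wc_new < 0.0) wc_new = 0.0;
    double wn_new = s.wn + src_n - snk_n; if (wn_new < 0.0) wn_new = 0.0;
    s.wc = wc_new; s.wn = wn_new;
    s.res_c += store_c - remob_res_c;
    s.res_n += store_n - remob_res_n;
    s.w_root += g_root - root_sen;
    s.w_protein += g_protein - prot_sen;

    // -- allocation relaxation ---------------------------------------
    {
      double wn_fl = s.wn > 1e-9 ? s.wn : 1e-9;
      double cn = s.wc / wn_fl;
      double target = pm.p_ref * (cn / pm.cn_target);
      if (target < pm.p_min) target = pm.p_min;
      if (target > pm.p_max) target = pm.p_max;
      double dt_rel = 1.0 / pm.tau_p; if (dt_rel > 1.0) dt_rel = 1.0;
      s.p = s.p + (target - s.p) * dt_rel;
      double ssum = a_light + a_cap;
      if (ssum > 0.0) {
        double delta = (a_light - a_cap) / ssum;
        double dq_rel = 1.0 / pm.tau_q; if (dq_rel > 1.0) dq_rel = 1.0;
        double q2 = s.q * (1.0 + delta * dq_rel);
        if (q2 < pm.q_min) q2 = pm.q_min;
        if (q2 > 1.0) q2 = 1.0;
        s.q = q2;
      }
    }

    // -- tiller demography and soil N --------------------------------
    double td_prev = s.td;
    {
      double crowd = lai / pm.lai_crit;
      double up = 1.0 - crowd; if (up < 0.0) up = 0.0;
      double dn = crowd - 1.0; if (dn < 0.0) dn = 0.0;
      double dtd = pm.tiller_app_rate * s.td * (fc * fn) * up -
                   pm.tiller_sen_rate * s.td * dn;
      s.td = s.td + dtd;
      if (s.td < pm.td_min) s.td = pm.td_min;
    }
    {
      double sn = s.soil_n + pm.mineralization - su * td_prev -
                  pm.leach_rate * s.soil_n;
      s.soil_n = sn > 0.0 ? sn : 0.0;
    }

    if (!std::isfinite(s.wc) || !std::isfinite(s.wn) || !std::isfinite(s.w_root) ||
        !std::isfinite(s.w_protein) || !std::isfinite(s.td) ||
        s.wc < 0.0 || s.wn < 0.0 || s.w_root < 0.0 || s.w_protein < 0.0)
      stop("simulation failure on day %d: non-finite or negative state", d + 1);

    double litter_c_all = litter_c_leaf + (prot_sen + root_sen) * pm.c_struct;
    double litter_n_all = litter_n_leaf +
      (1.0 - pm.remob_frac) * (prot_sen * pm.n_protein + root_sen * pm.n_struct);
    double wn_fl = s.wn > 1e-9 ? s.wn : 1e-9;

    int c = 0;
    daily(d, c++) = d + 1;                    // day
    daily(d, c++) = d_tt;
    daily(d, c++) = lai;
    daily(d, c++) = f_int;
    daily(d, c++) = photo;
    daily(d, c++) = resp_maint + resp_growth;
    daily(d, c++) = su;
    daily(d, c++) = a_light;
    daily(d, c++) = a_cap;
    daily(d, c++) = g_shoot;
    daily(d, c++) = g_protein;
    daily(d, c++) = g_root;
    daily(d, c++) = litter_mass_leaf + prot_sen + root_sen;
    daily(d, c++) = litter_c_all;
    daily(d, c++) = litter_n_all;
    daily(d, c++) = harvest_mass;
    daily(d, c++) = harvest_c;
    daily(d, c++) = harvest_n;
    daily(d, c++) = exud_c;
    daily(d, c++) = exud_n;
    daily(d, c++) = s.wc;
    daily(d, c++) = s.wn;
    daily(d, c++) = s.wc / wn_fl;
    daily(d, c++) = s.p;
    daily(d, c++) = s.q;
    daily(d, c++) = s.td;
    daily(d, c++) = shoot_mass(s, pm);
    daily(d, c++) = s.w_root;
    daily(d, c++) = s.w_protein;
    daily(d, c++) = plant_height(s, pm);
    daily(d, c++) = s.soil_n;
    daily(d, c++) = fc;
    daily(d, c++) = fn;
    daily(d, c++) = temp;
    daily(d, c++) = par;
    daily(d, c++) = s.res_c;
    daily(d, c++) = s.res_n;
  }

  List out_state = List::create(
    _["wc"] = s.wc, _["wn"] = s.wn, _["res_c"] = s.res_c, _["res_n"] = s.res_n,
    _["w_root"] = s.w_root, _["w_protein"] = s.w_protein,
    _["leaf_len"] = NumericVector(s.leaf_len.begin(), s.leaf_len.end()),
    _["leaf_age"] = NumericVector(s.leaf_age.begin(), s.leaf_age.end()),
    _["td"] = s.td, _["p"] = s.p, _["q"] = s.q, _["soil_n"] = s.soil_n,
    _["tt"] = s.tt, _["tt_leaf"] = s.tt_leaf);
  out_state.attr("class") = "plant_state";
  return List::create(_["daily"] = daily, _["state"] = out_state);
}
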