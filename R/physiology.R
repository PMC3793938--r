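#' Canopy light interception
#'
#' Beer-Lambert closure over a horizontally homogeneous canopy: the
#' fraction of incident photosynthetically active radiation intercepted
#' by a canopy of leaf area index `lai` is `1 - exp(-k_ext * lai)`.
#'
#' @param lai Leaf area index (m^2 leaf m^-2 ground), nonnegative.
#' @param k_ext Canopy extinction coefficient, positive.
#' @return Intercepted fraction in \[0, 1\], strictly increasing in `lai`.
#' @export
#' @examples
#' light_interception(2, 0.5)  # 1 - exp(-1)
light_interception <- function(lai, k_ext) {
  if (any(lai < 0)) stop("lai must be nonnegative", call. = FALSE)
  if (any(k_ext <= 0)) stop("k_ext must be positive", call. = FALSE)
  1 - exp(-k_ext * lai)
}

#' Gross photosynthesis under light/capacity co-limitation
#'
#' Gross daily C gain of one axis is the smooth minimum of a
#' light-limited rate (`eps_light * par_int`) and a capacity-limited rate
#' (`amax_protein * w_protein`, modulated by temperature), combined
#' through a non-rectangular hyperbola with curvature `theta_colim`.
#' The result never exceeds either limb; at exact co-limitation it lies
#' within a factor `(1 - sqrt(1 - theta))/theta` of the minimum.
#'
#' @param par_int Intercepted PAR (MJ axis^-1 d^-1).
#' @param w_protein Photosynthetic protein mass (g axis^-1).
#' @param params A [species_params()] set.
#' @param temp Mean air temperature (degrees C); scales the capacity limb
#'   linearly up to `temp_ref` and is capped at 1.25 above it.
#' @return Gross C assimilation (gC axis^-1 d^-1).
#' @export
photosynthesis <- function(par_int, w_protein, params, temp = params$temp_ref) {
  if (par_int < 0 || w_protein < 0) stop("photosynthesis inputs must be nonnegative", call. = FALSE)
  a <- params$eps_light * par_int
  f_t <- min(max(temp, 0) / params$temp_ref, 1.25)
  b <- params$amax_protein * w_protein * f_t
  smooth_min(a, b, params$theta_colim)
}

## Non-rectangular hyperbola: smaller root of
## theta x^2 - (a+b) x + a b = 0; tends to min(a, b) as theta -> 1.
smooth_min <- function(a, b, theta) {
  if (a <= 0 || b <= 0) return(0)
  s <- a + b
  disc <- s * s - 4 * theta * a * b
  (s - sqrt(max(disc, 0))) / (2 * theta)
}

#' Root nitrogen uptake
#'
#' Michaelis-Menten uptake proportional to root surface area:
#' `umax * sra * w_root * soil_n / (km + soil_n)`, truncated so an axis
#' never takes more than its per-axis share of the soil mineral pool in
#' one day.
#'
#' @param w_root Structural root mass (g axis^-1).
#' @param sra Specific root area (m^2 g^-1).
#' @param soil_n Soil mineral N pool (gN m^-2).
#' @param umax Maximum uptake per root area (gN m^-2 root d^-1).
#' @param km Half-saturation constant (gN m^-2 soil).
#' @param td Tiller density (axes m^-2); used to cap uptake at the
#'   per-axis share of the pool. `Inf` (default) disables the cap.
#' @return N uptake (gN axis^-1 d^-1).
#' @export
n_uptake <- function(w_root, sra, soil_n, umax, km, td = Inf) {
  if (any(c(w_root, sra, soil_n, umax, km) < 0)) {
    stop("n_uptake inputs must be nonnegative", call. = FALSE)
  }
  demand <- umax * sra * w_root * soil_n / (km + soil_n)
  if (is.finite(td) && td > 0) min(demand, soil_n / td) else demand
}

#' Update the C and N substrate pools from named fluxes
#'
#' Signed mass balance of the labile substrate pools:
#' `d wc = photosynthesis + remobilisation_c - respiration - partitioning_c
#'         - storage_c - exudation_c` and
#' `d wn = uptake + fixation + remobilisation_n - partitioning_n
#'         - storage_n - exudation_n`.
#' Missing fluxes default to zero (fixation is zero for grasses).  If the
#' sink fluxes of a pool would drive it negative, all sinks of that pool
#' are scaled by a common factor so the pool lands exactly at zero; the
#' applied fluxes are returned so ledgers stay exact.
#'
#' @param pools List with numeric `wc` (gC) and `wn` (gN).
#' @param fluxes Named list; recognised C fluxes: `photosynthesis`,
#'   `remobilisation_c` (sources), `respiration`, `partitioning_c`,
#'   `storage_c`, `exudation_c` (sinks); N fluxes: `uptake`, `fixation`,
#'   `remobilisation_n` (sources), `partitioning_n`, `storage_n`,
#'   `exudation_n` (sinks). All nonnegative.
#' @return List with updated `pools`, the `applied` flux list after any
#'   down-scaling, and the two scale factors `scale_c`, `scale_n`.
#' @export
substrate_balance <- function(pools, fluxes = list()) {
  f <- list(photosynthesis = 0, remobilisation_c = 0, respiration = 0,
            partitioning_c = 0, storage_c = 0, exudation_c = 0,
            uptake = 0, fixation = 0, remobilisation_n = 0,
            partitioning_n = 0, storage_n = 0, exudation_n = 0)
  bad <- setdiff(names(fluxes), names(f))
  if (length(bad)) stop("unknown flux(es): ", paste(bad, collapse = ", "), call. = FALSE)
  f[names(fluxes)] <- fluxes
  if (any(unlist(f) < 0)) stop("fluxes must be nonnegative (signs are structural)", call. = FALSE)

  src_c <- f$photosynthesis + f$remobilisation_c
  snk_c <- f$respiration + f$partitioning_c + f$storage_c + f$exudation_c
  scale_c <- 1
  if (snk_c > pools$wc + src_c && snk_c > 0) {
    scale_c <- (pools$wc + src_c) / snk_c
    f$respiration <- f$respiration * scale_c
    f$partitioning_c <- f$partitioning_c * scale_c
    f$storage_c <- f$storage_c * scale_c
    f$exudation_c <- f$exudation_c * scale_c
    snk_c <- pools$wc + src_c
  }
  src_n <- f$uptake + f$fixation + f$remobilisation_n
  snk_n <- f$partitioning_n + f$storage_n + f$exudation_n
  scale_n <- 1
  if (snk_n > pools$wn + src_n && snk_n > 0) {
    scale_n <- (pools$wn + src_n) / snk_n
    f$partitioning_n <- f$partitioning_n * scale_n
    f$storage_n <- f$storage_n * scale_n
    f$exudation_n <- f$exudation_n * scale_n
    snk_n <- pools$wn + src_n
  }
  wc <- pools$wc + src_c - snk_c
  wn <- pools$wn + src_n - snk_n
  ## guard against floating point undershoot only
  list(pools = list(wc = max(wc, 0), wn = max(wn, 0)),
       applied = f, scale_c = scale_c, scale_n = scale_n)
}

#' Functional-balance update of the root allocation coefficient P
#'
#' Root versus shoot allocation follows the functional-balance principle:
#' plants short of N relative to C (substrate C:N above its target) shift
#' allocation towards roots.  P relaxes with time constant `tau_p`
#' towards `p_ref * (cn_ratio / cn_target)`, clipped to
#' `[p_min, p_max]`.
#'
#' @param pools Substrate pools (`wc`, `wn` with `wn > 0`).
#' @param params [species_params()].
#' @param p Current root allocation fraction.
#' @param dt Time step (days).
#' @return Updated `p`.
#' @export
functional_balance_p <- function(pools, params, p, dt = 1) {
  if (pools$wn <= 0) stop("functional_balance_p requires wn > 0", call. = FALSE)
  cn <- pools$wc / pools$wn
  target <- params$p_ref * (cn / params$cn_target)
  target <- min(max(target, params$p_min), params$p_max)
  p + (target - p) * min(dt / params$tau_p, 1)
}

#' Coordination update of the protein allocation coefficient Q
#'
#' The fraction of shoot allocation directed to photosynthetic protein
#' adjusts so that light-limited and capacity-limited assimilation are
#' co-limiting: Q increases when light-limited assimilation exceeds the
#' protein-bound capacity (light is being wasted on under-provisioned
#' leaves) and decreases in the opposite case.  The update is a bounded
#' relaxation with time constant `tau_q`; at the fixed point the two
#' limbs agree.
#'
#' @param light_rate Light-limited assimilation (gC axis^-1 d^-1).
#' @param capacity_rate Capacity-limited assimilation (gC axis^-1 d^-1).
#' @param params [species_params()].
#' @param q Current protein allocation fraction.
#' @param dt Time step (days).
#' @return Updated `q` in `[q_min, 1]`.
#' @export
coordination_q <- function(light_rate, capacity_rate, params, q, dt = 1) {
  if (light_rate < 0 || capacity_rate < 0) stop("rates must be nonnegative", call. = FALSE)
  s <- light_rate + capacity_rate
  if (s <= 0) return(q)
  delta <- (light_rate - capacity_rate) / s
  q2 <- q * (1 + delta * min(dt / params$tau_q, 1))
  min(max(q2, params$q_min), 1)
}

#' Structural growth and respiration from substrate status
#'
#' Total structural growth follows a bilinear (two-substrate) control:
#' `G = g_max * d_tt * W * wc/(wc + kc W) * wn/(wn + kn W)` with `W` the
#' total structural mass.  Growth splits to roots (fraction `p`), shoot
#' protein (`(1-p) q`) and shoot structure (`(1-p)(1-q)`).  Shoot and
#' root components are capped by the morphogenetic sinks (`cap_shoot`,
#' `cap_root`; `Inf` disables).  The realised growth is then scaled by a
#' common factor so its stoichiometric C cost (structure plus growth
#' respiration, `c_struct/y_growth` per unit growth) and N cost
#' (`n_struct` for structure, `n_protein` for protein) never exceed the
#' available substrate.  Maintenance respiration is
#' `r_maint * W * q10^((temp - temp_ref)/10)`, taken with priority over
#' growth.
#'
#' @param pools Substrate pools (`wc`, `wn`).
#' @param w_shoot,w_root,w_protein Structural masses (g axis^-1).
#' @param params [species_params()].
#' @param p,q Allocation coefficients.
#' @param d_tt Thermal time increment (degree-days).
#' @param temp Mean temperature (C).
#' @param cap_shoot,cap_root Morphogenetic sink caps (g d^-1).
#' @return List with realised growth per compartment (`g_shoot`,
#'   `g_protein`, `g_root`), `resp_maint`, `resp_growth`, and the
#'   substrate costs `part_c` (= C incorporated in structure),
#'   `part_n` (N incorporated).
#' @export
growth_and_respiration <- function(pools, w_shoot, w_root, w_protein, params,
                                   p, q, d_tt, temp = params$temp_ref,
                                   cap_shoot = Inf, cap_root = Inf) {
  W <- w_shoot + w_root + w_protein
  f_t <- params$q10 ^ ((temp - params$temp_ref) / 10)
  resp_maint_demand <- params$r_maint * W * f_t
  ## maintenance has first call on the C substrate
  resp_maint <- min(resp_maint_demand, pools$wc)
  wc_avail <- pools$wc - resp_maint

  fc <- if (W > 0) pools$wc / (pools$wc + params$kc * W) else 0
  fn <- if (W > 0) pools$wn / (pools$wn + params$kn * W) else 0
  g_pot <- params$g_max * d_tt * W * fc * fn

  g_shoot <- min((1 - p) * (1 - q) * g_pot, cap_shoot)
  g_protein <- (1 - p) * q * g_pot
  g_root <- min(p * g_pot, cap_root)
  g_tot <- g_shoot + g_protein + g_root

  if (g_tot > 0) {
    c_need <- g_tot * params$c_struct / params$y_growth
    n_need <- (g_shoot + g_root) * params$n_struct + g_protein * params$n_protein
    scale <- min(1,
                 if (c_need > 0) wc_avail / c_need else 1,
                 if (n_need > 0) pools$wn / n_need else 1)
    scale <- max(scale, 0)
    g_shoot <- g_shoot * scale
    g_protein <- g_protein * scale
    g_root <- g_root * scale
    g_tot <- g_tot * scale
  }
  part_c <- g_tot * params$c_struct
  resp_growth <- g_tot * params$c_struct * (1 - params$y_growth) / params$y_growth
  part_n <- (g_shoot + g_root) * params$n_struct + g_protein * params$n_protein

  list(g_shoot = g_shoot, g_protein = g_protein, g_root = g_root,
       resp_maint = resp_maint, resp_growth = resp_growth,
       part_c = part_c, part_n = part_n, fc = fc, fn = fn)
}

#' Tiller density dynamics with self-thinning
#'
#' Axis demography follows
#' `d td/dt = app * td * s * max(0, 1 - lai/lai_crit)
#'          - sen * td * max(0, lai/lai_crit - 1)`
#' where `s` is the substrate saturation product (`fc * fn`): tillering
#' requires both C and N substrate, and net change vanishes at the
#' critical LAI.  Density is floored at `td_min`.
#'
#' @param td Tiller density (axes m^-2), positive.
#' @param lai Leaf area index.
#' @param s Substrate limitation factor in \[0, 1\].
#' @param params [species_params()].
#' @param dt Time step (days).
#' @return Updated tiller density.
#' @export
tiller_dynamics <- function(td, lai, s, params, dt = 1) {
  if (td <= 0) stop("td must be positive", call. = FALSE)
  crowd <- lai / params$lai_crit
  dtd <- params$tiller_app_rate * td * s * max(0, 1 - crowd) -
    params$tiller_sen_rate * td * max(0, crowd - 1)
  max(td + dtd * dt, params$td_min)
}
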