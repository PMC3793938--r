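## Leaf geometry closures.  A lamina of length len (cm) has area
## form * width * len (cm^2) and dry mass area * thickness * ldmc
## (unit fresh-tissue density), i.e. mass = area / SLA.

lamina_area <- function(len, params) params$leaf_form * params$leaf_width * len

lamina_mass_per_cm <- function(params) {
  params$leaf_form * params$leaf_width * params$leaf_thickness * params$ldmc
}

shoot_mass <- function(state, params) {
  (1 + params$sheath_ratio) * sum(lamina_area(state$leaf_len, params)) *
    params$leaf_thickness * params$ldmc
}

#' Per-axis lamina area (cm^2) of one plant state
#' @param state A plant state.
#' @param params [species_params()].
#' @return Lamina area per axis in cm^2.
#' @export
leaf_area_per_axis <- function(state, params) sum(lamina_area(state$leaf_len, params))

## Daily extension capacity of each expanding cohort (g lamina d^-1).
## A cohort expands while younger than t_expand phyllochrons and shorter
## than l0; its potential extension is l0 per expansion duration,
## expressed in thermal time.
lamina_capacity <- function(state, d_tt, params) {
  len <- state$leaf_len
  if (!length(len)) return(list(per_cohort = numeric(0), total = 0))
  l0 <- params$l0
  expand_tt <- params$t_expand * params$phyllochron
  dlen_max <- l0 * d_tt / expand_tt
  open <- (state$leaf_age < expand_tt) & (len < l0)
  cap_len <- pmin(dlen_max, l0 - len) * open
  cap <- cap_len * lamina_mass_per_cm(params)
  list(per_cohort = cap, total = sum(cap))
}

## Dynamic erectness: denser swards hold leaves more upright.
erectness <- function(td, params) {
  params$height_shape * (td / params$td0) ^ params$height_dens_exp
}

#' Plant height from leaf geometry and density
#'
#' Height is the tip height of the longest lamina under a
#' density-dependent erectness factor, capped at the potential height
#' `height_shape * l0`.
#' @param state A plant state.
#' @param params [species_params()].
#' @return Height (cm).
#' @export
plant_height <- function(state, params) {
  if (!length(state$leaf_len)) return(0)
  h_pot <- params$height_shape * params$l0
  min(h_pot, erectness(state$td, params) * max(state$leaf_len))
}

#' Advance leaf cohort demography by one thermal-time increment
#'
#' Ages all cohorts by `d_tt`; distributes realised lamina growth
#' `g_lamina` (g dry mass) over expanding cohorts in proportion to their
#' extension capacity; removes cohorts whose age reaches the leaf
#' lifespan, sending their mass (lamina plus attached sheath) to litter
#' and recycling `remob_frac` of their N to the substrate pool; and
#' initiates a new cohort each time accumulated thermal time crosses a
#' phyllochron multiple.
#'
#' @param state A plant state (see [new_plant_state()]).
#' @param d_tt Thermal time increment (degree-days), nonnegative.
#' @param params [species_params()].
#' @param g_lamina Realised lamina structural growth (g d^-1); must not
#'   exceed the capacity returned by the internal extension rule.
#' @return List with the updated `state`, `litter_mass` (g, lamina +
#'   sheath of senesced cohorts), `litter_c`, `litter_n` (after
#'   remobilisation), and `remob_n` (gN returned to the substrate pool).
#' @export
morphogenesis_step <- function(state, d_tt, params, g_lamina = 0) {
  if (d_tt < 0) stop("d_tt must be nonnegative", call. = FALSE)
  mpc <- lamina_mass_per_cm(params)

  ## extension: convert realised lamina mass growth into length
  if (g_lamina > 0 && length(state$leaf_len)) {
    cap <- lamina_capacity(state, d_tt, params)
    if (cap$total > 0) {
      share <- g_lamina * cap$per_cohort / cap$total
      state$leaf_len <- state$leaf_len + share / mpc
    }
  }

  ## ageing and senescence
  state$leaf_age <- state$leaf_age + d_tt
  dead <- state$leaf_age >= params$lls
  litter_mass <- 0; litter_c <- 0; litter_n <- 0; remob_n <- 0
  if (any(dead)) {
    m_lam <- sum(state$leaf_len[dead]) * mpc
    m <- m_lam * (1 + params$sheath_ratio)
    n_tot <- m * params$n_struct
    remob_n <- params$remob_frac * n_tot
    litter_mass <- m
    litter_c <- m * params$c_struct
    litter_n <- n_tot - remob_n
    state$leaf_len <- state$leaf_len[!dead]
    state$leaf_age <- state$leaf_age[!dead]
  }

  ## leaf initiation at phyllochron crossings
  state$tt_leaf <- state$tt_leaf + d_tt
  while (state$tt_leaf >= params$phyllochron) {
    state$tt_leaf <- state$tt_leaf - params$phyllochron
    state$leaf_len <- c(state$leaf_len, 0)
    state$leaf_age <- c(state$leaf_age, state$tt_leaf)
  }
  state$tt <- state$tt + d_tt

  list(state = state, litter_mass = litter_mass, litter_c = litter_c,
       litter_n = litter_n, remob_n = remob_n)
}

#' Apply a discrete management event
#'
#' Cutting removes, for every leaf cohort, the lamina fraction whose
#' vertical extent lies above the residual height (tip height =
#' erectness * lamina length, lamina distributed uniformly along its
#' extent), together with the proportional sheath mass and a protein
#' share equal to the removed fraction of total lamina area.  Removed
#' mass is recorded as harvest.  Fertilisation adds the event magnitude
#' (gN m^-2) to the soil mineral pool.
#'
#' @param state A plant state.
#' @param event A list with `kind` (`"cut"` or `"fertilize"`) and
#'   `magnitude` (residual height in cm, or gN m^-2).
#' @param params [species_params()].
#' @return List with updated `state` and `harvest_mass`, `harvest_c`,
#'   `harvest_n` (all g axis^-1; zero for fertilisation).
#' @export
apply_management <- function(state, event, params) {
  if (event$magnitude < 0) stop("event magnitude must be nonnegative", call. = FALSE)
  harvest_mass <- 0; harvest_c <- 0; harvest_n <- 0
  if (identical(event$kind, "fertilize")) {
    state$soil_n <- state$soil_n + event$magnitude
  } else if (identical(event$kind, "cut")) {
    if (length(state$leaf_len)) {
      er <- erectness(state$td, params)
      tip <- er * state$leaf_len
      frac <- ifelse(tip > 0, pmax(0, pmin(1, (tip - event$magnitude) / tip)), 0)
      mpc <- lamina_mass_per_cm(params)
      area_before <- sum(lamina_area(state$leaf_len, params))
      removed_lam <- sum(state$leaf_len * frac) * mpc
      state$leaf_len <- state$leaf_len * (1 - frac)
      area_removed <- area_before - sum(lamina_area(state$leaf_len, params))
      removed_struct <- removed_lam * (1 + params$sheath_ratio)
      prot_removed <- if (area_before > 0) state$w_protein * area_removed / area_before else 0
      state$w_protein <- state$w_protein - prot_removed
      harvest_mass <- removed_struct + prot_removed
      harvest_c <- (removed_struct + prot_removed) * params$c_struct
      harvest_n <- removed_struct * params$n_struct + prot_removed * params$n_protein
    }
  } else {
    stop("unknown management event kind: ", event$kind, call. = FALSE)
  }
  list(state = state, harvest_mass = harvest_mass,
       harvest_c = harvest_c, harvest_n = harvest_n)
}
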