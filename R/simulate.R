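#' Initialise the state of one average plant axis
#'
#' State is tracked per average axis (tiller); genet-level quantities are
#' obtained by scaling with `td / plant_density`.  The initial state is a
#' young vegetative tiller: two partly expanded leaf cohorts, a small
#' root system and small substrate pools.
#'
#' @param params [species_params()].
#' @return A list of class `plant_state` with substrate pools (`wc`,
#'   `wn`, gC/gN axis^-1), reserves (`res_c`, `res_n`), structural masses
#'   (`w_root`, `w_protein`; shoot mass follows from the leaf cohorts),
#'   leaf cohort vectors (`leaf_len` cm, `leaf_age` degree-days), tiller
#'   density `td`, allocation coefficients `p`, `q`, soil mineral pool
#'   `soil_n` (gN m^-2), cumulative thermal time `tt` and the phyllochron
#'   accumulator `tt_leaf`.
#' @export
new_plant_state <- function(params) {
  structure(list(
    wc = 0.003, wn = 0.0006,
    res_c = 0, res_n = 0,
    w_root = 0.006, w_protein = 0.0012,
    leaf_len = c(0.30, 0.15) * params$l0,
    leaf_age = c(0.6, 0.1) * params$phyllochron,
    td = params$td0,
    p = params$p_ref, q = params$q_init,
    soil_n = params$soil_n_init,
    tt = 0, tt_leaf = 0.1 * params$phyllochron
  ), class = "plant_state")
}

## Total plant C and N stocks per axis (used by the conservation ledger).
plant_carbon <- function(state, params) {
  state$wc + state$res_c +
    params$c_struct * (shoot_mass(state, params) + state$w_root + state$w_protein)
}

plant_nitrogen <- function(state, params) {
  state$wn + state$res_n +
    params$n_struct * (shoot_mass(state, params) + state$w_root) +
    params$n_protein * state$w_protein
}

sim_error <- function(day, reason) {
  structure(class = c("grasscape_sim_error", "error", "condition"),
            list(message = sprintf("simulation failure on day %d: %s", day, reason),
                 call = NULL, day = day, reason = reason))
}

#' Advance the plant state by one day
#'
#' Fixed process order: management events, canopy light interception,
#' photosynthesis, root N uptake, maintenance respiration and
#' substrate-driven growth (capped by the morphogenetic shoot and root
#' sinks), reserve storage/remobilisation, the substrate mass balance,
#' relaxation of the allocation coefficients P and Q, leaf cohort
#' demography, tiller dynamics, and the soil mineral N balance.
#'
#' @param state A `plant_state`.
#' @param driver A list/row with `par` (MJ m^-2 d^-1) and `temp` (C).
#' @param params [species_params()].
#' @param events Optional list of management events for this day, each a
#'   list with `kind` and `magnitude` (see [apply_management()]).
#' @param day Integer day index (for error reporting).
#' @return List with the updated `state` and `rec`, a named numeric
#'   vector of daily fluxes and state summaries (per axis unless noted).
#' @export
step_day <- function(state, driver, params, events = NULL, day = 1L) {
  par <- driver$par; temp <- driver$temp
  if (!is.finite(par) || !is.finite(temp) || par < 0) stop(sim_error(day, "invalid driver"))

  ## -- management ---------------------------------------------------
  harvest_mass <- 0; harvest_c <- 0; harvest_n <- 0
  if (!is.null(events)) {
    for (ev in events) {
      res <- apply_management(state, ev, params)
      state <- res$state
      harvest_mass <- harvest_mass + res$harvest_mass
      harvest_c <- harvest_c + res$harvest_c
      harvest_n <- harvest_n + res$harvest_n
    }
  }

  d_tt <- max(0, temp - params$t_base)

  ## -- canopy and resource capture ----------------------------------
  area_ax <- leaf_area_per_axis(state, params)        # cm^2 axis^-1
  lai <- area_ax * 1e-4 * state$td
  f_int <- light_interception(lai, params$k_ext)
  par_int <- if (state$td > 0) par * f_int / state$td else 0
  a_light <- params$eps_light * par_int
  f_pt <- min(max(temp, 0) / params$temp_ref, 1.25)
  a_cap <- params$amax_protein * state$w_protein * f_pt
  ## product feedback: assimilation and uptake shut down when the
  ## respective substrate pool saturates relative to structural mass
  w_shoot <- shoot_mass(state, params)
  W0 <- w_shoot + state$w_root + state$w_protein
  inh_c <- if (W0 > 0) 1 / (1 + (state$wc / (params$c_inh * W0))^params$inh_hill) else 1
  inh_n <- if (W0 > 0) 1 / (1 + (state$wn / (params$n_inh * W0))^params$inh_hill) else 1
  photo <- smooth_min(a_light, a_cap, params$theta_colim) * inh_c
  su <- inh_n * n_uptake(state$w_root, params$sra, state$soil_n, params$umax,
                         params$km, td = state$td)

  ## -- reserve storage / remobilisation -----------------------------
  wc_mid <- state$wc + photo; wn_mid <- state$wn + su
  store_c <- 0; store_n <- 0; remob_res_c <- 0; remob_res_n <- 0
  excess_c <- wc_mid - params$cn_target * wn_mid
  if (excess_c > 0) store_c <- params$store_frac * excess_c
  excess_n <- wn_mid - wc_mid / params$cn_target
  if (excess_n > 0) store_n <- params$store_frac * excess_n
  ## reserves are a linear buffer: constant fractional return to the
  ## substrate pool (threshold switches here produce multi-year limit
  ## cycles and are avoided)
  remob_res_c <- params$res_remob_rate * state$res_c
  remob_res_n <- params$res_remob_rate * state$res_n
  ## exudation disposes of substrate excess over the C:N target, closing
  ## the C balance when growth is sink- or N-limited
  exud_c <- params$exud_frac * max(excess_c, 0)
  exud_n <- params$exud_frac * max(excess_n, 0)

  ## -- growth under substrate and sink control ----------------------
  ## storage and exudation are committed first, so the growth scaling
  ## sees exactly the substrate that the balance can supply
  cap <- lamina_capacity(state, d_tt, params)
  cap_shoot <- cap$total * (1 + params$sheath_ratio)
  cap_root <- max(0, params$root_max_length * params$root_lin_density - state$w_root) +
    state$w_root * d_tt / params$root_lifespan
  pools0 <- list(wc = wc_mid + remob_res_c - store_c - exud_c,
                 wn = wn_mid + remob_res_n - store_n - exud_n)
  gr <- growth_and_respiration(pools0, w_shoot, state$w_root, state$w_protein,
                               params, state$p, state$q, d_tt, temp,
                               cap_shoot = cap_shoot, cap_root = cap_root)

  ## -- tissue turnover ----------------------------------------------
  prot_sen <- params$protein_turnover * state$w_protein
  root_sen <- state$w_root * d_tt / params$root_lifespan
  remob_prot_n <- params$remob_frac * prot_sen * params$n_protein
  remob_root_n <- params$remob_frac * root_sen * params$n_struct

  ## -- leaf demography (fluxes feed the same day's balance) ---------
  g_lamina <- gr$g_shoot / (1 + params$sheath_ratio)
  morph <- morphogenesis_step(state, d_tt, params, g_lamina = g_lamina)

  ## -- substrate mass balance ---------------------------------------
  bal <- substrate_balance(
    list(wc = state$wc, wn = state$wn),
    list(photosynthesis = photo,
         remobilisation_c = remob_res_c,
         respiration = gr$resp_maint + gr$resp_growth,
         partitioning_c = gr$part_c,
         storage_c = store_c,
         exudation_c = exud_c,
         uptake = su,
         remobilisation_n = morph$remob_n + remob_prot_n + remob_root_n + remob_res_n,
         partitioning_n = gr$part_n,
         storage_n = store_n,
         exudation_n = exud_n))
  if (bal$scale_c < 1 - 1e-9 || bal$scale_n < 1 - 1e-9) {
    stop(sim_error(day, "substrate sinks exceeded supply after demand scaling"))
  }

  state <- morph$state
  state$wc <- bal$pools$wc
  state$wn <- bal$pools$wn
  state$res_c <- state$res_c + store_c - remob_res_c
  state$res_n <- state$res_n + store_n - remob_res_n
  state$w_root <- state$w_root + gr$g_root - root_sen
  state$w_protein <- state$w_protein + gr$g_protein - prot_sen

  ## -- allocation relaxation ----------------------------------------
  ## wn floored inside the ratio only, so the C:N ratio stays defined
  state$p <- functional_balance_p(list(wc = state$wc, wn = max(state$wn, 1e-9)),
                                  params, state$p)
  state$q <- coordination_q(a_light, a_cap, params, state$q)

  ## -- tiller demography and soil N ---------------------------------
  td_prev <- state$td
  state$td <- tiller_dynamics(state$td, lai, gr$fc * gr$fn, params)
  state$soil_n <- max(0, state$soil_n + params$mineralization -
                        su * td_prev - params$leach_rate * state$soil_n)

  if (any(!is.finite(c(state$wc, state$wn, state$w_root, state$w_protein, state$td))) ||
      state$wc < 0 || state$wn < 0 || state$w_root < 0 || state$w_protein < 0) {
    stop(sim_error(day, "non-finite or negative state"))
  }

  litter_c <- morph$litter_c + (prot_sen + root_sen) * params$c_struct
  litter_n <- morph$litter_n +
    (1 - params$remob_frac) * (prot_sen * params$n_protein + root_sen * params$n_struct)

  rec <- c(day, d_tt, lai, f_int,
           photo, gr$resp_maint + gr$resp_growth,
           su, a_light, a_cap,
           gr$g_shoot, gr$g_protein, gr$g_root,
           morph$litter_mass + prot_sen + root_sen,
           litter_c, litter_n,
           harvest_mass, harvest_c, harvest_n,
           exud_c, exud_n,
           state$wc, state$wn,
           state$wc / max(state$wn, 1e-9),
           state$p, state$q, state$td,
           shoot_mass(state, params), state$w_root,
           state$w_protein,
           plant_height(state, params),
           state$soil_n, gr$fc, gr$fn, temp, par,
           state$res_c, state$res_n)
  names(rec) <- .rec_names
  list(state = state, rec = rec)
}

#' Run a multi-year daily simulation
#'
#' Drivers are recycled cyclically to cover the requested number of
#' years (365-day years).  The management schedule is applied by day of
#' year, every year.  The run is fully deterministic.
#'
#' @param params [species_params()].
#' @param drivers Data frame with columns `day`, `par`, `temp` covering
#'   at least one year (365 rows or a multiple).
#' @param schedule Data frame of management events with columns `day`
#'   (day of year), `kind`, `magnitude`, or `NULL` for none.
#' @param years Number of years to simulate.
#' @param state Optional starting `plant_state` (e.g. from [spin_up()]);
#'   default is [new_plant_state()].
#' @param engine `"cpp"` (compiled daily core, the default) or `"r"`
#'   (reference implementation composing the exported process
#'   functions).  The two engines agree numerically; the reference
#'   engine exists for transparency and testing.
#' @return A `grass_trajectory`: list with `daily` (matrix of per-day
#'   records), `yearly` (tibble of annual production per plant, split
#'   above/below ground, plus harvest), `params`, and `ledger` (initial
#'   and final per-axis C and N stocks with cumulative boundary fluxes).
#' @export
run_simulation <- function(params, drivers, schedule = NULL, years = 1,
                           state = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(years >= 1, nrow(drivers) >= 365)
  if (is.null(state)) state <- new_plant_state(params)
  ndrv <- nrow(drivers)
  ndays <- as.integer(365 * years)
  ## normalised event order: by day, cuts before fertilisation
  if (!is.null(schedule) && nrow(schedule)) {
    schedule <- schedule[order(schedule$day, schedule$kind), ]
  }

  c0 <- plant_carbon(state, params); n0 <- plant_nitrogen(state, params)
  par_v <- drivers$par; temp_v <- drivers$temp
  if (engine == "cpp") {
    fert_doy <- numeric(365); cut_doy <- rep(-1, 365)
    if (!is.null(schedule) && nrow(schedule)) {
      if (anyDuplicated(paste(schedule$day, schedule$kind))) {
        stop("duplicate same-day management events", call. = FALSE)
      }
      for (i in seq_len(nrow(schedule))) {
        if (schedule$kind[i] == "fertilize") {
          fert_doy[schedule$day[i]] <- schedule$magnitude[i]
        } else if (schedule$kind[i] == "cut") {
          cut_doy[schedule$day[i]] <- schedule$magnitude[i]
        } else stop("unknown management event kind: ", schedule$kind[i], call. = FALSE)
      }
    }
    res <- tryCatch(
      .sim_core_cpp(params, state, par_v, temp_v, fert_doy, cut_doy, ndays),
      error = function(e) {
        day <- suppressWarnings(as.integer(sub(".*day (\\d+).*", "\\1",
                                               conditionMessage(e))))
        stop(sim_error(if (is.na(day)) 0L else day, conditionMessage(e)))
      })
    daily <- res$daily
    colnames(daily) <- .rec_names
    state <- res$state
  } else {
    ev_list <- split_schedule(schedule)
    ev_by_doy <- vector("list", 365L)
    for (nm in names(ev_list)) ev_by_doy[[as.integer(nm)]] <- ev_list[[nm]]
    daily <- matrix(NA_real_, nrow = ndays, ncol = length(.rec_names),
                    dimnames = list(NULL, .rec_names))
    for (d in seq_len(ndays)) {
      i <- ((d - 1L) %% ndrv) + 1L
      doy <- ((d - 1L) %% 365L) + 1L
      out <- step_day(state, list(par = par_v[i], temp = temp_v[i]), params,
                      events = ev_by_doy[[doy]], day = d)
      state <- out$state
      daily[d, ] <- out$rec
    }
  }
  yr <- (seq_len(ndays) - 1L) %/% 365L + 1L
  per_plant <- daily[, "td"] / params$plant_density
  above <- (daily[, "g_shoot"] + daily[, "g_protein"]) * per_plant
  below <- daily[, "g_root"] * per_plant
  harv <- daily[, "harvest_mass"] * per_plant
  yearly <- tibble::tibble(
    year = seq_len(years),
    above = as.numeric(tapply(above, yr, sum)),
    below = as.numeric(tapply(below, yr, sum)),
    harvest = as.numeric(tapply(harv, yr, sum))
  )
  yearly$total <- yearly$above + yearly$below
  ledger <- list(
    c_initial = c0, n_initial = n0,
    c_final = plant_carbon(state, params), n_final = plant_nitrogen(state, params),
    photo = sum(daily[, "photo"]), resp = sum(daily[, "resp"]),
    uptake = sum(daily[, "uptake"]),
    litter_c = sum(daily[, "litter_c"]), litter_n = sum(daily[, "litter_n"]),
    harvest_c = sum(daily[, "harvest_c"]), harvest_n = sum(daily[, "harvest_n"]),
    exud_c = sum(daily[, "exud_c"]), exud_n = sum(daily[, "exud_n"])
  )
  structure(list(daily = daily, yearly = yearly, params = params,
                 state = state, ledger = ledger),
            class = "grass_trajectory")
}

.rec_names <- c("day", "d_tt", "lai", "f_int", "photo", "resp", "uptake",
                "a_light", "a_cap", "g_shoot", "g_protein", "g_root",
                "litter_mass", "litter_c", "litter_n", "harvest_mass",
                "harvest_c", "harvest_n", "exud_c", "exud_n", "wc", "wn",
                "cn", "p", "q", "td", "w_shoot", "w_root", "w_protein",
                "height", "soil_n", "fc", "fn", "temp", "par",
                "res_c", "res_n")

split_schedule <- function(schedule) {
  if (is.null(schedule) || !nrow(schedule)) return(list())
  key <- paste(schedule$day, schedule$kind)
  if (anyDuplicated(key)) stop("duplicate same-day management events", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    d <- as.character(schedule$day[i])
    out[[d]] <- c(out[[d]], list(list(kind = schedule$kind[i],
                                      magnitude = schedule$magnitude[i])))
  }
  out
}

#' Mean annual biomass production of a trajectory
#'
#' The performance measure of the virtual experiment: arithmetic mean
#' over simulated years of total structural production per plant
#' (above-ground growth, including tissue later harvested, plus
#' below-ground growth), in g plant^-1 yr^-1.
#'
#' @param traj A `grass_trajectory`.
#' @return Mean annual production (g plant^-1 yr^-1).
#' @export
performance <- function(traj) {
  if (!inherits(traj, "grass_trajectory") || !nrow(traj$yearly)) {
    stop("performance requires a trajectory with at least one complete year",
         call. = FALSE)
  }
  mean(traj$yearly$total)
}

#' Relative C and N conservation error of a trajectory
#'
#' Checks the closed-system ledgers per average axis: cumulative gross
#' photosynthesis must equal the change in plant C stocks plus
#' respiration, litter C, harvest C and exudation; cumulative N uptake
#' likewise against plant N stocks, litter N and harvest N.
#'
#' @param traj A `grass_trajectory`.
#' @return Named numeric vector with relative errors `c` and `n`.
#' @export
conservation_error <- function(traj) {
  l <- traj$ledger
  c_in <- l$photo
  c_out <- (l$c_final - l$c_initial) + l$resp + l$litter_c + l$harvest_c + l$exud_c
  n_in <- l$uptake
  n_out <- (l$n_final - l$n_initial) + l$litter_n + l$harvest_n + l$exud_n
  c(c = abs(c_in - c_out) / max(abs(c_in), 1e-12),
    n = abs(n_in - n_out) / max(abs(n_in), 1e-12))
}

#' Diagnostic summary of a trajectory
#'
#' Season-level diagnostics used by the landscape analyses: growing
#' season (days with mean temperature above 5 C) means of the substrate
#' C:N ratio, light interception fraction, net photosynthesis per ground
#' area, N uptake rate, allocation coefficients, and the efficiency
#' ratios NUE (biomass produced per N taken up) and RUE (biomass per MJ
#' PAR intercepted).
#'
#' @param traj A `grass_trajectory`.
#' @return A one-row tibble.
#' @export
diagnostics <- function(traj) {
  d <- traj$daily
  gs <- d[, "temp"] > 5
  if (!any(gs)) gs <- rep(TRUE, nrow(d))
  prod <- sum(d[, c("g_shoot", "g_protein", "g_root")])
  par_int <- sum(d[, "par"] * d[, "f_int"]) / traj$params$td0
  upt <- sum(d[, "uptake"])
  tibble::tibble(
    mean_cn = mean(d[gs, "cn"]),
    mean_f_int = mean(d[gs, "f_int"]),
    net_photo = mean((d[gs, "photo"] - d[gs, "resp"]) * d[gs, "td"]),
    su = mean(d[gs, "uptake"]),
    nue = if (upt > 0) prod / upt else NA_real_,
    rue = if (par_int > 0) prod / par_int else NA_real_,
    mean_p = mean(d[gs, "p"]),
    mean_q = mean(d[gs, "q"]),
    sra = traj$params$sra
  )
}
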