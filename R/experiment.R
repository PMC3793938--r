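#' Build a factorial grid of values for one trait
#'
#' Ten equidistant values spanning a symmetric fractional band around the
#' observed value (default +/-30%, so spacing `2 * fraction * observed /
#' (steps - 1)`), with the observed value itself inserted as an
#' additional point (deduplicated if it coincides with a step).
#'
#' @param observed Observed trait value (> 0).
#' @param fraction Half-width of the band as a fraction of `observed`.
#' @param steps Number of equidistant steps (>= 2).
#' @return Sorted numeric vector of grid values (length `steps + 1`
#'   unless the observed value coincides with a step).
#' @export
#' @examples
#' build_trait_grid(263)          # A. pratensis SLA: 184.1 ... 341.9
#' build_trait_grid(100, 0, 10)   # degenerate: single value
build_trait_grid <- function(observed, fraction = 0.30, steps = 10) {
  if (!is.numeric(observed) || length(observed) != 1L || observed <= 0) {
    stop("observed trait value must be a single positive number", call. = FALSE)
  }
  stopifnot(steps >= 2, fraction >= 0)
  g <- seq((1 - fraction) * observed, (1 + fraction) * observed, length.out = steps)
  g <- sort(unique(c(g, observed)))
  ## deduplicate values equal to floating-point tolerance
  keep <- c(TRUE, diff(g) > 1e-9 * observed)
  g[keep]
}

#' Total run count of a fully crossed trait design
#'
#' @param grids List of per-trait grid value vectors (or an integer
#'   vector of grid sizes).
#' @param n_species Number of species.
#' @param n_levels Number of N fertilisation levels.
#' @return Exact number of distinct simulation runs.
#' @export
#' @examples
#' enumerate_design(rep(11, 4), n_species = 12, n_levels = 2)  # 351384
enumerate_design <- function(grids, n_species = 1, n_levels = 1) {
  sizes <- if (is.list(grids)) lengths(grids) else grids
  prod(sizes) * n_species * n_levels
}

#' Spin the model up to quasi-equilibrium
#'
#' Repeats one-year cycles of the given drivers and schedule until the
#' end-of-year state (substrate and reserve pools, structural masses,
#' tiller density) changes by less than `tol` in relative terms, or the
#' cycle cap is reached.  Non-convergence is reported, not fatal: with
#' slow axis demography (the default, which preserves the
#' initial-density trait signal) tiller density keeps creeping towards
#' its self-thinning ceiling, so strict convergence is not expected
#' there; campaigns use a fixed small number of spin-up cycles, which
#' equilibrates the fast physiological state, and the convergence flag
#' is informative.
#'
#' @param params [species_params()].
#' @param drivers One year (or more) of daily drivers; cycled.
#' @param schedule Management schedule (day-of-year events).
#' @param tol Relative convergence tolerance on the end-of-year state.
#' @param max_cycles Cycle cap.
#' @param state Optional starting state.
#' @return List with the spun-up `state`, logical `converged`, the
#'   number of `cycles` run, and the final relative change `delta`.
#' @export
spin_up <- function(params, drivers, schedule = NULL, tol = 1e-3,
                    max_cycles = 20, state = NULL) {
  if (is.null(state)) state <- new_plant_state(params)
  ## year-mean state: instantaneous end-of-year snapshots carry leaf
  ## cohort phase, which shifts between cycles; the annual mean is the
  ## stable descriptor of the attractor
  key_cols <- c("wc", "wn", "res_c", "res_n", "w_root", "w_protein",
                "w_shoot", "td")
  k0 <- attr(state, "spin_key", exact = TRUE)
  delta <- Inf; cycles <- 0L
  while (cycles < max_cycles) {
    traj <- run_simulation(params, drivers, schedule, years = 1, state = state)
    state <- traj$state
    cycles <- cycles + 1L
    k1 <- colMeans(traj$daily[, key_cols, drop = FALSE])
    if (!is.null(k0)) {
      delta <- max(abs(k1 - k0) / pmax(abs(k0), 1e-6))
      if (delta < tol) { k0 <- k1; break }
    }
    k0 <- k1
  }
  attr(state, "spin_key") <- k0
  list(state = state, converged = delta < tol, cycles = cycles, delta = delta)
}

#' Specify a virtual-experiment campaign
#'
#' @param species Tibble of species with columns `species`, `sla`, `h`,
#'   `lls`, `td` (observed trait values), e.g. from [gen_species()] or
#'   [reference_species()].
#' @param n_levels Annual fertiliser N levels (kgN ha^-1 yr^-1).
#' @param fraction,steps Trait grid construction (see
#'   [build_trait_grid()]).
#' @param years Scored years per run.
#' @param spin_cycles Spin-up cycle cap.
#' @param spin_tol Spin-up tolerance.
#' @param drivers Daily drivers (one year, cycled); default is the
#'   seeded noise-free synthetic climate.
#' @param base Base [species_params()] shared by all species.
#' @param traits Character vector of traits to vary (subset of
#'   `c("sla", "h", "lls", "td0")`); the others stay at observed values.
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(species, n_levels = c(120, 360), fraction = 0.30,
                          steps = 10, years = 2, spin_cycles = 3,
                          spin_tol = 1e-3, drivers = NULL,
                          base = species_params(),
                          traits = c("sla", "h", "lls", "td0")) {
  stopifnot(years >= 1, all(n_levels > 0), nrow(species) >= 1)
  traits <- match.arg(traits, c("sla", "h", "lls", "td0"), several.ok = TRUE)
  if (is.null(drivers)) drivers <- gen_climate(1, noise_sd = c(0, 0))
  structure(list(species = species, n_levels = n_levels, fraction = fraction,
                 steps = steps, years = years, spin_cycles = spin_cycles,
                 spin_tol = spin_tol, drivers = drivers, base = base,
                 traits = traits),
            class = "campaign_spec")
}

#' Run a factorial trait-space campaign
#'
#' For every species, N level and trait combination of the fully crossed
#' design: map traits onto parameters, spin up to quasi-equilibrium, run
#' the scored years, and record performance and diagnostics.  Failed
#' runs are recorded with `status = "failed"` and never abort the
#' campaign.  The result is deterministic given the spec.
#'
#' @param spec A [campaign_spec()].
#' @param progress Print a line per species x N level.
#' @return A landscape tibble with one row per run: `species`,
#'   `n_level`, the four trait values and their grid indices, `perf`
#'   (g plant^-1 yr^-1), `mean_cn` and other diagnostics, and `status`.
#' @export
run_campaign <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "campaign_spec"))
  out <- vector("list", nrow(spec$species) * length(spec$n_levels))
  k <- 0L
  for (si in seq_len(nrow(spec$species))) {
    sp <- spec$species[si, ]
    observed <- c(sla = sp$sla, h = sp$h, lls = sp$lls, td0 = sp$td)
    grids <- lapply(c("sla", "h", "lls", "td0"), function(tr) {
      if (tr %in% spec$traits) build_trait_grid(observed[[tr]], spec$fraction, spec$steps)
      else observed[[tr]]
    })
    names(grids) <- c("sla", "h", "lls", "td0")
    idx <- expand.grid(i_sla = seq_along(grids$sla), i_h = seq_along(grids$h),
                       i_lls = seq_along(grids$lls), i_td0 = seq_along(grids$td0),
                       KEEP.OUT.ATTRS = FALSE)
    for (nl in spec$n_levels) {
      sched <- gen_management(nl)
      rows <- landscape_rows(sp$species, nl, grids, idx, observed, spec, sched)
      k <- k + 1L
      out[[k]] <- rows
      if (progress) {
        message(sprintf("campaign: %s at %g kgN: %d runs, %.4f ok",
                        sp$species, nl, nrow(rows), mean(rows$status == "ok")))
      }
    }
  }
  do.call(rbind, out)
}

landscape_rows <- function(species_id, n_level, grids, idx, observed, spec, sched) {
  n <- nrow(idx)
  perf <- rep(NA_real_, n)
  diag_cols <- c("mean_cn", "mean_f_int", "net_photo", "su", "nue", "rue",
                 "mean_p", "mean_q", "sra")
  dg <- matrix(NA_real_, n, length(diag_cols), dimnames = list(NULL, diag_cols))
  status <- character(n)
  for (r in seq_len(n)) {
    tv <- list(sla = grids$sla[idx$i_sla[r]], h = grids$h[idx$i_h[r]],
               lls = grids$lls[idx$i_lls[r]], td0 = grids$td0[idx$i_td0[r]])
    res <- tryCatch({
      pr <- map_traits_to_params(do.call(trait_vector, tv), spec$base)
      su <- spin_up(pr, spec$drivers, sched, tol = spec$spin_tol,
                    max_cycles = spec$spin_cycles)
      traj <- run_simulation(pr, spec$drivers, sched, years = spec$years,
                             state = su$state)
      list(perf = performance(traj), diag = diagnostics(traj))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[r] <- "failed"
    } else {
      status[r] <- "ok"
      perf[r] <- res$perf
      dg[r, ] <- as.numeric(res$diag[1, diag_cols])
    }
  }
  tibble::tibble(
    species = species_id, n_level = n_level,
    sla = grids$sla[idx$i_sla], h = grids$h[idx$i_h],
    lls = grids$lls[idx$i_lls], td0 = grids$td0[idx$i_td0],
    i_sla = idx$i_sla, i_h = idx$i_h, i_lls = idx$i_lls, i_td0 = idx$i_td0,
    perf = perf, tibble::as_tibble(dg), status = status
  )
}

## ---- 2-D box optimisation (coordinate golden-section with coarse
## restart), shared by the two calibration routines ----

golden_1d <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

#' Maximise a 2-D objective over a box
#'
#' Coordinate golden-section search seeded by a coarse-grid restart.  A
#' flat objective returns the box centre.
#'
#' @param f Function of `(x, y)` returning a scalar to maximise.
#' @param bounds List with `x = c(lo, hi)`, `y = c(lo, hi)`.
#' @param coarse Points per axis of the coarse seeding grid.
#' @param sweeps Coordinate sweeps.
#' @param tol Absolute tolerance per axis (default: 1e-3 of the span).
#' @return List with `x`, `y`, `value`.
#' @export
maximize_box_2d <- function(f, bounds, coarse = 7, sweeps = 4, tol = NULL) {
  bx <- bounds$x; by <- bounds$y
  stopifnot(all(is.finite(c(bx, by))), bx[1] < bx[2], by[1] < by[2])
  if (is.null(tol)) tol <- 1e-3 * c(diff(bx), diff(by)) else tol <- rep_len(tol, 2)
  gx <- seq(bx[1], bx[2], length.out = coarse)
  gy <- seq(by[1], by[2], length.out = coarse)
  vals <- outer(gx, gy, Vectorize(function(x, y) f(x, y)))
  if (max(vals) - min(vals) < 1e-12 * max(1, abs(max(vals)))) {
    ## flat response: documented tie rule, return the box centre
    return(list(x = mean(bx), y = mean(by), value = f(mean(bx), mean(by))))
  }
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  x <- gx[best[1]]; y <- gy[best[2]]
  for (s in seq_len(sweeps)) {
    x <- golden_1d(function(v) f(v, y), bx[1], bx[2], tol[1])
    y <- golden_1d(function(v) f(x, v), by[1], by[2], tol[2])
  }
  list(x = x, y = y, value = f(x, y))
}

## Equilibrium per-axis structural biomass W_G under given parameters.
equilibrium_axis_biomass <- function(params, drivers, schedule, spin_cycles = 3,
                                     years = 1) {
  su <- spin_up(params, drivers, schedule, max_cycles = spin_cycles)
  traj <- run_simulation(params, drivers, schedule, years = years, state = su$state)
  d <- traj$daily
  mean(d[, "w_shoot"] + d[, "w_root"] + d[, "w_protein"])
}

#' Calibrate the two fine-root parameters
#'
#' Optimises fine-root maximum length and fine-root lifespan by
#' maximising equilibrium per-axis structural biomass (W_G) over a 2-D
#' box, by coordinate golden-section search with a coarse-grid restart.
#'
#' @param params Base [species_params()].
#' @param drivers,schedule Simulation drivers and management.
#' @param bounds List with `root_max_length = c(lo, hi)` (cm) and
#'   `root_lifespan = c(lo, hi)` (degree-days).
#' @param objective Optional replacement objective
#'   `function(root_max_length, root_lifespan) -> W_G`; by default the
#'   equilibrium axis biomass of the simulator.
#' @param ... Passed to [maximize_box_2d()].
#' @return List with `root_max_length`, `root_lifespan`, `w_g`.
#' @export
calibrate_root_params <- function(params, drivers, schedule,
                                  bounds = list(root_max_length = c(10, 80),
                                                root_lifespan = c(300, 1500)),
                                  objective = NULL, ...) {
  if (is.null(objective)) {
    objective <- function(rl, rls) {
      p2 <- params; p2$root_max_length <- rl; p2$root_lifespan <- rls
      equilibrium_axis_biomass(p2, drivers, schedule)
    }
  }
  opt <- maximize_box_2d(objective,
                         list(x = bounds$root_max_length, y = bounds$root_lifespan),
                         ...)
  list(root_max_length = opt$x, root_lifespan = opt$y, w_g = opt$value)
}

#' Calibrate the two axis-demography parameters
#'
#' Optimises the tiller appearance and senescence rates by minimising
#' the squared deviation of equilibrium tiller density from the observed
#' density, with the same box search as [calibrate_root_params()].
#'
#' @param params Base [species_params()].
#' @param observed_td Observed tiller density (tillers m^-2), positive.
#' @param drivers,schedule Simulation drivers and management.
#' @param bounds List with `tiller_app_rate`, `tiller_sen_rate` ranges (d^-1).
#' @param objective Optional replacement objective returning the
#'   simulated equilibrium tiller density.
#' @param ... Passed to [maximize_box_2d()].
#' @return List with `tiller_app_rate`, `tiller_sen_rate`, `td`,
#'   `residual` (squared deviation).
#' @export
calibrate_demography <- function(params, observed_td, drivers, schedule,
                                 bounds = list(tiller_app_rate = c(5e-4, 0.02),
                                               tiller_sen_rate = c(5e-4, 0.05)),
                                 objective = NULL, ...) {
  stopifnot(observed_td > 0)
  if (is.null(objective)) {
    objective <- function(app, sen) {
      p2 <- params; p2$tiller_app_rate <- app; p2$tiller_sen_rate <- sen
      su <- spin_up(p2, drivers, schedule, max_cycles = 3)
      su$state$td
    }
  }
  opt <- maximize_box_2d(function(app, sen) -(objective(app, sen) - observed_td)^2,
                         list(x = bounds$tiller_app_rate, y = bounds$tiller_sen_rate),
                         ...)
  list(tiller_app_rate = opt$x, tiller_sen_rate = opt$y,
       td = objective(opt$x, opt$y), residual = -opt$value)
}
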