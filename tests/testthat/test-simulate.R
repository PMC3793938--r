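test_that("a dark, freezing day leaves only maintenance and turnover fluxes", {
  p <- species_params()
  st <- new_plant_state(p)
  st$soil_n <- 0   # root N uptake does not need light; silence it too
  out <- step_day(st, list(par = 0, temp = 0), p)
  expect_equal(out$rec[["d_tt"]], 0)
  expect_equal(out$rec[["photo"]], 0)
  expect_equal(out$rec[["g_shoot"]] + out$rec[["g_protein"]] + out$rec[["g_root"]], 0)
  ## hand-computed pool changes: maintenance respiration at Q10 scaling,
  ## protein turnover with N remobilisation; nothing else moves
  W <- grasscape:::shoot_mass(st, p) + st$w_root + st$w_protein
  resp <- min(p$r_maint * W * p$q10^((0 - p$temp_ref) / 10), st$wc)
  prot_sen <- p$protein_turnover * st$w_protein
  expect_equal(out$state$wc, st$wc - resp, tolerance = 1e-15)
  expect_equal(out$state$wn,
               st$wn + p$remob_frac * prot_sen * p$n_protein, tolerance = 1e-15)
  expect_equal(out$state$w_protein, st$w_protein - prot_sen)
  expect_equal(out$state$leaf_len, st$leaf_len)     # no extension, no senescence
  expect_equal(out$state$tt, st$tt)                 # no thermal time
})

test_that("the daily step is deterministic", {
  p <- species_params()
  st <- new_plant_state(p)
  a <- step_day(st, list(par = 6, temp = 14), p)
  b <- step_day(st, list(par = 6, temp = 14), p)
  expect_identical(a$rec, b$rec)
  expect_identical(a$state, b$state)
})

test_that("invalid drivers abort with a structured error carrying the day", {
  p <- species_params()
  st <- new_plant_state(p)
  err <- tryCatch(step_day(st, list(par = -1, temp = 10), p, day = 17L),
                  grasscape_sim_error = function(e) e)
  expect_s3_class(err, "grasscape_sim_error")
  expect_equal(err$day, 17L)
})

test_that("a run without light from empty pools produces exactly nothing", {
  p <- species_params()
  st <- new_plant_state(p)
  st$wc <- 0; st$wn <- 0; st$res_c <- 0; st$res_n <- 0
  drv <- quiet_climate(); drv$par[] <- 0
  traj <- run_simulation(p, drv, NULL, years = 1, state = st)
  expect_equal(traj$yearly$total, 0)
  expect_equal(sum(traj$daily[, "photo"]), 0)
})

test_that("compiled and reference engines agree over a managed multi-year run", {
  p <- species_params()
  drv <- gen_climate(1, noise_sd = c(0.5, 0.5), seed = 3)
  sched <- default_schedule(360)
  a <- run_simulation(p, drv, sched, years = 3, engine = "cpp")
  b <- run_simulation(p, drv, sched, years = 3, engine = "r")
  ## before chaotic amplification of sub-ulp rounding noise the two
  ## engines are bit-for-bit comparable; over years they stay within 1e-6
  expect_lt(max(abs(a$daily[1:30, ] - b$daily[1:30, ]) /
                  pmax(abs(b$daily[1:30, ]), 1e-9)), 1e-12)
  expect_lt(max(abs(a$daily - b$daily) / pmax(abs(b$daily), 1e-9)), 1e-6)
  expect_equal(performance(a), performance(b), tolerance = 1e-6)
})

test_that("closed-system C and N ledgers balance through cuts and fertilisation", {
  p <- species_params()
  traj <- run_simulation(p, quiet_climate(), default_schedule(360), years = 2)
  err <- conservation_error(traj)
  expect_lt(err[["c"]], 1e-6)
  expect_lt(err[["n"]], 1e-6)
  ## per-day closure of the C ledger
  d <- traj$daily
  cstock <- d[, "wc"] + d[, "res_c"] +
    p$c_struct * (d[, "w_shoot"] + d[, "w_root"] + d[, "w_protein"])
  lhs <- diff(c(traj$ledger$c_initial, cstock))
  rhs <- d[, "photo"] - d[, "resp"] - d[, "litter_c"] - d[, "harvest_c"] - d[, "exud_c"]
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("annual production satisfies the standing + litter + harvest identity", {
  p <- species_params()
  st <- new_plant_state(p)
  standing0 <- grasscape:::shoot_mass(st, p) + st$w_root + st$w_protein
  traj <- run_simulation(p, quiet_climate(), default_schedule(360), years = 2,
                         state = st)
  d <- traj$daily
  growth <- sum(d[, c("g_shoot", "g_protein", "g_root")])
  stf <- traj$state
  standing1 <- grasscape:::shoot_mass(stf, p) + stf$w_root + stf$w_protein
  expect_equal(growth,
               (standing1 - standing0) + sum(d[, "litter_mass"]) + sum(d[, "harvest_mass"]),
               tolerance = 1e-6)
})

test_that("state variables stay nonnegative and the C:N ratio stays finite", {
  p <- species_params()
  traj <- run_simulation(p, gen_climate(1, noise_sd = c(2, 3), seed = 9),
                         default_schedule(120), years = 2)
  d <- traj$daily
  expect_true(all(d[, c("wc", "wn", "w_shoot", "w_root", "w_protein", "td",
                        "soil_n")] >= 0))
  expect_true(all(is.finite(d[, "cn"])))
  expect_true(all(d[, "height"] <= p$height_shape * p$l0 + 1e-9))
})

test_that("after spin-up the model is quasi-stable year over year", {
  ## demography at its fixed point: the annual attractor is exact
  p <- species_params(tiller_app_rate = 0, tiller_sen_rate = 0)
  drv <- quiet_climate(); sched <- default_schedule(360)
  su <- spin_up(p, drv, sched, max_cycles = 20)
  traj <- run_simulation(p, drv, sched, years = 2, state = su$state)
  y <- traj$yearly$total
  expect_lt(abs(y[2] - y[1]) / y[1], 0.01)
  ## doubling the horizon with cyclic drivers leaves mean production unchanged
  traj4 <- run_simulation(p, drv, sched, years = 4, state = su$state)
  expect_lt(abs(performance(traj4) - performance(traj)) / performance(traj), 0.01)
})

test_that("the annual map has a fixed point when cohort phase is commensurate", {
  ## constant temperature with the phyllochron dividing the annual
  ## thermal time: the leaf cohort cycle closes exactly over a year and
  ## the spin-up finds a true quasi-equilibrium
  ph <- 365 * 15 / 36
  p <- species_params(tiller_app_rate = 0, tiller_sen_rate = 0,
                      lls = 3 * ph, phyllochron = ph)
  drv <- tibble::tibble(day = 1:365, par = 8, temp = 15)
  su <- spin_up(p, drv, NULL, max_cycles = 40)
  expect_true(su$converged)
  expect_lt(su$delta, 1e-3)
})

test_that("photosynthesis is co-limited on average at quasi-equilibrium", {
  ## the light limb oscillates with discrete leaf cohort turnover, so
  ## co-limitation is a temporal-mean statement: stationarity of the
  ## protein allocation coefficient forces the mean log ratio to zero
  ph <- 365 * 15 / 36
  p <- species_params(tiller_app_rate = 0, tiller_sen_rate = 0,
                      lls = 3 * ph, phyllochron = ph)
  drv <- tibble::tibble(day = 1:365, par = 8, temp = 15)
  su <- spin_up(p, drv, NULL, max_cycles = 40)
  traj <- run_simulation(p, drv, NULL, years = 1, state = su$state)
  d <- traj$daily
  expect_lt(abs(mean(log(d[, "a_light"] / d[, "a_cap"]))), 1e-3)
})

test_that("performance averages annual production and matches a daily re-summation", {
  p <- species_params()
  traj <- run_simulation(p, quiet_climate(), default_schedule(360), years = 3)
  expect_equal(performance(traj), mean(traj$yearly$total))
  ## independent re-summation from the daily ledger
  d <- traj$daily
  per_plant <- d[, "td"] / p$plant_density
  daily_tot <- (d[, "g_shoot"] + d[, "g_protein"] + d[, "g_root"]) * per_plant
  yr <- rep(1:3, each = 365)
  expect_equal(performance(traj), mean(tapply(daily_tot, yr, sum)),
               tolerance = 1e-12)
  expect_error(performance(list()), "trajectory")
})

test_that("performance rises with nitrogen supply at fixed traits", {
  p <- species_params()
  drv <- quiet_climate()
  perf <- sapply(c(120, 240, 360), function(n) {
    su <- spin_up(p, drv, gen_management(n), max_cycles = 3)
    performance(run_simulation(p, drv, gen_management(n), years = 2,
                               state = su$state))
  })
  expect_true(all(diff(perf) > 0))
})

test_that("diagnostics summarise the growing season sensibly", {
  p <- species_params()
  traj <- run_simulation(p, quiet_climate(), default_schedule(360), years = 2)
  dg <- diagnostics(traj)
  expect_true(dg$mean_f_int > 0 && dg$mean_f_int <= 1)
  expect_gte(dg$nue, 0)
  expect_gte(dg$rue, 0)
  expect_equal(dg$sra, p$sra)
  expect_true(dg$mean_p >= p$p_min && dg$mean_p <= p$p_max)
})
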