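test_that("light interception follows Beer-Lambert and its limits", {
  expect_equal(light_interception(0, 0.5), 0)
  expect_equal(light_interception(2, 0.5), 1 - exp(-1))
  expect_equal(light_interception(1e6, 0.5), 1)
  lai <- seq(0, 10, by = 0.5)
  expect_true(all(diff(light_interception(lai, 0.8)) > 0))
  expect_error(light_interception(-1, 0.5))
  expect_error(light_interception(1, 0))
})

test_that("photosynthesis is a smooth minimum of its two limbs", {
  p <- species_params()
  expect_equal(photosynthesis(0, 0.005, p), 0)
  expect_equal(photosynthesis(0.001, 0, p), 0)
  ## strictly below each limb away from co-limitation
  a <- p$eps_light * 0.001
  b <- p$amax_protein * 0.05
  expect_lt(photosynthesis(0.001, 0.05, p), min(a, b))
  ## co-limitation bound: within delta of the minimum, delta set by theta
  w <- a / p$amax_protein       # protein mass that equalises the limbs at temp_ref
  ph <- photosynthesis(0.001, w, p)
  delta <- 1 - (1 - sqrt(1 - p$theta_colim)) / p$theta_colim
  expect_lte(ph, a)
  expect_gte(ph, a * (1 - delta) - 1e-12)
})

test_that("N uptake saturates and never exceeds the per-axis soil share", {
  expect_equal(n_uptake(0.02, 0.1, 0, 0.3, 0.5), 0)
  half <- n_uptake(0.02, 0.1, 0.5, 0.3, km = 0.5)
  expect_equal(half, 0.3 * 0.1 * 0.02 / 2)
  sat <- n_uptake(0.02, 0.1, 5000, 0.3, km = 0.5)
  expect_equal(sat, 0.3 * 0.1 * 0.02, tolerance = 1e-3)
  ## cap: a dense stand cannot take more N than the pool holds
  capped <- n_uptake(10, 1, 1, 10, 0.5, td = 5000)
  expect_equal(capped, 1 / 5000)
})

test_that("substrate balance matches an independent signed-flux ledger", {
  expect_equal(substrate_balance(list(wc = 1, wn = 0.2))$pools,
               list(wc = 1, wn = 0.2))
  r <- substrate_balance(list(wc = 1, wn = 0.2), list(photosynthesis = 1))
  expect_equal(r$pools$wc, 2)
  set.seed(11)
  for (i in 1:25) {
    fx <- as.list(stats::setNames(runif(12, 0, 0.2),
      c("photosynthesis", "remobilisation_c", "respiration", "partitioning_c",
        "storage_c", "exudation_c", "uptake", "fixation", "remobilisation_n",
        "partitioning_n", "storage_n", "exudation_n")))
    pools <- list(wc = runif(1, 0.5, 2), wn = runif(1, 0.5, 2))
    out <- substrate_balance(pools, fx)
    ## independently coded ledger
    exp_wc <- pools$wc + fx$photosynthesis + fx$remobilisation_c -
      fx$respiration - fx$partitioning_c - fx$storage_c - fx$exudation_c
    exp_wn <- pools$wn + fx$uptake + fx$fixation + fx$remobilisation_n -
      fx$partitioning_n - fx$storage_n - fx$exudation_n
    expect_equal(out$pools$wc, exp_wc, tolerance = 1e-12)
    expect_equal(out$pools$wn, exp_wn, tolerance = 1e-12)
  }
})

test_that("sink down-scaling keeps pools at exactly zero, never negative", {
  out <- substrate_balance(list(wc = 0.1, wn = 0.1),
                           list(respiration = 1, partitioning_c = 1,
                                partitioning_n = 0.5))
  expect_equal(out$pools$wc, 0)
  expect_equal(out$pools$wn, 0)
  expect_equal(out$scale_c, 0.05)
  expect_equal(out$applied$respiration, 0.05)  # common factor on all C sinks
  expect_equal(out$applied$partitioning_c, 0.05)
  expect_error(substrate_balance(list(wc = 1, wn = 1), list(bogus = 1)), "unknown flux")
  expect_error(substrate_balance(list(wc = 1, wn = 1), list(respiration = -1)))
})

test_that("functional balance shifts allocation to roots under N scarcity", {
  p <- species_params()
  ## at the target C:N the fixed point is p_ref
  pools <- list(wc = p$cn_target * 0.01, wn = 0.01)
  x <- 0.5
  for (i in 1:200) x <- functional_balance_p(pools, p, x)
  expect_equal(x, p$p_ref, tolerance = 1e-6)
  ## doubled C:N doubles the target (inside the bounds)
  pools2 <- list(wc = 2 * p$cn_target * 0.01, wn = 0.01)
  y <- p$p_ref
  for (i in 1:200) y <- functional_balance_p(pools2, p, y)
  expect_equal(y, min(2 * p$p_ref, p$p_max), tolerance = 1e-6)
  expect_error(functional_balance_p(list(wc = 1, wn = 0), p, 0.3))
})

test_that("coordination drives Q to photosynthetic co-limitation", {
  p <- species_params()
  expect_equal(coordination_q(1, 1, p, 0.2), 0.2)      # equal rates: no update
  expect_gt(coordination_q(2, 1, p, 0.2), 0.2)         # light excess: invest in protein
  expect_lt(coordination_q(1, 2, p, 0.2), 0.2)
  ## closed loop: capacity proportional to q converges to the light limb
  light <- 1
  q <- 0.05
  for (i in 1:2000) q <- coordination_q(light, q * 5, p, q)
  expect_lt(abs(light - q * 5) / light, 1e-3)
  expect_true(q >= p$q_min && q <= 1)
})

test_that("growth follows bilinear substrate control with exact stoichiometry", {
  p <- species_params()
  W <- 0.06
  ## either substrate absent: no growth
  g0 <- growth_and_respiration(list(wc = 0, wn = 0.01), 0.04, 0.015, 0.005,
                               p, 0.3, 0.1, d_tt = 10)
  expect_equal(g0$g_shoot + g0$g_protein + g0$g_root, 0)
  gn <- growth_and_respiration(list(wc = 0.01, wn = 0), 0.04, 0.015, 0.005,
                               p, 0.3, 0.1, d_tt = 10)
  expect_equal(gn$g_shoot + gn$g_protein + gn$g_root, 0)
  ## both substrate terms at half saturation: G = g_max * d_tt * W / 4
  ## (tiny d_tt so neither caps nor substrate scaling bind)
  d_tt <- 1e-3
  pools <- list(wc = p$kc * W, wn = p$kn * W)
  gg <- growth_and_respiration(pools, 0.04, 0.015, 0.005, p, 0.3, 0.1,
                               d_tt = d_tt, temp = p$temp_ref)
  G <- gg$g_shoot + gg$g_protein + gg$g_root
  expect_equal(G, p$g_max * d_tt * W / 4, tolerance = 1e-9)
  ## stoichiometric ledger oracle over random states
  set.seed(5)
  for (i in 1:20) {
    pools <- list(wc = runif(1, 0.001, 0.02), wn = runif(1, 1e-4, 2e-3))
    pq <- c(runif(1, 0.1, 0.7), runif(1, 0.01, 0.5))
    gr <- growth_and_respiration(pools, 0.04, 0.015, 0.005, p, pq[1], pq[2],
                                 d_tt = runif(1, 0, 15))
    G <- gr$g_shoot + gr$g_protein + gr$g_root
    expect_equal(gr$part_c + gr$resp_growth,
                 G * (p$c_struct + (1 - p$y_growth) * p$c_struct / p$y_growth),
                 tolerance = 1e-12)
    expect_equal(gr$part_n,
                 (gr$g_shoot + gr$g_root) * p$n_struct + gr$g_protein * p$n_protein,
                 tolerance = 1e-15)
    ## consumption never exceeds supply
    expect_lte(gr$part_c + gr$resp_growth + gr$resp_maint, pools$wc + 1e-12)
    expect_lte(gr$part_n, pools$wn + 1e-12)
  }
})

test_that("tiller dynamics balance at the critical LAI and self-thin above it", {
  p <- species_params()
  expect_equal(tiller_dynamics(4000, p$lai_crit, 1, p), 4000)
  expect_lt(tiller_dynamics(4000, 2 * p$lai_crit, 1, p), 4000)
  expect_gt(tiller_dynamics(4000, 0.2 * p$lai_crit, 1, p), 4000)
  expect_equal(tiller_dynamics(11, 50 * p$lai_crit, 1, p), p$td_min) # floored
  expect_error(tiller_dynamics(0, 1, 1, p))
  ## sub-critical growth tracks a fine-step integration of the same ODE
  lai <- 0.2 * p$lai_crit; s <- 1
  r <- p$tiller_app_rate * s * (1 - lai / p$lai_crit)
  td_daily <- 4000
  for (d in 1:365) td_daily <- tiller_dynamics(td_daily, lai, s, p)
  td_fine <- 4000
  for (k in 1:(365 * 1000)) td_fine <- td_fine * (1 + r / 1000)
  expect_equal(td_daily, td_fine, tolerance = 1e-4)
})
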