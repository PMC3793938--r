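test_that("the adaptive peak matches a brute-force scan, with a documented tie rule", {
  ## separable quadratic with the maximum placed on a grid node
  f <- function(sla, h, lls, td0) {
    -(sla - 250)^2 / 1e4 - (h - 46)^2 / 100 - (lls - 500)^2 / 1e4 -
      (td0 - 4000)^2 / 1e6
  }
  tab <- analytic_landscape(f)
  opt <- find_trait_max(tab)
  expect_equal(unname(opt$traits), c(250, 46, 500, 4000))
  bf <- brute_force_max(tab)
  expect_equal(opt$perf, bf$perf)
  ## random landscapes agree with the exhaustive oracle
  set.seed(42)
  for (i in 1:10) {
    tab$perf <- rnorm(nrow(tab))
    expect_equal(find_trait_max(tab)$perf, brute_force_max(tab)$perf)
  }
  ## single row
  one <- tab[5, ]
  expect_equal(find_trait_max(one)$perf, one$perf)
  ## exact tie: lowest grid-index tuple wins
  tab$perf <- 1
  opt_tie <- find_trait_max(tab)
  expect_equal(unname(opt_tie$idx), c(1L, 1L, 1L, 1L))
  ## all-failed table rejected
  tab$status <- "failed"
  expect_error(find_trait_max(tab), "no successfully completed rows")
})

test_that("ridge fitting recovers an analytic locus exactly", {
  ## performance -(j - 0.5 i - 3)^2 on grids holding the exact optima:
  ## sla in {2,4,6,8} -> td0* = 0.5 sla + 3 in {4,5,6,7}
  grids <- list(sla = c(2, 4, 6, 8), h = 46, lls = 500, td0 = 4:7)
  f <- function(sla, h, lls, td0) -(td0 - 0.5 * sla - 3)^2
  tab <- analytic_landscape(f, grids)
  r <- fit_ridge(tab, "sla", "td0")
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 3, tolerance = 1e-12)
  expect_equal(r$r2, 1)
  expect_equal(r$n, 4L)
  ## permuting row order leaves the fit unchanged
  set.seed(1)
  tab2 <- tab[sample(nrow(tab)), ]
  r2 <- fit_ridge(tab2, "sla", "td0")
  expect_equal(r2$slope, r$slope)
  expect_equal(r2$intercept, r$intercept)
  ## performance independent of j: ties resolve to the lowest j, slope 0
  tab3 <- analytic_landscape(function(sla, h, lls, td0) sla, grids)
  r3 <- fit_ridge(tab3, "sla", "td0")
  expect_equal(r3$slope, 0)
  expect_true(all(r3$points$jstar == 4))
  ## missing sub-grid rows are rejected
  expect_error(fit_ridge(tab[-1, ], "sla", "td0"), "missing sub-grid")
})

test_that("the coordination index sums absolute relative slopes", {
  mk <- function(i, j, slope) {
    structure(list(trait_i = i, trait_j = j, slope = slope, intercept = 0,
                   r2 = 1, n = 5, points = NULL), class = "ridge_fit")
  }
  obs <- c(sla = 250, h = 46, lls = 500, td0 = 4000)
  pairs <- list(c("sla", "h"), c("sla", "lls"), c("sla", "td0"),
                c("h", "lls"), c("h", "td0"), c("lls", "td0"))
  zero <- lapply(pairs, function(p) mk(p[1], p[2], 0))
  expect_equal(alpha_sum(zero, obs)$alpha_sum, 0)
  ## one pair with relative slope -0.5
  one <- zero
  one[[2]] <- mk("sla", "lls", -0.5 * 500 / 250)
  expect_equal(alpha_sum(one, obs)$alpha_sum, 0.5)
  ## re-summation oracle on random slopes
  set.seed(7)
  sl <- rnorm(6)
  rl <- lapply(seq_along(pairs), function(k) mk(pairs[[k]][1], pairs[[k]][2], sl[k]))
  out <- alpha_sum(rl, obs)
  manual <- sum(abs(sapply(seq_along(pairs), function(k) {
    sl[k] * obs[[pairs[[k]][1]]] / obs[[pairs[[k]][2]]]
  })))
  expect_equal(out$alpha_sum, manual, tolerance = 1e-12)
  expect_error(alpha_sum(rl, c(sla = 0, h = 46, lls = 500, td0 = 4000)))
  expect_error(alpha_sum(rl[1:5], obs))
})

test_that("reduced major axis regression matches its closed form", {
  f <- rma_fit(1:3, c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)
  ## identity data
  g <- rma_fit(1:5, 1:5)
  expect_equal(g$slope, 1); expect_equal(g$intercept, 0); expect_equal(g$r2, 1)
  ## closed form on random data; swapping x and y inverts the slope
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.8 * x + rnorm(20, sd = 0.5)
    f <- rma_fit(x, y)
    expect_equal(abs(f$slope), sd(y) / sd(x), tolerance = 1e-12)
    expect_equal(sign(f$slope), sign(cor(x, y)))
    expect_equal(f$intercept, mean(y) - f$slope * mean(x), tolerance = 1e-12)
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-12)
    expect_equal(rma_fit(y, x)$slope, 1 / f$slope, tolerance = 1e-12)
  }
  ## anti-correlated data gets a negative slope
  expect_lt(rma_fit(1:10, -(1:10) + rnorm(10, sd = 0.1))$slope, 0)
  expect_error(rma_fit(rep(1, 5), 1:5), "degenerate")
  expect_error(rma_fit(1:2, 1:2), "length")
})

test_that("plasticity prediction equals the conditional argmax on the landscape", {
  f <- function(sla, h, lls, td0) {
    -(sla - 250)^2 / 1e4 - (h - 46)^2 / 100 - (lls - 500)^2 / 1e4 -
      (td0 - 4000)^2 / 1e6
  }
  tab <- analytic_landscape(f)
  opt <- find_trait_max(tab)
  ## fixing the others at the optimum returns the trait_max component
  fx <- as.list(opt$traits[c("h", "lls", "td0")])
  expect_equal(predict_plasticity(tab, fx, "sla")$value, opt$traits[["sla"]])
  ## separable landscape: conditional argmax equals the global component
  ## for any admissible fixed values (exhaustive conditional oracle)
  fx2 <- list(h = 40, lls = 600, td0 = 3000)
  pred <- predict_plasticity(tab, fx2, "sla")
  sub <- tab[tab$h == 40 & tab$lls == 600 & tab$td0 == 3000, ]
  expect_equal(pred$value, sub$sla[which.max(sub$perf)])
  expect_equal(pred$value, 250)
  ## non-grid fixed values snap to the nearest node
  pred2 <- predict_plasticity(tab, list(h = 41.2, lls = 590, td0 = 3100), "sla")
  expect_equal(pred2$fixed_used$h, 40)
  ## outside the hull: rejected
  expect_error(predict_plasticity(tab, list(h = 20, lls = 500, td0 = 4000), "sla"),
               "hull")
})

test_that("PCA comparison is exact for identical matrices and closed-form for two traits", {
  set.seed(8)
  X <- matrix(rnorm(48), 12, 4,
              dimnames = list(NULL, c("sla", "h", "lls", "td0")))
  pc <- pca_compare(X, X)
  expect_equal(pc$axes$slope, rep(1, 4), tolerance = 1e-9)
  expect_equal(pc$axes$r2, rep(1, 4), tolerance = 1e-9)
  expect_equal(pc$axes$rel_rmse, rep(0, 4), tolerance = 1e-9)
  expect_equal(sum(pc$var_frac_pred), 1)
  expect_equal(sum(pc$var_frac_obs), 1)
  ## loadings are orthonormal
  expect_equal(crossprod(pc$loadings_obs), diag(4), tolerance = 1e-9)
  ## two correlated variables: axis variances (1 + rho)/2 and (1 - rho)/2
  n <- 5000
  z <- rnorm(n); x1 <- z + rnorm(n); x2 <- z + rnorm(n)
  rho <- cor(x1, x2)
  pc2 <- grasscape:::trait_pca(cbind(a = x1, b = x2))
  expect_equal(pc2$var_frac, c((1 + rho) / 2, (1 - rho) / 2), tolerance = 1e-9)
  ## rank-deficient input rejected
  Y <- X; Y[, 2] <- 2 * Y[, 1]
  expect_error(pca_compare(Y, Y), "rank-deficient")
})

test_that("C:N regressions recover generating coefficients and are order-invariant", {
  set.seed(12)
  n <- 12
  lls <- runif(n, 350, 850)
  h_raw <- runif(n, 30, 57)
  h <- mean(h_raw) + stats::residuals(stats::lm(h_raw ~ lls))
  a <- -0.004; b <- 0.08
  cn <- 6 + a * lls + b * h + rnorm(n, sd = 0.05)
  optima <- tibble::tibble(cn = cn, lls = lls, h = h)
  fits <- cn_trait_regressions(optima)
  expect_lt(abs(fits$fit_lls$slope - a), 2 * fits$fit_lls$slope_se)
  expect_lt(abs(fits$fit_h_resid$slope - b), 2 * fits$fit_h_resid$slope_se)
  ## row order invariance
  perm <- sample(n)
  fits2 <- cn_trait_regressions(optima[perm, ])
  expect_equal(fits2$fit_lls$slope, fits$fit_lls$slope)
  expect_equal(fits2$fit_h_resid$slope, fits$fit_h_resid$slope)
  ## exactly linear in LLS: residuals vanish and the height fit is flat
  optima$cn <- 6 + a * optima$lls
  fits3 <- cn_trait_regressions(optima)
  expect_equal(fits3$residuals, rep(0, n), tolerance = 1e-10)
  expect_equal(fits3$fit_h_resid$slope, 0, tolerance = 1e-10)
  expect_error(cn_trait_regressions(optima[1:2, ]))
})

test_that("variance decomposition attributes shares that sum to one hundred", {
  set.seed(4)
  n <- 400
  u <- rnorm(n)
  v <- stats::residuals(stats::lm(rnorm(n) ~ u))  # exactly orthogonal to u
  tab <- tibble::tibble(perf = u, mean_f_int = u, net_photo = v, status = "ok")
  w <- variance_decomposition(tab, c("mean_f_int", "net_photo"))
  expect_equal(unname(w[1]), 100, tolerance = 1e-6)
  expect_equal(unname(w[2]), 0, tolerance = 1e-6)
  ## symmetric case: independent standardised contributions split evenly
  tab2 <- tibble::tibble(perf = u + v, mean_f_int = u, net_photo = v, status = "ok")
  w2 <- variance_decomposition(tab2, c("mean_f_int", "net_photo"))
  expect_equal(unname(w2[1]), 50, tolerance = 5)
  expect_equal(sum(w2), 100, tolerance = 1e-9)
  ## collinear pair: undefined
  tab3 <- tibble::tibble(perf = u, mean_f_int = u, net_photo = u * 2, status = "ok")
  expect_error(variance_decomposition(tab3, c("mean_f_int", "net_photo")),
               "collinear")
})
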