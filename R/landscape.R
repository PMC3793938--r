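#' Locate the adaptive peak of a landscape table
#'
#' Exact argmax of performance over the successfully completed rows of a
#' landscape table (one species, one N level).  Ties are broken towards
#' the lowest grid-index tuple (in the order SLA, H, LLS, TD), which is
#' deterministic and documented.
#'
#' @param table A landscape tibble from [run_campaign()] (single species
#'   and N level).
#' @return A list of class `optimum_result`: `traits` (named vector of
#'   the four trait values at the peak), `perf`, `cn` (mean substrate
#'   C:N at the peak), `idx` (grid indices), `row` (the winning row).
#' @export
find_trait_max <- function(table) {
  ok <- table[table$status == "ok" & is.finite(table$perf), ]
  if (!nrow(ok)) stop("no successfully completed rows in landscape table", call. = FALSE)
  best <- max(ok$perf)
  cand <- ok[ok$perf == best, , drop = FALSE]
  if (nrow(cand) > 1L) {
    o <- order(cand$i_sla, cand$i_h, cand$i_lls, cand$i_td0)
    cand <- cand[o[1L], , drop = FALSE]
  }
  structure(list(
    traits = c(sla = cand$sla, h = cand$h, lls = cand$lls, td0 = cand$td0),
    perf = cand$perf, cn = cand$mean_cn,
    idx = c(i_sla = cand$i_sla, i_h = cand$i_h, i_lls = cand$i_lls, i_td0 = cand$i_td0),
    row = cand
  ), class = "optimum_result")
}

.trait_cols <- c("sla", "h", "lls", "td0")
.idx_of <- function(trait) paste0("i_", trait)

#' Fit an adaptive ridge between two traits
#'
#' On the 2-D sub-grid where the other two traits are held at fixed
#' values, the ridge is the locus of locally optimal trait pairs: for
#' every grid value of trait `i`, the value of trait `j` maximising
#' performance is found (grid argmax, ties towards the lower `j`), and an
#' ordinary least-squares line through the `(i, j*)` points gives the
#' ridge slope alpha, intercept and r-squared.
#'
#' @param table Landscape tibble (single species and N level) containing
#'   the full `i` x `j` sub-grid at the fixed values.
#' @param trait_i,trait_j Trait names among `"sla"`, `"h"`, `"lls"`,
#'   `"td0"`.
#' @param fixed Named values of the other two traits selecting the
#'   sub-grid (default: the most frequent value present, i.e. the value
#'   used for slices); matching uses a relative tolerance of 1e-9.
#' @return A list of class `ridge_fit`: `trait_i`, `trait_j`, `slope`,
#'   `intercept`, `r2`, `n`, and the locus `points` (tibble `i`, `jstar`).
#' @export
fit_ridge <- function(table, trait_i, trait_j, fixed = NULL) {
  trait_i <- match.arg(trait_i, .trait_cols)
  trait_j <- match.arg(trait_j, .trait_cols)
  if (trait_i == trait_j) stop("trait_i and trait_j must differ", call. = FALSE)
  others <- setdiff(.trait_cols, c(trait_i, trait_j))
  tab <- table[table$status == "ok", ]
  for (tr in others) {
    val <- if (!is.null(fixed) && !is.null(fixed[[tr]])) fixed[[tr]] else {
      v <- tab[[tr]]; as.numeric(names(sort(table(v), decreasing = TRUE))[1])
    }
    tab <- tab[abs(tab[[tr]] - val) <= 1e-9 * max(abs(val), 1), ]
  }
  gi <- sort(unique(tab[[trait_i]]))
  gj <- sort(unique(tab[[trait_j]]))
  if (length(gi) < 2L) stop("ridge fit needs at least two values of trait_i", call. = FALSE)
  jstar <- numeric(length(gi))
  for (k in seq_along(gi)) {
    sub <- tab[tab[[trait_i]] == gi[k], ]
    if (nrow(sub) < length(gj)) {
      stop("missing sub-grid rows for ", trait_i, " = ", gi[k], call. = FALSE)
    }
    sub <- sub[order(sub[[trait_j]]), ]
    jstar[k] <- sub[[trait_j]][which.max(sub$perf)]  # ties: lower j
  }
  fit <- stats::lm(jstar ~ gi)
  sst <- sum((jstar - mean(jstar))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  structure(list(trait_i = trait_i, trait_j = trait_j,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, n = length(gi),
                 points = tibble::tibble(i = gi, jstar = jstar)),
            class = "ridge_fit")
}

#' Global trait-coordination index from six ridge slopes
#'
#' Each slope alpha(i, j) carries the units of trait `j` per trait `i`;
#' to combine them, every slope is non-dimensionalised by the observed
#' trait ratio (`alpha_rel = alpha * observed_i / observed_j`) and the
#' coordination index is the sum of absolute relative slopes.
#'
#' @param ridges List of six [fit_ridge()] results (one per unordered
#'   trait pair).
#' @param traits_observed Named vector/list of the observed trait values
#'   (`sla`, `h`, `lls`, `td0`), all nonzero.
#' @return A list with `table` (tibble: pair, slope, intercept, r2,
#'   rel_slope) and `alpha_sum`.
#' @export
alpha_sum <- function(ridges, traits_observed) {
  if (length(ridges) != 6L) stop("alpha_sum expects the six trait-pair ridges", call. = FALSE)
  obs <- unlist(traits_observed)[.trait_cols]
  if (any(!is.finite(obs)) || any(obs == 0)) {
    stop("observed trait values must be finite and nonzero", call. = FALSE)
  }
  rows <- lapply(ridges, function(r) {
    rel <- r$slope * obs[[r$trait_i]] / obs[[r$trait_j]]
    tibble::tibble(trait_i = r$trait_i, trait_j = r$trait_j, slope = r$slope,
                   intercept = r$intercept, r2 = r$r2, rel_slope = rel)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, alpha_sum = sum(abs(tab$rel_slope)))
}

#' Reduced major axis regression
#'
#' Symmetric line fit used when both variables carry error: the slope is
#' `sign(cor(x, y)) * sd(y) / sd(x)`, the intercept passes through the
#' means, and r-squared is the squared Pearson correlation.
#'
#' @param x,y Numeric vectors, `n >= 3`, `sd(x) > 0` and `sd(y) > 0`.
#' @return A list of class `rma_fit`: `slope`, `intercept`, `r2`, `n`.
#' @export
#' @examples
#' rma_fit(1:3, c(2, 4, 6))  # slope 2, intercept 0, r2 1
rma_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("rma_fit needs paired vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rma_fit is undefined for degenerate variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)  # zero correlation: magnitude kept
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r2 = r^2, n = length(x)),
            class = "rma_fit")
}

#' Predict a plastic trait response from a high-N landscape
#'
#' The value of the target trait that maximises performance locally when
#' the three remaining traits are forced to given (e.g. low-N observed)
#' values: the high-N landscape is restricted to the sub-grid nearest
#' the three fixed values and the grid argmax over the target trait is
#' returned.  A linear ridge-based prediction
#' `j* = j_peak + alpha * (i_fixed - i_peak)` can be reported alongside
#' for diagnostics via the returned `ridge_prediction` when `ridges` and
#' `optimum` are supplied.
#'
#' @param table High-N landscape tibble (single species).
#' @param fixed Named list of the three fixed trait values; each must
#'   lie within the hull of its grid.
#' @param target Name of the trait to predict.
#' @param ridges Optional list of [fit_ridge()] results with
#'   `trait_j == target` used for the linear diagnostic.
#' @param optimum Optional [find_trait_max()] result for the linear
#'   diagnostic.
#' @return A list with `value` (grid argmax prediction), `fixed_used`
#'   (the snapped grid values), and optionally `ridge_prediction`.
#' @export
predict_plasticity <- function(table, fixed, target, ridges = NULL, optimum = NULL) {
  target <- match.arg(target, .trait_cols)
  others <- setdiff(.trait_cols, target)
  if (!all(others %in% names(fixed))) {
    stop("fixed must name the three traits other than the target", call. = FALSE)
  }
  tab <- table[table$status == "ok", ]
  fixed_used <- list()
  for (tr in others) {
    g <- sort(unique(tab[[tr]]))
    v <- fixed[[tr]]
    if (v < min(g) - 1e-9 * max(abs(g)) || v > max(g) + 1e-9 * max(abs(g))) {
      stop("fixed value for ", tr, " lies outside the grid hull", call. = FALSE)
    }
    snap <- g[which.min(abs(g - v))]
    fixed_used[[tr]] <- snap
    tab <- tab[tab[[tr]] == snap, ]
  }
  if (!nrow(tab)) stop("no landscape rows at the fixed sub-grid", call. = FALSE)
  tab <- tab[order(tab[[target]]), ]
  value <- tab[[target]][which.max(tab$perf)]
  out <- list(value = value, fixed_used = fixed_used)
  if (!is.null(ridges) && !is.null(optimum)) {
    preds <- vapply(ridges, function(r) {
      if (r$trait_j != target) return(NA_real_)
      optimum$traits[[target]] +
        r$slope * (fixed[[r$trait_i]] - optimum$traits[[r$trait_i]])
    }, numeric(1))
    out$ridge_prediction <- mean(preds, na.rm = TRUE)
  }
  out
}

#' Compare predicted and observed trait syndromes by PCA
#'
#' Principal component analysis of each trait matrix on its correlation
#' matrix (traits have incommensurable units), with the sign of each
#' axis fixed so the largest-magnitude loading is positive.  Species
#' scores of the predicted matrix are regressed on those of the observed
#' matrix axis by axis (ordinary least squares), reporting slope,
#' r-squared, and a relative RMSE normalised by the observed score range
#' (in percent).
#'
#' @param predicted,observed Numeric matrices or data frames (species x
#'   traits) with matching rows and columns.
#' @return A list of class `pca_comparison`: `loadings_pred`,
#'   `loadings_obs`, `var_frac_pred`, `var_frac_obs`, and `axes` (tibble
#'   with `axis`, `slope`, `r2`, `rel_rmse`).
#' @export
pca_compare <- function(predicted, observed) {
  P <- as.matrix(predicted); O <- as.matrix(observed)
  if (!identical(dim(P), dim(O))) stop("matrices must have matching dimensions", call. = FALSE)
  pca1 <- trait_pca(P); pca2 <- trait_pca(O)
  k <- ncol(P)
  axes <- lapply(seq_len(k), function(a) {
    x <- pca2$scores[, a]; y <- pca1$scores[, a]
    fit <- stats::lm(y ~ x)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    rng <- diff(range(x))
    sst <- sum((y - mean(y))^2)
    tibble::tibble(axis = a, slope = unname(stats::coef(fit)[2L]),
                   r2 = if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0,
                   rel_rmse = 100 * rmse / rng)
  })
  structure(list(loadings_pred = pca1$loadings, loadings_obs = pca2$loadings,
                 var_frac_pred = pca1$var_frac, var_frac_obs = pca2$var_frac,
                 axes = do.call(rbind, axes)),
            class = "pca_comparison")
}

trait_pca <- function(X) {
  Z <- scale(X)
  if (any(!is.finite(Z))) stop("rank-deficient or constant trait column", call. = FALSE)
  ce <- eigen(stats::cor(X), symmetric = TRUE)
  if (ce$values[length(ce$values)] < 1e-10) {
    stop("rank-deficient trait matrix", call. = FALSE)
  }
  L <- ce$vectors
  ## sign convention: the largest-|loading| trait of each axis is positive
  for (a in seq_len(ncol(L))) {
    big <- which.max(abs(L[, a]))
    if (L[big, a] < 0) L[, a] <- -L[, a]
  }
  rownames(L) <- colnames(X)
  list(loadings = L, var_frac = ce$values / sum(ce$values), scores = Z %*% L)
}

#' Regress optimal substrate C:N on leaf lifespan, then residuals on height
#'
#' Two sequential ordinary least-squares fits across species optima: the
#' optimal substrate C:N ratio against leaf lifespan (the leaf-economics
#' driver), then the residuals of that fit against plant height (the
#' stature driver).
#'
#' @param optima Tibble/data frame with columns `cn`, `lls`, `h`
#'   (one row per species, >= 3 rows).
#' @return A list with `fit_lls` (`slope`, `intercept`, `r2`),
#'   `fit_h_resid` (same, fitted on the residuals), and `residuals`.
#' @export
cn_trait_regressions <- function(optima) {
  if (nrow(optima) < 3L) stop("need at least three species optima", call. = FALSE)
  if (stats::sd(optima$lls) == 0 || stats::sd(optima$h) == 0) {
    stop("degenerate trait variance", call. = FALSE)
  }
  f1 <- stats::lm(cn ~ lls, data = optima)
  res <- stats::residuals(f1)
  f2 <- stats::lm(res ~ h, data = optima)
  summ <- function(f) {
    cf <- stats::coef(f)
    r <- stats::residuals(f)
    y <- r + stats::fitted(f)
    sst <- sum((y - mean(y))^2)
    x <- stats::model.matrix(f)[, 2L]
    se <- sqrt(sum(r^2) / (length(r) - 2L) / sum((x - mean(x))^2))
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
         r2 = if (sst > 0) 1 - sum(r^2) / sst else 0,
         slope_se = se)
  }
  list(fit_lls = summ(f1), fit_h_resid = summ(f2), residuals = unname(res))
}

#' Relative-importance decomposition for a pair of diagnostics
#'
#' Shares of explained variance in performance attributed to two
#' (standardised) explanatory variables, as incremental R-squared
#' averaged over both orders of entry, normalised to sum to 100.
#'
#' @param table Landscape tibble with a `perf` column.
#' @param variable_pair Character vector of two column names.
#' @return Named numeric vector of percentage weights summing to 100.
#' @export
variance_decomposition <- function(table, variable_pair) {
  stopifnot(length(variable_pair) == 2L)
  u <- variable_pair[1L]; v <- variable_pair[2L]
  tab <- table[table$status == "ok", ]
  d <- data.frame(y = tab$perf, u = as.numeric(scale(tab[[u]])),
                  v = as.numeric(scale(tab[[v]])))
  if (abs(stats::cor(d$u, d$v)) > 0.999) {
    stop("variable pair is collinear; decomposition undefined", call. = FALSE)
  }
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- function(fml) {
    if (sst == 0) return(0)
    1 - sum(stats::residuals(stats::lm(fml, data = d))^2) / sst
  }
  r2_u <- r2(y ~ u); r2_v <- r2(y ~ v); r2_uv <- r2(y ~ u + v)
  ## averaged-over-orderings incremental shares
  share_u <- (r2_u + (r2_uv - r2_v)) / 2
  share_v <- (r2_v + (r2_uv - r2_u)) / 2
  tot <- share_u + share_v
  if (tot <= 0) return(stats::setNames(c(50, 50), variable_pair))
  stats::setNames(100 * c(share_u, share_v) / tot, variable_pair)
}

#' Substrate C:N homeostasis along versus across an adaptive ridge
#'
#' Quantifies the homeostasis property of trait coordination: along the
#' fitted ridge locus (the coordinated trait combinations) the mean
#' substrate C:N ratio stays in a narrow range, whereas breaking the
#' coordination moves it far from its optimum.  The broken-coordination
#' locus is the ridge reversed across its midpoint (the through-peak
#' direction orthogonal to the ridge in grid coordinates): it visits the
#' same marginal trait values but pairs them in the opposite order, so
#' the two loci differ only in the trait co-variation.
#'
#' @param table Landscape tibble containing the full 2-D sub-grid.
#' @param trait_i,trait_j Trait pair (see [fit_ridge()]).
#' @param fixed Fixed values of the remaining traits (see [fit_ridge()]).
#' @return List with `cv_ridge` and `cv_broken` (coefficients of
#'   variation of mean substrate C:N along the two loci) and the
#'   underlying `ridge` fit.
#' @export
ridge_homeostasis <- function(table, trait_i, trait_j, fixed = NULL) {
  r <- fit_ridge(table, trait_i, trait_j, fixed = fixed)
  tab <- table[table$status == "ok", ]
  cn_at <- function(iv, jv) {
    hit <- abs(tab[[trait_i]] - iv) <= 1e-9 * max(abs(iv), 1) &
      abs(tab[[trait_j]] - jv) <= 1e-9 * max(abs(jv), 1)
    mean(tab$mean_cn[hit])
  }
  jrev <- rev(r$points$jstar)
  cn_ridge <- mapply(cn_at, r$points$i, r$points$jstar)
  cn_broken <- mapply(cn_at, r$points$i, jrev)
  cv <- function(x) stats::sd(x) / mean(x)
  list(cv_ridge = cv(cn_ridge), cv_broken = cv(cn_broken), ridge = r)
}
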