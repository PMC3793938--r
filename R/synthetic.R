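#' Generate a panel of grass species archetypes
#'
#' Draws `n` trait vectors with the correlation structure the trait
#' literature reports for temperate grasses: a negative rank correlation
#' between SLA and leaf lifespan (the leaf economics spectrum) and a
#' negative rank correlation between plant height and tiller density
#' (the stature/allometry spectrum), with the two spectra independent.
#' Correlations are imposed through a Gaussian copula on ranks; marginals
#' are uniform over the configured ranges.  Remaining physiological
#' parameters are the package defaults.
#'
#' @param n Number of archetype species (>= 1).
#' @param ranges Named list of `c(min, max)` ranges for `sla`
#'   (cm^2 g^-1), `h` (cm), `lls` (degree-days), `td` (tillers m^-2).
#'   Defaults span the observed range of field-parameterised temperate
#'   grasses.
#' @param rho_leaf,rho_stature Copula correlations (negative) for the
#'   SLA-LLS and H-TD pairs.
#' @param seed Integer seed; generation is a pure function of
#'   `(config, seed)`.
#' @return A tibble with columns `species`, `sla`, `h`, `lls`, `td`.
#' @export
#' @examples
#' gen_species(4, seed = 1)
gen_species <- function(n,
                        ranges = list(sla = c(126, 329), h = c(30.5, 56.8),
                                      lls = c(346, 842), td = c(2591, 10053)),
                        rho_leaf = -0.6, rho_stature = -0.6, seed = 1) {
  stopifnot(n >= 1)
  for (nm in c("sla", "h", "lls", "td")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] <= 0 || r[2] < r[1]) {
      stop("ranges$", nm, " must be a positive ordered pair", call. = FALSE)
    }
  }
  ## Gaussian copula: block-diagonal correlation, (sla, lls) and (h, td)
  sigma <- diag(4)
  sigma[1, 3] <- sigma[3, 1] <- rho_leaf      # sla-lls
  sigma[2, 4] <- sigma[4, 2] <- rho_stature   # h-td
  ch <- chol(sigma)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  z <- matrix(stats::rnorm(4L * n), nrow = n) %*% ch
  u <- stats::pnorm(z)
  scale_to <- function(u, r) r[1] + u * (r[2] - r[1])
  tibble::tibble(
    species = sprintf("arch%02d", seq_len(n)),
    sla = scale_to(u[, 1], ranges$sla),
    h = scale_to(u[, 2], ranges$h),
    lls = scale_to(u[, 3], ranges$lls),
    td = scale_to(u[, 4], ranges$td)
  )
}

## Seed hygiene: set the RNG inside a generator and restore afterwards,
## so generators are pure functions of (config, seed).
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Generate multi-year daily weather drivers
#'
#' Sinusoidal seasonal cycles of daily PAR and mean temperature (peak at
#' mid-summer, day 196 of a 365-day year) with independent Gaussian
#' day-to-day noise; PAR is truncated at zero.  With `noise_sd = 0` every
#' year is identical, matching the cyclic-climate convention of
#' multi-year virtual experiments.
#'
#' @param years Number of years (>= 1).
#' @param mean_par,amp_par Mean and seasonal amplitude of PAR
#'   (MJ m^-2 d^-1).
#' @param mean_temp,amp_temp Mean and seasonal amplitude of temperature (C).
#' @param noise_sd Day-to-day noise standard deviations, recycled to the
#'   two variables.
#' @param seed Integer seed.
#' @return A tibble with `day`, `par`, `temp` (365 * years rows).
#' @export
gen_climate <- function(years, mean_par = 8, amp_par = 6, mean_temp = 10,
                        amp_temp = 8, noise_sd = c(1, 1.5), seed = 1) {
  stopifnot(years >= 1)
  noise_sd <- rep_len(noise_sd, 2)
  nd <- 365L * as.integer(years)
  doy <- ((seq_len(nd) - 1L) %% 365L) + 1L
  phase <- cos(2 * pi * (doy - 196) / 365)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  par <- mean_par + amp_par * phase +
    if (noise_sd[1] > 0) stats::rnorm(nd, 0, noise_sd[1]) else 0
  temp <- mean_temp + amp_temp * phase +
    if (noise_sd[2] > 0) stats::rnorm(nd, 0, noise_sd[2]) else 0
  tibble::tibble(day = seq_len(nd), par = pmax(par, 0), temp = temp)
}

#' Generate an annual management schedule
#'
#' Fertilisation events split the annual N total (kgN ha^-1 yr^-1,
#' converted to gN m^-2 by dividing by 10) into equal applications at the
#' configured days; cutting events at the configured days share one
#' residual height.
#'
#' @param annual_n Annual fertiliser N (kgN ha^-1 yr^-1), nonnegative.
#' @param n_apps Number of equal fertiliser applications.
#' @param fert_days Days of year for applications (length `n_apps`).
#' @param cut_days Days of year for cuts.
#' @param residual Residual height after cutting (cm).
#' @return A tibble of events with `day`, `kind`, `magnitude`, sorted by
#'   day.
#' @export
#' @examples
#' gen_management(360)  # four applications of 9 gN m^-2
gen_management <- function(annual_n, n_apps = 4,
                           fert_days = c(75, 135, 195, 255),
                           cut_days = c(150, 210, 270), residual = 5) {
  stopifnot(annual_n >= 0, n_apps >= 0)
  ev <- tibble::tibble(day = integer(), kind = character(), magnitude = numeric())
  if (annual_n > 0 && n_apps > 0) {
    fd <- fert_days[seq_len(n_apps)]
    ev <- rbind(ev, tibble::tibble(day = as.integer(fd), kind = "fertilize",
                                   magnitude = annual_n / 10 / n_apps))
  }
  if (length(cut_days)) {
    ev <- rbind(ev, tibble::tibble(day = as.integer(cut_days), kind = "cut",
                                   magnitude = residual))
  }
  if (anyDuplicated(paste(ev$day, ev$kind))) {
    stop("overlapping same-day duplicate events", call. = FALSE)
  }
  if (any(ev$day < 1 | ev$day > 365)) stop("event days must lie in [1, 365]", call. = FALSE)
  ev[order(ev$day), ]
}
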