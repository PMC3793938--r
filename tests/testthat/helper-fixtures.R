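options(grasscape.quiet = TRUE)

# Shared fixtures, built in code at test time.

quiet_climate <- function(years = 1) gen_climate(years, noise_sd = c(0, 0))

default_schedule <- function(n = 360) gen_management(n)

# Landscape tibble for a single species/level built from an analytic
# performance function perf_fn(sla, h, lls, td0) on the given grids.
analytic_landscape <- function(perf_fn,
                               grids = list(sla = c(200, 250, 300),
                                            h = c(40, 46, 52),
                                            lls = c(400, 500, 600),
                                            td0 = c(3000, 4000, 5000)),
                               cn_fn = function(sla, h, lls, td0) 5) {
  idx <- expand.grid(i_sla = seq_along(grids$sla), i_h = seq_along(grids$h),
                     i_lls = seq_along(grids$lls), i_td0 = seq_along(grids$td0),
                     KEEP.OUT.ATTRS = FALSE)
  sla <- grids$sla[idx$i_sla]; h <- grids$h[idx$i_h]
  lls <- grids$lls[idx$i_lls]; td0 <- grids$td0[idx$i_td0]
  tibble::tibble(
    species = "synthetic", n_level = 360,
    sla = sla, h = h, lls = lls, td0 = td0,
    i_sla = idx$i_sla, i_h = idx$i_h, i_lls = idx$i_lls, i_td0 = idx$i_td0,
    perf = mapply(perf_fn, sla, h, lls, td0),
    mean_cn = mapply(cn_fn, sla, h, lls, td0),
    mean_f_int = 0.7, net_photo = 1, su = 1e-4, nue = 40, rue = 1,
    mean_p = 0.3, mean_q = 0.1, sra = 0.1,
    status = "ok")
}

# Exhaustive argmax oracle over the ok rows of a landscape table.
brute_force_max <- function(table) {
  ok <- table[table$status == "ok", ]
  ok[which.max(ok$perf), ]
}

ref_species_row <- function(abbr) {
  sp <- reference_species()
  i <- match(abbr, sp$abbr)
  tibble::tibble(species = sp$abbr[i], sla = sp$sla[i], h = sp$h[i],
                 lls = sp$lls[i], td = sp$td[i])
}
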