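#' Construct a functional trait vector
#'
#' The four manipulated traits of the virtual experiment: specific leaf
#' area (SLA), potential plant height (H), leaf lifespan (LLS) and initial
#' tiller density (TD0).
#'
#' @param sla Specific leaf area, leaf area per dry mass (cm^2 g^-1).
#'   Must lie in \[50, 500\].
#' @param h Potential plant height (cm).
#' @param lls Leaf lifespan in thermal time (degree-days). Must lie in
#'   \[100, 1500\].
#' @param td0 Initial tiller density (tillers m^-2).
#'
#' @return A named list of class `trait_vector`.
#' @export
#' @examples
#' trait_vector(sla = 263, h = 56.8, lls = 549, td0 = 2591)
trait_vector <- function(sla, h, lls, td0) {
  tv <- list(sla = sla, h = h, lls = lls, td0 = td0)
  validate_trait_vector(tv)
  structure(tv, class = "trait_vector")
}

validate_trait_vector <- function(tv) {
  for (nm in c("sla", "h", "lls", "td0")) {
    v <- tv[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("trait_validation_error: trait '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (tv$sla < 50 || tv$sla > 500) {
    stop("trait_validation_error: sla must lie in [50, 500] cm^2 g^-1", call. = FALSE)
  }
  if (tv$lls < 100 || tv$lls > 1500) {
    stop("trait_validation_error: lls must lie in [100, 1500] degree-days", call. = FALSE)
  }
  invisible(tv)
}

#' Default species parameter set
#'
#' Returns the full physiological and morphological parameter set of one
#' average temperate C3 grass, broadly representative of a productive
#' perennial ryegrass-type species.  Trait-derived parameters (`ldmc`,
#' `l0`, `phyllochron`, `td0`) are consistent with the default observed
#' traits (SLA 250 cm^2 g^-1, H 46 cm, LLS 500 degree-days, TD 4000
#' tillers m^-2).  Any entry can be overridden through `...`.
#'
#' Units follow field conventions: masses in g (dry matter, C or N),
#' lengths in cm, areas in cm^2 (leaves) or m^2 (roots, ground), thermal
#' time in degree-days above 0 degrees C, rates per day unless stated.
#'
#' @param ... Named overrides of individual parameters.
#' @return A named list of class `species_params`.
#' @export
#' @examples
#' p <- species_params(lai_crit = 4.5)
#' p$ldmc
species_params <- function(...) {
  p <- list(
    ## observed traits (the grid centres of the virtual experiment)
    sla = 250, h = 46, lls = 500, td0 = 4000,

    ## shoot morphology
    ldmc           = 0.2,    # leaf dry-matter content (g g^-1); = 1/(sla * thickness * 1 g cm^-3)
    l0             = 23,     # potential mature lamina length (cm); = h / height_shape
    phyllochron    = 500 / 3, # thermal time between leaf appearances (degree-days)
    leaf_thickness = 0.02,   # fresh lamina thickness (cm)
    leaf_width     = 0.12,   # lamina width (cm)
    leaf_form      = 0.75,   # lamina area form factor (area = form * width * length)
    sheath_ratio   = 0.3,    # sheath mass : lamina mass
    height_shape   = 2.0,    # plant height per longest lamina length at reference density
    height_dens_exp = 0.1,   # erectness exponent on td/td0 (denser swards grow more erect)
    n_leaves_alive = 3,      # live leaves per tiller; phyllochron = lls / n_leaves_alive
    t_expand       = 2,      # lamina expansion duration, in phyllochrons

    ## tissue composition
    c_struct  = 0.42,  # C fraction of structural dry mass (g g^-1)
    n_struct  = 0.008, # N fraction of structural dry mass (g g^-1)
    n_protein = 0.16,  # N fraction of photosynthetic protein (g g^-1)

    ## photosynthesis
    amax_protein = 1.0,  # capacity-limited assimilation per protein mass (gC gProtein^-1 d^-1)
    eps_light    = 0.68,  # light-limited conversion (gC MJ^-1 PAR intercepted)
    k_ext        = 0.8,  # canopy extinction coefficient
    theta_colim  = 0.99, # curvature of the smooth-minimum co-limitation response
    c_inh        = 4,    # substrate C feedback threshold (x structural mass)
    n_inh        = 0.2,  # substrate N feedback threshold (x structural mass)
    inh_hill     = 4,    # steepness of the substrate feedback

    ## roots and N uptake
    umax            = 0.3,   # N uptake per root area at saturation (gN m^-2 root d^-1)
    km              = 0.5,   # uptake half-saturation (gN m^-2 soil)
    sra             = 0.1,   # specific root area (m^2 g^-1)
    root_max_length = 40,    # fine root maximum length per axis (cm)
    root_lin_density = 5e-4, # root mass per unit length (g cm^-1)
    root_lifespan   = 800,   # fine root lifespan (degree-days)

    ## tiller demography
    tiller_app_rate = 3e-4,  # relative axis appearance rate (d^-1)
    tiller_sen_rate = 2e-3,  # relative axis senescence rate under crowding (d^-1)
    lai_crit        = 5,     # critical leaf area index for self-thinning
    td_min          = 10,    # floor on tiller density (tillers m^-2)
    plant_density   = 400,   # genets per m^2; tillers per plant = td / plant_density

    ## respiration and growth
    r_maint   = 0.008, # maintenance respiration (gC gDM^-1 d^-1 at 20 C)
    q10       = 2,     # temperature sensitivity of maintenance respiration
    temp_ref  = 20,    # reference temperature (C)
    t_base    = 0,     # base temperature for thermal time (C)
    y_growth  = 0.75,  # growth yield (g structure per g substrate C equivalent)
    g_max     = 0.012, # maximum relative growth (g g^-1 degree-day^-1)
    kc        = 0.05,  # C substrate half-saturation, relative to structural mass
    kn        = 0.004, # N substrate half-saturation, relative to structural mass

    ## allocation
    p_ref = 0.3,  # reference root allocation fraction
    p_min = 0.1, p_max = 0.7,
    tau_p = 5,    # relaxation time of P (days)
    tau_q = 5,    # relaxation time of Q (days)
    q_init = 0.1, # initial fraction of shoot allocation to protein
    q_min  = 0.001,

    ## turnover, reserves, recycling
    protein_turnover = 0.02, # protein degradation rate (d^-1)
    remob_frac   = 0.5,   # fraction of N in senescing tissue recycled to the substrate pool
    store_frac   = 0.05,  # daily fraction of substrate excess over cn_target moved to reserves
    res_remob_rate = 0.02, # daily fraction of reserves remobilised to the substrate pool
    exud_frac    = 0.05,  # daily exudation of substrate excess over cn_target
    cn_target    = 5,     # target substrate C:N (gC gN^-1)

    ## soil mineral N
    soil_n_init    = 2,    # initial mineral N (gN m^-2)
    mineralization = 0.02, # background mineral N supply (gN m^-2 d^-1)
    leach_rate     = 0.02  # first-order loss of mineral N (d^-1)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown species parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_species_params(p)
  structure(p, class = "species_params")
}

validate_species_params <- function(p) {
  stopifnot(
    p$ldmc > 0, p$ldmc < 1,
    p$y_growth > 0, p$y_growth <= 1,
    p$p_min < p$p_max,
    p$phyllochron > 0, p$l0 > 0, p$td0 > 0
  )
  rates <- c("umax", "r_maint", "g_max", "tiller_app_rate", "tiller_sen_rate",
             "protein_turnover", "store_frac", "res_remob_rate", "mineralization",
             "leach_rate", "exud_frac")
  for (nm in rates) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  }
  invisible(p)
}

#' Map the four manipulated traits onto model parameters
#'
#' Trait variation enters the simulator through simple parameter
#' mappings: SLA through leaf dry-matter content (constant lamina
#' thickness and unit fresh-tissue density, so `ldmc = 1/(sla *
#' leaf_thickness)`); plant height through the potential mature lamina
#' length (`l0 = h / height_shape`); leaf lifespan through the
#' phyllochron, keeping the number of live leaves per tiller constant
#' (`phyllochron = lls / n_leaves_alive`); and tiller density as the
#' initial value of the tiller-density state variable.
#'
#' @param traits A [trait_vector()].
#' @param base A [species_params()] set supplying all other parameters.
#' @return A `species_params` copy of `base` with the trait-derived
#'   entries replaced.
#' @export
#' @examples
#' p <- map_traits_to_params(trait_vector(263, 56.8, 549, 2591), species_params())
#' p$ldmc  # 1/(263 * 0.02)
map_traits_to_params <- function(traits, base) {
  if (!inherits(traits, "trait_vector")) traits <- do.call(trait_vector, as.list(traits)[c("sla", "h", "lls", "td0")])
  validate_trait_vector(traits)
  p <- base
  p$sla <- traits$sla
  p$h <- traits$h
  p$lls <- traits$lls
  p$ldmc <- 1 / (traits$sla * p$leaf_thickness * 1)
  p$l0 <- traits$h / p$height_shape
  p$phyllochron <- traits$lls / p$n_leaves_alive
  p$td0 <- traits$td0
  validate_species_params(p)
  p
}

#' Read the packaged reference table of grass species traits
#'
#' Twelve temperate C3 grass species (eleven natives and one cultivar)
#' with field-parameterised trait values -- SLA (cm^2 g^-1), plant height
#' (cm), leaf lifespan (degree-days), tiller density (tillers m^-2) --
#' and the substrate C:N ratio (gC gN^-1) associated with their
#' performance optimum.
#'
#' @return A tibble with columns `species`, `abbr`, `sla`, `h`, `lls`,
#'   `td`, `cn_ratio`.
#' @export
reference_species <- function() {
  path <- system.file("extdata", "grass_species_reference.csv", package = "grasscape")
  read_table_checked(path, schema = c(
    species = "character", abbr = "character", sla = "numeric", h = "numeric",
    lls = "numeric", td = "numeric", cn_ratio = "numeric"
  ))
}
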