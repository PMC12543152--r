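# Central parameter registry. Every tunable constant of the reduced model lives
# here so that alternative readings (soil topology, envelopes, fire split, ...)
# are config edits, not code edits.

#' Plant functional types
#'
#' The four PFTs of the simulator: needle-leaved evergreen (NE), needle-leaved
#' deciduous (ND), broadleaved deciduous (BD) and broadleaved evergreen (BE).
#' @export
PFT_LEVELS <- c("NE", "ND", "BD", "BE")

#' Soil pool identifiers
#'
#' Stable names of the ten CENTURY-style carbon pools, in cascade order:
#' surface coarse/fine woody debris, surface structural/metabolic litter,
#' surface humus, soil structural/metabolic litter, and the active, slow and
#' passive soil organic matter pools.
#' @export
SOIL_POOLS <- c("SURFCWD", "SURFFWD", "SURFSTRUCT", "SURFMETA", "SURFHUMUS",
                "SOILSTRUCT", "SOILMETA", "ACTIVE", "SLOW", "PASSIVE")

#' Climatic zone labels
#'
#' The five retained grouped Koppen-style classes. Tundra is recognised by
#' [assign_zone()] but never assigned to synthetic grid cells because forests
#' rarely clear the height threshold there.
#' @export
ZONE_LEVELS <- c("arid",
                 "cold with cold summer",
                 "cold with warm summer",
                 "temperate without dry season",
                 "temperate with dry summer")

#' Management scenario labels, also the documented tie-break order
#' @export
SCENARIO_LEVELS <- c("base", "toNE", "toBD", "toBE", "unmanaged")

default_pft_params <- function() {
  data.frame(
    pft            = PFT_LEVELS,
    group          = c("needleleaved", "needleleaved", "broadleaved", "broadleaved"),
    evergreen      = c(TRUE, FALSE, FALSE, TRUE),
    # production
    p_max          = c(3.2, 3.0, 4.0, 3.6),      # kgC m-2 yr-1 at full light capture
    t_opt          = c(11, 9, 16, 20),           # degC, growing-season optimum
    t_width        = c(15, 14, 13, 12),          # degC, breadth of thermal response
    k_leaf         = c(7, 7, 8, 8),              # m2 kgC-1, light-capture saturation
    # allocation of surplus NPP (sum to 1); leaf/fine-root shares divert to
    # stem once the canopy / root system is saturated
    alloc_leaf     = c(0.25, 0.30, 0.30, 0.28),
    alloc_froot    = c(0.25, 0.25, 0.25, 0.25),
    alloc_stem     = c(0.50, 0.45, 0.45, 0.47),
    cleaf_max      = c(0.50, 0.30, 0.30, 0.45),  # kgC m-2, canopy saturation
    cfroot_max     = c(0.30, 0.25, 0.25, 0.30),  # kgC m-2
    # tissue turnover (years)
    leaf_longevity = c(4, 1, 1, 2),
    froot_longevity = c(1, 1, 1, 1),
    # maintenance respiration coefficients, yr-1 at the reference
    # temperature; deciduous tissues respire for roughly half the year,
    # giving broadleaved deciduous stands their higher carbon-use efficiency
    resp_leaf      = c(0.10, 0.06, 0.06, 0.10),
    resp_froot     = c(0.10, 0.08, 0.08, 0.10),
    resp_stem      = c(0.012, 0.010, 0.010, 0.018),
    # mortality
    mort_bg        = c(0.005, 0.006, 0.008, 0.010),  # yr-1 background
    longevity      = c(400, 350, 300, 250),          # years, scales the age term
    ge_threshold   = c(0.20, 0.20, 0.20, 0.20),      # NPP per unit leaf C, yr-1
    # litter quality: metabolic (vs structural) fraction of soft litter
    metabolic_frac = c(0.45, 0.50, 0.60, 0.55),
    # bioclimatic envelope: coldest-month temperature range and minimum GDD5
    tc_min         = c(-35, -60, -25, 0.5),
    tc_max         = c(9, -2, 13, 30),
    gdd_min        = c(400, 350, 400, 1600),
    row.names      = PFT_LEVELS,
    stringsAsFactors = FALSE
  )
}

default_soil_params <- function() {
  k <- c(SURFCWD = 0.04, SURFFWD = 0.20, SURFSTRUCT = 0.50, SURFMETA = 6.0,
         SURFHUMUS = 0.02, SOILSTRUCT = 0.45, SOILMETA = 7.0, ACTIVE = 0.70,
         SLOW = 0.012, PASSIVE = 0.002)
  # Respired fraction of decayed C per source pool; the remainder follows the
  # transfer topology below (dest rows x source columns).
  resp_frac <- c(SURFCWD = 0.55, SURFFWD = 0.55, SURFSTRUCT = 0.55,
                 SURFMETA = 0.55, SURFHUMUS = 0.55, SOILSTRUCT = 0.55,
                 SOILMETA = 0.55, ACTIVE = 0.60, SLOW = 0.55, PASSIVE = 0.55)
  tr <- matrix(0, 10, 10, dimnames = list(SOIL_POOLS, SOIL_POOLS))
  tr["SURFHUMUS", "SURFCWD"]    <- 0.45
  tr["SURFHUMUS", "SURFFWD"]    <- 0.45
  tr["SURFHUMUS", "SURFSTRUCT"] <- 0.30
  tr["ACTIVE",    "SURFSTRUCT"] <- 0.15
  tr["ACTIVE",    "SURFMETA"]   <- 0.45
  tr["ACTIVE",    "SURFHUMUS"]  <- 0.45
  tr["ACTIVE",    "SOILSTRUCT"] <- 0.25
  tr["SLOW",      "SOILSTRUCT"] <- 0.20
  tr["ACTIVE",    "SOILMETA"]   <- 0.45
  tr["SLOW",      "ACTIVE"]     <- 0.37
  tr["PASSIVE",   "ACTIVE"]     <- 0.03
  tr["ACTIVE",    "SLOW"]       <- 0.43
  tr["PASSIVE",   "SLOW"]       <- 0.02
  tr["ACTIVE",    "PASSIVE"]    <- 0.45
  stopifnot(max(abs(resp_frac + colSums(tr) - 1)) < 1e-12)
  list(
    k = k,                      # yr-1 at reference temperature, moist soil
    resp_frac = resp_frac,
    transfer = tr,
    q10 = 2,                    # temperature sensitivity of decomposition
    t_ref = 10,                 # degC
    moist_half = 400,           # mm yr-1 half-saturation of the moisture factor
    doc_leach = 0.01            # DOC fraction of ACTIVE-pool decay (x moisture)
  )
}

#' Model parameters for the reduced forest carbon simulator
#'
#' Returns the full parameter list: PFT physiology and envelopes, allometry,
#' mortality, disturbance, fire, harvest partitioning, Reineke thinning, and
#' the CENTURY-style soil constants. All values are documented defaults; the
#' harvest-partitioning and product-pool constants follow the standard
#' forest-management accounting convention (66%/30% removal of wood/leaf,
#' 67% same-year oxidation of removed wood, 4%/yr product oxidation), the
#' disturbance return interval is 400 years, and the stand has 25 patches.
#'
#' @param overrides named list; entries replace the defaults (one level deep:
#'   a named element of a sub-list replaces only that element).
#' @return A list of class `forest_params`.
#' @examples
#' p <- forest_params()
#' p$harvest$wood_removed
#' p2 <- forest_params(list(disturbance_interval = 200))
#' @export
forest_params <- function(overrides = list()) {
  p <- list(
    n_patches = 25L,
    patch_area = 1000,            # m2, sets the stem count for binomial draws
    # production
    q10_plant = 2,
    resp_t_ref = 10,              # degC
    growth_resp_frac = 0.25,      # fraction of surplus production respired
    co2_beta = 0.5,               # logarithmic CO2 fertilisation factor
    co2_ref = 400,                # ppm
    gpp_moist_half = 300,         # mm yr-1 half-saturation for production
    t_grow_amp_frac = 0.5,        # growing-season T = mean T + frac * seasonal amplitude
    # allometry: per-stem stem mass m (kgC) -> height (m) and diameter (cm)
    allom_height_coef = 5,
    allom_height_exp = 1 / 3,
    allom_mass_coef = 0.06,       # m = coef * D^mass_exp
    allom_mass_exp = 2.5,
    # planting
    sapling_density = 0.5,        # stems m-2
    sapling_cstem = 0.10,         # kgC m-2
    sapling_cleaf = 0.04,
    sapling_cfroot = 0.04,
    replant_lag = 1L,             # years, unless death cause is a clear-cut
    # mortality
    mort_age_scale = 0.3,
    mort_age_exp = 5,
    mort_stress_max = 0.3,
    density_floor = 1e-4,         # stems m-2 below which a cohort is cleared
    # disturbance
    disturbance_interval = 400,   # years, average patch-destroying return interval
    # fire (parametric stand-in; managed stands burn nothing)
    fire = list(
      base_rate = 0.004,          # yr-1 baseline burned fraction
      dry_ref = 800,              # mm yr-1; drier cells burn more
      combust_leaf = 0.9,
      combust_stem = 0.3,
      combust_froot = 0,
      combust_litter = c(SURFCWD = 0.2, SURFFWD = 0.5,
                         SURFSTRUCT = 0.6, SURFMETA = 0.8)
    ),
    # harvest partitioning and product pool
    harvest = list(
      wood_removed = 0.66,        # removed fraction of felled wood (stem+twigs+coarse roots)
      leaf_removed = 0.30,        # removed fraction of felled leaf biomass
      removed_wood_atm = 0.67,    # same-year oxidised fraction of removed wood
      product_oxidation = 0.04    # yr-1 product-pool oxidation rate
    ),
    # litter routing
    cwd_frac = 0.7,               # coarse fraction of dead stem litter (rest is FWD)
    # Reineke thinning
    reineke = list(
      exponent = 1.605,
      sdi = c(needleleaved = 1100, broadleaved = 700),  # stems ha-1 at D = 25 cm
      d_ref = 25,                 # cm
      trigger_frac = 1.0,
      target_frac = 0.9
    ),
    height_threshold = 5,         # m, forest definition
    pft = default_pft_params(),
    soil = default_soil_params()
  )
  for (nm in names(overrides)) {
    if (is.list(p[[nm]]) && !is.data.frame(p[[nm]]) && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) p[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  class(p) <- "forest_params"
  p
}

# height (m) from per-stem stem mass (kgC); zero-density cohorts have height 0
stem_height <- function(cstem, density, params) {
  h <- numeric(length(cstem))
  ok <- density > 0
  h[ok] <- params$allom_height_coef *
    (cstem[ok] / density[ok])^params$allom_height_exp
  h
}

# diameter (cm) from per-stem stem mass (kgC), inverse of the mass allometry
stem_diameter <- function(cstem, density, params) {
  d <- numeric(length(cstem))
  ok <- density > 0
  d[ok] <- (cstem[ok] / density[ok] / params$allom_mass_coef)^(1 / params$allom_mass_exp)
  d
}
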