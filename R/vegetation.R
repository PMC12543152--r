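# Annual cohort dynamics on patches: production and allocation, the three
# mortality channels, stochastic patch-destroying disturbance, the parametric
# fire flux, and height bookkeeping. A cohort is one row of a numeric matrix
# with columns PFT (integer code into PFT_LEVELS), AGE (years), DENS
# (stems m-2), CSTEM, CLEAF, CFROOT (kgC m-2; CSTEM is stem + branches +
# coarse roots). A patch is such a matrix (possibly 0-row).

COH_COLS <- c("PFT", "AGE", "DENS", "CSTEM", "CLEAF", "CFROOT")

#' Create a cohort matrix
#'
#' @param pft PFT labels (see [PFT_LEVELS]) or integer codes.
#' @param density stems per m2.
#' @param cstem,cleaf,cfroot carbon pools, kgC m-2 (stem includes branches and
#'   coarse roots).
#' @param age cohort age in years.
#' @return a cohort matrix with one row per cohort.
#' @export
new_cohorts <- function(pft, density, cstem, cleaf, cfroot, age = 0) {
  code <- if (is.character(pft)) match(pft, PFT_LEVELS) else as.integer(pft)
  if (anyNA(code)) stop("unknown PFT")
  m <- cbind(PFT = code, AGE = age, DENS = density, CSTEM = cstem,
             CLEAF = cleaf, CFROOT = cfroot)
  if (any(m[, c("DENS", "CSTEM", "CLEAF", "CFROOT")] < 0))
    stop("cohort pools and density must be nonnegative")
  m
}

empty_cohorts <- function() {
  matrix(numeric(0), ncol = 6, dimnames = list(NULL, COH_COLS))
}

#' Annual production, allocation and tissue turnover for one patch
#'
#' Gross primary production is a light-and-temperature-limited saturating
#' function of leaf carbon with a logarithmic CO2 multiplier and a saturating
#' moisture factor. Autotrophic respiration is Q10 maintenance on all live
#' pools plus a fixed growth fraction of surplus production, capped at GPP so
#' net primary production is never negative. NPP first replaces leaf and
#' fine-root turnover (which falls as litter every year); any surplus is
#' allocated to leaf, fine root and stem growth by PFT-specific fractions.
#' This demand-first allocation gives an undisturbed cohort an interior fixed
#' point.
#'
#' @param cohorts a cohort matrix (may be empty).
#' @param temp annual mean temperature, degC (negative values allowed).
#' @param rad radiation index in `[0, 1]`.
#' @param precip annual precipitation, mm.
#' @param co2 atmospheric CO2, ppm.
#' @param t_amp seasonal half-amplitude, degC; the photosynthesis temperature
#'   is `temp + t_grow_amp_frac * t_amp`.
#' @param params a [forest_params()] list.
#' @return list with updated `cohorts`, patch totals `gpp`, `fra`, `npp`
#'   (kgC m-2 yr-1), litter fluxes `litter_leaf`, `litter_froot`, and the
#'   per-cohort growth efficiency `ge` (NPP per unit leaf C) used by the
#'   stress-mortality channel.
#' @export
annual_production <- function(cohorts, temp, rad, precip, co2, t_amp = 0,
                              params = forest_params()) {
  if (any(!is.finite(c(temp, rad, precip, co2))))
    stop("non-finite forcing")
  if (nrow(cohorts) == 0)
    return(list(cohorts = cohorts, gpp = 0, fra = 0, npp = 0,
                litter_leaf = 0, litter_froot = 0, ge = numeric(0)))
  pp <- params$pft
  i <- cohorts[, "PFT"]
  cleaf <- cohorts[, "CLEAF"]; cfroot <- cohorts[, "CFROOT"]
  cstem <- cohorts[, "CSTEM"]

  t_grow <- temp + params$t_grow_amp_frac * t_amp
  f_t <- exp(-((t_grow - pp$t_opt[i]) / pp$t_width[i])^2)
  f_co2 <- pmax(0, 1 + params$co2_beta * log(co2 / params$co2_ref))
  f_m <- precip / (precip + params$gpp_moist_half)
  # shared canopy: light capture saturates on the total patch leaf carbon
  # and is divided among cohorts by their leaf share
  cleaf_tot <- sum(cleaf)
  share <- if (cleaf_tot > 0) cleaf / cleaf_tot else cleaf
  gpp <- pp$p_max[i] * rad * f_t * f_co2 * f_m *
    (1 - exp(-pp$k_leaf[i] * cleaf_tot)) * share

  q10 <- params$q10_plant^((temp - params$resp_t_ref) / 10)
  maint <- q10 * (pp$resp_leaf[i] * cleaf + pp$resp_froot[i] * cfroot +
                    pp$resp_stem[i] * cstem)
  surplus_pot <- gpp - maint
  surplus_pot[surplus_pot < 0] <- 0
  growth_resp <- params$growth_resp_frac * surplus_pot
  npp <- surplus_pot - growth_resp
  fra <- gpp - npp                         # starvation: FRa capped at GPP

  # turnover demand and demand-first allocation
  lit_leaf <- cleaf / pp$leaf_longevity[i]
  lit_froot <- cfroot / pp$froot_longevity[i]
  demand <- lit_leaf + lit_froot
  cover <- rep(1, length(npp))
  nz <- demand > 0
  cover[nz] <- pmin(1, npp[nz] / demand[nz])
  surplus <- npp - demand
  surplus[surplus < 0] <- 0

  # saturating soft-tissue pools: once leaf/fine-root pools reach their PFT
  # maxima their surplus share diverts to stem growth
  al <- pp$alloc_leaf[i] * (cleaf < pp$cleaf_max[i])
  af <- pp$alloc_froot[i] * (cfroot < pp$cfroot_max[i])
  cohorts[, "CLEAF"] <- cleaf - lit_leaf + cover * lit_leaf + al * surplus
  cohorts[, "CFROOT"] <- cfroot - lit_froot + cover * lit_froot + af * surplus
  cohorts[, "CSTEM"] <- cstem + (1 - al - af) * surplus
  cohorts[, "AGE"] <- cohorts[, "AGE"] + 1

  met <- pp$metabolic_frac[i]
  list(cohorts = cohorts, gpp = sum(gpp), fra = sum(fra), npp = sum(npp),
       litter_leaf = sum(lit_leaf), litter_froot = sum(lit_froot),
       litter_leaf_met = sum(met * lit_leaf),
       litter_froot_met = sum(met * lit_froot),
       ge = ifelse(cleaf > 0, npp / cleaf, 0))
}

#' Apply the three mortality channels to one patch
#'
#' Channels: (1) background mortality rising with relative age,
#' `mort_bg + mort_age_scale * (age/longevity)^mort_age_exp`; (2)
#' growth-efficiency stress, with probability increasing linearly as NPP per
#' unit leaf carbon falls below the PFT threshold; (3) bioclimatic kill, the
#' whole cohort dying when the coldest-month temperature or growing-degree
#' days fall outside the PFT envelope. The killed fraction is drawn
#' binomially over the patch's stems (or applied as the expected fraction
#' when `stochastic = FALSE`). Dead carbon is returned by organ.
#'
#' @param cohorts cohort matrix.
#' @param ge per-cohort growth efficiency from [annual_production()]; pass
#'   `NULL` to skip the stress channel.
#' @param climate a [climate_summary()] list (`t_cold`, `gdd5`), or `NULL` to
#'   skip the bioclimatic channel.
#' @param params a [forest_params()] list.
#' @param stochastic draw binomial kills (default) or remove the expected
#'   fraction.
#' @return list: `cohorts` (survivors), `dead_stem`, `dead_leaf`,
#'   `dead_froot` (kgC m-2).
#' @export
apply_mortality <- function(cohorts, ge = NULL, climate = NULL,
                            params = forest_params(), stochastic = TRUE) {
  if (nrow(cohorts) == 0)
    return(list(cohorts = cohorts, dead_stem = 0, dead_leaf = 0, dead_froot = 0))
  pp <- params$pft
  i <- cohorts[, "PFT"]
  p_bg <- pp$mort_bg[i] +
    params$mort_age_scale * (cohorts[, "AGE"] / pp$longevity[i])^params$mort_age_exp
  p_str <- 0
  if (!is.null(ge)) {
    thr <- pp$ge_threshold[i]
    p_str <- params$mort_stress_max * pmax(0, 1 - ge / thr)
  }
  p <- 1 - (1 - pmin(1, p_bg)) * (1 - pmin(1, p_str))
  if (!is.null(climate)) {
    out_env <- climate$t_cold < pp$tc_min[i] | climate$t_cold > pp$tc_max[i] |
      climate$gdd5 < pp$gdd_min[i]
    p[out_env] <- 1
  }
  n_stems <- round(cohorts[, "DENS"] * params$patch_area)
  if (stochastic) {
    nr <- nrow(cohorts)
    killed <- stats::rbinom(nr, n_stems, pmin(1, p)) / pmax(1, n_stems)
    killed[n_stems == 0 | p >= 1] <- p[n_stems == 0 | p >= 1]
    killed[p >= 1] <- 1
  } else {
    killed <- pmin(1, p)
  }
  # cohorts falling below the density floor die entirely (their remaining
  # carbon is routed to litter with the rest of the kill)
  floor_kill <- (1 - killed) * cohorts[, "DENS"] <= params$density_floor
  killed[floor_kill] <- 1
  dead_stem <- sum(killed * cohorts[, "CSTEM"])
  dead_leaf <- sum(killed * cohorts[, "CLEAF"])
  dead_froot <- sum(killed * cohorts[, "CFROOT"])
  met <- pp$metabolic_frac[i]
  dead_leaf_met <- sum(killed * met * cohorts[, "CLEAF"])
  dead_froot_met <- sum(killed * met * cohorts[, "CFROOT"])
  keep <- 1 - killed
  cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT")] <-
    cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT"), drop = FALSE] * keep
  cohorts <- cohorts[cohorts[, "DENS"] > 0, , drop = FALSE]
  list(cohorts = cohorts, dead_stem = dead_stem, dead_leaf = dead_leaf,
       dead_froot = dead_froot, dead_leaf_met = dead_leaf_met,
       dead_froot_met = dead_froot_met)
}

#' Draw which patches are destroyed by disturbance this year
#'
#' Each patch is independently destroyed with annual probability
#' `1 / return_interval`. An infinite interval disables the process.
#'
#' @param n_patches number of patches.
#' @param return_interval average return interval in years (> 0; may be `Inf`).
#' @return logical vector of destroyed patches.
#' @export
disturbance_draw <- function(n_patches, return_interval) {
  if (is.na(return_interval) || return_interval <= 0)
    stop("return_interval must be positive")
  if (!is.finite(return_interval)) return(rep(FALSE, n_patches))
  stats::runif(n_patches) < 1 / return_interval
}

#' Simulate a multi-patch disturbance record
#'
#' Convenience wrapper for calibration experiments: draws the annual
#' destruction indicator for every patch over many years.
#'
#' @param n_patches,years dimensions of the record.
#' @param return_interval average return interval, years.
#' @param seed integer seed.
#' @return logical matrix (years x patches).
#' @export
simulate_disturbance <- function(n_patches, years, return_interval, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  matrix(stats::runif(n_patches * years) < 1 / return_interval,
         nrow = years, ncol = n_patches)
}

#' Empirical mean interval between destruction events
#'
#' @param events logical matrix from [simulate_disturbance()].
#' @return list: `mean` interval (years), `n` complete intervals, `se`
#'   (standard error of the mean).
#' @export
mean_disturbance_interval <- function(events) {
  gaps <- unlist(lapply(seq_len(ncol(events)), function(j) {
    yrs <- which(events[, j])
    if (length(yrs) > 1) diff(yrs) else numeric(0)
  }))
  list(mean = mean(gaps), n = length(gaps),
       se = stats::sd(gaps) / sqrt(length(gaps)))
}

#' Parametric fire flux for one unmanaged patch
#'
#' Managed patches burn nothing, exactly. On unmanaged patches an annual
#' burned fraction (base rate times a dryness multiplier) combusts fixed
#' fractions of leaf, stem and surface litter carbon; killed-but-uncombusted
#' biomass of burned stems goes to litter.
#'
#' @param cohorts cohort matrix.
#' @param surf_litter named vector of the four surface litter pools
#'   (`SURFCWD`, `SURFFWD`, `SURFSTRUCT`, `SURFMETA`), kgC m-2.
#' @param managed logical; managed patches return zero flux.
#' @param precip annual precipitation (mm), drives the dryness multiplier
#'   `max(0.2, 2 - precip / dry_ref)`.
#' @param params a [forest_params()] list.
#' @return list: updated `cohorts` and `surf_litter`, total `ffire`,
#'   `ffire_stem` (live-stem combustion only, for the stem turnover ledger),
#'   and `dead_stem`, `dead_leaf`, `dead_froot` killed but not combusted.
#' @export
apply_fire <- function(cohorts, surf_litter, managed, precip,
                       params = forest_params()) {
  zero <- list(cohorts = cohorts, surf_litter = surf_litter, ffire = 0,
               ffire_stem = 0, ffire_litter = 0, dead_stem = 0,
               dead_leaf = 0, dead_froot = 0)
  if (managed) return(zero)
  fp <- params$fire
  fb <- fp$base_rate * max(0.2, 2 - precip / fp$dry_ref)
  if (fb < 0 || fb > 1) stop("burned fraction outside [0, 1]")
  if (fb == 0 || nrow(cohorts) == 0) {
    if (fb == 0) return(zero)
  }
  ffire <- 0; ffire_stem <- 0
  dead_stem <- dead_leaf <- dead_froot <- 0
  if (nrow(cohorts) > 0) {
    kfrac <- rep(fb, nrow(cohorts))
    kfrac[(1 - fb) * cohorts[, "DENS"] <= params$density_floor] <- 1
    ks <- kfrac * cohorts[, "CSTEM"]; kl <- kfrac * cohorts[, "CLEAF"]
    kf <- kfrac * cohorts[, "CFROOT"]
    ffire_stem <- sum(fp$combust_stem * ks)
    ffire <- ffire_stem + sum(fp$combust_leaf * kl) + sum(fp$combust_froot * kf)
    dead_stem <- sum((1 - fp$combust_stem) * ks)
    dead_leaf <- sum((1 - fp$combust_leaf) * kl)
    dead_froot <- sum((1 - fp$combust_froot) * kf)
    cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT")] <-
      cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT"), drop = FALSE] * (1 - kfrac)
    cohorts <- cohorts[cohorts[, "DENS"] > 0, , drop = FALSE]
  }
  cl <- fp$combust_litter[names(surf_litter)]
  burn_lit <- fb * cl * surf_litter
  ffire_litter <- sum(burn_lit)
  ffire <- ffire + ffire_litter
  surf_litter <- surf_litter - burn_lit
  list(cohorts = cohorts, surf_litter = surf_litter, ffire = ffire,
       ffire_stem = ffire_stem, ffire_litter = ffire_litter,
       dead_stem = dead_stem, dead_leaf = dead_leaf, dead_froot = dead_froot)
}

#' Density-weighted mean tree height of a set of patches
#'
#' @param patches list of cohort matrices (or a single matrix).
#' @param params a [forest_params()] list.
#' @return mean height in metres; 0 for an empty stand.
#' @export
mean_height <- function(patches, params = forest_params()) {
  if (is.matrix(patches)) patches <- list(patches)
  dens <- h <- numeric(0)
  for (p in patches) {
    if (nrow(p) == 0) next
    dens <- c(dens, p[, "DENS"])
    h <- c(h, stem_height(p[, "CSTEM"], p[, "DENS"], params))
  }
  if (!length(dens) || sum(dens) == 0) return(0)
  sum(h * dens) / sum(dens)
}

#' Filter cells by the forest height threshold
#'
#' Retains the cells whose scenario-average tree height over the analysis
#' window reaches the threshold (closed lower bound: exactly 5 m is
#' retained).
#'
#' @param heights named numeric vector of cell mean heights (m).
#' @param threshold metres; default the 5-m forest definition.
#' @return the retained names (cell identifiers).
#' @export
forest_filter <- function(heights, threshold = 5) {
  names(heights)[!is.na(heights) & heights >= threshold]
}
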