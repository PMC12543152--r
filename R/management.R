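# Scenario engine: rotation clear-cut scheduling, Reineke-rule thinning,
# scenario-specific replanting, and the wave-based age-structure
# initialisation that converts pristine patches to managed ones every 10
# years before the management period.

#' Is this a clear-cut year?
#'
#' Clear-cuts are synchronised: in every managed option they occur when
#' `year - management_start` is a nonnegative multiple of the rotation
#' length, the first one at the management start itself. The unmanaged
#' option never clear-cuts after the start.
#'
#' @param year simulation year (any integer scale, consistent with
#'   `management_start`).
#' @param cfg list with `option`, `rotation`, `management_start`.
#' @return logical.
#' @examples
#' cfg <- list(option = "base", rotation = 80, management_start = 0)
#' schedule_clearcut(0, cfg); schedule_clearcut(80, cfg); schedule_clearcut(40, cfg)
#' @export
schedule_clearcut <- function(year, cfg) {
  if (cfg$option == "unmanaged") return(FALSE)
  dy <- year - cfg$management_start
  dy >= 0 && dy %% cfg$rotation == 0
}

#' Quadratic mean diameter of a patch
#'
#' @param cohorts cohort matrix.
#' @param params a [forest_params()] list.
#' @return diameter in cm (0 for an empty patch).
#' @export
quad_mean_diameter <- function(cohorts, params = forest_params()) {
  if (nrow(cohorts) == 0) return(0)
  dens <- cohorts[, "DENS"]
  if (any(dens > 0 & cohorts[, "CSTEM"] <= 0))
    stop("nonpositive stem mass with positive density")
  d <- stem_diameter(cohorts[, "CSTEM"], dens, params)
  if (sum(dens) == 0) return(0)
  sqrt(sum(dens * d^2) / sum(dens))
}

#' Reineke-rule thinning of one managed patch
#'
#' The maximum stand density follows Reineke's rule,
#' `N_max = SDI * (D_q / D_ref)^(-a)` with exponent `a = 1.605` and a
#' PFT-group specific stand density index (broadleaves have the lower SDI,
#' so they thin at lower densities). When total stem density exceeds
#' `trigger_frac * N_max`, stems are removed proportionally across cohorts
#' down to `target_frac * N_max`; the removed biomass is returned by organ
#' for harvest partitioning.
#'
#' @param cohorts cohort matrix.
#' @param params a [forest_params()] list.
#' @return list: `cohorts` (after thinning), `felled` (list `wood`, `leaf`,
#'   `froot`, kgC m-2), `removed_frac` of stems.
#' @export
reineke_thin <- function(cohorts, params = forest_params()) {
  none <- list(cohorts = cohorts,
               felled = list(wood = 0, leaf = 0, froot = 0), removed_frac = 0)
  if (nrow(cohorts) == 0) return(none)
  rk <- params$reineke
  dq <- quad_mean_diameter(cohorts, params)
  if (dq <= 0) return(none)
  n_tot <- sum(cohorts[, "DENS"])
  # density-weighted group SDI (stems ha-1 -> stems m-2)
  grp <- params$pft$group[cohorts[, "PFT"]]
  sdi <- sum(rk$sdi[grp] * cohorts[, "DENS"]) / n_tot / 1e4
  n_max <- sdi * (dq / rk$d_ref)^(-rk$exponent)
  if (n_tot <= rk$trigger_frac * n_max) return(none)
  rem_frac <- 1 - rk$target_frac * n_max / n_tot
  felled <- list(wood = rem_frac * sum(cohorts[, "CSTEM"]),
                 leaf = rem_frac * sum(cohorts[, "CLEAF"]),
                 froot = rem_frac * sum(cohorts[, "CFROOT"]))
  cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT")] <-
    cohorts[, c("DENS", "CSTEM", "CLEAF", "CFROOT"), drop = FALSE] * (1 - rem_frac)
  list(cohorts = cohorts, felled = felled, removed_frac = rem_frac)
}

#' Decide the replanting composition and year after a death event
#'
#' The species depend on the scenario: the baseline replants the pre-death
#' composition, the transition options replant only their target PFT, and
#' unmanaged stands regenerate naturally with the locally viable PFTs.
#' Replanting happens with a one-year lag unless the cause is a clear-cut,
#' in which case it happens the same year.
#'
#' @param option one of [SCENARIO_LEVELS].
#' @param prior_composition matrix/data.frame with columns `pft` (codes or
#'   labels) and `share`; used by the baseline option.
#' @param cause `"clearcut"` or `"other-death"`.
#' @param year the event year.
#' @param viable_pfts character vector of locally viable PFTs (for natural
#'   regeneration).
#' @param params a [forest_params()] list (supplies `replant_lag`).
#' @return list: `year` (planting year), `pft` (labels), `share` (fractions
#'   summing to 1), or `NULL` when nothing can be planted.
#' @export
replant_plan <- function(option, prior_composition = NULL,
                         cause = c("other-death", "clearcut"), year,
                         viable_pfts = PFT_LEVELS, params = forest_params()) {
  cause <- match.arg(cause)
  when <- if (cause == "clearcut") year else year + params$replant_lag
  if (option %in% c("toNE", "toBD", "toBE")) {
    pft <- sub("to", "", option)
    return(list(year = when, pft = pft, share = 1))
  }
  if (option == "base") {
    if (is.null(prior_composition) || nrow(prior_composition) == 0) return(NULL)
    pft <- prior_composition[, "pft"]
    if (is.numeric(pft)) pft <- PFT_LEVELS[pft]
    share <- prior_composition[, "share"]
    return(list(year = when, pft = pft, share = share / sum(share)))
  }
  # unmanaged: natural regeneration of viable PFTs
  if (!length(viable_pfts)) return(NULL)
  list(year = when, pft = viable_pfts,
       share = rep(1 / length(viable_pfts), length(viable_pfts)))
}

# plant a composition into a patch: one sapling cohort per PFT, pools scaled
# by share
plant_cohorts <- function(cohorts, pft, share, params) {
  add <- new_cohorts(pft = pft,
                     density = params$sapling_density * share,
                     cstem = params$sapling_cstem * share,
                     cleaf = params$sapling_cleaf * share,
                     cfroot = params$sapling_cfroot * share,
                     age = 0)
  rbind(cohorts, add)
}

#' Plan the age-structure initialisation waves
#'
#' Starting from an all-pristine stand, clear-cut waves every `wave_step`
#' years during the history period convert patches to managed so that the
#' managed age histogram at the management start matches a target
#' distribution over 10-year age bins, to within one patch quantum
#' (largest-remainder apportionment). Patches apportioned to the oldest
#' (">140 years") bin are never converted and remain pristine.
#'
#' @param target_dist numeric vector of length `n_bins + 1`: mass in age bins
#'   `(0,10], (10,20], ..., (130,140]` and a final ">140" (pristine) bin.
#'   Must sum to 1.
#' @param n_patches patches per stand.
#' @param history_years length of the initialisation period (default 140,
#'   i.e. waves at offsets 0, 10, ..., 130).
#' @param wave_step years between waves.
#' @return list: `convert_offset` integer vector (per patch, the history-year
#'   offset of its conversion clear-cut, `NA` for pristine patches),
#'   `pristine` logical vector, `wave_offsets` the offsets used.
#' @export
init_age_structure <- function(target_dist, n_patches = 25L,
                               history_years = 140L, wave_step = 10L) {
  n_bins <- history_years %/% wave_step
  if (length(target_dist) != n_bins + 1)
    stop("target_dist must have ", n_bins + 1, " bins (", n_bins,
         " age bins plus the >", history_years, "-year pristine bin)")
  if (any(target_dist < 0)) stop("target masses must be nonnegative")
  if (abs(sum(target_dist) - 1) > 1e-9) stop("target_dist must sum to 1")
  # largest-remainder apportionment of patches to bins
  quota <- target_dist * n_patches
  n_bin <- floor(quota)
  left <- n_patches - sum(n_bin)
  if (left > 0) {
    rem <- quota - n_bin
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    n_bin[take] <- n_bin[take] + 1
  }
  # bin j (ages (10(j-1), 10j]) is produced by the wave at offset
  # history_years - wave_step * j; the last bin is pristine
  convert_offset <- rep(NA_integer_, n_patches)
  k <- 1L
  for (j in seq_len(n_bins)) {
    if (n_bin[j] == 0) next
    off <- history_years - wave_step * j
    idx <- seq.int(k, length.out = n_bin[j])
    convert_offset[idx] <- off
    k <- k + n_bin[j]
  }
  list(convert_offset = convert_offset,
       pristine = is.na(convert_offset),
       wave_offsets = sort(unique(convert_offset[!is.na(convert_offset)])))
}
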