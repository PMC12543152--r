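# Carbon turnover time diagnostics: pool / outflow ratios over an averaging
# window, for the ecosystem, the stem pool, the bulk soil and named soil
# sub-pools; the GPP-based equilibrium cross-check; window selection and
# extreme-value trimming.
#
# τ conventions: τ = mean(pool over window) / mean(outflow over window), NA
# (missing, never infinite) when the mean outflow is zero. The ecosystem
# pool is live biomass (including leaves and fine roots) plus litter and
# soil carbon; the product pool is outside the ecosystem. The ecosystem
# outflow is FRa + FRh + FDOC + Ffire + Fharv_to_products + Fharv_to_atm.
# The stem outflow is Fmort + Fdist + live-stem fire + the whole felled stem
# flux (including the residue that stays as litter).

window_rows <- function(ledger, window) {
  if (length(window) != 2 || window[2] <= window[1]) stop("empty window")
  rows <- which(ledger$year >= window[1] & ledger$year < window[2])
  if (length(rows) == 0) stop("window outside the simulated years")
  rows
}

ratio_tau <- function(pool, outflow) {
  mp <- mean(pool); mf <- mean(outflow)
  if (!is.finite(mp) || !is.finite(mf) || mf <= 0)
    return(list(tau = NA_real_, pool = mp, outflow = mf))
  list(tau = mp / mf, pool = mp, outflow = mf)
}

#' Ecosystem carbon turnover time
#'
#' τ_eco = mean ecosystem carbon (live + litter + soil, product pool
#' excluded) divided by the mean sum of the fluxes leaving the ecosystem
#' (autotrophic and heterotrophic respiration, DOC, fire, and the harvest
#' exports to products and atmosphere), over a half-open year window.
#'
#' @param ledger a [simulate_stand()] ledger.
#' @param window `c(start, end)`, half-open `[start, end)` in ledger years.
#' @return list: `tau` (years, `NA` when the outflow is zero), `pool`,
#'   `outflow` (window means).
#' @export
tau_eco <- function(ledger, window) {
  r <- window_rows(ledger, window)
  out <- ledger$FRa[r] + ledger$FRh[r] + ledger$FDOC[r] + ledger$Ffire[r] +
    ledger$Fharv_to_products[r] + ledger$Fharv_to_atm[r]
  ratio_tau(ledger$C_eco[r], out)
}

#' Stem carbon turnover time
#'
#' τ_stem over the stem pool (stem + branches + coarse roots; leaves and
#' fine roots excluded) with outflow mortality + disturbance + the
#' live-stem-combusted share of fire + the whole harvested stem flux.
#'
#' @inheritParams tau_eco
#' @export
tau_stem <- function(ledger, window) {
  r <- window_rows(ledger, window)
  out <- ledger$Fmort_stem[r] + ledger$Fdist_stem[r] +
    ledger$Ffire_stem[r] + ledger$Fharv_stem[r]
  ratio_tau(ledger$C_stem[r], out)
}

#' Soil carbon turnover time (bulk soil, outflow = total Rh)
#'
#' @inheritParams tau_eco
#' @export
tau_soil <- function(ledger, window) {
  r <- window_rows(ledger, window)
  ratio_tau(ledger$C_soil[r], ledger$FRh[r])
}

# pool-kind id -> ledger stock/outflow columns
TAU_POOL_IDS <- c(surfcwd = "SURFCWD", surffwd = "SURFFWD",
                  surfstruct = "SURFSTRUCT", surfmeta = "SURFMETA",
                  surfhum = "SURFHUMUS", soilstruct = "SOILSTRUCT",
                  soilmeta = "SOILMETA", active = "ACTIVE", slow = "SLOW",
                  passive = "PASSIVE")

#' Turnover time of a named soil sub-pool
#'
#' Per-pool outflow is the pool's total decay (respiration plus transfers to
#' downstream pools plus leaching), not respiration alone.
#'
#' @param pool_id one of `"surfcwd"`, `"surffwd"`, `"surfhum"`, `"slow"`
#'   (any of the ten pool names is accepted).
#' @inheritParams tau_eco
#' @export
tau_pool <- function(pool_id, ledger, window) {
  if (!pool_id %in% names(TAU_POOL_IDS)) stop("unknown pool id: ", pool_id)
  nm <- TAU_POOL_IDS[[pool_id]]
  r <- window_rows(ledger, window)
  ratio_tau(ledger[[paste0("soil_", nm)]][r],
            ledger[[paste0("out_", nm)]][r])
}

#' GPP-based ecosystem turnover time (equilibrium cross-check)
#'
#' τ_gpp = mean ecosystem carbon divided by mean GPP (the flux entering the
#' ecosystem). Equals τ_eco exactly at steady state; smaller than τ_eco in
#' an accumulating forest.
#'
#' @inheritParams tau_eco
#' @export
tau_gpp <- function(ledger, window) {
  r <- window_rows(ledger, window)
  ratio_tau(ledger$C_eco[r], ledger$GPP[r])
}

#' Select the τ averaging window
#'
#' Management-only runs use the last `window_length` years of the third
#' rotation cycle; climate-change runs the last `window_length` years of the
#' first cycle (the 2060-2089 analogue). The window is returned half-open,
#' `[start, end)`, and ends right before a synchronised clear-cut year, so
#' the clear-cut flux itself is excluded.
#'
#' @param management_start year index of the first clear-cut.
#' @param rotation rotation length, years.
#' @param mode `"management"` (cycle 3) or `"climate"` (cycle 1).
#' @param window_length years (default 30).
#' @param run_years optionally the run length, to error early when the run
#'   is too short.
#' @return integer vector `c(start, end)`.
#' @examples
#' select_window(0, 80, "management")  # c(210, 240)
#' select_window(0, 80, "climate")     # c(50, 80)
#' @export
select_window <- function(management_start, rotation,
                          mode = c("management", "climate"),
                          window_length = 30, run_years = NULL) {
  mode <- match.arg(mode)
  cycle <- if (mode == "management") 3 else 1
  end <- management_start + cycle * rotation
  start <- end - window_length
  if (!is.null(run_years) && end > run_years + 1)
    stop("run too short for the requested window")
  c(start = start, end = end)
}

#' Trim extreme values to a central quantile band
#'
#' Retains the values inside the central `coverage` band (default the 99%
#' interquantile range, i.e. [0.5%, 99.5%] quantiles, inclusive); used
#' before zone averaging to exclude the few cells where tiny outflows
#' produce distorted τ.
#'
#' @param values numeric vector (NAs are dropped first).
#' @param coverage central probability mass retained, in (0, 1].
#' @return list: `values` (retained), `excluded` (count), `bounds`.
#' @export
trim_extremes <- function(values, coverage = 0.99) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to trim")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (coverage == 1)
    return(list(values = values, excluded = 0L,
                bounds = range(values)))
  lo <- (1 - coverage) / 2
  # inverse-ECDF quantiles: the band is a pair of order statistics, so small
  # samples are never trimmed away entirely
  b <- stats::quantile(values, c(lo, 1 - lo), names = FALSE, type = 1)
  keep <- values >= b[1] & values <= b[2]
  list(values = values[keep], excluded = sum(!keep), bounds = b)
}

#' Build the τ table for one scenario
#'
#' One row per cell and pool kind (`eco`, `stem`, `soil`, `surfcwd`,
#' `surffwd`, `surfhum`, `slow`), with the window means behind each τ, the
#' GPP-based cross-check for the ecosystem rows, the cell's zone and initial
#' dominance labels, the scenario-average height over the window, and the
#' forest-filter outcome (`retained`).
#'
#' @param sims result of [run_simulation()] (list of per-cell stand results).
#' @param grid the grid the cells came from.
#' @param window half-open year window from [select_window()].
#' @param scenario scenario label stored in the table.
#' @param params a [forest_params()] list (height threshold).
#' @return data.frame of class `tau_table`.
#' @export
tau_table <- function(sims, grid, window, scenario = "base",
                      params = forest_params()) {
  kinds <- c("eco", "stem", "soil", "surfcwd", "surffwd", "surfhum", "slow")
  rows <- list()
  for (i in seq_along(sims)) {
    led <- sims[[i]]$ledger
    r <- window_rows(led, window)
    h <- mean(led$height[r])
    retained <- !is.na(h) && h >= params$height_threshold
    tg <- tau_gpp(led, window)
    for (k in kinds) {
      t_k <- switch(k,
                    eco = tau_eco(led, window),
                    stem = tau_stem(led, window),
                    soil = tau_soil(led, window),
                    tau_pool(k, led, window))
      rows[[length(rows) + 1L]] <- data.frame(
        cell = grid$cell[i], zone = grid$zone[i],
        initial_dominant = grid$initial_dominant[i],
        scenario = scenario, pool = k,
        tau = t_k$tau, mean_pool = t_k$pool, mean_outflow = t_k$outflow,
        tau_gpp = if (k == "eco") tg$tau else NA_real_,
        window_start = window[1], window_end = window[2],
        height = h, retained = retained,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tau_table", "data.frame")
  out
}

#' Write a τ table as tidy CSV
#' @param tau a [tau_table()] data.frame.
#' @param path file path.
#' @export
write_tau_csv <- function(tau, path) {
  utils::write.csv(tau, path, row.names = FALSE)
  invisible(path)
}
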