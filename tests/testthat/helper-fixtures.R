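# Shared fixtures: small grids, forcing and stand runs built once per test
# session. Everything is generated in code; no stored data.

fixture_env <- new.env(parent = emptyenv())

# memoised small baseline run used by several turnover/aggregation tests
small_run <- function() {
  if (is.null(fixture_env$small)) {
    g <- make_grid(4, seed = 11)
    phases <- list(spinup = 80, history = 140, management = 240)
    f <- gen_forcing(g, "fixed", years = sum(unlist(phases)), seed = 12)
    sims <- lapply(seq_len(nrow(g)), function(i)
      simulate_stand(g[i, ], f[f$cell == g$cell[i], ], option = "base",
                     phases = phases, seed = 100 + i))
    names(sims) <- as.character(g$cell)
    fixture_env$small <- list(grid = g, forcing = f, sims = sims,
                              phases = phases,
                              y0 = sims[[1]]$management_start)
  }
  fixture_env$small
}

# independent simplified-Koppen oracle, written against the documented
# thresholds (kept deliberately separate from assign_zone's code path)
oracle_zone <- function(s) {
  if (s$precip < 20 * s$t_mean + 280) return("arid")
  if (s$t_warm < 10) return("tundra")
  if (s$t_cold <= -3) {
    if (s$months_above_10 >= 4 || s$t_warm >= 22) return("cold with warm summer")
    return("cold with cold summer")
  }
  if (s$summer_frac < 0.35) return("temperate with dry summer")
  "temperate without dry season"
}

# one-cohort patch for unit tests
one_cohort <- function(pft = "BD", density = 0.5, cstem = 5, cleaf = 0.3,
                       cfroot = 0.2, age = 40) {
  new_cohorts(pft, density, cstem, cleaf, cfroot, age)
}

# whole-stand ledger mass-balance residuals (the accelerator replacement
# year, if any, is excluded)
balance_residuals <- function(ledger, accel_year = NULL) {
  d <- diff(ledger$C_eco_all)
  fl <- (ledger$GPP_all + ledger$Fplant_all - ledger$FRa_all -
           ledger$FRh_all - ledger$FDOC_all - ledger$Ffire_all -
           ledger$Fharv_to_products_all - ledger$Fharv_to_atm_all)[-1]
  r <- d - fl
  if (!is.null(accel_year)) r[accel_year + c(-1L, 0L)] <- NA
  r
}
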