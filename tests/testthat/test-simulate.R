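# Whole-stand simulator: reproducibility, conservation, scenario contracts

test_that("a stand run is byte-identical under the same seed", {
  fx <- small_run()
  g <- fx$grid
  s1 <- fx$sims[[1]]
  s2 <- simulate_stand(g[1, ], fx$forcing[fx$forcing$cell == g$cell[1], ],
                       option = "base", phases = fx$phases, seed = 101)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("every ledger year closes the carbon balance", {
  fx <- small_run()
  for (s in fx$sims) {
    r <- balance_residuals(s$ledger, accel_year = fx$phases$spinup)
    expect_lt(max(abs(r), na.rm = TRUE) / max(1, max(s$ledger$C_eco_all)),
              1e-9)
    led <- s$ledger
    flux_cols <- c("GPP", "FRa", "NPP", "FRh", "FDOC", "Ffire", "Fmort",
                   "Fdist", "Fharv_total", "Fharv_to_products",
                   "Fharv_to_atm", "Fharv_to_litter")
    vals <- as.matrix(led[!is.na(led$GPP), flux_cols])
    expect_true(all(vals >= 0))              # every ledger flux nonnegative
    expect_equal(led$NPP, led$GPP - led$FRa, tolerance = 1e-12)
    expect_equal(led$Fharv_total,
                 led$Fharv_to_products + led$Fharv_to_atm +
                   led$Fharv_to_litter, tolerance = 1e-9)
  }
})

test_that("the unmanaged option never harvests after the start", {
  fx <- small_run()
  g <- fx$grid
  s <- simulate_stand(g[2, ], fx$forcing[fx$forcing$cell == g$cell[2], ],
                      option = "unmanaged", phases = fx$phases, seed = 102)
  led <- s$ledger
  post <- led$year >= s$management_start
  expect_true(all(led$Fharv_total[post] == 0))
  # the matching managed run does harvest (first clear-cut at the start)
  s_base <- simulate_stand(g[2, ], fx$forcing[fx$forcing$cell == g$cell[2], ],
                           option = "base", phases = fx$phases, seed = 102)
  expect_gt(s_base$ledger$Fharv_total[s_base$management_start], 0)
})

test_that("clear-cuts are synchronised across managed options on a cell", {
  fx <- small_run()
  g <- fx$grid
  f2 <- fx$forcing[fx$forcing$cell == g$cell[2], ]
  cut_years <- function(s) {
    led <- s$ledger
    led$year[!is.na(led$Fharv_stem) & led$Fharv_stem > 0.5 &
               led$year >= s$management_start]
  }
  s_a <- simulate_stand(g[2, ], f2, option = "base", phases = fx$phases,
                        seed = 102)
  s_b <- simulate_stand(g[2, ], f2, option = "toNE", phases = fx$phases,
                        seed = 102)
  y0 <- s_a$management_start
  expected <- y0 + c(0, 80, 160)
  expect_true(all(expected %in% cut_years(s_a)))
  expect_true(all(expected %in% cut_years(s_b)))
})

test_that("transition scenarios become pure plantations after the start", {
  fx <- small_run()
  g <- fx$grid
  s <- simulate_stand(g[3, ], fx$forcing[fx$forcing$cell == g$cell[3], ],
                      option = "toNE", phases = fx$phases, seed = 103)
  st <- s$final_state
  managed_pfts <- unlist(lapply(which(st$analysis), function(p) {
    m <- st$cohorts[[p]]
    if (nrow(m)) m[, "PFT"] else integer(0)
  }))
  expect_true(all(PFT_LEVELS[managed_pfts] == "NE"))
})

test_that("fire is off on managed patches and the age waves hit on schedule", {
  fx <- small_run()
  g <- fx$grid
  s <- simulate_stand(g[1, ], fx$forcing[fx$forcing$cell == g$cell[1], ],
                      option = "base", phases = fx$phases, seed = 101)
  led <- s$ledger
  # analysis = managed fraction in a managed option: fire flux exactly 0
  post <- !is.na(led$Ffire) & led$year >= s$management_start
  expect_true(all(led$Ffire[post] == 0))
  # conversion clear-cuts appear as harvest pulses at 10-yr spacing in the
  # history phase
  hist_rows <- !is.na(led$Fharv_stem) &
    led$year > fx$phases$spinup & led$year < s$management_start
  pulses <- led$year[hist_rows & led$Fharv_stem > 0.2]
  if (length(pulses) > 1)
    expect_true(all(diff(sort(pulses)) %% 10 == 0 | diff(sort(pulses)) < 10))
})

test_that("config validation fails fast on inconsistent windows", {
  expect_error(scenario_config(rotation = 70), "rotation")
  expect_error(scenario_config(management_years = 100), "too short")
  expect_error(scenario_config(scenarios = c("base", "coppice")), "unknown")
  cfg <- scenario_config(n_cells = 2, spinup_years = 10, history_years = 0,
                         management_years = 240)
  expect_s3_class(cfg, "scenario_config")
})

test_that("configs round-trip through YAML", {
  cfg <- scenario_config(n_cells = 3, seed = 7, spinup_years = 20,
                         history_years = 140, management_years = 240)
  path <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  expect_equal(cfg2$n_cells, 3)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$target_age_dist, cfg$target_age_dist)
  unlink(path)
})
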