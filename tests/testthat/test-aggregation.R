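# Cross-scenario comparison logic on constructed τ tables

fake_tau <- function(cells = 1:4, scenarios = c("base", "toBD"),
                     pools = c("eco", "soil"),
                     zone = rep("arid", length(cells)),
                     dominant = rep("broadleaved", length(cells)),
                     tau_fun = function(cell, sc, pool) 40,
                     retained = TRUE) {
  rows <- expand.grid(cell = cells, scenario = scenarios, pool = pools,
                      stringsAsFactors = FALSE)
  rows$zone <- zone[match(rows$cell, cells)]
  rows$initial_dominant <- dominant[match(rows$cell, cells)]
  rows$tau <- mapply(tau_fun, rows$cell, rows$scenario, rows$pool)
  rows$retained <- retained
  rows
}

test_that("the common mask intersects retained cells across scenarios", {
  tt <- fake_tau()
  m <- common_cell_mask(tt)
  expect_setequal(as.integer(m), 1:4)
  # a cell dropped in one scenario is masked everywhere
  tt$retained[tt$cell == 3 & tt$scenario == "toBD"] <- FALSE
  m <- common_cell_mask(tt)
  expect_false(3 %in% m)
  expect_setequal(as.integer(m), c(1, 2, 4))
  # empty intersection errors
  tt$retained <- FALSE
  expect_error(common_cell_mask(tt), "no cell")
})

test_that("scenarios retaining too few cells are flagged", {
  tt <- fake_tau(cells = 1:10, scenarios = c("base", "toBE"))
  tt$retained[tt$scenario == "toBE" & tt$cell > 4] <- FALSE
  m <- common_cell_mask(tt, min_fraction = 0.5)
  expect_identical(attr(m, "flagged_scenarios"), "toBE")
})

test_that("zone summaries reproduce hand arithmetic", {
  taus <- c(`1` = 30, `2` = 34, `3` = 50, `4` = 54)
  tt <- fake_tau(cells = 1:4, scenarios = "base", pools = "eco",
                 zone = c("arid", "arid", "cold with cold summer",
                          "cold with cold summer"),
                 tau_fun = function(cell, sc, pool) taus[[as.character(cell)]])
  zs <- zone_summary(tt, mask = 1:4)
  arid <- zs[zs$zone == "arid", ]
  expect_equal(arid$mean_tau, 32)
  expect_equal(arid$se, sd(c(30, 34)) / sqrt(2))
  expect_equal(zs[zs$zone == "cold with cold summer", "mean_tau"], 52)
  # single-cell group: SE zero and flagged
  zs1 <- zone_summary(tt[tt$cell %in% c(1, 3), ], mask = c(1, 3))
  expect_true(all(zs1$se == 0) && all(zs1$se_undefined))
})

test_that("deltas vanish for identical scenarios and are antisymmetric", {
  tt <- fake_tau(tau_fun = function(cell, sc, pool) 40 + cell)
  zs <- zone_summary(tt, mask = 1:4)
  d <- scenario_deltas(zs, baseline = "base")
  expect_true(all(d$delta_tau == 0))
  # antisymmetry on distinct fields
  tt2 <- fake_tau(tau_fun = function(cell, sc, pool)
    if (sc == "base") 40 else 47)
  zs2 <- zone_summary(tt2, mask = 1:4)
  d_ab <- scenario_deltas(zs2, baseline = "base")$delta_tau
  d_ba <- scenario_deltas(zs2, baseline = "toBD")$delta_tau
  expect_equal(d_ab, -d_ba)
  # scenario-permutation invariance of the zone means themselves
  zs_perm <- zone_summary(tt2[rev(seq_len(nrow(tt2))), ], mask = 1:4)
  expect_equal(sort(zs_perm$mean_tau), sort(zs2$mean_tau))
})

test_that("the longest-τ label is an argmax with documented tie-breaking", {
  # one scenario strictly dominates
  tt <- fake_tau(scenarios = c("base", "toNE", "toBD"),
                 tau_fun = function(cell, sc, pool)
                   if (sc == "toBD") 60 else 40)
  lm <- longest_tau_map(tt)
  expect_true(all(lm$longest == "toBD"))
  expect_true(all(lm$longest %in% unique(tt$scenario)))
  # exact tie: first in the documented order wins, tie flagged
  tt <- fake_tau(scenarios = c("base", "toNE"),
                 tau_fun = function(cell, sc, pool) 40)
  lm <- longest_tau_map(tt)
  expect_true(all(lm$longest == "base") && all(lm$tie))
  # excluding unmanaged changes the winner where unmanaged led
  tt <- fake_tau(scenarios = c("base", "toBD", "unmanaged"),
                 tau_fun = function(cell, sc, pool)
                   switch(sc, unmanaged = 70, toBD = 60, 40))
  expect_true(all(longest_tau_map(tt)$longest == "unmanaged"))
  expect_true(all(longest_tau_map(tt, exclude_unmanaged = TRUE)$longest ==
                    "toBD"))
  # constructed field: toBD wins only in cold zones
  tt <- fake_tau(cells = 1:4, scenarios = c("base", "toBD"), pools = "eco",
                 zone = c("arid", "arid", "cold with cold summer",
                          "cold with cold summer"),
                 tau_fun = function(cell, sc, pool)
                   if (sc == "toBD" && cell > 2) 60 else 40)
  lm <- longest_tau_map(tt)
  expect_equal(lm$longest[match(1:4, lm$cell)],
               c("base", "base", "toBD", "toBD"))
})

test_that("dominance stratification recovers a constructed offset", {
  # +5 yr offset for toBD in needle-leaved cells only
  tt <- fake_tau(cells = 1:6, scenarios = c("base", "toBD"), pools = "eco",
                 dominant = rep(c("needleleaved", "broadleaved"), each = 3),
                 tau_fun = function(cell, sc, pool)
                   40 + 5 * (sc == "toBD" && cell <= 3))
  ds <- dominance_stratify(tt)
  nd <- ds[ds$group == "needleleaved" & ds$scenario == "toBD", ]
  bd <- ds[ds$group == "broadleaved" & ds$scenario == "toBD", ]
  expect_equal(nd$delta_tau, 5)
  expect_equal(bd$delta_tau, 0)
  # baseline against itself is a zero delta by construction
  tt0 <- fake_tau(scenarios = c("base", "toNE"),
                  tau_fun = function(cell, sc, pool) 40)
  ds0 <- dominance_stratify(tt0)
  expect_true(all(ds0$delta_tau[!ds0$empty_group] == 0))
  # empty group flagged
  tt1 <- fake_tau(cells = 1:4, scenarios = c("base", "toBD"),
                  dominant = rep("broadleaved", 4))
  ds1 <- dominance_stratify(tt1)
  expect_true(all(ds1$empty_group[ds1$group == "needleleaved"]))
})
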