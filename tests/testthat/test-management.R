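# Scenario engine: clear-cut scheduling, Reineke thinning, replanting,
# age-structure initialisation

test_that("clear-cuts are synchronised multiples of the rotation", {
  cfg <- list(option = "base", rotation = 80, management_start = 0)
  expect_true(schedule_clearcut(0, cfg))     # first cut at the start
  expect_false(schedule_clearcut(40, cfg))
  expect_true(schedule_clearcut(160, cfg))
  expect_false(schedule_clearcut(-80, cfg))
  # a 240-yr managed run holds exactly 3 cuts (start, +80, +160; the cut
  # closing cycle 3 falls at year 240, outside the run)
  yrs <- 0:239
  expect_equal(sum(vapply(yrs, schedule_clearcut, logical(1), cfg = cfg)), 3)
  cfg$option <- "unmanaged"
  expect_false(any(vapply(yrs, schedule_clearcut, logical(1), cfg = cfg)))
})

test_that("Reineke thinning triggers at the group density ceiling", {
  p <- forest_params()
  # below trigger: nothing removed
  coh <- new_cohorts("NE", 0.3, 3, 0.2, 0.1, age = 30)
  expect_equal(reineke_thin(coh, p)$removed_frac, 0)

  # density at 2 x N_max with target 0.9 removes 1 - 0.9/2 of stems
  mass <- 30                      # kgC per stem
  d_cm <- (mass / p$allom_mass_coef)^(1 / p$allom_mass_exp)
  n_max <- p$reineke$sdi[["needleleaved"]] / 1e4 *
    (d_cm / p$reineke$d_ref)^(-p$reineke$exponent)
  coh <- new_cohorts("NE", 2 * n_max, mass * 2 * n_max, 0.3, 0.2, age = 60)
  th <- reineke_thin(coh, p)
  expect_equal(th$removed_frac, 1 - 0.9 / 2, tolerance = 1e-12)
  expect_equal(th$felled$wood, (1 - 0.9 / 2) * mass * 2 * n_max,
               tolerance = 1e-12)
  # removals never drive density negative; post <= pre
  expect_true(all(th$cohorts[, "DENS"] >= 0))
  expect_lt(sum(th$cohorts[, "DENS"]), sum(coh[, "DENS"]))

  # identical state: the broadleaf group thins at a lower density
  coh_bd <- new_cohorts("BD", 2 * n_max, mass * 2 * n_max, 0.3, 0.2, age = 60)
  th_bd <- reineke_thin(coh_bd, p)
  expect_gt(th_bd$removed_frac, th$removed_frac)

  # nonpositive diameter with positive density is an error
  bad <- new_cohorts("NE", 0.5, 0, 0.2, 0.1)
  expect_error(reineke_thin(bad, p), "nonpositive stem mass")
})

test_that("replanting follows the scenario and the one-year lag rule", {
  p <- forest_params()
  # clear-cut: same year; other deaths: one-year lag
  pl <- replant_plan("toBD", cause = "clearcut", year = 2010, params = p)
  expect_equal(pl$year, 2010)
  expect_equal(pl$pft, "BD")
  pl <- replant_plan("toNE", cause = "other-death", year = 2010, params = p)
  expect_equal(pl$year, 2011)
  expect_equal(pl$pft, "NE")
  # baseline: identity replant of a mixed stand
  comp <- cbind(pft = c(1, 3), share = c(0.4, 0.6))
  pl <- replant_plan("base", comp, "other-death", 5, params = p)
  expect_equal(pl$pft, c("NE", "BD"))
  expect_equal(pl$share, c(0.4, 0.6))
  # unmanaged: natural regeneration of the viable set
  pl <- replant_plan("unmanaged", NULL, "other-death", 5,
                     viable_pfts = c("NE", "BD"), params = p)
  expect_setequal(pl$pft, c("NE", "BD"))
  expect_equal(sum(pl$share), 1)
})

test_that("age-structure waves reproduce the target histogram", {
  # all mass in the >140 bin: no waves, all pristine
  tgt <- c(rep(0, 14), 1)
  init <- init_age_structure(tgt, n_patches = 25)
  expect_true(all(init$pristine))
  expect_length(init$wave_offsets, 0)

  # uniform target over 14 bins with 28 patches: 2 patches per wave,
  # waves every 10 years at offsets 0..130 (bookkeeping oracle)
  tgt <- c(rep(1 / 14, 14), 0)
  init <- init_age_structure(tgt, n_patches = 28)
  expect_equal(init$wave_offsets, seq(0, 130, by = 10))
  expect_equal(unname(table(init$convert_offset)),
               array(rep(2L, 14)), ignore_attr = TRUE)
  # realised ages at the management start: bin j <- offset 140 - 10j
  ages <- 140 - init$convert_offset
  expect_setequal(unique(ages), seq(10, 140, by = 10))

  # apportionment is within one patch quantum of the target
  tgt <- default_age_dist()
  init <- init_age_structure(tgt, n_patches = 25)
  realised <- c(vapply(seq(130, 0, by = -10), function(o)
    sum(!is.na(init$convert_offset) & init$convert_offset == o) / 25,
    numeric(1)), mean(init$pristine))
  expect_lt(max(abs(realised - tgt)), 1 / 25 + 1e-12)

  expect_error(init_age_structure(c(rep(0.1, 14), 0)), "sum to 1")
  expect_error(init_age_structure(rep(0.5, 2)), "bins")
  expect_error(init_age_structure(c(-0.1, rep(0.1, 13), 0)), "nonnegative")
})
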