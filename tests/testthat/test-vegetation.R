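# Cohort production, mortality, disturbance, fire, height

test_that("production is zero without leaves and CO2-neutral with beta 0", {
  p <- forest_params()
  coh <- new_cohorts("BD", 0.5, 2, 0, 0.1, age = 20)
  r <- annual_production(coh, temp = 12, rad = 0.6, precip = 800, co2 = 400,
                         params = p)
  expect_identical(r$gpp, 0)
  # disabled fertilisation: doubling CO2 changes nothing
  p0 <- forest_params(list(co2_beta = 0))
  coh <- one_cohort()
  r1 <- annual_production(coh, 12, 0.6, 800, 400, params = p0)
  r2 <- annual_production(coh, 12, 0.6, 800, 800, params = p0)
  expect_equal(r1$gpp, r2$gpp)
  # NaN forcing is rejected, negative temperature is not
  expect_error(annual_production(coh, NaN, 0.6, 800, 400, params = p0),
               "non-finite")
  expect_silent(annual_production(coh, -15, 0.6, 800, 400, params = p0))
})

test_that("an undisturbed cohort grows monotonically to a fixed point", {
  # elevated stem maintenance makes the annual map contract quickly; the
  # oracle is an independent reimplementation of the closed-form update
  p <- forest_params()
  p$pft["BD", "resp_stem"] <- 0.15
  coh <- new_cohorts("BD", 0.5, 0.1, 0.04, 0.04, age = 0)
  live <- function(m) sum(m[, c("CSTEM", "CLEAF", "CFROOT")])
  tot_prev <- live(coh)
  nondec <- TRUE
  for (i in 1:400) {
    r <- annual_production(coh, 16, 0.6, 800, 400, params = p)
    coh <- r$cohorts
    if (live(coh) < tot_prev - 1e-12) nondec <- FALSE
    tot_prev <- live(coh)
  }
  r <- annual_production(coh, 16, 0.6, 800, 400, params = p)
  expect_true(nondec)
  expect_lt(abs(live(r$cohorts) - tot_prev), 1e-6)

  # oracle: independent iteration of the documented update equations
  pf <- p$pft["BD", ]
  st <- c(cs = 0.1, cl = 0.04, cf = 0.04)
  for (i in 1:400) {
    gpp <- pf$p_max * 0.6 * exp(-((16 + 0 - pf$t_opt) / pf$t_width)^2) *
      (1 + p$co2_beta * log(400 / p$co2_ref)) * (800 / (800 + p$gpp_moist_half)) *
      (1 - exp(-pf$k_leaf * st["cl"]))
    maint <- p$q10_plant^((16 - p$resp_t_ref) / 10) *
      (pf$resp_leaf * st["cl"] + pf$resp_froot * st["cf"] +
         pf$resp_stem * st["cs"])
    npp <- 0.75 * max(0, gpp - maint)
    dem <- st["cl"] / pf$leaf_longevity + st["cf"] / pf$froot_longevity
    cov <- if (dem > 0) min(1, npp / dem) else 1
    sur <- max(0, npp - dem)
    al <- if (st["cl"] < pf$cleaf_max) pf$alloc_leaf else 0
    af <- if (st["cf"] < pf$cfroot_max) pf$alloc_froot else 0
    st["cl"] <- st["cl"] - st["cl"] / pf$leaf_longevity +
      cov * st["cl"] / pf$leaf_longevity + al * sur
    st["cf"] <- st["cf"] - st["cf"] / pf$froot_longevity +
      cov * st["cf"] / pf$froot_longevity + af * sur
    st["cs"] <- st["cs"] + (1 - al - af) * sur
  }
  expect_equal(unname(sum(st)), live(r$cohorts), tolerance = 1e-6)
})

test_that("mortality has no effect on an empty patch and matches the binomial", {
  p <- forest_params()
  r <- apply_mortality(empty_cohorts(), params = p)
  expect_equal(r$dead_stem + r$dead_leaf + r$dead_froot, 0)

  # Monte-Carlo: background rate only, stress and envelope off
  p$mort_age_scale <- 0
  m <- p$pft["NE", "mort_bg"]
  coh <- new_cohorts("NE", 0.5, 5, 0.3, 0.2, age = 10)
  n_stems <- round(0.5 * p$patch_area)
  reps <- 3000
  set.seed(99)
  killed <- replicate(reps, {
    r <- apply_mortality(coh, ge = NULL, climate = NULL, params = p)
    r$dead_stem / 5
  })
  se <- sqrt(m * (1 - m) / n_stems / reps)
  expect_lt(abs(mean(killed) - m), 3 * se)
})

test_that("a PFT outside its bioclimatic envelope dies entirely", {
  p <- forest_params()
  clim <- climate_summary(-2, 14, 550, 0.45)   # cold with cold summer
  coh <- new_cohorts("BE", 0.5, 5, 0.3, 0.2, age = 10)
  r <- apply_mortality(coh, ge = NULL, climate = clim, params = p)
  expect_equal(nrow(r$cohorts), 0)
  expect_equal(r$dead_stem, 5)
  # NE tolerates the same climate
  coh <- new_cohorts("NE", 0.5, 5, 0.3, 0.2, age = 10)
  set.seed(1)
  r <- apply_mortality(coh, ge = NULL, climate = clim, params = p)
  expect_gt(nrow(r$cohorts), 0)
})

test_that("mortality conserves carbon", {
  p <- forest_params()
  coh <- rbind(one_cohort("BD"), one_cohort("NE", cstem = 3, age = 120))
  before <- sum(coh[, c("CSTEM", "CLEAF", "CFROOT")])
  set.seed(5)
  r <- apply_mortality(coh, ge = c(0.05, 2), climate = NULL, params = p)
  after <- sum(r$cohorts[, c("CSTEM", "CLEAF", "CFROOT")]) +
    r$dead_stem + r$dead_leaf + r$dead_froot
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("disturbance draws respect the return interval contract", {
  expect_error(disturbance_draw(25, 0), "positive")
  expect_error(disturbance_draw(25, -5), "positive")
  expect_false(any(disturbance_draw(25, Inf)))
  ev1 <- simulate_disturbance(25, 500, 400, seed = 8)
  ev2 <- simulate_disturbance(25, 500, 400, seed = 8)
  expect_identical(ev1, ev2)   # fixed seed, identical destruction sequence
  # empirical mean interval consistent with the nominal one (99% CI)
  ev <- simulate_disturbance(25, 5000, 400, seed = 8)
  est <- mean_disturbance_interval(ev)
  z <- qnorm(0.995)
  expect_lt(abs(est$mean - 400), z * est$se)
})

test_that("fire is exactly zero on managed patches and follows the arithmetic", {
  p <- forest_params()
  lit <- c(SURFCWD = 1, SURFFWD = 0.5, SURFSTRUCT = 0.3, SURFMETA = 0.1)
  coh <- one_cohort("NE", cstem = 6)
  r <- apply_fire(coh, lit, managed = TRUE, precip = 300, params = p)
  expect_identical(r$ffire, 0)
  expect_identical(r$cohorts, coh)
  # disabled fire
  p0 <- forest_params(list(fire = list(base_rate = 0)))
  r <- apply_fire(coh, lit, managed = FALSE, precip = 300, params = p0)
  expect_identical(r$ffire, 0)
  # burned fraction f with stem combustion completeness c on stem pool S:
  # live-stem fire flux = f * c * S
  fb <- p$fire$base_rate * max(0.2, 2 - 700 / p$fire$dry_ref)
  r <- apply_fire(coh, lit * 0, managed = FALSE, precip = 700, params = p)
  expect_equal(r$ffire_stem, fb * p$fire$combust_stem * 6, tolerance = 1e-12)
  # conservation: combusted + killed + surviving = original
  r <- apply_fire(coh, lit, managed = FALSE, precip = 700, params = p)
  total_after <- sum(r$cohorts[, c("CSTEM", "CLEAF", "CFROOT")]) +
    sum(r$surf_litter) + r$ffire + r$dead_stem + r$dead_leaf + r$dead_froot
  expect_equal(total_after, 6 + 0.3 + 0.2 + sum(lit), tolerance = 1e-12)
})

test_that("mean height and the forest filter honour the 5-m closed bound", {
  p <- forest_params()
  expect_equal(mean_height(empty_cohorts(), p), 0)
  # per-stem mass chosen so every cohort is exactly 12 m tall
  mass_per_stem <- (12 / p$allom_height_coef)^(1 / p$allom_height_exp)
  coh <- new_cohorts(c("BD", "NE"), c(0.3, 0.2),
                     mass_per_stem * c(0.3, 0.2), 0.1, 0.1)
  h <- mean_height(coh, p)
  expect_equal(h, 12, tolerance = 1e-9)
  heights <- c(a = 4.9, b = 5.0, c = 12, d = 0)
  expect_identical(forest_filter(heights), c("b", "c"))
})
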