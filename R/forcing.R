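# Synthetic grid and forcing generator. Stands in for the external climate,
# CO2, N-deposition and forest-structure datasets a continental run would
# ingest: a small grid with Koppen-style zone labels, and annual forcing
# series in a fixed (detrended, recycled) or warming-trend mode.

# Zone climate archetypes; per-cell jitter is added in make_grid(). Chosen so
# that assign_zone() on the archetype recovers the zone label (an invariant
# tested in the suite).
zone_archetypes <- function() {
  data.frame(
    zone   = ZONE_LEVELS,
    t_mean = c(17, -2, 5, 9, 15),        # degC annual mean
    t_amp  = c(8, 14, 12, 8, 8),         # degC seasonal half-amplitude
    precip = c(300, 550, 700, 800, 700), # mm yr-1
    summer_frac = c(0.30, 0.45, 0.45, 0.50, 0.18),  # share of precip in Apr-Sep
    rad    = c(0.75, 0.45, 0.50, 0.55, 0.70),       # dimensionless 0-1
    p_needle = c(0.15, 0.90, 0.70, 0.35, 0.25),     # P(initial dominant = needleleaved)
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic grid with zone labels and initial dominant PFT groups
#'
#' Cells are assigned to the five retained climatic zones by sampling the
#' given weights; each cell gets a zone-typical climate archetype (mean
#' temperature, seasonal amplitude, precipitation, summer-precipitation share,
#' radiation index) with small deterministic-seeded jitter, and an initial
#' dominant group ("needleleaved" or "broadleaved") drawn with zone-specific
#' probabilities. Tundra is never assigned.
#'
#' @param n_cells number of grid cells (>= 1).
#' @param zone_weights named nonnegative weights over [ZONE_LEVELS]; default
#'   equal weights. Zones absent from the vector get weight 0.
#' @param seed integer seed; the grid is a pure function of its arguments.
#' @return A `data.frame` of class `forest_grid` with one row per cell:
#'   `cell`, `zone`, `t_mean`, `t_amp`, `precip`, `summer_frac`, `rad`,
#'   `initial_dominant`, `initial_pft`.
#' @examples
#' g <- make_grid(10, seed = 1)
#' table(g$zone)
#' @export
make_grid <- function(n_cells, zone_weights = NULL, seed = 1L) {
  if (length(n_cells) != 1 || is.na(n_cells) || n_cells < 1)
    stop("n_cells must be a positive count")
  n_cells <- as.integer(n_cells)
  if (is.null(zone_weights))
    zone_weights <- stats::setNames(rep(1, 5), ZONE_LEVELS)
  if (any(zone_weights < 0)) stop("zone weights must be nonnegative")
  bad <- setdiff(names(zone_weights), ZONE_LEVELS)
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  w <- stats::setNames(numeric(5), ZONE_LEVELS)
  w[names(zone_weights)] <- zone_weights
  if (sum(w) <= 0) stop("zone weights sum to zero")
  w <- w / sum(w)

  arch <- zone_archetypes()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  zone <- sample(ZONE_LEVELS, n_cells, replace = TRUE, prob = w)
  i <- match(zone, arch$zone)
  g <- data.frame(
    cell = seq_len(n_cells),
    zone = zone,
    t_mean = arch$t_mean[i] + stats::rnorm(n_cells, 0, 0.4),
    t_amp  = pmax(1, arch$t_amp[i] + stats::rnorm(n_cells, 0, 0.5)),
    precip = pmax(50, arch$precip[i] + stats::rnorm(n_cells, 0, 40)),
    summer_frac = pmin(0.95, pmax(0.05, arch$summer_frac[i] +
                                    stats::rnorm(n_cells, 0, 0.03))),
    rad = pmin(1, pmax(0.05, arch$rad[i] + stats::rnorm(n_cells, 0, 0.03))),
    stringsAsFactors = FALSE
  )
  # keep each cell's jittered climate consistent with its zone label; the
  # rare borderline draw falls back to the archetype climate
  for (c_i in seq_len(n_cells)) {
    if (assign_zone(grid_climate(g, c_i)) != g$zone[c_i]) {
      g$t_mean[c_i] <- arch$t_mean[i[c_i]]
      g$t_amp[c_i] <- arch$t_amp[i[c_i]]
      g$precip[c_i] <- arch$precip[i[c_i]]
      g$summer_frac[c_i] <- arch$summer_frac[i[c_i]]
    }
  }
  needle <- stats::runif(n_cells) < arch$p_needle[i]
  g$initial_dominant <- ifelse(needle, "needleleaved", "broadleaved")
  # concrete planted PFT: conifers -> NE; broadleaves -> BE in the dry-summer
  # and arid zones, BD elsewhere
  g$initial_pft <- ifelse(needle, "NE",
                          ifelse(zone %in% c("arid", "temperate with dry summer"),
                                 "BE", "BD"))
  class(g) <- c("forest_grid", "data.frame")
  g
}

# save/restore helpers so grid/forcing generation does not clobber the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate annual forcing series for a grid
#'
#' Fixed mode emulates a detrended, recycled climate: each cell gets one
#' `block_years`-long anomaly block (zero-mean, zero-OLS-slope) that is
#' recycled verbatim for the whole run, with constant CO2 and N deposition.
#' Warming mode adds a linear temperature trend and a linear CO2 ramp on top
#' of the same recycled anomalies, from `trend_start` onwards.
#'
#' @param grid a [make_grid()] grid.
#' @param mode `"fixed"` or `"warming"`.
#' @param years run length (>= 1).
#' @param seed integer seed; identical arguments give a bit-identical series.
#' @param trend list of warming-mode settings: `temp` (degC yr-1, default
#'   0.04), `co2_start`/`co2_end` (ppm, default 400 to 850 across the trend
#'   period), `ndep_end` (gN m-2 yr-1 reached at the end of the run).
#' @param noise list of interannual standard deviations: `temp_sd` (degC),
#'   `precip_rel_sd` (relative), `rad_sd`.
#' @param block_years length of the recycled anomaly block (default 20).
#' @param trend_start first year index at which the warming trend and CO2 ramp
#'   apply (default 1); earlier years use the fixed-mode values.
#' @param co2_fixed,ndep_fixed constant values used in fixed mode and before
#'   `trend_start`.
#' @return A long `data.frame`: `cell`, `year`, `temp` (degC), `precip` (mm),
#'   `rad` (0-1), `co2` (ppm), `ndep` (gN m-2 yr-1).
#' @examples
#' g <- make_grid(3, seed = 1)
#' f <- gen_forcing(g, "fixed", years = 40, seed = 2)
#' @export
gen_forcing <- function(grid, mode = c("fixed", "warming"), years, seed = 1L,
                        trend = list(), noise = list(), block_years = 20L,
                        trend_start = 1L, co2_fixed = 400, ndep_fixed = 2) {
  mode <- match.arg(mode)
  if (length(years) != 1 || is.na(years) || years < 1) stop("years must be >= 1")
  years <- as.integer(years)
  tr <- utils::modifyList(list(temp = 0.04, co2_start = 400, co2_end = 850,
                               ndep_end = 3), trend)
  nz <- utils::modifyList(list(temp_sd = 0.6, precip_rel_sd = 0.15,
                               rad_sd = 0.04), noise)
  block_years <- max(1L, as.integer(block_years))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- nrow(grid)
  detrend <- function(x) {
    t <- seq_along(x)
    stats::residuals(stats::lm.fit(cbind(1, t), x))
  }
  out <- vector("list", n)
  yr <- seq_len(years)
  idx <- ((yr - 1L) %% block_years) + 1L
  ramp <- pmax(0, yr - trend_start)          # years since trend onset
  ramp_span <- max(1L, years - trend_start)  # so co2_end is reached at the horizon
  for (c_i in seq_len(n)) {
    ta <- detrend(stats::rnorm(block_years, 0, nz$temp_sd))
    pa <- detrend(stats::rnorm(block_years, 0, nz$precip_rel_sd))
    ra <- detrend(stats::rnorm(block_years, 0, nz$rad_sd))
    temp <- grid$t_mean[c_i] + ta[idx]
    precip <- pmax(0, grid$precip[c_i] * (1 + pa[idx]))
    rad <- pmin(1, pmax(0, grid$rad[c_i] + ra[idx]))
    co2 <- rep(co2_fixed, years)
    ndep <- rep(ndep_fixed, years)
    if (mode == "warming") {
      temp <- temp + tr$temp * ramp
      co2 <- tr$co2_start + (tr$co2_end - tr$co2_start) * ramp / ramp_span
      co2[yr < trend_start] <- co2_fixed
      ndep <- ndep_fixed + (tr$ndep_end - ndep_fixed) * ramp / ramp_span
    }
    out[[c_i]] <- data.frame(cell = grid$cell[c_i], year = yr, temp = temp,
                             precip = precip, rad = rad, co2 = co2, ndep = ndep)
  }
  do.call(rbind, out)
}

#' Summarise a cell's climate for zone assignment and bioclimatic checks
#'
#' Builds the 30-year-style climate summary from an annual mean temperature,
#' a seasonal half-amplitude (monthly temperature = mean + amplitude *
#' cos(2 pi (m - 7) / 12), peaking in July), annual precipitation and its
#' April-September share.
#'
#' @param t_mean annual mean temperature (degC).
#' @param t_amp seasonal half-amplitude (degC).
#' @param precip annual precipitation (mm).
#' @param summer_frac fraction of precipitation falling April-September.
#' @return list with `t_mean`, `t_cold`, `t_warm`, `months_above_10`, `gdd5`,
#'   `precip`, `summer_frac`.
#' @export
climate_summary <- function(t_mean, t_amp, precip, summer_frac) {
  m <- 1:12
  tm <- t_mean + t_amp * cos(2 * pi * (m - 7) / 12)
  list(
    t_mean = t_mean,
    t_cold = min(tm),
    t_warm = max(tm),
    months_above_10 = sum(tm > 10),
    gdd5 = sum(pmax(0, tm - 5)) * 365.25 / 12,
    precip = precip,
    summer_frac = summer_frac
  )
}

#' Assign a climatic zone from a climate summary
#'
#' Deterministic simplified Koppen-style mapping into the five retained
#' grouped classes (plus "tundra", which the grid generator never uses).
#' Documented thresholds: arid when annual precipitation < 20 * T_mean + 280
#' (mm); tundra when the warmest month stays below 10 degC; cold when the
#' coldest month is at or below -3 degC, split into warm-summer (at least 4
#' months above 10 degC or warmest month at/above 22 degC) and cold-summer;
#' otherwise temperate, split by a dry summer (April-September share of
#' precipitation below 0.35).
#'
#' @param summary a [climate_summary()] list; all fields must be present.
#' @return one zone label.
#' @export
assign_zone <- function(summary) {
  need <- c("t_mean", "t_cold", "t_warm", "months_above_10",
            "precip", "summer_frac")
  miss <- need[!vapply(need, function(f)
    !is.null(summary[[f]]) && !is.na(summary[[f]]), logical(1))]
  if (length(miss))
    stop("climate summary is missing field(s): ", paste(miss, collapse = ", "))
  if (summary$precip < 20 * summary$t_mean + 280) return("arid")
  if (summary$t_warm < 10) return("tundra")
  if (summary$t_cold <= -3) {
    if (summary$months_above_10 >= 4 || summary$t_warm >= 22)
      return("cold with warm summer")
    return("cold with cold summer")
  }
  if (summary$summer_frac < 0.35) return("temperate with dry summer")
  "temperate without dry season"
}

# climate summary for one grid row
grid_climate <- function(grid, cell_index, t_mean_override = NULL) {
  tm <- if (is.null(t_mean_override)) grid$t_mean[cell_index] else t_mean_override
  climate_summary(tm, grid$t_amp[cell_index], grid$precip[cell_index],
                  grid$summer_frac[cell_index])
}

#' Write / read forcing series as long-format CSV
#' @param forcing a [gen_forcing()] data.frame.
#' @param path file path.
#' @export
write_forcing_csv <- function(forcing, path) {
  utils::write.csv(forcing, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
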