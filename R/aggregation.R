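# Comparison logic across scenarios: the common retained-cell mask, zone
# means with standard errors, per-cell longest-τ labels, and stratification
# by the pre-management dominant PFT group.

#' Cells retained in every compared scenario
#'
#' Intersection of the cells passing the forest height filter in all
#' scenarios of a combined τ table. Scenarios whose retained set shrinks
#' below `min_fraction` of the baseline's (the broadleaved-evergreen
#' transition in much of Europe) are flagged in the `"flagged_scenarios"`
#' attribute so that dominance-stratified tables can exclude them.
#'
#' @param tau a combined [tau_table()] across scenarios.
#' @param min_fraction flag threshold relative to the baseline retained set.
#' @return integer/character vector of retained cell ids, with attribute
#'   `flagged_scenarios`.
#' @export
common_cell_mask <- function(tau, min_fraction = 0.5) {
  eco <- tau[tau$pool == "eco", ]
  scen <- unique(eco$scenario)
  kept <- lapply(scen, function(s)
    unique(eco$cell[eco$scenario == s & eco$retained]))
  names(kept) <- scen
  cells <- Reduce(intersect, kept)
  if (!length(cells)) stop("no cell is retained in every scenario")
  base_n <- if ("base" %in% scen) length(kept[["base"]])
  else max(lengths(kept))
  flagged <- names(kept)[lengths(kept) < min_fraction * base_n]
  structure(cells, flagged_scenarios = flagged)
}

#' Zone means of τ with standard errors
#'
#' Per zone, scenario and pool kind: the arithmetic mean and standard error
#' (sd / sqrt(n), the variation across grid cells) of τ over the masked
#' cells, after trimming to the central 99% band. Single-cell groups get
#' SE 0 and a flag.
#'
#' @param tau combined [tau_table()].
#' @param mask cells to include (from [common_cell_mask()]); `NULL` keeps
#'   every retained cell per scenario.
#' @param coverage trimming coverage (see [trim_extremes()]).
#' @return data.frame: `zone`, `scenario`, `pool`, `mean_tau`, `se`,
#'   `n_cells`, `n_trimmed`, `se_undefined`.
#' @export
zone_summary <- function(tau, mask = NULL, coverage = 0.99) {
  d <- if (is.null(mask)) tau[tau$retained, ] else tau[tau$cell %in% mask, ]
  d <- d[!is.na(d$tau), ]
  if (!nrow(d)) stop("no τ values to summarise")
  key <- interaction(d$zone, d$scenario, d$pool, drop = TRUE)
  out <- lapply(split(d, key), function(g) {
    tr <- trim_extremes(g$tau, coverage)
    n <- length(tr$values)
    data.frame(zone = g$zone[1], scenario = g$scenario[1], pool = g$pool[1],
               mean_tau = mean(tr$values),
               se = if (n > 1) stats::sd(tr$values) / sqrt(n) else 0,
               n_cells = n, n_trimmed = tr$excluded,
               se_undefined = n <= 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$zone, out$pool, match(out$scenario, SCENARIO_LEVELS)), ]
}

#' Deltas of zone means against a baseline scenario
#'
#' @param summary a [zone_summary()] table containing the baseline.
#' @param baseline scenario subtracted from the others.
#' @return the non-baseline rows with `delta_tau` (scenario - baseline)
#'   added.
#' @export
scenario_deltas <- function(summary, baseline = "base") {
  b <- summary[summary$scenario == baseline, c("zone", "pool", "mean_tau")]
  names(b)[3] <- "base_tau"
  m <- merge(summary[summary$scenario != baseline, ], b,
             by = c("zone", "pool"))
  m$delta_tau <- m$mean_tau - m$base_tau
  m
}

#' Deltas between two forcing modes (climate minus fixed)
#'
#' @param summary_fixed,summary_climate [zone_summary()] tables from the two
#'   experiment families.
#' @return merged table with `delta_tau = climate - fixed` per zone,
#'   scenario and pool.
#' @export
mode_deltas <- function(summary_fixed, summary_climate) {
  m <- merge(summary_fixed, summary_climate,
             by = c("zone", "scenario", "pool"),
             suffixes = c("_fixed", "_climate"))
  m$delta_tau <- m$mean_tau_climate - m$mean_tau_fixed
  m
}

#' Management option with the longest τ per cell
#'
#' Argmax of τ over scenarios for each cell and pool kind. Ties go to the
#' first scenario in the documented order (base, toNE, toBD, toBE,
#' unmanaged) and are flagged.
#'
#' @param tau combined [tau_table()].
#' @param exclude_unmanaged drop the unmanaged option before the argmax.
#' @param mask optional cell mask.
#' @return data.frame: `cell`, `pool`, `longest` (scenario label), `tie`.
#' @export
longest_tau_map <- function(tau, exclude_unmanaged = FALSE, mask = NULL) {
  d <- tau
  if (exclude_unmanaged) d <- d[d$scenario != "unmanaged", ]
  if (!is.null(mask)) d <- d[d$cell %in% mask, ]
  d <- d[!is.na(d$tau), ]
  key <- interaction(d$cell, d$pool, drop = TRUE)
  out <- lapply(split(d, key), function(g) {
    g <- g[order(match(g$scenario, SCENARIO_LEVELS)), ]
    best <- which(g$tau == max(g$tau))
    data.frame(cell = g$cell[1], pool = g$pool[1],
               longest = g$scenario[best[1]], tie = length(best) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scenario-minus-baseline deltas stratified by initial dominance
#'
#' Groups cells by the pre-management dominant PFT group (needle-leaved vs
#' broadleaved), and reports per group, scenario and pool the mean paired
#' per-cell delta against the baseline, with its standard error across
#' cells. Scenarios flagged by [common_cell_mask()] (e.g. a
#' broadleaved-evergreen transition retaining too few cells) are excluded;
#' empty groups are flagged.
#'
#' @param tau combined [tau_table()].
#' @param mask cell mask with the `flagged_scenarios` attribute (from
#'   [common_cell_mask()]); `NULL` uses all retained cells, no exclusion.
#' @param baseline baseline scenario.
#' @return data.frame: `group`, `scenario`, `pool`, `delta_tau`, `se`, `n`,
#'   `empty_group`.
#' @export
dominance_stratify <- function(tau, mask = NULL, baseline = "base") {
  d <- if (is.null(mask)) tau[tau$retained, ] else tau[tau$cell %in% mask, ]
  flagged <- attr(mask, "flagged_scenarios")
  if (length(flagged)) d <- d[!d$scenario %in% flagged, ]
  b <- d[d$scenario == baseline, c("cell", "pool", "tau")]
  names(b)[3] <- "base_tau"
  m <- merge(d[d$scenario != baseline, ], b, by = c("cell", "pool"))
  m$delta <- m$tau - m$base_tau
  m <- m[!is.na(m$delta), ]
  groups <- c("needleleaved", "broadleaved")
  out <- list()
  for (gr in groups) for (sc in unique(m$scenario)) for (pl in unique(m$pool)) {
    g <- m[m$initial_dominant == gr & m$scenario == sc & m$pool == pl, ]
    n <- nrow(g)
    out[[length(out) + 1L]] <- data.frame(
      group = gr, scenario = sc, pool = pl,
      delta_tau = if (n) mean(g$delta) else NA_real_,
      se = if (n > 1) stats::sd(g$delta) / sqrt(n) else 0,
      n = n, empty_group = n == 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
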