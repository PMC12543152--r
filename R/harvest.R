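# Harvest partitioning and the wood product pool. Felled biomass is split
# between removal and in-stand residue, removals between same-year oxidation
# and the product pool (outside the ecosystem), and the product pool is
# oxidised at a fixed annual rate.

#' Partition felled biomass between removal and residue
#'
#' 66% of felled wood (stem, twigs and coarse roots) and 30% of felled leaf
#' biomass are removed from the stand; the rest, and all fine roots, remain
#' as litter.
#'
#' @param felled named vector or list with `wood`, `leaf`, `froot` (kgC m-2;
#'   missing organs count as 0).
#' @param params a [forest_params()] list.
#' @return list: `removed_wood`, `removed_leaf`, and `residue` (named vector
#'   `wood`, `leaf`, `froot`).
#' @examples
#' partition_harvest(c(wood = 1, leaf = 0.2, froot = 0.1))
#' @export
partition_harvest <- function(felled, params = forest_params()) {
  f <- c(wood = 0, leaf = 0, froot = 0)
  f[names(felled)] <- unlist(felled)
  if (any(f < 0)) stop("felled biomass must be nonnegative")
  h <- params$harvest
  removed_wood <- h$wood_removed * f[["wood"]]
  removed_leaf <- h$leaf_removed * f[["leaf"]]
  list(removed_wood = removed_wood,
       removed_leaf = removed_leaf,
       residue = c(wood = f[["wood"]] - removed_wood,
                   leaf = f[["leaf"]] - removed_leaf,
                   froot = f[["froot"]]))
}

#' Route removed biomass to the atmosphere and the product pool
#'
#' All removed leaf biomass and 67% of removed wood biomass are oxidised in
#' the harvest year; the remaining 33% of removed wood enters the product
#' pool.
#'
#' @param removed_wood,removed_leaf kgC m-2 (nonnegative).
#' @param params a [forest_params()] list.
#' @return list: `to_atm`, `to_products` (kgC m-2).
#' @export
route_removals <- function(removed_wood, removed_leaf,
                           params = forest_params()) {
  if (removed_wood < 0 || removed_leaf < 0) stop("removals must be nonnegative")
  a <- params$harvest$removed_wood_atm
  list(to_atm = removed_leaf + a * removed_wood,
       to_products = (1 - a) * removed_wood)
}

#' Advance the product pool by one year
#'
#' The pool oxidises at the fixed annual rate before this year's input is
#' added (oxidise-before-input convention).
#'
#' @param pool product pool, kgC m-2 (>= 0).
#' @param input this year's input from harvest removals, kgC m-2 (>= 0).
#' @param params a [forest_params()] list.
#' @return list: `pool` (updated), `oxidation` (kgC m-2 yr-1).
#' @examples
#' step_product_pool(1, 0)  # oxidises 0.04
#' @export
step_product_pool <- function(pool, input = 0, params = forest_params()) {
  if (pool < 0 || input < 0) stop("pool and input must be nonnegative")
  r <- params$harvest$product_oxidation
  ox <- r * pool
  list(pool = pool - ox + input, oxidation = ox)
}

# Fell a set of cohorts entirely (clear-cut); returns organ totals and an
# empty patch.
fell_all <- function(cohorts) {
  list(wood = sum(cohorts[, "CSTEM"]),
       leaf = sum(cohorts[, "CLEAF"]),
       froot = sum(cohorts[, "CFROOT"]))
}
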