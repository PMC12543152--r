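# CENTURY-style litter and soil organic matter cascade: ten pools linked by a
# configurable transfer topology, climate-modified first-order decay,
# heterotrophic respiration and DOC export. All functions operate on a pool
# vector (length 10, named as SOIL_POOLS) or a 10 x P matrix (one column per
# patch).

#' Create an empty (or preset) soil pool vector
#'
#' @param values optional named values (kgC m-2); unnamed pools start at 0.
#' @return named numeric vector over [SOIL_POOLS].
#' @export
new_soil_pools <- function(values = NULL) {
  p <- stats::setNames(numeric(10), SOIL_POOLS)
  if (!is.null(values)) {
    bad <- setdiff(names(values), SOIL_POOLS)
    if (length(bad)) stop("unknown soil pool(s): ", paste(bad, collapse = ", "))
    p[names(values)] <- values
  }
  if (any(p < 0)) stop("soil pools must be nonnegative")
  p
}

#' Route litter by organ into soil pool additions
#'
#' Dead stem carbon is split between surface coarse and fine woody debris by
#' the configured size split; leaf litter goes to the surface metabolic /
#' structural pools and fine-root litter to the soil metabolic / structural
#' pools, split by the PFT's metabolic fraction. Totals are conserved
#' exactly.
#'
#' @param stem,leaf,froot litter amounts, kgC m-2 (nonnegative).
#' @param metabolic_frac metabolic share of soft litter (leaf and fine root).
#' @param params a [forest_params()] list.
#' @return named additions vector over [SOIL_POOLS].
#' @export
route_litter <- function(stem = 0, leaf = 0, froot = 0, metabolic_frac = 0.5,
                         params = forest_params()) {
  if (stem < 0 || leaf < 0 || froot < 0) stop("litter must be nonnegative")
  add <- new_soil_pools()
  add["SURFCWD"] <- params$cwd_frac * stem
  add["SURFFWD"] <- (1 - params$cwd_frac) * stem
  add["SURFMETA"] <- metabolic_frac * leaf
  add["SURFSTRUCT"] <- (1 - metabolic_frac) * leaf
  add["SOILMETA"] <- metabolic_frac * froot
  add["SOILSTRUCT"] <- (1 - metabolic_frac) * froot
  add
}

# climate modifiers of decomposition
soil_f_temp <- function(temp, sp) sp$q10^((temp - sp$t_ref) / 10)
soil_g_moist <- function(precip, sp) precip / (precip + sp$moist_half)

#' Advance the soil cascade by one year
#'
#' Each pool decays by the annual fraction `min(1, k * f(T) * g(moisture))`
#' (linear first-order kinetics on the annual step, so an isolated pool at
#' equilibrium has exactly τ = 1 / (k f g)).
#' Decayed carbon splits into a respired share (heterotrophic respiration),
#' transfers to downstream pools following the configured topology matrix,
#' and - for the ACTIVE pool - a DOC leaching share proportional to the
#' moisture factor. Inputs are added after decay. The step conserves mass
#' exactly: d(total) = inputs - Rh - DOC.
#'
#' @param pools named vector over [SOIL_POOLS], or a 10 x P matrix.
#' @param temp annual mean temperature, degC.
#' @param precip annual precipitation, mm (moisture proxy).
#' @param inputs litter additions (same shape as `pools`), added after decay.
#' @param params a [forest_params()] list.
#' @return list: `pools` (updated), `rh` (per-pool respiration), `doc`
#'   (scalar or per-patch vector), `outflow` (per-pool total decay: respired
#'   + transferred + leached).
#' @export
step_soil <- function(pools, temp, precip, inputs = NULL,
                      params = forest_params()) {
  sp <- params$soil
  vec <- !is.matrix(pools)
  if (vec) pools <- matrix(pools, ncol = 1, dimnames = list(SOIL_POOLS, NULL))
  if (any(pools < 0)) stop("soil pools must be nonnegative")
  if (is.null(inputs)) inputs <- 0 * pools
  if (!is.matrix(inputs))
    inputs <- matrix(inputs, ncol = ncol(pools), dimnames = dimnames(pools))
  f <- soil_f_temp(temp, sp); g <- soil_g_moist(precip, sp)
  if (f <= 0 || g <= 0) stop("climate modifiers must be positive")
  dfrac <- pmin(1, sp$k * f * g)   # annual decay fraction, capped for the
                                   # fast metabolic pools
  decay <- pools * dfrac
  resp <- sp$resp_frac
  doc_frac <- sp$doc_leach * g
  resp_eff <- resp
  resp_eff["ACTIVE"] <- resp["ACTIVE"] - doc_frac
  if (resp_eff["ACTIVE"] < 0) stop("DOC leaching exceeds ACTIVE respired fraction")
  rh <- decay * resp_eff
  doc <- decay["ACTIVE", ] * doc_frac
  new <- pools - decay + sp$transfer %*% decay + inputs
  if (any(new < 0)) stop("negative soil pool after step")
  if (vec) {
    new <- stats::setNames(as.vector(new), SOIL_POOLS)
    rh <- stats::setNames(as.vector(rh), SOIL_POOLS)
    decay <- stats::setNames(as.vector(decay), SOIL_POOLS)
    doc <- as.vector(doc)
  }
  list(pools = new, rh = rh, doc = doc, outflow = decay)
}

#' Total heterotrophic respiration from per-pool respiration
#'
#' @param rh per-pool respiration vector or 10 x P matrix.
#' @return scalar (vector input) or per-patch totals.
#' @export
total_Rh <- function(rh) {
  if (is.matrix(rh)) colSums(rh) else sum(rh)
}

#' Analytic equilibrium of the soil cascade for a constant input
#'
#' Solves the linear balance `outflow = inputs + transfer %*% outflow` for
#' the per-pool outflow, then converts to pools through the annual decay
#' fraction. Used to accelerate soil spin-up and as a closed-form oracle for
#' pool turnover times.
#'
#' @param inputs named annual litter additions over [SOIL_POOLS], kgC m-2 yr-1.
#' @param temp,precip climate at which to equilibrate.
#' @param params a [forest_params()] list.
#' @return named equilibrium pool vector, kgC m-2.
#' @export
soil_equilibrium <- function(inputs, temp, precip, params = forest_params()) {
  sp <- params$soil
  f <- soil_f_temp(temp, sp); g <- soil_g_moist(precip, sp)
  dfrac <- pmin(1, sp$k * f * g)
  x <- solve(diag(10) - sp$transfer, inputs[SOIL_POOLS])
  stats::setNames(as.vector(x / dfrac), SOIL_POOLS)
}
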