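# Gordon-Taylor mixture glass transition with Simha-Boyer coefficients, and
# the "escape glass transition" (eGT) locus where the mixture Tg equals the
# dissolution-medium temperature.

#' Simha-Boyer Gordon-Taylor coefficient
#'
#' \deqn{K_{i,ref} = \frac{\rho_{ref} T_{g,ref}}{\rho_i T_{g,i}}}
#' with temperatures in kelvin. The reference component (the polymer, by
#' convention) gets K = 1; the Gordon-Taylor mixture Tg is invariant under a
#' common rescaling of all K, so the reference choice is presentational.
#'
#' @param component,reference [pureComponent()] records with density and
#'   glass-transition temperature set.
#' @return dimensionless K.
#' @export
simhaBoyerK <- function(component, reference) {
  for (cc in list(component, reference)) {
    if (!is.finite(cc$density) || cc$density <= 0 ||
        !is.finite(cc$glass_T) || cc$glass_T <= 0)
      stop("component '", cc$name, "' needs positive density and glass_T")
  }
  (reference$density * reference$glass_T) /
    (component$density * component$glass_T)
}

#' Gordon-Taylor glass-transition temperature of a mixture
#'
#' \deqn{T_g = \frac{\sum_i K_i w_i T_{g,i}}{\sum_i K_i w_i}}
#' with \eqn{K_i} from the Simha-Boyer rule relative to the reference
#' component.
#'
#' @param w mass fractions, same order as `components`.
#' @param components list of [pureComponent()] records (or a
#'   `ternary_system`, whose API/polymer/water order applies).
#' @param reference index or name of the reference component for the
#'   Simha-Boyer rule; defaults to the component with the largest molar mass
#'   (the polymer).
#' @return mixture glass-transition temperature, K.
#' @export
gordonTaylorTg <- function(w, components, reference = NULL) {
  if (inherits(components, "ternary_system")) components <- components$components
  if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-8)
    stop("mass fractions must be a simplex point")
  w <- pmax(w, 0)
  if (is.null(reference)) {
    reference <- which.max(vapply(components, `[[`, 0, "molar_mass"))
  } else if (is.character(reference)) {
    reference <- match(reference, vapply(components, `[[`, "", "name"))
  }
  ref <- components[[reference]]
  K <- vapply(components, simhaBoyerK, 0, reference = ref)
  Tg <- vapply(components, `[[`, 0, "glass_T")
  sum(K * w * Tg) / sum(K * w)
}

#' Water content where a hydrating ASD reaches the escape glass transition
#'
#' Along the straight hydration line of fixed API:polymer ratio, finds the
#' water mass fraction \eqn{w^*} at which the Gordon-Taylor mixture Tg equals
#' the dissolution-medium temperature: the point where the gel layer becomes
#' mobile enough to release ("escape glass transition", eGT).
#'
#' @param drug_load API mass fraction on the water-free basis, in `[0, 1)`.
#' @param T_medium dissolution-medium temperature, K.
#' @param system a `ternary_system` (API, polymer, water order).
#' @return water mass fraction at eGT. If the dry ASD's Tg is already at or
#'   below `T_medium`, returns 0 with attribute `dry_below_medium = TRUE`.
#' @export
egtWaterContent <- function(drug_load, T_medium, system) {
  stopifnot(drug_load >= 0, drug_load < 1)
  comps <- system$components
  tg_of <- function(ww) gordonTaylorTg(c((1 - ww) * drug_load,
                                         (1 - ww) * (1 - drug_load), ww), comps)
  if (tg_of(0) <= T_medium) {
    out <- 0
    attr(out, "dry_below_medium") <- TRUE
    return(out)
  }
  if (tg_of(0.999) > T_medium)
    stop("medium temperature below the fully hydrated Tg; no eGT on the path")
  stats::uniroot(function(ww) tg_of(ww) - T_medium, c(0, 0.999),
                 tol = 1e-10)$root
}

#' Escape-glass-transition locus over a drug-load grid
#'
#' @param T_medium dissolution-medium temperature, K.
#' @param system a `ternary_system`.
#' @param drug_loads water-free API mass fractions to evaluate (defaults to a
#'   uniform grid).
#' @return data frame with columns `drug_load`, `w_api`, `w_polymer`,
#'   `w_water`, `Tg` (K): one full composition per drug load, each satisfying
#'   `|Tg - T_medium| < 0.01 K` (or the zero-water endpoint when the dry Tg is
#'   below the medium temperature).
#' @export
egtLocus <- function(T_medium, system, drug_loads = seq(0, 0.99, by = 0.01)) {
  stopifnot(all(drug_loads >= 0 & drug_loads <= 1))
  rows <- lapply(drug_loads, function(dl) {
    ww <- egtWaterContent(dl, T_medium, system)
    w <- c((1 - ww) * dl, (1 - ww) * (1 - dl), ww)
    data.frame(drug_load = dl, w_api = w[1], w_polymer = w[2], w_water = w[3],
               Tg = gordonTaylorTg(w, system$components))
  })
  do.call(rbind, rows)
}
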