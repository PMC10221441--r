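# Internal canonical units: K, Pa, J, mol, kg, angstrom.
# Parameter files carry explicit unit strings; loaders normalize (kJ/mol -> J/mol,
# degC -> K) so downstream code never sees mixed units.

.known_units <- list(
  molar_mass       = c("g/mol"),
  segment_ratio    = c("mol/g"),
  segment_diameter = c("angstrom", "A"),
  dispersion_energy = c("K"),
  assoc_energy     = c("K"),
  assoc_volume     = c("1", ""),
  melting_T        = c("K", "degC"),
  melting_enthalpy = c("kJ/mol", "J/mol"),
  delta_cp         = c("J/mol/K"),
  density          = c("kg/m3"),
  glass_T          = c("K", "degC"),
  kij_m            = c("1/K"),
  kij_b            = c("1", "")
)

#' Create a pure-component parameter record
#'
#' Bundles all per-substance constants used by the package: PC-SAFT
#' pure-component parameters (molar mass \eqn{M_i}, segment number per mass
#' \eqn{m_i^{seg}/M_i}, segment diameter \eqn{\sigma_i}, dispersion energy
#' \eqn{u_i/k_B}, association energy \eqn{\epsilon^{A_iB_i}/k_B}, association
#' volume \eqn{\kappa^{A_iB_i}}, association site counts), melting properties
#' (\eqn{T_i^{SL}}, \eqn{\Delta h_i^{SL}}, \eqn{\Delta c_{p,i}^{SL}}), true
#' density and glass-transition temperature.
#'
#' @param name component identifier.
#' @param molar_mass molar mass, g/mol.
#' @param segment_ratio PC-SAFT segment number divided by molar mass, mol/g.
#' @param segment_diameter PC-SAFT segment diameter, angstrom. `NA` together
#'   with `sigma_temperature_dependent = TRUE` selects the temperature-dependent
#'   water diameter correlation (see [sigmaWater()]).
#' @param dispersion_energy dispersion-energy parameter \eqn{u_i/k_B}, K.
#' @param assoc_energy association-energy parameter, K (0 for non-associating).
#' @param assoc_volume association-volume parameter, dimensionless (`NA` if
#'   the component carries no sites).
#' @param assoc_sites integer vector `c(donors, acceptors)`.
#' @param melting_T melting temperature, K, or `NA`.
#' @param melting_enthalpy melting enthalpy, J/mol (canonical), or `NA`.
#' @param delta_cp solid-liquid heat-capacity difference, J/mol/K, or `NA`
#'   (the solubility equation drops its term when absent).
#' @param density true density, kg/m3.
#' @param glass_T glass-transition temperature, K.
#' @param sigma_temperature_dependent logical; use the water sigma(T) correlation.
#' @return object of class `pure_component`.
#' @export
pureComponent <- function(name, molar_mass, segment_ratio, segment_diameter,
                          dispersion_energy, assoc_energy = 0,
                          assoc_volume = NA_real_, assoc_sites = c(0L, 0L),
                          melting_T = NA_real_, melting_enthalpy = NA_real_,
                          delta_cp = NA_real_, density = NA_real_,
                          glass_T = NA_real_,
                          sigma_temperature_dependent = FALSE) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("pureComponent '", name, "': molar_mass must be > 0")
  if (!is.finite(segment_ratio) || segment_ratio <= 0)
    stop("pureComponent '", name, "': segment_ratio must be > 0")
  if (!sigma_temperature_dependent &&
      (!is.finite(segment_diameter) || segment_diameter <= 0))
    stop("pureComponent '", name, "': segment_diameter must be > 0")
  if (!is.finite(dispersion_energy) || dispersion_energy <= 0)
    stop("pureComponent '", name, "': dispersion_energy must be > 0")
  assoc_sites <- as.integer(assoc_sites)
  if (length(assoc_sites) != 2 || any(assoc_sites < 0))
    stop("pureComponent '", name, "': assoc_sites must be two counts >= 0")
  # melting fields travel together (delta_cp may be absent alone)
  have_melt <- c(is.finite(melting_T), is.finite(melting_enthalpy))
  if (xor(have_melt[1], have_melt[2]))
    stop("pureComponent '", name,
         "': melting_T and melting_enthalpy must be present together")
  structure(list(
    name = name, molar_mass = molar_mass, segment_ratio = segment_ratio,
    segment_diameter = if (sigma_temperature_dependent) NA_real_ else segment_diameter,
    sigma_temperature_dependent = isTRUE(sigma_temperature_dependent),
    dispersion_energy = dispersion_energy,
    assoc_energy = if (sum(assoc_sites) > 0) assoc_energy else 0,
    assoc_volume = if (sum(assoc_sites) > 0) assoc_volume else NA_real_,
    assoc_sites = assoc_sites,
    melting_T = melting_T, melting_enthalpy = melting_enthalpy,
    delta_cp = delta_cp, density = density, glass_T = glass_T,
    m_seg = segment_ratio * molar_mass
  ), class = "pure_component")
}

#' @export
print.pure_component <- function(x, ...) {
  cat("<pure_component> ", x$name, "\n", sep = "")
  cat(sprintf("  M = %g g/mol, m_seg = %.4g, sigma = %s A, u/kB = %g K\n",
              x$molar_mass, x$m_seg,
              if (x$sigma_temperature_dependent) "sigma(T)" else
                format(x$segment_diameter),
              x$dispersion_energy))
  if (sum(x$assoc_sites) > 0)
    cat(sprintf("  assoc: eps/kB = %g K, kappa = %g, sites %d/%d\n",
                x$assoc_energy, x$assoc_volume,
                x$assoc_sites[1], x$assoc_sites[2]))
  if (is.finite(x$melting_T))
    cat(sprintf("  melting: Tm = %g K, dh = %g J/mol, dcp = %s\n",
                x$melting_T, x$melting_enthalpy,
                if (is.finite(x$delta_cp)) paste(x$delta_cp, "J/mol/K") else "absent"))
  cat(sprintf("  rho = %g kg/m3, Tg = %g K\n", x$density, x$glass_T))
  invisible(x)
}

#' Create a binary-interaction record
#'
#' Holds the linear temperature dependence of the PC-SAFT binary interaction
#' parameter, \eqn{k_{ij} = k_{ij,m} T + k_{ij,b}}. The pair is unordered.
#'
#' @param pair character vector of two component names.
#' @param kij_m slope, 1/K.
#' @param kij_b intercept, dimensionless.
#' @return object of class `binary_interaction`.
#' @export
binaryInteraction <- function(pair, kij_m = 0, kij_b = 0) {
  stopifnot(is.character(pair), length(pair) == 2)
  if (pair[1] == pair[2] && (kij_m != 0 || kij_b != 0))
    stop("self-pair (", pair[1], ",", pair[1], ") must have kij = 0")
  structure(list(pair = sort(pair), kij_m = kij_m, kij_b = kij_b),
            class = "binary_interaction")
}

#' Evaluate the binary interaction parameter at a temperature
#'
#' @param interaction a `binary_interaction`.
#' @param T temperature, K.
#' @return dimensionless \eqn{k_{ij}(T) = k_{ij,m} T + k_{ij,b}}.
#' @export
kijAt <- function(interaction, T) {
  stopifnot(inherits(interaction, "binary_interaction"), T > 0)
  interaction$kij_m * T + interaction$kij_b
}

#' Temperature-dependent water segment diameter
#'
#' Evaluates the published correlation for the PC-SAFT segment diameter of
#' water, in angstrom, with `T` in kelvin:
#' \deqn{\sigma_w(T) = 2.7927 + 10.11 e^{-0.01755 T} - 1.417 e^{-0.01146 T}}
#'
#' @param T temperature, K.
#' @return segment diameter, angstrom.
#' @export
sigmaWater <- function(T) {
  stopifnot(all(T > 0))
  2.7927 + 10.11 * exp(-0.01755 * T) - 1.417 * exp(-0.01146 * T)
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Assemble a validated parameter set
#'
#' @param components list of [pureComponent()] records.
#' @param interactions list of [binaryInteraction()] records.
#' @param provenance free-text description of the parameter source.
#' @return object of class `parameter_set` with named component lookup and a
#'   pair-indexed interaction table. Looking up a missing pair is an error,
#'   never a silent `kij = 0`.
#' @export
parameterSet <- function(components, interactions = list(), provenance = "") {
  stopifnot(length(components) >= 1)
  names(components) <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(names(components)))
    stop("duplicate component names in parameter set")
  inter <- list()
  for (bi in interactions) {
    stopifnot(inherits(bi, "binary_interaction"))
    missing <- setdiff(bi$pair, names(components))
    if (length(missing))
      stop("interaction (", paste(bi$pair, collapse = ", "),
           ") references unregistered component(s): ",
           paste(missing, collapse = ", "))
    inter[[.pair_key(bi$pair[1], bi$pair[2])]] <- bi
  }
  structure(list(components = components, interactions = inter,
                 provenance = provenance),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", length(x$components), " components, ",
      length(x$interactions), " interactions\n", sep = "")
  cat("  components: ", paste(names(x$components), collapse = ", "), "\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ",
                                substr(x$provenance, 1, 70), "...\n", sep = "")
  invisible(x)
}

#' Look up the interaction record for a component pair
#'
#' @param params a `parameter_set`.
#' @param i,j component names. The self pair returns an identically-zero record.
#' @return a `binary_interaction`.
#' @export
getInteraction <- function(params, i, j) {
  stopifnot(inherits(params, "parameter_set"))
  if (i == j) return(binaryInteraction(c(i, j), 0, 0))
  bi <- params$interactions[[.pair_key(i, j)]]
  if (is.null(bi))
    stop("no interaction parameters registered for pair (", i, ", ", j, ")")
  bi
}

.convert_unit <- function(value, unit, field) {
  if (is.null(value) || length(value) == 0 || !is.numeric(value) || is.na(value))
    return(NA_real_)
  if (is.null(unit)) return(value)
  ok <- .known_units[[field]]
  if (!is.null(ok) && !(unit %in% c(ok, "degC"))) {
    stop("unrecognized unit '", unit, "' for field '", field, "'")
  }
  switch(unit,
         "kJ/mol" = value * 1000,
         "degC"   = value + 273.15,
         value)
}

.component_from_record <- function(rec, units) {
  need <- c("name", "molar_mass", "segment_ratio", "dispersion_energy")
  for (f in need)
    if (is.null(rec[[f]])) stop("component record missing field '", f, "'")
  num <- function(f) .convert_unit(rec[[f]], units[[f]], f)
  sites <- rec$assoc_sites
  if (is.null(sites)) sites <- c(0L, 0L)
  pureComponent(
    name = rec$name,
    molar_mass = num("molar_mass"),
    segment_ratio = num("segment_ratio"),
    segment_diameter = num("segment_diameter"),
    dispersion_energy = num("dispersion_energy"),
    assoc_energy = if (is.null(rec$assoc_energy) || is.na(num("assoc_energy"))) 0
                   else num("assoc_energy"),
    assoc_volume = num("assoc_volume"),
    assoc_sites = unlist(sites),
    melting_T = num("melting_T"),
    melting_enthalpy = num("melting_enthalpy"),
    delta_cp = num("delta_cp"),
    density = num("density"),
    glass_T = num("glass_T"),
    sigma_temperature_dependent = isTRUE(rec$sigma_temperature_dependent)
  )
}

#' Load a parameter set from a JSON or YAML file
#'
#' The file schema mirrors the record types: a `components` list, an
#' `interactions` list, an optional `units` map of explicit unit strings and a
#' `provenance` string. Temperatures are normalized to K and enthalpies to
#' J/mol internally. The packaged fixture name `"dohrn2023"` (published
#' naproxen/venetoclax/PVPVA64/water tables) resolves without a path.
#'
#' @param path file path, or a packaged fixture name.
#' @return a `parameter_set`.
#' @export
loadParameters <- function(path = "dohrn2023") {
  if (!file.exists(path)) {
    pkg_path <- system.file("extdata", paste0(path, ".json"), package = "asdphase")
    if (nzchar(pkg_path)) path <- pkg_path
    else stop("parameter file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML parameter files require the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  }
  if (is.null(raw$components)) stop("parameter file has no 'components' list")
  units <- raw$units
  comps <- lapply(raw$components, .component_from_record, units = units)
  inters <- lapply(raw$interactions, function(rec) {
    if (is.null(rec$pair) || length(unlist(rec$pair)) != 2)
      stop("interaction record missing two-name 'pair' field")
    binaryInteraction(unlist(rec$pair),
                      kij_m = .convert_unit(rec$kij_m, units$kij_m, "kij_m"),
                      kij_b = .convert_unit(rec$kij_b, units$kij_b, "kij_b"))
  })
  parameterSet(comps, inters,
               provenance = if (is.null(raw$provenance)) "" else raw$provenance)
}

#' Save a parameter set to JSON
#'
#' Writes the same schema [loadParameters()] reads, in canonical units
#' (K, J/mol, ...), so save -> load is the identity on all numeric fields.
#'
#' @param params a `parameter_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveParameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  comps <- lapply(params$components, function(cc) {
    rec <- list(name = cc$name, molar_mass = cc$molar_mass,
                segment_ratio = cc$segment_ratio,
                segment_diameter = if (cc$sigma_temperature_dependent) NULL
                                   else cc$segment_diameter,
                dispersion_energy = cc$dispersion_energy,
                assoc_energy = cc$assoc_energy,
                assoc_volume = if (is.finite(cc$assoc_volume)) cc$assoc_volume else NULL,
                assoc_sites = cc$assoc_sites,
                melting_T = if (is.finite(cc$melting_T)) cc$melting_T else NULL,
                melting_enthalpy = if (is.finite(cc$melting_enthalpy))
                                     cc$melting_enthalpy else NULL,
                delta_cp = if (is.finite(cc$delta_cp)) cc$delta_cp else NULL,
                density = cc$density, glass_T = cc$glass_T)
    if (cc$sigma_temperature_dependent) rec$sigma_temperature_dependent <- TRUE
    rec
  })
  inters <- lapply(unname(params$interactions), function(bi)
    list(pair = bi$pair, kij_m = bi$kij_m, kij_b = bi$kij_b))
  out <- list(provenance = params$provenance,
              units = list(melting_enthalpy = "J/mol"),
              components = unname(comps), interactions = inters)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
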