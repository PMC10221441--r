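# Ternary system container and mole/mass composition conversions.

#' Define an ordered (API, polymer, water) ternary system
#'
#' Binds three registered components and their pair interactions into the
#' ordered triple all phase-diagram code works with. Compositions passed to
#' and returned by the equilibrium solvers follow this order.
#'
#' @param params a `parameter_set` (see [loadParameters()]).
#' @param api,polymer,water component names registered in `params`.
#' @return object of class `ternary_system`.
#' @export
ternarySystem <- function(params, api, polymer = "PVPVA64", water = "water") {
  stopifnot(inherits(params, "parameter_set"))
  nm <- c(api, polymer, water)
  missing <- setdiff(nm, names(params$components))
  if (length(missing)) stop("unregistered component(s): ",
                            paste(missing, collapse = ", "))
  # fail early on missing pair data
  for (i in 1:2) for (j in (i + 1):3) getInteraction(params, nm[i], nm[j])
  structure(list(params = params, names = nm,
                 components = params$components[nm],
                 M = vapply(params$components[nm], `[[`, 0, "molar_mass"),
                 cache = new.env(parent = emptyenv())),
            class = "ternary_system")
}

#' @export
print.ternary_system <- function(x, ...) {
  cat("<ternary_system> API =", x$names[1], "| polymer =", x$names[2],
      "| water =", x$names[3], "\n")
  invisible(x)
}

#' Convert mass fractions to mole fractions
#'
#' @param w mass fractions (vector or matrix with components in columns).
#' @param M molar masses, g/mol, or a `ternary_system`.
#' @return mole fractions, same shape, summing to 1.
#' @export
massToMole <- function(w, M) {
  if (inherits(M, "ternary_system")) M <- M$M
  if (is.matrix(w)) {
    n <- sweep(w, 2, M, "/")
    n / rowSums(n)
  } else {
    n <- w / M
    n / sum(n)
  }
}

#' Convert mole fractions to mass fractions
#'
#' @param x mole fractions (vector or matrix with components in columns).
#' @param M molar masses, g/mol, or a `ternary_system`.
#' @return mass fractions, same shape, summing to 1.
#' @export
moleToMass <- function(x, M) {
  if (inherits(M, "ternary_system")) M <- M$M
  if (is.matrix(x)) {
    g <- sweep(x, 2, M, "*")
    g / rowSums(g)
  } else {
    g <- x * M
    g / sum(g)
  }
}
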