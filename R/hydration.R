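# Hydration pathways, locus-crossing detection, loss-of-release (LoR)
# classification, lever-rule phase fractions and Table-style hydration
# reports.

# half-up rounding to one decimal, for report columns (R's round() is
# round-half-even)
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Build a straight hydration path
#'
#' The hydration pathway of an ASD surface: the straight line in
#' mass-fraction space from the dry ASD composition `(DL, 1-DL, 0)` toward
#' the pure-water vertex, holding the API:polymer ratio fixed.
#'
#' @param drug_load API mass fraction on the water-free basis, in (0, 1).
#' @return object of class `hydration_path` with fields `drug_load` and
#'   `composition(w_water)` returning the full mass-fraction triple.
#' @export
buildPath <- function(drug_load) {
  if (!is.finite(drug_load) || drug_load <= 0 || drug_load >= 1)
    stop("drug_load must lie strictly between 0 and 1")
  structure(list(drug_load = drug_load,
                 composition = function(w_water) .path_mass(drug_load, w_water)),
            class = "hydration_path")
}

#' @export
print.hydration_path <- function(x, ...) {
  cat(sprintf("<hydration_path> DL = %.3g: (%.3g, %.3g, 0) -> (0, 0, 1)\n",
              x$drug_load, x$drug_load, 1 - x$drug_load))
  invisible(x)
}

#' Ordered locus crossings of a hydration path
#'
#' Finds where the straight hydration path of a drug load crosses the escape
#' glass transition (eGT) line, the API solubility line, and the
#' liquid-liquid binodal, each annotated with the full composition and the
#' Gordon-Taylor Tg. Dry-state supersaturation is flagged when the dry ASD
#' already exceeds the solubility limit.
#'
#' @inheritParams sleSolubility
#' @param drug_load API mass fraction on the water-free basis.
#' @param T_medium dissolution-medium temperature, K (defaults to `T`).
#' @param loci which loci to intersect (subset of `"egt"`, `"solubility"`,
#'   `"binodal"`).
#' @return object of class `crossing_events`: data frame sorted by water
#'   content with columns `locus`, `w_water`, `w_api`, `w_polymer`, `Tg_C`,
#'   `note`; the binodal row carries the conjugate (API-rich) phase in
#'   attribute `conjugate`.
#' @export
findCrossings <- function(system, T, P = 1e5, drug_load, T_medium = T,
                          loci = c("egt", "solubility", "binodal")) {
  rows <- list()
  conj <- NULL
  add <- function(locus, ww, note = "") {
    w <- .path_mass(drug_load, ww)
    rows[[length(rows) + 1]] <<- data.frame(
      locus = locus, w_water = ww, w_api = w[1], w_polymer = w[2],
      Tg_C = gordonTaylorTg(w, system$components) - 273.15, note = note)
  }
  if ("egt" %in% loci) {
    we <- egtWaterContent(drug_load, T_medium, system)
    add("egt", as.numeric(we),
        if (isTRUE(attr(we, "dry_below_medium"))) "dry Tg below medium" else "")
  }
  if ("solubility" %in% loci &&
      is.finite(system$components[[1]]$melting_T)) {
    ws <- sleCrossingWater(system, T, P, drug_load)
    if (isTRUE(attr(ws, "supersaturated_dry"))) {
      add("solubility", 0, "API supersaturated in the dry state")
    } else if (is.finite(ws)) {
      add("solubility", as.numeric(ws))
    }
  }
  if ("binodal" %in% loci) {
    bc <- tryCatch(binodalCrossing(system, T, P, drug_load),
                   error = function(e) list(outcome = conditionMessage(e)))
    if (identical(bc$outcome, "crossing")) {
      add("binodal", bc$w_water)
      conj <- bc$w_conjugate
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$w_water), ]
  rownames(out) <- NULL
  attr(out, "conjugate") <- conj
  attr(out, "drug_load") <- drug_load
  class(out) <- c("crossing_events", "data.frame")
  out
}

#' Classify the loss-of-release mechanism from ordered crossings
#'
#' Type I (interfacial crystallization): a fast crystallizer whose
#' solubility-line crossing occurs at a water content at or before the eGT
#' crossing. Type II (interfacial amorphous-amorphous phase separation): the
#' binodal crossing occurs at or before eGT for a slow crystallizer. When
#' both transformations precede eGT for a fast crystallizer, both mechanisms
#' can contribute ("mixed"). Crossings within 0.05 wt\% water of eGT are
#' flagged as sitting at the gel-layer boundary.
#'
#' @param crossings a `crossing_events` data frame (see [findCrossings()]).
#' @param crystallization_propensity `"fast"` or `"slow"`.
#' @return object of class `lor_classification`: list with `lor_type` (one
#'   of `"none"`, `"Type I"`, `"Type II"`, `"mixed"`), `rationale`,
#'   `release_expectation`, `boundary` (logical: crossing within the
#'   tolerance band of eGT).
#' @export
classifyLor <- function(crossings, crystallization_propensity = c("fast", "slow")) {
  prop <- match.arg(crystallization_propensity)
  band <- 0.0005   # 0.05 wt% water
  egt <- crossings$w_water[crossings$locus == "egt"]
  sol <- crossings$w_water[crossings$locus == "solubility"]
  bin <- crossings$w_water[crossings$locus == "binodal"]
  if (!length(egt))
    stop("crossings carry no eGT event; classification needs one")
  sol_before <- length(sol) > 0 && sol[1] <= egt[1] + band
  bin_before <- length(bin) > 0 && bin[1] <= egt[1] + band
  boundary <- (length(sol) > 0 && abs(sol[1] - egt[1]) <= band) ||
              (length(bin) > 0 && abs(bin[1] - egt[1]) <= band)
  type <- if (prop == "fast" && sol_before && bin_before) "mixed"
          else if (prop == "fast" && sol_before) "Type I"
          else if (bin_before) "Type II"
          else "none"
  release <- switch(type,
                    "none" = "congruent release",
                    "Type I" = "congruent loss (API+polymer)",
                    "mixed" = "congruent loss (API+polymer)",
                    "Type II" = "incongruent (polymer-only) release")
  rationale <- paste0(
    "eGT at ", .round1(egt[1] * 100), " wt% water",
    if (length(sol)) paste0("; solubility crossing at ",
                            .round1(sol[1] * 100), " wt%") else
      "; no solubility crossing",
    if (length(bin)) paste0("; binodal crossing at ",
                            .round1(bin[1] * 100), " wt%") else
      "; no binodal crossing",
    "; crystallization propensity ", prop)
  structure(list(lor_type = type, rationale = rationale,
                 release_expectation = release, boundary = boundary),
            class = "lor_classification")
}

#' @export
print.lor_classification <- function(x, ...) {
  cat("<lor_classification>", x$lor_type,
      if (x$boundary) "(at the gel-layer boundary)" else "", "\n")
  cat("  ", x$rationale, "\n  expected:", x$release_expectation, "\n")
  invisible(x)
}

# does the path of this drug load undergo a phase transformation in the gel
# layer (at or before its eGT water content)? Cheap check used by the
# threshold bisection: solubility via a bounded crossing search, LLPS via
# stability tests at the dry point, eGT point and midpoint.
.lor_at_dl <- function(system, T, P, drug_load, T_medium, prop) {
  band <- 0.0005
  we <- as.numeric(egtWaterContent(drug_load, T_medium, system))
  sol_before <- FALSE
  if (prop == "fast" && is.finite(system$components[[1]]$melting_T)) {
    ws <- sleCrossingWater(system, T, P, drug_load, w_max = min(we + 0.05, 0.95))
    sol_before <- isTRUE(attr(ws, "supersaturated_dry")) ||
      (is.finite(ws) && ws <= we + band)
  }
  if (sol_before) return(TRUE)
  # quick LLPS check: short tangent-plane minimizations at the dry, half-way
  # and eGT points of the gel-layer segment
  lnact <- .lnact_factory(system, T, P)
  for (ww in c(we, we / 2, 0)) {
    z <- massToMole(.path_mass(drug_load, ww), system)
    seeds <- list(c(0.93, 0, 0.07), pmax(z * c(5, 0.2, 1), 1e-12))
    seeds <- lapply(seeds, function(s) { s[z == 0] <- 0; s / sum(s) })
    for (s in seeds) {
      r <- tryCatch(.tpd_minimize(lnact, z, s, maxit = 35, tol = 1e-8,
                                  early_exit = TRUE),
                    error = function(e) NULL)
      if (!is.null(r) && r$tpd < -1e-8) return(TRUE)
    }
  }
  FALSE
}

#' Smallest drug load with a gel-layer phase transformation
#'
#' Bisects the drug load for the onset of loss of release: the smallest DL
#' at which the hydration path undergoes crystallization (fast crystallizer)
#' or liquid-liquid demixing at or before its eGT composition.
#'
#' @inheritParams sleSolubility
#' @param crystallization_propensity `"fast"` or `"slow"`.
#' @param T_medium dissolution-medium temperature, K.
#' @param dl_lo,dl_hi search bounds for the drug load.
#' @param tol bisection tolerance on the drug load (0.1 wt\% default).
#' @return threshold drug load (mass fraction), or `NA` with attribute
#'   `outcome = "no threshold"` when no searched DL shows LoR.
#' @export
lorThresholdDl <- function(system, T, P = 1e5,
                           crystallization_propensity = c("fast", "slow"),
                           T_medium = T, dl_lo = 0.002, dl_hi = 0.99,
                           tol = 0.001) {
  prop <- match.arg(crystallization_propensity)
  f <- function(dl) .lor_at_dl(system, T, P, dl, T_medium, prop)
  if (f(dl_lo)) return(dl_lo)
  if (!f(dl_hi)) {
    out <- NA_real_
    attr(out, "outcome") <- "no threshold"
    return(out)
  }
  lo <- dl_lo; hi <- dl_hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Lever-rule phase fractions
#'
#' Mass fractions of the two coexisting phases for a feed on a tie line.
#'
#' @param feed mass-fraction feed composition.
#' @param tie a `tie_line` (see [lleFlash()]).
#' @param tol_collinear largest accepted distance of the feed from the tie
#'   segment (mass-fraction units).
#' @return named vector `c(polymer_rich = , api_rich = )` summing to 1.
#' @export
leverFractions <- function(feed, tie, tol_collinear = 1e-6) {
  stopifnot(inherits(tie, "tie_line"), tie$outcome == "two phases")
  feed <- feed / sum(feed)
  d <- tie$w2 - tie$w1
  k <- which.max(abs(d))
  beta <- (feed[k] - tie$w1[k]) / d[k]
  resid <- feed - (tie$w1 + beta * d)
  if (max(abs(resid)) > tol_collinear)
    stop("feed is not collinear with the tie line (off by ",
         signif(max(abs(resid)), 3), ")")
  if (beta < -1e-10 || beta > 1 + 1e-10)
    stop("feed lies outside the tie segment")
  beta <- min(max(beta, 0), 1)
  c(polymer_rich = 1 - beta, api_rich = beta)
}

#' Required dose strength for a supersaturation target
#'
#' Dose (mg) that, fully dissolved in the medium volume, yields a maximum
#' concentration of `supersaturation_factor` times the aqueous solubility.
#'
#' @param aqueous_solubility solubility in the medium, g/L.
#' @param volume medium volume, L.
#' @param supersaturation_factor target concentration as a multiple of the
#'   solubility.
#' @return dose in mg, rounded to the nearest integer.
#' @export
doseStrength <- function(aqueous_solubility, volume, supersaturation_factor) {
  stopifnot(aqueous_solubility > 0, volume > 0, supersaturation_factor > 0)
  round(aqueous_solubility * volume * supersaturation_factor * 1000)
}

#' Hydration-pathway report for a set of drug loads
#'
#' For each drug load: the dry-ASD row, the eGT row, the solubility-limit row
#' (or a dry-state supersaturation note), and the binodal rows (path-side
#' polymer-rich phase and conjugate API-rich phase), each with compositions
#' and Gordon-Taylor Tg, plus the LoR classification.
#'
#' @inheritParams findCrossings
#' @param drug_loads vector of API mass fractions (water-free basis).
#' @param crystallization_propensity `"fast"` or `"slow"`.
#' @return object of class `hydration_report`: list with `table` (data frame
#'   with columns `drug_load`, `row`, `w_water`, `w_api`, `w_polymer`,
#'   `Tg_C`, `note`, in wt\% rounded half-up to one decimal, plus exact
#'   `*_raw` columns) and `classification` (named list per drug load).
#' @export
hydrationReport <- function(system, T, P = 1e5, drug_loads, T_medium = T,
                            crystallization_propensity = c("fast", "slow")) {
  prop <- match.arg(crystallization_propensity)
  tg <- function(w) gordonTaylorTg(w, system$components) - 273.15
  rows <- list()
  cls <- list()
  add <- function(dl, label, w, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      drug_load = dl * 100, row = label,
      w_water = if (all(is.finite(w))) .round1(w[3] * 100) else NA_real_,
      w_api = if (all(is.finite(w))) .round1(w[1] * 100) else NA_real_,
      w_polymer = if (all(is.finite(w))) .round1(w[2] * 100) else NA_real_,
      Tg_C = if (all(is.finite(w))) .round1(tg(w)) else NA_real_,
      w_water_raw = w[3], w_api_raw = w[1], w_polymer_raw = w[2],
      Tg_C_raw = if (all(is.finite(w))) tg(w) else NA_real_,
      note = note)
  }
  for (dl in drug_loads) {
    add(dl, "ASD (dry)", .path_mass(dl, 0))
    cr <- findCrossings(system, T, P, dl, T_medium)
    egt_w <- cr$w_water[cr$locus == "egt"]
    bin_w <- cr$w_water[cr$locus == "binodal"]
    if (length(bin_w) && length(egt_w) && bin_w[1] < egt_w[1] - 0.0005) {
      add(dl, "eGT", rep(NA_real_, 3), "LLPS occurs before eGT")
    } else if (length(egt_w)) {
      add(dl, "eGT", .path_mass(dl, egt_w[1]))
    }
    srow <- cr[cr$locus == "solubility", , drop = FALSE]
    if (nrow(srow)) {
      if (nzchar(srow$note[1])) {
        add(dl, "Solubility limit", rep(NA_real_, 3), srow$note[1])
      } else {
        add(dl, "Solubility limit", .path_mass(dl, srow$w_water[1]))
      }
    }
    if (length(bin_w)) {
      add(dl, "Polymer-rich phase at binodal line", .path_mass(dl, bin_w[1]))
      conj <- attr(cr, "conjugate")
      if (!is.null(conj)) add(dl, "API-rich phase at binodal line", conj)
    }
    cls[[as.character(dl)]] <- classifyLor(cr, prop)
  }
  structure(list(system = system$names, T = T, P = P, T_medium = T_medium,
                 crystallization_propensity = prop,
                 table = do.call(rbind, rows), classification = cls),
            class = "hydration_report")
}

#' @export
print.hydration_report <- function(x, ...) {
  cat(sprintf("<hydration_report> %s at %.2f K (medium %.2f K)\n",
              paste(x$system, collapse = "/"), x$T, x$T_medium))
  print(x$table[, c("drug_load", "row", "w_water", "w_api", "w_polymer",
                    "Tg_C", "note")], row.names = FALSE)
  for (nm in names(x$classification))
    cat(sprintf("  DL %s: %s\n", nm, x$classification[[nm]]$lor_type))
  invisible(x)
}

#' Export a hydration report to CSV
#'
#' Columns mirror the report table order (water, API, polymer, Tg).
#'
#' @param report a `hydration_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportReportCSV <- function(report, path) {
  utils::write.csv(report$table[, c("drug_load", "row", "w_water", "w_api",
                                    "w_polymer", "Tg_C", "note")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a hydration report (with classifications) to JSON
#'
#' @param report a `hydration_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
exportReportJSON <- function(report, path) {
  payload <- list(system = report$system, T = report$T, P = report$P,
                  T_medium = report$T_medium,
                  crystallization_propensity = report$crystallization_propensity,
                  table = report$table,
                  classification = lapply(report$classification, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
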