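# Verification machinery: closed-form toy activity models whose phase
# behavior is known analytically, a brute-force tangent-plane grid oracle,
# and the transcribed expected-value regression tables.

#' Margules-type toy activity model
#'
#' Multicomponent regular-solution (two-suffix Margules) excess Gibbs model,
#' \eqn{g^E/RT = \sum_{i<j} A_{ij} x_i x_j}, with closed-form binary
#' spinodal and critical point (for the symmetric binary: critical at
#' \eqn{A = 2}, \eqn{x = 1/2}; spinodal \eqn{1/x_1 + 1/x_2 = 2A}). Used as
#' an independent oracle for the equilibrium solvers.
#'
#' @param A symmetric matrix of pairwise interaction strengths (diagonal 0).
#' @return object of class `toy_activity_model` with elements `lnact(x)`
#'   (ln activities), `lngamma(x)`, `n` (component count) and `A`.
#' @export
toyActivityModel <- function(A) {
  A <- as.matrix(A)
  stopifnot(isSymmetric(A), all(diag(A) == 0))
  n <- nrow(A)
  lngamma <- function(x) {
    x <- x / sum(x)
    gE <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) gE <- gE + A[i, j] * x[i] * x[j]
    drop(A %*% x) - gE
  }
  lnact <- function(x) {
    x <- x / sum(x)
    ifelse(x > 0, log(x) + lngamma(x), -Inf)
  }
  structure(list(lnact = lnact, lngamma = lngamma, n = n, A = A),
            class = "toy_activity_model")
}

#' Closed-form binary spinodal of the symmetric toy model
#'
#' Roots of \eqn{1/x_1 + 1/x_2 - 2A = 0}: the local-instability boundary of
#' the two-suffix Margules binary.
#'
#' @param A interaction strength (must exceed the critical value 2).
#' @return vector of the two spinodal compositions \eqn{x_1}.
#' @export
toySpinodal <- function(A) {
  if (A <= 2) return(numeric(0))
  # 1/x + 1/(1-x) = 2A  =>  2A x^2 - 2A x + 1 = 0
  disc <- sqrt(1 - 2 / A)
  c((1 - disc) / 2, (1 + disc) / 2)
}

#' Closed-form binary binodal of the symmetric toy model
#'
#' Solves \eqn{\ln(x/(1-x)) + A(1-2x) = 0} for the nontrivial root: the
#' coexisting compositions are `x` and `1-x` by symmetry.
#'
#' @param A interaction strength (> 2).
#' @return vector of the two coexisting compositions \eqn{x_1}.
#' @export
toyBinodal <- function(A) {
  if (A <= 2) return(numeric(0))
  f <- function(x) log(x / (1 - x)) + A * (1 - 2 * x)
  r <- stats::uniroot(f, c(1e-12, 0.5 - 1e-9), tol = 1e-14)$root
  c(r, 1 - r)
}

#' Brute-force tangent-plane stability map on a composition grid
#'
#' Exhaustively evaluates the tangent-plane distance of every grid
#' composition against trial phases drawn from the same grid: ground truth
#' for [stabilityTest()] and [traceBinodal()] on small instances.
#'
#' @param lnact ln-activity closure (`function(x)`), e.g. a
#'   `toy_activity_model$lnact` or the PC-SAFT closure of a ternary system.
#' @param n number of components (2 or 3).
#' @param grid_n grid resolution per dimension.
#' @param w_limit for ternary grids, largest water coordinate scanned.
#' @return data frame with grid compositions, the minimal tangent-plane
#'   distance `tpd_min` over grid trials, and `stable`.
#' @export
oracleTangentPlaneGrid <- function(lnact, n = 2, grid_n = 100, w_limit = 1) {
  stopifnot(grid_n >= 10)
  if (n == 2) {
    xs <- seq(1e-6, 1 - 1e-6, length.out = grid_n)
    la <- t(vapply(xs, function(x) lnact(c(x, 1 - x)), numeric(2)))
    gmix <- xs * la[, 1] + (1 - xs) * la[, 2]  # not needed downstream; kept cheap
    tpd_min <- numeric(grid_n)
    stable <- logical(grid_n)
    for (k in seq_len(grid_n)) {
      d <- la[k, ]
      vals <- (xs * (la[, 1] - d[1]) + (1 - xs) * (la[, 2] - d[2]))
      tpd_min[k] <- min(vals)
      stable[k] <- tpd_min[k] > -1e-9
    }
    data.frame(x1 = xs, tpd_min = tpd_min, stable = stable)
  } else if (n == 3) {
    xs <- seq(1e-6, 1 - 1e-6, length.out = grid_n)
    pts <- list(); las <- list()
    for (x1 in xs) for (x3 in xs) {
      if (x1 + x3 < 1 - 1e-6 && x3 <= w_limit) {
        pts[[length(pts) + 1]] <- c(x1, 1 - x1 - x3, x3)
      }
    }
    P <- do.call(rbind, pts)
    L <- t(apply(P, 1, lnact))
    m <- nrow(P)
    tpd_min <- numeric(m)
    for (k in seq_len(m)) {
      d <- L[k, ]
      vals <- P[, 1] * (L[, 1] - d[1]) + P[, 2] * (L[, 2] - d[2]) +
        P[, 3] * (L[, 3] - d[3])
      tpd_min[k] <- min(vals)
    }
    data.frame(x1 = P[, 1], x2 = P[, 2], x3 = P[, 3],
               tpd_min = tpd_min, stable = tpd_min > -1e-9)
  } else stop("n must be 2 or 3")
}

#' Expected-value regression table
#'
#' The published hydration-pathway tables (naproxen and venetoclax systems
#' at 37 degC), transcribed with one row per printed quantity, its units,
#' and the comparison tolerance class: Gordon-Taylor closed-form outputs
#' carry +/-1.5 degC on Tg and +/-0.5 wt\% on compositions; PC-SAFT-derived
#' loci carry +/-1.0 wt\% on compositions and +/-3 degC on the Tg evaluated
#' at them.
#'
#' @return data frame with columns `api`, `temperature_c`, `drug_load_wtpc`,
#'   `row`, `quantity`, `value`, `units`, `tolerance`, `tolerance_class`.
#' @export
regressionTables <- function() {
  path <- system.file("extdata", "regression_tables.csv", package = "asdphase")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one expected value from the regression table
#'
#' @param api `"naproxen"` or `"venetoclax"`.
#' @param temperature_c report temperature, degC.
#' @param drug_load_wtpc drug load, wt\% (as printed).
#' @param row row label, e.g. `"solubility"`, `"egt"`, `"binodal-polymer-rich"`,
#'   `"binodal-api-rich"`, `"dry"`.
#' @param quantity `"water"`, `"api"`, `"polymer"` (wt\%) or `"Tg"` (degC).
#' @return list with `value` and `tolerance`, or `NULL` when the table has
#'   no such row (an absent marker, never zero).
#' @export
lookupExpected <- function(api, temperature_c, drug_load_wtpc, row, quantity) {
  tb <- regressionTables()
  hit <- tb[tb$api == api & tb$temperature_c == temperature_c &
              tb$drug_load_wtpc == drug_load_wtpc & tb$row == row &
              tb$quantity == quantity, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  list(value = hit$value[1], tolerance = hit$tolerance[1])
}
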