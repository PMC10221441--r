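# PC-SAFT equation of state: hard-chain + dispersion + association residual
# Helmholtz energy, liquid density at fixed T and P, fugacity and activity
# coefficients. Reduced quantities throughout (a = A/(N kB T)); lengths in
# angstrom, number densities in molecules/angstrom^3.

.kB <- 1.380649e-23   # J/K
.NA <- 6.02214076e23  # 1/mol
.R  <- 8.31446261815324 # J/mol/K

# Universal model constants of the dispersion term (power series in packing
# fraction, coefficients depending on mean segment number).
.disp_a <- matrix(c(
   0.9105631445, -0.3084016918, -0.0906148351,
   0.6361281449,  0.1860531159,  0.4527842806,
   2.6861347891, -2.5030047259,  0.5962700728,
 -26.547362491,  21.419793629,  -1.7241829131,
  97.759208784, -65.255885330,  -4.1302112531,
-159.59154087,   83.318680481,  13.776631870,
  91.297774084, -33.746922930,  -8.6728470368), ncol = 3, byrow = TRUE)
.disp_b <- matrix(c(
   0.7240946941, -0.5755498075,  0.0976883116,
   2.2382791861,  0.6995095521, -0.2557574982,
  -4.0025849485,  3.8925673390, -9.1558561530,
 -21.003576815, -17.215471648,  20.642075974,
  26.855641363, 192.67226447,  -38.804430052,
 206.55133841, -161.82646165,   93.626774077,
-355.60235612, -165.20769346,  -29.666905585), ncol = 3, byrow = TRUE)

#' Build a PC-SAFT mixture
#'
#' Collects the pure-component parameters and pair interactions of an
#' arbitrary subset of registered components into the object all equation of
#' state routines consume.
#'
#' @param x a `ternary_system`, or a list of [pureComponent()] records.
#' @param params a `parameter_set` supplying the binary interaction
#'   coefficients (taken from `x` when `x` is a `ternary_system`). May be
#'   `NULL` when `x` has a single component.
#' @return object of class `saft_mixture`.
#' @export
saftMixture <- function(x, params = NULL) {
  if (inherits(x, "ternary_system")) {
    comps <- x$components
    params <- x$params
  } else {
    comps <- x
    names(comps) <- vapply(comps, `[[`, "", "name")
  }
  n <- length(comps)
  nm <- names(comps)
  km <- matrix(0, n, n); kb <- matrix(0, n, n)
  if (n > 1) {
    if (is.null(params)) stop("parameter_set required for mixtures")
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      bi <- getInteraction(params, nm[i], nm[j])
      km[i, j] <- km[j, i] <- bi$kij_m
      kb[i, j] <- kb[j, i] <- bi$kij_b
    }
  }
  structure(list(
    names = nm,
    n = n,
    M = vapply(comps, `[[`, 0, "molar_mass"),
    m = vapply(comps, `[[`, 0, "m_seg"),
    sigma0 = vapply(comps, function(cc)
      if (cc$sigma_temperature_dependent) NA_real_ else cc$segment_diameter, 0),
    sigmaT = vapply(comps, `[[`, TRUE, "sigma_temperature_dependent"),
    u = vapply(comps, `[[`, 0, "dispersion_energy"),
    eps = vapply(comps, `[[`, 0, "assoc_energy"),
    kap = vapply(comps, function(cc)
      if (is.finite(cc$assoc_volume)) cc$assoc_volume else 0, 0),
    NA_sites = vapply(comps, function(cc) cc$assoc_sites[1], 0L),
    NB_sites = vapply(comps, function(cc) cc$assoc_sites[2], 0L),
    kij_m = km, kij_b = kb,
    components = comps,
    cache = new.env(parent = emptyenv())
  ), class = "saft_mixture")
}

#' Temperature-dependent cross parameters for a component pair
#'
#' Conventional combining rules: arithmetic-mean segment diameter,
#' geometric-mean dispersion energy corrected by \eqn{(1-k_{ij}(T))}, and the
#' Wolbach-Sandler rules for the cross association energy (arithmetic mean)
#' and volume (geometric mean times a segment-diameter ratio factor).
#'
#' @param ci,cj [pureComponent()] records.
#' @param T temperature, K.
#' @param kij dimensionless binary interaction parameter at `T` (see
#'   [kijAt()]); defaults to 0.
#' @return list with `sigma_ij` (angstrom), `u_ij` (K), `eps_ij` (K),
#'   `kappa_ij` (dimensionless).
#' @export
crossParameters <- function(ci, cj, T, kij = 0) {
  si <- if (ci$sigma_temperature_dependent) sigmaWater(T) else ci$segment_diameter
  sj <- if (cj$sigma_temperature_dependent) sigmaWater(T) else cj$segment_diameter
  ki <- if (is.finite(ci$assoc_volume)) ci$assoc_volume else 0
  kj <- if (is.finite(cj$assoc_volume)) cj$assoc_volume else 0
  list(sigma_ij = (si + sj) / 2,
       u_ij = sqrt(ci$dispersion_energy * cj$dispersion_energy) * (1 - kij),
       eps_ij = (ci$assoc_energy + cj$assoc_energy) / 2,
       kappa_ij = sqrt(ki * kj) * (sqrt(si * sj) / ((si + sj) / 2))^3)
}

# Precompute all temperature-dependent arrays for a mixture at T.
.saft_tp <- function(mix, T) {
  key <- paste0("tp", format(T, digits = 15))
  hit <- mix$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- mix$n
  sig <- ifelse(mix$sigmaT, sigmaWater(T), mix$sigma0)
  d <- sig * (1 - 0.12 * exp(-3 * mix$u / T))
  kij <- mix$kij_m * T + mix$kij_b
  sig_ij <- outer(sig, sig, `+`) / 2
  u_ij <- sqrt(outer(mix$u, mix$u)) * (1 - kij)
  eps_ij <- outer(mix$eps, mix$eps, `+`) / 2
  kap_ij <- sqrt(outer(mix$kap, mix$kap)) *
    (sqrt(outer(sig, sig)) / sig_ij)^3
  # association strength prefactor (without g_ij which is density dependent)
  assoc_pref <- sig_ij^3 * kap_ij * (exp(eps_ij / T) - 1)
  has_sites <- (mix$NA_sites + mix$NB_sites) > 0
  # pair participates if either direction A_i-B_j can bond
  assoc_any <- any(assoc_pref[has_sites, has_sites, drop = FALSE] > 0)
  dd <- outer(d, d) / outer(d, d, `+`)   # d_i d_j / (d_i + d_j)
  uT <- u_ij / T
  tp <- list(T = T, sig = sig, d = d, d2 = d^2, d3 = d^3, kij = kij,
             sig_ij = sig_ij, u_ij = u_ij, uT_ij = uT,
             eps_ij = eps_ij, kap_ij = kap_ij, assoc_pref = assoc_pref,
             has_sites = has_sites, assoc_any = assoc_any,
             md3 = mix$m * d^3, dd = dd, dd2 = dd^2,
             S1 = uT * sig_ij^3, S2 = uT^2 * sig_ij^3,
             act = which(has_sites),
             symmetric_sites = all(mix$NA_sites == mix$NB_sites))
  mix$cache[[key]] <- tp
  tp
}

# Solve unbonded-site fractions XA, XB. Default path: Newton on the
# mass-action system, with damped successive substitution as a fallback for
# hard states. `ax` may be unnormalized mole numbers (derivative evaluation
# perturbs compositions without renormalizing). For the symmetric donor/
# acceptor schemes used here (N/N sites, symmetric cross energies) XA == XB
# and the system reduces to one unknown per associating component.
.site_fractions <- function(mix, tp, ax, rho, gij,
                            damping = 0.5, maxit = 10000) {
  act <- tp$act
  na <- length(act)
  Dij <- tp$assoc_pref[act, act, drop = FALSE] * gij[act, act, drop = FALSE]
  xj <- ax[act]
  CA <- Dij * rep(rho * xj * mix$NB_sites[act], each = na)
  XAf <- rep(1, mix$n); XBf <- rep(1, mix$n)
  if (tp$symmetric_sites) {
    # XA = XB = X solves X_i (1 + (C X)_i) = 1
    X <- 1 / (1 + rowSums(CA))
    ok <- FALSE
    for (it in 1:80) {
      CX <- drop(CA %*% X)
      Fx <- X * (1 + CX) - 1
      if (max(abs(Fx)) < 1e-14) { ok <- TRUE; break }
      J <- X * CA
      diag(J) <- diag(J) + 1 + CX
      step <- tryCatch(solve(J, Fx), error = function(e) NULL)
      if (is.null(step)) break
      Xn <- X - step
      if (any(!is.finite(Xn)) || any(Xn <= 0) || any(Xn > 1.5)) {
        Xn <- pmin(pmax(X - 0.5 * step, 1e-15), 1)
      }
      X <- Xn
    }
    if (!ok) {
      # damped successive substitution fallback
      X <- rep(0.5, na)
      for (it in seq_len(maxit)) {
        Xn <- damping / (1 + drop(CA %*% X)) + (1 - damping) * X
        if (max(abs(Xn - X)) < 1e-15) { X <- Xn; ok <- TRUE; break }
        X <- Xn
      }
      if (!ok) stop("association solver did not converge")
    }
    XAf[act] <- X; XBf[act] <- X
    return(list(XA = XAf, XB = XBf))
  }
  CB <- Dij * rep(rho * xj * mix$NA_sites[act], each = na)
  XA <- rep(0.5, na); XB <- rep(0.5, na)
  for (it in seq_len(maxit)) {
    XA_new <- damping / (1 + drop(CA %*% XB)) + (1 - damping) * XA
    XB_new <- damping / (1 + drop(CB %*% XA)) + (1 - damping) * XB
    err <- max(abs(XA_new - XA), abs(XB_new - XB))
    XA <- XA_new; XB <- XB_new
    if (err < 1e-10) break
    if (it == maxit)
      stop("association solver did not converge (residual ", signif(err, 3), ")")
  }
  # Newton polish to near machine precision (the Helmholtz formula is not
  # stationary in X, so downstream derivatives need tight X).
  for (it in 1:50) {
    FA <- XA * (1 + drop(CA %*% XB)) - 1
    FB <- XB * (1 + drop(CB %*% XA)) - 1
    if (max(abs(FA), abs(FB)) < 1e-14) break
    J <- matrix(0, 2 * na, 2 * na)
    diag(J)[1:na] <- 1 + drop(CA %*% XB)
    diag(J)[(na + 1):(2 * na)] <- 1 + drop(CB %*% XA)
    J[1:na, (na + 1):(2 * na)] <- XA * CA
    J[(na + 1):(2 * na), 1:na] <- XB * CB
    step <- tryCatch(solve(J, c(FA, FB)), error = function(e) NULL)
    if (is.null(step)) break
    XA <- pmin(pmax(XA - step[1:na], 1e-15), 1)
    XB <- pmin(pmax(XB - step[(na + 1):(2 * na)], 1e-15), 1)
  }
  XAf[act] <- XA; XBf[act] <- XB
  list(XA = XAf, XB = XBf)
}

# Reduced residual Helmholtz energy a = A^res/(N kB T) and its breakdown.
# ax: mole fractions (may be unnormalized for derivative evaluation);
# rho: number density, molecules/A^3.
.a_res <- function(mix, tp, ax, rho, want_sites = FALSE) {
  m <- mix$m
  mbar <- sum(ax * m)
  z0 <- pi / 6 * rho * sum(ax * m)
  z1 <- pi / 6 * rho * sum(ax * m * tp$d)
  z2 <- pi / 6 * rho * sum(ax * m * tp$d2)
  z3 <- pi / 6 * rho * sum(ax * m * tp$d3)
  om <- 1 - z3
  # hard-sphere + chain
  a_hs <- (3 * z1 * z2 / om + z2^3 / (z3 * om^2) +
             (z2^3 / z3^2 - z0) * log(om)) / z0
  gij <- 1 / om + tp$dd * (3 * z2 / om^2) + tp$dd2 * (2 * z2^2 / om^3)
  a_hc <- mbar * a_hs - sum(ax * (m - 1) * log(diag(gij)))
  # dispersion
  eta <- z3
  mr <- (mbar - 1) / mbar
  mr2 <- mr * (mbar - 2) / mbar
  ai <- .disp_a[, 1] + mr * .disp_a[, 2] + mr2 * .disp_a[, 3]
  bi <- .disp_b[, 1] + mr * .disp_b[, 2] + mr2 * .disp_b[, 3]
  etapow <- eta^(0:6)
  I1 <- sum(ai * etapow)
  I2 <- sum(bi * etapow)
  C1 <- 1 / (1 + mbar * (8 * eta - 2 * eta^2) / om^4 +
               (1 - mbar) * (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
               (om * (2 - eta))^2)
  xm <- ax * m
  m2es3 <- drop(xm %*% tp$S1 %*% xm)
  m2e2s3 <- drop(xm %*% tp$S2 %*% xm)
  a_disp <- -2 * pi * rho * I1 * m2es3 - pi * rho * mbar * C1 * I2 * m2e2s3
  # association
  if (tp$assoc_any) {
    sf <- .site_fractions(mix, tp, ax, rho, gij)
    a_assoc <- sum(ax * (mix$NA_sites * (log(sf$XA) - sf$XA / 2 + 0.5) +
                           mix$NB_sites * (log(sf$XB) - sf$XB / 2 + 0.5)))
  } else {
    sf <- list(XA = rep(1, mix$n), XB = rep(1, mix$n))
    a_assoc <- 0
  }
  out <- list(a_hc = a_hc, a_disp = a_disp, a_assoc = a_assoc,
              a_res = a_hc + a_disp + a_assoc, eta = z3)
  if (want_sites) out$sites <- sf
  out
}

# Analytic first derivatives of the reduced residual Helmholtz energy:
# composition gradient at constant number density (for chemical potentials)
# and the density derivative (for the compressibility factor). The
# association contribution uses the stationarity of the underlying
# mass-action functional, so site-fraction derivatives never appear.
# Requires the symmetric N/N site scheme (donor count == acceptor count per
# component), which covers every system here.
.a_core <- function(mix, tp, ax, rho, want_dx = TRUE) {
  m <- mix$m
  n <- mix$n
  d <- tp$d
  mbar <- sum(ax * m)
  pir <- pi / 6 * rho
  zk0 <- pir * m; zk1 <- zk0 * d; zk2 <- zk0 * tp$d2; zk3 <- zk0 * tp$d3
  z0 <- sum(ax * zk0); z1 <- sum(ax * zk1)
  z2 <- sum(ax * zk2); z3 <- sum(ax * zk3)
  om <- 1 - z3
  lom <- log(om)
  # hard sphere
  A <- 3 * z1 * z2 / om
  B <- z2^3 / (z3 * om^2)
  C <- (z2^3 / z3^2 - z0) * lom
  a_hs <- (A + B + C) / z0
  dahs <- c(
    -(a_hs + lom) / z0,
    3 * z2 / (om * z0),
    (3 * z1 / om + 3 * z2^2 / (z3 * om^2) + 3 * z2^2 * lom / z3^2) / z0,
    (3 * z1 * z2 / om^2 + z2^3 * (2 / (z3 * om^3) - 1 / (z3^2 * om^2)) -
       2 * z2^3 * lom / z3^3 - (z2^3 / z3^2 - z0) / om) / z0)
  # radial distribution function at contact and its zeta derivatives
  gij <- 1 / om + tp$dd * (3 * z2 / om^2) + tp$dd2 * (2 * z2^2 / om^3)
  dg_dz2 <- tp$dd * (3 / om^2) + tp$dd2 * (4 * z2 / om^3)
  dg_dz3 <- 1 / om^2 + tp$dd * (6 * z2 / om^3) + tp$dd2 * (6 * z2^2 / om^4)
  gdiag <- diag(gij)
  a_hc <- mbar * a_hs - sum(ax * (m - 1) * log(gdiag))
  # dispersion
  eta <- z3
  mr1 <- (mbar - 1) / mbar
  mr2 <- (mbar - 1) * (mbar - 2) / mbar^2
  ai <- .disp_a[, 1] + mr1 * .disp_a[, 2] + mr2 * .disp_a[, 3]
  bi <- .disp_b[, 1] + mr1 * .disp_b[, 2] + mr2 * .disp_b[, 3]
  dmr1 <- 1 / mbar^2
  dmr2 <- (2 * mbar - 3) / mbar^2 - 2 * (mbar - 1) * (mbar - 2) / mbar^3
  dai <- dmr1 * .disp_a[, 2] + dmr2 * .disp_a[, 3]
  dbi <- dmr1 * .disp_b[, 2] + dmr2 * .disp_b[, 3]
  ip <- 0:6
  etapow <- eta^ip
  etapow1 <- c(0, ip[-1] * eta^(ip[-1] - 1))
  I1 <- sum(ai * etapow); I2 <- sum(bi * etapow)
  I1p <- sum(ai * etapow1); I2p <- sum(bi * etapow1)
  dI1m <- sum(dai * etapow); dI2m <- sum(dbi * etapow)
  h1 <- (8 * eta - 2 * eta^2) / om^4
  N2 <- 20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4
  v <- om * (2 - eta)
  h2 <- N2 / v^2
  D <- 1 + mbar * h1 + (1 - mbar) * h2
  C1 <- 1 / D
  h1p <- (8 - 4 * eta) / om^4 + 4 * (8 * eta - 2 * eta^2) / om^5
  u2 <- 20 - 54 * eta + 36 * eta^2 - 8 * eta^3
  vp <- -3 + 2 * eta
  h2p <- u2 / v^2 - 2 * N2 * vp / v^3
  dC1eta <- -C1^2 * (mbar * h1p + (1 - mbar) * h2p)
  dC1m <- -C1^2 * (h1 - h2)
  xm <- ax * m
  M1v <- drop(tp$S1 %*% xm)   # (S1 xm)_k
  M2v <- drop(tp$S2 %*% xm)
  M1 <- sum(xm * M1v)
  M2 <- sum(xm * M2v)
  a_disp <- -2 * pi * rho * I1 * M1 - pi * rho * mbar * C1 * I2 * M2
  # association (symmetric site scheme)
  if (tp$assoc_any) {
    sf <- .site_fractions(mix, tp, ax, rho, gij)
    X <- sf$XA
    Nst <- mix$NA_sites
    a_assoc <- sum(ax * 2 * Nst * (log(X) - X / 2 + 0.5))
    xNX <- ax * Nst * X
    Tm <- outer(xNX, xNX) * tp$assoc_pref    # T_ij = x x N N X X * pref
    sumTg <- sum(Tm * gij)
    sumT2 <- sum(Tm * dg_dz2)
    sumT3 <- sum(Tm * dg_dz3)
  } else {
    X <- rep(1, n); a_assoc <- 0
    sumTg <- sumT2 <- sumT3 <- 0
    Nst <- mix$NA_sites
  }
  a_res <- a_hc + a_disp + a_assoc
  # density derivative -> compressibility factor
  rho_dahs <- z0 * dahs[1] + z1 * dahs[2] + z2 * dahs[3] + z3 * dahs[4]
  wge <- ax * (m - 1) / gdiag
  rho_dghc <- sum(wge * (z2 * diag(dg_dz2) + z3 * diag(dg_dz3)))
  Zhc <- mbar * rho_dahs - rho_dghc
  Zdisp <- -2 * pi * rho * (I1 + eta * I1p) * M1 -
    pi * rho * mbar * M2 * (C1 * I2 + eta * (dC1eta * I2 + C1 * I2p))
  Zassoc <- -rho * (sumTg + z2 * sumT2 + z3 * sumT3)
  Z <- 1 + Zhc + Zdisp + Zassoc
  out <- list(a_hc = a_hc, a_disp = a_disp, a_assoc = a_assoc, a_res = a_res,
              Z = Z, eta = z3)
  if (want_dx) {
    dahs_dx <- zk0 * dahs[1] + zk1 * dahs[2] + zk2 * dahs[3] + zk3 * dahs[4]
    s2 <- sum(wge * diag(dg_dz2)); s3 <- sum(wge * diag(dg_dz3))
    dahc <- m * a_hs + mbar * dahs_dx - (m - 1) * log(gdiag) -
      (s2 * zk2 + s3 * zk3)
    dM1 <- 2 * m * M1v
    dM2 <- 2 * m * M2v
    dadisp <- -2 * pi * rho * ((dI1m * m + I1p * zk3) * M1 + I1 * dM1) -
      pi * rho * (m * C1 * I2 * M2 +
                    mbar * (dC1m * m + dC1eta * zk3) * I2 * M2 +
                    mbar * C1 * (dI2m * m + I2p * zk3) * M2 +
                    mbar * C1 * I2 * dM2)
    if (tp$assoc_any) {
      daassoc <- 2 * Nst * log(X) - rho * (sumT2 * zk2 + sumT3 * zk3)
    } else daassoc <- numeric(n)
    out$dadx <- dahc + dadisp + daassoc
  }
  out
}

# Compressibility factor by central differencing of a_res in density.
.z_factor <- function(mix, tp, x, rho) {
  h <- rho * 1e-5
  ap <- .a_res(mix, tp, x, rho + h)$a_res
  am <- .a_res(mix, tp, x, rho - h)$a_res
  1 + rho * (ap - am) / (2 * h)
}

.pressure <- function(mix, tp, x, rho) {
  # rho in molecules/A^3 -> P in Pa
  Z <- if (tp$symmetric_sites) .a_core(mix, tp, x, rho, want_dx = FALSE)$Z
       else .z_factor(mix, tp, x, rho)
  Z * rho * 1e30 * .kB * tp$T
}

.eta_to_rho <- function(tp, x, eta) 6 * eta / (pi * sum(x * tp$md3))

#' Solve the liquid density of a mixture at fixed T and P
#'
#' Finds the liquid-like root of \eqn{P(\rho) = P}: a Newton iteration started
#' at high packing fraction, with a bracketing grid-scan fallback that picks
#' the mechanically stable root of largest packing fraction (lowest Gibbs
#' energy among stable roots).
#'
#' @param mix a `saft_mixture`.
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param x mole fractions.
#' @param eta_guess optional starting packing fraction.
#' @return molar density, mol/m3, with attributes `eta` (packing fraction)
#'   and `Z` (compressibility factor).
#' @export
solveLiquidDensity <- function(mix, T, P, x, eta_guess = 0.45) {
  stopifnot(P > 0, all(x >= 0), abs(sum(x) - 1) < 1e-8)
  # memoize the root per exact state: downstream isoactivity residuals
  # compare phases evaluated at different times, and the polymer chemical
  # potential amplifies even sub-ULP density path dependence
  key <- paste0("rho|", sprintf("%.17g", T), "|", sprintf("%.17g", P), "|",
                paste(sprintf("%.17g", x), collapse = ","))
  hit <- mix$cache[[key]]
  if (!is.null(hit)) return(hit)
  tp <- .saft_tp(mix, T)
  f <- function(eta) .pressure(mix, tp, x, .eta_to_rho(tp, x, eta)) - P
  # secant iteration on the liquid branch (one pressure evaluation per step)
  e0 <- eta_guess; e1 <- eta_guess * (1 + 1e-4)
  f0 <- f(e0); f1 <- f(e1)
  eta <- e1; fe <- f1
  ok <- FALSE
  for (it in 1:60) {
    den <- f1 - f0
    if (!is.finite(den) || den == 0) break
    slope <- den / (e1 - e0)
    if (slope <= 0) break                    # left the liquid branch
    e2 <- e1 - f1 / slope
    if (!is.finite(e2) || e2 <= 1e-4 || e2 >= 0.7405) break
    if (abs(e2 - e1) > 0.1) e2 <- e1 - sign(f1 / slope) * 0.1
    f2 <- f(e2)
    if (!is.finite(f2)) break
    converged <- abs(e2 - e1) < 1e-12 * max(e1, e2) || abs(f2) < P * 1e-9
    e0 <- e1; f0 <- f1; e1 <- e2; f1 <- f2
    eta <- e1; fe <- f1
    if (converged && abs(fe) < P * 1e-6) { ok <- TRUE; break }
  }
  if (ok) {
    # deterministic Newton polish: collapses any warm-start-dependent eta
    # within ~1e-12 of the root onto (almost) the same float, because the
    # polymer chemical potential amplifies ULP-level density differences
    # into observable isoactivity residuals downstream
    for (it in 1:2) {
      h <- eta * 1e-7
      dfe <- (f(eta + h) - fe) / h
      if (!is.finite(dfe) || dfe <= 0) break
      eta <- eta - fe / dfe
      fe <- f(eta)
    }
  }
  if (!ok || abs(fe) > P * 1e-6) {
    # grid scan for sign changes, keep stable roots, take largest eta
    etas <- seq(1e-4, 0.72, length.out = 160)
    vals <- vapply(etas, f, 0)
    roots <- c()
    for (k in seq_len(length(etas) - 1)) {
      if (is.finite(vals[k]) && is.finite(vals[k + 1]) &&
          vals[k] < 0 && vals[k + 1] > 0) {   # increasing crossing = stable
        r <- stats::uniroot(f, c(etas[k], etas[k + 1]), tol = 1e-13)$root
        roots <- c(roots, r)
      }
    }
    if (!length(roots))
      stop("no liquid density root in bounds at T = ", T, " K, P = ", P, " Pa")
    eta <- max(roots)
    # Newton polish
    fe <- f(eta)
    for (it in 1:20) {
      if (abs(fe) < P * 1e-9) break
      h <- max(eta * 1e-7, 1e-10)
      dfe <- (f(eta + h) - fe) / h
      eta <- eta - fe / dfe
      fe <- f(eta)
    }
  }
  rho <- .eta_to_rho(tp, x, eta)
  out <- rho * 1e30 / .NA
  attr(out, "eta") <- eta
  # consistent compressibility factor from the pressure the root satisfies
  # (more accurate than differencing a_res at liquid-like Z ~ 1e-5)
  attr(out, "Z") <- P / (rho * 1e30 * .kB * T)
  mix$cache[[key]] <- out
  out
}

#' Resolve a mixture state at fixed temperature and pressure
#'
#' Solves the liquid density and packages temperature, pressure, composition
#' and density for the Helmholtz-energy routines.
#'
#' @inheritParams solveLiquidDensity
#' @return object of class `mixture_state` with fields `T`, `P`,
#'   `mole_fractions`, `molar_density` (mol/m3), `eta`, `Z`.
#' @export
mixtureState <- function(mix, T, P, x, eta_guess = 0.45) {
  if (abs(sum(x) - 1) > 1e-12) stop("mole fractions must sum to 1")
  if (any(x < 0)) stop("mole fractions must be >= 0")
  rho <- solveLiquidDensity(mix, T, P, x, eta_guess)
  structure(list(mix = mix, T = T, P = P, mole_fractions = x,
                 molar_density = as.numeric(rho),
                 eta = attr(rho, "eta"), Z = attr(rho, "Z")),
            class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("<mixture_state> T = %.2f K, P = %g Pa, rho = %.1f mol/m3, eta = %.4f\n",
              x$T, x$P, x$molar_density, x$eta))
  cat("  x =", paste(sprintf("%s %.4g", x$mix$names, x$mole_fractions),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Residual Helmholtz energy breakdown
#'
#' Evaluates the reduced residual Helmholtz energy per mole,
#' \eqn{a^{res} = a^{hc} + a^{disp} + a^{assoc}}, at a resolved state.
#'
#' @param state a `mixture_state` (see [mixtureState()]).
#' @return list with `a_hc`, `a_disp`, `a_assoc`, `a_res` (dimensionless).
#' @export
residualHelmholtz <- function(state) {
  stopifnot(inherits(state, "mixture_state"))
  tp <- .saft_tp(state$mix, state$T)
  rho <- state$molar_density * .NA * 1e-30
  out <- .a_res(state$mix, tp, state$mole_fractions, rho)
  out[c("a_hc", "a_disp", "a_assoc", "a_res")]
}

#' Fraction of unbonded association sites
#'
#' Solves the mass-action equations for the fractions of donor (A) and
#' acceptor (B) sites not engaged in a hydrogen bond, per component.
#'
#' @param state a `mixture_state`.
#' @return matrix with columns `XA`, `XB` and one row per component;
#'   components without sites report 1.
#' @export
siteFractions <- function(state) {
  stopifnot(inherits(state, "mixture_state"))
  tp <- .saft_tp(state$mix, state$T)
  if (!tp$assoc_any)
    stop("no component in the mixture carries association sites")
  rho <- state$molar_density * .NA * 1e-30
  res <- .a_res(state$mix, tp, state$mole_fractions, rho, want_sites = TRUE)
  cbind(XA = res$sites$XA, XB = res$sites$XB)
}

# ln fugacity coefficients at fixed T, P, x. Residual chemical potentials
# from the analytic composition gradient of a_res at constant number
# density (symmetric site schemes); the finite-difference path remains for
# asymmetric schemes and as the test oracle.
.lnphi <- function(mix, T, P, x, eta_guess = 0.45) {
  tp <- .saft_tp(mix, T)
  rho_m <- solveLiquidDensity(mix, T, P, x, eta_guess)
  eta <- attr(rho_m, "eta"); Z <- attr(rho_m, "Z")
  rho <- .eta_to_rho(tp, x, eta)
  if (tp$symmetric_sites) {
    core <- .a_core(mix, tp, x, rho, want_dx = TRUE)
    mu_res <- core$a_res + (Z - 1) + core$dadx - sum(x * core$dadx)
    return(list(lnphi = mu_res - log(Z), Z = Z, eta = eta,
                rho_molar = as.numeric(rho_m)))
  }
  a0 <- .a_res(mix, tp, x, rho)$a_res
  n <- mix$n
  dadx <- numeric(n)
  # fourth-order differences: the association term makes a_res extremely
  # stiff in the polymer mole fraction (653 sites), so second-order central
  # at h = 1e-6 is not converged
  h <- 1e-6
  av <- function(xx) .a_res(mix, tp, xx, rho)$a_res
  for (k in seq_len(n)) {
    xk <- x
    if (x[k] >= 2 * h) {
      xk[k] <- x[k] + 2 * h; f2p <- av(xk)
      xk[k] <- x[k] + h;     f1p <- av(xk)
      xk[k] <- x[k] - h;     f1m <- av(xk)
      xk[k] <- x[k] - 2 * h; f2m <- av(xk)
      dadx[k] <- (-f2p + 8 * f1p - 8 * f1m + f2m) / (12 * h)
    } else {
      xk[k] <- x[k] + h;     f1 <- av(xk)
      xk[k] <- x[k] + 2 * h; f2 <- av(xk)
      xk[k] <- x[k] + 3 * h; f3 <- av(xk)
      xk[k] <- x[k] + 4 * h; f4 <- av(xk)
      dadx[k] <- (-25 * a0 + 48 * f1 - 36 * f2 + 16 * f3 - 3 * f4) / (12 * h)
    }
  }
  mu_res <- a0 + (Z - 1) + dadx - sum(x * dadx)
  list(lnphi = mu_res - log(Z), Z = Z, eta = eta,
       rho_molar = as.numeric(rho_m))
}

#' Fugacity coefficients of a liquid mixture
#'
#' @inheritParams solveLiquidDensity
#' @return list with `lnphi` (named per component), `Z`, `eta`,
#'   `rho_molar` (mol/m3).
#' @export
fugacityCoefficients <- function(mix, T, P, x, eta_guess = 0.45) {
  out <- .lnphi(mix, T, P, x, eta_guess)
  names(out$lnphi) <- mix$names
  out
}

# Cached pure-component reference ln phi at (component, T, P).
.lnphi_pure <- function(mix, k, T, P) {
  key <- paste0("pure", k, "|", format(T, digits = 15), "|", format(P, digits = 12))
  hit <- mix$cache[[key]]
  if (!is.null(hit)) return(hit)
  sub <- saftMixture(mix$components[k])
  tp <- .saft_tp(sub, T)
  rho_m <- tryCatch(solveLiquidDensity(sub, T, P, 1),
                    error = function(e)
                      stop("pure-component density failed for '",
                           mix$names[k], "': ", conditionMessage(e)))
  eta <- attr(rho_m, "eta"); Z <- attr(rho_m, "Z")
  rho <- .eta_to_rho(tp, 1, eta)
  a0 <- .a_res(sub, tp, 1, rho)$a_res
  val <- a0 + (Z - 1) - log(Z)
  mix$cache[[key]] <- val
  val
}

#' Activity coefficients from PC-SAFT
#'
#' Mole-fraction based activity coefficients
#' \eqn{\gamma_i = \varphi_i(T,P,x) / \varphi_i^{0,L}(T,P)} with the pure
#' liquid at the same temperature and pressure as reference state (the
#' hypothetical pure liquid for the polymer), so \eqn{\gamma_i \to 1} as
#' \eqn{x_i \to 1}.
#'
#' @inheritParams solveLiquidDensity
#' @return named vector of activity coefficients. See
#'   [lnActivityCoefficients()] for the log-space form, which does not
#'   underflow for the polymer (whose activity coefficient can be below
#'   the double-precision range in solvent-rich mixtures).
#' @export
activityCoefficients <- function(mix, T, P, x, eta_guess = 0.45) {
  g <- exp(lnActivityCoefficients(mix, T, P, x, eta_guess))
  names(g) <- mix$names
  g
}

#' @rdname activityCoefficients
#' @return `lnActivityCoefficients`: named vector of \eqn{\ln\gamma_i}.
#' @export
lnActivityCoefficients <- function(mix, T, P, x, eta_guess = 0.45) {
  mixres <- .lnphi(mix, T, P, x, eta_guess)
  ref <- vapply(seq_len(mix$n), function(k) .lnphi_pure(mix, k, T, P), 0)
  lg <- mixres$lnphi - ref
  names(lg) <- mix$names
  lg
}

# ln activities (ln x_i + ln gamma_i) with safe handling of x_i = 0.
.ln_activity <- function(mix, T, P, x, eta_guess = 0.45) {
  lg <- lnActivityCoefficients(mix, T, P, x, eta_guess)
  ifelse(x > 0, log(x) + lg, -Inf)
}
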