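# Solid-liquid solubility, liquid-liquid equilibria (binodal, tie lines,
# spinodal), and phase-stability analysis for API/polymer/water systems.
#
# All equilibrium equations are solved in mole-fraction space (log variables
# where compositions get small: the polymer's 65 kg/mol molar mass pushes its
# mole fractions to O(1e-5)); results are reported in mass fractions.

# ---------------------------------------------------------------------------
# generic machinery on a ln-activity closure: lnact(x) -> per-component
# ln(x_i gamma_i). Lets the same solvers run on PC-SAFT and on closed-form
# toy models.

# damped Newton with finite-difference Jacobian
.newton <- function(fn, x0, tol = 1e-10, maxit = 60, fd_h = 1e-6) {
  x <- x0
  fx <- fn(x)
  n <- length(x)
  for (it in seq_len(maxit)) {
    if (all(is.finite(fx)) && max(abs(fx)) < tol)
      return(list(x = x, f = fx, iter = it, converged = TRUE))
    J <- matrix(0, length(fx), n)
    # forward differences while far out; central once close (truncation of
    # the forward Jacobian stalls the iteration near tight tolerances)
    central <- all(is.finite(fx)) && max(abs(fx)) < 1e4 * tol
    for (k in seq_len(n)) {
      xk <- x; xk[k] <- x[k] + fd_h
      if (central) {
        xm <- x; xm[k] <- x[k] - fd_h
        J[, k] <- (fn(xk) - fn(xm)) / (2 * fd_h)
      } else {
        J[, k] <- (fn(xk) - fx) / fd_h
      }
    }
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, f = fx, iter = it, converged = FALSE))
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn_new <- tryCatch(fn(xn), error = function(e) rep(NA_real_, length(fx)))
      if (all(is.finite(fn_new)) &&
          (max(abs(fn_new)) < max(abs(fx)) || lambda < 0.1)) break
      lambda <- lambda / 2
      if (lambda < 1e-4) return(list(x = x, f = fx, iter = it, converged = FALSE))
    }
    x <- x - lambda * step
    fx <- fn_new
  }
  list(x = x, f = fx, iter = maxit,
       converged = all(is.finite(fx)) && max(abs(fx)) < tol)
}

# ln-activity closure for a ternary system at fixed T, P, with liquid-density
# warm starts carried between calls
.lnact_factory <- function(system, T, P) {
  # reuse one mixture object (and its temperature/pure-reference caches)
  # across all solver calls on the same system
  mix <- if (!is.null(system$cache)) {
    if (is.null(system$cache$mix)) system$cache$mix <- saftMixture(system)
    system$cache$mix
  } else saftMixture(system)
  env <- new.env(parent = emptyenv())
  env$eta <- 0.45
  function(x) {
    x <- pmax(x, 0)
    x <- x / sum(x)
    res <- .lnphi(mix, T, P, x, eta_guess = env$eta)
    env$eta <- res$eta
    ref <- vapply(seq_len(mix$n), function(k) .lnphi_pure(mix, k, T, P), 0)
    ifelse(x > 0, log(x) + res$lnphi - ref, -Inf)
  }
}

# tangent-plane distance of a trial composition y against feed z:
# tpd(y) = sum y_i (ln a_i(y) - ln a_i(z)); negative => z unstable.
# Trial phases live on the support of the feed (a component absent from the
# feed cannot appear in an incipient phase), so -Inf activities cancel out.
.tpd <- function(lnact, y, d_feed) {
  la <- lnact(y)
  on <- y > 1e-150
  sum(y[on] * (la[on] - d_feed[on]))
}

# Michelsen-style successive substitution minimization of the tangent-plane
# distance from one seed; returns the locally minimal trial composition.
# early_exit stops as soon as instability is certain.
.tpd_minimize <- function(lnact, z, seed, maxit = 150, tol = 1e-9,
                          early_exit = FALSE) {
  # the seed's support defines the face searched: a zero seed component stays
  # zero, which keeps the successive substitution stable when one component's
  # activity coefficient varies over hundreds of log units (the polymer)
  supp <- z > 0 & seed > 0
  d_feed <- lnact(z)
  lg_feed <- d_feed
  lg_feed[supp] <- d_feed[supp] - log(z[supp])   # ln gamma at feed
  Y <- seed
  Y[!supp] <- 0
  Y <- Y / sum(Y)
  it <- 0
  for (it in seq_len(maxit)) {
    y <- Y / sum(Y)
    la <- lnact(y)
    lgy <- la
    on <- y > 1e-150
    lgy[on] <- la[on] - log(y[on])               # ln gamma at trial
    lnY_new <- rep(-745, length(z))
    lnY_new[supp] <- log(z[supp]) + lg_feed[supp] - lgy[supp]
    lnY_new <- pmin(pmax(lnY_new, -745), 50)
    Y_new <- exp(lnY_new)
    delta <- max(abs(Y_new - Y))
    Y <- Y_new
    if (early_exit && it >= 5 && it %% 5 == 0) {
      tpd_now <- .tpd(lnact, Y / sum(Y), d_feed)
      if (tpd_now < -1e-5) break
    }
    if (delta < tol) break
  }
  y <- Y / sum(Y)
  list(trial = y, tpd = .tpd(lnact, y, d_feed), iter = it)
}

# quasi-Newton minimization of Michelsen's modified tangent-plane function
# tm(Y) = 1 + sum Y_i (ln Y_i + ln gamma_i(y) - d_i - 1) in ln-Y variables.
# Finds the shallow minima that successive substitution escapes (the
# naproxen system's instability basin is O(1e-4) deep near its binodal).
.tpd_bfgs <- function(lnact, z, seed, maxit = 80) {
  supp <- z > 0 & seed > 0
  d_feed <- lnact(z)
  obj <- function(lnY) {
    Y <- exp(pmin(lnY, 50))
    yfull <- numeric(length(z)); yfull[supp] <- Y
    y <- yfull / sum(yfull)
    la <- lnact(y)
    lgy <- la[supp] - log(y[supp])
    1 + sum(Y * (lnY + lgy - d_feed[supp] - 1))
  }
  o <- tryCatch(stats::optim(log(seed[supp]), obj, method = "BFGS",
                             control = list(maxit = maxit, reltol = 1e-9)),
                error = function(e) NULL)
  if (is.null(o)) return(NULL)
  yfull <- numeric(length(z)); yfull[supp] <- exp(o$par)
  y <- yfull / sum(yfull)
  list(trial = y, tpd = .tpd(lnact, y, d_feed), tm = o$value)
}

# Rachford-Rice successive-substitution flash on K-values: the classical
# isothermal two-phase split. Robust (if slow) where the Newton formulations
# lose their footing in shallow basins; used as the workhorse for interior
# feeds whose phases all carry every component.
.rr_flash <- function(lnact, z, K0, maxit = 800, tol = 1e-9) {
  K <- pmin(pmax(K0, 1e-12), 1e12)
  beta <- 0.5
  for (it in seq_len(maxit)) {
    g <- function(b) sum(z * (K - 1) / (1 + b * (K - 1)))
    g0 <- g(1e-12); g1 <- g(1 - 1e-12)
    if (g0 < 0 || g1 > 0) {
      # feed outside the two-phase region for these K-values
      return(list(converged = FALSE, outside = TRUE, beta = if (g0 < 0) 0 else 1,
                  K = K, iter = it))
    }
    beta <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    x1 <- z / (1 + beta * (K - 1)); x1 <- pmax(x1 / sum(x1), 1e-250)
    x2 <- K * z / (1 + beta * (K - 1)); x2 <- pmax(x2 / sum(x2), 1e-250)
    la1 <- lnact(x1); la2 <- lnact(x2)
    lg1 <- la1 - log(x1); lg2 <- la2 - log(x2)
    lnK_new <- pmin(pmax(lg1 - lg2, -300), 300)
    err <- max(abs(lnK_new - log(K)))
    K <- exp(lnK_new)
    if (err < tol)
      return(list(converged = TRUE, outside = FALSE, beta = beta,
                  x1 = x1, x2 = x2, K = K, iter = it,
                  residual = max(abs(exp(la1) - exp(la2)))))
  }
  list(converged = FALSE, outside = FALSE, beta = beta, x1 = x1, x2 = x2,
       K = K, iter = maxit)
}

# ---------------------------------------------------------------------------
# solid-liquid equilibrium

# ln of the API activity at saturation (right-hand side of the SLE relation):
# ln(x gamma) = -dh/(RT) (1 - T/Tm) - dcp/R (ln(Tm/T) - Tm/T + 1)
# The heat-capacity term is dropped exactly when delta_cp is absent.
.ln_sat_activity <- function(component, T) {
  if (!is.finite(component$melting_T) || !is.finite(component$melting_enthalpy))
    stop("component '", component$name, "' has no melting properties")
  Tm <- component$melting_T
  out <- -component$melting_enthalpy / (.R * T) * (1 - T / Tm)
  if (is.finite(component$delta_cp))
    out <- out - component$delta_cp / .R * (log(Tm / T) - Tm / T + 1)
  out
}

#' Ideal mole-fraction solubility of a crystalline component
#'
#' Solves the solid-liquid equilibrium relation with the activity coefficient
#' set to 1. The heat-capacity term is included exactly when the component
#' carries a `delta_cp` value.
#'
#' @param component a [pureComponent()] with melting properties.
#' @param T temperature, K.
#' @return mole-fraction solubility (equals 1 at the melting point).
#' @export
idealSolubility <- function(component, T) {
  exp(.ln_sat_activity(component, T))
}

# path composition (mass fractions) of a fixed-DL hydration line at water w
.path_mass <- function(drug_load, w_water) {
  c((1 - w_water) * drug_load, (1 - w_water) * (1 - drug_load), w_water)
}

#' Solid-liquid solubility of the API in a polymer/water solvent
#'
#' Solves the crystalline-API solubility relation with PC-SAFT activity
#' coefficients at a fixed polymer:water solvent mass ratio: the API mass
#' fraction at which the liquid is exactly saturated.
#'
#' @param system a `ternary_system`.
#' @param T temperature, K.
#' @param P pressure, Pa (0.1 MPa default).
#' @param solvent_ratio polymer:water mass ratio of the API-free solvent;
#'   `Inf` means dry polymer, 0 means pure water.
#' @return object of class `solubility_point`: list with `w` (mass fractions,
#'   API/polymer/water), `x` (mole fractions), `gamma_api`, `residual`.
#' @export
sleSolubility <- function(system, T, P = 1e5, solvent_ratio = Inf) {
  api <- system$components[[1]]
  lnK <- .ln_sat_activity(api, T)
  q_p <- if (is.infinite(solvent_ratio)) 1 else solvent_ratio / (1 + solvent_ratio)
  lnact <- .lnact_factory(system, T, P)
  f <- function(w_api) {
    w <- c(w_api, (1 - w_api) * q_p, (1 - w_api) * (1 - q_p))
    x <- massToMole(w, system)
    lnact(x)[1] - lnK
  }
  # bracket: activity -> -Inf as w_api -> 0 and -> 0 >= lnK at w_api -> 1
  lo <- 1e-10
  if (f(lo) > 0) stop("API saturated at vanishing content; no solubility point")
  hi <- 1 - 1e-10
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  w <- c(root, (1 - root) * q_p, (1 - root) * (1 - q_p))
  x <- massToMole(w, system)
  gam <- exp(lnact(x)[1] - log(x[1]))
  structure(list(T = T, P = P, w = w, x = x, gamma_api = gam,
                 residual = lnact(x)[1] - lnK),
            class = "solubility_point")
}

#' @export
print.solubility_point <- function(x, ...) {
  cat(sprintf("<solubility_point> T = %.2f K: w = (%.4f, %.4f, %.4f), residual %.2e\n",
              x$T, x$w[1], x$w[2], x$w[3], x$residual))
  invisible(x)
}

#' Water content where a hydration path crosses the solubility line
#'
#' Along the straight hydration line of fixed drug load, finds the water mass
#' fraction at which the path composition is exactly saturated in API.
#'
#' @inheritParams sleSolubility
#' @param drug_load API mass fraction on the water-free basis.
#' @param w_max largest water content searched.
#' @return water mass fraction of the crossing, or 0 with attribute
#'   `supersaturated_dry = TRUE` when the dry ASD already exceeds the
#'   solubility limit, or `NA` when the path never saturates below `w_max`.
#' @export
sleCrossingWater <- function(system, T, P = 1e5, drug_load, w_max = 0.95) {
  api <- system$components[[1]]
  lnK <- .ln_sat_activity(api, T)
  lnact <- .lnact_factory(system, T, P)
  f <- function(ww) lnact(massToMole(.path_mass(drug_load, ww), system))[1] - lnK
  f0 <- f(0)
  if (f0 > 0) {
    out <- 0
    attr(out, "supersaturated_dry") <- TRUE
    return(out)
  }
  # API activity rises along the hydration path (water is the anti-solvent);
  # scan for a bracket, then refine
  grid <- seq(0.02, w_max, by = 0.02)
  prev_w <- 0; prev_f <- f0
  for (ww in grid) {
    fw <- f(ww)
    if (is.finite(fw) && fw > 0)
      return(stats::uniroot(f, c(prev_w, ww), f.lower = prev_f, f.upper = fw,
                            tol = 1e-10)$root)
    prev_w <- ww; prev_f <- fw
  }
  NA_real_
}

#' Solubility line of the ternary diagram
#'
#' @inheritParams sleSolubility
#' @param n number of points along the solvent-composition coordinate.
#' @return data frame (ordered from dry polymer toward water) with columns
#'   `w_api`, `w_polymer`, `w_water`.
#' @export
solubilityLocus <- function(system, T, P = 1e5, n = 40) {
  # parametrize by water fraction of the API-free solvent
  qw <- seq(0, 1, length.out = n)^1.5  # denser near the dry edge
  rows <- lapply(qw, function(q) {
    r <- if (q >= 1) 0 else (1 - q) / q
    sp <- tryCatch(sleSolubility(system, T, P, solvent_ratio = if (q == 0) Inf else r),
                   error = function(e) NULL)
    if (is.null(sp)) return(NULL)
    data.frame(w_api = sp$w[1], w_polymer = sp$w[2], w_water = sp$w[3])
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# liquid-liquid equilibrium

.mass_from_mole <- function(x, system) moleToMass(x, system)

# residual vector of the isoactivity conditions between two phases given in
# mole fractions
.isoact_residual <- function(lnact, x1, x2) {
  la1 <- lnact(x1)
  la2 <- lnact(x2)
  la1 - la2
}

#' Tangent-plane stability test of a liquid composition
#'
#' Minimizes the tangent-plane distance over trial compositions from several
#' seeds. A negative minimum marks the composition as unstable (inside the
#' binodal); the minimizing trial phase is returned as a flash seed.
#'
#' @inheritParams sleSolubility
#' @param w mass-fraction composition (API, polymer, water).
#' @param seeds optional list of mole-fraction trial seeds.
#' @return list with `stable` (logical), `tpd_min`, `trial` (mass fractions
#'   of the minimizing trial phase), `trial_x` (mole fractions).
#' @export
stabilityTest <- function(system, T, P = 1e5, w, seeds = NULL) {
  z <- massToMole(w, system)
  if (sum(z > 0) <= 1) {
    # a pure phase cannot split
    return(list(stable = TRUE, tpd_min = 0, trial = w / sum(w),
                trial_x = z))
  }
  lnact <- .lnact_factory(system, T, P)
  if (is.null(seeds)) {
    seeds <- list(c(0.98, 0, 0.02),        # API-rich, polymer-free face
                  c(0.98, 1e-8, 0.02),     # API-rich
                  c(0.02, 1e-8, 0.98),     # water-rich
                  c(1e-4, 0.02, 0.98),     # polymer-in-water
                  pmax(z * c(4, 0.25, 1), 1e-10),
                  pmax(z * c(0.25, 1, 4), 1e-10))
    # restrict trials to the feed's support and drop degenerate seeds
    seeds <- lapply(seeds, function(s) { s[z == 0] <- 0; s })
    seeds <- Filter(function(s) sum(s) > 0 && sum(s > 0) > 1, seeds)
    seeds <- lapply(seeds, function(s) s / sum(s))
  }
  best <- NULL
  for (s in seeds) {
    r <- tryCatch(.tpd_minimize(lnact, z, s, early_exit = TRUE),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$tpd < best$tpd)) best <- r
    if (!is.null(best) && best$tpd < -1e-5) break   # already decidedly unstable
  }
  if (is.null(best) || best$tpd > -1e-9) {
    # shallow basins escape successive substitution; quasi-Newton pass
    for (s in seeds[seq_len(min(3, length(seeds)))]) {
      r <- .tpd_bfgs(lnact, z, s)
      if (!is.null(r) && (is.null(best) || r$tpd < best$tpd)) best <- r
      if (best$tpd < -1e-6) break
    }
  }
  if (is.null(best)) stop("stability test failed from all seeds")
  list(stable = best$tpd > -1e-9, tpd_min = best$tpd,
       trial = moleToMass(best$trial, system), trial_x = best$trial)
}

# Two-phase split of a water-free API/polymer binary, solved on the dry face
# of the ternary. The API-rich phase holds a vanishing polymer mole fraction
# (far below floating-point relevance for these systems), so a joint Newton
# is badly conditioned; instead the API isoactivity is solved for the
# polymer-rich composition by bracketed root finding and the polymer
# isoactivity then gives the conjugate polymer content in log space.
.dry_binary_flash <- function(system, T, P = 1e5) {
  lnact <- .lnact_factory(system, T, P)
  la_at <- function(xp) lnact(c(1 - xp, xp, 0))
  ln_xp2 <- -Inf                     # start from the pure-API conjugate
  la2 <- function() {                # activities of the API-rich phase
    if (!is.finite(ln_xp2) || ln_xp2 < -700) {
      la <- la_at(1e-300)
      la[2] <- -Inf                  # treated via the closed-form step below
      la
    } else la_at(exp(ln_xp2))
  }
  # infinite-dilution ln gamma of the polymer in the API
  la_dil <- la_at(1e-12)
  lg_pol_inf <- la_dil[2] - log(1e-12)
  xp1 <- NA_real_
  for (pass in 1:3) {
    target <- la2()[1]
    f <- function(xp) la_at(xp)[1] - target
    # rightmost sign change = the polymer-rich binodal composition
    grid <- seq(0.95, 0.02, by = -0.03)
    vals <- vapply(grid, f, 0)
    k <- which(vals[-length(vals)] < 0 & vals[-1] > 0)
    if (!length(k)) return(NULL)     # miscible dry binary
    xp1 <- stats::uniroot(f, c(grid[k[1] + 1], grid[k[1]]), tol = 1e-12)$root
    ln_xp2_new <- la_at(xp1)[2] - lg_pol_inf
    if (is.finite(ln_xp2) && abs(ln_xp2_new - ln_xp2) < 1e-10) {
      ln_xp2 <- ln_xp2_new; break
    }
    ln_xp2 <- ln_xp2_new
  }
  xp2 <- exp(ln_xp2)                 # may underflow to 0; physically nil
  x1 <- c(1 - xp1, xp1, 0)
  x2 <- c(1 - xp2, xp2, 0)
  w1 <- moleToMass(x1, system); w2 <- moleToMass(x2, system)
  if (w2[2] > w1[2]) { tmp <- w1; w1 <- w2; w2 <- tmp
                       tmp <- x1; x1 <- x2; x2 <- tmp }
  resid <- abs(la_at(xp1)[1] - la2()[1])
  list(w1 = w1, w2 = w2, x1 = x1, x2 = x2, residual = resid,
       ln_xp_api_rich = ln_xp2)
}

# Newton solve of a two-phase isoactivity split in log-mole-fraction
# variables, with an optional extra constraint closing the system.
# vars: (ln x_api^L1, ln x_pol^L1, ln x_api^L2, ln x_pol^L2)
.tie_from_logvars <- function(v) {
  x1 <- c(exp(v[1]), exp(v[2]))
  x2 <- c(exp(v[3]), exp(v[4]))
  list(x1 = c(x1, 1 - sum(x1)), x2 = c(x2, 1 - sum(x2)))
}

#' Isothermal liquid-liquid flash
#'
#' Splits a feed inside the miscibility gap into two liquid phases satisfying
#' per-component isoactivity and overall mass balance. The solver works in
#' log-mole-fraction variables (Newton with damping); the feed-collinearity
#' condition closes the system, and phase fractions follow from the lever
#' rule.
#'
#' @inheritParams sleSolubility
#' @param feed mass-fraction feed composition (API, polymer, water).
#' @param initial_guess optional list with mole-fraction phase guesses
#'   `x1`, `x2`; defaults to a tangent-plane seed.
#' @return object of class `tie_line`: list with mass-fraction phases `w1`
#'   (polymer-rich), `w2` (API-rich), mole-fraction phases `x1`, `x2`, lever
#'   fractions `beta` (phase-2 mole fraction of the feed) and `beta_mass`,
#'   and the isoactivity `residual`. Returns an object with
#'   `outcome = "single phase"` when the feed is stable.
#' @export
lleFlash <- function(system, T, P = 1e5, feed, initial_guess = NULL) {
  z <- massToMole(feed, system)
  lnact <- .lnact_factory(system, T, P)
  if (feed[3] == 0) {
    # water-free feed: the split stays on the dry API/polymer face
    st <- stabilityTest(system, T, P, feed)
    if (st$stable)
      return(structure(list(outcome = "single phase", feed = feed),
                       class = "tie_line"))
    fl <- .dry_binary_flash(system, T, P)
    if (is.null(fl)) stop("LLE flash did not converge on the dry binary")
    k <- which.max(abs(fl$x2 - fl$x1))
    beta <- (z[k] - fl$x1[k]) / (fl$x2[k] - fl$x1[k])
    km <- which.max(abs(fl$w2 - fl$w1))
    beta_mass <- (feed[km] - fl$w1[km]) / (fl$w2[km] - fl$w1[km])
    return(structure(list(outcome = "two phases", T = T, P = P, feed = feed,
                          w1 = fl$w1, w2 = fl$w2, x1 = fl$x1, x2 = fl$x2,
                          beta = beta, beta_mass = beta_mass,
                          residual = fl$residual),
                     class = "tie_line"))
  }
  if (is.null(initial_guess)) {
    st <- stabilityTest(system, T, P, feed)
    if (st$stable)
      return(structure(list(outcome = "single phase", feed = feed),
                       class = "tie_line"))
    # trial phase on one side, mirrored feed perturbation on the other
    x2 <- st$trial_x
    x1 <- pmax(z - 0.5 * (x2 - z), 1e-300); x1 <- x1 / sum(x1)
    initial_guess <- list(x1 = x1, x2 = x2)
  }
  if (initial_guess$x2[2] < 1e-8) {
    # polymer-free conjugate regime: unknowns (ln x_api', ln x_pol',
    # ln x_water''); polymer content of the API-rich phase from the polymer
    # isoactivity in closed form
    fnp <- function(v) {
      x1 <- c(exp(v[1]), exp(v[2]))
      x1 <- c(x1, 1 - sum(x1))
      xw2 <- exp(v[3])
      if (x1[3] <= 0 || xw2 >= 1) return(rep(NA_real_, 3))
      x2 <- c(1 - xw2, 0, xw2)
      r <- .isoact_residual(lnact, x1, x2)[c(1, 3)]
      col <- (x2[1] - x1[1]) * (z[2] - x1[2]) -
             (x2[2] - x1[2]) * (z[1] - x1[1])
      c(r, col * 1e3)
    }
    v0 <- log(c(max(initial_guess$x1[1], 1e-12),
                max(initial_guess$x1[2], 1e-12),
                max(initial_guess$x2[3], 1e-3)))
    sol <- .newton(fnp, v0, tol = 1e-9, maxit = 150, fd_h = 1e-7)
    if (!sol$converged && max(abs(sol$f)) > 5e-8)
      stop("LLE flash did not converge (polymer-free conjugate)")
    x1 <- c(exp(sol$x[1]), exp(sol$x[2]))
    x1 <- c(x1, 1 - sum(x1))
    xw2 <- exp(sol$x[3])
    la1 <- lnact(x1)
    la_dil <- lnact(c((1 - xw2) * (1 - 1e-12), 1e-12, xw2 * (1 - 1e-12)))
    ln_xp2 <- la1[2] - (la_dil[2] - log(1e-12))
    x2 <- c(1 - xw2 - exp(ln_xp2), exp(ln_xp2), xw2)
    w1 <- moleToMass(x1, system); w2 <- moleToMass(x2, system)
    if (w2[2] > w1[2]) { tmp <- w1; w1 <- w2; w2 <- tmp
                         tmp <- x1; x1 <- x2; x2 <- tmp }
    k <- which.max(abs(x2 - x1))
    beta <- (z[k] - x1[k]) / (x2[k] - x1[k])
    wfeed <- feed / sum(feed)
    km <- which.max(abs(w2 - w1))
    beta_mass <- (wfeed[km] - w1[km]) / (w2[km] - w1[km])
    return(structure(list(outcome = "two phases", T = T, P = P, feed = feed,
                          w1 = w1, w2 = w2, x1 = x1, x2 = x2,
                          beta = beta, beta_mass = beta_mass,
                          residual = max(abs(sol$f[1:2]))),
                     class = "tie_line"))
  }
  v0 <- log(c(initial_guess$x1[1:2], initial_guess$x2[1:2]))
  v0 <- pmax(v0, -700)
  fn <- function(v) {
    ph <- .tie_from_logvars(v)
    if (ph$x1[3] <= 0 || ph$x2[3] <= 0) return(rep(NA_real_, 4))
    r <- .isoact_residual(lnact, ph$x1, ph$x2)
    # collinearity of feed with the phase segment (mole-fraction space)
    col <- (ph$x2[1] - ph$x1[1]) * (z[2] - ph$x1[2]) -
           (ph$x2[2] - ph$x1[2]) * (z[1] - ph$x1[1])
    c(r, col * 1e3)
  }
  sol <- .newton(fn, v0, tol = 1e-9)
  if (!sol$converged) {
    # retry with perturbed guesses
    for (fac in c(0.5, 2, 0.25)) {
      v0p <- v0 + log(fac) * c(1, 0, -1, 0)
      sol <- .newton(fn, v0p, tol = 1e-9)
      if (sol$converged) break
    }
  }
  if (!sol$converged) stop("LLE flash did not converge")
  ph <- .tie_from_logvars(sol$x)
  if (max(abs(ph$x1 - ph$x2)) < 1e-4) stop("LLE flash converged to the trivial root")
  # order phases: phase 1 = polymer-rich (higher polymer mass fraction)
  w1 <- moleToMass(ph$x1, system); w2 <- moleToMass(ph$x2, system)
  if (w2[2] > w1[2]) { tmp <- w1; w1 <- w2; w2 <- tmp
                       tmp <- ph$x1; ph$x1 <- ph$x2; ph$x2 <- tmp }
  # lever rule (mole basis along the API coordinate, the best-conditioned one)
  k <- which.max(abs(ph$x2 - ph$x1))
  beta <- (z[k] - ph$x1[k]) / (ph$x2[k] - ph$x1[k])
  wfeed <- feed / sum(feed)
  km <- which.max(abs(w2 - w1))
  beta_mass <- (wfeed[km] - w1[km]) / (w2[km] - w1[km])
  structure(list(outcome = "two phases", T = T, P = P, feed = feed,
                 w1 = w1, w2 = w2, x1 = ph$x1, x2 = ph$x2,
                 beta = beta, beta_mass = beta_mass,
                 residual = max(abs(sol$f[1:3]))),
            class = "tie_line")
}

#' @export
print.tie_line <- function(x, ...) {
  if (!is.null(x$outcome) && x$outcome == "single phase") {
    cat("<tie_line> single phase (feed stable)\n"); return(invisible(x))
  }
  cat(sprintf("<tie_line> polymer-rich (%.4f, %.4f, %.4f) | API-rich (%.4f, %.4f, %.4f)\n",
              x$w1[1], x$w1[2], x$w1[3], x$w2[1], x$w2[2], x$w2[3]))
  cat(sprintf("  beta_mass = %.4f, isoactivity residual = %.2e\n",
              x$beta_mass, x$residual))
  invisible(x)
}

#' Binodal crossing of a hydration path
#'
#' Finds the smallest water content at which the straight hydration path of a
#' given drug load reaches the liquid-liquid binodal: the path composition is
#' itself an equilibrium phase there, and the conjugate phase closes the tie
#' line. Solved as a Newton system in (water content, conjugate-phase
#' composition).
#'
#' @inheritParams sleSolubility
#' @param drug_load API mass fraction on the water-free basis.
#' @param w_start starting guess for the crossing water content (optional; a
#'   coarse stability scan locates the bracket when absent).
#' @param conjugate_guess optional mole-fraction guess for the conjugate phase.
#' @return list with `w_water` (crossing water content), `w_path` (full
#'   path-phase mass fractions), `w_conjugate` (conjugate-phase mass
#'   fractions), `x_path`, `x_conjugate`, `residual`; or an object with
#'   `outcome = "no crossing"` when the path stays stable up to `w_max`.
#' @param w_max largest water content scanned.
#' @export
binodalCrossing <- function(system, T, P = 1e5, drug_load,
                            w_start = NULL, conjugate_guess = NULL,
                            w_max = 0.6) {
  lnact <- .lnact_factory(system, T, P)
  Mv <- system$M
  # instability probe at one path point by successive substitution (fast;
  # finds the deep basins); returns the minimizing trial or NULL
  probe <- function(ww, extra_seed = NULL) {
    z <- massToMole(.path_mass(drug_load, ww), system)
    seeds <- list(c(0.93, 0, 0.07),              # polymer-free API-rich
                  c(0.25, 0.001, 0.749),         # hydrated API-rich w/ polymer
                  pmax(z * c(5, 0.2, 1), 1e-12)) # scaled feed
    if (!is.null(extra_seed)) seeds <- c(list(extra_seed), seeds)
    seeds <- lapply(seeds, function(s) { s[z == 0] <- 0; s / sum(s) })
    for (s in seeds) {
      r <- tryCatch(.tpd_minimize(lnact, z, s, maxit = 40, tol = 1e-8,
                                  early_exit = TRUE),
                    error = function(e) NULL)
      if (!is.null(r) && r$tpd < -1e-8) return(r$trial)
    }
    NULL
  }
  # candidate solve, polymer-free-conjugate regime:
  # unknowns (w_water, ln x_water''); conjugate polymer from the polymer
  # isoactivity in closed form (must self-consistently stay negligible)
  solve_polyfree <- function(ww0, xw0) {
    fn2 <- function(v) {
      ww <- v[1]; xw2 <- exp(v[2])
      if (ww < 0 || ww > 0.95 || xw2 >= 1) return(rep(NA_real_, 2))
      x1 <- massToMole(.path_mass(drug_load, ww), Mv)
      x2 <- c(1 - xw2, 0, xw2)
      .isoact_residual(lnact, x1, x2)[c(1, 3)]
    }
    sol <- .newton(fn2, c(max(ww0, 1e-4), log(max(xw0, 1e-3))), tol = 1e-9,
                   maxit = 80, fd_h = 1e-7)
    if (!sol$converged && max(abs(sol$f)) > 5e-8) return(NULL)
    ww <- sol$x[1]
    if (ww <= 0 || ww > w_max + 0.05) return(NULL)
    xw2 <- exp(sol$x[2])
    x1 <- massToMole(.path_mass(drug_load, ww), Mv)
    la1 <- lnact(x1)
    la_dil <- lnact(c((1 - xw2) * (1 - 1e-12), 1e-12, xw2 * (1 - 1e-12)))
    ln_xp2 <- la1[2] - (la_dil[2] - log(1e-12))
    if (ln_xp2 > log(1e-6)) return(NULL)   # conjugate carries real polymer
    x2 <- c(1 - xw2 - exp(ln_xp2), exp(ln_xp2), xw2)
    if (max(abs(x2 - x1)) < 1e-4) return(NULL)
    list(ww = ww, x2 = x2, resid = max(abs(sol$f)))
  }
  # candidate solve, full ternary regime:
  # unknowns (w_water, ln x_api'', ln x_pol'')
  solve_full <- function(ww0, x2g) {
    fn <- function(v) {
      ww <- v[1]
      if (ww < 0 || ww > 0.95) return(rep(NA_real_, 3))
      x1 <- massToMole(.path_mass(drug_load, ww), Mv)
      x2 <- c(exp(v[2]), exp(v[3]))
      x2 <- c(x2, 1 - sum(x2))
      if (x2[3] <= 0) return(rep(NA_real_, 3))
      .isoact_residual(lnact, x1, x2)
    }
    x2g <- pmax(x2g, 1e-300)
    sol <- .newton(fn, c(max(ww0, 1e-4), log(x2g[1]), log(x2g[2])),
                   tol = 1e-9, maxit = 80, fd_h = 1e-7)
    if (!sol$converged && max(abs(sol$f)) > 5e-8) return(NULL)
    ww <- sol$x[1]
    if (ww <= 0 || ww > w_max + 0.05) return(NULL)
    x2 <- c(exp(sol$x[2]), exp(sol$x[3]))
    x2 <- c(x2, 1 - sum(x2))
    x1 <- massToMole(.path_mass(drug_load, ww), Mv)
    if (any(x2 < 0) || any(x2 > 1) || max(abs(x2 - x1)) < 1e-4) return(NULL)
    list(ww = ww, x2 = x2, resid = max(abs(sol$f)))
  }
  if (is.null(w_start) || is.null(conjugate_guess)) {
    # coarse successive-substitution scan for the first detectable
    # instability (the binodal crossing of the deepest sheet)
    found <- FALSE
    for (ww in seq(0.01, w_max, by = 0.05)) {
      tr <- probe(ww)
      if (!is.null(tr)) { w_start <- ww; conjugate_guess <- tr; found <- TRUE
                          break }
    }
    if (!found) {
      # shallow basins everywhere: quasi-Newton tangent-plane scan
      for (ww in seq(0.05, w_max, by = 0.08)) {
        z <- massToMole(.path_mass(drug_load, ww), system)
        r <- .tpd_bfgs(lnact, z, c(0.25, 0.001, 0.749), maxit = 60)
        if (!is.null(r) && r$tpd < -1e-8) {
          w_start <- ww; conjugate_guess <- r$trial; found <- TRUE; break
        }
      }
    }
    if (!found)
      return(list(outcome = "no crossing", drug_load = drug_load))
  }
  # assemble candidate crossings from both regimes; the smallest valid
  # water content is the first binodal contact
  candidates <- list()
  if (conjugate_guess[2] < 1e-8) {
    c1 <- solve_polyfree(w_start, conjugate_guess[3])
    if (!is.null(c1)) candidates <- c(candidates, list(c1))
  } else {
    c1 <- solve_full(w_start, conjugate_guess[1:2])
    if (!is.null(c1)) candidates <- c(candidates, list(c1))
  }
  # second regime: a shallower binodal sheet (API-rich-with-polymer
  # conjugate) can lie below the deep instability the scan detected. The
  # quasi-Newton tangent-plane minimization sees it; bisect its stability
  # boundary, where the minimizing trial converges to the conjugate phase,
  # then polish with the Newton from that tight seed. Systems whose dry
  # API/polymer binary already demixes expose only the polymer-free sheet
  # (water shifts that same gap), so the search is skipped there.
  dry_demixes <- local({
    z_dry <- massToMole(c(0.5, 0.5, 0), system)
    r <- tryCatch(.tpd_minimize(lnact, z_dry, c(0.98, 0, 0.02), maxit = 40,
                                tol = 1e-8, early_exit = TRUE),
                  error = function(e) NULL)
    !is.null(r) && r$tpd < -1e-8
  })
  if (conjugate_guess[2] < 1e-8 && !dry_demixes) {
    bprobe <- function(ww) {
      z <- massToMole(.path_mass(drug_load, ww), system)
      for (s in list(c(0.25, 0.001, 0.749),    # API-rich conjugate
                     c(0.03, 0.001, 0.969))) { # water/polymer-rich conjugate
        r <- .tpd_bfgs(lnact, z, s, maxit = 35)
        if (!is.null(r) && r$tpd < -1e-8 && r$trial[2] > 1e-8 &&
            max(abs(r$trial - z)) > 0.02) return(r$trial)
      }
      NULL
    }
    hi <- w_start; tr_hi <- bprobe(hi)
    if (!is.null(tr_hi)) {
      lo <- max(hi - 0.1, 0.005)
      ext <- 0
      while (lo > 0.005 && ext < 4) {
        tr <- bprobe(lo)
        if (is.null(tr)) break
        hi <- lo; tr_hi <- tr; lo <- max(lo - 0.1, 0.005); ext <- ext + 1
      }
      while (hi - lo > 0.005) {
        mid <- (lo + hi) / 2
        tr <- bprobe(mid)
        if (is.null(tr)) lo <- mid else { hi <- mid; tr_hi <- tr }
      }
      c2 <- solve_full(hi, tr_hi[1:2])
      if (!is.null(c2)) {
        candidates <- c(candidates, list(c2))
      } else {
        # fall back to the bisection estimate: at the boundary the trial is
        # the conjugate phase to tangent-construction accuracy
        x2b <- tr_hi
        la_p <- lnact(massToMole(.path_mass(drug_load, hi), Mv))
        la_c <- lnact(x2b)
        candidates <- c(candidates,
                        list(list(ww = hi, x2 = x2b,
                                  resid = max(abs(la_p - la_c)))))
      }
    }
  }
  if (!length(candidates))
    stop("binodal-crossing solve did not converge (DL = ", drug_load, ")")
  best <- candidates[[which.min(vapply(candidates, `[[`, 0, "ww"))]]
  ww <- best$ww
  w1 <- .path_mass(drug_load, ww)
  list(outcome = "crossing", drug_load = drug_load, w_water = ww,
       w_path = w1, w_conjugate = moleToMass(best$x2, system),
       x_path = massToMole(w1, system), x_conjugate = best$x2,
       residual = best$resid)
}

#' Trace the liquid-liquid binodal with tie lines
#'
#' Tie-line continuation: starting from a robust first split (the dry
#' API/polymer binary when it demixes, otherwise the first unstable point
#' found on a composition scan), the polymer-rich phase water content is
#' stepped and the remaining three unknowns re-solved, halving the step on
#' convergence failure, until the branches merge (plait point), an axis is
#' reached, or `w_water_max`.
#'
#' @inheritParams sleSolubility
#' @param w_water_max largest polymer-rich-branch water content traced.
#' @param step initial continuation step in the water coordinate (mass
#'   fraction; 0.5 wt\% default).
#' @param min_step smallest step before the trace stops (plait-point
#'   approach).
#' @return object of class `binodal_trace`: list with `tie_lines` (data
#'   frame: one row per tie line, mass fractions of both phases), and
#'   `binodal` (data frame: ordered locus points, both branches).
#' @export
traceBinodal <- function(system, T, P = 1e5, w_water_max = 0.5,
                         step = 0.005, min_step = 1e-4) {
  lnact <- .lnact_factory(system, T, P)
  # --- first tie line: try the dry API/polymer binary
  first <- NULL
  fl <- tryCatch(lleFlash(system, T, P, feed = c(0.5, 0.5, 0)),
                 error = function(e) NULL)
  if (!is.null(fl) && fl$outcome == "two phases") first <- fl
  if (is.null(first)) {
    # scan the interior for an unstable feed: quick successive-substitution
    # probes only, and a bounded number of flash attempts. Systems whose
    # instability basins are too shallow for this probe (no dry demixing,
    # gap confined to a narrow hydrated band) report "no LLPS" here; their
    # per-path crossings remain available from binodalCrossing().
    attempts <- 0
    for (ww in seq(0.1, w_water_max, by = 0.05)) {
      for (wa in c(0.3, 0.2, 0.4, 0.1)) {
        w <- c(wa * (1 - ww), (1 - wa) * (1 - ww), ww)
        z <- massToMole(w, system)
        seeds <- list(c(0.93, 0, 0.07), pmax(z * c(5, 0.2, 1), 1e-12))
        seeds <- lapply(seeds, function(s) { s[z == 0] <- 0; s / sum(s) })
        unstable <- FALSE
        for (s in seeds) {
          r <- tryCatch(.tpd_minimize(lnact, z, s, maxit = 40, tol = 1e-8,
                                      early_exit = TRUE),
                        error = function(e) NULL)
          if (!is.null(r) && r$tpd < -1e-8) { unstable <- TRUE; break }
        }
        if (unstable) {
          attempts <- attempts + 1
          fl <- tryCatch(lleFlash(system, T, P, feed = w),
                         error = function(e) NULL)
          if (!is.null(fl) && fl$outcome == "two phases") { first <- fl; break }
          if (attempts >= 2) break
        }
      }
      if (!is.null(first) || attempts >= 2) break
    }
  }
  if (is.null(first))
    return(structure(list(outcome = "no LLPS", tie_lines = NULL, binodal = NULL),
                     class = "binodal_trace"))
  # continuation in the water mass fraction of the polymer-rich phase;
  # unknowns: (ln w_api^L1 , ln x_api^L2, ln x_pol^L2)
  tie_rows <- list()
  push_tie <- function(w1, w2, x1, x2) {
    tie_rows[[length(tie_rows) + 1]] <<- data.frame(
      w_api_1 = w1[1], w_polymer_1 = w1[2], w_water_1 = w1[3],
      w_api_2 = w2[1], w_polymer_2 = w2[2], w_water_2 = w2[3])
  }
  solve_at <- function(ww1, w1_prev, x2_prev) {
    fn <- function(v) {
      wa1 <- exp(v[1])
      if (wa1 + ww1 >= 1) return(rep(NA_real_, 3))
      w1 <- c(wa1, 1 - wa1 - ww1, ww1)
      x1 <- massToMole(w1, system)
      x2 <- c(exp(v[2]), exp(v[3]))
      x2 <- c(x2, 1 - sum(x2))
      if (x2[3] <= 0 || x2[3] > 1) return(rep(NA_real_, 3))
      .isoact_residual(lnact, x1, x2)
    }
    v0 <- c(log(max(w1_prev[1], 1e-12)),
            log(max(x2_prev[1], 1e-300)), log(max(x2_prev[2], 1e-300)))
    sol <- .newton(fn, v0, tol = 1e-9, fd_h = 1e-7)
    if (!sol$converged) return(NULL)
    wa1 <- exp(sol$x[1])
    w1 <- c(wa1, 1 - wa1 - ww1, ww1)
    x2 <- c(exp(sol$x[2]), exp(sol$x[3]))
    x2 <- c(x2, 1 - sum(x2))
    w2 <- moleToMass(x2, system)
    if (max(abs(w2 - w1)) < 1e-4) return(NULL)  # branches merged
    list(w1 = w1, w2 = w2, x2 = x2)
  }
  w1 <- first$w1; x2 <- first$x2
  # nudge a water-free conjugate guess into the interior so the first
  # continuation step starts feasible
  if (x2[3] <= 0) {
    x2 <- c(x2[1] - 1e-4, x2[2], 0)
    x2[3] <- 1 - x2[1] - x2[2]
  }
  push_tie(first$w1, first$w2, first$x1, first$x2)
  ww1 <- w1[3]
  h <- step
  while (ww1 < w_water_max && h >= min_step) {
    res <- solve_at(min(ww1 + h, w_water_max), w1, x2)
    if (is.null(res)) { h <- h / 2; next }
    ww1 <- min(ww1 + h, w_water_max)
    w1 <- res$w1; x2 <- res$x2
    push_tie(res$w1, res$w2, NULL, NULL)
    if (h < step) h <- min(step, h * 2)
  }
  ties <- do.call(rbind, tie_rows)
  binodal <- rbind(
    data.frame(branch = "polymer-rich", w_api = ties$w_api_1,
               w_polymer = ties$w_polymer_1, w_water = ties$w_water_1),
    data.frame(branch = "API-rich", w_api = rev(ties$w_api_2),
               w_polymer = rev(ties$w_polymer_2), w_water = rev(ties$w_water_2)))
  structure(list(outcome = "LLPS", tie_lines = ties, binodal = binodal,
                 T = T, P = P),
            class = "binodal_trace")
}

#' @export
print.binodal_trace <- function(x, ...) {
  if (x$outcome == "no LLPS") { cat("<binodal_trace> no LLPS region found\n")
    return(invisible(x)) }
  cat("<binodal_trace>", nrow(x$tie_lines), "tie lines, polymer-rich branch water",
      sprintf("%.3f-%.3f\n", min(x$tie_lines$w_water_1), max(x$tie_lines$w_water_1)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# spinodal

# determinant of the Hessian of the molar Gibbs energy of mixing with respect
# to the two independent mole fractions (API, polymer), by differencing the
# chemical-potential differences (exact gradient components of g_mix)
.spinodal_det <- function(lnact, x, h = 1e-5) {
  grad <- function(x12) {
    x3 <- 1 - sum(x12)
    la <- lnact(c(x12, x3))
    c(la[1] - la[3], la[2] - la[3])
  }
  x12 <- x[1:2]
  h1 <- min(h, x12[1] / 2, (1 - sum(x12)) / 2)
  h2 <- min(h, x12[2] / 2, (1 - sum(x12)) / 2)
  g1p <- grad(x12 + c(h1, 0)); g1m <- grad(x12 - c(h1, 0))
  g2p <- grad(x12 + c(0, h2)); g2m <- grad(x12 - c(0, h2))
  H11 <- (g1p[1] - g1m[1]) / (2 * h1)
  H12 <- (g2p[1] - g2m[1]) / (2 * h2)
  H21 <- (g1p[2] - g1m[2]) / (2 * h1)
  H22 <- (g2p[2] - g2m[2]) / (2 * h2)
  Hs <- (H12 + H21) / 2   # symmetrize FD noise
  H11 * H22 - Hs^2
}

#' Spinodal locus of the ternary system
#'
#' Locates, along hydration rays of fixed drug load, the compositions where
#' the determinant of the Gibbs-mixing-energy Hessian (mole-fraction
#' curvature) changes sign: the boundary of local instability.
#'
#' @inheritParams sleSolubility
#' @param drug_loads water-free API mass fractions of the rays scanned.
#' @param w_max largest water content scanned along each ray.
#' @return data frame with columns `drug_load`, `w_api`, `w_polymer`,
#'   `w_water` (one row per sign change found; rays without a sign change
#'   contribute nothing).
#' @export
spinodalLocus <- function(system, T, P = 1e5,
                          drug_loads = seq(0.05, 0.6, by = 0.05),
                          w_max = 0.7) {
  lnact <- .lnact_factory(system, T, P)
  rows <- list()
  for (dl in drug_loads) {
    f <- function(ww) .spinodal_det(lnact, massToMole(.path_mass(dl, ww), system))
    ws <- seq(0.005, w_max, by = 0.025)
    vals <- vapply(ws, function(ww) tryCatch(f(ww), error = function(e) NA_real_), 0)
    for (k in seq_len(length(ws) - 1)) {
      if (!is.na(vals[k]) && !is.na(vals[k + 1]) &&
          sign(vals[k]) != sign(vals[k + 1])) {
        r <- stats::uniroot(f, c(ws[k], ws[k + 1]), tol = 1e-8)$root
        w <- .path_mass(dl, r)
        rows[[length(rows) + 1]] <- data.frame(
          drug_load = dl, w_api = w[1], w_polymer = w[2], w_water = w[3])
      }
    }
  }
  if (!length(rows)) return(data.frame(drug_load = numeric(), w_api = numeric(),
                                       w_polymer = numeric(), w_water = numeric()))
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# full diagram assembly and export

#' Compute a full ternary phase diagram
#'
#' Assembles, at fixed temperature and pressure: the API solubility line, the
#' liquid-liquid binodal with tie lines, the spinodal, and the escape-glass-
#' transition (eGT) locus. Solubility and binodal are computed independently;
#' neither masks the other.
#'
#' @inheritParams sleSolubility
#' @param T_medium dissolution-medium temperature for the eGT line, K
#'   (defaults to `T`).
#' @param loci character vector choosing which loci to compute, any of
#'   `"solubility"`, `"binodal"`, `"spinodal"`, `"egt"`.
#' @param n_solubility points along the solubility line.
#' @param spinodal_drug_loads rays for [spinodalLocus()].
#' @return object of class `ternary_diagram` with the computed loci.
#' @export
ternaryDiagram <- function(system, T, P = 1e5, T_medium = T,
                           loci = c("solubility", "binodal", "spinodal", "egt"),
                           n_solubility = 25,
                           spinodal_drug_loads = seq(0.05, 0.6, by = 0.05)) {
  out <- list(system = system, T = T, P = P, T_medium = T_medium)
  has_melt <- is.finite(system$components[[1]]$melting_T)
  if ("solubility" %in% loci && has_melt)
    out$solubility <- solubilityLocus(system, T, P, n = n_solubility)
  if ("binodal" %in% loci) {
    tr <- traceBinodal(system, T, P)
    out$binodal <- tr$binodal
    out$tie_lines <- tr$tie_lines
  }
  if ("spinodal" %in% loci)
    out$spinodal <- spinodalLocus(system, T, P, drug_loads = spinodal_drug_loads)
  if ("egt" %in% loci)
    out$egt <- egtLocus(T_medium, system)
  structure(out, class = "ternary_diagram")
}

#' @export
print.ternary_diagram <- function(x, ...) {
  cat(sprintf("<ternary_diagram> %s at %.2f K, %.3g Pa\n",
              paste(x$system$names, collapse = "/"), x$T, x$P))
  for (nm in c("solubility", "binodal", "spinodal", "egt"))
    if (!is.null(x[[nm]])) cat("  ", nm, ": ", nrow(x[[nm]]), " points\n", sep = "")
  invisible(x)
}

#' Export a ternary diagram to CSV
#'
#' One row per locus point with columns `locus_type`, `w_api`, `w_polymer`,
#' `w_water`, `Tg_celsius` (blank except on the eGT locus), `tie_id` (blank
#' except on binodal points that terminate a tie line).
#'
#' @param diagram a `ternary_diagram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportDiagramCSV <- function(diagram, path) {
  rows <- list()
  add <- function(type, df, Tg = NA_real_, tie = NA_integer_) {
    if (is.null(df) || !nrow(df)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      locus_type = type, w_api = df$w_api, w_polymer = df$w_polymer,
      w_water = df$w_water,
      Tg_celsius = if (length(Tg) == nrow(df)) Tg else rep(Tg, nrow(df)),
      tie_id = if (length(tie) == nrow(df)) tie else rep(tie, nrow(df)))
  }
  add("solubility", diagram$solubility)
  if (!is.null(diagram$tie_lines)) {
    tl <- diagram$tie_lines
    n <- nrow(tl)
    add("binodal", data.frame(w_api = tl$w_api_1, w_polymer = tl$w_polymer_1,
                              w_water = tl$w_water_1), tie = seq_len(n))
    add("binodal", data.frame(w_api = tl$w_api_2, w_polymer = tl$w_polymer_2,
                              w_water = tl$w_water_2), tie = seq_len(n))
  }
  add("spinodal", diagram$spinodal)
  if (!is.null(diagram$egt))
    add("egt", diagram$egt, Tg = diagram$egt$Tg - 273.15)
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a ternary diagram to JSON
#'
#' @param diagram a `ternary_diagram`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
exportDiagramJSON <- function(diagram, path) {
  payload <- list(
    components = diagram$system$names,
    T = diagram$T, P = diagram$P, T_medium = diagram$T_medium,
    solubility = diagram$solubility, binodal = diagram$binodal,
    tie_lines = diagram$tie_lines, spinodal = diagram$spinodal,
    egt = diagram$egt)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
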