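# equation of state core: combining rules, Helmholtz breakdown, association,
# density solving, fugacity and activity coefficients

test_that("cross parameters follow the combining rules", {
  ps <- fixture_params()
  nap <- ps$components$naproxen
  pvp <- ps$components$PVPVA64
  wat <- ps$components$water
  cp <- crossParameters(nap, pvp, 310.15)
  expect_equal(cp$sigma_ij, (2.939 + 2.947) / 2)
  expect_equal(cp$sigma_ij, 2.943)
  # arithmetic-mean association energy with one non-associating partner
  cp2 <- crossParameters(wat, pvp, 310.15)
  expect_equal(cp2$eps_ij, (2425.7 + 0) / 2)
  # diagonal equals pure-component values
  cpd <- crossParameters(wat, wat, 310.15)
  expect_equal(cpd$sigma_ij, sigmaWater(310.15))
  expect_equal(cpd$u_ij, wat$dispersion_energy)
  expect_equal(cpd$eps_ij, wat$assoc_energy)
  expect_equal(cpd$kappa_ij, wat$assoc_volume)
  # dispersion energy scales with (1 - kij)
  k <- kijAt(getInteraction(ps, "naproxen", "water"), 310.15)
  cp3 <- crossParameters(nap, wat, 310.15, kij = k)
  expect_equal(cp3$u_ij,
               sqrt(nap$dispersion_energy * wat$dispersion_energy) * (1 - k))
})

test_that("Helmholtz breakdown is additive and association vanishes without sites", {
  ps <- fixture_params()
  mixv <- saftMixture(ps$components["venetoclax"])
  st <- mixtureState(mixv, 310.15, 1e5, 1)
  br <- residualHelmholtz(st)
  expect_equal(br$a_assoc, 0)
  expect_equal(br$a_res, br$a_hc + br$a_disp + br$a_assoc, tolerance = 1e-14)
  # associating mixture: still exactly additive
  sys <- naproxen_system()
  mix <- saftMixture(sys)
  st2 <- mixtureState(mix, 310.15, 1e5, massToMole(c(0.2, 0.5, 0.3), sys))
  br2 <- residualHelmholtz(st2)
  expect_lt(abs(br2$a_res - (br2$a_hc + br2$a_disp + br2$a_assoc)), 1e-12)
  expect_lt(br2$a_assoc, 0)   # hydrogen bonding lowers the energy
})

test_that("binary mixture approaches the pure-component limit", {
  ps <- fixture_params()
  mix2 <- saftMixture(ps$components[c("naproxen", "water")], ps)
  mix1 <- saftMixture(ps$components["naproxen"])
  st2 <- mixtureState(mix2, 310.15, 1e5, c(1 - 1e-10, 1e-10))
  st1 <- mixtureState(mix1, 310.15, 1e5, 1)
  expect_equal(residualHelmholtz(st2)$a_res, residualHelmholtz(st1)$a_res,
               tolerance = 1e-6)
})

test_that("site fractions solve the mass-action equations", {
  ps <- fixture_params()
  mixw <- saftMixture(ps$components["water"])
  st <- mixtureState(mixw, 310.15, 1e5, 1)
  X <- siteFractions(st)
  expect_true(all(X > 0 & X <= 1))
  # symmetric 1/1 scheme: donor and acceptor fractions coincide
  expect_equal(unname(X[, "XA"]), unname(X[, "XB"]), tolerance = 1e-12)
  # oracle: plain successive substitution from scratch
  tp <- asdphase:::.saft_tp(mixw, 310.15)
  rho <- st$molar_density * 6.02214076e23 * 1e-30
  om <- 1 - st$eta
  d <- tp$d
  g <- 1 / om + (d / 2) * 3 * (st$eta / d) / om^2 +
    (d / 2)^2 * 2 * (st$eta / d)^2 / om^3  # pure fluid: zeta2 = eta/d
  delta <- tp$assoc_pref[1, 1] * g
  Xss <- 0.5
  for (i in 1:4000) Xss <- 0.5 * Xss + 0.5 / (1 + rho * Xss * delta)
  expect_equal(unname(X[1, "XA"]), unname(Xss), tolerance = 1e-8)
  # vanishing association strength: all sites unbonded
  weak <- pureComponent("weakwater", 18.015, 0.0669, 3.0, 353.95,
                        assoc_energy = 1e-6, assoc_volume = 1e-12,
                        assoc_sites = c(1, 1), density = 1000, glass_T = 138)
  mixweak <- saftMixture(list(weak))
  stw <- mixtureState(mixweak, 310.15, 1e5, 1)
  expect_equal(unname(siteFractions(stw)[1, ]), c(1, 1), tolerance = 1e-6)
})

test_that("liquid density root is physical, consistent and monotone in P", {
  ps <- fixture_params()
  mixw <- saftMixture(ps$components["water"])
  rho <- solveLiquidDensity(mixw, 310.15, 1e5, 1)
  # physical check: water near 1000 kg/m3
  expect_equal(as.numeric(rho) * 0.018015, 1000, tolerance = 0.05)
  # pressure consistency at the root
  tp <- asdphase:::.saft_tp(mixw, 310.15)
  rhoN <- as.numeric(rho) * 6.02214076e23 * 1e-30
  P_back <- asdphase:::.pressure(mixw, tp, 1, rhoN)
  expect_equal(P_back, 1e5, tolerance = 1e-6)
  # grid-scan oracle: the root matches a dense scan of P(eta)
  etas <- seq(0.3, 0.6, length.out = 400)
  Ps <- vapply(etas, function(e)
    asdphase:::.pressure(mixw, tp, 1, asdphase:::.eta_to_rho(tp, 1, e)), 0)
  k <- which(Ps[-length(Ps)] < 1e5 & Ps[-1] >= 1e5)
  expect_equal(attr(rho, "eta"), etas[k[length(k)]], tolerance = 2e-3)
  # monotone: density never decreases with pressure
  rhos <- vapply(c(0.05, 0.1, 0.15, 0.2) * 1e6, function(P)
    as.numeric(solveLiquidDensity(mixw, 310.15, P, 1)), 0)
  expect_true(all(diff(rhos) >= 0))
})

test_that("activity coefficients have exact pure limits and obey Gibbs-Duhem", {
  ps <- fixture_params()
  for (nm in c("naproxen", "water", "PVPVA64")) {
    mix2 <- saftMixture(ps$components[c(nm, "water")][!duplicated(c(nm, "water"))],
                        ps)
    if (mix2$n == 1) next
    g <- activityCoefficients(mix2, 310.15, 1e5, c(1, 0))
    expect_equal(unname(g[1]), 1, tolerance = 1e-8, label = nm)
  }
  # Gibbs-Duhem on a composition grid (4th-order outer differences; the
  # residual is an independent consistency oracle for the chemical potentials)
  mix <- saftMixture(ps$components[c("naproxen", "water")], ps)
  gd <- function(x1, h = 2e-5) {
    lg <- function(x) lnActivityCoefficients(mix, 310.15, 1e5, c(x, 1 - x))
    d <- (-lg(x1 + 2 * h) + 8 * lg(x1 + h) - 8 * lg(x1 - h) + lg(x1 - 2 * h)) /
      (12 * h)
    abs(x1 * d[1] + (1 - x1) * d[2])
  }
  for (x1 in c(0.1, 0.35, 0.7)) expect_lt(gd(x1), 1e-4)
  # polymer-bearing binary at realistic (tiny) polymer mole fractions
  mixp <- saftMixture(ps$components[c("PVPVA64", "water")], ps)
  gdp <- function(x1, h) {
    lg <- function(x) lnActivityCoefficients(mixp, 310.15, 1e5, c(x, 1 - x))
    d <- (-lg(x1 + 2 * h) + 8 * lg(x1 + h) - 8 * lg(x1 - h) + lg(x1 - 2 * h)) /
      (12 * h)
    abs(x1 * d[1] + (1 - x1) * d[2])
  }
  expect_lt(gdp(1e-3, 2e-5), 1e-4)
})

test_that("indistinguishable species have unit activity coefficients", {
  # two components with identical parameters and kij = 0 cannot be told
  # apart: the mixture is thermodynamically ideal
  a <- pureComponent("ida", 100, 0.03, 3.2, 250, density = 1200, glass_T = 300)
  b <- pureComponent("idb", 100, 0.03, 3.2, 250, density = 1200, glass_T = 300)
  psid <- parameterSet(list(a, b), list(binaryInteraction(c("ida", "idb"), 0, 0)))
  mix <- saftMixture(psid$components, psid)
  for (x1 in c(0.2, 0.5, 0.8)) {
    g <- activityCoefficients(mix, 310.15, 1e5, c(x1, 1 - x1))
    expect_equal(unname(g), c(1, 1), tolerance = 1e-6)
  }
})

test_that("water's temperature-dependent diameter propagates to the mixture", {
  ps <- fixture_params()
  mix <- saftMixture(ps$components[c("naproxen", "water")], ps)
  tp1 <- asdphase:::.saft_tp(mix, 310.15)
  tp2 <- asdphase:::.saft_tp(mix, 323.15)
  expect_equal(unname(tp1$sig[2]), sigmaWater(310.15))
  expect_equal(unname(tp2$sig[2]), sigmaWater(323.15))
  # cross diameter moves with it; the naproxen diameter does not
  expect_equal(unname(tp1$sig_ij[1, 2]), (2.939 + sigmaWater(310.15)) / 2)
  expect_identical(tp1$sig[1], tp2$sig[1])
})

test_that("analytic chemical-potential derivatives agree with FD of a_res", {
  ps <- fixture_params()
  sysn <- naproxen_system()
  mix <- saftMixture(sysn)
  tp <- asdphase:::.saft_tp(mix, 310.15)
  x <- massToMole(c(0.2, 0.5, 0.3), sysn)
  rho <- 0.004
  core <- asdphase:::.a_core(mix, tp, x, rho)
  # fourth-order central differences as the independent oracle
  h <- 1e-6
  av <- function(xx) asdphase:::.a_res(mix, tp, xx, rho)$a_res
  for (k in 1:3) {
    xp <- x
    xp[k] <- x[k] + 2 * h; f2p <- av(xp)
    xp[k] <- x[k] + h;     f1p <- av(xp)
    xp[k] <- x[k] - h;     f1m <- av(xp)
    xp[k] <- x[k] - 2 * h; f2m <- av(xp)
    fd <- (-f2p + 8 * f1p - 8 * f1m + f2m) / (12 * h)
    expect_equal(unname(core$dadx[k]), fd, tolerance = 1e-5)
  }
  hr <- rho * 1e-6
  Zfd <- 1 + rho * (av2 <- (asdphase:::.a_res(mix, tp, x, rho + hr)$a_res -
                              asdphase:::.a_res(mix, tp, x, rho - hr)$a_res) /
                      (2 * hr))
  expect_equal(core$Z, Zfd, tolerance = 1e-6)
})
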