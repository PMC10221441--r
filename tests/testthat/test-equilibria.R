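# solubility, LLE, stability and spinodal: closed-form and brute-force
# oracles on toy models, plus cheap PC-SAFT checks (the expensive full-table
# comparisons live in test-acceptance.R)

test_that("ideal solubility matches the closed form and the melting identity", {
  ps <- fixture_params()
  ven <- ps$components$venetoclax
  nap <- ps$components$naproxen
  R <- 8.31446261815324
  # venetoclax: no heat-capacity term (printed as absent)
  x_ven <- exp(-(59900 / (R * 310.15)) * (1 - 310.15 / 418.15))
  expect_equal(idealSolubility(ven, 310.15), x_ven, tolerance = 1e-12)
  expect_equal(idealSolubility(ven, 310.15), 2.48e-3, tolerance = 1e-2)
  # naproxen: full expression including the delta-cp group
  T <- 310.15; Tm <- 429.47
  x_nap <- exp(-(31500 / (R * T)) * (1 - T / Tm) -
                 (87 / R) * (log(Tm / T) - Tm / T + 1))
  expect_equal(idealSolubility(nap, 310.15), x_nap, tolerance = 1e-12)
  # melting point: solubility is exactly 1
  expect_equal(idealSolubility(nap, Tm), 1)
  expect_equal(idealSolubility(ven, 418.15), 1)
})

test_that("mole/mass conversion round-trips at machine precision", {
  sysn <- naproxen_system()
  W <- simplex_points(25)
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    expect_equal(unname(moleToMass(massToMole(w, sysn), sysn)), unname(w),
                 tolerance = 1e-12)
    x <- massToMole(w, sysn)
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
  # matrix form agrees with row-wise form
  expect_equal(massToMole(W, sysn),
               t(apply(W, 1, function(w) massToMole(w, sysn$M))),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("toy-model binodal and spinodal match their closed forms", {
  A <- 2.6
  toy <- toyActivityModel(matrix(c(0, A, A, 0), 2))
  # spinodal: roots of 1/x1 + 1/x2 = 2A
  sp <- toySpinodal(A)
  for (x1 in sp) {
    h <- 1e-5
    g <- function(x) {
      la <- toy$lnact(c(x, 1 - x)); x * la[1] + (1 - x) * la[2]
    }
    d2 <- (g(x1 + h) - 2 * g(x1) + g(x1 - h)) / h^2
    expect_lt(abs(d2), 1e-4)
  }
  # binodal: isoactivity between x and 1-x
  bn <- toyBinodal(A)
  la1 <- toy$lnact(c(bn[1], 1 - bn[1]))
  la2 <- toy$lnact(c(bn[2], 1 - bn[2]))
  expect_equal(la1[1], la2[1], tolerance = 1e-10)
  expect_equal(la1[2], la2[2], tolerance = 1e-10)
  # spinodal strictly inside the binodal
  expect_true(bn[1] < sp[1] && sp[2] < bn[2])
  # subcritical model: no two-phase region
  expect_length(toyBinodal(1.5), 0)
  expect_length(toySpinodal(1.9), 0)
})

test_that("tangent-plane grid oracle reproduces the toy two-phase region", {
  A <- 2.6
  toy <- toyActivityModel(matrix(c(0, A, A, 0), 2))
  om <- oracleTangentPlaneGrid(toy$lnact, n = 2, grid_n = 400)
  bn <- toyBinodal(A)
  unstable <- om$x1[!om$stable]
  # symmetric about the midpoint
  expect_equal(min(unstable) + max(unstable), 1, tolerance = 0.01)
  # grid two-phase region matches the closed-form binodal to grid resolution
  expect_lt(abs(min(unstable) - bn[1]), 0.005)
  expect_lt(abs(max(unstable) - bn[2]), 0.005)
})

test_that("the generic tie-line machinery solves the symmetric toy split", {
  A <- 2.6
  toy <- toyActivityModel(matrix(c(0, A, A, 0), 2))
  fn <- function(v) {
    x1 <- exp(v[1]); x2 <- exp(v[2])
    toy$lnact(c(x1, 1 - x1)) - toy$lnact(c(x2, 1 - x2))
  }
  sol <- asdphase:::.newton(fn, log(c(0.05, 0.95)), tol = 1e-12)
  expect_true(sol$converged)
  got <- sort(exp(sol$x))
  expect_equal(got, toyBinodal(A), tolerance = 1e-8)
  # symmetric split: x1(L1) = x2(L2)
  expect_equal(got[1], 1 - got[2], tolerance = 1e-8)
})

test_that("stability test recognizes pure phases and miscibility-gap interiors", {
  sysv <- venetoclax_system()
  expect_true(stabilityTest(sysv, T37, P0, c(0, 0, 1))$stable)
  expect_true(stabilityTest(sysv, T37, P0, c(0, 1, 0))$stable)
  # deep inside the dry miscibility gap
  st <- stabilityTest(sysv, T37, P0, c(0.5, 0.5, 0))
  expect_false(st$stable)
  expect_lt(st$tpd_min, -0.01)
  # the returned trial is a valid composition on the feed's support
  expect_equal(sum(st$trial_x), 1, tolerance = 1e-8)
  expect_equal(st$trial_x[3], 0)
})

test_that("dry venetoclax split is a genuine tie line and matches the grid oracle", {
  sysv <- venetoclax_system()
  fl <- memo("dryflash", lleFlash(sysv, T37, P0, feed = c(0.5, 0.5, 0)))
  expect_s3_class(fl, "tie_line")
  expect_identical(fl$outcome, "two phases")
  # isoactivity for the two participating components (polymer content of the
  # API-rich phase is below floating-point resolution; its residual is the
  # closed-form identity)
  lnact <- asdphase:::.lnact_factory(sysv, T37, P0)
  r <- abs(exp(lnact(fl$x1)[1:2]) - exp(lnact(fl$x2)[1:2]))
  expect_lt(max(r[is.finite(r)]), 1e-8)
  # phases distinct and feed between them
  expect_gt(max(abs(fl$w1 - fl$w2)), 1e-4)
  expect_gte(fl$beta_mass, 0); expect_lte(fl$beta_mass, 1)
  # grid oracle on the dry binary face: the polymer-rich boundary agrees
  grid_x <- seq(1e-4, 0.9999, length.out = 600)
  la <- t(vapply(grid_x, function(xp) lnact(c(1 - xp, xp, 0))[1:2], numeric(2)))
  tpd_min <- vapply(seq_along(grid_x), function(k) {
    vals <- (1 - grid_x) * (la[, 1] - la[k, 1]) + grid_x * (la[, 2] - la[k, 2])
    min(vals)
  }, 0)
  unstable <- grid_x[tpd_min < -1e-9]
  # boundary in API mass fraction: oracle vs flash within 1 wt%
  xp_boundary <- min(unstable)   # smallest unstable polymer mole fraction is
                                 # on the API-rich side; polymer-rich side:
  xp_rich <- max(unstable)
  w_api_oracle <- moleToMass(c(1 - xp_rich, xp_rich, 0), sysv)[1]
  expect_lt(abs(w_api_oracle - fl$w1[1]), 0.01)
})

test_that("tie lines satisfy lever-rule collinearity", {
  sysv <- venetoclax_system()
  fl <- memo("dryflash", lleFlash(sysv, T37, P0, feed = c(0.5, 0.5, 0)))
  z <- c(0.5, 0.5, 0)
  recon <- (1 - fl$beta_mass) * fl$w1 + fl$beta_mass * fl$w2
  expect_equal(unname(recon), z, tolerance = 1e-8)
})

test_that("spinodal determinant vanishes on the locus and the binary slice
          matches a one-dimensional oracle", {
  # toy ternary with one demixing pair: the machinery sees a closed form
  A <- 2.8
  toy <- toyActivityModel(matrix(c(0, A, 0, A, 0, 0, 0, 0, 0), 3))
  det_at <- function(x) asdphase:::.spinodal_det(toy$lnact, x)
  sp <- toySpinodal(A)
  # on the binary edge (x3 -> 0) the ternary determinant condition reduces
  # to the 1-D curvature condition solved by bisection
  f1d <- function(x1) {
    h <- 1e-5
    g <- function(x) {
      la <- toy$lnact(c(x, 1 - x - 1e-9, 1e-9))
      x * la[1] + (1 - x - 1e-9) * la[2] + 1e-9 * la[3]
    }
    (g(x1 + h) - 2 * g(x1) + g(x1 - h)) / h^2
  }
  r1d <- stats::uniroot(f1d, c(0.05, 0.45), tol = 1e-10)$root
  expect_equal(r1d, sp[1], tolerance = 1e-4)
  # ternary determinant changes sign across the spinodal near the edge
  eps <- 1e-6
  inside <- c(0.5, 0.5 - eps, eps)
  outside <- c(sp[1] / 2, 1 - sp[1] / 2 - eps, eps)
  expect_lt(det_at(inside), 0)
  expect_gt(det_at(outside), 0)
})

test_that("tie-line continuation traces an ordered, consistent binodal", {
  sysv <- venetoclax_system()
  tr <- memo("trace_ven", traceBinodal(sysv, T37, P0, w_water_max = 0.25))
  expect_identical(tr$outcome, "LLPS")
  ties <- tr$tie_lines
  expect_gt(nrow(ties), 20)
  # polymer-rich branch marches monotonically in water
  expect_true(all(diff(ties$w_water_1) > 0))
  # the first tie line is the dry binary split
  fl <- memo("dryflash", lleFlash(sysv, T37, P0, feed = c(0.5, 0.5, 0)))
  expect_equal(unname(ties$w_api_1[1]), unname(fl$w1[1]), tolerance = 1e-6)
  expect_equal(ties$w_water_1[1], 0)
  # tie lines never cross: the conjugate branch marches the same direction
  expect_true(all(diff(ties$w_water_2) >= -1e-9))
  # both endpoints of a mid-trace tie line pass the stability test and its
  # midpoint does not (interior of the miscibility gap)
  k <- floor(nrow(ties) / 2)
  w1 <- c(ties$w_api_1[k], ties$w_polymer_1[k], ties$w_water_1[k])
  w2 <- c(ties$w_api_2[k], ties$w_polymer_2[k], ties$w_water_2[k])
  expect_false(stabilityTest(sysv, T37, P0, (w1 + w2) / 2)$stable)
  # the polymer-rich branch passes through the path-crossing solutions
  bc25 <- ven_crossing(0.025)
  j <- which.min(abs(ties$w_water_1 - bc25$w_water))
  expect_lt(abs(ties$w_api_1[j] - bc25$w_path[1]), 0.005)
})

test_that("the naproxen ternary tie line reproduces the published 10 wt%-DL row", {
  sysn <- naproxen_system()
  bc <- memo("napx10", binodalCrossing(sysn, T37, P0, 0.10))
  expect_identical(bc$outcome, "crossing")
  # path-side (polymer-rich) crossing at 31.0 wt% water
  expect_lt(abs(bc$w_water - 0.310), 0.01)
  # conjugate API-rich phase: (35.2, 53.8, 11.0) wt%
  expect_lt(max(abs(bc$w_conjugate - c(0.352, 0.538, 0.110))), 0.01)
  # a converged tie line: isoactivity in activity units
  lnact <- asdphase:::.lnact_factory(sysn, T37, P0)
  a1 <- exp(lnact(bc$x_path)); a2 <- exp(lnact(bc$x_conjugate))
  expect_lt(max(abs(a1 - a2)), 1e-8)
})
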