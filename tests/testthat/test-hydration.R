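# hydration paths, crossing logic, LoR classification, lever rule, dose

test_that("hydration paths preserve the API:polymer ratio", {
  p <- buildPath(0.10)
  expect_equal(p$composition(0), c(0.10, 0.90, 0))
  expect_equal(p$composition(0.50), c(0.05, 0.45, 0.50))
  p3 <- buildPath(0.30)
  for (ww in seq(0, 0.95, by = 0.05)) {
    w <- p3$composition(ww)
    expect_equal(w[1] / (w[1] + w[2]), 0.30, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-14)
  }
  expect_error(buildPath(0), "between 0 and 1")
  expect_error(buildPath(1), "between 0 and 1")
})

# synthetic crossing frames exercise every branch of the classifier without
# any thermodynamics
fake_crossings <- function(egt, sol = NULL, bin = NULL) {
  rows <- data.frame(locus = "egt", w_water = egt, w_api = NA, w_polymer = NA,
                     Tg_C = NA, note = "")
  if (!is.null(sol))
    rows <- rbind(rows, data.frame(locus = "solubility", w_water = sol,
                                   w_api = NA, w_polymer = NA, Tg_C = NA,
                                   note = ""))
  if (!is.null(bin))
    rows <- rbind(rows, data.frame(locus = "binodal", w_water = bin,
                                   w_api = NA, w_polymer = NA, Tg_C = NA,
                                   note = ""))
  rows[order(rows$w_water), ]
}

test_that("classification follows the crossing order and propensity", {
  # fast crystallizer, solubility before eGT: interfacial crystallization
  c1 <- classifyLor(fake_crossings(egt = 0.073, sol = 0.061, bin = 0.22), "fast")
  expect_identical(c1$lor_type, "Type I")
  expect_identical(c1$release_expectation, "congruent loss (API+polymer)")
  # same order but slow crystallizer: crystallization cannot passivate
  c2 <- classifyLor(fake_crossings(egt = 0.073, sol = 0.061, bin = 0.22), "slow")
  expect_identical(c2$lor_type, "none")
  # binodal before eGT: amorphous-amorphous passivation
  c3 <- classifyLor(fake_crossings(egt = 0.11, bin = 0.06), "slow")
  expect_identical(c3$lor_type, "Type II")
  expect_identical(c3$release_expectation, "incongruent (polymer-only) release")
  # both precede eGT for a fast crystallizer: both mechanisms contribute
  c4 <- classifyLor(fake_crossings(egt = 0.11, sol = 0.0, bin = 0.06), "fast")
  expect_identical(c4$lor_type, "mixed")
  # all transformations beyond the gel layer: clean release
  c5 <- classifyLor(fake_crossings(egt = 0.093, sol = 0.163, bin = 0.31), "fast")
  expect_identical(c5$lor_type, "none")
  expect_identical(c5$release_expectation, "congruent release")
  # near-coincident crossing sits at the gel-layer boundary
  c6 <- classifyLor(fake_crossings(egt = 0.0730, sol = 0.0734), "fast")
  expect_true(c6$boundary)
  # classification is invariant to locus computation order
  shuffled <- fake_crossings(egt = 0.073, sol = 0.061, bin = 0.22)
  shuffled <- shuffled[c(3, 1, 2), ]
  expect_identical(classifyLor(shuffled, "fast")$lor_type, "Type I")
})

test_that("lever fractions recover endpoints, midpoints and mass balance", {
  tie <- structure(list(outcome = "two phases",
                        w1 = c(0.05, 0.90, 0.05),
                        w2 = c(0.85, 0.05, 0.10)),
                   class = "tie_line")
  expect_equal(unname(leverFractions(tie$w1, tie)), c(1, 0))
  expect_equal(unname(leverFractions(tie$w2, tie)), c(0, 1))
  mid <- (tie$w1 + tie$w2) / 2
  expect_equal(unname(leverFractions(mid, tie)), c(0.5, 0.5))
  fr <- leverFractions(0.25 * tie$w2 + 0.75 * tie$w1, tie)
  expect_equal(unname(fr), c(0.75, 0.25), tolerance = 1e-12)
  # off-tie-line feeds are rejected
  expect_error(leverFractions(c(0.3, 0.3, 0.4), tie), "not collinear")
})

test_that("dose strength is the solubility-volume-supersaturation product", {
  # printed worked example: 10-fold supersaturation of the base aqueous
  # solubility in a 900 mL vessel
  expect_identical(doseStrength(0.0429, 0.900, 10), 386)
  expect_identical(doseStrength(1, 1, 1), 1000)
  # linear in each argument
  expect_equal(doseStrength(2 * 0.0429, 0.900, 10), 2 * 386, tolerance = 1)
  expect_equal(doseStrength(0.0429, 1.800, 10), 2 * 386, tolerance = 1)
  expect_equal(doseStrength(0.0429, 0.900, 20), 2 * 386, tolerance = 1)
})

test_that("solubility and eGT crossings order correctly for naproxen", {
  sysn <- naproxen_system()
  cr20 <- memo("crossings_nap20",
               findCrossings(sysn, T37, P0, 0.20, loci = c("egt", "solubility")))
  expect_identical(cr20$locus, c("solubility", "egt"))
  expect_lt(abs(cr20$w_water[cr20$locus == "solubility"] - 0.061), 0.01)
  expect_lt(abs(cr20$w_water[cr20$locus == "egt"] - 0.073), 0.005)
  # compositions lie on the path
  for (i in seq_len(nrow(cr20))) {
    w <- c(cr20$w_api[i], cr20$w_polymer[i], cr20$w_water[i])
    expect_equal(w[1] / (w[1] + w[2]), 0.20, tolerance = 1e-8)
  }
  # 30 wt% DL: dry-state supersaturation flag
  cr30 <- memo("crossings_nap30",
               findCrossings(sysn, T37, P0, 0.30, loci = c("egt", "solubility")))
  srow <- cr30[cr30$locus == "solubility", ]
  expect_match(srow$note, "supersaturated in the dry state")
  expect_equal(srow$w_water, 0)
})

test_that("solubility crossings move to lower water content as DL rises", {
  sysn <- naproxen_system()
  w10 <- memo("slecross10", sleCrossingWater(sysn, T37, P0, 0.10))
  cr20 <- memo("crossings_nap20",
               findCrossings(sysn, T37, P0, 0.20, loci = c("egt", "solubility")))
  w20 <- cr20$w_water[cr20$locus == "solubility"]
  expect_gt(as.numeric(w10), w20)   # 16.3 -> 6.1 -> supersaturated-dry
})

test_that("the venetoclax hydration report mirrors the published table layout", {
  sysv <- venetoclax_system()
  rep <- memo("report_ven",
              hydrationReport(sysv, T37, P0, c(0.005, 0.025),
                              crystallization_propensity = "slow"))
  tb <- rep$table
  # every drug load carries a dry row and a supersaturation note
  for (dl in c(0.5, 2.5)) {
    rows <- tb[tb$drug_load == dl, ]
    expect_true("ASD (dry)" %in% rows$row)
    expect_true(any(grepl("supersaturated", rows$note)))
  }
  # dry Tg values, half-up rounded to one decimal as reported
  expect_equal(tb$Tg_C[tb$drug_load == 0.5 & tb$row == "ASD (dry)"], 111.0)
  expect_equal(tb$Tg_C[tb$drug_load == 2.5 & tb$row == "ASD (dry)"], 111.2)
  # 2.5 wt% DL: LLPS precedes the escape glass transition
  expect_match(tb$note[tb$drug_load == 2.5 & tb$row == "eGT"], "LLPS")
  expect_equal(tb$Tg_C[tb$drug_load == 2.5 &
                         tb$row == "API-rich phase at binodal line"], 118.3,
               tolerance = 3 / 118.3)
  # classifications: congruent release at 0.5 wt%, Type II at 2.5 wt%
  expect_identical(rep$classification[["0.005"]]$lor_type, "none")
  expect_identical(rep$classification[["0.025"]]$lor_type, "Type II")
  # CSV/JSON export round
  csv <- tempfile(fileext = ".csv"); jsn <- tempfile(fileext = ".json")
  on.exit(unlink(c(csv, jsn)))
  exportReportCSV(rep, csv)
  exportReportJSON(rep, jsn)
  got <- utils::read.csv(csv)
  expect_identical(nrow(got), nrow(tb))
  payload <- jsonlite::fromJSON(jsn)
  expect_identical(payload$classification[["0.025"]]$lor_type, "Type II")
})
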