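test_that("observed exchange rate follows the two-state model", {
  # no ligand term: rate reduces to the dissociation rate
  kin0 <- bindingKinetics(kOn = 1e6, kOff = 0.3, ligandConc = 0)
  expect_equal(observedExchangeRate(kin0, kex = 1), 0.3)

  # hand arithmetic: 0.3 * 1 / (1e6 * 2e-5 + 1) = 0.3 / 21
  kin <- bindingKinetics(kOn = 1e6, kOff = 0.3, ligandConc = 2e-5)
  expect_equal(observedExchangeRate(kin, kex = 1), 0.3 / 21,
               tolerance = 1e-12)
  expect_equal(observedExchangeRate(kin, kex = 1), 1.4286e-2,
               tolerance = 1e-4)

  expect_error(
    observedExchangeRate(bindingKinetics(kOn = 1e6, ligandConc = 1e-5),
                         kex = 1), "kOff")
  expect_error(observedExchangeRate(kin, kex = -1), "kex")
})

test_that("observed rate is bounded by kOff and decreases with ligand", {
  set.seed(11)
  for (i in 1:200) {
    kOff <- 10^runif(1, -3, 1)
    kex <- 10^runif(1, -2, 1)
    L <- 10^runif(1, -7, -2)
    kin <- bindingKinetics(kOn = 1e6, kOff = kOff, ligandConc = L)
    k1 <- observedExchangeRate(kin, kex)
    expect_gt(k1, 0)
    expect_lte(k1, kOff)
    kin2 <- bindingKinetics(kOn = 1e6, kOff = kOff, ligandConc = L * 2)
    expect_lt(observedExchangeRate(kin2, kex), k1)
  }
})

test_that("limiting rate reproduces hand arithmetic and edge cases", {
  expect_equal(limitingRate(KD = 0, kex = 1, ligandConc = 1e-5), 0)
  # radicicol: 1.9e-8 * 1 / 2e-5
  expect_equal(limitingRate(KD = 1.9e-8, kex = 1, ligandConc = 2e-5),
               9.5e-4)
  # fragment 2: 5.7e-4 * 1 / 5e-3
  expect_equal(limitingRate(KD = 5.7e-4, kex = 1, ligandConc = 5e-3),
               0.114)
  expect_error(limitingRate(KD = 1e-8, kex = 1, ligandConc = 0),
               "ligandConc")
})

test_that("observed rate converges to the limiting form in excess ligand", {
  set.seed(7)
  for (i in 1:200) {
    kex <- 10^runif(1, -2, 1)
    kOn <- 10^runif(1, 5, 7)
    L <- 100 * kex / kOn * 10^runif(1, 0, 2)   # kOn*L >= 100*kex
    KD <- 10^runif(1, -9, -4)
    kin <- bindingKinetics(kOn = kOn, KD = KD, ligandConc = L)
    full <- observedExchangeRate(kin, kex)
    lim <- limitingRate(KD, kex, L)
    expect_lt(abs(full - lim) / lim, 0.01)
  }
})

test_that("fractional occupancy matches the quadratic-root oracle", {
  expect_equal(fractionalOccupancy(1e-6, 1e-6, 0), 0)
  expect_equal(fractionalOccupancy(0, 1e-6, 2e-6), 1)     # stoichiometric
  occ <- fractionalOccupancy(1.9e-8, 3.3e-6, 2e-5)
  expect_equal(occ, 0.9989, tolerance = 1e-4)
  expect_equal(occ, bisectOccupancy(1.9e-8, 3.3e-6, 2e-5),
               tolerance = 1e-9)

  set.seed(42)
  for (i in 1:1000) {
    KD <- 10^runif(1, -9, -2)
    P <- 10^runif(1, -7, -4)
    L <- 10^runif(1, -8, -2)
    expect_equal(fractionalOccupancy(KD, P, L), bisectOccupancy(KD, P, L),
                 tolerance = 1e-9)
  }
})

test_that("occupancy is monotone in ligand concentration and within [0,1]", {
  L <- 10^seq(-9, -2, length.out = 50)
  occ <- fractionalOccupancy(5e-7, 3.3e-6, L)
  expect_true(all(diff(occ) >= 0))
  expect_true(all(occ >= 0 & occ <= 1))
})

test_that("mix arithmetic reproduces the exchange-reaction dilution", {
  d <- mixDesign(volume = c(1, 27, 2), soluteConc = c(100, 0, 0),
                 d2oFraction = c(0, 0.999, 0),
                 solute = c("protein", "", ""))
  m <- mixConcentrations(d)
  expect_equal(unname(m$concentrations["protein"]), 10 / 3,
               tolerance = 1e-12)
  expect_equal(m$d2oFraction, 27 * 0.999 / 30, tolerance = 1e-12)
  # two-significant-figure report: 3.3 uM protein, 90% D2O
  expect_equal(m$summary$value[m$summary$quantity == "protein"], 3.3)
  expect_equal(m$summary$value[m$summary$quantity == "D2O fraction"], 0.9)

  single <- mixConcentrations(mixDesign(10, 7, 0.5, "x"))
  expect_equal(unname(single$concentrations["x"]), 7)
  expect_equal(single$d2oFraction, 0.5)

  half <- mixConcentrations(mixDesign(c(10, 10), c(10, 0), 0,
                                      c("x", "x")))
  expect_equal(unname(half$concentrations["x"]), 5)

  expect_error(mixConcentrations(mixDesign(c(0, 0))), "volume")
})

test_that("mixing conserves solute mass under arbitrary partition", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    vol <- runif(n, 0.5, 20)
    conc <- runif(n, 0, 100)
    m <- mixConcentrations(mixDesign(vol, conc, 0, "s"))
    expect_equal(unname(m$concentrations["s"]) * sum(vol),
                 sum(vol * conc), tolerance = 1e-9)
    # splitting one component in two leaves the result unchanged
    vol2 <- c(vol[-1], vol[1] / 2, vol[1] / 2)
    conc2 <- c(conc[-1], conc[1], conc[1])
    m2 <- mixConcentrations(mixDesign(vol2, conc2, 0, "s"))
    expect_equal(unname(m2$concentrations["s"]),
                 unname(m$concentrations["s"]), tolerance = 1e-12)
  }
})

test_that("ligand:protein ratios render at two significant figures", {
  r <- ligandProteinRatio(20, 10 / 3)
  expect_equal(r$ratio, 6, tolerance = 1e-12)
  expect_identical(r$label, "6:1")
  r2 <- ligandProteinRatio(5000, 10 / 3)
  expect_equal(r2$ratio, 1500, tolerance = 1e-12)
  expect_identical(r2$label, "1500:1")
  expect_equal(ligandProteinRatio(3.3, 3.3)$ratio, 1)
  # against the rounded 3.3 uM report the exact ratio is ~6.06
  expect_equal(ligandProteinRatio(20, 3.3)$ratio, 6.06, tolerance = 1e-2)
  expect_error(ligandProteinRatio(1, 0), "proteinConc")
})

test_that("saturation check classifies the three kinetic scenarios", {
  kin <- bindingKinetics(kOn = 1e6, KD = 1.9e-8, ligandConc = 2e-5,
                         proteinConc = 3.3e-6)
  v <- saturationCheck(kin, kex = 0.1)
  expect_identical(v$scenario, "saturating")
  expect_equal(v$saturationRatio, 200)
  expect_gt(v$occupancy, 0.99)

  v0 <- saturationCheck(bindingKinetics(kOn = 1e6, KD = 1.9e-8,
                                        ligandConc = 0,
                                        proteinConc = 3.3e-6), kex = 1)
  expect_identical(v0$scenario, "no-binding")
  expect_equal(v0$occupancy, 0)
  expect_match(v0$message, "no binding expected")

  slow <- saturationCheck(bindingKinetics(kOn = 1e6, kOff = 1e-3,
                                          ligandConc = 1e-4,
                                          proteinConc = 3.3e-6), kex = 1)
  expect_identical(slow$scenario, "slow-off")
  expect_match(slow$message, "would not dissociate")

  mid <- saturationCheck(bindingKinetics(kOn = 1e4, kOff = 0.5,
                                         ligandConc = 1e-5,
                                         proteinConc = 3.3e-6), kex = 1)
  expect_identical(mid$scenario, "intermediate")
})

test_that("binding kinetics validity enforces KD = kOff/kOn", {
  k <- bindingKinetics(kOn = 1e6, kOff = 0.019)
  expect_equal(k@KD, 1.9e-8)
  expect_error(
    bindingKinetics(kOn = 1e6, kOff = 0.019, KD = 1e-6), "inconsistent")
  expect_error(bindingKinetics(kOff = -1), "non-negative")
})

test_that("concentration strings with molar suffixes parse to molar", {
  expect_equal(parseConcentration(c("20uM", "19nM", "5mM", "1M")),
               c(2e-5, 1.9e-8, 5e-3, 1))
  expect_equal(parseConcentration("3.3e-6"), 3.3e-6)
  expect_equal(parseConcentration(2e-5), 2e-5)
  expect_error(parseConcentration("20 bananas"), "cannot parse")
})
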