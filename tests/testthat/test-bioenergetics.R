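test_that("phase levels (100, 40, 180, 20) give the textbook parameters", {
  p <- extractMitoParams(mito_trace(c(100, 40, 180, 20)))
  expect_equal(nonMitoRespiration(p), 20)
  expect_equal(basalRespiration(p), 80)
  expect_equal(protonLeak(p), 20)
  expect_equal(atpLinkedRespiration(p), 60)
  expect_equal(maximalRespiration(p), 160)
  expect_equal(spareCapacity(p), 80)
  expect_equal(couplingEfficiency(p), 0.75)
})

test_that("a flat trace yields zero basal and an undefined coupling", {
  p <- extractMitoParams(mito_trace(c(50, 50, 50, 50)))
  expect_equal(basalRespiration(p), 0)
  expect_equal(spareCapacity(p), 0)
  expect_true(is.na(couplingEfficiency(p)))
  expect_true("coupling_undefined" %in% flags(p))
})

test_that("a missing or out-of-order phase is rejected", {
  tr <- mito_trace(c(100, 40, 180, 20))
  expect_error(extractMitoParams(tr[tr$phase != "fccp", ]), "fccp")
  expect_error(extractMitoParams(tr[c(2, 1, 3, 4), ]), "order")
})

test_that("internal identities hold on random traces", {
  set.seed(5)
  for (i in 1:25) {
    p <- extractMitoParams(mito_trace(runif(4, 1, 200), cycles = 3L))
    expect_equal(basalRespiration(p),
                 atpLinkedRespiration(p) + protonLeak(p), tolerance = 1e-12)
    expect_equal(spareCapacity(p),
                 maximalRespiration(p) - basalRespiration(p), tolerance = 1e-12)
  }
})

test_that("stoichiometric yields match the molar constants", {
  k <- stoichiometryConstants()
  expect_equal(glycolyticATP(1, k), 2)
  expect_equal(glycolyticATP(0, k), 0)
  expect_equal(glycolyticATP(3.25, k), 6.5)
  expect_equal(maxOxidativeATPFromGlucose(1, k), 30)
  expect_equal(maxOxidativeATPFromGlucose(0.5, k), 15)
  expect_equal(maxATPFromGlutamine(1, k), 10)
  expect_equal(maxATPFromGlutamine(2.3, k), 23)
  expect_equal(atpPerO2(k), 5)
  expect_equal(mitoATPFromOCR(1, k), 5)
  expect_equal(mitoATPFromOCR(0, k), 0)
  expect_error(mitoATPFromOCR(-1, k), ">= 0")
})

test_that("yield operations are linear and mutually consistent", {
  k <- stoichiometryConstants()
  set.seed(9)
  for (g in c(0, runif(10, 0, 50))) {
    # one glucose fully oxidised consumes 6 O2
    expect_equal(mitoATPFromOCR(6 * g, k), maxOxidativeATPFromGlucose(g, k))
    a <- runif(1, 0.1, 10)
    expect_equal(glycolyticATP(a * g, k), a * glycolyticATP(g, k))
    expect_equal(maxATPFromGlutamine(a * g, k), a * maxATPFromGlutamine(g, k))
  }
})

test_that("glutamine requirement inverts the yield with its oxygen cost", {
  req <- glutamineRequired(10)
  expect_equal(as.numeric(req), 1)
  expect_equal(attr(req, "o2Required"), 2)
  expect_equal(as.numeric(glutamineRequired(0)), 0)
  req5 <- glutamineRequired(5, measuredGlutamineFlux = 0.4)
  expect_equal(as.numeric(req5), 0.5)
  expect_equal(attr(req5, "o2Required"), 1.0)
  expect_false(attr(req5, "sufficient"))
})

test_that("the budget reconciles its panels", {
  fx <- rbind(
    data.frame(substrate = "glucose", condition = "x", delta = NA, volume = NA,
               duration = NA, cells = NA, flux = 2, reliable = TRUE),
    data.frame(substrate = "glutamine", condition = "x", delta = NA, volume = NA,
               duration = NA, cells = NA, flux = 1, reliable = TRUE)
  )
  p <- extractMitoParams(mito_trace(c(100, 40, 180, 20)))
  # glycolytic = 4, mito = 5 * 60 = 300
  b <- buildATPBudget(fx, p, atpContent = 1, condition = "x")
  expect_equal(b@glycolyticATP, 4)
  expect_equal(b@mitoATPFromOCR, 300)
  expect_equal(b@totalATPCapacity, 304)
  expect_equal(b@fractionGlycolysis + b@fractionOxphos, 1)
  expect_equal(b@glnRequired, 30)
  expect_false(b@glnSufficient)
})

test_that("equal glycolytic and mitochondrial production split 50/50", {
  fx <- rbind(
    data.frame(substrate = "glucose", condition = "c", delta = NA, volume = NA,
               duration = NA, cells = NA, flux = 2, reliable = TRUE),
    data.frame(substrate = "glutamine", condition = "c", delta = NA, volume = NA,
               duration = NA, cells = NA, flux = 1, reliable = TRUE)
  )
  # atpLinked = 0.8 -> mito = 4 = glycolytic
  p <- extractMitoParams(mito_trace(c(1.2, 0.4, 2.0, 0.2)))
  b <- buildATPBudget(fx, p, atpContent = 1)
  expect_equal(b@fractionGlycolysis, 0.5)
  expect_equal(b@fractionOxphos, 0.5)
  # zero glucose: all production oxidative
  fx0 <- fx
  fx0$flux[fx0$substrate == "glucose"] <- 0
  b0 <- buildATPBudget(fx0, p, atpContent = 1)
  expect_equal(b0@fractionGlycolysis, 0)
  expect_equal(b0@fractionOxphos, 1)
})

test_that("missing budget inputs are rejected naming the panel", {
  p <- extractMitoParams(mito_trace(c(100, 40, 180, 20)))
  fx_glc <- data.frame(substrate = "glucose", condition = "c", delta = NA,
                       volume = NA, duration = NA, cells = NA, flux = 2,
                       reliable = TRUE)
  expect_error(buildATPBudget(fx_glc, p, atpContent = 1), "panel 5")
  expect_error(
    buildATPBudget(fx_glc[0, ], p, atpContent = 1), "panel 1"
  )
  expect_error(buildATPBudget(fx_glc, p), "panel 8")
})

test_that("budget conservation holds for random inputs", {
  set.seed(21)
  for (i in 1:20) {
    fx <- rbind(
      data.frame(substrate = "glucose", condition = "c", delta = NA,
                 volume = NA, duration = NA, cells = NA,
                 flux = runif(1, 0, 20), reliable = TRUE),
      data.frame(substrate = "glutamine", condition = "c", delta = NA,
                 volume = NA, duration = NA, cells = NA,
                 flux = runif(1, 0, 5), reliable = TRUE)
    )
    lv <- sort(runif(4, 1, 30))
    p <- extractMitoParams(mito_trace(c(lv[3], lv[2], lv[4], lv[1])))
    b <- buildATPBudget(fx, p, atpContent = 1)
    expect_equal(b@totalATPCapacity, b@glycolyticATP + b@mitoATPFromOCR,
                 tolerance = 1e-12)
  }
})
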