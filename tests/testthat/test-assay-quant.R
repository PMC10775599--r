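test_that("medium subtraction handles both directions and the LA lactate rule", {
  expect_equal(as.numeric(mediumDelta(4.5, 5.5, "consumption")), 1.0)
  expect_equal(as.numeric(mediumDelta(2.0, 0, "production")), 2.0)
  d <- mediumDelta(26, 24, "production", substrate = "lactate", condition = "LA")
  expect_false(attr(d, "reliable"))
  d2 <- mediumDelta(26, 24, "production", substrate = "lactate", condition = "HCl")
  expect_true(attr(d2, "reliable"))
  expect_error(mediumDelta(-1, 5, "consumption"), ">= 0")
})

test_that("flux normalization does the unit arithmetic", {
  # 1 umol consumed in a 1 l well, 48 h, 100,000 cells
  fx <- fluxNormalize(1e-3, 1, 2880, 1e5)
  expect_equal(fx$flux, 1e6 / 2880 / 100)
  expect_equal(fluxNormalize(0, 1, 2880, 1e5)$flux, 0)
  expect_error(fluxNormalize(1, 1, 0, 1e5), "duration")
  expect_error(fluxNormalize(1, 1, 10, 0), "cells")
})

test_that("flux satisfies the algebraic identity for random inputs", {
  set.seed(11)
  for (i in 1:50) {
    delta <- runif(1, -5, 5)
    volume <- runif(1, 1e-4, 1e-2)
    duration <- runif(1, 10, 5000)
    cells <- runif(1, 1e3, 1e6)
    fx <- fluxNormalize(delta, volume, duration, cells)
    expect_equal(
      fx$flux * duration * cells / 1000,
      delta * volume * 1e9,
      tolerance = 1e-12
    )
  }
})

test_that("lactate/glucose ratio identifies pure glycolysis and degenerate input", {
  r <- lactateGlucoseRatio(6, 3)
  expect_equal(as.numeric(r), 2)
  expect_true(attr(r, "pure_glycolysis"))
  r0 <- lactateGlucoseRatio(0, 3)
  expect_equal(as.numeric(r0), 0)
  expect_false(attr(r0, "pure_glycolysis"))
  und <- lactateGlucoseRatio(5, 0)
  expect_true(is.na(as.numeric(und)))
  expect_identical(attr(und, "flags"), "undefined")
  expect_error(lactateGlucoseRatio(5, 3, reliable = FALSE), "reliable")
})

test_that("LDH release fraction is bounded and rejects the empty case", {
  expect_equal(ldhReleaseFraction(20, 80), 0.20)
  expect_equal(ldhReleaseFraction(0, 50), 0)
  expect_error(ldhReleaseFraction(0, 0), "zero")
  set.seed(3)
  m <- runif(100, 0, 10)
  l <- runif(100, 0.1, 10)
  fr <- ldhReleaseFraction(m, l)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("specific activity normalizes to time and protein", {
  expect_equal(specificActivity(90, 90, 10), 0.1)
  expect_equal(specificActivity(0, 90, 10), 0)
  expect_error(specificActivity(1, 0, 10), "time")
  expect_error(specificActivity(1, 10, 0), "protein")
})
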