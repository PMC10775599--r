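test_that("identical seeds give bit-identical experiments", {
  d <- experimentDesign(seed = 99L)
  for (gen in list(
    function() simulatePlateAssay(d, "glucose", noiseCV = 0.05),
    function() simulateOCRTraces(d, noiseCV = 0.03),
    function() simulateDEGTables(nGenes = 500L, seed = 99L)
  )) {
    expect_identical(gen(), gen())
  }
  # and a different seed changes the noise
  d2 <- experimentDesign(seed = 100L)
  expect_false(identical(
    simulatePlateAssay(d, "glucose", noiseCV = 0.05)$signal,
    simulatePlateAssay(d2, "glucose", noiseCV = 0.05)$signal
  ))
})

test_that("unknown assay labels are rejected with a message", {
  d <- experimentDesign()
  expect_error(simulatePlateAssay(d, "telomerase"), "unknown assay")
  expect_error(simulatePlateAssay(d, "glucose", noiseCV = -0.1), ">= 0")
})

test_that("zero-noise plates round-trip through quantification exactly", {
  d <- experimentDesign(replicates = 2L, seed = 4L)
  for (assay in c("glucose", "lactate", "glutamine", "ATP", "caspase",
                  "protein")) {
    q <- quantifyPlate(simulatePlateAssay(d, assay, noiseCV = 0))
    expect_equal(q$amount, q$true_amount, tolerance = 1e-9,
                 label = paste(assay, "recovery"))
  }
})

test_that("the LA supernatant carries the 24 mmol/l lactate background", {
  d <- experimentDesign(seed = 2L)
  q <- quantifyPlate(simulatePlateAssay(d, "lactate", noiseCV = 0))
  la <- q$amount[q$condition == "LA"]
  expect_true(all(la > 24))
  ctrl <- q$amount[q$condition == "ctrl"]
  expect_true(all(ctrl < 24))
})

test_that("noisy plate quantification is unbiased within Monte-Carlo error", {
  d <- experimentDesign(conditions = "ctrl", replicates = 1000L,
                        lactateBackground = c(ctrl = 0), seed = 8L)
  # quantify noisy sample wells against an error-free standard curve: a
  # single noisy 6-point curve would correlate all per-well errors, which is
  # a calibration-uncertainty question, not a bias question
  exact <- simulatePlateAssay(d, "glucose", noiseCV = 0)
  curve <- fitCalibration(
    exact[exact$role %in% c("standard", "blank"), c("amount", "signal")]
  )
  noisy <- simulatePlateAssay(d, "glucose", noiseCV = 0.05)
  smp <- noisy[noisy$role == "sample", ]
  err <- as.numeric(quantify(smp$signal, curve)) - smp$true_amount
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("OCR traces honour the phase structure and recover parameters", {
  d <- experimentDesign(replicates = 1L, seed = 3L)
  tr1 <- simulateOCRTraces(d, cyclesPerPhase = 1L, noiseCV = 0)
  expect_equal(nrow(tr1), 4L * length(conditions(d)))
  ctrl <- tr1[tr1$condition == "ctrl", ]
  p <- extractMitoParams(ctrl)
  truth <- trueMitoParams(defaultGroundTruth(), "ctrl")
  expect_equal(basalRespiration(p), basalRespiration(truth))
  expect_equal(couplingEfficiency(p), couplingEfficiency(truth))
  expect_error(simulateOCRTraces(d, cyclesPerPhase = 0L), "cyclesPerPhase")
})

test_that("noisy OCR parameter estimates are unbiased within 3 SE", {
  d <- experimentDesign(conditions = "ctrl", replicates = 200L,
                        lactateBackground = c(ctrl = 0), seed = 12L)
  traces <- simulateOCRTraces(d, cyclesPerPhase = 3L, noiseCV = 0.03)
  truth <- trueMitoParams(defaultGroundTruth(), "ctrl")
  # per-phase means are the unbiased summary choice for a recovery check
  # (min/max summaries are order statistics and sit slightly off-centre
  # under noise by construction)
  means <- c(baseline = "mean", oligo = "mean", fccp = "mean", rotAA = "mean")
  est <- vapply(unique(traces$well), function(w) {
    basalRespiration(extractMitoParams(traces[traces$well == w, ],
                                       summary = means))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - basalRespiration(truth)), 3 * se)
})

test_that("the default truth reproduces the condition ordering", {
  truth <- defaultGroundTruth()
  eff <- function(substrate, cond) {
    abs(trueFlux(truth, substrate, cond) - trueFlux(truth, substrate, "ctrl"))
  }
  for (substrate in c("glucose", "glutamine")) {
    expect_gt(eff(substrate, "LA"), eff(substrate, "HCl"))
    expect_gt(eff(substrate, "HCl"), eff(substrate, "Na_lactate"))
  }
  tabs <- simulateDEGTables(nGenes = 5000L, seed = 1L)
  n_deg <- vapply(tabs, function(t) nrow(filterDEGs(t)), integer(1))
  expect_gt(n_deg[["LA"]], n_deg[["HCl"]])
  expect_gt(n_deg[["HCl"]], n_deg[["Na_lactate"]])
})

test_that("DEG generator controls concordance and slope exactly", {
  tabs <- simulateDEGTables(nGenes = 400L, flipProb = 0, seed = 6L)
  cr <- concordance(tabs$LA, tabs$HCl)
  expect_equal(fractionSameSign(cr), 1.0)
  # noiseless scaled effects: OLS on collinear points recovers the slope
  tabs2 <- simulateDEGTables(nGenes = 400L, flipProb = 0, slope = 0.45,
                             noiseSd = 0, seed = 6L)
  expect_equal(concordanceSlope(concordance(tabs2$LA, tabs2$HCl)), 0.45,
               tolerance = 1e-10)
  expect_error(simulateDEGTables(nGenes = 0L), "nGenes")
  expect_error(simulateDEGTables(flipProb = 1.5), "flipProb")
})

test_that("5% sign flips over 10,000 genes land in the binomial 99% CI", {
  tabs <- simulateDEGTables(nGenes = 10000L, flipProb = 0.05, seed = 17L)
  fr <- fractionSameSign(concordance(tabs$LA, tabs$HCl))
  half <- qnorm(0.995) * sqrt(0.95 * 0.05 / 10000)
  expect_gt(fr, 0.95 - half)
  expect_lt(fr, 0.95 + half)
})
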