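#' @include synthetic-design.R
NULL

.PLATE_ASSAYS <- c(
  "glucose", "lactate", "glutamine", "ATP", "LDH_media", "LDH_lysate",
  "caspase", "BrdU", "protein"
)

# True instrument response per assay: signal = intercept + slope * amount.
# Arbitrary but fixed; round-trip tests must recover amounts regardless.
.assayResponse <- function(assay) {
  switch(assay,
    glucose = c(intercept = 0.05, slope = 0.18),
    lactate = c(intercept = 0.04, slope = 0.09),
    glutamine = c(intercept = 0.03, slope = 0.40),
    ATP = c(intercept = 120, slope = 5200),
    LDH_media = c(intercept = 0.02, slope = 0.011),
    LDH_lysate = c(intercept = 0.02, slope = 0.011),
    caspase = c(intercept = 15, slope = 310),
    BrdU = c(intercept = 0.06, slope = 1.1),
    protein = c(intercept = 0.08, slope = 0.021)
  )
}

# multiplicative Gaussian noise with CV `cv`, truncated at zero
.mnoise <- function(x, cv) {
  if (cv == 0) return(x)
  x * pmax(0, stats::rnorm(length(x), mean = 1, sd = cv))
}

# true per-well amount for an assay/condition (concentrations in mmol/l for
# the substrate assays, assay-native units otherwise)
.trueAmount <- function(design, truth, assay, condition) {
  conc_of <- function(flux) {
    flux * design@duration * (design@cellsPerWell / 1000) /
      design@volumeL / 1e9
  }
  switch(assay,
    glucose = design@mediumGlucose - conc_of(trueFlux(truth, "glucose", condition)),
    lactate = design@lactateBackground[[condition]] +
      conc_of(trueFlux(truth, "lactate", condition)),
    glutamine = design@mediumGlutamine - conc_of(trueFlux(truth, "glutamine", condition)),
    {
      al <- truth@assayLevels
      lv <- al$level[al$assay == assay & al$condition == condition]
      if (!length(lv)) stop("no true level for assay '", assay, "'")
      lv
    }
  )
}

#' Simulate a plate-reader assay with known ground truth
#'
#' Generates one virtual plate for the requested assay: a six-point linear
#' standard series (including the blank at amount zero) spanning the true
#' sample range, plus one sample well per condition and replicate. Signals
#' follow the assay's linear instrument response with multiplicative
#' Gaussian noise (truncated at zero) of coefficient of variation `noiseCV`
#' on every well. The planted true amount of each sample well is recorded in
#' the `true_amount` column, so downstream quantification has an exact
#' recovery target: at `noiseCV = 0` the full calibrate-and-quantify path
#' reproduces `true_amount` to machine precision.
#'
#' For the substrate assays the amount is the supernatant concentration in
#' mmol/l: fresh-medium concentration minus the consumed equivalent for
#' glucose and glutamine, lactate background plus the produced equivalent for
#' lactate — under lactic acidosis and Na-lactate the generated supernatant
#' therefore carries the 24 mmol/l background.
#'
#' @param design an [ExperimentDesign-class].
#' @param assay one of `"glucose"`, `"lactate"`, `"glutamine"`, `"ATP"`,
#'   `"LDH_media"`, `"LDH_lysate"`, `"caspase"`, `"BrdU"`, `"protein"`.
#' @param truth a [GroundTruth-class] (default [defaultGroundTruth()]).
#' @param noiseCV coefficient of variation of the multiplicative noise
#'   (>= 0; default 0.05).
#' @return data.frame with columns `well`, `role`
#'   (`standard` / `blank` / `sample`), `amount` (standards only), `signal`,
#'   `condition` (samples only), `protein_ug` (samples only), `true_amount`
#'   (samples only).
#' @export
simulatePlateAssay <- function(design, assay, truth = defaultGroundTruth(),
                               noiseCV = 0.05) {
  stopifnot(is(design, "ExperimentDesign"), is(truth, "GroundTruth"))
  validObject(design)
  validObject(truth)
  if (length(assay) != 1L || !assay %in% .PLATE_ASSAYS) {
    stop(
      "unknown assay '", assay, "'; supported: ",
      paste(.PLATE_ASSAYS, collapse = ", ")
    )
  }
  if (noiseCV < 0) stop("'noiseCV' must be >= 0")
  set.seed(.substreamSeed(design@seed, paste0("plate_", assay)))
  resp <- .assayResponse(assay)

  true_amounts <- vapply(
    design@conditions, function(cn) .trueAmount(design, truth, assay, cn),
    numeric(1)
  )
  # 6-point standard series: blank + 5 levels spanning the sample range
  top <- max(true_amounts, 1e-6) * 1.25
  std_amounts <- seq(0, top, length.out = 6)
  std_signal <- .mnoise(resp["intercept"] + resp["slope"] * std_amounts, noiseCV)
  standards <- data.frame(
    well = sprintf("S%02d", seq_along(std_amounts)),
    role = ifelse(std_amounts == 0, "blank", "standard"),
    amount = std_amounts,
    signal = unname(std_signal),
    condition = NA_character_,
    protein_ug = NA_real_,
    true_amount = NA_real_,
    stringsAsFactors = FALSE
  )

  al <- truth@assayLevels
  prot <- al$level[al$assay == "protein"]
  names(prot) <- al$condition[al$assay == "protein"]
  samples <- do.call(rbind, lapply(seq_along(design@conditions), function(i) {
    cn <- design@conditions[i]
    ta <- rep(true_amounts[[cn]], design@replicates)
    data.frame(
      well = sprintf("%s_%02d", cn, seq_len(design@replicates)),
      role = "sample",
      amount = NA_real_,
      signal = .mnoise(resp["intercept"] + resp["slope"] * ta, noiseCV),
      condition = cn,
      protein_ug = .mnoise(rep(prot[[cn]], design@replicates), noiseCV),
      true_amount = ta,
      stringsAsFactors = FALSE
    )
  }))
  out <- rbind(standards, samples)
  rownames(out) <- NULL
  out
}

#' Quantify the sample wells of a simulated (or real) plate
#'
#' Convenience wrapper over [fitCalibration()] and [quantify()]: fits the
#' standard curve on the `standard`/`blank` wells and inverts it on the
#' `sample` wells.
#'
#' @param plate a plate table in the schema of [simulatePlateAssay()].
#' @param r2Warn forwarded to [fitCalibration()].
#' @return the sample rows with an added `amount` column (the quantified
#'   amounts) and attribute `curve` (the fitted [CalibrationCurve-class]).
#' @export
quantifyPlate <- function(plate, r2Warn = 0.98) {
  std <- plate[plate$role %in% c("standard", "blank"), ]
  smp <- plate[plate$role == "sample", ]
  if (!nrow(std)) stop("plate has no standard wells")
  if (!nrow(smp)) stop("plate has no sample wells")
  curve <- fitCalibration(std[, c("amount", "signal")], r2Warn = r2Warn)
  smp$amount <- as.numeric(quantify(smp$signal, curve))
  attr(smp, "curve") <- curve
  smp
}
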