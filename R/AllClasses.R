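#' @import methods
NULL

#' Linear calibration curve for a plate-reader assay
#'
#' Ordinary least-squares standard curve (signal = slope * amount + intercept)
#' fitted to a dilution series. Every colorimetric / luminescent / fluorescent
#' assay in the workflow (glucose, lactate, glutamine, ATP, LDH, caspase, BrdU,
#' protein) is quantified against such a curve. The blank is the fitted signal
#' at amount zero, i.e. the intercept.
#'
#' @slot slope signal units per amount unit; never zero for a valid curve.
#' @slot intercept fitted signal at amount 0 (the blank).
#' @slot rSquared coefficient of determination of the fit, in \[0, 1\].
#' @slot blank fitted signal at amount 0 (equal to `intercept`).
#' @slot nStandards number of standards used (>= 2).
#' @slot flags character vector of quality labels, e.g. `"low_r_squared"`.
#'
#' @seealso [fitCalibration()], [quantify()]
#' @export
setClass("CalibrationCurve",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    blank = "numeric",
    nStandards = "integer",
    flags = "character"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope)) {
    msg <- c(msg, "'slope' must be a single finite number")
  } else if (object@slope == 0) {
    msg <- c(msg, "'slope' must be non-zero")
  }
  if (object@nStandards < 2L) {
    msg <- c(msg, "'nStandards' must be >= 2")
  }
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)) {
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Two-point intracellular pH calibration
#'
#' BCECF fluorescence-ratio calibration from two nigericin clamps of known pH.
#' Two points admit exactly a linear map from ratio to pH; values outside the
#' calibrated ratio interval are extrapolated (allowed, but flagged by
#' [phFromRatio()]).
#'
#' @slot ph the two clamped pH values (must differ).
#' @slot ratio the two measured BCECF ratios (must differ).
#'
#' @seealso [phCalibration()], [phFromRatio()]
#' @export
setClass("PhCalibration",
  representation(ph = "numeric", ratio = "numeric")
)

setValidity("PhCalibration", function(object) {
  msg <- character()
  if (length(object@ph) != 2L || length(object@ratio) != 2L) {
    msg <- c(msg, "exactly two calibration points are required")
  } else {
    if (object@ph[1] == object@ph[2]) {
      msg <- c(msg, "the two calibration pH values must differ")
    }
    if (object@ratio[1] == object@ratio[2]) {
      msg <- c(msg, "the two calibration ratios must differ")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ATP-yield stoichiometry constants
#'
#' Molar yields used by the ATP budget: net glycolytic yield of 2 ATP per
#' glucose converted to lactate; maximal oxidative yield of 30 ATP per glucose
#' fully oxidised; 10 ATP per glutamine oxidised, consuming 2 O2. Both printed
#' yields imply the same conversion of 5 ATP per O2 (10/2 for glutamine,
#' 30/6 for glucose), which is the constant used to turn ATP-synthesis-linked
#' oxygen consumption into a mitochondrial ATP production rate.
#'
#' @slot atpPerGlucoseGlycolysis net ATP per glucose via glycolysis (default 2).
#' @slot atpPerGlucoseOxidation maximal ATP per glucose fully oxidised
#'   (default 30).
#' @slot atpPerGlutamine ATP per glutamine oxidised (default 10).
#' @slot o2PerGlutamine O2 consumed per glutamine oxidised (default 2).
#'
#' @seealso [stoichiometryConstants()], [atpPerO2()]
#' @export
setClass("StoichiometryConstants",
  representation(
    atpPerGlucoseGlycolysis = "numeric",
    atpPerGlucoseOxidation = "numeric",
    atpPerGlutamine = "numeric",
    o2PerGlutamine = "numeric"
  )
)

setValidity("StoichiometryConstants", function(object) {
  vals <- c(
    object@atpPerGlucoseGlycolysis, object@atpPerGlucoseOxidation,
    object@atpPerGlutamine, object@o2PerGlutamine
  )
  if (length(vals) != 4L || any(!is.finite(vals)) || any(vals <= 0)) {
    return("all stoichiometric yields must be single positive finite numbers")
  }
  TRUE
})

#' Mito-Stress respiratory parameters
#'
#' The six mitochondrial parameters derived from an injection-annotated
#' oxygen-consumption trace: non-mitochondrial respiration (rotenone/antimycin
#' floor), basal respiration, ATP-synthesis-linked respiration, proton leak,
#' maximal (FCCP-uncoupled) respiration, spare respiratory capacity, and
#' coupling efficiency. All rates share the trace's units
#' (pmol O2 min^-1 (1000 cells)^-1). The internal identities
#' `basal = atpLinked + protonLeak` and `spare = maximal - basal` hold exactly.
#' Negative baseline-corrected rates are retained (flag `"negative_rate"`),
#' never clamped, so replicate averages stay unbiased.
#'
#' @slot nonMito non-mitochondrial respiration.
#' @slot basal basal respiration (last baseline measurement minus `nonMito`).
#' @slot atpLinked ATP-synthesis-linked respiration (`basal - protonLeak`).
#' @slot protonLeak oligomycin-insensitive mitochondrial respiration.
#' @slot maximal FCCP-uncoupled respiration minus `nonMito`.
#' @slot spare `maximal - basal`.
#' @slot couplingEfficiency `atpLinked / basal`; `NA` when basal is not
#'   positive (flag `"coupling_undefined"`).
#' @slot flags character vector of quality labels.
#'
#' @seealso [extractMitoParams()]
#' @export
setClass("MitoParams",
  representation(
    nonMito = "numeric",
    basal = "numeric",
    atpLinked = "numeric",
    protonLeak = "numeric",
    maximal = "numeric",
    spare = "numeric",
    couplingEfficiency = "numeric",
    flags = "character"
  )
)

setValidity("MitoParams", function(object) {
  msg <- character()
  tol <- 1e-9 * max(1, abs(object@basal))
  if (abs(object@basal - (object@atpLinked + object@protonLeak)) > tol) {
    msg <- c(msg, "'basal' must equal 'atpLinked' + 'protonLeak'")
  }
  if (abs(object@spare - (object@maximal - object@basal)) > tol) {
    msg <- c(msg, "'spare' must equal 'maximal' - 'basal'")
  }
  if (length(msg)) msg else TRUE
})

#' Nine-panel ATP budget for one condition
#'
#' Reconciliation of glycolytic and oxidative ATP production for a single
#' treatment condition: measured glucose consumption flux (panel 1), its
#' glycolytic ATP equivalent (panel 2), the maximal oxidative ATP were all
#' consumed glucose fully oxidised (panel 3), mitochondrial ATP production
#' computed from ATP-synthesis-linked oxygen consumption (panel 4), measured
#' glutamine consumption flux (panel 5), its maximal oxidative ATP equivalent
#' (panel 6), the total ATP production capacity (panel 7 = panel 2 + panel 4),
#' the independently measured cellular ATP content (panel 8), and the
#' glycolytic/oxidative fractions of total production (panel 9). The red-line
#' quantity is the glutamine flux required to fuel panel 4; `glnSufficient`
#' records whether the measured glutamine consumption covers it. All fluxes in
#' pmol min^-1 (1000 cells)^-1.
#'
#' @slot condition condition label.
#' @slot glucoseFlux measured glucose consumption flux (panel 1).
#' @slot glycolyticATP panel 2.
#' @slot maxOxATPFromGlucose panel 3.
#' @slot mitoATPFromOCR panel 4.
#' @slot glutamineFlux measured glutamine consumption flux (panel 5).
#' @slot maxATPFromGlutamine panel 6.
#' @slot totalATPCapacity panel 7.
#' @slot measuredATPContent panel 8 (a measured input, never derived).
#' @slot fractionGlycolysis,fractionOxphos panel 9; sum to 1 when total > 0.
#' @slot glnRequired glutamine flux required to fuel panel 4 (the red line).
#' @slot o2Required oxygen flux for complete oxidation of `glnRequired`.
#' @slot glnSufficient `TRUE` when `glutamineFlux >= glnRequired`.
#'
#' @seealso [buildATPBudget()]
#' @export
setClass("ATPBudget",
  representation(
    condition = "character",
    glucoseFlux = "numeric",
    glycolyticATP = "numeric",
    maxOxATPFromGlucose = "numeric",
    mitoATPFromOCR = "numeric",
    glutamineFlux = "numeric",
    maxATPFromGlutamine = "numeric",
    totalATPCapacity = "numeric",
    measuredATPContent = "numeric",
    fractionGlycolysis = "numeric",
    fractionOxphos = "numeric",
    glnRequired = "numeric",
    o2Required = "numeric",
    glnSufficient = "logical"
  )
)

setValidity("ATPBudget", function(object) {
  msg <- character()
  tot <- object@glycolyticATP + object@mitoATPFromOCR
  if (abs(object@totalATPCapacity - tot) > 1e-9 * max(1, abs(tot))) {
    msg <- c(msg, "'totalATPCapacity' must equal glycolyticATP + mitoATPFromOCR")
  }
  fr <- object@fractionGlycolysis + object@fractionOxphos
  if (tot > 0 && is.finite(fr) && abs(fr - 1) > 1e-9) {
    msg <- c(msg, "ATP fractions must sum to 1 when total capacity is positive")
  }
  if (length(msg)) msg else TRUE
})

#' Three-set Venn partition of DEG lists
#'
#' The seven disjoint regions of three labelled differentially-expressed-gene
#' sets, plus per-set totals. Region names join set labels with `"&"`
#' (e.g. `"HCl&LA"`); each set's total equals the sum of the four regions that
#' contain it.
#'
#' @slot setNames labels of the three input sets.
#' @slot regions named list of seven disjoint character vectors of gene ids.
#' @slot totals named numeric vector of per-set sizes.
#'
#' @seealso [vennPartition()]
#' @export
setClass("VennPartition",
  representation(
    setNames = "character",
    regions = "list",
    totals = "numeric"
  )
)

setValidity("VennPartition", function(object) {
  msg <- character()
  if (length(object@setNames) != 3L) {
    msg <- c(msg, "exactly three set labels are required")
  }
  if (length(object@regions) != 7L) {
    msg <- c(msg, "exactly seven regions are required")
  }
  all_ids <- unlist(object@regions, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    msg <- c(msg, "regions must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Sign-concordance between two differential-expression contrasts
#'
#' For genes shared by two contrasts: the fraction regulated in the same sense
#' (sign of log2 fold change agrees; an exact zero is discordant with any
#' non-zero), and the slope/intercept of the regression of contrast B's
#' log2FC on contrast A's. A slope below 1 means contrast A's effects are the
#' more pronounced; the bisector deviation is `slope - 1`.
#'
#' @slot nUnion number of genes in the union of the two tables.
#' @slot nCommon number of shared genes the statistics are computed over.
#' @slot fractionSameSign fraction of shared genes with concordant sign.
#' @slot slope regression slope of B on A.
#' @slot intercept regression intercept.
#' @slot slopeMethod `"ols"` or `"tls"` (total least squares).
#'
#' @seealso [concordance()]
#' @export
setClass("ConcordanceResult",
  representation(
    nUnion = "integer",
    nCommon = "integer",
    fractionSameSign = "numeric",
    slope = "numeric",
    intercept = "numeric",
    slopeMethod = "character"
  )
)

setValidity("ConcordanceResult", function(object) {
  if (is.finite(object@fractionSameSign) &&
      (object@fractionSameSign < 0 || object@fractionSameSign > 1)) {
    return("'fractionSameSign' must lie in [0, 1]")
  }
  TRUE
})

#' Design of a virtual acidosis experiment
#'
#' The five-condition treatment design the synthetic generator emulates:
#' control (pH 7.4), hydrochloric acidosis (HCl, pH 6.8), lactic acidosis
#' (LA, pH 6.8 plus 24 mmol/l lactate), the hyperosmolarity control mannitol
#' (pH 7.4, 24 mmol/l), and Na-lactate (pH 7.4, 24 mmol/l). Treatment runs
#' for 48 h (2880 min) in medium containing 5.5 mmol/l glucose; the LA and
#' Na-lactate media carry a 24 mmol/l lactate background.
#'
#' @slot conditions ordered condition labels.
#' @slot replicates wells per condition (>= 1).
#' @slot duration treatment duration in minutes (> 0).
#' @slot cellsPerWell cells per well (> 0).
#' @slot volumeL medium volume per well in litres (> 0). The generator needs a
#'   volume to turn true fluxes into supernatant concentrations; downstream
#'   flux normalization still takes the volume as an explicit argument.
#' @slot mediumGlucose glucose concentration of fresh medium, mmol/l.
#' @slot mediumGlutamine glutamine concentration of fresh medium, mmol/l.
#' @slot lactateBackground named per-condition lactate background, mmol/l.
#' @slot seed integer seed; identical seeds give bit-identical experiments.
#'
#' @seealso [experimentDesign()]
#' @export
setClass("ExperimentDesign",
  representation(
    conditions = "character",
    replicates = "integer",
    duration = "numeric",
    cellsPerWell = "numeric",
    volumeL = "numeric",
    mediumGlucose = "numeric",
    mediumGlutamine = "numeric",
    lactateBackground = "numeric",
    seed = "integer"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
  if (object@cellsPerWell <= 0) msg <- c(msg, "'cellsPerWell' must be > 0")
  if (object@volumeL <= 0) msg <- c(msg, "'volumeL' must be > 0")
  if (object@replicates < 1L) {
    msg <- c(msg, "every condition needs at least one replicate")
  }
  if (!length(object@conditions)) msg <- c(msg, "at least one condition")
  if (!all(object@conditions %in% names(object@lactateBackground))) {
    msg <- c(msg, "'lactateBackground' must name every condition")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a virtual experiment
#'
#' Per-condition true values the generator plants and recovery tests check:
#' substrate fluxes (pmol min^-1 (1000 cells)^-1, consumption positive for
#' glucose/glutamine, production positive for lactate), the four true
#' oxygen-consumption phase levels, intracellular pH, relative ATP content,
#' per-assay viability/phenotype levels, and the parameters of the paired
#' DEG-table model (effect scaling slope and sign-flip probability between
#' contrasts).
#'
#' @slot fluxes data.frame with columns `condition`, `substrate`, `flux`.
#' @slot ocrPhases data.frame with columns `condition`, `baseline`, `oligo`,
#'   `fccp`, `rotAA` (pmol O2 min^-1 (1000 cells)^-1).
#' @slot ph named numeric, true intracellular pH per condition.
#' @slot atpContent named numeric, relative cellular ATP content per condition.
#' @slot assayLevels data.frame with columns `assay`, `condition`, `level` for
#'   the plate assays that are not substrate concentrations (ATP, LDH,
#'   caspase, BrdU, protein).
#' @slot degSlope effect scaling of the second contrast relative to the first.
#' @slot degFlipProb per-gene sign-flip probability between contrasts, in
#'   \[0, 1\].
#'
#' @seealso [defaultGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    fluxes = "data.frame",
    ocrPhases = "data.frame",
    ph = "numeric",
    atpContent = "numeric",
    assayLevels = "data.frame",
    degSlope = "numeric",
    degFlipProb = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(is.finite(object@fluxes$flux))) {
    msg <- c(msg, "all true fluxes must be finite")
  }
  if (object@degFlipProb < 0 || object@degFlipProb > 1) {
    msg <- c(msg, "'degFlipProb' must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
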