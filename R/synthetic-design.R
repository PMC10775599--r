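#' @include AllClasses.R AllGenerics.R
NULL

# Deterministic sub-stream seed per (run seed, artifact label), kept below
# 2^31 so it is a valid R integer. A cheap polynomial string hash is enough:
# the goal is reproducibility without cross-assay coupling, not cryptography.
.substreamSeed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.CONDITIONS <- c("ctrl", "HCl", "LA", "mannitol", "Na_lactate")

#' Construct a virtual experiment design
#'
#' Defaults encode the study conditions: five treatment groups (control
#' pH 7.4; HCl pH 6.8; lactic acidosis pH 6.8 + 24 mmol/l lactate; mannitol
#' 24 mmol/l hyperosmolarity control; Na-lactate 24 mmol/l at pH 7.4),
#' 48 hours of treatment (2880 min) in medium with 5.5 mmol/l glucose and
#' 2 mmol/l glutamine, a 24 mmol/l lactate background in the LA and
#' Na-lactate media, 100,000 cells per well and a 2 ml well volume.
#'
#' @param conditions ordered condition labels.
#' @param replicates wells per condition (default 6).
#' @param duration treatment duration, minutes (default 2880 = 48 h).
#' @param cellsPerWell cells per well (default 1e5).
#' @param volumeL well volume, litres (default 0.002).
#' @param mediumGlucose fresh-medium glucose, mmol/l (default 5.5).
#' @param mediumGlutamine fresh-medium glutamine, mmol/l (default 2).
#' @param lactateBackground named per-condition lactate background, mmol/l;
#'   default 24 for `LA` and `Na_lactate`, 0 otherwise.
#' @param seed integer seed; identical seeds give bit-identical experiments.
#' @return an [ExperimentDesign-class].
#' @export
experimentDesign <- function(conditions = .CONDITIONS,
                             replicates = 6L,
                             duration = 2880,
                             cellsPerWell = 1e5,
                             volumeL = 0.002,
                             mediumGlucose = 5.5,
                             mediumGlutamine = 2,
                             lactateBackground = NULL,
                             seed = 1L) {
  if (is.null(lactateBackground)) {
    lactateBackground <- stats::setNames(
      ifelse(conditions %in% c("LA", "Na_lactate"), 24, 0), conditions
    )
  }
  new("ExperimentDesign",
    conditions = conditions,
    replicates = as.integer(replicates),
    duration = duration,
    cellsPerWell = cellsPerWell,
    volumeL = volumeL,
    mediumGlucose = mediumGlucose,
    mediumGlutamine = mediumGlutamine,
    lactateBackground = lactateBackground,
    seed = as.integer(seed)
  )
}

#' @rdname conditions
#' @export
setMethod("conditions", "ExperimentDesign", function(object) {
  object@conditions
})

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", length(object@conditions), "conditions x",
      object@replicates, "replicates\n")
  cat(
    "  ", object@duration, "min |", object@cellsPerWell, "cells/well |",
    object@volumeL * 1000, "ml/well | seed", object@seed, "\n"
  )
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  invisible(NULL)
})

#' Default ground truth of the virtual experiment
#'
#' The planted per-condition true values, chosen to reproduce the study's
#' qualitative picture while remaining internally consistent with the
#' stoichiometric budget:
#'
#' * Glucose consumption is high under control and mannitol, reduced under
#'   HCl, and almost abolished under lactic acidosis
#'   (|effect LA| > |effect HCl| >> |effect Na-lactate| ~ 0); lactate
#'   production is exactly twice glucose consumption in every condition
#'   (purely glycolytic glucose disposal).
#' * Glutamine consumption falls under both acidoses, more under LA; with the
#'   default OCR levels the control and HCl consumption covers the glutamine
#'   needed to fuel OCR-derived mitochondrial ATP production while the LA
#'   consumption does not.
#' * OCR phase levels give a slightly increased basal respiration and proton
#'   leak, a substantially increased maximal respiration/spare capacity and a
#'   slightly reduced coupling efficiency under both acidoses.
#' * True intracellular pH: 7.53 under control, 6.8 under both acidoses.
#' * Relative cellular ATP content maintained under HCl, reduced under LA.
#' * Paired DEG tables: the HCl contrast's effects are the LA effects scaled
#'   by 0.5 with a 5 percent per-gene sign-flip probability.
#'
#' @param degSlope effect scaling of HCl relative to LA (default 0.5).
#' @param degFlipProb per-gene sign-flip probability (default 0.05).
#' @return a [GroundTruth-class].
#' @export
defaultGroundTruth <- function(degSlope = 0.5, degFlipProb = 0.05) {
  cond <- .CONDITIONS
  glucose <- c(14, 8, 0.5, 14, 13.5)
  fluxes <- rbind(
    data.frame(condition = cond, substrate = "glucose", flux = glucose),
    data.frame(condition = cond, substrate = "lactate", flux = 2 * glucose),
    data.frame(
      condition = cond, substrate = "glutamine",
      flux = c(3.5, 2.9, 1.2, 3.5, 3.3)
    )
  )
  ocr <- data.frame(
    condition = cond,
    baseline = c(9.3, 10.0, 10.4, 9.3, 9.5),
    oligo = c(3.7, 4.4, 4.6, 3.7, 3.8),
    fccp = c(16.7, 19.4, 20.7, 16.7, 17.0),
    rotAA = c(1.9, 1.9, 1.9, 1.9, 1.9)
  )
  assay_levels <- rbind(
    data.frame(assay = "ATP", condition = cond,
               level = c(2.0, 1.94, 1.4, 2.0, 1.96)),
    data.frame(assay = "LDH_media", condition = cond,
               level = c(10, 8, 8, 8, 12)),
    data.frame(assay = "LDH_lysate", condition = cond,
               level = c(90, 90, 90, 90, 90)),
    data.frame(assay = "caspase", condition = cond,
               level = c(5, 5, 5.5, 5, 6)),
    data.frame(assay = "BrdU", condition = cond,
               level = c(1.0, 0.7, 0.5, 1.0, 0.95)),
    data.frame(assay = "protein", condition = cond,
               level = c(20, 21, 22, 20, 20))
  )
  new("GroundTruth",
    fluxes = fluxes,
    ocrPhases = ocr,
    ph = stats::setNames(c(7.53, 6.8, 6.8, 7.5, 7.5), cond),
    atpContent = stats::setNames(c(1.0, 0.97, 0.70, 1.0, 0.98), cond),
    assayLevels = assay_levels,
    degSlope = degSlope,
    degFlipProb = degFlipProb
  )
}

#' True flux lookup
#'
#' @param truth a [GroundTruth-class].
#' @param substrate `"glucose"`, `"lactate"` or `"glutamine"`.
#' @param condition condition label(s).
#' @return numeric flux (pmol min^-1 (1000 cells)^-1).
#' @export
trueFlux <- function(truth, substrate, condition) {
  fx <- truth@fluxes
  rows <- fx[fx$substrate == substrate, ]
  out <- rows$flux[match(condition, rows$condition)]
  if (any(is.na(out))) stop("unknown condition or substrate")
  out
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth for", length(unique(object@fluxes$condition)),
      "conditions\n")
  cat("  substrates:",
      paste(unique(object@fluxes$substrate), collapse = ", "), "\n")
  cat("  DEG model: slope", object@degSlope,
      "| sign-flip prob", object@degFlipProb, "\n")
  invisible(NULL)
})
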