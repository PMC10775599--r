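#' @include synthetic-design.R
NULL

#' Simulate Mito-Stress oxygen-consumption traces
#'
#' One trace per condition and replicate well, with the four injection phases
#' (baseline, post-oligomycin, post-FCCP, post-rotenone/antimycin A) at the
#' per-condition true levels from the ground truth and multiplicative
#' Gaussian noise of coefficient of variation `noiseCV` on every measurement
#' cycle. With the default truth the level ordering is
#' baseline > post-oligomycin > post-rotenone/antimycin and
#' post-FCCP >= baseline, so extracted parameters are positive.
#'
#' @param design an [ExperimentDesign-class].
#' @param truth a [GroundTruth-class].
#' @param cyclesPerPhase measurement cycles per phase (>= 1; default 3).
#' @param noiseCV coefficient of variation (>= 0; default 0.03).
#' @return data.frame with columns `well`, `condition`, `time_min`, `ocr`,
#'   `phase`, `true_level`; OCR in pmol O2 min^-1 (1000 cells)^-1.
#' @export
simulateOCRTraces <- function(design, truth = defaultGroundTruth(),
                              cyclesPerPhase = 3L, noiseCV = 0.03) {
  stopifnot(is(design, "ExperimentDesign"), is(truth, "GroundTruth"))
  if (cyclesPerPhase < 1L) stop("'cyclesPerPhase' must be >= 1")
  if (noiseCV < 0) stop("'noiseCV' must be >= 0")
  ph <- truth@ocrPhases
  if (any(as.matrix(ph[.PHASES]) <= 0)) {
    stop("all true OCR phase levels must be positive")
  }
  set.seed(.substreamSeed(design@seed, "ocr"))
  n_cycle <- 4L * cyclesPerPhase
  times <- seq_len(n_cycle) * 6.5
  phase_seq <- rep(.PHASES, each = cyclesPerPhase)
  out <- do.call(rbind, lapply(design@conditions, function(cn) {
    row <- ph[ph$condition == cn, ]
    if (!nrow(row)) stop("no true OCR levels for condition '", cn, "'")
    levels_seq <- rep(
      as.numeric(row[1, .PHASES]),
      each = cyclesPerPhase
    )
    do.call(rbind, lapply(seq_len(design@replicates), function(r) {
      data.frame(
        well = sprintf("%s_%02d", cn, r),
        condition = cn,
        time_min = times,
        ocr = .mnoise(levels_seq, noiseCV),
        phase = phase_seq,
        true_level = levels_seq,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' True Mito-Stress parameters implied by the ground truth
#'
#' The parameters a noiseless trace of the given condition yields; the
#' recovery target for Monte-Carlo tests.
#'
#' @param truth a [GroundTruth-class].
#' @param condition condition label.
#' @return a [MitoParams-class].
#' @export
trueMitoParams <- function(truth, condition) {
  ph <- truth@ocrPhases
  row <- ph[ph$condition == condition, ]
  if (!nrow(row)) stop("unknown condition '", condition, "'")
  trace <- data.frame(
    time_min = 1:4,
    ocr = as.numeric(row[1, .PHASES]),
    phase = .PHASES
  )
  extractMitoParams(trace)
}
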