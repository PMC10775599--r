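#' @include AllGenerics.R
NULL

.PHASES <- c("baseline", "oligo", "fccp", "rotAA")

#' ATP-yield stoichiometry constants
#'
#' Defaults encode the molar yields the budget is built on: net 2 ATP per
#' glucose converted to lactate; a maximum of 30 ATP per glucose fully
#' oxidised; 10 ATP per glutamine oxidised at a cost of 2 O2. The implied
#' ATP:O2 conversion is 5 either way (10/2 and 30/6), so the single constant
#' returned by [atpPerO2()] is used for the OCR-to-ATP conversion. All four
#' yields are configurable; they are parameters of the budget, not hard-coded
#' inside the operations.
#'
#' @param atpPerGlucoseGlycolysis net glycolytic ATP per glucose (default 2).
#' @param atpPerGlucoseOxidation maximal oxidative ATP per glucose
#'   (default 30).
#' @param atpPerGlutamine ATP per glutamine (default 10).
#' @param o2PerGlutamine O2 per glutamine (default 2).
#' @return a [StoichiometryConstants-class].
#' @examples
#' k <- stoichiometryConstants()
#' atpPerO2(k)  # 5
#' @export
stoichiometryConstants <- function(atpPerGlucoseGlycolysis = 2,
                                   atpPerGlucoseOxidation = 30,
                                   atpPerGlutamine = 10,
                                   o2PerGlutamine = 2) {
  new("StoichiometryConstants",
    atpPerGlucoseGlycolysis = atpPerGlucoseGlycolysis,
    atpPerGlucoseOxidation = atpPerGlucoseOxidation,
    atpPerGlutamine = atpPerGlutamine,
    o2PerGlutamine = o2PerGlutamine
  )
}

#' @rdname atpPerO2
#' @export
setMethod("atpPerO2", "StoichiometryConstants", function(object) {
  object@atpPerGlutamine / object@o2PerGlutamine
})

setMethod("show", "StoichiometryConstants", function(object) {
  cat("StoichiometryConstants:\n")
  cat("  glycolysis:", object@atpPerGlucoseGlycolysis, "ATP / glucose\n")
  cat("  oxidation: ", object@atpPerGlucoseOxidation, "ATP / glucose\n")
  cat(
    "  glutamine: ", object@atpPerGlutamine, "ATP /", object@o2PerGlutamine,
    "O2  (", atpPerO2(object), "ATP per O2 )\n"
  )
  invisible(NULL)
})

#' Extract Mito-Stress parameters from an oxygen-consumption trace
#'
#' Summarises the four injection phases of a Mito Stress run and derives the
#' six respiratory parameters. The phase summaries follow the standard
#' convention — last baseline cycle, minimum after oligomycin, maximum after
#' FCCP, minimum after rotenone/antimycin A — with per-phase means selectable
#' instead. The rotenone/antimycin floor is the non-mitochondrial rate and is
#' subtracted from every other level. Negative corrected rates are retained
#' and flagged `"negative_rate"`, never clamped. A trace with non-positive
#' basal respiration leaves the coupling efficiency undefined (`NA`, flag
#' `"coupling_undefined"`).
#'
#' @param trace data.frame with columns `time_min`, `ocr`
#'   (pmol O2 min^-1 (1000 cells)^-1) and `phase`
#'   (one of `"baseline"`, `"oligo"`, `"fccp"`, `"rotAA"`, in that order).
#' @param summary named character vector choosing per-phase statistics;
#'   entries from `c(baseline=, oligo=, fccp=, rotAA=)` with values
#'   `"last"`, `"min"`, `"max"` or `"mean"`.
#' @return a [MitoParams-class].
#' @examples
#' tr <- data.frame(
#'   time_min = 1:4 * 6.5,
#'   ocr = c(100, 40, 180, 20),
#'   phase = c("baseline", "oligo", "fccp", "rotAA")
#' )
#' extractMitoParams(tr)
#' @export
extractMitoParams <- function(trace,
                              summary = c(
                                baseline = "last", oligo = "min",
                                fccp = "max", rotAA = "min"
                              )) {
  if (!is.data.frame(trace) || !all(c("ocr", "phase") %in% names(trace))) {
    stop("'trace' must be a data.frame with columns 'ocr' and 'phase'")
  }
  phase <- as.character(trace$phase)
  missing_ph <- setdiff(.PHASES, unique(phase))
  if (length(missing_ph)) {
    stop("trace is missing phase(s): ", paste(missing_ph, collapse = ", "))
  }
  runs <- rle(phase)$values
  if (!identical(runs, .PHASES)) {
    stop(
      "phases must appear contiguously in the order ",
      paste(.PHASES, collapse = " -> ")
    )
  }
  if (any(!is.finite(trace$ocr))) stop("all OCR values must be finite")
  stat <- function(x, how) {
    switch(how,
      last = x[length(x)], min = min(x), max = max(x), mean = mean(x),
      stop("unknown phase summary '", how, "'")
    )
  }
  lev <- vapply(
    .PHASES,
    function(p) stat(trace$ocr[phase == p], summary[[p]]),
    numeric(1)
  )
  non_mito <- lev[["rotAA"]]
  basal <- lev[["baseline"]] - non_mito
  leak <- lev[["oligo"]] - non_mito
  atp_linked <- basal - leak
  maximal <- lev[["fccp"]] - non_mito
  spare <- maximal - basal
  fl <- character()
  if (any(c(basal, leak, atp_linked, maximal, spare) < 0)) {
    fl <- c(fl, "negative_rate")
  }
  if (basal > 0) {
    coupling <- atp_linked / basal
  } else {
    coupling <- NA_real_
    fl <- c(fl, "coupling_undefined")
  }
  new("MitoParams",
    nonMito = non_mito, basal = basal, atpLinked = atp_linked,
    protonLeak = leak, maximal = maximal, spare = spare,
    couplingEfficiency = coupling, flags = fl
  )
}

#' @rdname mito-accessors
#' @export
setMethod("basalRespiration", "MitoParams", function(object) object@basal)

#' @rdname mito-accessors
#' @export
setMethod("protonLeak", "MitoParams", function(object) object@protonLeak)

#' @rdname mito-accessors
#' @export
setMethod("atpLinkedRespiration", "MitoParams", function(object) object@atpLinked)

#' @rdname mito-accessors
#' @export
setMethod("maximalRespiration", "MitoParams", function(object) object@maximal)

#' @rdname mito-accessors
#' @export
setMethod("spareCapacity", "MitoParams", function(object) object@spare)

#' @rdname mito-accessors
#' @export
setMethod("nonMitoRespiration", "MitoParams", function(object) object@nonMito)

#' @rdname mito-accessors
#' @export
setMethod("couplingEfficiency", "MitoParams", function(object) {
  object@couplingEfficiency
})

#' @rdname calibration-accessors
#' @export
setMethod("flags", "MitoParams", function(object) object@flags)

setMethod("show", "MitoParams", function(object) {
  cat("MitoParams (pmol O2 / min / 1000 cells):\n")
  cat(sprintf(
    "  non-mito %.4g | basal %.4g | ATP-linked %.4g | leak %.4g\n",
    object@nonMito, object@basal, object@atpLinked, object@protonLeak
  ))
  cat(sprintf(
    "  maximal %.4g | spare %.4g | coupling %.4g\n",
    object@maximal, object@spare, object@couplingEfficiency
  ))
  if (length(object@flags)) {
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Stoichiometric ATP-yield conversions
#'
#' Linear molar conversions between substrate fluxes, oxygen consumption and
#' ATP production rates. All are homogeneous: `f(a * x) = a * f(x)`.
#' `glycolyticATP` applies the net glycolytic yield; `maxOxidativeATPFromGlucose`
#' the maximal oxidative yield; `maxATPFromGlutamine` the glutamine yield;
#' `mitoATPFromOCR` converts ATP-synthesis-linked oxygen consumption to ATP
#' production at [atpPerO2()] ATP per O2; `glutamineRequired` inverts the
#' glutamine yield to give the glutamine flux (and the oxygen it would
#' consume) needed to fuel a given mitochondrial ATP production rate.
#'
#' @param glucoseFlux,glutamineFlux,atpLinkedOCR,mitoATPFlux input flux
#'   (pmol min^-1 (1000 cells)^-1); `atpLinkedOCR` and `mitoATPFlux` must be
#'   >= 0.
#' @param k a [StoichiometryConstants-class] (default
#'   [stoichiometryConstants()]).
#' @param measuredGlutamineFlux optional measured glutamine consumption; when
#'   supplied, `glutamineRequired` adds a `sufficient` attribute
#'   (`measured >= required`).
#' @return numeric ATP (or substrate) flux in the input units;
#'   `glutamineRequired` returns the required glutamine flux with attribute
#'   `o2Required` (and optionally `sufficient`).
#' @examples
#' glycolyticATP(1)             # 2
#' maxOxidativeATPFromGlucose(1)  # 30
#' maxATPFromGlutamine(1)       # 10
#' mitoATPFromOCR(6)            # 30: one glucose worth of O2
#' glutamineRequired(10)        # 1 (needing 2 O2)
#' @name atp-yields
NULL

#' @rdname atp-yields
#' @export
glycolyticATP <- function(glucoseFlux, k = stoichiometryConstants()) {
  k@atpPerGlucoseGlycolysis * as.numeric(glucoseFlux)
}

#' @rdname atp-yields
#' @export
maxOxidativeATPFromGlucose <- function(glucoseFlux,
                                       k = stoichiometryConstants()) {
  k@atpPerGlucoseOxidation * as.numeric(glucoseFlux)
}

#' @rdname atp-yields
#' @export
maxATPFromGlutamine <- function(glutamineFlux, k = stoichiometryConstants()) {
  k@atpPerGlutamine * as.numeric(glutamineFlux)
}

#' @rdname atp-yields
#' @export
mitoATPFromOCR <- function(atpLinkedOCR, k = stoichiometryConstants()) {
  if (any(atpLinkedOCR < 0)) {
    stop("'atpLinkedOCR' must be >= 0")
  }
  atpPerO2(k) * as.numeric(atpLinkedOCR)
}

#' @rdname atp-yields
#' @export
glutamineRequired <- function(mitoATPFlux, k = stoichiometryConstants(),
                              measuredGlutamineFlux = NULL) {
  if (any(mitoATPFlux < 0)) stop("'mitoATPFlux' must be >= 0")
  required <- as.numeric(mitoATPFlux) / k@atpPerGlutamine
  attr(required, "o2Required") <- k@o2PerGlutamine * required
  if (!is.null(measuredGlutamineFlux)) {
    attr(required, "sufficient") <- measuredGlutamineFlux >= required
  }
  required
}
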