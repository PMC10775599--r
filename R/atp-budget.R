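#' @include bioenergetics.R
NULL

#' Build the nine-panel ATP budget for one condition
#'
#' Combines the measured substrate fluxes, the Mito-Stress parameters and the
#' measured cellular ATP content of one condition into the full budget:
#' glycolytic ATP from glucose consumption, maximal oxidative ATP were the
#' same glucose fully oxidised, mitochondrial ATP production from the
#' ATP-synthesis-linked oxygen consumption, the glutamine equivalents, total
#' production capacity (glycolytic + mitochondrial), the glycolysis/OXPHOS
#' split of that total, and the glutamine flux required to fuel the
#' mitochondrial production (the red line), with a sufficiency flag against
#' the measured glutamine consumption. The ATP content is an independent
#' measurement and is carried through untouched — the budget compares
#' production capacity against content, it never derives one from the other.
#'
#' @param fluxes data.frame of flux records (from [fluxNormalize()]) holding
#'   at least rows with `substrate == "glucose"` and `substrate == "glutamine"`
#'   for this condition; multiple rows per substrate are averaged.
#' @param params a [MitoParams-class] for the same condition.
#' @param atpContent measured cellular ATP content (panel 8), any unit.
#' @param k a [StoichiometryConstants-class].
#' @param condition condition label stored in the result.
#' @return an [ATPBudget-class].
#' @examples
#' fx <- rbind(
#'   fluxNormalize(2e-3, 1, 2880, 1e5, substrate = "glucose"),
#'   fluxNormalize(5e-4, 1, 2880, 1e5, substrate = "glutamine")
#' )
#' tr <- data.frame(
#'   time_min = 1:4, ocr = c(10, 4, 18, 2),
#'   phase = c("baseline", "oligo", "fccp", "rotAA")
#' )
#' buildATPBudget(fx, extractMitoParams(tr), atpContent = 1, condition = "ctrl")
#' @export
buildATPBudget <- function(fluxes, params, atpContent,
                           k = stoichiometryConstants(),
                           condition = NA_character_) {
  if (missing(fluxes) || !is.data.frame(fluxes)) {
    stop("panel 1/5 input missing: 'fluxes' must be a flux-record data.frame")
  }
  if (missing(params) || !is(params, "MitoParams")) {
    stop("panel 4 input missing: 'params' must be a MitoParams object")
  }
  if (missing(atpContent)) {
    stop("panel 8 input missing: 'atpContent' is required")
  }
  pick <- function(substrate, panel) {
    fx <- fluxes$flux[fluxes$substrate == substrate]
    if (!length(fx)) {
      stop("panel ", panel, " input missing: no '", substrate, "' flux record")
    }
    mean(fx)
  }
  glucose <- pick("glucose", 1)
  glutamine <- pick("glutamine", 5)

  glyc <- glycolyticATP(glucose, k)
  max_ox <- maxOxidativeATPFromGlucose(glucose, k)
  mito <- mitoATPFromOCR(max(params@atpLinked, 0), k)
  gln_max <- maxATPFromGlutamine(glutamine, k)
  total <- glyc + mito
  if (total > 0) {
    f_glyc <- glyc / total
    f_ox <- mito / total
  } else {
    f_glyc <- NA_real_
    f_ox <- NA_real_
  }
  required <- glutamineRequired(mito, k)
  new("ATPBudget",
    condition = as.character(condition),
    glucoseFlux = glucose,
    glycolyticATP = glyc,
    maxOxATPFromGlucose = max_ox,
    mitoATPFromOCR = mito,
    glutamineFlux = glutamine,
    maxATPFromGlutamine = gln_max,
    totalATPCapacity = total,
    measuredATPContent = as.numeric(atpContent),
    fractionGlycolysis = f_glyc,
    fractionOxphos = f_ox,
    glnRequired = as.numeric(required),
    o2Required = attr(required, "o2Required"),
    glnSufficient = glutamine >= as.numeric(required)
  )
}

#' Flatten an ATP budget to a one-row data.frame
#'
#' @param budget an [ATPBudget-class].
#' @return one-row data.frame with a column per panel quantity.
#' @export
atpBudgetTable <- function(budget) {
  stopifnot(is(budget, "ATPBudget"))
  data.frame(
    condition = budget@condition,
    glucose_flux = budget@glucoseFlux,
    glycolytic_atp = budget@glycolyticATP,
    max_ox_atp_from_glucose = budget@maxOxATPFromGlucose,
    mito_atp_from_ocr = budget@mitoATPFromOCR,
    glutamine_flux = budget@glutamineFlux,
    max_atp_from_glutamine = budget@maxATPFromGlutamine,
    total_atp_capacity = budget@totalATPCapacity,
    measured_atp_content = budget@measuredATPContent,
    fraction_glycolysis = budget@fractionGlycolysis,
    fraction_oxphos = budget@fractionOxphos,
    glutamine_required = budget@glnRequired,
    o2_required = budget@o2Required,
    glutamine_sufficient = budget@glnSufficient,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "ATPBudget", function(object) {
  cat("ATPBudget [", object@condition, "] (pmol ATP / min / 1000 cells):\n")
  cat(sprintf(
    "  glucose flux %.4g -> glycolytic %.4g | max oxidative %.4g\n",
    object@glucoseFlux, object@glycolyticATP, object@maxOxATPFromGlucose
  ))
  cat(sprintf(
    "  mito (from OCR) %.4g | glutamine flux %.4g -> max %.4g\n",
    object@mitoATPFromOCR, object@glutamineFlux, object@maxATPFromGlutamine
  ))
  cat(sprintf(
    "  total capacity %.4g (glycolysis %.3f / OXPHOS %.3f) | content %.4g\n",
    object@totalATPCapacity, object@fractionGlycolysis,
    object@fractionOxphos, object@measuredATPContent
  ))
  cat(sprintf(
    "  glutamine required %.4g (O2 %.4g) -> %s\n",
    object@glnRequired, object@o2Required,
    if (object@glnSufficient) "sufficient" else "INSUFFICIENT"
  ))
  invisible(NULL)
})
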