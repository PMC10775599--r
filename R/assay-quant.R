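#' @include calibration.R
NULL

#' Concentration change relative to fresh medium
#'
#' Consumption is `medium - sample`, production `sample - medium`, both in
#' mmol/l. Lactate deltas measured under the lactic-acidosis condition are
#' marked unreliable regardless of their numeric value: the 24 mmol/l lactate
#' background swamps the cells' own production, so a reliable delta-lactate
#' can only be determined for hydrochloric acidosis.
#'
#' @param sampleConc supernatant concentration after treatment, mmol/l (>= 0).
#' @param mediumConc concentration in fresh medium, mmol/l (>= 0).
#' @param direction `"consumption"` or `"production"`.
#' @param substrate optional substrate label (used for the lactate/LA rule).
#' @param condition optional condition label(s).
#' @return numeric vector of deltas with a logical attribute `reliable`.
#' @examples
#' mediumDelta(4.5, 5.5, "consumption")                       # 1.0
#' d <- mediumDelta(26, 24, "production", "lactate", "LA")
#' attr(d, "reliable")                                        # FALSE
#' @export
mediumDelta <- function(sampleConc, mediumConc,
                        direction = c("consumption", "production"),
                        substrate = NULL, condition = NULL) {
  direction <- match.arg(direction)
  sampleConc <- as.numeric(sampleConc)
  mediumConc <- as.numeric(mediumConc)
  if (any(sampleConc < 0, na.rm = TRUE) || any(mediumConc < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0")
  }
  delta <- if (direction == "consumption") {
    mediumConc - sampleConc
  } else {
    sampleConc - mediumConc
  }
  reliable <- rep(TRUE, length(delta))
  if (!is.null(substrate) && !is.null(condition)) {
    reliable <- !(rep_len(substrate, length(delta)) == "lactate" &
                    rep_len(condition, length(delta)) == "LA")
  }
  attr(delta, "reliable") <- reliable
  delta
}

#' Normalize a concentration change to a per-cell flux
#'
#' Converts a concentration change over the treatment interval to
#' pmol min^-1 (1000 cells)^-1:
#' `flux = delta * volume * 1e9 / duration / (cells / 1000)`
#' (1 mmol = 1e9 pmol). The well volume has no default: it must be supplied
#' explicitly for every conversion.
#'
#' @param delta concentration change, mmol/l (sign as produced by
#'   [mediumDelta()]).
#' @param volume well volume in litres (> 0).
#' @param duration treatment duration in minutes (> 0).
#' @param cells cell count per well (> 0).
#' @param substrate,condition optional labels carried into the record.
#' @param reliable logical; defaults to the `reliable` attribute of `delta`
#'   when present, else `TRUE`.
#' @return a data.frame (one row per delta) with columns `substrate`,
#'   `condition`, `delta`, `volume`, `duration`, `cells`, `flux`, `reliable`.
#' @examples
#' # 1 umol consumed in a 1 l well over 48 h by 100,000 cells:
#' fluxNormalize(1e-3, 1, 2880, 1e5)$flux  # ~3.472
#' @export
fluxNormalize <- function(delta, volume, duration, cells,
                          substrate = NA_character_, condition = NA_character_,
                          reliable = NULL) {
  if (any(duration <= 0)) stop("'duration' must be > 0")
  if (any(cells <= 0)) stop("'cells' must be > 0")
  if (any(volume <= 0)) stop("'volume' must be > 0")
  if (is.null(reliable)) {
    reliable <- attr(delta, "reliable")
    if (is.null(reliable)) reliable <- TRUE
  }
  delta <- as.numeric(delta)
  flux <- delta * volume * 1e9 / duration / (cells / 1000)
  data.frame(
    substrate = rep_len(substrate, length(delta)),
    condition = rep_len(condition, length(delta)),
    delta = delta,
    volume = rep_len(volume, length(delta)),
    duration = rep_len(duration, length(delta)),
    cells = rep_len(cells, length(delta)),
    flux = flux,
    reliable = rep_len(reliable, length(delta)),
    stringsAsFactors = FALSE
  )
}

#' Molar lactate-production to glucose-consumption ratio
#'
#' A ratio of 2 indicates purely glycolytic glucose disposal (each glucose
#' yields two lactate); the result carries a `pure_glycolysis` attribute set
#' when the ratio falls within `tol` of 2. A zero glucose flux leaves the
#' ratio undefined (`NA`, flagged `"undefined"`); an unreliable lactate flux
#' is an error because the ratio would be meaningless.
#'
#' @param lactateFlux lactate production flux.
#' @param glucoseFlux glucose consumption flux (same units).
#' @param reliable logical, whether the lactate flux is reliable.
#' @param tol half-width of the window around 2 tagged as pure glycolysis.
#' @return single numeric with attributes `pure_glycolysis` and `flags`.
#' @export
lactateGlucoseRatio <- function(lactateFlux, glucoseFlux, reliable = TRUE,
                                tol = 0.1) {
  if (!isTRUE(reliable)) {
    stop("lactate flux is not reliable; ratio not computed")
  }
  fl <- character()
  if (glucoseFlux == 0) {
    ratio <- NA_real_
    fl <- "undefined"
  } else {
    ratio <- lactateFlux / glucoseFlux
  }
  attr(ratio, "pure_glycolysis") <- is.finite(ratio) && abs(ratio - 2) <= tol
  attr(ratio, "flags") <- fl
  ratio
}

#' Fraction of lactate dehydrogenase released into the medium
#'
#' Necrosis marker: `media / (media + lysate)` from LDH activities measured
#' in the supernatant and in the cell lysate.
#'
#' @param mediaActivity LDH activity in the supernatant (>= 0).
#' @param lysateActivity LDH activity in the lysate (>= 0).
#' @return numeric in \[0, 1\].
#' @export
ldhReleaseFraction <- function(mediaActivity, lysateActivity) {
  mediaActivity <- as.numeric(mediaActivity)
  lysateActivity <- as.numeric(lysateActivity)
  if (any(mediaActivity < 0) || any(lysateActivity < 0)) {
    stop("activities must be >= 0")
  }
  total <- mediaActivity + lysateActivity
  if (any(total == 0)) {
    stop("media and lysate activity must not both be zero")
  }
  mediaActivity / total
}

#' Protein-normalized specific activity
#'
#' Amount of substrate converted per minute per microgram protein, the
#' normalization applied to caspase (cleaved AFC), ALPL and ENPP1 readouts.
#'
#' @param amountConverted amount converted (e.g. nmol).
#' @param time incubation time, minutes (> 0).
#' @param protein protein amount, micrograms (> 0).
#' @return numeric, amount min^-1 ug^-1.
#' @examples
#' specificActivity(90, 90, 10)  # 0.1
#' @export
specificActivity <- function(amountConverted, time, protein) {
  if (any(time <= 0)) stop("'time' must be > 0")
  if (any(protein <= 0)) stop("'protein' must be > 0")
  as.numeric(amountConverted) / time / protein
}
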