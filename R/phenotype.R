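#' @include assay-quant.R
NULL

#' Senescence index from C12FDG and Hoechst counts
#'
#' Senescence-associated beta-galactosidase signal per nucleus: C12FDG-positive
#' counts divided by Hoechst (nuclei) counts.
#'
#' @param c12fdgCount C12FDG-positive event count (>= 0).
#' @param hoechstCount Hoechst nuclei count (> 0).
#' @return numeric ratio.
#' @export
senescenceIndex <- function(c12fdgCount, hoechstCount) {
  if (any(hoechstCount <= 0)) stop("'hoechstCount' must be > 0")
  if (any(c12fdgCount < 0)) stop("'c12fdgCount' must be >= 0")
  as.numeric(c12fdgCount) / hoechstCount
}

#' Cell-shape circularity
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle (round cells),
#' values near 0 for elongated, spindle-shaped cells. Pixel discretization of
#' the perimeter can push the raw value marginally above 1; such values are
#' clipped to 1 and flagged `"clipped"`.
#'
#' @param area cell area (> 0), any consistent unit.
#' @param perimeter cell perimeter (> 0), same length unit.
#' @return numeric vector in \[0, 1\] with attribute `flags`.
#' @examples
#' circularity(pi, 2 * pi)  # circle of radius 1 -> 1
#' circularity(1, 4)        # unit square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0)) stop("'area' must be > 0")
  if (any(perimeter <= 0)) stop("'perimeter' must be > 0")
  raw <- 4 * pi * as.numeric(area) / perimeter^2
  fl <- lapply(raw, function(x) if (x > 1) "clipped" else character())
  out <- pmin(raw, 1)
  attr(out, "flags") <- fl
  out
}

#' Protein-per-cell hypertrophy index relative to control
#'
#' Hypertrophy marker: protein amount per cell, expressed relative to the
#' control condition, so the control maps to 1 and a hypertrophic condition
#' to a value above 1.
#'
#' @param proteinPerWell protein amount in the treated wells.
#' @param cellsPerWell cell count in the treated wells (> 0).
#' @param proteinCtrl,cellsCtrl the control-condition reference (required).
#' @return numeric vector, fold protein/cell relative to control.
#' @export
hypertrophyIndex <- function(proteinPerWell, cellsPerWell,
                             proteinCtrl, cellsCtrl) {
  if (missing(proteinCtrl) || missing(cellsCtrl)) {
    stop("control reference ('proteinCtrl', 'cellsCtrl') is required")
  }
  if (any(cellsPerWell <= 0) || any(cellsCtrl <= 0)) {
    stop("cell counts must be > 0")
  }
  (as.numeric(proteinPerWell) / cellsPerWell) / (proteinCtrl / cellsCtrl)
}
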