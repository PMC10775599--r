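#' @include AllGenerics.R
NULL

#' Fit a linear calibration curve to assay standards
#'
#' Ordinary least squares of signal on amount, with intercept. The blank is
#' the fitted signal at amount zero. A curve whose coefficient of
#' determination falls below `r2Warn` is flagged `"low_r_squared"` but not
#' rejected; a degenerate series (all amounts identical, or zero slope) is an
#' error because it cannot be inverted.
#'
#' @param standards data.frame with numeric columns `amount` and `signal`,
#'   one row per standard (include the blank as amount 0).
#' @param r2Warn r-squared below which the curve is flagged (default 0.98).
#' @return a [CalibrationCurve-class].
#' @examples
#' cc <- fitCalibration(data.frame(amount = 0:2, signal = c(0, 0.5, 1)))
#' slope(cc)      # 0.5
#' rSquared(cc)   # 1
#' @export
fitCalibration <- function(standards, r2Warn = 0.98) {
  if (!is.data.frame(standards) ||
      !all(c("amount", "signal") %in% names(standards))) {
    stop("'standards' must be a data.frame with columns 'amount' and 'signal'")
  }
  amount <- as.numeric(standards$amount)
  signal <- as.numeric(standards$signal)
  keep <- is.finite(amount) & is.finite(signal)
  amount <- amount[keep]
  signal <- signal[keep]
  if (length(unique(amount)) < 2L) {
    stop("at least two distinct standard amounts are required")
  }
  if (sum((amount - mean(amount)) * (signal - mean(signal))) == 0) {
    stop("degenerate calibration: fitted slope is zero")
  }
  fit <- stats::lm(signal ~ amount)
  b <- unname(stats::coef(fit))
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  fl <- character()
  if (!is.na(r2) && r2 < r2Warn) fl <- "low_r_squared"
  new("CalibrationCurve",
    slope = b[2], intercept = b[1], rSquared = r2, blank = b[1],
    nStandards = length(amount), flags = fl
  )
}

#' Quantify a sample signal against a calibration curve
#'
#' Inverts the standard curve: `amount = (signal - intercept) / slope`.
#' Amounts below the blank come out negative; they are retained (so replicate
#' averages stay unbiased) and flagged `"below_blank"` in the `"flags"`
#' attribute of the result.
#'
#' @param signal numeric vector of raw plate-reader signals.
#' @param curve a [CalibrationCurve-class].
#' @return numeric vector of amounts, with attribute `flags` (a list, one
#'   character vector per element).
#' @export
quantify <- function(signal, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  validObject(curve)
  amount <- (as.numeric(signal) - curve@intercept) / curve@slope
  fl <- lapply(amount, function(a) {
    if (is.finite(a) && a < 0) "below_blank" else character()
  })
  attr(amount, "flags") <- fl
  amount
}

#' Construct a two-point pH calibration
#'
#' @param ph numeric of length 2: the nigericin-clamped pH values.
#' @param ratio numeric of length 2: the BCECF ratios measured at those pH
#'   values.
#' @return a [PhCalibration-class].
#' @export
phCalibration <- function(ph, ratio) {
  if (length(ratio) == 2L && ratio[1] == ratio[2]) {
    stop("the two calibration ratios must differ")
  }
  new("PhCalibration", ph = as.numeric(ph), ratio = as.numeric(ratio))
}

#' Convert a BCECF ratio to intracellular pH
#'
#' Linear interpolation in (ratio, pH) between the two nigericin calibration
#' points. Ratios outside the calibrated interval are extrapolated with the
#' same line and flagged `"extrapolated"` rather than blocked: two points
#' admit no richer model, and clipping would bias replicate averages.
#'
#' @param R numeric vector of BCECF fluorescence ratios.
#' @param cal a [PhCalibration-class].
#' @return numeric vector of pH values with attribute `flags`.
#' @examples
#' cal <- phCalibration(ph = c(6.8, 7.5), ratio = c(1.2, 2.0))
#' phFromRatio(1.6, cal)  # midway: (6.8 + 7.5) / 2
#' @export
phFromRatio <- function(R, cal) {
  stopifnot(is(cal, "PhCalibration"))
  validObject(cal)
  m <- (cal@ph[2] - cal@ph[1]) / (cal@ratio[2] - cal@ratio[1])
  ph <- cal@ph[1] + m * (as.numeric(R) - cal@ratio[1])
  lo <- min(cal@ratio)
  hi <- max(cal@ratio)
  fl <- lapply(as.numeric(R), function(r) {
    if (is.finite(r) && (r < lo || r > hi)) "extrapolated" else character()
  })
  attr(ph, "flags") <- fl
  ph
}

#' @rdname calibration-accessors
#' @export
setMethod("slope", "CalibrationCurve", function(object) object@slope)

#' @rdname calibration-accessors
#' @export
setMethod("intercept", "CalibrationCurve", function(object) object@intercept)

#' @rdname calibration-accessors
#' @export
setMethod("rSquared", "CalibrationCurve", function(object) object@rSquared)

#' @rdname calibration-accessors
#' @export
setMethod("blankSignal", "CalibrationCurve", function(object) object@blank)

#' @rdname calibration-accessors
#' @export
setMethod("nStandards", "CalibrationCurve", function(object) object@nStandards)

#' @rdname calibration-accessors
#' @export
setMethod("flags", "CalibrationCurve", function(object) object@flags)

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve:", object@nStandards, "standards\n")
  cat(sprintf(
    "  signal = %.6g * amount + %.6g   (r^2 = %.4f)\n",
    object@slope, object@intercept, object@rSquared
  ))
  if (length(object@flags)) {
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "PhCalibration", function(object) {
  cat("PhCalibration (nigericin two-point):\n")
  cat(sprintf(
    "  pH %.2f at ratio %.4g; pH %.2f at ratio %.4g\n",
    object@ph[1], object@ratio[1], object@ph[2], object@ratio[2]
  ))
  invisible(NULL)
})
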