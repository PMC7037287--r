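#' Fit a calibration curve and derive detection limits
#'
#' Ordinary least-squares line through (level, response) calibration points.
#' The limit of detection and quantification follow the calibration-curve
#' method: LoD = 3 SD / s and LoQ = 10 SD / s, with s the fitted slope and SD
#' the standard deviation of the regression residuals (n - 2 denominator).
#'
#' @param points Data frame with columns \code{level} and \code{response},
#'   at least 3 distinct levels.
#' @return An object of class \code{calibration_curve} with fields
#'   \code{slope}, \code{intercept}, \code{resid_sd}, \code{lod}, \code{loq}
#'   and \code{n}.
#' @examples
#' fit_calibration(generate_calibration(seed = 7, slope = 2, resid_sd = 0.1))
#' @export
fit_calibration <- function(points) {
  stopifnot(all(c("level", "response") %in% names(points)))
  if (length(unique(points$level)) < 3)
    stop("at least 3 distinct calibration levels are required")
  fit <- stats::lm(response ~ level, data = points)
  s <- unname(stats::coef(fit)[2])
  if (is.na(s) || s <= 0)
    stop("fitted slope is not positive; detection limits are undefined")
  resid_sd <- sqrt(sum(stats::residuals(fit)^2) / (nrow(points) - 2))
  out <- list(slope = s, intercept = unname(stats::coef(fit)[1]),
              resid_sd = resid_sd,
              lod = 3 * resid_sd / s, loq = 10 * resid_sd / s,
              n = nrow(points))
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve (", x$n, " points)\n", sep = "")
  cat(sprintf("  slope %.6g, intercept %.6g, residual SD %.6g\n",
              x$slope, x$intercept, x$resid_sd))
  cat(sprintf("  LoD = %.6g, LoQ = %.6g (concentration units)\n",
              x$lod, x$loq))
  invisible(x)
}

#' Analytical recovery percentage
#'
#' @param measured Measured concentration(s).
#' @param expected Expected (spiked) concentration, strictly positive.
#' @return 100 * measured / expected.
#' @examples
#' recovery_pct(0.8732, 1) # 87.32
#' @export
recovery_pct <- function(measured, expected) {
  if (any(expected <= 0)) stop("expected concentration must be positive")
  100 * measured / expected
}
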