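#' Fit the fraction-to-molecular-weight calibration
#'
#' SEC fraction number and apparent molecular weight follow a log-linear
#' relationship; protein standards of known MW define an ordinary
#' least-squares fit of `log10(MW kDa) = slope * fraction + intercept`.
#' Larger assemblies elute earlier, so the slope must be negative.
#'
#' @param standards data.frame with columns `fraction_index`, `mw_kda`
#'   (>= 2 distinct points, all MW > 0).
#' @return `fraction_calibration` object: slope, intercept, r_squared and the
#'   fit points.
#' @export
fit_calibration <- function(standards) {
  s <- as.data.table(standards)
  if (!all(c("fraction_index", "mw_kda") %in% names(s))) {
    stop2("standards need columns fraction_index, mw_kda")
  }
  if (nrow(s) < 2L || uniqueN(s$fraction_index) < 2L) {
    stop2("need at least 2 distinct calibration standards")
  }
  if (any(!is.finite(s$mw_kda) | s$mw_kda <= 0)) stop2("standard MW must be > 0")
  fit <- stats::lm(log10(mw_kda) ~ fraction_index, data = s)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop2("calibration slope must be negative (MW decreases with fraction)")
  }
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    ## exact standards trip summary.lm's perfect-fit warning; R^2 = 1 is fine
    r_squared = suppressWarnings(summary(fit)$r.squared),
    fit_points = s[, .(fraction_index, mw_kda)]
  ), class = "fraction_calibration")
}

#' Read calibration standards and fit
#' @param path TSV with header `fraction_index`, `mw_kda`.
#' @export
read_calibration <- function(path) fit_calibration(fread(path, sep = "\t"))

#' Convert molecular weight to (fractional) fraction index
#'
#' May return values outside the measured grid; clamping is the caller's
#' responsibility (see [assembled_cutoff_fraction()]).
#'
#' @param cal `fraction_calibration`.
#' @param mw molecular weight in kDa (> 0), vectorized.
#' @export
mw_to_fraction <- function(cal, mw) {
  stopifnot(inherits(cal, "fraction_calibration"))
  if (any(!is.finite(mw) | mw <= 0)) stop2("mw must be > 0")
  (log10(mw) - cal$intercept) / cal$slope
}

#' Convert fraction index to apparent molecular weight (kDa)
#' @param cal `fraction_calibration`.
#' @param fraction fraction index (may be fractional), vectorized.
#' @export
fraction_to_mw <- function(cal, fraction) {
  stopifnot(inherits(cal, "fraction_calibration"))
  10^(cal$slope * fraction + cal$intercept)
}

#' @export
print.fraction_calibration <- function(x, ...) {
  cat(sprintf("<fraction_calibration> log10(MW kDa) = %.5g * fraction + %.5g (R^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$fit_points)))
  invisible(x)
}
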