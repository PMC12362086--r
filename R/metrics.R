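#' Average absolute relative deviation (AARD)
#'
#' AARD (%) = 100/N * sum(|T_meas - T_pred| / T_meas). The companion [ard()]
#' drops the absolute value and so carries the sign of the mean deviation.
#'
#' @param measured,predicted Equal-length numeric vectors; `measured` must be
#'   nonzero.
#' @return Percentage deviation.
#' @export
#' @examples
#' aard(c(350, 340), c(343, 340)) # 1.0
aard <- function(measured, predicted) {
  check_dev_args(measured, predicted)
  100 * mean(abs(measured - predicted) / abs(measured))
}

#' Signed average relative deviation (ARD)
#'
#' @inheritParams aard
#' @return Signed percentage deviation (positive when predictions are low).
#' @export
ard <- function(measured, predicted) {
  check_dev_args(measured, predicted)
  100 * mean((measured - predicted) / measured)
}

check_dev_args <- function(measured, predicted) {
  if (length(measured) != length(predicted)) abort("length mismatch")
  if (length(measured) == 0) abort("empty input")
  if (any(!is.finite(measured)) || any(!is.finite(predicted))) {
    abort("non-finite values")
  }
  if (any(measured == 0)) abort("measured values must be nonzero")
  invisible(TRUE)
}

# shared fit-report container: every fitted model in the package carries one
new_fit_report <- function(model, params, measured, predicted, extra = list()) {
  out <- c(list(model = model, params = params,
                aard_pct = aard(measured, predicted),
                ard_pct = ard(measured, predicted),
                n_points = length(measured),
                residuals = measured - predicted,
                measured = measured, predicted = predicted), extra)
  class(out) <- c(paste0(model, "_fit"), "asdkit_fit")
  out
}

#' @export
print.asdkit_fit <- function(x, ...) {
  cat("<", x$model, " fit>\n", sep = "")
  cat("  parameters: ",
      paste(names(x$params), signif(unlist(x$params), 6), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  AARD %.4g %%, ARD %.4g %%, n = %d\n",
              x$aard_pct, x$ard_pct, x$n_points))
  invisible(x)
}

#' Tidy the parameters of a fitted model
#'
#' @param x An `asdkit_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.asdkit_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' One-row fit summary
#'
#' @param x An `asdkit_fit` object.
#' @param ... Unused.
#' @return Tibble with `model`, `aard_pct`, `ard_pct`, `n_points`.
#' @export
glance.asdkit_fit <- function(x, ...) {
  tibble::tibble(model = x$model, aard_pct = x$aard_pct,
                 ard_pct = x$ard_pct, n_points = x$n_points)
}
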