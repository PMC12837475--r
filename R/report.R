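#' Expanded uncertainty
#'
#' U = k * uc. The coverage factor k = 2 gives approximately 95% coverage
#' for a normally distributed measurand.
#'
#' @param uc combined standard uncertainty (same unit as the measurand,
#'   ≥ 0).
#' @param k coverage factor (> 0; default 2).
#' @return Expanded uncertainty in the unit of `uc`.
#' @examples
#' expand_uncertainty(11.75, k = 2) # 23.5
#' @export
expand_uncertainty <- function(uc, k = 2) {
  stopifnot(is.numeric(uc), is.numeric(k), length(k) == 1L)
  if (any(uc < 0)) stop("'uc' must be >= 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("'k' must be > 0", call. = FALSE)
  k * uc
}

#' Relative expanded uncertainty
#'
#' 100 * U / X, in percent. Conventionally displayed at 1 decimal.
#'
#' @param X measurand estimate (> 0).
#' @param U expanded uncertainty (same unit).
#' @return Relative expanded uncertainty in percent (full precision).
#' @examples
#' round(relative_expanded(188.10, 23.5), 1) # 12.5
#' @export
relative_expanded <- function(X, U) {
  stopifnot(is.numeric(X), is.numeric(U))
  if (any(X <= 0)) {
    stop("relative expanded uncertainty requires X > 0", call. = FALSE)
  }
  100 * U / X
}

format_expanded <- function(U) {
  # 3 significant figures, printed with the decimals that implies
  U3 <- signif(U, 3)
  decimals <- if (U3 > 0) max(0L, 2L - floor(log10(U3))) else 2L
  sprintf("%.*f", decimals, U3)
}

#' Format a measurement as "X ± U unit (k = k)"
#'
#' X is printed at the reader's display resolution (0.01 µg/kg, i.e. 2
#' decimals, by default) and U to 3 significant figures.
#'
#' @param X measurand estimate.
#' @param U expanded uncertainty.
#' @param k coverage factor.
#' @param unit unit label.
#' @param x_decimals decimals for X.
#' @return A single string.
#' @examples
#' format_measurement(188.10, 23.5) # "188.10 ± 23.5 µg/kg (k = 2)"
#' @export
format_measurement <- function(X, U, k = 2, unit = "µg/kg",
                               x_decimals = 2) {
  k_txt <- if (k == round(k)) sprintf("%d", as.integer(k)) else
    sprintf("%g", k)
  sprintf("%.*f ± %s %s (k = %s)", x_decimals, X, format_expanded(U),
          unit, k_txt)
}

#' Build a measurement report with expanded uncertainty
#'
#' Scales a relative combined standard uncertainty by the measurand
#' estimate, expands it with the coverage factor, and reports the coverage
#' interval \[X − U, X + U\] together with the conventional
#' "X ± U µg/kg (k = 2)" text.
#'
#' @param X measurand estimate in µg/kg (≥ 0).
#' @param uc_rel combined relative standard uncertainty (fraction, ≥ 0).
#' @param k coverage factor (> 0; default 2).
#' @param unit unit label for the formatted text.
#' @param x_decimals decimals at which X is displayed (default 2, the
#'   reader's 0.01 µg/kg resolution).
#' @return An object of class `measurement_report`: list with `X`, `uc`
#'   (absolute, µg/kg), `uc_rel`, `k`, `U`, `interval` (length-2 numeric),
#'   and `text`.
#' @examples
#' rep <- measurement_report(188.10, uc_rel = 11.75 / 188.10, k = 2)
#' rep$text
#' rep$interval
#' @export
measurement_report <- function(X, uc_rel, k = 2, unit = "µg/kg",
                               x_decimals = 2) {
  stopifnot(is.numeric(X), length(X) == 1L, is.finite(X),
            is.numeric(uc_rel), length(uc_rel) == 1L, is.finite(uc_rel))
  if (X < 0) stop("'X' must be >= 0", call. = FALSE)
  if (uc_rel < 0) stop("'uc_rel' must be >= 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("'k' must be > 0", call. = FALSE)
  uc <- uc_rel * X
  U <- expand_uncertainty(uc, k)
  structure(
    list(
      X = X, uc = uc, uc_rel = uc_rel, k = k, U = U,
      interval = c(X - U, X + U),
      text = format_measurement(X, U, k, unit = unit,
                                x_decimals = x_decimals)
    ),
    class = "measurement_report"
  )
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(x$text, "\n")
  cat(sprintf("  coverage interval: %.1f to %.1f\n",
              x$interval[1], x$interval[2]))
  if (x$X > 0) {
    cat(sprintf("  relative expanded uncertainty: %.1f%%\n",
                relative_expanded(x$X, x$U)))
  }
  invisible(x)
}
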