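#' Replicate measurement sets
#'
#' A `replicate_set` holds repeated measurements of one quantity in a shared
#' unit (e.g. pipetted volumes in µL, or strip readouts in µg/kg), optionally
#' with the nominal target value. It is the carrier for all type A
#' (statistical) uncertainty evaluation: the relative standard deviation and
#' the relative standard uncertainty are computed from its sample standard
#' deviation and mean.
#'
#' @param values numeric vector of repeated measurements; all finite, at
#'   least 2 values for any dispersion statistic.
#' @param nominal optional nominal/target value in the same unit.
#' @param unit optional unit label (informational).
#'
#' @return An object of class `replicate_set`.
#' @examples
#' reps <- replicate_set(c(98, 100, 102), nominal = 100, unit = "µL")
#' rsd(reps)
#' @export
replicate_set <- function(values, nominal = NULL, unit = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values))) {
    stop("'values' must be a non-empty vector of finite numbers", call. = FALSE)
  }
  if (!is.null(nominal)) {
    nominal <- as.numeric(nominal)
    stopifnot(length(nominal) == 1L, is.finite(nominal))
  }
  structure(
    list(values = values, nominal = nominal, unit = unit),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  unit <- if (is.null(x$unit)) "" else paste0(" ", x$unit)
  cat(sprintf("Replicate set: n = %d%s\n", length(x$values), unit))
  cat(sprintf("  mean = %.6g, sd = %.6g", mean(x$values), stats::sd(x$values)))
  if (!is.null(x$nominal)) cat(sprintf(", nominal = %.6g", x$nominal))
  cat("\n")
  invisible(x)
}

rep_values <- function(reps) {
  if (inherits(reps, "replicate_set")) reps$values else as.numeric(reps)
}

check_dispersion_input <- function(values, what = "dispersion statistic") {
  if (length(values) < 2L) {
    stop("insufficient replicates: at least 2 values are required for a ",
         what, call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all replicate values must be finite", call. = FALSE)
  }
  invisible(values)
}

#' Relative standard deviation (RSD) of a replicate set
#'
#' RSD = SD / mean × 100%, with the sample standard deviation (n − 1
#' denominator). This is the repeatability metric used both for per-operator
#' pipetting precision and for strip batch-to-batch variability.
#'
#' @param reps a [replicate_set] or numeric vector of length ≥ 2.
#' @return RSD in percent. Invariant under positive rescaling of all values.
#' @examples
#' rsd(c(98, 100, 102)) # 2
#' @export
rsd <- function(reps) {
  values <- rep_values(reps)
  check_dispersion_input(values, "relative standard deviation")
  m <- mean(values)
  if (m == 0) stop("RSD is undefined for a zero mean", call. = FALSE)
  stats::sd(values) / abs(m) * 100
}

#' Type A relative standard uncertainty from replicates
#'
#' The statistical (type A) evaluation of standard uncertainty: the sample
#' standard deviation of repeated measurements, expressed relative to their
#' mean as a dimensionless fraction. By default the dispersion of a single
#' observation is used (the replicate RSD, as a fraction); set
#' `of_mean = TRUE` to evaluate the standard uncertainty of the mean
#' (division by √n).
#'
#' @param reps a [replicate_set] or numeric vector of length ≥ 2.
#' @param of_mean if `TRUE`, return (SD/√n)/mean instead of SD/mean.
#' @return Relative standard uncertainty as a fraction, with the degrees of
#'   freedom n − 1 attached as attribute `"dof"`.
#' @examples
#' type_a_uncertainty(c(98, 100, 102))                 # 0.02
#' type_a_uncertainty(c(98, 100, 102), of_mean = TRUE) # 0.02/sqrt(3)
#' @export
type_a_uncertainty <- function(reps, of_mean = FALSE) {
  values <- rep_values(reps)
  check_dispersion_input(values, "type A uncertainty evaluation")
  m <- mean(values)
  if (m == 0) {
    stop("relative type A uncertainty is undefined for a zero mean",
         call. = FALSE)
  }
  u <- stats::sd(values) / abs(m)
  if (isTRUE(of_mean)) u <- u / sqrt(length(values))
  structure(u, dof = length(values) - 1L)
}
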