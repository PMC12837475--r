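#' Canonical uncertainty source names for the QQ assay
#'
#' The five contributors of the assay's additive measurement model, in the
#' order they appear in the source-resolved budget: sample weighing, the
#' extraction/pipetting step, zeroing of the reader against the blank card,
#' the calibration-curve fit, and the test strip itself (a composite of
#' strip-to-strip, application and reading variability).
#'
#' @return Character vector of the five canonical component names.
#' @export
canonical_sources <- function() {
  c("Sample Weighing", "Extractor", "zero-card Calibration",
    "Curve Fitting", "Lab Card")
}

#' Define one uncertainty component
#'
#' A named source of measurement uncertainty. `u` is the standard
#' uncertainty expressed RELATIVE to the measurand (a dimensionless
#' fraction, e.g. 0.045 for a 4.5% strip RSD); `c` is the sensitivity
#' coefficient. The assay's measurement model is additive, so all
#' sensitivity coefficients default to 1.
#'
#' @param name component label; the canonical set is given by
#'   [canonical_sources()], but custom names are allowed.
#' @param u relative standard uncertainty (fraction, ≥ 0).
#' @param c sensitivity coefficient (dimensionless, finite; default 1).
#' @param eval_type `"A"` (statistical, from replicates) or `"B"`
#'   (from other information: certificates, assumed distributions).
#' @param dof optional degrees of freedom.
#' @return An object of class `uncertainty_component`.
#' @examples
#' uncertainty_component("Lab Card", u = 0.045, eval_type = "A", dof = 9)
#' @export
uncertainty_component <- function(name, u, c = 1, eval_type = c("B", "A"),
                                  dof = NA_real_) {
  eval_type <- match.arg(eval_type)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("component 'name' must be a non-empty string", call. = FALSE)
  }
  u <- as.numeric(u)
  if (length(u) != 1L || !is.finite(u) || u < 0) {
    stop("component 'u' must be a single finite value >= 0", call. = FALSE)
  }
  c <- as.numeric(c)
  if (length(c) != 1L || !is.finite(c)) {
    stop("sensitivity coefficient 'c' must be a single finite value",
         call. = FALSE)
  }
  dof_attr <- attr(u, "dof")
  if (is.na(dof) && !is.null(dof_attr)) dof <- dof_attr
  structure(
    list(name = name, u = as.numeric(u), c = c, eval_type = eval_type,
         dof = as.numeric(dof)),
    class = "uncertainty_component"
  )
}

#' @export
print.uncertainty_component <- function(x, ...) {
  cat(sprintf("%s: u = %.6g (type %s, c = %g)\n", x$name, x$u, x$eval_type,
              x$c))
  invisible(x)
}

#' Type B relative standard uncertainty
#'
#' Converts a stated half-width bound into a relative standard uncertainty
#' using the standard divisors for an assumed distribution: √3 for
#' rectangular, √6 for triangular, and the stated coverage factor for a
#' normally distributed quantity (e.g. a certificate quoting an expanded
#' uncertainty).
#'
#' @param half_width half-width of the bound, in the same unit as `nominal`
#'   (≥ 0).
#' @param distribution `"rectangular"`, `"triangular"` or `"normal"`.
#' @param nominal the nominal value the bound refers to (non-zero); the
#'   result is expressed relative to it.
#' @param k_source coverage factor of the stated bound (normal only, > 0).
#' @return Relative standard uncertainty as a fraction.
#' @examples
#' type_b_uncertainty(0.6, "triangular", nominal = 100) # 0.6/sqrt(6)/100
#' @export
type_b_uncertainty <- function(half_width,
                               distribution = c("rectangular", "triangular",
                                                "normal"),
                               nominal = 1, k_source = NULL) {
  if (length(distribution) == 1L &&
      !distribution %in% c("rectangular", "triangular", "normal")) {
    stop("unknown distribution '", distribution,
         "': use rectangular, triangular or normal", call. = FALSE)
  }
  distribution <- match.arg(distribution)
  half_width <- as.numeric(half_width)
  nominal <- as.numeric(nominal)
  stopifnot(length(half_width) == 1L, is.finite(half_width),
            length(nominal) == 1L, is.finite(nominal))
  if (half_width < 0) stop("'half_width' must be >= 0", call. = FALSE)
  if (nominal == 0) {
    stop("'nominal' must be non-zero to express a relative uncertainty",
         call. = FALSE)
  }
  divisor <- switch(distribution,
    rectangular = sqrt(3),
    triangular  = sqrt(6),
    normal = {
      if (is.null(k_source) || !is.finite(k_source) || k_source <= 0) {
        stop("'k_source' > 0 is required for a normal distribution",
             call. = FALSE)
      }
      k_source
    }
  )
  (half_width / divisor) / abs(nominal)
}

as_component_list <- function(components) {
  if (inherits(components, "uncertainty_component")) {
    return(list(components))
  }
  if (inherits(components, "uncertainty_budget")) {
    return(components$components)
  }
  if (is.numeric(components)) {
    nms <- names(components)
    if (is.null(nms)) nms <- paste0("component_", seq_along(components))
    return(Map(function(nm, u) uncertainty_component(nm, u), nms,
               as.numeric(components)))
  }
  if (is.list(components)) {
    return(lapply(components, function(x) {
      if (inherits(x, "uncertainty_component")) x
      else stop("all elements must be 'uncertainty_component' objects",
                call. = FALSE)
    }))
  }
  stop("cannot interpret 'components'", call. = FALSE)
}

component_contributions <- function(components) {
  comps <- as_component_list(components)
  vapply(comps, function(x) x$c * x$u, numeric(1),
         USE.NAMES = FALSE) -> contrib
  names(contrib) <- vapply(comps, `[[`, character(1), "name")
  contrib
}

#' Combine standard uncertainties (law of propagation)
#'
#' Root-sum-of-squares combination of sensitivity-weighted component
#' uncertainties: uc = sqrt(sum((c_i * u_i)^2)), valid for independent
#' inputs of an additive model. Order-independent, and never less than any
#' single |c_i * u_i|.
#'
#' @param components a list of [uncertainty_component] objects, a named
#'   numeric vector of relative uncertainties (c = 1), or an
#'   [uncertainty_budget].
#' @return Combined relative standard uncertainty (fraction).
#' @examples
#' combine_uncertainty(c(a = 3, b = 4)) # 5
#' @export
combine_uncertainty <- function(components) {
  contrib <- component_contributions(components)
  if (length(contrib) == 0L) {
    stop("empty budget: at least one component is required", call. = FALSE)
  }
  sqrt(sum(contrib^2))
}

#' Percentage share of each component in the combined uncertainty
#'
#' share_i = 100 * (c_i u_i)^2 / uc^2. Shares sum to 100 before any display
#' rounding; components with u = 0 contribute 0%.
#'
#' @inheritParams combine_uncertainty
#' @return Named numeric vector of shares in percent (full precision;
#'   conventionally displayed at 1 decimal).
#' @examples
#' round(budget_shares(c(a = 3, b = 4)), 1) # 36, 64
#' @export
budget_shares <- function(components) {
  contrib <- component_contributions(components)
  if (length(contrib) == 0L) {
    stop("empty budget: at least one component is required", call. = FALSE)
  }
  total <- sum(contrib^2)
  if (total == 0) {
    stop("shares are undefined for an all-zero budget (uc = 0)",
         call. = FALSE)
  }
  100 * contrib^2 / total
}

#' Assemble an uncertainty budget
#'
#' Bundles an ordered list of components with their combined relative
#' standard uncertainty and percentage shares.
#'
#' @inheritParams combine_uncertainty
#' @return An object of class `uncertainty_budget` with elements
#'   `components`, `uc_rel`, and `shares` (`NULL` when uc = 0, in which
#'   case shares are undefined).
#' @examples
#' b <- uncertainty_budget(c(`Lab Card` = 0.045, Extractor = 0.03))
#' b$uc_rel
#' @export
uncertainty_budget <- function(components) {
  comps <- as_component_list(components)
  uc <- combine_uncertainty(comps)
  shares <- if (uc > 0) budget_shares(comps) else NULL
  structure(
    list(components = comps, uc_rel = uc, shares = shares),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncertainty budget\n")
  for (comp in x$components) {
    share <- if (is.null(x$shares)) NA_real_ else x$shares[[comp$name]]
    cat(sprintf("  %-22s u = %-10.6g type %s  share %s\n",
                comp$name, comp$u, comp$eval_type,
                if (is.na(share)) "--" else sprintf("%.1f%%", share)))
  }
  cat(sprintf("  combined relative standard uncertainty uc = %.6g (%.2f%%)\n",
              x$uc_rel, 100 * x$uc_rel))
  invisible(x)
}
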