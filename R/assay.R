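#' Assay run inputs
#'
#' One QQ immunoassay run: sample preparation parameters and the strip
#' reader's concentration readout. The reader reports directly in µg/kg of
#' sample over the method's 0–300 µg/kg working range (0.01 µg/kg display
#' resolution), so mass, volumes and dilution do not rescale the result;
#' they enter the measurement only through their uncertainty components.
#'
#' @param strip_reading reader output in µg/kg (working range 0–300).
#' @param sample_mass sample portion in g (> 0; nominal 1 g).
#' @param extraction_volume extract volume in µL (> 0).
#' @param dilution_ratio integer vector `c(parts_extract, parts_diluent)`;
#'   default `c(1, 9)` (the 1:9 v/v dilution).
#' @param applied_volume volume applied to the strip's sample well, µL
#'   (default 100).
#' @param incubation_temp incubation temperature in °C (nominal 24 ± 2).
#' @param incubation_time incubation time in min (nominal 10).
#' @return An object of class `assay_inputs`.
#' @examples
#' assay_inputs(strip_reading = 188.10)
#' @export
assay_inputs <- function(strip_reading, sample_mass = 1.0,
                         extraction_volume = 1000,
                         dilution_ratio = c(1L, 9L),
                         applied_volume = 100,
                         incubation_temp = 24, incubation_time = 10) {
  structure(
    list(strip_reading = as.numeric(strip_reading),
         sample_mass = as.numeric(sample_mass),
         extraction_volume = as.numeric(extraction_volume),
         dilution_ratio = as.numeric(dilution_ratio),
         applied_volume = as.numeric(applied_volume),
         incubation_temp = as.numeric(incubation_temp),
         incubation_time = as.numeric(incubation_time)),
    class = "assay_inputs"
  )
}

#' Validate assay inputs against the instrument's operating ranges
#'
#' Every field is checked; all violations are collected and reported
#' together (no fail-fast, no silent clamping). Out-of-tolerance incubation
#' conditions (24 ± 2 °C, 10 min nominal) raise warnings, not errors: they
#' are prompts to the operator, not invalid data.
#'
#' @param inputs an [assay_inputs] object.
#' @return A list with `valid` (logical), `violations` (character vector,
#'   each naming the field, its value and the permitted range) and
#'   `warnings` (character vector), plus the echoed `inputs`.
#' @examples
#' validate_inputs(assay_inputs(strip_reading = 305))$violations
#' @export
validate_inputs <- function(inputs) {
  stopifnot(inherits(inputs, "assay_inputs"))
  violations <- character(0)
  warnings <- character(0)
  bad <- function(msg) violations <<- c(violations, msg)

  sr <- inputs$strip_reading
  if (!is.finite(sr) || sr < 0 || sr > 300) {
    bad(sprintf("strip_reading = %s outside [0, 300] µg/kg", format(sr)))
  }
  if (!is.finite(inputs$sample_mass) || inputs$sample_mass <= 0) {
    bad(sprintf("sample_mass = %s must be > 0 g", format(inputs$sample_mass)))
  }
  if (!is.finite(inputs$extraction_volume) || inputs$extraction_volume <= 0) {
    bad(sprintf("extraction_volume = %s must be > 0 µL",
                format(inputs$extraction_volume)))
  }
  dr <- inputs$dilution_ratio
  if (length(dr) != 2L || any(!is.finite(dr)) || any(dr <= 0) ||
      any(dr != round(dr))) {
    bad(sprintf("dilution_ratio = %s must be two positive integers (parts extract : parts diluent)",
                paste(format(dr), collapse = ":")))
  }
  if (!is.finite(inputs$applied_volume) || inputs$applied_volume <= 0) {
    bad(sprintf("applied_volume = %s must be > 0 µL",
                format(inputs$applied_volume)))
  }
  if (is.finite(inputs$incubation_temp) &&
      abs(inputs$incubation_temp - 24) > 2) {
    warnings <- c(warnings,
      sprintf("incubation_temp = %s °C outside the nominal 24 ± 2 °C window",
              format(inputs$incubation_temp)))
  }
  if (is.finite(inputs$incubation_time) && inputs$incubation_time != 10) {
    warnings <- c(warnings,
      sprintf("incubation_time = %s min differs from the nominal 10 min",
              format(inputs$incubation_time)))
  }
  list(valid = length(violations) == 0L, violations = violations,
       warnings = warnings, inputs = inputs)
}

#' Assemble the five-source QQ assay budget
#'
#' Binds the five canonical uncertainty sources of the QQ workflow
#' ([canonical_sources()]) into an [uncertainty_budget]. Each source may be
#' given either as a fixed relative standard uncertainty (a single fraction,
#' type B), as a numeric vector of replicates, or as a [replicate_set]
#' (both evaluated through [type_a_uncertainty()]). All five canonical
#' names must be present; extra sources are kept with a warning.
#'
#' @param sources named list: one entry per source.
#' @param of_mean passed to [type_a_uncertainty()] for replicate entries.
#' @return An [uncertainty_budget] with components in canonical order
#'   (extras appended).
#' @examples
#' assemble_budget(list(
#'   "Sample Weighing" = 0.014, "Extractor" = 0.025,
#'   "zero-card Calibration" = 0.010, "Curve Fitting" = 0.003,
#'   "Lab Card" = 0.045))
#' @export
assemble_budget <- function(sources, of_mean = FALSE) {
  stopifnot(is.list(sources))
  nms <- names(sources)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("'sources' must be a fully named list", call. = FALSE)
  }
  canon <- canonical_sources()
  missing <- setdiff(canon, nms)
  if (length(missing) > 0L) {
    stop("incomplete budget: missing canonical source(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extras <- setdiff(nms, canon)
  if (length(extras) > 0L) {
    warning("non-canonical source(s) included in the budget: ",
            paste(extras, collapse = ", "), call. = FALSE)
  }
  ordered <- c(canon, extras)
  comps <- lapply(ordered, function(nm) {
    x <- sources[[nm]]
    if (inherits(x, "uncertainty_component")) {
      return(x)
    }
    if (inherits(x, "replicate_set") ||
        (is.numeric(x) && length(x) >= 2L)) {
      u <- type_a_uncertainty(x, of_mean = of_mean)
      return(uncertainty_component(nm, u = as.numeric(u), eval_type = "A",
                                   dof = attr(u, "dof")))
    }
    if (is.numeric(x) && length(x) == 1L) {
      return(uncertainty_component(nm, u = x, eval_type = "B"))
    }
    stop("source '", nm, "' must be a relative u (length-1 numeric), ",
         "a replicate vector, a replicate_set, or an uncertainty_component",
         call. = FALSE)
  })
  uncertainty_budget(comps)
}

#' Measure a sample: concentration with expanded uncertainty
#'
#' Runs the full measurement: input validation, the combined uncertainty
#' from the five-source budget, expansion by the coverage factor, and a
#' stepwise calculation record for traceability. The measurand estimate X
#' is the strip reader's concentration readout.
#'
#' @param inputs an [assay_inputs] object (must pass [validate_inputs()]).
#' @param budget an [uncertainty_budget], e.g. from [assemble_budget()].
#' @param k coverage factor (default 2).
#' @param x_decimals display decimals for X in the formatted text.
#' @return An object of class `assay_result`: list with `inputs`, `budget`,
#'   `report` (a [measurement_report]) and `record` (a data.frame of
#'   calculation steps with columns step, quantity, value, unit, source).
#' @examples
#' b <- assemble_budget(list(
#'   "Sample Weighing" = 0.014, "Extractor" = 0.025,
#'   "zero-card Calibration" = 0.010, "Curve Fitting" = 0.003,
#'   "Lab Card" = 0.045))
#' res <- measure_sample(assay_inputs(strip_reading = 188.10), b)
#' res$report$text
#' @export
measure_sample <- function(inputs, budget, k = 2, x_decimals = 2) {
  stopifnot(inherits(inputs, "assay_inputs"),
            inherits(budget, "uncertainty_budget"))
  chk <- validate_inputs(inputs)
  if (!chk$valid) {
    stop("invalid assay inputs:\n  ",
         paste(chk$violations, collapse = "\n  "), call. = FALSE)
  }
  for (w in chk$warnings) warning(w, call. = FALSE)

  X <- inputs$strip_reading
  report <- measurement_report(X, uc_rel = budget$uc_rel, k = k,
                               x_decimals = x_decimals)

  row <- function(step, quantity, value, unit, source) {
    data.frame(step = step, quantity = quantity, value = value,
               unit = unit, source = source, stringsAsFactors = FALSE)
  }
  record <- rbind(
    row("input", "sample_mass", inputs$sample_mass, "g", "operator"),
    row("input", "extraction_volume", inputs$extraction_volume, "µL",
        "operator"),
    row("input", "dilution_parts_extract", inputs$dilution_ratio[1], "",
        "operator"),
    row("input", "dilution_parts_diluent", inputs$dilution_ratio[2], "",
        "operator"),
    row("input", "applied_volume", inputs$applied_volume, "µL", "operator"),
    row("input", "strip_reading", X, "µg/kg", "reader"),
    do.call(rbind, lapply(budget$components, function(comp) {
      row("component", "relative_u_contribution", comp$c * comp$u,
          "fraction", comp$name)
    })),
    row("combine", "uc_rel", budget$uc_rel, "fraction",
        "root-sum-of-squares"),
    row("scale", "uc", report$uc, "µg/kg", "uc_rel * X"),
    row("input", "k", k, "", "configuration"),
    row("expand", "U", report$U, "µg/kg", "k * uc"),
    row("result", "X", X, "µg/kg", "strip_reading"),
    row("result", "interval_lower", report$interval[1], "µg/kg", "X - U"),
    row("result", "interval_upper", report$interval[2], "µg/kg", "X + U")
  )
  structure(
    list(inputs = inputs, budget = budget, report = report,
         record = record),
    class = "assay_result"
  )
}

#' @export
print.assay_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Export / re-read / replay the stepwise calculation record
#'
#' `export_record()` writes the calculation record to CSV (UTF-8, comma
#' separated, '.' decimals, fixed column order step, quantity, value, unit,
#' source); numeric values are written with 17 significant digits so the
#' round trip is bit-exact. `read_record()` reads such a CSV back;
#' `replay_record()` recomputes X and U from the recorded rows (components
#' recombined by root-sum-of-squares, rescaled and re-expanded), so an
#' exported record can be verified independently of the object that
#' produced it.
#'
#' @param result an `assay_result` from [measure_sample()], or a record
#'   data.frame.
#' @param path file path for the CSV.
#' @return `export_record()` returns `path` invisibly; `read_record()` the
#'   record data.frame; `replay_record()` a list with `X`, `uc_rel`, `U`.
#' @examples
#' b <- assemble_budget(list(
#'   "Sample Weighing" = 0.014, "Extractor" = 0.025,
#'   "zero-card Calibration" = 0.010, "Curve Fitting" = 0.003,
#'   "Lab Card" = 0.045))
#' res <- measure_sample(assay_inputs(strip_reading = 188.10), b)
#' f <- tempfile(fileext = ".csv")
#' export_record(res, f)
#' replay_record(read_record(f))$U == res$report$U
#' @export
export_record <- function(result, path) {
  record <- if (inherits(result, "assay_result")) result$record else result
  stopifnot(is.data.frame(record))
  out <- record[, c("step", "quantity", "value", "unit", "source"),
                drop = FALSE]
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname export_record
#' @export
read_record <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"),
                         fileEncoding = "UTF-8")
  rec$value <- as.numeric(rec$value)
  rec
}

#' @rdname export_record
#' @export
replay_record <- function(result) {
  record <- if (inherits(result, "assay_result")) result$record else result
  stopifnot(is.data.frame(record))
  contrib <- record$value[record$step == "component"]
  if (length(contrib) == 0L) {
    stop("record contains no uncertainty components", call. = FALSE)
  }
  X <- record$value[record$step == "result" & record$quantity == "X"]
  k <- record$value[record$step == "input" & record$quantity == "k"]
  stopifnot(length(X) == 1L, length(k) == 1L)
  uc_rel <- sqrt(sum(contrib^2))
  list(X = X, uc_rel = uc_rel, U = k * (uc_rel * X))
}
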