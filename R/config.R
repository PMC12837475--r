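#' Test-strip repeatability presets
#'
#' Two defensible defaults for the Lab Card (test strip) component: the
#' multi-batch measured strip RSD of 4.5%, and the manufacturer's
#' specification of 4%. Neither is privileged; choose via
#' `run_config(lab_card_preset = ...)` or pass an explicit value.
#'
#' @return Named numeric vector of strip RSDs in percent.
#' @export
lab_card_presets <- function() {
  c(measured = 4.5, manufacturer = 4.0)
}

#' Run configuration
#'
#' The tunable parameters of the workflow, with their defaults: coverage
#' factor k = 2, MRL = 100 µg/kg, normality-gate alpha 0.05, bootstrap
#' B = 10000, display rounding profile, and the Lab Card preset. Every
#' output of the CLI echoes the effective configuration for traceability.
#'
#' @param k coverage factor (default 2).
#' @param mrl maximum residue limit, µg/kg (default 100).
#' @param alpha_normality normality-gate significance level (default 0.05).
#' @param bootstrap_B bootstrap resamples (default 10000).
#' @param seed integer seed for stochastic operations (default NULL).
#' @param x_decimals display decimals for X (default 2).
#' @param share_decimals display decimals for budget shares (default 1).
#' @param lab_card_preset `"measured"` (4.5%) or `"manufacturer"` (4.0%).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(k = 2, mrl = 100, alpha_normality = 0.05,
                       bootstrap_B = 10000, seed = NULL, x_decimals = 2,
                       share_decimals = 1,
                       lab_card_preset = c("measured", "manufacturer")) {
  lab_card_preset <- match.arg(lab_card_preset)
  stopifnot(k > 0, mrl > 0, alpha_normality > 0, alpha_normality < 1,
            bootstrap_B >= 1)
  structure(
    list(k = k, mrl = mrl, alpha_normality = alpha_normality,
         bootstrap_B = bootstrap_B, seed = seed, x_decimals = x_decimals,
         share_decimals = share_decimals,
         lab_card_preset = lab_card_preset,
         lab_card_rsd = unname(lab_card_presets()[lab_card_preset])),
    class = "run_config"
  )
}

#' Read a configuration file (JSON or YAML)
#'
#' Keys present in the file override the [run_config()] defaults; unknown
#' keys raise an error rather than being silently ignored.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "': use JSON or YAML",
         call. = FALSE)
  )
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

# FNV-1a over the canonical JSON serialization; a short fingerprint that
# lets log lines and outputs be matched to the exact configuration used.
config_fingerprint <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in double precision (split to avoid overflow)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
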