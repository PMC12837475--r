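#' Specification of a paired operator cohort
#'
#' Defines the generator truth for a before/after pipetting-competency
#' cohort: per-volume means and SDs of the between-operator distribution
#' of pipetting CVs (%), the pre/post correlation, and the session size.
#' The defaults are the study conditions of the 20-technician cohort:
#' 4.10 ± 0.68 → 1.79 ± 0.41 (%) at 100 µL and 2.52 ± 0.49 → 1.08 ± 0.33
#' (%) at 1000 µL, ten replicates per session.
#'
#' @param n_operators number of paired operators (default 20).
#' @param volumes nominal pipetting volumes in µL.
#' @param pre_cv_mean,pre_cv_sd,post_cv_mean,post_cv_sd numeric vectors
#'   (one entry per volume) of the between-operator CV distribution, in %.
#' @param rho latent pre/post correlation across operators (|rho| < 1;
#'   default 0.5).
#' @param replicates_per_session replicates per operator/volume/phase
#'   (default 10).
#' @param cv_floor lower truncation of drawn CVs, % (default 0.1).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_operators = 20,
                        volumes = c(100, 1000),
                        pre_cv_mean = c(4.10, 2.52),
                        pre_cv_sd = c(0.68, 0.49),
                        post_cv_mean = c(1.79, 1.08),
                        post_cv_sd = c(0.41, 0.33),
                        rho = 0.5,
                        replicates_per_session = 10,
                        cv_floor = 0.1) {
  nv <- length(volumes)
  stopifnot(n_operators >= 2, nv >= 1,
            length(pre_cv_mean) == nv, length(pre_cv_sd) == nv,
            length(post_cv_mean) == nv, length(post_cv_sd) == nv,
            all(pre_cv_mean > 0), all(post_cv_mean > 0),
            all(pre_cv_sd > 0), all(post_cv_sd > 0),
            abs(rho) < 1, replicates_per_session >= 2, cv_floor > 0)
  structure(
    list(n_operators = as.integer(n_operators), volumes = volumes,
         pre_cv_mean = pre_cv_mean, pre_cv_sd = pre_cv_sd,
         post_cv_mean = post_cv_mean, post_cv_sd = post_cv_sd,
         rho = rho,
         replicates_per_session = as.integer(replicates_per_session),
         cv_floor = cv_floor),
    class = "cohort_spec"
  )
}

#' Specification of a near-MRL sample panel
#'
#' @param n_samples number of samples (default 100).
#' @param mrl maximum residue limit, µg/kg (default 100).
#' @param truth_range range of the uniform true-concentration draw,
#'   µg/kg (default 80–120, straddling the MRL).
#' @param rel_uc relative combined standard uncertainty of the measurement
#'   (default 0.0625, the assay's typical level).
#' @param k coverage factor (default 2).
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_samples = 100, mrl = 100,
                       truth_range = c(80, 120), rel_uc = 0.0625, k = 2) {
  stopifnot(n_samples >= 1, mrl > 0, length(truth_range) == 2L,
            truth_range[1] <= truth_range[2], truth_range[1] > 0,
            rel_uc >= 0, k > 0)
  structure(
    list(n_samples = as.integer(n_samples), mrl = mrl,
         truth_range = truth_range, rel_uc = rel_uc, k = k),
    class = "panel_spec"
  )
}

#' Simulate a pipetting replicate session
#'
#' Draws `n` dispensed volumes from a normal law with mean `nominal` and
#' SD `nominal * cv / 100`. A pure function of its arguments: the same
#' seed always yields the same set, and the session RNG state is left
#' untouched.
#'
#' @param nominal nominal volume, µL.
#' @param cv true pipetting CV in % (≥ 0).
#' @param n number of replicates (≥ 2).
#' @param seed integer seed (required).
#' @return A [replicate_set].
#' @export
simulate_pipetting <- function(nominal, cv, n, seed) {
  stopifnot(is.numeric(nominal), nominal > 0, is.numeric(cv), cv >= 0,
            n >= 2)
  if (missing(seed) || is.null(seed)) {
    stop("a 'seed' is required", call. = FALSE)
  }
  values <- withr::with_seed(as.integer(seed),
                             stats::rnorm(n, nominal, nominal * cv / 100))
  replicate_set(values, nominal = nominal, unit = "µL")
}

# Affine standardization: exact sample mean = nominal, exact sample RSD = cv.
# Conditions a simulated session on its observed summary statistics, so the
# per-operator metric equals the drawn generator truth.
standardize_session <- function(values, nominal, cv) {
  s <- stats::sd(values)
  if (s == 0 || cv == 0) return(rep(nominal, length(values)))
  nominal + (values - mean(values)) * (nominal * cv / 100) / s
}

#' Simulate a paired before/after operator cohort
#'
#' Per operator and volume, latent (pre, post) pipetting CVs are drawn
#' from a correlated bivariate normal (correlation `rho`), truncated below
#' at `cv_floor` by redrawing. Replicate sessions are then generated with
#' [simulate_pipetting()] and affinely standardized so each session's
#' sample mean equals the nominal volume and its sample RSD equals the
#' drawn CV exactly — the per-operator metric is thereby identical to the
#' generator truth, and [operator_rsd()] on a session reproduces it.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed (required).
#' @return An object of class `qq_cohort`: list with `cohorts` (one
#'   data.frame per volume: operator_id, pre, post — the paired CV metric
#'   in %), `sessions` (long data.frame: operator_id, phase, volume,
#'   replicate_index, value), `truth` (the spec) and `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed)) {
    stop("a 'seed' is required", call. = FALSE)
  }
  seed <- as.integer(seed)
  n <- spec$n_operators

  draw_truncated_pair <- function(mu_pre, sd_pre, mu_post, sd_post, rho,
                                  floor_) {
    repeat {
      z1 <- stats::rnorm(1)
      z2 <- stats::rnorm(1)
      pre <- mu_pre + sd_pre * z1
      post <- mu_post + sd_post * (rho * z1 + sqrt(1 - rho^2) * z2)
      if (pre > floor_ && post > floor_) return(c(pre, post))
    }
  }

  out <- withr::with_seed(seed, {
    cohorts <- list()
    sessions <- list()
    for (v in seq_along(spec$volumes)) {
      vol <- spec$volumes[v]
      cvs <- t(vapply(seq_len(n), function(i) {
        draw_truncated_pair(spec$pre_cv_mean[v], spec$pre_cv_sd[v],
                            spec$post_cv_mean[v], spec$post_cv_sd[v],
                            spec$rho, spec$cv_floor)
      }, numeric(2)))
      cohorts[[as.character(vol)]] <- data.frame(
        operator_id = sprintf("op_%02d", seq_len(n)),
        pre = cvs[, 1], post = cvs[, 2], stringsAsFactors = FALSE
      )
      for (i in seq_len(n)) {
        for (phase in c("pre", "post")) {
          cv_i <- cvs[i, if (phase == "pre") 1 else 2]
          raw <- stats::rnorm(spec$replicates_per_session, vol,
                              vol * cv_i / 100)
          vals <- standardize_session(raw, vol, cv_i)
          sessions[[length(sessions) + 1L]] <- data.frame(
            operator_id = sprintf("op_%02d", i), phase = phase,
            volume = vol,
            replicate_index = seq_len(spec$replicates_per_session),
            value = vals, stringsAsFactors = FALSE
          )
        }
      }
    }
    list(cohorts = cohorts, sessions = do.call(rbind, sessions))
  })
  structure(
    list(cohorts = out$cohorts, sessions = out$sessions, truth = spec,
         seed = seed),
    class = "qq_cohort"
  )
}

#' @export
print.qq_cohort <- function(x, ...) {
  cat(sprintf("Paired operator cohort: %d operators, volumes %s µL, seed %d\n",
              x$truth$n_operators,
              paste(x$truth$volumes, collapse = "/"), x$seed))
  for (vol in names(x$cohorts)) {
    ch <- x$cohorts[[vol]]
    cat(sprintf("  %s µL: pre CV %.2f ± %.2f %%, post CV %.2f ± %.2f %%\n",
                vol, mean(ch$pre), stats::sd(ch$pre), mean(ch$post),
                stats::sd(ch$post)))
  }
  invisible(x)
}

#' Simulate a near-MRL conformity panel
#'
#' True concentrations are drawn uniformly over `truth_range`; measured
#' values are X = truth · (1 + e) with e ~ N(0, rel_uc), and
#' U = k · rel_uc · X. The truth label is the point comparison of the true
#' concentration against the MRL.
#'
#' @param spec a [panel_spec].
#' @param seed integer seed (required).
#' @return data.frame with columns `sample_id`, `truth_conc`, `truth`,
#'   `X`, `U`, `mrl`.
#' @export
simulate_panel <- function(spec = panel_spec(), seed) {
  stopifnot(inherits(spec, "panel_spec"))
  if (missing(seed) || is.null(seed)) {
    stop("a 'seed' is required", call. = FALSE)
  }
  seed <- as.integer(seed)
  n <- spec$n_samples
  withr::with_seed(seed, {
    truth_conc <- stats::runif(n, spec$truth_range[1], spec$truth_range[2])
    X <- truth_conc * (1 + stats::rnorm(n, 0, spec$rel_uc))
    U <- spec$k * spec$rel_uc * X
    data.frame(
      sample_id = sprintf("s_%04d", seq_len(n)),
      truth_conc = truth_conc,
      truth = ifelse(truth_conc < spec$mrl, "compliant", "non_compliant"),
      X = X, U = U, mrl = spec$mrl, stringsAsFactors = FALSE
    )
  })
}
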