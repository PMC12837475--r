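#' Per-operator pipetting repeatability
#'
#' RSD (%) of one operator's replicate session; delegates to [rsd()].
#'
#' @param session a [replicate_set], a numeric vector, or a list with a
#'   `replicates` element (an operator session).
#' @return RSD in percent.
#' @export
operator_rsd <- function(session) {
  if (is.list(session) && !inherits(session, "replicate_set") &&
      !is.null(session$replicates)) {
    session <- session$replicates
  }
  rsd(session)
}

#' Paired pre/post comparison with a normality gate
#'
#' The before–after protocol for operator-level paired metrics (e.g.
#' pipetting RSD): paired differences d = pre − post (so an improvement is
#' a positive reduction) are first checked for normality with the
#' Shapiro–Wilk test. If `p > alpha_normality`, a two-tailed paired t-test
#' is run, with the t-based 95% CI for the mean difference and Cohen's
#' d_z = mean(d)/SD(d) (= t/√n). Otherwise an exact Wilcoxon signed-rank
#' test is used (exact for n ≤ 25, zero differences dropped by
#' convention), with the Hodges–Lehmann pseudomedian as the location
#' surrogate; d_z is still reported from the raw differences for
#' comparability.
#'
#' @param pre,post numeric vectors of the paired per-operator metric, or
#'   `pre` may be a data.frame/list with `pre` and `post` elements.
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @param conf_level confidence level of the interval (default 0.95).
#' @return An object of class `paired_test`: list with `test`
#'   (`"paired_t"` or `"wilcoxon"`), `normality_W`, `normality_p`,
#'   `statistic`, `dof` (t branch only), `p`, `mean_diff`, `ci`, `dz`,
#'   and `n`.
#' @export
paired_compare <- function(pre, post = NULL, alpha_normality = 0.05,
                           conf_level = 0.95) {
  if (is.null(post)) {
    stopifnot(!is.null(pre$pre), !is.null(pre$post))
    post <- pre$post
    pre <- pre$pre
  }
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  if (length(pre) != length(post)) {
    stop("'pre' and 'post' must be paired (equal length)", call. = FALSE)
  }
  n <- length(pre)
  if (n < 3L) {
    stop("insufficient pairs: at least 3 are required for the normality gate",
         call. = FALSE)
  }
  d <- pre - post
  if (stats::sd(d) == 0) {
    stop("degenerate differences: all paired differences are identical",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(d)
  dz <- mean(d) / stats::sd(d)

  if (sw$p.value > alpha_normality) {
    tt <- stats::t.test(d, conf.level = conf_level)
    res <- list(
      test = "paired_t",
      normality_W = unname(sw$statistic), normality_p = sw$p.value,
      statistic = unname(tt$statistic), dof = unname(tt$parameter),
      p = tt$p.value, mean_diff = mean(d),
      ci = as.numeric(tt$conf.int), dz = dz, n = n
    )
  } else {
    exact <- n <= 25L
    dnz <- d[d != 0]
    wt <- stats::wilcox.test(dnz, exact = exact, conf.int = TRUE,
                             conf.level = conf_level)
    res <- list(
      test = "wilcoxon",
      normality_W = unname(sw$statistic), normality_p = sw$p.value,
      statistic = unname(wt$statistic), dof = NA_real_,
      p = wt$p.value, mean_diff = unname(wt$estimate),
      ci = as.numeric(wt$conf.int), dz = dz, n = n
    )
  }
  structure(res, class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired comparison (n = %d): %s\n", x$n, x$test))
  cat(sprintf("  Shapiro-Wilk W = %.3f, p = %.3f\n", x$normality_W,
              x$normality_p))
  if (x$test == "paired_t") {
    cat(sprintf("  t(%d) = %.2f, p = %.3g\n", as.integer(x$dof),
                x$statistic, x$p))
  } else {
    cat(sprintf("  V = %.1f, p = %.3g\n", x$statistic, x$p))
  }
  cat(sprintf("  mean reduction %.2f (95%% CI %.2f to %.2f), d_z = %.2f\n",
              x$mean_diff, x$ci[1], x$ci[2], x$dz))
  invisible(x)
}

#' Cohen's d_z from a paired t statistic
#'
#' For a paired design, d_z = mean(d)/SD(d) = t/√n.
#'
#' @param t paired t statistic.
#' @param n number of pairs (≥ 2).
#' @return d_z (full precision; conventionally displayed at 2 decimals).
#' @examples
#' round(cohens_dz_from_t(19.26, 20), 2) # 4.31
#' @export
cohens_dz_from_t <- function(t, n) {
  stopifnot(is.numeric(t), is.numeric(n), length(n) == 1L)
  if (!is.finite(n) || n < 2) stop("'n' must be >= 2", call. = FALSE)
  t / sqrt(n)
}

#' t-based confidence interval from summary statistics
#'
#' Reconstructs the paired-t confidence interval for a mean difference
#' from the reported mean and t statistic: se = mean/t, then
#' mean ± t_crit((1+level)/2, n−1) · se.
#'
#' @param mean_diff mean paired difference.
#' @param t_stat the paired t statistic (non-zero).
#' @param n number of pairs (≥ 2).
#' @param level confidence level (default 0.95).
#' @return Numeric length-2 vector `(lo, hi)` (full precision;
#'   conventionally displayed at 2 decimals).
#' @examples
#' round(mean_ci(2.32, 19.26, 20), 2) # 2.07 2.57
#' @export
mean_ci <- function(mean_diff, t_stat, n, level = 0.95) {
  stopifnot(is.numeric(mean_diff), is.numeric(t_stat), is.numeric(n))
  if (t_stat == 0) {
    stop("standard error is undefined for t = 0", call. = FALSE)
  }
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  se <- mean_diff / t_stat
  crit <- stats::qt((1 + level) / 2, df = n - 1)
  c(mean_diff - crit * se, mean_diff + crit * se)
}

#' Inter-operator coefficient of variation
#'
#' CV (%) of a per-operator metric across the cohort: sample SD divided by
#' the mean, × 100. Summarizes between-operator variability, as opposed to
#' the within-operator repeatability measured by [rsd()].
#'
#' @param values per-operator metric values (length ≥ 2, non-zero mean).
#' @return CV in percent.
#' @export
inter_operator_cv <- function(values) {
  rsd(values)
}

#' Bootstrap CI for the change in inter-operator CV
#'
#' Resamples operators (paired indices) with replacement `B` times,
#' computes CV(pre) − CV(post) in each resample, and returns the observed
#' point change with the percentile 2.5/97.5% interval. Seeded and
#' bit-reproducible; the RNG state of the session is left untouched.
#'
#' @param pre,post paired per-operator metric vectors (length ≥ 2).
#' @param B number of bootstrap resamples (default 10000; < 100 warns).
#' @param seed integer seed (required).
#' @param conf_level confidence level (default 0.95).
#' @return List with `point` (pp change), `ci` (lo, hi), `B`, `seed`.
#' @export
bootstrap_cv_change <- function(pre, post, B = 10000, seed,
                                conf_level = 0.95) {
  if (missing(seed) || is.null(seed)) {
    stop("a 'seed' is required for reproducible bootstrap resampling",
         call. = FALSE)
  }
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  n <- length(pre)
  stopifnot(length(post) == n, n >= 2L)
  if (B < 100) {
    warning("B < 100 gives an unstable percentile interval", call. = FALSE)
  }
  cv <- function(x) stats::sd(x) / mean(x) * 100
  point <- cv(pre) - cv(post)
  changes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- pre[idx]
      q <- post[idx]
      if (mean(p) == 0 || mean(q) == 0) return(NA_real_)
      cv(p) - cv(q)
    }, numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(changes, c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE))
  list(point = point, ci = ci, B = B, seed = as.integer(seed))
}

#' Exact McNemar test for paired binary outcomes
#'
#' For paired correct/incorrect outcomes (same subjects pre and post), the
#' discordant counts are b = #(pre correct, post incorrect) and
#' c = #(pre incorrect, post correct). The exact two-sided p-value is the
#' binomial doubled-tail probability of the smaller discordant count out
#' of b + c under p0 = 0.5, capped at 1; with no discordant pairs p = 1.
#' The exact form is used because the cohorts are small (n ≈ 20), where
#' the chi-square approximation is unreliable; the mid-p variant is not
#' used. p depends on (b, c) only: concordant pairs never change it.
#'
#' @param pre_correct,post_correct logical (or 0/1) vectors of paired
#'   outcomes; alternatively `pre_correct` may be a 2-column
#'   matrix/data.frame of pairs.
#' @return List with `b`, `c` and `p`.
#' @examples
#' mcnemar_exact(c(1, 0, 0, 0), c(1, 1, 1, 1)) # b = 0, c = 3
#' @export
mcnemar_exact <- function(pre_correct, post_correct = NULL) {
  if (is.null(post_correct)) {
    stopifnot(NCOL(pre_correct) == 2L)
    post_correct <- pre_correct[, 2]
    pre_correct <- pre_correct[, 1]
  }
  check_binary <- function(x, nm) {
    if (is.logical(x)) return(x)
    if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
    stop("'", nm, "' must be logical or 0/1", call. = FALSE)
  }
  pre_correct <- check_binary(pre_correct, "pre_correct")
  post_correct <- check_binary(post_correct, "post_correct")
  n <- length(pre_correct)
  stopifnot(length(post_correct) == n, n >= 1L)
  b <- sum(pre_correct & !post_correct)
  cc <- sum(!pre_correct & post_correct)
  m <- b + cc
  p <- if (m == 0L) 1.0 else min(1, 2 * stats::pbinom(min(b, cc), m, 0.5))
  list(b = b, c = cc, p = p)
}

#' Pre/post improvement accounting
#'
#' Tabulates baseline and outcome percentages with their improvement in
#' percentage points (post − pre).
#'
#' @param pre_pct,post_pct numeric vectors of percentages in \[0, 100\],
#'   equal length.
#' @param labels row labels (default metric_1, ...).
#' @return data.frame with columns `label`, `pre`, `post`, `improvement`.
#' @examples
#' improvement_table(c(30, 25), c(80, 70),
#'                   c("X ± U interpretation", "conformity assessment"))
#' @export
improvement_table <- function(pre_pct, post_pct, labels = NULL) {
  pre_pct <- as.numeric(pre_pct)
  post_pct <- as.numeric(post_pct)
  if (length(pre_pct) != length(post_pct)) {
    stop("'pre_pct' and 'post_pct' must have equal length", call. = FALSE)
  }
  if (any(pre_pct < 0 | pre_pct > 100 | post_pct < 0 | post_pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("metric_", seq_along(pre_pct))
  stopifnot(length(labels) == length(pre_pct))
  data.frame(label = as.character(labels), pre = pre_pct, post = post_pct,
             improvement = post_pct - pre_pct, stringsAsFactors = FALSE)
}
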