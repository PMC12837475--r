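#' Conformity decision: coverage interval against an MRL
#'
#' The interval-against-MRL rule: a sample is `compliant` when the entire
#' coverage interval \[X − U, X + U\] lies below the maximum residue limit,
#' `non_compliant` when the entire interval lies above it, and
#' `inconclusive` when the MRL falls within the interval. Boundary equality
#' (an interval endpoint exactly on the MRL) is treated as inconclusive —
#' the consumer-protective reading of "entire interval below/above". With
#' U = 0 the rule reduces to the point comparison of X against the MRL.
#'
#' @param X measurand estimate(s), µg/kg.
#' @param U expanded uncertainty(ies), µg/kg (≥ 0).
#' @param mrl maximum residue limit, µg/kg (> 0; default 100, the limit for
#'   total fluoroquinolones in fish muscle).
#' @return Character vector: `"compliant"`, `"non_compliant"` or
#'   `"inconclusive"` (exactly one per input).
#' @examples
#' assess_conformity(188.10, 23.5)        # non_compliant
#' assess_conformity(95, 10)              # inconclusive
#' assess_conformity(80, 10)              # compliant
#' @export
assess_conformity <- function(X, U, mrl = 100) {
  stopifnot(is.numeric(X), is.numeric(U), is.numeric(mrl))
  if (any(!is.finite(X)) || any(!is.finite(U))) {
    stop("'X' and 'U' must be finite", call. = FALSE)
  }
  if (any(U < 0)) stop("'U' must be >= 0", call. = FALSE)
  if (any(!is.finite(mrl)) || any(mrl <= 0)) {
    stop("'mrl' must be > 0", call. = FALSE)
  }
  ifelse(X + U < mrl, "compliant",
         ifelse(X - U > mrl, "non_compliant", "inconclusive"))
}

#' Batch conformity assessment
#'
#' Applies [assess_conformity()] row-wise to a data frame with columns
#' `X` and `U` (and optionally `mrl` and `truth`), appending `decision`
#' and, when truth labels are present, `correct`.
#'
#' @param samples data.frame with numeric columns `X`, `U`, optionally
#'   `mrl` (otherwise the `mrl` argument applies) and character column
#'   `truth` (`"compliant"` / `"non_compliant"`).
#' @param mrl default MRL, used when the data has no `mrl` column.
#' @return The input with `decision` (and `correct`) columns appended.
#' @export
assess_batch <- function(samples, mrl = 100) {
  stopifnot(is.data.frame(samples), all(c("X", "U") %in% names(samples)))
  mrl_vec <- if ("mrl" %in% names(samples)) samples$mrl else
    rep(mrl, nrow(samples))
  samples$decision <- vapply(seq_len(nrow(samples)), function(i) {
    assess_conformity(samples$X[i], samples$U[i], mrl_vec[i])
  }, character(1))
  if ("truth" %in% names(samples)) {
    samples$correct <- samples$decision == samples$truth
  }
  samples
}

#' Decision accuracy against reference truth
#'
#' Fraction of decisions matching the reference (e.g. LC–MS/MS) truth
#' label, in percent. Truth is binary (compliant / non_compliant); an
#' inconclusive decision therefore counts as incorrect.
#'
#' @param decisions character vector of decisions, or a data.frame from
#'   [assess_batch()] with `decision` and `truth` columns.
#' @param truth character vector of reference labels (ignored when
#'   `decisions` is a data.frame).
#' @return Accuracy in percent.
#' @examples
#' score_accuracy(c("compliant", "inconclusive"),
#'                c("compliant", "compliant")) # 50
#' @export
score_accuracy <- function(decisions, truth = NULL) {
  if (is.data.frame(decisions)) {
    stopifnot(all(c("decision", "truth") %in% names(decisions)))
    truth <- decisions$truth
    decisions <- decisions$decision
  }
  if (length(decisions) == 0L) {
    stop("cannot score an empty set of decisions", call. = FALSE)
  }
  if (is.null(truth) || length(truth) != length(decisions)) {
    stop("every decision needs a truth label", call. = FALSE)
  }
  if (any(!truth %in% c("compliant", "non_compliant"))) {
    stop("truth labels must be 'compliant' or 'non_compliant'",
         call. = FALSE)
  }
  100 * sum(decisions == truth) / length(decisions)
}
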