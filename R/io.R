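#' Read a budget definition file
#'
#' JSON dialect: an object with a `components` array, each element having
#' `name` plus either `u` (relative standard uncertainty, fraction),
#' `replicates` (numeric array, evaluated type A), or `half_width` with
#' `distribution` and `nominal` (and `k_source` for normal), evaluated
#' type B. CSV dialect: columns `name,u` with one fixed relative
#' uncertainty per row. UTF-8, '.' decimal separator.
#'
#' @param path path to a `.json` or `.csv` budget definition.
#' @return Named list of sources suitable for [assemble_budget()].
#' @export
read_budget <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    if (!all(c("name", "u") %in% names(df))) {
      stop("budget CSV needs columns 'name' and 'u'", call. = FALSE)
    }
    sources <- as.list(as.numeric(df$u))
    names(sources) <- df$name
    return(sources)
  }
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    comps <- obj$components
    if (is.null(comps)) stop("budget JSON needs a 'components' array",
                             call. = FALSE)
    sources <- lapply(comps, function(comp) {
      if (!is.null(comp$u)) {
        as.numeric(comp$u)
      } else if (!is.null(comp$replicates)) {
        as.numeric(unlist(comp$replicates))
      } else if (!is.null(comp$half_width)) {
        uncertainty_component(
          comp$name,
          u = type_b_uncertainty(comp$half_width, comp$distribution,
                                 nominal = comp$nominal,
                                 k_source = comp$k_source),
          eval_type = "B"
        )
      } else {
        stop("component '", comp$name,
             "' needs 'u', 'replicates', or 'half_width'", call. = FALSE)
      }
    })
    names(sources) <- vapply(comps, `[[`, character(1), "name")
    return(sources)
  }
  stop("unsupported budget format '.", ext, "': use JSON or CSV",
       call. = FALSE)
}

#' Read an operator cohort CSV
#'
#' Accepts either the long layout (columns `operator_id, phase, volume,
#' replicate_index, value`) or the wide layout (`operator_id, phase,
#' volume, rep_1 .. rep_k`); returns the long layout.
#'
#' @param path CSV path (UTF-8, '.' decimals, header row mandatory).
#' @return Long-format data.frame `operator_id, phase, volume,
#'   replicate_index, value`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("operator_id", "phase", "volume")
  if (!all(need %in% names(df))) {
    stop("cohort CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("replicate_index", "value") %in% names(df))) {
    return(df[, c(need, "replicate_index", "value")])
  }
  rep_cols <- grep("^rep_[0-9]+$", names(df), value = TRUE)
  if (length(rep_cols) == 0L) {
    stop("cohort CSV needs either replicate_index/value columns or rep_1..rep_k",
         call. = FALSE)
  }
  rep_cols <- rep_cols[order(as.integer(sub("^rep_", "", rep_cols)))]
  long <- do.call(rbind, lapply(seq_along(rep_cols), function(j) {
    data.frame(df[, need, drop = FALSE], replicate_index = j,
               value = as.numeric(df[[rep_cols[j]]]),
               stringsAsFactors = FALSE)
  }))
  long[order(long$operator_id, long$phase, long$volume,
             long$replicate_index), , drop = FALSE]
}

#' Write an operator cohort to CSV (long layout)
#'
#' @param cohort a `qq_cohort` from [simulate_cohort()], or a long-format
#'   sessions data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  sessions <- if (inherits(cohort, "qq_cohort")) cohort$sessions else cohort
  stopifnot(is.data.frame(sessions))
  out <- sessions
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Paired per-operator metric from session data
#'
#' Computes the per-operator RSD (%) for one volume and both phases from
#' long-format session data and pairs them by operator.
#'
#' @param sessions long-format data.frame (see [read_cohort_csv()]).
#' @param volume which nominal volume to extract.
#' @return data.frame `operator_id, pre, post` (RSD in %).
#' @export
cohort_metric <- function(sessions, volume) {
  stopifnot(is.data.frame(sessions))
  sub <- sessions[sessions$volume == volume, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no sessions at volume ", volume, call. = FALSE)
  }
  ops <- sort(unique(sub$operator_id))
  get_rsd <- function(op, phase) {
    vals <- sub$value[sub$operator_id == op & sub$phase == phase]
    if (length(vals) < 2L) {
      stop("operator ", op, " lacks ", phase, " replicates at volume ",
           volume, call. = FALSE)
    }
    rsd(vals)
  }
  data.frame(
    operator_id = ops,
    pre = vapply(ops, get_rsd, numeric(1), phase = "pre"),
    post = vapply(ops, get_rsd, numeric(1), phase = "post"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
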