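# Western-blot-style marker validation: loading-control normalisation,
# threshold calls, and sensitivity/specificity summaries.

#' Normalise a marker band to its loading control
#'
#' Densitometric marker intensity divided by the loading-control (e.g.
#' beta-actin) band of the same lane; scale-invariant in the common
#' exposure factor.
#'
#' @param marker Marker band intensity (>= 0).
#' @param loading Loading-control intensity (> 0).
#' @return Normalised ratio(s).
#' @examples
#' normalize_band(10, 5)   # 2
#' @export
normalize_band <- function(marker, loading) {
  stopifnot(is.numeric(marker), is.numeric(loading))
  if (any(marker < 0)) stop("marker intensity must be >= 0", call. = FALSE)
  if (any(loading <= 0)) stop("loading-control intensity must be > 0",
                              call. = FALSE)
  marker / loading
}

#' Binary marker calls at a threshold
#'
#' A sample is called positive iff its normalised ratio is strictly greater
#' than the threshold; ties are negative, which makes threshold sweeps
#' deterministic.
#'
#' @param ratios Numeric vector of normalised ratios (may be named by
#'   sample).
#' @param threshold Call threshold (>= 0).
#' @return Logical vector of calls.
#' @export
call_marker <- function(ratios, threshold) {
  stopifnot(is.numeric(ratios), length(threshold) == 1L, threshold >= 0)
  ratios > threshold
}

#' Diagnostic summary of binary calls against group labels
#'
#' Builds the confusion matrix (cases are the positive class) and the
#' derived sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)`.
#' A metric whose denominator is zero (no cases, or no controls) is
#' reported as `NA`, never as 0.
#'
#' @param calls Logical vector of marker calls.
#' @param truth Group labels, `"case"` or `"control"`, same length/order.
#' @return An object of class `diagnostic_summary`: list with `confusion`
#'   (named integer vector TP/FP/TN/FN), `sensitivity`, `specificity`,
#'   `n`.
#' @examples
#' diagnostic_summary(c(TRUE, TRUE, FALSE, FALSE),
#'                    c("case", "case", "case", "control"))
#' @export
diagnostic_summary <- function(calls, truth) {
  stopifnot(is.logical(calls), length(calls) == length(truth))
  if (!all(truth %in% c("case", "control"))) {
    stop("truth labels must be 'case' or 'control'", call. = FALSE)
  }
  tp <- sum(calls & truth == "case")
  fn <- sum(!calls & truth == "case")
  tn <- sum(!calls & truth == "control")
  fp <- sum(calls & truth == "control")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = sens, specificity = spec,
                 n = length(calls)),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("n = %d  TP %d  FP %d  TN %d  FN %d\n", x$n,
              cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]]))
  cat(sprintf("sensitivity %s, specificity %s\n",
              ifelse(is.na(x$sensitivity), "n/a",
                     sprintf("%.1f%%", 100 * x$sensitivity)),
              ifelse(is.na(x$specificity), "n/a",
                     sprintf("%.1f%%", 100 * x$specificity))))
  invisible(x)
}

#' Validate a marker from a densitometry table
#'
#' Convenience wrapper: normalises each sample's marker band to its
#' loading control, calls at the threshold, and summarises.
#'
#' @param table Data.frame with columns `sample_id`, `group`,
#'   `marker_intensity`, `actin_intensity` (the [read_densitometry()]
#'   schema).
#' @param threshold Positivity threshold on the normalised ratio. The
#'   study does not state its criterion, so this is a required parameter.
#' @return A `diagnostic_summary` with the per-sample `ratios` and `calls`
#'   attached.
#' @export
validate_marker <- function(table, threshold) {
  need <- c("sample_id", "group", "marker_intensity", "actin_intensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("densitometry table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ratios <- stats::setNames(
    normalize_band(table$marker_intensity, table$actin_intensity),
    table$sample_id)
  calls <- call_marker(ratios, threshold)
  out <- diagnostic_summary(calls, table$group)
  out$threshold <- threshold
  out$ratios <- ratios
  out$calls <- calls
  out
}
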