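# Peak lists and internal recalibration against standard peptides.
#
# MALDI mass axes drift; the study spiked standard peptides into every
# sample and calibrated internally. Two standards determine an affine map
# exactly, so the calibration family here is reference = a * observed + b.

#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Matching intensities (>= 0, arbitrary units); defaults
#'   to 1.
#' @param id Spot/sample identifier.
#' @param calibrated Logical; whether the mass axis has been recalibrated.
#' @return A `peak_list`: a data.frame with columns `mz`, `intensity`,
#'   sorted ascending by m/z, carrying `id` and `calibrated` attributes.
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz)), id = "spot",
                      calibrated = FALSE) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (any(mz <= 0)) stop("m/z values must be strictly positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  structure(data.frame(mz = mz[ord], intensity = intensity[ord]),
            class = c("peak_list", "data.frame"),
            id = id, calibrated = isTRUE(calibrated))
}

is_calibrated <- function(peaks) isTRUE(attr(peaks, "calibrated"))

#' Default internal calibration standards
#'
#' Des-Arg1-bradykinin and the ACTH 18-39 clip, the two standard peptides
#' spiked into each sample. Reference m/z values are the singly protonated
#' monoisotopic masses computed from the sequences via [peptide_mass()],
#' not hard-coded numbers.
#'
#' @param standards Named character vector of peptide sequences; names are
#'   the standard names.
#' @return A data.frame with columns `name`, `sequence`, `ref_mz`.
#' @examples
#' reference_standards()
#' @export
reference_standards <- function(standards = c(
  "des-Arg1-bradykinin" = "PPGFSPFR",
  "ACTH_18-39" = "RPVKVYPNGAEDESAEAFPLEF")) {
  stopifnot(is.character(standards), !is.null(names(standards)))
  data.frame(
    name = names(standards),
    sequence = unname(standards),
    ref_mz = vapply(unname(standards),
                    function(s) mz_from_mass(peptide_mass(s), 1L), numeric(1),
                    USE.NAMES = FALSE)
  )
}

#' Match standard peptides to observed peaks
#'
#' Each standard is matched to the nearest peak within `coarse_tol`; ties
#' between two equidistant peaks break deterministically to the lower m/z.
#' The coarse window (default 1 Da) is far below inter-peptide spacing yet
#' far above pre-calibration MALDI error.
#'
#' @param peaks A [peak_list()].
#' @param standards A data.frame with `name` and `ref_mz` columns, e.g.
#'   [reference_standards()].
#' @param coarse_tol Matching window half-width in Da (> 0).
#' @return A data.frame `name`, `ref_mz`, `obs_mz` (NA when unmatched),
#'   `matched`. A warning is raised when fewer than 2 standards match
#'   (calibration impossible).
#' @export
match_references <- function(peaks, standards = reference_standards(),
                             coarse_tol = 1.0) {
  stopifnot(coarse_tol > 0, all(c("name", "ref_mz") %in% names(standards)))
  obs <- vapply(standards$ref_mz, function(ref) {
    d <- abs(peaks$mz - ref)
    i <- which(d <= coarse_tol)
    if (!length(i)) return(NA_real_)
    i <- i[order(d[i], peaks$mz[i])][1L]  # nearest; tie -> lower m/z
    peaks$mz[i]
  }, numeric(1))
  out <- data.frame(name = standards$name, ref_mz = standards$ref_mz,
                    obs_mz = obs, matched = !is.na(obs))
  if (sum(out$matched) < 2L) {
    warning("fewer than 2 standards matched: internal calibration impossible",
            call. = FALSE)
  }
  out
}

#' Fit the internal calibration model
#'
#' Least-squares fit of `reference = a * observed + b` over the matched
#' standard pairs. With exactly two pairs the fit is exact and both
#' residuals are zero.
#'
#' @param pairs Output of [match_references()], or any data.frame with
#'   `obs_mz` and `ref_mz` (rows with `matched == FALSE` are dropped).
#' @return A `calibration_model`: list with slope `a`, intercept `b` (Da)
#'   and per-reference `residuals` (Da).
#' @export
fit_calibration <- function(pairs) {
  if ("matched" %in% names(pairs)) pairs <- pairs[pairs$matched, , drop = FALSE]
  if (nrow(pairs) < 2L) {
    stop("need at least 2 matched reference pairs to calibrate", call. = FALSE)
  }
  if (anyDuplicated(pairs$obs_mz)) {
    stop("duplicate observed m/z among reference pairs", call. = FALSE)
  }
  fit <- stats::lm(ref_mz ~ obs_mz, data = pairs)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  if (a <= 0.9 || a >= 1.1) {
    warning(sprintf("calibration slope %.4f outside the (0.9, 1.1) sanity band", a),
            call. = FALSE)
  }
  res <- pairs$ref_mz - (a * pairs$obs_mz + b)
  names(res) <- if ("name" %in% names(pairs)) pairs$name else NULL
  structure(list(a = a, b = b, residuals = res, n_pairs = nrow(pairs)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration: ref = %.8f * obs + %.5f Da (%d standards, max |resid| %.2g Da)\n",
              x$a, x$b, x$n_pairs, max(abs(x$residuals))))
  invisible(x)
}

#' Apply a calibration model to a peak list
#'
#' Maps every m/z through `a * mz + b`; intensities and peak count are
#' untouched and the `calibrated` flag is set.
#'
#' @param peaks A raw [peak_list()].
#' @param model A [fit_calibration()] model.
#' @param override Set `TRUE` to recalibrate an already-calibrated list.
#' @return The calibrated `peak_list`.
#' @export
apply_calibration <- function(peaks, model, override = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  if (is_calibrated(peaks) && !override) {
    stop("peak list is already calibrated (use override = TRUE to recalibrate)",
         call. = FALSE)
  }
  peak_list(model$a * peaks$mz + model$b, peaks$intensity,
            id = attr(peaks, "id"), calibrated = TRUE)
}

#' Write a calibration report as JSON
#'
#' @param model A `calibration_model`.
#' @param pairs The matched reference pairs used for the fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(model, pairs, path) {
  jsonlite::write_json(
    list(a = model$a, b = model$b,
         residuals_da = as.list(model$residuals),
         standards = pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
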