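# Peptide mass fingerprinting: tolerance matching of calibrated peaks
# against a theoretical digest index, binomial chance scoring, and b/y
# fragment-ion confirmation for ambiguous spots.

#' PMF search parameters
#'
#' The default tolerance is 0.0025% of the theoretical mass (2.5e-5
#' relative), the setting used for the saliva spot searches. The mass
#' convention controls how theoretical peptides are rendered before
#' comparison: `"protonated"` ([M+H]+, the quantity a MALDI peak list
#' reports, the default) or `"neutral"`.
#'
#' @param tolerance Relative mass tolerance (fraction of theoretical mass).
#' @param mass_convention `"protonated"` or `"neutral"`.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @param min_matched Minimum matched peaks for a candidate to be reported.
#' @return An object of class `search_params`.
#' @export
search_params <- function(tolerance = 2.5e-5,
                          mass_convention = c("protonated", "neutral"),
                          mass_type = c("monoisotopic", "average"),
                          min_matched = 1L) {
  if (tolerance <= 0) stop("'tolerance' must be > 0", call. = FALSE)
  structure(list(tolerance = tolerance,
                 mass_convention = match.arg(mass_convention),
                 mass_type = match.arg(mass_type),
                 min_matched = as.integer(min_matched)),
            class = "search_params")
}

# theoretical peptide mass rendered in the search convention
.conventional_mass <- function(mass, params) {
  if (params$mass_convention == "protonated") mass + mass_constants()$proton
  else mass
}

#' Match observed peaks against a peptide index
#'
#' A peak p matches a theoretical peptide t iff
#' `|m(p) - m(t)| <= tolerance * m(t)`, with m(t) in the configured mass
#' convention. All matches are returned: one peak may match several
#' peptides and no greedy assignment is made.
#'
#' @param peaks A calibrated [peak_list()]. Uncalibrated input is refused
#'   unless `allow_uncalibrated = TRUE` (the search then proceeds with a
#'   warning).
#' @param index A [digest_database()] peptide index.
#' @param params A [search_params()].
#' @param allow_uncalibrated Explicit override for raw peak lists.
#' @return A data.frame with one row per (peak, peptide) match:
#'   `peak_mz`, `accession`, `start`, `end`, `sequence`, `missed`, `mass`
#'   (neutral), `conv_mass` (in the search convention) and `error_da`.
#' @export
match_peaks <- function(peaks, index, params = search_params(),
                        allow_uncalibrated = FALSE) {
  stopifnot(inherits(index, "peptide_index"))
  if (!nrow(index)) stop("peptide index is empty", call. = FALSE)
  if (!is_calibrated(peaks)) {
    if (!allow_uncalibrated) {
      stop("peak list is not calibrated; pass allow_uncalibrated = TRUE to search anyway",
           call. = FALSE)
    }
    warning("searching an uncalibrated peak list", call. = FALSE)
  }
  conv <- .conventional_mass(index$mass, params)   # ascending, same order
  tol <- params$tolerance
  hits <- lapply(seq_len(nrow(peaks)), function(i) {
    obs <- peaks$mz[i]
    # |obs - m| <= tol * m  <=>  m in [obs / (1 + tol), obs / (1 - tol)]
    lo <- findInterval(obs / (1 + tol), conv, left.open = TRUE) + 1L
    hi <- findInterval(obs / (1 - tol), conv)
    if (hi < lo) return(NULL)
    j <- lo:hi
    data.frame(peak_mz = obs, index[j, , drop = FALSE],
               conv_mass = conv[j], error_da = obs - conv[j])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(peak_mz = numeric(), accession = character(),
                      start = integer(), end = integer(),
                      sequence = character(), missed = integer(),
                      mass = numeric(), conv_mass = numeric(),
                      error_da = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Score and rank candidate proteins
#'
#' For each candidate the matched peak count k (distinct peaks; duplicate
#' peptide masses from sequence repeats count once), the sequence coverage,
#' and a chance score: -log10 of the binomial tail probability of observing
#' >= k matches among the n peaks when each peak independently matches the
#' candidate with probability
#' `p = (candidate peptides within the observed mass range * mean window
#' width) / observed mass range`. Ranking is total and deterministic:
#' chance score desc, matched count desc, coverage desc, accession.
#'
#' @param matches Output of [match_peaks()].
#' @param index The peptide index searched.
#' @param peaks The peak list searched.
#' @param params The [search_params()] used.
#' @return A data.frame of ranked candidates: `rank`, `accession`,
#'   `n_matched`, `coverage`, `score`, `peptides` (semicolon-joined
#'   matched sequences).
#' @export
score_candidates <- function(matches, index, peaks, params = search_params()) {
  empty <- data.frame(rank = integer(), accession = character(),
                      n_matched = integer(), coverage = numeric(),
                      score = numeric(), peptides = character())
  if (!nrow(matches)) return(empty)
  n <- nrow(peaks)
  rng <- range(peaks$mz)
  span <- diff(rng)
  conv <- .conventional_mass(index$mass, params)
  plen <- attr(index, "protein_lengths")
  cand <- split(matches, matches$accession)
  rows <- lapply(names(cand), function(acc) {
    m <- cand[[acc]]
    k <- length(unique(m$peak_mz))
    # coverage: union of matched residue intervals over the parent length
    covered <- unique(unlist(mapply(seq, m$start, m$end, SIMPLIFY = FALSE)))
    coverage <- length(covered) / plen[[acc]]
    in_range <- which(index$accession == acc & conv >= rng[1] & conv <= rng[2])
    p_hat <- if (span > 0 && length(in_range)) {
      length(in_range) * mean(2 * params$tolerance * conv[in_range]) / span
    } else {
      # degenerate spectrum (single peak) or no candidate peptide in range:
      # fall back to the width of one window at the spectrum location
      2 * params$tolerance
    }
    p_hat <- min(max(p_hat, 1e-12), 1 - 1e-12)
    log_tail <- stats::pbinom(k - 1L, n, p_hat, lower.tail = FALSE,
                              log.p = TRUE)
    score <- -log_tail / log(10)
    pep <- sort(unique(m$sequence))
    data.frame(accession = acc, n_matched = k, coverage = coverage,
               score = score, peptides = paste(pep, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_matched >= params$min_matched, , drop = FALSE]
  if (!nrow(out)) return(empty)
  ord <- order(-out$score, -out$n_matched, -out$coverage, out$accession)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Full PMF search of one spot
#'
#' Composes [digest_database()], [match_peaks()] and [score_candidates()].
#' The result is invariant to the order of the input peaks and fully
#' determined by inputs and parameters.
#'
#' @param peaks A calibrated [peak_list()].
#' @param records Protein database records (see [digest_database()]), or a
#'   prebuilt `peptide_index`.
#' @param params A [search_params()].
#' @param rule,digestion Digestion settings ([cleavage_rule()] and
#'   [digest_params()]) used when `records` is not already an index.
#' @param allow_uncalibrated Passed to [match_peaks()].
#' @return An object of class `pmf_result`: list with `spot`, `candidates`
#'   (ranked data.frame), `n_peaks`, `n_unmatched_peaks` and `params`.
#' @export
pmf_search <- function(peaks, records, params = search_params(),
                       rule = cleavage_rule(),
                       digestion = digest_params(),
                       allow_uncalibrated = FALSE) {
  index <- if (inherits(records, "peptide_index")) records
           else digest_database(records, rule, digestion,
                                mass_type = params$mass_type)
  matches <- match_peaks(peaks, index, params, allow_uncalibrated)
  cand <- score_candidates(matches, index, peaks, params)
  structure(list(spot = attr(peaks, "id"),
                 candidates = cand,
                 n_peaks = nrow(peaks),
                 n_unmatched_peaks = nrow(peaks) -
                   length(unique(matches$peak_mz)),
                 params = unclass(params)),
            class = "pmf_result")
}

#' @export
print.pmf_result <- function(x, ...) {
  cat(sprintf("PMF search of spot '%s': %d peaks (%d unmatched), %d candidates\n",
              x$spot, x$n_peaks, x$n_unmatched_peaks, nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("rank", "accession", "n_matched",
                                       "coverage", "score")], 5))
  }
  invisible(x)
}

#' Serialise a PMF result as JSON
#'
#' The report embeds the search parameters verbatim for provenance; field
#' order is stable so identical inputs give byte-identical reports.
#'
#' @param result A `pmf_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_result <- function(result, path) {
  stopifnot(inherits(result, "pmf_result"))
  jsonlite::write_json(
    list(schema = "pmf2de/pmf_result/1", spot = result$spot,
         params = result$params, n_peaks = result$n_peaks,
         n_unmatched_peaks = result$n_unmatched_peaks,
         candidates = result$candidates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fragment-ion confirmation of a candidate peptide
#'
#' Counts fragment peaks (from a LIFT TOF/TOF experiment) that match the
#' singly charged b/y ladders of the candidate within a relative tolerance.
#' An n-residue peptide has 2(n-1) ladder ions; the matched fraction is
#' `matched / (2(n-1))`.
#'
#' @param sequence Candidate peptide (length >= 2).
#' @param fragment_peaks A [peak_list()] of fragment ions.
#' @param tolerance Relative tolerance (fraction of the theoretical
#'   fragment m/z). Default 2.5e-4, looser than the MS-mode tolerance as
#'   LIFT fragment masses are less accurate.
#' @return List with `n_matched`, `n_ions`, `fraction` and a logical
#'   `matched` vector over the named ladder ions.
#' @export
fragment_confirm <- function(sequence, fragment_peaks, tolerance = 2.5e-4) {
  ladder <- c(fragment_ions(sequence, "b"), fragment_ions(sequence, "y"))
  matched <- vapply(ladder, function(mz) {
    any(abs(fragment_peaks$mz - mz) <= tolerance * mz)
  }, logical(1))
  list(n_matched = sum(matched), n_ions = length(ladder),
       fraction = sum(matched) / length(ladder), matched = matched)
}
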