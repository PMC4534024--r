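# Mass tables and peptide chemistry.
#
# Element masses are pinned here, in one place, so every downstream mass in
# the package is bit-reproducible. Monoisotopic masses are the CODATA/NIST
# values for the principal isotope; average masses are the IUPAC 2005
# standard atomic weights.

.element_masses <- data.frame(
  symbol = c("C", "H", "N", "O", "S"),
  monoisotopic = c(12.0, 1.00782503207, 14.0030740048, 15.99491461956,
                   31.972071),
  average = c(12.0107, 1.00794, 14.0067, 15.9994, 32.065),
  stringsAsFactors = FALSE
)

# Elemental composition of each residue *after* peptide-bond condensation
# (i.e. the free amino acid minus one water). Columns follow
# .element_masses$symbol. Exactly the 20 standard residues.
.residue_composition <- matrix(
  c( # C   H   N  O  S
     3,  5,  1, 1, 0,  # A
     3,  5,  1, 1, 1,  # C
     4,  5,  1, 3, 0,  # D
     5,  7,  1, 3, 0,  # E
     9,  9,  1, 1, 0,  # F
     2,  3,  1, 1, 0,  # G
     6,  7,  3, 1, 0,  # H
     6, 11,  1, 1, 0,  # I
     6, 12,  2, 1, 0,  # K
     6, 11,  1, 1, 0,  # L
     5,  9,  1, 1, 1,  # M
     4,  6,  2, 2, 0,  # N
     5,  7,  1, 1, 0,  # P
     5,  8,  2, 2, 0,  # Q
     6, 12,  4, 1, 0,  # R
     3,  5,  1, 2, 0,  # S
     4,  7,  1, 2, 0,  # T
     5,  9,  1, 1, 0,  # V
    11, 10,  2, 1, 0,  # W
     9,  9,  1, 2, 0), # Y
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S"))
)

.residue_masses <- list(
  monoisotopic = drop(.residue_composition %*% .element_masses$monoisotopic),
  average      = drop(.residue_composition %*% .element_masses$average)
)

#' Physical mass constants
#'
#' Water (lost on peptide-bond condensation, regained at the termini) and the
#' proton (gained on MALDI ionisation), in daltons.
#'
#' @return Named list with `water_monoisotopic`, `water_average` and
#'   `proton` (Da).
#' @examples
#' mass_constants()$proton
#' @export
mass_constants <- function() {
  el <- .element_masses
  rownames(el) <- el$symbol
  list(
    water_monoisotopic = 2 * el["H", "monoisotopic"] + el["O", "monoisotopic"],
    water_average      = 2 * el["H", "average"] + el["O", "average"],
    proton             = 1.00727646677
  )
}

.check_sequence <- function(sequence, min_length = 1L) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence) ||
      nchar(sequence) < min_length) {
    stop("'sequence' must be a single residue string of length >= ",
         min_length, call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), rownames(.residue_composition))
  if (length(bad)) {
    stop("unknown residue(s) in sequence: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  res
}

#' Neutral mass of a peptide
#'
#' Sums residue masses over the sequence and adds one water for the termini.
#'
#' @param sequence Peptide as a string of one-letter codes for the 20
#'   standard residues (unmodified; see `fixed_modification`).
#' @param mass_type `"monoisotopic"` (default, as used throughout the
#'   pipeline) or `"average"`.
#' @param fixed_modification Optional named numeric vector of per-residue
#'   mass offsets in Da (e.g. `c(C = 57.02146)` for carbamidomethyl-Cys),
#'   added once per occurrence of the residue.
#' @return Neutral peptide mass in Da.
#' @examples
#' peptide_mass("G")                       # glycine, 75.03203 Da
#' peptide_mass("PEPTIDE", "average")
#' @export
peptide_mass <- function(sequence,
                         mass_type = c("monoisotopic", "average"),
                         fixed_modification = NULL) {
  mass_type <- match.arg(mass_type)
  res <- .check_sequence(sequence)
  m <- sum(.residue_masses[[mass_type]][res]) +
    if (mass_type == "monoisotopic") mass_constants()$water_monoisotopic
    else mass_constants()$water_average
  if (!is.null(fixed_modification)) {
    stopifnot(is.numeric(fixed_modification), !is.null(names(fixed_modification)))
    counts <- table(factor(res, levels = names(fixed_modification)))
    m <- m + sum(as.numeric(counts) * fixed_modification)
  }
  unname(m)
}

#' m/z of a protonated ion
#'
#' MALDI produces predominantly singly protonated ions; the observed m/z of
#' `[M + zH]^z+` is `(M + z * proton) / z`.
#'
#' @param neutral_mass Neutral mass M in Da (> 0).
#' @param charge Positive integer charge state (default 1).
#' @return m/z value.
#' @examples
#' mz_from_mass(1000, 1)   # 1001.00728
#' @export
mz_from_mass <- function(neutral_mass, charge = 1L) {
  if (any(neutral_mass <= 0)) stop("'neutral_mass' must be > 0", call. = FALSE)
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != as.integer(charge)) {
    stop("'charge' must be a positive integer", call. = FALSE)
  }
  (neutral_mass + charge * mass_constants()$proton) / charge
}

#' b- and y-series fragment ions
#'
#' Singly charged b (N-terminal prefix) and y (C-terminal suffix) ladder
#' m/z values, as produced by MALDI LIFT-TOF/TOF laser-induced dissociation.
#' An n-residue peptide yields n-1 ions per series: `b_i` covers the prefix
#' of length i, `y_j` the suffix of length j.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param series `"b"` or `"y"`.
#' @param charge Charge state; only 1 is used by the pipeline.
#' @return Numeric vector of n-1 m/z values, named `b1..b(n-1)` or
#'   `y1..y(n-1)`.
#' @examples
#' fragment_ions("PEPTIDE", "y")
#' @export
fragment_ions <- function(sequence, series = c("b", "y"), charge = 1L) {
  series <- match.arg(series)
  res <- .check_sequence(sequence, min_length = 2L)
  n <- length(res)
  rm <- .residue_masses$monoisotopic
  const <- mass_constants()
  if (series == "b") {
    # b_i = prefix residue sum + proton (acylium-type, no water)
    neutral <- cumsum(rm[res])[-n]
  } else {
    # y_j = suffix residue sum + water + proton (a truncated peptide)
    neutral <- cumsum(rm[rev(res)])[-n] + const$water_monoisotopic
  }
  mz <- (neutral + charge * const$proton) / charge
  names(mz) <- paste0(series, seq_len(n - 1L))
  mz
}

#' Export the pinned mass constants as JSON
#'
#' Writes the element table, the per-residue compositions and masses, and
#' the water/proton constants to a JSON file for external audit.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_mass_constants <- function(path) {
  comp <- as.data.frame(.residue_composition)
  comp$residue <- rownames(.residue_composition)
  out <- list(
    elements = .element_masses,
    residues = data.frame(
      comp[, c("residue", "C", "H", "N", "O", "S")],
      monoisotopic = unname(.residue_masses$monoisotopic),
      average = unname(.residue_masses$average)
    ),
    constants = mass_constants()
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
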