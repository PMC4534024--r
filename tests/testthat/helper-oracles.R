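# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# --- elemental-composition oracle for peptide masses -----------------------
# Free amino-acid molecular formulas (entered independently of the package's
# residue table); the peptide is n free acids minus (n-1) waters.
.ORACLE_AA_FORMULA <- list(
  A = c(C = 3, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  D = c(C = 4, H = 7, N = 1, O = 4, S = 0),
  E = c(C = 5, H = 9, N = 1, O = 4, S = 0),
  F = c(C = 9, H = 11, N = 1, O = 2, S = 0),
  G = c(C = 2, H = 5, N = 1, O = 2, S = 0),
  H = c(C = 6, H = 9, N = 3, O = 2, S = 0),
  I = c(C = 6, H = 13, N = 1, O = 2, S = 0),
  K = c(C = 6, H = 14, N = 2, O = 2, S = 0),
  L = c(C = 6, H = 13, N = 1, O = 2, S = 0),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  N = c(C = 4, H = 8, N = 2, O = 3, S = 0),
  P = c(C = 5, H = 9, N = 1, O = 2, S = 0),
  Q = c(C = 5, H = 10, N = 2, O = 3, S = 0),
  R = c(C = 6, H = 14, N = 4, O = 2, S = 0),
  S = c(C = 3, H = 7, N = 1, O = 3, S = 0),
  T = c(C = 4, H = 9, N = 1, O = 3, S = 0),
  V = c(C = 5, H = 11, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 12, N = 2, O = 2, S = 0),
  Y = c(C = 9, H = 11, N = 1, O = 3, S = 0))

.ORACLE_ELEMENT <- list(
  monoisotopic = c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.99491461956, S = 31.972071),
  average = c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065))

oracle_peptide_mass <- function(sequence, mass_type = "monoisotopic") {
  res <- strsplit(sequence, "")[[1]]
  atoms <- Reduce(`+`, .ORACLE_AA_FORMULA[res])
  el <- .ORACLE_ELEMENT[[mass_type]]
  water <- 2 * el[["H"]] + el[["O"]]
  sum(atoms * el[names(atoms)]) - (length(res) - 1) * water
}

random_peptide <- function(len) {
  paste(sample(names(.ORACLE_AA_FORMULA), len, replace = TRUE), collapse = "")
}

# --- brute-force peak/peptide matcher --------------------------------------
# Quadratic all-pairs scan over (peak, index row); mirrors the matching
# definition, not the package's binary-search implementation.
oracle_match_peaks <- function(peaks, index, tolerance,
                               convention = "protonated") {
  proton <- 1.00727646677
  conv <- if (convention == "protonated") index$mass + proton else index$mass
  hits <- which(outer(peaks$mz, conv,
                      function(p, m) abs(p - m) <= tolerance * m),
                arr.ind = TRUE)
  data.frame(peak_mz = peaks$mz[hits[, 1]],
             accession = index$accession[hits[, 2]],
             sequence = index$sequence[hits[, 2]])
}

# canonical key for comparing match sets regardless of row order
match_key <- function(df) {
  sort(sprintf("%.6f|%s|%s", df$peak_mz, df$accession, df$sequence))
}

# --- normal-equations line-fit oracle ---------------------------------------
oracle_line_fit <- function(x, y) {
  n <- length(x)
  a <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- (sum(y) - a * sum(x)) / n
  c(a = a, b = b)
}

# --- brute-force missed-cleavage digest oracle ------------------------------
# Enumerates every (start site, end site) pair of cleavage boundaries and
# keeps peptides with at most `max_missed` retained internal sites.
oracle_digest_sequences <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  sites <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  bounds <- c(0, sites, n)
  out <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(length(bounds) - 1, i + max_missed)) {
      out <- c(out, substr(sequence, bounds[i] + 1, bounds[j + 1]))
    }
  }
  out
}
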