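# Rule-based in-silico protease digestion and the mass-sorted peptide index.

#' Protease cleavage rule
#'
#' A rule cleaves C-terminal to any residue in `cleave_after` unless the
#' following residue is in `suppress_before`. The default is trypsin:
#' after K or R, not before P.
#'
#' @param name Rule name (informational).
#' @param cleave_after Character vector of residues cut after.
#' @param suppress_before Residues that suppress cleavage when they follow
#'   the site.
#' @return An object of class `cleavage_rule`.
#' @examples
#' cleavage_rule()            # trypsin
#' @export
cleavage_rule <- function(name = "trypsin",
                          cleave_after = c("K", "R"),
                          suppress_before = "P") {
  if (!length(cleave_after)) stop("'cleave_after' must be non-empty", call. = FALSE)
  if (length(intersect(cleave_after, suppress_before))) {
    stop("'cleave_after' and 'suppress_before' must be disjoint", call. = FALSE)
  }
  structure(list(name = name, cleave_after = cleave_after,
                 suppress_before = suppress_before),
            class = "cleavage_rule")
}

#' Digestion parameters
#'
#' Defaults: one missed cleavage (the conventional PMF setting) and a
#' 500-4000 Da peptide window, the usable range of a MALDI reflector
#' instrument. Pass `min_mass = 0, max_mass = Inf` to disable filtering.
#'
#' @param max_missed Maximum missed cleavages (integer >= 0).
#' @param min_length,max_length Peptide length bounds in residues.
#' @param min_mass,max_mass Neutral monoisotopic mass bounds in Da.
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(max_missed = 1L, min_length = 1L, max_length = Inf,
                          min_mass = 500, max_mass = 4000) {
  stopifnot(max_missed >= 0, min_length <= max_length, min_mass <= max_mass)
  structure(list(max_missed = as.integer(max_missed),
                 min_length = min_length, max_length = max_length,
                 min_mass = min_mass, max_mass = max_mass),
            class = "digest_params")
}

# 0-based positions after which the rule cleaves (i.e. cut between i and i+1)
.cleavage_sites <- function(res, rule) {
  n <- length(res)
  if (n < 2L) return(integer(0))
  i <- which(res[-n] %in% rule$cleave_after &
             !(res[-1L] %in% rule$suppress_before))
  i
}

#' In-silico digestion of one protein
#'
#' Enumerates all peptides bounded by cleavage sites (or the protein
#' termini) with at most `params$max_missed` internal sites retained, then
#' applies the length and mass windows. Output is ordered by start
#' coordinate, then peptide length.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param rule A [cleavage_rule()].
#' @param params A [digest_params()].
#' @param mass_type Passed to [peptide_mass()].
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `sequence`, `missed`, `mass`.
#' @examples
#' digest("MKRA", params = digest_params(max_missed = 0, min_mass = 0,
#'                                       max_mass = Inf))
#' @export
digest <- function(sequence, rule = cleavage_rule(), params = digest_params(),
                   mass_type = "monoisotopic") {
  res <- .check_sequence(sequence)
  n <- length(res)
  sites <- .cleavage_sites(res, rule)
  bounds <- c(0L, sites, n)           # fragment boundaries
  nf <- length(bounds) - 1L           # number of fully cleaved fragments
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + params$max_missed)
    starts <- bounds[i] + 1L
    ends <- bounds[(i + 1L):(jmax + 1L)]
    out[[i]] <- data.frame(start = starts, end = ends,
                           missed = seq_along(ends) - 1L)
  }
  pep <- do.call(rbind, out)
  pep$sequence <- substring(sequence, pep$start, pep$end)
  len <- pep$end - pep$start + 1L
  keep <- len >= params$min_length & len <= params$max_length
  pep <- pep[keep, , drop = FALSE]
  pep$mass <- vapply(pep$sequence, peptide_mass, numeric(1),
                     mass_type = mass_type, USE.NAMES = FALSE)
  pep <- pep[pep$mass >= params$min_mass & pep$mass <= params$max_mass, ,
             drop = FALSE]
  pep <- pep[order(pep$start, pep$end), c("start", "end", "sequence",
                                          "missed", "mass")]
  rownames(pep) <- NULL
  pep
}

#' Digest a protein database into a mass-sorted peptide index
#'
#' Digests every record and concatenates the peptides into an index sorted
#' ascending by mass, supporting O(log N) mass-window queries via
#' [query_index()]. Every peptide stays traceable to its parent accession
#' and coordinates.
#'
#' @param records Protein records: a data.frame with columns `accession`
#'   and `sequence` (as returned by [read_fasta()] or
#'   [simulate_protein_db()]), or a named character vector.
#' @inheritParams digest
#' @return An object of class `peptide_index`: a data.frame
#'   (`accession`, `start`, `end`, `sequence`, `missed`, `mass`) sorted by
#'   mass, with the digestion settings and per-protein lengths as
#'   attributes.
#' @export
digest_database <- function(records, rule = cleavage_rule(),
                            params = digest_params(),
                            mass_type = "monoisotopic") {
  records <- .as_protein_records(records)
  if (anyDuplicated(records$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "), call. = FALSE)
  }
  per <- lapply(seq_len(nrow(records)), function(i) {
    d <- digest(records$sequence[i], rule, params, mass_type)
    if (nrow(d)) d$accession <- records$accession[i]
    d
  })
  idx <- do.call(rbind, per[vapply(per, nrow, integer(1)) > 0L])
  if (is.null(idx)) {
    idx <- data.frame(accession = character(), start = integer(),
                      end = integer(), sequence = character(),
                      missed = integer(), mass = numeric())
  }
  idx <- idx[order(idx$mass), c("accession", "start", "end", "sequence",
                                "missed", "mass")]
  rownames(idx) <- NULL
  structure(idx, class = c("peptide_index", "data.frame"),
            rule = rule, params = params, mass_type = mass_type,
            protein_lengths = stats::setNames(nchar(records$sequence),
                                              records$accession))
}

.as_protein_records <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records))) {
      stop("protein records given as a character vector must be named by accession",
           call. = FALSE)
    }
    records <- data.frame(accession = names(records), sequence = unname(records))
  }
  if (!all(c("accession", "sequence") %in% names(records))) {
    stop("protein records need 'accession' and 'sequence' columns", call. = FALSE)
  }
  records
}

#' Mass-window query on a peptide index
#'
#' Binary search (via `findInterval` on the mass-sorted index) for all
#' peptides with mass in `[mass - half_width, mass + half_width]`.
#'
#' @param index A `peptide_index` from [digest_database()].
#' @param mass Query mass in Da (same mass scale the index was built on).
#' @param half_width Window half-width in Da.
#' @return The matching rows of the index.
#' @export
query_index <- function(index, mass, half_width) {
  stopifnot(inherits(index, "peptide_index"), half_width >= 0)
  lo <- findInterval(mass - half_width, index$mass, left.open = TRUE) + 1L
  hi <- findInterval(mass + half_width, index$mass)
  if (hi < lo) return(index[0L, , drop = FALSE])
  index[lo:hi, , drop = FALSE]
}

#' Export a digest as TSV
#'
#' Columns: accession (omitted for a single-protein digest), start, end,
#' sequence, missed, mass. Coordinates are 1-based inclusive; masses are
#' written with 5 decimal places.
#'
#' @param digest_table Output of [digest()] or [digest_database()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(digest_table, path) {
  tab <- as.data.frame(digest_table)
  tab$mass <- sprintf("%.5f", tab$mass)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# in-silico digest; start/end are 1-based inclusive residue coordinates",
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
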