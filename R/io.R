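# Readers and writers for the pipeline's file formats: FASTA protein
# databases, two-column TSV and minimal-MGF peak lists, spot-volume CSV
# and densitometry CSV tables. Validation errors name the file and, where
# possible, the offending line or column.

#' Read a protein FASTA file
#'
#' Multi-line (wrapped) sequences and `>accession description` headers are
#' handled by `Biostrings::readAAStringSet`; the accession is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @return Data.frame with `accession`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  data.frame(accession = acc, sequence = as.character(aa),
             description = desc, row.names = NULL)
}

#' Write protein records as FASTA
#'
#' @param records Data.frame with `accession`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- .as_protein_records(records)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- if (!is.null(records$description) &&
                   any(nzchar(records$description))) {
    trimws(paste(records$accession, records$description))
  } else records$accession
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read a two-column peak-list TSV
#'
#' Format: optional `#` comment lines, then one `m/z<TAB>intensity` pair
#' per line.
#'
#' @param path File path.
#' @param id Spot identifier (defaults to the file name without
#'   extension).
#' @param calibrated Whether the file holds an already-calibrated mass
#'   axis.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, id = NULL, calibrated = FALSE) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (is.null(id)) {
    # recover the id recorded by write_peaklist, else fall back to the name
    m <- regmatches(lines, regexec("^# peak list '([^']*)'", lines))
    hit <- which(lengths(m) == 2L)
    id <- if (length(hit)) m[[hit[1L]]][2L]
          else sub("\\.[^.]*$", "", basename(path))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) return(peak_list(numeric(0), numeric(0), id, calibrated))
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(path, " line ", rows[bad[1L]],
         ": expected two whitespace-separated columns (m/z, intensity)",
         call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(int) | mz <= 0 | int < 0)
  if (length(bad)) {
    stop(path, " line ", rows[bad[1L]],
         ": invalid m/z or intensity value", call. = FALSE)
  }
  peak_list(mz, int, id = id, calibrated = calibrated)
}

#' Write a peak list as two-column TSV
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# peak list '%s'%s", attr(peaks, "id"),
                     if (is_calibrated(peaks)) " (calibrated)" else ""), con)
  writeLines(sprintf("%.5f\t%g", peaks$mz, peaks$intensity), con)
  invisible(path)
}

#' Read a minimal MGF peak-list file
#'
#' Supports the dialect `BEGIN IONS` / `TITLE=...` / one `m/z intensity`
#' pair per line / `END IONS`; one or more blocks per file.
#'
#' @param path File path.
#' @param calibrated Whether the mass axes are calibrated.
#' @return A list of [peak_list()] objects, one per IONS block, named by
#'   TITLE.
#' @export
read_mgf <- function(path, calibrated = FALSE) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop(path, ": unbalanced BEGIN IONS / END IONS", call. = FALSE)
  }
  if (!length(begins)) stop(path, ": no IONS block found", call. = FALSE)
  out <- lapply(seq_along(begins), function(k) {
    body <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    title_i <- grep("^TITLE=", body)
    title <- if (length(title_i)) sub("^TITLE=", "", body[title_i[1L]])
             else sprintf("ions_%d", k)
    ion_lines <- body[!grepl("^[A-Z]+=", body) & nzchar(trimws(body))]
    if (!length(ion_lines)) {
      return(peak_list(numeric(0), numeric(0), title, calibrated))
    }
    parts <- strsplit(trimws(ion_lines), "\\s+")
    if (any(lengths(parts) < 2L)) {
      stop(path, ": malformed ion line in block ", k, call. = FALSE)
    }
    mz <- as.numeric(vapply(parts, `[[`, "", 1L))
    int <- as.numeric(vapply(parts, `[[`, "", 2L))
    if (anyNA(mz) || anyNA(int)) {
      stop(path, ": non-numeric ion line in block ", k, call. = FALSE)
    }
    peak_list(mz, int, id = title, calibrated = calibrated)
  })
  names(out) <- vapply(out, attr, "", "id")
  out
}

#' Write peak lists as minimal MGF
#'
#' @param peaks A [peak_list()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(peaks, path) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in peaks) {
    writeLines(c("BEGIN IONS", paste0("TITLE=", attr(p, "id")),
                 sprintf("%.5f %g", p$mz, p$intensity), "END IONS"), con)
  }
  invisible(path)
}

#' Read a spot-volume CSV table
#'
#' Schema (header required): `gel_id,group,fraction,spot_id,protein,
#' raw_volume`, UTF-8, '.' decimal. Rows with negative volumes or groups
#' other than case/control are rejected with their line number.
#'
#' @param path CSV file path.
#' @return The validated spot table data.frame.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gel_id", "group", "fraction", "spot_id", "protein", "raw_volume")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!tab$group %in% c("case", "control"))
  if (length(bad)) {
    stop(path, " line ", bad[1L] + 1L, ": group must be 'case' or 'control'",
         call. = FALSE)
  }
  bad <- which(!is.finite(tab$raw_volume) | tab$raw_volume < 0)
  if (length(bad)) {
    stop(path, " line ", bad[1L] + 1L, ": raw_volume must be >= 0",
         call. = FALSE)
  }
  .check_spot_table(tab)
  tab
}

#' Write a spot-volume CSV table
#'
#' @param table A spot table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(table, path) {
  .check_spot_table(table, require_fraction = TRUE)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a densitometry CSV table
#'
#' Schema: `sample_id,group,marker_intensity,actin_intensity`.
#'
#' @param path CSV file path.
#' @return Validated data.frame for [validate_marker()].
#' @export
read_densitometry <- function(path) {
  if (!file.exists(path)) stop("densitometry table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "marker_intensity", "actin_intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(tab$actin_intensity <= 0)
  if (length(bad)) {
    stop(path, " line ", bad[1L] + 1L, ": actin_intensity must be > 0",
         call. = FALSE)
  }
  tab
}
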