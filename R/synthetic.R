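# Seeded generators emulating the study's inputs: protein databases,
# MALDI peak lists with realistic corruptions (missing peptides, relative
# mass error, noise peaks, linear calibration drift), and two-group
# spot-volume tables with planted fold changes.
#
# Every generator is a pure function of its arguments including the
# mandatory seed: identical calls give byte-identical outputs. The RNG
# state of the session is left untouched.

.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a protein database
#'
#' Uniform random sequences over the 20 standard residues, standing in for
#' a reference protein database in end-to-end simulations.
#'
#' @param n Number of proteins (>= 1).
#' @param length_range Integer range of sequence lengths (inclusive).
#' @param seed RNG seed (required).
#' @return A data.frame with `accession` (`SYN0001`...), `sequence` and
#'   `description` columns, usable directly by [digest_database()] and
#'   [write_fasta()].
#' @export
simulate_protein_db <- function(n = 50, length_range = c(100, 400), seed) {
  stopifnot(n >= 1, length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  aa <- rownames(.residue_composition)
  .with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
    data.frame(accession = sprintf("SYN%04d", seq_len(n)),
               sequence = seqs,
               description = sprintf("synthetic protein %d length %d",
                                     seq_len(n), lens))
  })
}

#' Simulate a PMF spectrum from a database protein
#'
#' Emulates MALDI acquisition of one digested spot: tryptic peptides of the
#' source protein (default digestion settings, unique [M+H]+ masses) are
#' retained i.i.d. with `detection_prob`; each surviving mass is perturbed
#' by Gaussian relative error of `mass_error_ppm` ppm (1 sd); `n_noise`
#' spurious peaks are drawn uniformly over `noise_range`; the calibration
#' standards are appended when `include_standards`; finally every m/z is
#' passed through the instrument drift `m -> drift_a * m + drift_b`.
#'
#' @param db Protein records (see [digest_database()]).
#' @param accession Source protein accession (must be in `db`).
#' @param detection_prob Per-peptide detection probability in \[0, 1\].
#' @param mass_error_ppm Relative mass error sd, ppm.
#' @param n_noise Number of spurious peaks.
#' @param noise_range m/z range of spurious peaks, Da.
#' @param drift_a,drift_b Affine drift applied to the final mass axis; the
#'   identity `(1, 0)` means a perfectly calibrated instrument.
#' @param include_standards Append the [reference_standards()] peptides
#'   (at their exact reference m/z, before drift) so the spectrum can be
#'   internally recalibrated.
#' @param seed RNG seed (required).
#' @param rule,digestion Digestion settings for the source protein.
#' @return List with `peaks` (an uncalibrated [peak_list()]) and `truth`
#'   (list: `accession`, data.frame `peptides` with `sequence`, `true_mz`,
#'   `observed_mz`, plus `n_noise`, `n_standards`, `drift_a`, `drift_b`).
#' @export
simulate_pmf_spectrum <- function(db, accession,
                                  detection_prob = 0.8,
                                  mass_error_ppm = 10,
                                  n_noise = 5,
                                  noise_range = c(500, 4000),
                                  drift_a = 1, drift_b = 0,
                                  include_standards = FALSE,
                                  seed,
                                  rule = cleavage_rule(),
                                  digestion = digest_params()) {
  db <- .as_protein_records(db)
  stopifnot(detection_prob >= 0, detection_prob <= 1, mass_error_ppm >= 0,
            n_noise >= 0)
  i <- match(accession, db$accession)
  if (is.na(i)) stop("accession ", sQuote(accession), " not in the database",
                     call. = FALSE)
  dig <- digest(db$sequence[i], rule, digestion)
  # unique [M+H]+ ladder; each unique m/z keeps one representative sequence
  mzs <- round(mz_from_mass(dig$mass, 1L), 9)
  first <- !duplicated(mzs)
  ord <- order(mzs[first])
  true_mz <- mzs[first][ord]
  rep_seq <- dig$sequence[first][ord]
  .with_seed(seed, {
    keep <- stats::runif(length(true_mz)) < detection_prob
    observed <- true_mz[keep] *
      (1 + stats::rnorm(sum(keep), 0, mass_error_ppm * 1e-6))
    noise <- if (n_noise > 0) {
      stats::runif(n_noise, noise_range[1], noise_range[2])
    } else numeric(0)
    std <- if (include_standards) reference_standards()$ref_mz else numeric(0)
    all_mz <- drift_a * c(observed, noise, std) + drift_b
    intensity <- stats::runif(length(all_mz), 10, 100)
    peaks <- peak_list(all_mz, intensity, id = accession, calibrated = FALSE)
    list(peaks = peaks,
         truth = list(accession = accession,
                      peptides = data.frame(sequence = rep_seq[keep],
                                            true_mz = true_mz[keep],
                                            observed_mz = drift_a * observed +
                                              drift_b),
                      n_noise = as.integer(n_noise),
                      n_standards = length(std),
                      drift_a = drift_a, drift_b = drift_b))
  })
}

#' Simulate two-group spot-volume tables
#'
#' Emulates the study's gel comparison: 5 case and 5 control gels with up
#' to 800 matched spots each. Per-spot baseline abundances are log-normal;
#' each gel's measurement multiplies the baseline by log-normal noise of
#' sd `noise_sd` (on the log scale); planted spots are multiplied by their
#' fold in case gels; dropout zeroes a measurement with probability
#' `dropout`.
#'
#' @param n_case,n_control Gels per group (defaults 5 + 5, the study
#'   design).
#' @param n_spots Matched spots per gel (default 800).
#' @param planted Data.frame with `spot` (spot number or id) and `fold`
#'   columns; `NULL` for a null table.
#' @param noise_sd Log-normal noise sd (log scale).
#' @param dropout Per-measurement dropout probability.
#' @param fraction Fraction label for the whole table (`"A"` debris or
#'   `"B"` supernatant).
#' @param seed RNG seed (required).
#' @return List with `table` (spot CSV schema: `gel_id`, `group`,
#'   `fraction`, `spot_id`, `protein`, `raw_volume`), `design`
#'   ([gel_design()]) and `truth` (the planted data.frame with spot ids).
#' @export
simulate_spot_tables <- function(n_case = 5, n_control = 5, n_spots = 800,
                                 planted = NULL, noise_sd = 0.2,
                                 dropout = 0, fraction = "B", seed) {
  stopifnot(n_case >= 1, n_control >= 1, n_spots >= 1,
            dropout >= 0, dropout <= 1, noise_sd >= 0)
  spot_ids <- sprintf("SPOT%04d", seq_len(n_spots))
  if (!is.null(planted)) {
    stopifnot(all(c("spot", "fold") %in% names(planted)))
    planted$spot_id <- if (is.numeric(planted$spot)) spot_ids[planted$spot]
                       else planted$spot
    if (anyNA(planted$spot_id) || !all(planted$spot_id %in% spot_ids)) {
      stop("planted spots must lie within the simulated spot set", call. = FALSE)
    }
  }
  gels <- data.frame(
    gel_id = c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    fraction = fraction)
  .with_seed(seed, {
    baseline <- stats::rlnorm(n_spots, meanlog = log(1000), sdlog = 1)
    tabs <- lapply(seq_len(nrow(gels)), function(g) {
      vol <- baseline * exp(stats::rnorm(n_spots, 0, noise_sd))
      if (gels$group[g] == "case" && !is.null(planted)) {
        j <- match(planted$spot_id, spot_ids)
        vol[j] <- vol[j] * planted$fold
      }
      if (dropout > 0) vol[stats::runif(n_spots) < dropout] <- 0
      data.frame(gel_id = gels$gel_id[g], group = gels$group[g],
                 fraction = fraction, spot_id = spot_ids,
                 protein = spot_ids, raw_volume = round(vol, 4))
    })
    table <- do.call(rbind, tabs)
    rownames(table) <- NULL
    list(table = table, design = gels,
         truth = if (is.null(planted)) {
           data.frame(spot_id = character(), fold = numeric())
         } else planted[, c("spot_id", "fold")])
  })
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "pmf2de", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture ", file, " not found", call. = FALSE)
  p
}

#' Packaged transcription of the study's protein list (Table 1)
#'
#' All identified saliva proteins with their fraction of origin
#' (A: epithelial cell debris, B: supernatant, or both), matched-peptide
#' count and the original score annotation. Duplicate gene-product rows
#' are preserved verbatim so the transcription stays auditable;
#' deduplicate explicitly if needed.
#'
#' @return Data.frame with columns `fraction`, `accession`, `matched`,
#'   `score_annotation`, `protein_name`.
#' @export
table1_fixture <- function() {
  utils::read.csv(.fixture_path("table1_saliva_proteins.csv"),
                  colClasses = c(matched = "integer"))
}

#' Packaged transcription of the tumour-specific protein list (Table 2)
#'
#' The 25 proteins detected in the saliva of every carcinoma patient and
#' no healthy control. `cms_control` is 0 for every row; `cms_case` is the
#' printed case spot count (annotation only; its derivation is not stated
#' in the source and it is not recomputed here).
#'
#' @return Data.frame with columns `sw_name`, `cms_control`, `cms_case`,
#'   `protein_name`, `accessions`.
#' @export
table2_fixture <- function() {
  utils::read.csv(.fixture_path("table2_tumour_specific.csv"),
                  colClasses = c(cms_control = "integer",
                                 cms_case = "integer"))
}

#' Presence matrix implied by the Table 2 fixture
#'
#' The study reports these proteins as present in all five case samples
#' and absent from all five controls; this expands the fixture into the
#' corresponding protein x gel logical presence matrix for
#' [specificity_filter()].
#'
#' @param n_case,n_control Gels per group (study design: 5 + 5).
#' @return List with `presence` (logical matrix) and `design`
#'   (a [gel_design()] data.frame).
#' @export
table2_presence_matrix <- function(n_case = 5, n_control = 5) {
  tab <- table2_fixture()
  gels <- c(sprintf("case_%02d", seq_len(n_case)),
            sprintf("ctrl_%02d", seq_len(n_control)))
  presence <- cbind(
    matrix(tab$cms_case > 0, nrow(tab), n_case),
    matrix(tab$cms_control > 0, nrow(tab), n_control))
  dimnames(presence) <- list(tab$sw_name, gels)
  list(presence = presence,
       design = data.frame(gel_id = gels,
                           group = rep(c("case", "control"),
                                       c(n_case, n_control)),
                           fraction = "A+B"))
}
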