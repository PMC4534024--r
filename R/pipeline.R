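# End-to-end pipeline: calibrate -> search each spot -> quantify ->
# differential filters -> optional marker validation. A run is a pure
# function of its configuration, so identical configs give identical
# reports.

#' Build a pipeline configuration
#'
#' Collects every tunable of the pipeline with the package defaults.
#' Unknown fields are rejected so typos fail loudly. The resolved
#' configuration is echoed verbatim into the run report.
#'
#' @param fasta Path to the protein database FASTA.
#' @param peaklists Character vector of peak-list TSV paths (one spot
#'   each), or a single MGF path holding several spots.
#' @param spot_table Optional path to a spot-volume CSV.
#' @param densitometry Optional path to a densitometry CSV.
#' @param wb_threshold Positivity threshold for marker validation
#'   (required when `densitometry` is given).
#' @param standards Named character vector of calibration standard
#'   sequences (default [reference_standards()]).
#' @param coarse_tol Standard-matching window, Da.
#' @param tolerance Relative search tolerance (default 2.5e-5 = 0.0025%).
#' @param mass_convention `"protonated"` or `"neutral"`.
#' @param max_missed,min_mass,max_mass Digestion settings.
#' @param fold_threshold,presence_threshold Differential settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, peaklists = character(0),
                            spot_table = NULL, densitometry = NULL,
                            wb_threshold = NULL,
                            standards = NULL, coarse_tol = 1.0,
                            tolerance = 2.5e-5,
                            mass_convention = "protonated",
                            max_missed = 1L, min_mass = 500,
                            max_mass = 4000,
                            fold_threshold = 1.5, presence_threshold = 0) {
  structure(list(fasta = fasta, peaklists = peaklists,
                 spot_table = spot_table, densitometry = densitometry,
                 wb_threshold = wb_threshold, standards = standards,
                 coarse_tol = coarse_tol, tolerance = tolerance,
                 mass_convention = mass_convention,
                 max_missed = max_missed, min_mass = min_mass,
                 max_mass = max_mass, fold_threshold = fold_threshold,
                 presence_threshold = presence_threshold),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in order: database digestion; per-spot internal calibration
#' (standard matching, affine fit, application) and PMF search; percent
#' volume quantification with fold-change and specificity filters; and,
#' when a densitometry table is configured, marker validation. Stage
#' failures abort with the stage named; per-file parse errors name the
#' file.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with `config`, `identifications` (per
#'   spot: calibration model and top candidates), `differential`,
#'   `diagnostics` and `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)

  if (!file.exists(config$fasta)) {
    stop("[stage: database] FASTA not found: ", config$fasta, call. = FALSE)
  }
  db <- read_fasta(config$fasta)
  dparams <- digest_params(max_missed = config$max_missed,
                           min_mass = config$min_mass,
                           max_mass = config$max_mass)
  sparams <- search_params(tolerance = config$tolerance,
                           mass_convention = config$mass_convention)
  index <- digest_database(db, cleavage_rule(), dparams)

  standards <- if (is.null(config$standards)) reference_standards()
               else reference_standards(config$standards)

  spots <- list()
  if (length(config$peaklists) == 1L &&
      grepl("\\.mgf$", config$peaklists, ignore.case = TRUE)) {
    spots <- read_mgf(config$peaklists)
  } else if (length(config$peaklists)) {
    spots <- lapply(config$peaklists, read_peaklist)
    names(spots) <- vapply(spots, attr, "", "id")
  }

  identifications <- lapply(spots, function(peaks) {
    pairs <- match_references(peaks, standards, config$coarse_tol)
    if (sum(pairs$matched) >= 2L) {
      model <- fit_calibration(pairs)
      cal <- apply_calibration(peaks, model)
      result <- pmf_search(cal, index, sparams)
    } else {
      note(sprintf("spot '%s': <2 standards matched, searched uncalibrated",
                   attr(peaks, "id")))
      model <- NULL
      result <- suppressWarnings(
        pmf_search(peaks, index, sparams, allow_uncalibrated = TRUE))
    }
    list(spot = attr(peaks, "id"),
         calibration = if (is.null(model)) NULL else
           list(a = model$a, b = model$b,
                residuals_da = as.list(model$residuals)),
         top_candidates = utils::head(result$candidates, 5),
         n_peaks = result$n_peaks,
         n_unmatched_peaks = result$n_unmatched_peaks)
  })

  differential <- NULL
  if (!is.null(config$spot_table)) {
    tab <- read_spot_table(config$spot_table)
    differential <- differential_report(tab, config$fold_threshold,
                                        config$presence_threshold)
  }

  diagnostics <- NULL
  if (!is.null(config$densitometry)) {
    if (is.null(config$wb_threshold)) {
      stop("[stage: diagnostics] 'wb_threshold' is required with a densitometry table",
           call. = FALSE)
    }
    diagnostics <- validate_marker(read_densitometry(config$densitometry),
                                   config$wb_threshold)
  }

  structure(list(config = unclass(config),
                 n_proteins = nrow(db),
                 n_theoretical_peptides = nrow(index),
                 identifications = identifications,
                 differential = differential,
                 diagnostics = diagnostics,
                 warnings = warnings),
            class = "run_report")
}

#' Serialise a run report as JSON
#'
#' Field order is stable; reruns of an identical configuration give
#' byte-identical files.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  diffr <- report$differential
  diag <- report$diagnostics
  jsonlite::write_json(
    list(schema = "pmf2de/run_report/1",
         config = report$config,
         n_proteins = report$n_proteins,
         n_theoretical_peptides = report$n_theoretical_peptides,
         identifications = report$identifications,
         differential = if (is.null(diffr)) NULL else
           list(summary = as.list(diffr$summary),
                fold_threshold = diffr$fold_threshold,
                results = diffr$results),
         diagnostics = if (is.null(diag)) NULL else
           list(confusion = as.list(diag$confusion),
                sensitivity = diag$sensitivity,
                specificity = diag$specificity,
                threshold = diag$threshold, n = diag$n),
         warnings = report$warnings),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
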