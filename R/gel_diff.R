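# Percent-volume quantification of matched 2-D gel spots and the two
# differential filters used in the study: a >= 1.5-fold change between
# group means, and strict tumour specificity (present in every case gel,
# absent from every control gel).
#
# Spots arrive pre-matched across gels by shared spot IDs; image-based spot
# detection and matching are outside this package's scope.

#' Percent-volume normalisation of one gel
#'
#' Each spot's volume is expressed as a percentage of the summed volume of
#' all spots in its gel: `%vol = 100 * vol / sum(gel volumes)`. This removes
#' gel-to-gel loading and staining differences; per-gel percent volumes sum
#' to 100 by construction.
#'
#' @param volumes Numeric vector of raw spot volumes (>= 0) for one gel.
#' @return Percent volumes, same length and names.
#' @examples
#' percent_volume(c(2, 3, 5))   # 20 30 50
#' @export
percent_volume <- function(volumes) {
  stopifnot(is.numeric(volumes))
  if (any(volumes < 0)) stop("raw volumes must be >= 0", call. = FALSE)
  total <- sum(volumes)
  if (total <= 0) {
    stop("all spot volumes are zero: no normaliser for this gel", call. = FALSE)
  }
  100 * volumes / total
}

#' Add percent volumes to a spot table
#'
#' Applies [percent_volume()] gel by gel.
#'
#' @param table Spot table data.frame with at least `gel_id`, `spot_id`,
#'   `raw_volume` (the CSV schema of [read_spot_table()]).
#' @return The table with a `percent_volume` column appended.
#' @export
add_percent_volume <- function(table) {
  .check_spot_table(table, require_fraction = FALSE)
  table$percent_volume <- stats::ave(table$raw_volume, table$gel_id,
                                     FUN = percent_volume)
  table
}

.check_spot_table <- function(table, require_fraction = TRUE) {
  need <- c("gel_id", "group", "spot_id", "raw_volume")
  if (require_fraction) need <- c(need, "fraction")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table[c("gel_id", "spot_id")])) {
    stop("duplicate (gel_id, spot_id) measurements", call. = FALSE)
  }
  invisible(table)
}

#' Gel design from a spot table
#'
#' @param table A spot table with `gel_id`, `group` and (optionally)
#'   `fraction` columns.
#' @return A data.frame with one row per gel: `gel_id`, `group`,
#'   `fraction`. Errors if a gel carries more than one group or fraction
#'   label, or a group outside case/control.
#' @export
gel_design <- function(table) {
  cols <- intersect(c("gel_id", "group", "fraction"), names(table))
  d <- unique(table[cols])
  if (anyDuplicated(d$gel_id)) {
    stop("inconsistent design: a gel is assigned more than one group/fraction",
         call. = FALSE)
  }
  if (!all(d$group %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'", call. = FALSE)
  }
  rownames(d) <- NULL
  d
}

# group means of percent volume for one spot; absent measurements count 0
.group_means <- function(pv, design) {
  full <- merge(design, pv, by = "gel_id", all.x = TRUE)
  full$percent_volume[is.na(full$percent_volume)] <- 0
  tapply(full$percent_volume, full$group, mean)
}

#' Fold change of one spot between groups
#'
#' `FC = mean(case percent volume) / mean(control percent volume)`, signed
#' by direction (`"up"` when FC > 1). A spot with control mean 0 and case
#' mean > 0 has no finite fold change and is flagged `case_specific`
#' (symmetrically `control_specific`).
#'
#' @param table A spot table (percent volumes are computed if absent).
#' @param spot Spot identifier to evaluate.
#' @param design Optional [gel_design()]; derived from the table if omitted.
#' @return One-row data.frame: `spot_id`, `mean_case`, `mean_control`,
#'   `fold_change`, `direction`, `case_specific`, `control_specific`.
#' @export
fold_change <- function(table, spot, design = gel_design(table)) {
  if (!"percent_volume" %in% names(table)) table <- add_percent_volume(table)
  pv <- table[table$spot_id == spot, c("gel_id", "percent_volume")]
  if (!nrow(pv)) stop("spot ", sQuote(spot), " absent from the table", call. = FALSE)
  gm <- .group_means(pv, design)
  if (all(gm == 0)) stop("spot ", sQuote(spot), " absent from both groups",
                         call. = FALSE)
  case_spec <- gm[["control"]] == 0 && gm[["case"]] > 0
  ctrl_spec <- gm[["case"]] == 0 && gm[["control"]] > 0
  fc <- if (case_spec || ctrl_spec) NA_real_ else gm[["case"]] / gm[["control"]]
  data.frame(spot_id = spot,
             mean_case = gm[["case"]], mean_control = gm[["control"]],
             fold_change = fc,
             direction = if (case_spec) "up" else if (ctrl_spec) "down"
                         else if (fc > 1) "up" else if (fc < 1) "down" else "none",
             case_specific = case_spec, control_specific = ctrl_spec)
}

#' Tumour-specificity filter
#'
#' Returns the proteins detected in ALL case gels and NO control gel — the
#' study's definition of a tumour-specific protein. Detection means percent
#' volume above `presence_threshold` (default 0: any positive volume).
#'
#' @param presence Logical matrix, proteins (rows, named) x gels (columns
#'   named by gel_id), or a numeric percent-volume matrix thresholded at
#'   `presence_threshold`.
#' @param design A [gel_design()] covering every column.
#' @param presence_threshold Percent-volume detection threshold.
#' @return Character vector of specific proteins, sorted by accession.
#' @export
specificity_filter <- function(presence, design, presence_threshold = 0) {
  if (!nrow(design)) stop("empty gel design", call. = FALSE)
  if (!all(colnames(presence) %in% design$gel_id) ||
      !all(design$gel_id %in% colnames(presence))) {
    stop("presence matrix columns and design gels disagree", call. = FALSE)
  }
  if (is.numeric(presence)) presence <- presence > presence_threshold
  case_gels <- design$gel_id[design$group == "case"]
  ctrl_gels <- design$gel_id[design$group == "control"]
  in_all_cases <- rowSums(presence[, case_gels, drop = FALSE]) ==
    length(case_gels)
  in_no_control <- rowSums(presence[, ctrl_gels, drop = FALSE]) == 0
  sort(rownames(presence)[in_all_cases & in_no_control])
}

#' Spot table to percent-volume matrix
#'
#' @param table A spot table (one fraction); percent volumes computed if
#'   absent. Missing (gel, spot) measurements become 0.
#' @return Numeric matrix, spots x gels.
#' @export
percent_volume_matrix <- function(table) {
  if (!"percent_volume" %in% names(table)) table <- add_percent_volume(table)
  spots <- sort(unique(table$spot_id))
  gels <- sort(unique(table$gel_id))
  m <- matrix(0, length(spots), length(gels), dimnames = list(spots, gels))
  m[cbind(match(table$spot_id, spots), match(table$gel_id, gels))] <-
    table$percent_volume
  m
}

#' Full differential report
#'
#' Normalises each gel to percent volumes, then applies both filters to
#' every spot: fold change of group means against `fold_threshold`
#' (flagging changes in either direction, FC >= threshold or
#' <= 1/threshold), and strict presence/absence specificity. Fractions
#' (A: epithelial cell debris, B: supernatant) are analysed separately.
#'
#' @param table A spot table in the [read_spot_table()] schema.
#' @param fold_threshold Fold-change threshold (default 1.5, the study's
#'   reproducible-detection limit).
#' @param presence_threshold Detection threshold on percent volume
#'   (default 0).
#' @return An object of class `differential_report`: list with `results`
#'   (per spot x fraction data.frame with flags `differential`,
#'   `case_specific`, `control_specific` — mutually exclusive, specificity
#'   taking precedence), `summary` counts, and the thresholds used.
#' @export
differential_report <- function(table, fold_threshold = 1.5,
                                presence_threshold = 0) {
  .check_spot_table(table)
  if (fold_threshold < 1) stop("'fold_threshold' must be >= 1", call. = FALSE)
  per_fraction <- lapply(split(table, table$fraction), function(tf) {
    tf <- add_percent_volume(tf)
    design <- gel_design(tf)
    m <- percent_volume_matrix(tf)
    specific <- specificity_filter(m, design, presence_threshold)
    rows <- lapply(rownames(m), function(sp) {
      fcrow <- fold_change(tf, sp, design)
      fcrow$fraction <- tf$fraction[1L]
      fcrow
    })
    res <- do.call(rbind, rows)
    res$differential <- !res$case_specific & !res$control_specific &
      !is.na(res$fold_change) &
      (res$fold_change >= fold_threshold |
         res$fold_change <= 1 / fold_threshold)
    # strict specificity (all cases / no controls) as an annotation
    res$strictly_specific <- res$spot_id %in% specific
    res
  })
  results <- do.call(rbind, per_fraction)
  rownames(results) <- NULL
  structure(list(
    results = results,
    summary = c(n_spots = nrow(results),
                n_differential = sum(results$differential),
                n_case_specific = sum(results$case_specific),
                n_control_specific = sum(results$control_specific)),
    fold_threshold = fold_threshold,
    presence_threshold = presence_threshold),
    class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("differential report: %d spots, %d >= %.2g-fold, ",
                     "%d case-specific, %d control-specific\n"),
              s[["n_spots"]], s[["n_differential"]], x$fold_threshold,
              s[["n_case_specific"]], s[["n_control_specific"]]))
  invisible(x)
}

#' Write a differential report
#'
#' @param report A `differential_report`.
#' @param csv_path,json_path Output paths; either may be `NULL`.
#' @return Invisible list of the paths written.
#' @export
write_differential_report <- function(report, csv_path = NULL,
                                      json_path = NULL) {
  stopifnot(inherits(report, "differential_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$results, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(schema = "pmf2de/differential_report/1",
           fold_threshold = report$fold_threshold,
           presence_threshold = report$presence_threshold,
           summary = as.list(report$summary),
           results = report$results),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
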