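# Percent-volume quantification and the two differential filters.

mini_table <- function(case_vals, ctrl_vals, spots = paste0("S", seq_along(case_vals[[1]]))) {
  # case_vals/ctrl_vals: lists of per-gel raw-volume vectors over `spots`
  rows <- list()
  for (g in seq_along(case_vals)) {
    rows[[length(rows) + 1]] <- data.frame(
      gel_id = sprintf("case_%02d", g), group = "case", fraction = "B",
      spot_id = spots, protein = spots, raw_volume = case_vals[[g]])
  }
  for (g in seq_along(ctrl_vals)) {
    rows[[length(rows) + 1]] <- data.frame(
      gel_id = sprintf("ctrl_%02d", g), group = "control", fraction = "B",
      spot_id = spots, protein = spots, raw_volume = ctrl_vals[[g]])
  }
  do.call(rbind, rows)
}

test_that("percent volumes normalise, conserve and scale-invariate", {
  expect_equal(percent_volume(c(2, 3, 5)), c(20, 30, 50))
  expect_equal(percent_volume(7), 100)
  v <- c(1.2, 8, 0, 3.3)
  expect_equal(percent_volume(v), percent_volume(17 * v))
  expect_equal(sum(percent_volume(v)), 100, tolerance = 1e-12)
  expect_error(percent_volume(c(0, 0)), "no normaliser")
  expect_error(percent_volume(c(-1, 2)), ">= 0")
})

test_that("per-gel percent volumes sum to 100 on generated tables", {
  for (seed in c(1, 2)) {
    st <- simulate_spot_tables(n_spots = 200, dropout = 0.1, seed = seed)
    pv <- add_percent_volume(st$table)
    sums <- tapply(pv$percent_volume, pv$gel_id, sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})

test_that("fold change follows group means of percent volume", {
  # one gel per group; spot A has case 3% vs control 1.5% by construction
  tab <- mini_table(list(c(3, 97)), list(c(1.5, 98.5)), spots = c("A", "Z"))
  fc <- fold_change(tab, "A")
  expect_equal(fc$fold_change, 2.0)
  expect_equal(fc$direction, "up")
  expect_false(fc$case_specific)
  # equal means -> FC 1, no direction
  tab2 <- mini_table(list(c(10, 90)), list(c(10, 90)), spots = c("A", "Z"))
  expect_equal(fold_change(tab2, "A")$fold_change, 1.0)
  # control absent -> case specific, no finite FC
  tab3 <- mini_table(list(c(0.4, 99.6)), list(c(0, 100)), spots = c("A", "Z"))
  fc3 <- fold_change(tab3, "A")
  expect_true(fc3$case_specific)
  expect_true(is.na(fc3$fold_change))
  expect_error(fold_change(tab, "NOPE"), "absent")
})

test_that("specificity filter demands all cases and no controls", {
  design <- data.frame(gel_id = c(paste0("case_0", 1:5), paste0("ctrl_0", 1:5)),
                       group = rep(c("case", "control"), each = 5),
                       fraction = "B")
  pres <- matrix(FALSE, 3, 10,
                 dimnames = list(c("P1", "P2", "P3"), design$gel_id))
  pres["P1", 1:5] <- TRUE                      # all cases, no controls
  pres["P2", 1:4] <- TRUE                      # 4 of 5 cases
  pres["P3", c(1:5, 6)] <- TRUE                # leaks into a control
  expect_equal(specificity_filter(pres, design), "P1")
  expect_error(specificity_filter(pres, design[0, ]), "empty")
})

test_that("exactly one of the 2^10 presence patterns is tumour-specific", {
  design <- data.frame(gel_id = sprintf("g%02d", 1:10),
                       group = rep(c("case", "control"), each = 5))
  hits <- 0
  for (code in 0:1023) {
    pat <- as.logical(bitwAnd(code, 2^(0:9)) > 0)
    pres <- matrix(pat, 1, 10, dimnames = list("P", design$gel_id))
    hits <- hits + length(specificity_filter(pres, design))
  }
  expect_equal(hits, 1)
})

test_that("the packaged tumour-specific table yields 25 specific proteins", {
  tp <- table2_presence_matrix()
  expect_equal(length(specificity_filter(tp$presence, tp$design)), 25)
})

test_that("differential report flags exactly the planted spots", {
  planted <- data.frame(spot = c(10, 250, 611), fold = 2)
  st <- simulate_spot_tables(n_spots = 700, planted = planted,
                             noise_sd = 0, dropout = 0, seed = 61)
  rep <- differential_report(st$table, fold_threshold = 1.5)
  flagged <- rep$results$spot_id[rep$results$differential]
  expect_setequal(flagged, st$truth$spot_id)
  expect_equal(rep$summary[["n_case_specific"]], 0)
  # threshold 1.0 flags a superset of threshold 1.5
  rep1 <- differential_report(st$table, fold_threshold = 1.0)
  expect_true(all(flagged %in% rep1$results$spot_id[rep1$results$differential]))
})

test_that("a null table yields no specific proteins and few flags", {
  st <- simulate_spot_tables(n_spots = 300, planted = NULL, noise_sd = 0,
                             dropout = 0, seed = 62)
  rep <- differential_report(st$table)
  expect_equal(rep$summary[["n_case_specific"]], 0)
  expect_equal(rep$summary[["n_control_specific"]], 0)
  expect_equal(rep$summary[["n_differential"]], 0)
  m <- percent_volume_matrix(add_percent_volume(st$table))
  expect_length(specificity_filter(m, st$design), 0)
})

test_that("null fold-change exceedance stays inside the frozen band", {
  # band [0, 0.0075] frozen from a 400-replicate simulation of the same
  # model (log-normal noise sd 0.2, 5 vs 5 gels, no effects)
  for (seed in c(71, 72)) {
    st <- simulate_spot_tables(n_spots = 800, planted = NULL, noise_sd = 0.2,
                               dropout = 0, seed = seed)
    rep <- differential_report(st$table, fold_threshold = 1.5)
    frac <- rep$summary[["n_differential"]] / rep$summary[["n_spots"]]
    expect_gte(frac, 0)
    expect_lte(frac, 0.0075)
  }
})

test_that("report serialisation writes CSV and JSON", {
  st <- simulate_spot_tables(n_spots = 50, seed = 63)
  rep <- differential_report(st$table)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_differential_report(rep, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(rep$results))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$summary$n_spots, 50)
})
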