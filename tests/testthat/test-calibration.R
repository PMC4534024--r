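# Internal recalibration: standard matching, affine fit, application.

test_that("peak lists validate and stay sorted", {
  p <- peak_list(c(2000, 900, 1500), c(1, 2, 3), id = "s1")
  expect_equal(p$mz, c(900, 1500, 2000))
  expect_equal(p$intensity, c(2, 3, 1))
  expect_false(attr(p, "calibrated"))
  expect_error(peak_list(c(-1, 5)), "strictly positive")
  expect_error(peak_list(c(1, 5), c(-1, 1)), ">= 0")
})

test_that("standards match to the nearest peak within the coarse window", {
  peaks <- peak_list(c(904.7, 2465.5, 3000))
  std <- data.frame(name = c("brady", "acth"), ref_mz = c(904.5, 2465.2))
  m <- match_references(peaks, std, coarse_tol = 1.0)
  expect_true(all(m$matched))
  expect_equal(m$obs_mz, c(904.7, 2465.5))
  # no peak within the window -> unmatched, and <2 matches warns
  far <- peak_list(c(904.7, 500))
  expect_warning(m2 <- match_references(far, std, coarse_tol = 1.0),
                 "calibration impossible")
  expect_equal(m2$matched, c(TRUE, FALSE))
})

test_that("equidistant peaks tie-break to the lower m/z", {
  peaks <- peak_list(c(999.9, 1000.1, 2000.0))
  std <- data.frame(name = c("a", "b"), ref_mz = c(1000.0, 2000.0))
  m <- match_references(peaks, std, coarse_tol = 1.0)
  expect_equal(m$obs_mz[1], 999.9)
})

test_that("two-point fits are exact and the identity is recovered", {
  id <- fit_calibration(data.frame(obs_mz = c(1000, 2000),
                                   ref_mz = c(1000, 2000)))
  expect_equal(id$a, 1)
  expect_equal(id$b, 0)
  two <- fit_calibration(data.frame(obs_mz = c(1000.1, 2000.3),
                                    ref_mz = c(1000.0, 2000.0)))
  expect_equal(unname(two$residuals), c(0, 0), tolerance = 1e-10)
  expect_error(fit_calibration(data.frame(obs_mz = 1000, ref_mz = 1000)),
               "at least 2")
  expect_error(fit_calibration(data.frame(obs_mz = c(1000, 1000),
                                          ref_mz = c(1000, 1001))),
               "duplicate observed")
})

test_that("noiseless fits recover generating coefficients to 1e-9", {
  a <- 1.00013; b <- -0.21
  obs <- c(950.3, 1677.8, 2465.2)
  pairs <- data.frame(obs_mz = obs, ref_mz = a * obs + b)
  fit <- fit_calibration(pairs)
  expect_equal(fit$a, a, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
  # agrees with the closed-form normal-equations oracle
  oracle <- oracle_line_fit(pairs$obs_mz, pairs$ref_mz)
  expect_equal(fit$a, unname(oracle["a"]), tolerance = 1e-10)
  expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-10)
})

test_that("applying calibration maps masses and preserves everything else", {
  p <- peak_list(c(1000, 1500), c(5, 7), id = "s")
  id_model <- fit_calibration(data.frame(obs_mz = c(1000, 2000),
                                         ref_mz = c(1000, 2000)))
  expect_equal(apply_calibration(p, id_model)$mz, p$mz)
  shift <- fit_calibration(data.frame(obs_mz = c(1000, 2000),
                                      ref_mz = c(1000.5, 2000.5)))
  cal <- apply_calibration(p, shift)
  expect_equal(cal$mz, c(1000.5, 1500.5))
  expect_equal(cal$intensity, p$intensity)
  expect_equal(nrow(cal), nrow(p))
  expect_true(attr(cal, "calibrated"))
  expect_error(apply_calibration(cal, shift), "already calibrated")
  expect_silent(apply_calibration(cal, shift, override = TRUE))
})

test_that("generator drift is removed by match/fit/apply round trip", {
  db <- simulate_protein_db(10, seed = 31)
  drift_a <- 1.0002; drift_b <- -0.35
  sim <- simulate_pmf_spectrum(db, "SYN0003", detection_prob = 1,
                               mass_error_ppm = 0, n_noise = 0,
                               drift_a = drift_a, drift_b = drift_b,
                               include_standards = TRUE, seed = 32)
  pairs <- match_references(sim$peaks)
  expect_true(all(pairs$matched))
  model <- fit_calibration(pairs)
  # fitted map inverts the drift: a*drift_a = 1, a*drift_b + b = 0
  expect_lt(abs(model$a * drift_a - 1), 1e-6)
  expect_lt(abs(model$a * drift_b + model$b), 1e-3)
  cal <- apply_calibration(sim$peaks, model)
  # every true peptide m/z is restored to within 1e-6 relative error
  true_mz <- sort(sim$truth$peptides$true_mz)
  got <- vapply(true_mz, function(m) cal$mz[which.min(abs(cal$mz - m))],
                numeric(1))
  expect_true(all(abs(got - true_mz) / true_mz < 1e-6))
})
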