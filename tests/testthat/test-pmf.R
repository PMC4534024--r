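# PMF core: tolerance matching, candidate scoring, search, fragment
# confirmation.

# a hand-built index bypassing digestion, for window arithmetic tests
fake_index <- function(masses, accession = "P1", plen = 100) {
  structure(data.frame(accession = accession,
                       start = 1L, end = 10L,
                       sequence = strrep("A", 10),
                       missed = 0L, mass = sort(masses)),
            class = c("peptide_index", "data.frame"),
            protein_lengths = stats::setNames(rep(plen, length(unique(accession))),
                                              unique(accession)))
}

test_that("the 0.0025% window is relative to the theoretical mass", {
  idx <- fake_index(2000.00)
  params <- search_params(tolerance = 2.5e-5, mass_convention = "neutral")
  inside <- peak_list(2000.0499, calibrated = TRUE)
  outside <- peak_list(2000.06, calibrated = TRUE)
  expect_equal(nrow(match_peaks(inside, idx, params)), 1)
  expect_equal(nrow(match_peaks(outside, idx, params)), 0)
  # doubling the mass doubles the absolute half-width
  idx2 <- fake_index(4000.00)
  expect_equal(nrow(match_peaks(peak_list(4000.0999, calibrated = TRUE),
                                idx2, params)), 1)
  expect_equal(nrow(match_peaks(peak_list(4000.12, calibrated = TRUE),
                                idx2, params)), 0)
})

test_that("empty peak lists and uncalibrated input are handled", {
  idx <- fake_index(c(1000, 2000))
  params <- search_params()
  expect_equal(nrow(match_peaks(peak_list(numeric(0), calibrated = TRUE),
                                idx, params)), 0)
  raw <- peak_list(1000)
  expect_error(match_peaks(raw, idx, params), "not calibrated")
  expect_warning(match_peaks(raw, idx, params, allow_uncalibrated = TRUE),
                 "uncalibrated")
})

test_that("matching equals the brute-force all-pairs oracle", {
  db <- simulate_protein_db(50, seed = 41)
  idx <- digest_database(db)
  params <- search_params()
  for (s in 1:5) {
    sim <- simulate_pmf_spectrum(db, sprintf("SYN%04d", s * 7),
                                 detection_prob = 0.8, mass_error_ppm = 10,
                                 n_noise = 5, seed = 400 + s)
    peaks <- peak_list(sim$peaks$mz, sim$peaks$intensity, calibrated = TRUE)
    got <- match_peaks(peaks, idx, params)
    want <- oracle_match_peaks(peaks, idx, params$tolerance)
    expect_identical(match_key(got), match_key(want))
  }
})

test_that("a noiseless single-protein spectrum ranks its source first", {
  db <- simulate_protein_db(30, seed = 43)
  sim <- simulate_pmf_spectrum(db, "SYN0012", detection_prob = 1,
                               mass_error_ppm = 0, n_noise = 0, seed = 44)
  peaks <- peak_list(sim$peaks$mz, sim$peaks$intensity, id = "SYN0012",
                     calibrated = TRUE)
  res <- pmf_search(peaks, db)
  expect_equal(res$candidates$accession[1], "SYN0012")
  expect_equal(res$candidates$n_matched[1], nrow(peaks))
  expect_equal(res$n_unmatched_peaks, 0)
})

test_that("chance score increases with matched count at fixed n and p", {
  # two proteins sharing the same mass neighbourhood; A matched 4 peaks,
  # B matched 1 among the same 5-peak spectrum
  masses <- seq(1000, 1800, by = 200)
  idx <- structure(
    data.frame(accession = rep(c("A", "B"), c(5, 5)),
               start = 1L, end = 10L, sequence = strrep("G", 10),
               missed = 0L,
               mass = c(masses, masses + 50)),
    class = c("peptide_index", "data.frame"),
    protein_lengths = c(A = 100, B = 100))
  idx <- idx[order(idx$mass), ]
  params <- search_params(mass_convention = "neutral")
  peaks <- peak_list(c(masses[1:4], masses[5] + 50), calibrated = TRUE)
  res <- score_candidates(match_peaks(peaks, idx, params), idx, peaks, params)
  expect_equal(res$accession, c("A", "B"))
  expect_equal(res$n_matched, c(4L, 1L))
  expect_gt(res$score[1], res$score[2])
})

test_that("search is invariant to peak order and to absent proteins", {
  db <- simulate_protein_db(25, seed = 45)
  sim <- simulate_pmf_spectrum(db, "SYN0005", detection_prob = 0.9,
                               mass_error_ppm = 5, n_noise = 3, seed = 46)
  mz <- sim$peaks$mz; int <- sim$peaks$intensity
  p1 <- peak_list(mz, int, id = "x", calibrated = TRUE)
  set.seed(1)
  perm <- sample(length(mz))
  p2 <- peak_list(mz[perm], int[perm], id = "x", calibrated = TRUE)
  r1 <- pmf_search(p1, db)
  r2 <- pmf_search(p2, db)
  expect_identical(r1$candidates, r2$candidates)
  # a database without the source never reports it
  db_without <- db[db$accession != "SYN0005", ]
  r3 <- pmf_search(p1, db_without)
  expect_false("SYN0005" %in% r3$candidates$accession)
})

test_that("serialised results are byte-identical across reruns", {
  db <- simulate_protein_db(10, seed = 47)
  sim <- simulate_pmf_spectrum(db, "SYN0002", seed = 48)
  peaks <- peak_list(sim$peaks$mz, sim$peaks$intensity, id = "spot1",
                     calibrated = TRUE)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_pmf_result(pmf_search(peaks, db), f1)
  write_pmf_result(pmf_search(peaks, db), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("rank-1 recovery does not improve as noise peaks are added", {
  db <- simulate_protein_db(30, seed = 49)
  set.seed(50)
  sources <- sprintf("SYN%04d", sample.int(30, 15))
  idx <- digest_database(db)
  recovery <- vapply(c(0, 10, 40), function(nn) {
    hits <- vapply(seq_along(sources), function(i) {
      sim <- simulate_pmf_spectrum(db, sources[i], detection_prob = 0.6,
                                   mass_error_ppm = 10, n_noise = nn,
                                   seed = 5000 + i)
      peaks <- peak_list(sim$peaks$mz, sim$peaks$intensity, calibrated = TRUE)
      res <- pmf_search(peaks, idx)
      nrow(res$candidates) > 0 && res$candidates$accession[1] == sources[i]
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recovery) <= 0))
})

test_that("fragment confirmation counts ladder matches", {
  seqs <- "ELVISLIVESK"
  ladder <- c(fragment_ions(seqs, "b"), fragment_ions(seqs, "y"))
  full <- peak_list(unname(ladder))
  expect_equal(fragment_confirm(seqs, full)$fraction, 1.0)
  none <- peak_list(c(100, 200))
  expect_equal(fragment_confirm(seqs, none)$n_matched, 0)
  expect_error(fragment_confirm("A", full), "length >= 2")
  # seeded deletion of exactly 20% of the ions
  set.seed(51)
  n_del <- round(0.2 * length(ladder))
  kept <- peak_list(unname(ladder[-sample(length(ladder), n_del)]))
  got <- fragment_confirm(seqs, kept)
  expect_equal(got$fraction, 1 - n_del / length(ladder))
})
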