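test_that("detect_ms1 finds the single noise-free peak without an RT hint", {
  run <- make_demo_run()
  tg <- target_definition("heroin", 370.1642)
  det <- detect_ms1(run, tg)
  expect_equal(det$estimated_mz, 370.1642)
  expect_equal(det$rt, 685)
})

test_that("detect_ms1 equals brute-force argmax over all centroids", {
  run <- make_demo_run(noise_sd = 20, seed = 11)
  tg <- target_definition("x", 286.1430, mz_tol_ppm = 1000)
  det <- detect_ms1(run, tg)
  # brute force: enumerate every (spectrum, centroid) pair
  best_int <- -Inf; best <- NULL
  half <- tg$ms1_mz * tg$mz_tol_ppm * 1e-6
  for (s in run$spectra) {
    if (s$ms_level != 1L) next
    for (j in seq_along(s$mz)) {
      if (abs(s$mz[j] - tg$ms1_mz) <= half && s$intensity[j] > best_int) {
        best_int <- s$intensity[j]; best <- c(s$mz[j], s$rt)
      }
    }
  }
  expect_equal(c(det$estimated_mz, det$rt), best)
})

test_that("detect_ms1 picks the taller of two in-tolerance peaks and NAs outside", {
  sp <- list(ms_spectrum(c(100.00, 100.05), c(10, 100), rt = 5),
             ms_spectrum(c(100.00, 100.05), c(8, 60), rt = 10))
  run <- ms_run(sp)
  tg <- target_definition("t", 100.02, mz_tol_ppm = 1000)  # 0.1 Da window
  det <- detect_ms1(run, tg)
  expect_equal(det$estimated_mz, 100.05)
  expect_equal(det$rt, 5)
  # offset 2000 ppm with a 1000 ppm window -> not found, NA not error
  off <- target_definition("t", 100.05 * (1 + 2000e-6), mz_tol_ppm = 1000)
  expect_true(is.na(detect_ms1(run, off)$estimated_mz))
})

test_that("fragment windows honour Da vs ppm tolerance modes", {
  run <- make_demo_run()
  # nominal integer fragment list: 100 ppm of 328 is 0.033 Da, too narrow
  # to admit the 0.15 Da gap to the true fragment at 328.15
  tg_ppm <- target_definition("heroin", 370.1642,
                              fragment_mz = c(328, 268, 211),
                              fragment_tol = 100, fragment_tol_unit = "ppm")
  m_ppm <- match_ms2(run, tg_ppm, rt = 685)
  expect_true(is.na(m_ppm$abundance[m_ppm$true_mz == 328]))
  tg_da <- target_definition("heroin", 370.1642,
                             fragment_mz = c(328, 268, 211),
                             fragment_tol = 0.5, fragment_tol_unit = "Da")
  m_da <- match_ms2(run, tg_da, rt = 685)
  expect_equal(m_da$estimated_mz[m_da$true_mz == 328], 328.15)
  expect_equal(m_da$abundance, c(182, 193, 108))
})

test_that("all-present fragments match generated intensities; empty RT window all NA", {
  run <- make_demo_run()
  tg <- target_definition("morphine", 286.1430,
                          fragment_mz = c(286.14, 268.13, 229.09, 201.09),
                          fragment_tol = 0.05)
  m <- match_ms2(run, tg, rt = 146)
  expect_false(any(is.na(m$abundance)))
  expect_equal(m$abundance, c(800, 24, 72, 104))
  far <- match_ms2(run, tg, rt = 400)
  expect_true(all(is.na(far$abundance)))
})

test_that("integrated abundance is monotone in the RT window and zero on empty runs", {
  run <- make_demo_run()
  a_full <- integrate_abundance(run, 370.1642, 685, rt_window = 50)
  a_half <- integrate_abundance(run, 370.1642, 685, rt_window = 25)
  expect_true(a_half <= a_full)
  expect_warning(a0 <- integrate_abundance(run, 370.1642, 5000, rt_window = 1),
                 "empty|no MS1")
  expect_equal(a0, 0)
})

test_that("signal_to_noise matches its closed forms", {
  expect_equal(signal_to_noise(c(5, 15)), 10 / sd(c(5, 15)))
  expect_equal(signal_to_noise(c(5, 15)), 1.4142, tolerance = 1e-4)
  expect_warning(sn <- signal_to_noise(c(10, 10, 10)), "Inf")
  expect_identical(sn, Inf)
  expect_error(signal_to_noise(7), "at least 2")
  ladder <- seq(100, 1100, by = 100)
  expect_equal(signal_to_noise(ladder), mean(ladder) / sd(ladder),
               tolerance = 1e-12)
})

test_that("relative abundance scales to the base peak and propagates NA", {
  expect_equal(relative_abundance(c(200, 50)), c(100, 25))
  expect_equal(relative_abundance(7), 100)
  expect_equal(relative_abundance(c(3, 1, NA)),
               c(100, 33.3333, NA), tolerance = 1e-4)
  expect_true(all(is.na(relative_abundance(c(NA, NA)))))
})

test_that("analyze_targets handles batches, misses and reordering", {
  run <- make_demo_run()
  targets <- list(
    target_definition("heroin", 370.1642,
                      fragment_mz = c(370.16, 328.15), fragment_tol = 0.05),
    target_definition("morphine", 286.1430,
                      fragment_mz = c(286.14, 201.09), fragment_tol = 0.05),
    target_definition("absent", 999.9))
  res <- analyze_targets(run, targets)
  expect_equal(nrow(res$ms1), 3L)
  expect_true(is.na(res$ms1$estimated_mz[res$ms1$name == "absent"]))
  expect_false(any(is.na(res$ms1$estimated_mz[res$ms1$name != "absent"])))
  # base-peak normalization: max relative abundance is exactly 100
  for (nm in unique(res$ms2$name)) {
    ra <- res$ms2$relative_abundance[res$ms2$name == nm]
    if (any(!is.na(ra))) expect_identical(max(ra, na.rm = TRUE), 100)
  }
  # order invariance
  res_rev <- analyze_targets(run, rev(targets))
  expect_equal(res_rev$ms1[order(res_rev$ms1$name), ],
               res$ms1[order(res$ms1$name), ], ignore_attr = TRUE)
})
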