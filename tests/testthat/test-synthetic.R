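test_that("default band set encodes the serum signature", {
  bands <- default_serum_bands()
  centers <- vapply(bands, `[[`, 0, "center")
  expect_length(bands, 11)
  expect_equal(centers, sort(centers))
  expect_equal(centers, c(637, 722, 810, 888, 1003, 1134, 1203, 1333,
                          1432, 1557, 1652))
  mult <- function(cm1) bands[[which(centers == cm1)]]$class_multipliers
  expect_lt(mult(888)[["stone"]], mult(888)[["healthy"]])
  expect_gt(mult(1203)[["polyp"]], mult(1203)[["healthy"]])
  for (b in c(637, 722, 1203, 1432, 1652)) {
    expect_false(mult(b)[["stone"]] == mult(b)[["polyp"]])
  }
  expect_false(mult(1134)[["polyp"]] == mult(1134)[["healthy"]])
  for (b in c(810, 1003, 1333, 1557)) {
    expect_true(all(mult(b) == mult(b)[[1]]))
  }
  # effect_scale = 0 removes all class differences
  flat <- default_serum_bands(effect_scale = 0)
  for (b in flat) expect_true(all(b$class_multipliers == 1))
})

test_that("default cohort has the study's size and composition", {
  sim <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(sim$spectra$intensities), 148)
  expect_equal(as.vector(table(sim$spectra$labels)), c(72, 51, 25))
  expect_equal(length(sim$spectra$wavenumbers), 601)
  expect_equal(range(sim$spectra$wavenumbers), c(600, 1800))
  expect_equal(length(sim$truth$labels), 148)
})

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  c <- generate_cohort(cohort_config(seed = 43))
  expect_identical(a$spectra$intensities, b$spectra$intensities)
  expect_false(identical(a$spectra$intensities, c$spectra$intensities))
})

test_that("noise-free effect-free single-band cohort is exactly reproducible", {
  band <- band_spec(1000, width = 16, base_amplitude = 2,
                    class_multipliers = c(healthy = 1, stone = 1))
  cfg <- cohort_config(
    class_sizes = c(healthy = 4, stone = 4), bands = list(band),
    baseline_params = list(amplitude = 1.5, center = 1300, fwhm = 600,
                           slope = 0),
    noise_sd = 0, replicates_per_sample = 1, band_jitter_sd = 0,
    baseline_jitter_sd = 0, seed = 5)
  sim <- generate_cohort(cfg)
  m <- sim$spectra$intensities
  # all samples identical
  expect_true(all(apply(m, 2, function(col) max(col) - min(col)) < 1e-12))
  # intensity at the band centre = amplitude + baseline there
  i1000 <- which(sim$spectra$wavenumbers == 1000)
  baseline_there <- 1.5 * exp(-(1000 - 1300)^2 / (2 * (600 / 2.3548200450309493)^2))
  expect_equal(unname(m[1, i1000]), 2 + baseline_there, tolerance = 1e-10)
})

test_that("without noise and with unit multipliers class means coincide", {
  cfg <- cohort_config(
    class_sizes = c(healthy = 5, stone = 5),
    bands = default_serum_bands(effect_scale = 0),
    noise_sd = 0, replicates_per_sample = 1, band_jitter_sd = 0,
    baseline_jitter_sd = 0, seed = 2)
  sim <- generate_cohort(cfg)
  mh <- colMeans(sim$spectra$intensities[sim$spectra$labels == "healthy", ])
  ms <- colMeans(sim$spectra$intensities[sim$spectra$labels == "stone", ])
  expect_equal(mh, ms, tolerance = 1e-12)
})

test_that("raising a class multiplier raises that class's mean at the centre", {
  mk <- function(mult_stone) {
    band <- band_spec(900, base_amplitude = 1,
                      class_multipliers = c(healthy = 1, stone = mult_stone))
    cfg <- cohort_config(class_sizes = c(healthy = 4, stone = 4),
                         bands = list(band), noise_sd = 0,
                         replicates_per_sample = 1, band_jitter_sd = 0,
                         baseline_jitter_sd = 0, seed = 1)
    sim <- generate_cohort(cfg)
    i <- which.min(abs(sim$spectra$wavenumbers - 900))
    mean(sim$spectra$intensities[sim$spectra$labels == "stone", i])
  }
  vals <- vapply(c(1, 1.2, 1.5, 2), mk, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("replicate averaging shrinks noise variance by the replicate count", {
  base <- list(class_sizes = c(healthy = 400),
               bands = list(band_spec(1000, base_amplitude = 0,
                                      class_multipliers = c(healthy = 1))),
               baseline_params = list(amplitude = 0, center = 1300,
                                      fwhm = 600, slope = 0),
               noise_sd = 0.5, band_jitter_sd = 0, baseline_jitter_sd = 0,
               grid_start = 1000, grid_stop = 1100, grid_step = 10)
  for (reps in c(1, 5)) {
    cfg <- do.call(cohort_config,
                   c(base, list(replicates_per_sample = reps, seed = 9)))
    sim <- generate_cohort(cfg)
    v <- var(as.vector(sim$spectra$intensities))
    expect_equal(v, 0.5^2 / reps, tolerance = 0.05)
  }
})

test_that("bands outside the grid are rejected with the band named", {
  band <- band_spec(2000, class_multipliers = c(healthy = 1))
  cfg <- cohort_config(class_sizes = c(healthy = 4), bands = list(band))
  expect_error(generate_cohort(cfg), "2000")
})

test_that("band and config invariants are enforced", {
  expect_error(band_spec(700, width = -1,
                         class_multipliers = c(healthy = 1)))
  expect_error(band_spec(700, class_multipliers = c(healthy = -2)),
               "positive")
  expect_error(cohort_config(class_sizes = c(healthy = 0)))
  expect_error(cohort_config(noise_sd = -1))
  expect_error(cohort_config(replicates_per_sample = 0))
})

test_that("ground truth serializes to JSON", {
  sim <- small_cohort(seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$labels, as.character(sim$truth$labels))
  expect_equal(back$band_centers, sim$truth$band_centers)
})
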