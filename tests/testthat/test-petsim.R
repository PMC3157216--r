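test_that("forward projection is linear and zero-preserving", {
  g <- pet_geometry(64, 2, n_angles = 24)
  zero <- matrix(0, 64, 64)
  expect_true(all(forward_project(zero, NULL, g) == 0))
  img <- disk_image(64, 2, 30, value = 1.3)
  s1 <- forward_project(img, NULL, g, fwhm_mm = 0)
  s2 <- forward_project(2 * img, NULL, g, fwhm_mm = 0)
  expect_equal(s2, 2 * s1)
  expect_error(forward_project(img, matrix(0, 32, 32), g), "attenuation")
  expect_error(forward_project(matrix(-1, 64, 64), NULL, g), "negative")
})

test_that("projections of a uniform disk match the chord-length integral", {
  n <- 128; px <- 1.5
  g <- pet_geometry(n, px, n_angles = 32)
  act <- disk_image(n, px, 50, value = 2.5)
  sino <- forward_project(act, NULL, g, fwhm_mm = 0)
  chord <- function(s) ifelse(abs(s) < 50, 2 * sqrt(pmax(50^2 - s^2, 0)), 0)
  interior <- abs(g$s_mm) < 42   # away from the tangential singularity
  for (j in c(1, 9, 20)) {
    err <- max(abs(sino[interior, j] - 2.5 * chord(g$s_mm[interior])))
    expect_lt(err / max(sino), 0.02)
  }
})

test_that("a central point source projects consistently across angles", {
  g <- pet_geometry(64, 1, n_angles = 24)
  img <- matrix(0, 64, 64)
  ctr <- (64 + 1) / 2
  img[32:33, 32:33] <- 1  # smallest symmetric source about the center
  sino <- forward_project(img, NULL, g, fwhm_mm = 0)
  tot <- colSums(sino)
  expect_lt(diff(range(tot)) / mean(tot), 0.1)
})

test_that("count scale integrates the decay over the scan window", {
  acq <- acquisition_params()
  hl <- 6588
  expected <- 10 * 0.97 * (hl / log(2)) *
    (2^(-7200 / hl) - 2^(-8400 / hl))
  expect_equal(count_scale(acq), expected)
  # no-decay limit: sensitivity x dose x yield x duration
  acq_inf <- acquisition_params(half_life = Inf, sensitivity = 2)
  expect_equal(count_scale(acq_inf), 2 * 10 * 0.97 * 1200)
  acq_dbl <- acquisition_params(half_life = Inf, sensitivity = 2,
                                scan_duration = 2400)
  expect_equal(count_scale(acq_dbl), 2 * count_scale(acq_inf))
  # vanishing duration gives a vanishing multiplier
  acq_tiny <- acquisition_params(frame_interval = 1e-6,
                                 scan_duration = 1e-6)
  expect_lt(count_scale(acq_tiny) / count_scale(acq), 1e-8)
})

test_that("acquisition parameter validation enforces the invariants", {
  expect_error(acquisition_params(scatter_fraction = 0.5), "scatter")
  expect_error(acquisition_params(scan_duration = 1100), "multiple")
  expect_error(acquisition_params(half_life = -1), "half_life")
})

test_that("scatter and noise injection is seeded and Poisson", {
  acq <- acquisition_params(scatter_fraction = 0)
  zero <- matrix(0, 10, 10)
  expect_true(all(add_scatter_and_noise(zero, acq, seed = 1)$counts == 0))
  expected <- matrix(200, 20, 10)
  acq15 <- acquisition_params(scatter_fraction = 0.15)
  a <- add_scatter_and_noise(expected, acq15, seed = 3)
  b <- add_scatter_and_noise(expected, acq15, seed = 3)
  expect_identical(a$counts, b$counts)
  # scatter adds sf/(1-sf) of total trues
  expect_equal(a$scatter_mean, 0.15 / 0.85 * sum(expected) / 200)
  # large-mean Poisson: sample mean and variance agree across many bins
  m <- mean(a$counts)
  expect_lt(abs(m - (200 + a$scatter_mean)) / m, 0.05)
  expect_error(add_scatter_and_noise(matrix(-1, 2, 2), acq), "non-negative")
})

test_that("filtered back-projection recovers a uniform disk level", {
  n <- 128; px <- 1.5
  g <- pet_geometry(n, px, n_angles = 64)
  act <- disk_image(n, px, 55, value = 2.5)
  sino <- forward_project(act, NULL, g, fwhm_mm = 0)
  img <- reconstruct(sino, g)
  plateau <- img[disk_image(n, px, 35) > 0]
  expect_lt(abs(mean(plateau) / 2.5 - 1), 0.05)
  expect_lt(max(abs(reconstruct(matrix(0, n, g$n_angles), g))), 1e-10)
  # recovered contrast is monotone in true contrast
  rec_contrast <- vapply(c(2, 5, 10), function(hot) {
    a <- disk_image(n, px, 55, value = 1)
    a[disk_image(n, px, 12, center_mm = c(15, 0)) > 0] <- hot
    r <- reconstruct(forward_project(a, NULL, g, fwhm_mm = 0), g)
    mean(r[disk_image(n, px, 8, center_mm = c(15, 0)) > 0])
  }, 0)
  expect_true(all(diff(rec_contrast) > 0))
})

test_that("attenuation is corrected through the reconstruction", {
  n <- 96; px <- 2
  g <- pet_geometry(n, px, n_angles = 48)
  act <- disk_image(n, px, 60, value = 3)
  mu <- disk_image(n, px, 70, value = 0.0096)
  sino <- forward_project(act, mu, g, fwhm_mm = 0)
  att <- attr(sino, "att")
  expect_true(all(att <= 1))
  img <- reconstruct(sino, g, att = att)
  plateau <- img[disk_image(n, px, 35) > 0]
  expect_lt(abs(mean(plateau) / 3 - 1), 0.05)
})

test_that("paired scans share their noise realization", {
  n <- 96
  act <- disk_image(n, 2, 60, value = 1)
  mu <- disk_image(n, 2, 70, value = 0.0096)
  acq <- acquisition_params()
  g <- pet_geometry(n, 2, n_angles = 48)
  acq$sensitivity <- calibrate_sensitivity(
    forward_project(act, mu, g), acq, 2e5)
  res <- simulate_scan(list(lesion_free = act, lesion = act), mu, acq,
                       geometry = g, seed = 9)
  expect_identical(res$lesion_free, res$lesion)
  counts <- attr(res, "total_counts")
  expect_equal(unname(counts["lesion_free"] / 2e5), 1, tolerance = 0.2)
})

test_that("a lesion-only scan concentrates energy at the lesion", {
  n <- 96
  act <- disk_image(n, 2, 10, value = 1, center_mm = c(-20, 14))
  mu <- disk_image(n, 2, 70, value = 0.0096)
  acq <- acquisition_params()
  g <- pet_geometry(n, 2, n_angles = 48)
  res <- simulate_scan(list(lesion_only = act), mu, acq, geometry = g)
  img <- res$lesion_only
  w <- pmax(img, 0)
  ctr <- (n + 1) / 2
  xs <- (1:n - ctr) * 2
  cx <- sum(outer(xs, rep(1, n)) * w) / sum(w)
  cy <- sum(outer(rep(1, n), xs) * w) / sum(w)
  expect_lt(abs(cx - (-20)), 3)
  expect_lt(abs(cy - 14), 3)
})
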