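test_that("reference lesion sites land in their placement classes", {
  vol <- phantom_128()
  lab <- vol$labels
  d <- dim(lab)
  lt <- reference_lesion_table(d)
  for (i in seq_len(nrow(lt))) {
    x <- lt$x[i]; y <- lt$y[i]; z <- lt$z[i]
    nb <- lab[max(1, x - 3):min(d[1], x + 3),
              max(1, y - 3):min(d[2], y + 3),
              max(1, z - 3):min(d[3], z + 3)]
    if (lt$placement_class[i] == "interior_wm") {
      expect_identical(lab[x, y, z], 3L)
      expect_false(any(nb == 2L))
    } else {
      expect_true(any(nb == 3L) && any(nb == 2L))
    }
  }
})

test_that("full-resolution grid honors the published coordinates", {
  vol <- generate_head_phantom()  # 256 x 256 x 128, 1.1 mm
  expect_identical(vol$labels[103, 123, 52], 3L)
  nb <- vol$labels[139:145, 141:147, 49:55]
  expect_true(any(nb == 3L) && any(nb == 2L))
})

test_that("white/gray matter voxel split tracks the brain mass split", {
  vol <- phantom_128()
  wm <- sum(vol$labels == 3L)
  gm <- sum(vol$labels == 2L)
  expect_lt(abs(wm / (wm + gm) / (42 / 98) - 1), 0.15)
  expect_lt(abs(gm / (wm + gm) / (56 / 98) - 1), 0.15)
})

test_that("phantom generation is deterministic for a seed", {
  a <- generate_head_phantom(dim = c(64, 64, 32), seed = 5)
  b <- generate_head_phantom(dim = c(64, 64, 32), seed = 5)
  expect_identical(a$labels, b$labels)
  c <- generate_head_phantom(dim = c(64, 64, 32), seed = 6)
  expect_false(identical(a$labels, c$labels))
  expect_error(generate_head_phantom(dim = c(32, 32, 16)), "too small")
})

test_that("lesion insertion relabels a sphere-equivalent voxel count", {
  vol <- generate_head_phantom(dim = c(128, 128, 64), voxel_mm = 1.0,
                               seed = 1)
  ctr <- scale_ref_coords(c(110, 105, 45), dim(vol$labels))
  spec <- lesion_spec(as.numeric(ctr), 10, "interior_wm")
  vol2 <- insert_spherical_lesion(vol, spec)
  n_vox <- sum(vol2$labels == 4L)
  expect_lt(abs(n_vox - (4 / 3) * pi * 5^3) / ((4 / 3) * pi * 5^3), 0.10)
  # relabel-only: head extent and non-brain labels untouched
  expect_identical(sum(vol2$labels > 0L), sum(vol$labels > 0L))
  expect_identical(sum(vol2$labels == 0L), sum(vol$labels == 0L))
  expect_identical(sum(vol2$labels == 1L), sum(vol$labels == 1L))
  # input volume not modified, zero diameter is a no-op
  expect_false(any(vol$labels == 4L))
  spec0 <- lesion_spec(as.numeric(ctr), 0, "interior_wm")
  expect_identical(insert_spherical_lesion(vol, spec0)$labels, vol$labels)
})

test_that("disjoint lesion insertions commute", {
  vol <- phantom_128()
  lt <- reference_lesion_table(dim(vol$labels))
  s1 <- lesion_spec(unlist(lt[1, c("x", "y", "z")]), 4, "interior_wm")
  s2 <- lesion_spec(unlist(lt[2, c("x", "y", "z")]), 6, "interior_wm")
  a <- insert_spherical_lesion(insert_spherical_lesion(vol, s1), s2)
  b <- insert_spherical_lesion(insert_spherical_lesion(vol, s2), s1)
  # ids are assigned in insertion order; compare voxel sets per lesion
  expect_identical(which(a$labels == 4L), which(b$labels == 5L))
  expect_identical(which(a$labels == 5L), which(b$labels == 4L))
  expect_error(insert_spherical_lesion(vol, lesion_spec(c(2, 2, 2), 4)),
               "background")
})

test_that("lesion diameters reproduce the published size distribution", {
  d <- sample_lesion_diameters(1e5, seed = 11)
  expect_equal(mean(d >= 3.5 & d <= 9), 0.60, tolerance = 0.01 / 0.60)
  expect_equal(mean(d > 9), 0.20, tolerance = 0.01 / 0.20)
  expect_identical(d, sample_lesion_diameters(1e5, seed = 11))
  # quantile stability across seeds within binomial 3-sigma
  sd_bin <- sqrt(0.6 * 0.4 / 1e5)
  for (s in 1:4) {
    di <- sample_lesion_diameters(1e5, seed = s)
    expect_lt(abs(mean(di >= 3.5 & di <= 9) - 0.6), 3.5 * sd_bin)
  }
  expect_error(sample_lesion_diameters(0), "n must be")
})

test_that("activity assignment is a label lookup", {
  vol <- phantom_128()
  lt <- reference_lesion_table(dim(vol$labels))
  spec <- lesion_spec(unlist(lt[3, c("x", "y", "z")]), 8, "interior_wm")
  vol2 <- insert_spherical_lesion(vol, spec)
  map <- c("1" = 0.5, "2" = 1, "3" = 2, "4" = 1.5)
  act <- assign_activity(vol2, map)
  expect_identical(sum(act == 2), sum(vol2$labels == 3L))
  expect_identical(sum(act == 1.5), sum(vol2$labels == 4L))
  # lesion-only mode zeroes everything below the lesion ids
  only <- assign_activity(vol2, map, lesion_only = TRUE)
  expect_true(all(only[vol2$labels < 4L] == 0))
  expect_true(all(only[vol2$labels == 4L] == 1.5))
  expect_true(all(assign_activity(vol2, c("3" = 0)) == 0))
  expect_error(assign_activity(vol2, c("3" = -1)), "negative")
})

test_that("activity patching commutes with lesion insertion", {
  vol <- phantom_128()
  lt <- reference_lesion_table(dim(vol$labels))
  spec <- lesion_spec(unlist(lt[4, c("x", "y", "z")]), 10, "interior_wm")
  vol2 <- insert_spherical_lesion(vol, spec)
  map <- c("1" = 0.2, "2" = 1, "3" = 2)
  a <- assign_activity(vol2, c(map, "4" = 0.7))
  b <- assign_activity(vol, map)
  b[vol2$labels == 4L] <- 0.7
  expect_identical(a, b)
})

test_that("volumes survive a NIfTI round trip", {
  vol <- generate_head_phantom(dim = c(64, 64, 32), seed = 2)
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol$labels, vol$voxel_mm, path)
  back <- read_volume_nifti(path)
  expect_identical(as.integer(back$data), as.integer(vol$labels))
  expect_equal(back$voxel_mm, vol$voxel_mm, tolerance = 1e-6)
  unlink(path)
})

test_that("lesion specs load from the packaged CSV and scale with the grid", {
  specs <- read_lesion_specs(dim = c(128, 128, 64))
  expect_length(specs, 8)
  ref <- reference_lesion_table(c(128, 128, 64))
  for (i in seq_along(specs)) {
    expect_s3_class(specs[[i]], "lesion_spec")
    expect_equal(specs[[i]]$center,
                 as.numeric(unlist(ref[i, c("x", "y", "z")])))
    expect_equal(specs[[i]]$diameter_mm, ref$diameter_mm[i])
  }
})
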