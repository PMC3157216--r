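test_that("the ROI cutoff sits a quarter of the peak above baseline", {
  expect_equal(lesion_cutoff(matrix(c(rep(0, 99), 40), 10, 10)),
               mean(c(rep(0, 99), 40)) + (40 - mean(c(rep(0, 99), 40))) / 4)
  # compensated construction with baseline exactly 10 and max 50
  v <- c(rep((1000 - 50) / 99, 99), 50)
  expect_equal(mean(v), 10)
  expect_equal(lesion_cutoff(matrix(v, 10, 10)), 20)
  # identity against a direct two-pass oracle on random images
  set.seed(1)
  for (i in 1:10) {
    r <- matrix(rexp(400), 20, 20)
    expect_equal(lesion_cutoff(r), mean(r) + (max(r) - mean(r)) / 4)
  }
  expect_error(lesion_cutoff(matrix(3, 5, 5)), "constant")
})

test_that("ROI definition finds blurred lesions as components", {
  n <- 80
  img <- disk_image(n, 1, 6, value = 1, center_mm = c(-12, 5))
  img <- EBImage::gblur(img, sigma = 2)
  cut <- lesion_cutoff(img)
  rois <- define_roi(img, cut, centers = matrix(c(n / 2 - 12, n / 2 + 5),
                                                1))
  expect_length(rois, 1)
  ctr_pix <- c((n + 1) / 2 - 12, (n + 1) / 2 + 5)
  idx <- (round(ctr_pix[2]) - 1) * n + round(ctr_pix[1])
  expect_true(idx %in% rois[[1]]$pixels)
  expect_identical(rois[[1]]$lesion, 1L)
  # two well-separated lesions give two components
  img2 <- img + disk_image(n, 1, 6, value = 1, center_mm = c(20, -15))
  rois2 <- define_roi(img2, lesion_cutoff(img2))
  expect_length(rois2, 2)
  expect_error(define_roi(img, max(img) + 1), "empty")
})

test_that("negative-contrast SNR matches its defining arithmetic", {
  dim2 <- c(3, 5)
  free <- matrix(100 + c(-5, -5, 0, 5, 5, rep(0, 10)), 3, 5)
  les <- matrix(90 + c(-5, 5, -5, 5, 0, rep(0, 10)), 3, 5)
  roi <- structure(list(pixels = 1:5, dim = dim2, area = 5L,
                        centroid = c(2, 1)), class = "roi_mask")
  res <- snr_negative(les, free, roi)
  expect_equal(res$mu_bgr, 100)
  expect_equal(res$mu_les, 90)
  expect_equal(res$sigma_bgr, 5)
  expect_equal(res$snr, 2)
  expect_equal(as.character(res$feasibility), "feasible")
  # identical images score zero
  res0 <- snr_negative(free, free, roi)
  expect_equal(res0$snr, 0)
  # SNR definition identity against a two-pass oracle on random data
  set.seed(2)
  for (i in 1:10) {
    f <- matrix(rnorm(60, 50, 4), 6, 10)
    l <- matrix(rnorm(60, 45, 4), 6, 10)
    r <- structure(list(pixels = sample(60, 20), dim = c(6, 10),
                        area = 20L, centroid = c(3, 5)),
                   class = "roi_mask")
    got <- snr_negative(l, f, r)$snr
    fb <- f[r$pixels]
    expect_equal(got, (mean(fb) - mean(l[r$pixels])) /
                   sqrt(sum((fb - mean(fb))^2) / (length(fb) - 1)))
  }
  expect_error(snr_negative(les, matrix(1, 3, 5), roi), "sigma_bgr")
})

test_that("SNR is invariant to common shifts and scalings", {
  set.seed(3)
  f <- matrix(rnorm(100, 30, 3), 10, 10)
  l <- matrix(rnorm(100, 25, 3), 10, 10)
  roi <- structure(list(pixels = 11:40, dim = c(10, 10), area = 30L,
                        centroid = c(5, 3)), class = "roi_mask")
  base <- snr_negative(l, f, roi)$snr
  expect_equal(snr_negative(l + 7, f + 7, roi)$snr, base)
  expect_equal(snr_negative(l * 3.2, f * 3.2, roi)$snr, base)
})

test_that("feasibility classes follow the SNR thresholds", {
  expect_identical(as.character(classify_feasibility(0.61)), "not_feasible")
  expect_identical(as.character(classify_feasibility(1.01)), "maybe")
  expect_identical(as.character(classify_feasibility(2.0)), "feasible")
  expect_identical(as.character(classify_feasibility(1.0)), "maybe")
  # stricter lower threshold of 1.3
  expect_identical(
    as.character(classify_feasibility(1.1, thresholds = c(1.3, 2))),
    "not_feasible")
  expect_error(classify_feasibility(1, thresholds = c(2, 1)))
})

test_that("ROI inflation grows by adjacent rings to the exact target", {
  mask <- disk_image(40, 1, 5.6415)  # ~100 px disk
  pix <- which(mask > 0)
  rc <- arrayInd(pix, c(40, 40))
  roi <- structure(list(pixels = pix, dim = c(40, 40),
                        area = length(pix), centroid = colMeans(rc)),
                   class = "roi_mask")
  expect_identical(inflate_roi(roi, 1)$pixels, roi$pixels)
  inf <- inflate_roi(roi, 1.5)
  expect_identical(inf$area, as.integer(round(1.5 * roi$area)))
  new_pix <- setdiff(inf$pixels, roi$pixels)
  # every added pixel touches the original region within two rings
  nrc <- arrayInd(new_pix, c(40, 40))
  dmin <- vapply(seq_along(new_pix), function(k)
    min(pmax(abs(nrc[k, 1] - rc[, 1]), abs(nrc[k, 2] - rc[, 2]))), 0)
  expect_true(all(dmin <= 2))
  # deterministic
  expect_identical(inflate_roi(roi, 1.5)$pixels, inf$pixels)
  # exact areas on random blobs
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(FALSE, 30, 30)
    m[sample(900, 40)] <- TRUE
    m <- m & !is.na(m)
    p <- which(m)
    r <- structure(list(pixels = p, dim = c(30, 30), area = length(p),
                        centroid = colMeans(arrayInd(p, c(30, 30)))),
                   class = "roi_mask")
    expect_identical(inflate_roi(r, 1.3)$area,
                     as.integer(round(1.3 * length(p))))
  }
  # inflation beyond what the image can hold fails
  full <- structure(list(pixels = 1:90, dim = c(10, 10), area = 90L,
                         centroid = c(5, 5)), class = "roi_mask")
  expect_error(inflate_roi(full, 1.5), "bounds")
})
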