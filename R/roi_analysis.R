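# Negative-contrast lesion detectability analysis: lesion ROIs are defined
# on a lesion-only reconstruction, then scored on a paired lesion-free /
# lesion-bearing image pair with SNR = (mu_BGR - mu_LES) / sigma_BGR.

#' Intensity cutoff for lesion ROI definition
#'
#' The ROI threshold is placed at 25% of the lesion-only peak height above
#' the image baseline: `cutoff = baseline + (max - baseline) / 4`, where
#' the baseline is the mean intensity over the entire image. (The cutoff
#' can equivalently be written `(max - baseline) / 4` above baseline; the
#' two published phrasings coincide when the lesion-only baseline is zero,
#' and the 25%-of-height reading is adopted here.) Raising the cutoff well
#' above the baseline excludes peripheral, small-fluctuation pixels.
#'
#' @param lesion_only_image 2D reconstruction with activity modeled only
#'   in the lesions.
#' @return scalar intensity threshold.
#' @export
lesion_cutoff <- function(lesion_only_image) {
  baseline <- mean(lesion_only_image)
  max_signal <- max(lesion_only_image)
  if (max_signal <= baseline)
    stop("constant lesion-only image: no ROI definable")
  baseline + (max_signal - baseline) / 4
}

#' Define lesion ROIs on a lesion-only image
#'
#' Pixels strictly above the cutoff are lesion candidates; connected
#' components (8-neighborhood) become one ROI each. When known lesion
#' centers are supplied, each component is assigned to the nearest center.
#'
#' @param lesion_only_image 2D image.
#' @param cutoff threshold from [lesion_cutoff()].
#' @param centers optional matrix of known lesion centers (x, y) in pixel
#'   coordinates, one row per lesion.
#' @return list of `roi_mask` objects, each with `pixels` (linear
#'   indices), `dim`, `area`, `centroid` and (if centers were given)
#'   `lesion` (row index of the nearest center).
#' @export
define_roi <- function(lesion_only_image, cutoff, centers = NULL) {
  mask <- lesion_only_image > cutoff
  if (!any(mask)) stop("empty ROI: cutoff above image maximum")
  comp <- EBImage::bwlabel(mask)
  ids <- setdiff(sort(unique(as.vector(comp))), 0)
  out <- lapply(ids, function(id) {
    pix <- which(comp == id)
    rc <- arrayInd(pix, dim(lesion_only_image))
    roi <- structure(list(pixels = pix, dim = dim(lesion_only_image),
                          area = length(pix),
                          centroid = colMeans(rc)),
                     class = "roi_mask")
    if (!is.null(centers)) {
      d2 <- rowSums((centers - matrix(roi$centroid, nrow(centers), 2,
                                      byrow = TRUE))^2)
      roi$lesion <- which.min(d2)
    }
    roi
  })
  out
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px, centroid (%.1f, %.1f)%s\n", x$area,
              x$centroid[1], x$centroid[2],
              if (!is.null(x$lesion)) paste0(", lesion ", x$lesion) else ""))
  invisible(x)
}

#' Negative-contrast signal-to-noise ratio of a lesion
#'
#' Scores a signal deficit: `snr = (mu_BGR - mu_LES) / sigma_BGR`, with the
#' background mean and standard deviation taken over the ROI pixels of the
#' lesion-FREE image and the lesion mean over the same pixels of the
#' lesion-bearing image. The sample (n-1) standard deviation is used.
#' The statistic is invariant to adding a common constant to both images
#' and to scaling both by a positive factor, and may be negative if the
#' "lesion" is hotter than its background.
#'
#' @param lesion_image lesion-bearing reconstruction.
#' @param lesion_free_image paired lesion-free reconstruction (congruent).
#' @param roi a `roi_mask` from [define_roi()].
#' @param thresholds feasibility thresholds passed to
#'   [classify_feasibility()].
#' @return object of class `snr_result` with `mu_bgr`, `mu_les`,
#'   `sigma_bgr`, `snr`, `area`, `feasibility`.
#' @export
snr_negative <- function(lesion_image, lesion_free_image, roi,
                         thresholds = c(1, 2)) {
  stopifnot(inherits(roi, "roi_mask"),
            all(dim(lesion_image) == dim(lesion_free_image)),
            all(dim(lesion_image) == roi$dim))
  if (roi$area < 2) stop("ROI too small for a standard deviation")
  bgr <- lesion_free_image[roi$pixels]
  les <- lesion_image[roi$pixels]
  mu_bgr <- mean(bgr)
  sigma_bgr <- stats::sd(bgr)
  if (sigma_bgr == 0) stop("sigma_bgr is zero")
  snr <- (mu_bgr - mean(les)) / sigma_bgr
  structure(list(mu_bgr = mu_bgr, mu_les = mean(les),
                 sigma_bgr = sigma_bgr, snr = snr, area = roi$area,
                 feasibility = classify_feasibility(snr, thresholds)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf(
    "<snr_result> snr %.3f (%s) | mu_bgr %.4g mu_les %.4g sigma %.3g | %d px\n",
    x$snr, x$feasibility, x$mu_bgr, x$mu_les, x$sigma_bgr, x$area))
  invisible(x)
}

#' Classify imaging feasibility from an SNR value
#'
#' Regions with SNR below the lower threshold are not imageable (signal
#' comparable to noise), above the upper threshold imageable, and in
#' between possibly imageable depending on reference anatomy, observer and
#' analysis software. The default thresholds are (1, 2); a stricter lower
#' threshold of 1.3 is also in use.
#'
#' @param snr numeric vector of SNR values.
#' @param thresholds increasing pair `(low, high)`.
#' @return factor with levels `not_feasible`, `maybe`, `feasible`;
#'   boundaries are inclusive upwards (`snr >= high` is feasible).
#' @export
classify_feasibility <- function(snr, thresholds = c(1, 2)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lv <- c("not_feasible", "maybe", "feasible")
  out <- ifelse(snr >= thresholds[2], "feasible",
                ifelse(snr >= thresholds[1], "maybe", "not_feasible"))
  factor(out, levels = lv)
}

# 8-neighborhood binary dilation of a logical matrix
dilate8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  sh <- function(mat, di, dj) {
    res <- matrix(FALSE, n, m)
    ri <- seq_len(n) + di; rj <- seq_len(m) + dj
    ok_i <- ri >= 1 & ri <= n; ok_j <- rj >= 1 & rj <= m
    res[ok_i, ok_j] <- mat[ri[ok_i], rj[ok_j]]
    res
  }
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- out | sh(mask, di, dj)
  out
}

#' Inflate an ROI to a target area
#'
#' Emulates inaccurate lesion delineation: the mask is grown by whole
#' dilation rings (8-neighborhood) until its area reaches
#' `area_factor * original`, then the pixels of the last ring farthest
#' from the original centroid are trimmed to hit the target area exactly
#' (ties broken by column-major scan order).
#'
#' @param roi a `roi_mask`.
#' @param area_factor target area as a multiple of the original (>= 1).
#' @return a new `roi_mask` with `area == round(area_factor * area)`.
#' @export
inflate_roi <- function(roi, area_factor = 1.5) {
  stopifnot(inherits(roi, "roi_mask"))
  if (!is.finite(area_factor) || area_factor < 1)
    stop("area_factor must be >= 1")
  target <- round(area_factor * roi$area)
  if (target == roi$area) return(roi)
  mask <- matrix(FALSE, roi$dim[1], roi$dim[2])
  mask[roi$pixels] <- TRUE
  prev <- mask
  repeat {
    cur <- dilate8(prev)
    if (sum(cur) >= target || all(cur == prev)) break
    prev <- cur
  }
  if (sum(cur) < target)
    stop("inflation exceeds image bounds before reaching target area")
  keep <- which(prev)
  ring <- setdiff(which(cur), keep)
  need <- target - length(keep)
  rc <- arrayInd(ring, roi$dim)
  d2 <- (rc[, 1] - roi$centroid[1])^2 + (rc[, 2] - roi$centroid[2])^2
  ring_sorted <- ring[order(d2, ring)]
  pixels <- sort(c(keep, ring_sorted[seq_len(need)]))
  structure(list(pixels = pixels, dim = roi$dim, area = length(pixels),
                 centroid = roi$centroid, lesion = roi$lesion),
            class = "roi_mask")
}
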