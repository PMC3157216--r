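# Synthetic voxel head phantom emulating the published head-phantom
# geometry: ellipsoidal head, cortical gray-matter shell with a seeded wavy
# boundary, white-matter interior with ventricle voids, and deep gray
# structures placed so that the published lesion coordinates fall in their
# stated placement classes. Label legend: 0 background, 1 other head tissue
# (skull/CSF/soft tissue), 2 gray matter, 3 white matter, 4+ lesion ids.

PHANTOM_REF_DIM <- c(256, 256, 128)

# reference geometry in 256 x 256 x 128 voxel units
phantom_ref_geometry <- function() {
  list(
    head_center = c(128.5, 128.5, 60), head_semi = c(95, 115, 62),
    brain_center = c(128.5, 128.5, 66), brain_semi = c(78, 95, 54),
    shell_radius = 0.783,       # normalized WM/GM boundary radius
    shell_ripple = 0.02,        # seeded boundary waviness amplitude
    ventricle_centers = rbind(c(116.5, 128.5, 64), c(140.5, 128.5, 64)),
    ventricle_semi = c(6, 20, 7),
    # deep gray nuclei: spheres whose surfaces pass through the published
    # border-class lesion coordinates (center = point + radius towards the
    # brain center)
    deep_gm_points = rbind(c(142, 144, 52), c(144, 86, 63),
                           c(139, 140, 45), c(109, 141, 58)),
    deep_gm_radius = 8)
}

#' Scale reference (256 x 256 x 128) voxel coordinates to a phantom grid
#'
#' The published lesion coordinates are indices on a 256 x 256 x 128 head
#' grid; smaller simulation grids reuse them after proportional scaling.
#'
#' @param coords matrix or vector of (x, y, z) 1-based voxel indices on the
#'   reference grid.
#' @param dim target grid dimensions, length 3.
#' @return matrix of scaled, rounded 1-based indices.
#' @export
scale_ref_coords <- function(coords, dim = PHANTOM_REF_DIM) {
  if (is.null(nrow(coords))) coords <- matrix(coords, nrow = 1)
  s <- dim / PHANTOM_REF_DIM
  out <- round(sweep(sweep(coords, 2, s, "*"), 2, (s - 1) / 2, "+"))
  out[] <- pmax(1, pmin(out, matrix(dim, nrow(out), 3, byrow = TRUE)))
  storage.mode(out) <- "integer"
  out
}

#' Generate the synthetic head phantom
#'
#' Builds a deterministic-for-seed label volume: ellipsoidal head (label 1),
#' brain with a cortical gray-matter shell (label 2) whose inner boundary
#' carries a small seeded angular ripple, white-matter interior (label 3)
#' with ventricle voids (label 1), and deep gray-matter nuclei placed so
#' that the published white-matter lesion sites are fully inside white
#' matter and the border-class sites sit on a white/gray interface.
#'
#' @param dim grid dimensions (x, y, z); every component must be >= 64 in
#'   reference proportion (i.e. z may be half of x/y, as in the reference
#'   256 x 256 x 128 grid).
#' @param voxel_mm isotropic voxel size in mm; defaults to keeping the
#'   physical head size of the reference grid (1.1 mm at 256).
#' @param seed integer seed controlling the cortical boundary ripple.
#' @return object of class `phantom_volume`: `labels` (integer 3D array),
#'   `voxel_mm`, `legend`, `lesions` (empty data.frame until lesions are
#'   inserted).
#' @export
generate_head_phantom <- function(dim = PHANTOM_REF_DIM,
                                  voxel_mm = 1.1 * 256 / dim[1],
                                  seed = 1) {
  stopifnot(length(dim) == 3)
  if (dim[1] < 64 || dim[2] < 64 || dim[3] < 32)
    stop("grid too small to honor lesion placement classes")
  g <- phantom_ref_geometry()
  s <- dim / PHANTOM_REF_DIM
  sc <- function(p) p * s            # scale a reference point
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]

  hc <- sc(g$head_center); hs <- g$head_semi * s
  bc <- sc(g$brain_center); bs <- g$brain_semi * s
  ux2 <- ((1:nx - hc[1]) / hs[1])^2
  uy2 <- ((1:ny - hc[2]) / hs[2])^2
  uz2 <- ((1:nz - hc[3]) / hs[3])^2
  r2_head <- outer(outer(ux2, uy2, "+"), uz2, "+")

  vx2 <- ((1:nx - bc[1]) / bs[1])^2
  vy2 <- ((1:ny - bc[2]) / bs[2])^2
  vz2 <- ((1:nz - bc[3]) / bs[3])^2
  r2_brain <- outer(outer(vx2, vy2, "+"), vz2, "+")

  # seeded smooth angular ripple of the cortical boundary radius
  phases <- withr::with_seed(seed, stats::runif(3, 0, 2 * pi))
  theta <- atan2(outer(rep(1, nx), 1:ny - bc[2]),
                 outer(1:nx - bc[1], rep(1, ny)))
  rip_xy <- sin(3 * theta + phases[1]) + 0.5 * cos(5 * theta + phases[2])
  rip_z <- cos(2 * pi * (1:nz) / nz + phases[3])
  thr <- g$shell_radius +
    g$shell_ripple * outer(rip_xy, rip_z) / 1.5

  labels <- array(0L, dim)
  labels[r2_head <= 1] <- 1L
  brain <- r2_brain <= 1
  labels[brain & (r2_brain > thr^2)] <- 2L
  labels[brain & (r2_brain <= thr^2)] <- 3L

  # ventricles: fluid voids inside white matter
  for (k in seq_len(nrow(g$ventricle_centers))) {
    vc <- sc(g$ventricle_centers[k, ]); vs <- g$ventricle_semi * s
    idx <- ellipsoid_box_indices(dim, vc, vs)
    inside <- idx$r2 <= 1
    sel <- idx$lin[inside]
    labels[sel][labels[sel] == 3L] <- 1L
  }

  # deep gray nuclei anchored to the border-class lesion sites
  rad <- g$deep_gm_radius * s[1]
  for (k in seq_len(nrow(g$deep_gm_points))) {
    pt <- sc(g$deep_gm_points[k, ])
    u <- sc(g$brain_center) - pt
    ctr <- pt + rad * u / sqrt(sum(u^2))
    idx <- ellipsoid_box_indices(dim, ctr, rep(rad, 3))
    sel <- idx$lin[idx$r2 <= 1]
    labels[sel][labels[sel] == 3L] <- 2L
  }

  structure(list(labels = labels, voxel_mm = voxel_mm,
                 legend = c(background = 0, other = 1, gray_matter = 2,
                            white_matter = 3),
                 lesions = empty_lesion_table()),
            class = "phantom_volume")
}

empty_lesion_table <- function() {
  data.frame(id = integer(), diameter_mm = numeric(), x = integer(),
             y = integer(), z = integer(), placement_class = character())
}

# linear indices and normalized squared radii of the bounding box of an
# ellipsoid at `center` with semi-axes `semi` (voxel units)
ellipsoid_box_indices <- function(dim, center, semi) {
  lo <- pmax(1, floor(center - semi))
  hi <- pmin(dim, ceiling(center + semi))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / semi[1])^2
  dy2 <- ((ys - center[2]) / semi[2])^2
  dz2 <- ((zs - center[3]) / semi[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  lin <- outer(outer(xs, (ys - 1) * dim[1], "+"),
               (zs - 1) * dim[1] * dim[2], "+")
  list(lin = as.vector(lin), r2 = as.vector(r2))
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_volume> %d x %d x %d voxels @ %.3g mm, %d lesion(s)\n",
              d[1], d[2], d[3], x$voxel_mm, nrow(x$lesions)))
  invisible(x)
}

#' Specify a spherical lesion
#'
#' @param center (x, y, z) 1-based voxel indices of the lesion center.
#' @param diameter_mm lesion diameter in mm, in (0, 20].
#' @param placement_class `"interior_wm"` or `"wm_gm_border"`.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, diameter_mm,
                        placement_class = c("interior_wm", "wm_gm_border")) {
  placement_class <- match.arg(placement_class)
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (!is.finite(diameter_mm) || diameter_mm < 0 || diameter_mm > 20)
    stop("diameter_mm must lie in [0, 20]")
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm,
                 placement_class = placement_class),
            class = "lesion_spec")
}

#' The published lesion insertion table, scaled to a grid
#'
#' Four diameters (4, 6, 8, 10 mm), each at one site completely within
#' white matter and one at the white/gray border, on the reference
#' 256 x 256 x 128 grid.
#'
#' @param dim target grid dimensions.
#' @return data.frame with `diameter_mm`, `x`, `y`, `z`,
#'   `placement_class`.
#' @export
reference_lesion_table <- function(dim = PHANTOM_REF_DIM) {
  interior <- rbind(c(103, 123, 52), c(106, 84, 63),
                    c(110, 105, 45), c(151, 127, 58))
  border <- rbind(c(142, 144, 52), c(144, 86, 63),
                  c(139, 140, 45), c(109, 141, 58))
  ci <- scale_ref_coords(interior, dim)
  cb <- scale_ref_coords(border, dim)
  data.frame(
    diameter_mm = rep(c(4, 6, 8, 10), 2),
    x = c(ci[, 1], cb[, 1]), y = c(ci[, 2], cb[, 2]),
    z = c(ci[, 3], cb[, 3]),
    placement_class = rep(c("interior_wm", "wm_gm_border"), each = 4))
}

#' Read lesion specifications from CSV
#'
#' The CSV mirrors the published insertion table layout
#' (`diameter_mm, x, y, z, placement_class` with coordinates on the
#' reference 256 x 256 x 128 grid); coordinates are scaled to `dim`.
#'
#' @param path CSV file path; defaults to the packaged reference table.
#' @param dim target grid dimensions.
#' @return list of [lesion_spec()] objects.
#' @export
read_lesion_specs <- function(path = system.file("extdata",
                                                 "reference_lesions.csv",
                                                 package = "myelinpet"),
                              dim = PHANTOM_REF_DIM) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- scale_ref_coords(as.matrix(tab[, c("x", "y", "z")]), dim)
  lapply(seq_len(nrow(tab)), function(i)
    lesion_spec(coords[i, ], tab$diameter_mm[i], tab$placement_class[i]))
}

#' Insert a spherical lesion into a phantom
#'
#' Voxels whose centers lie within `diameter_mm / 2` of the lesion center
#' and which are currently white or gray matter are relabeled to a fresh
#' lesion id (4, 5, ...). The input volume is not modified; a new volume is
#' returned. A zero diameter is a no-op.
#'
#' @param vol a `phantom_volume`.
#' @param spec a [lesion_spec()].
#' @return a new `phantom_volume` with the lesion added and recorded in
#'   `vol$lesions`.
#' @export
insert_spherical_lesion <- function(vol, spec) {
  stopifnot(inherits(vol, "phantom_volume"), inherits(spec, "lesion_spec"))
  d <- dim(vol$labels)
  ctr <- spec$center
  if (any(ctr < 1) || any(ctr > d)) stop("lesion center outside the grid")
  if (vol$labels[ctr[1], ctr[2], ctr[3]] == 0L)
    stop("lesion center lies in the background")
  if (spec$diameter_mm == 0) return(vol)
  new_id <- if (nrow(vol$lesions)) max(vol$lesions$id) + 1L else 4L
  r_vox <- spec$diameter_mm / 2 / vol$voxel_mm
  idx <- ellipsoid_box_indices(d, ctr, rep(r_vox, 3))
  sel <- idx$lin[idx$r2 <= 1]
  sel <- sel[vol$labels[sel] %in% c(2L, 3L)]
  vol$labels[sel] <- as.integer(new_id)
  vol$lesions <- rbind(vol$lesions, data.frame(
    id = as.integer(new_id), diameter_mm = spec$diameter_mm,
    x = as.integer(round(ctr[1])), y = as.integer(round(ctr[2])),
    z = as.integer(round(ctr[3])),
    placement_class = spec$placement_class))
  vol
}

#' Sample lesion diameters from the MS lesion-size distribution
#'
#' A two-parameter log-normal calibrated so that 20% of lesions are smaller
#' than 3.5 mm and 20% larger than 9 mm (hence 60% between 3.5 and 9 mm),
#' matching the published survey of 2766 MS lesions. The log-normal is
#' fitted to the two quantile constraints `P(d < 3.5) = 0.2` and
#' `P(d > 9) = 0.2`; the middle-bin mass follows.
#'
#' @param n number of draws (> 0).
#' @param seed integer seed.
#' @return numeric vector of diameters in mm.
#' @export
sample_lesion_diameters <- function(n, seed = 1) {
  if (!is.finite(n) || n <= 0) stop("n must be > 0")
  par <- lesion_diameter_lognormal()
  withr::with_seed(seed, stats::rlnorm(n, par$meanlog, par$sdlog))
}

#' Parameters of the calibrated lesion-diameter log-normal
#'
#' @return list with `meanlog` and `sdlog` solving the 20/60/20 quantile
#'   constraints at 3.5 and 9 mm.
#' @export
lesion_diameter_lognormal <- function() {
  z80 <- stats::qnorm(0.8)
  list(meanlog = (log(3.5) + log(9)) / 2,
       sdlog = (log(9) - log(3.5)) / (2 * z80))
}

#' Map compartment activities onto phantom voxels
#'
#' @param vol a `phantom_volume`.
#' @param activity_by_label named numeric vector mapping label values
#'   (as names, e.g. `"3"` for white matter) to activity concentrations;
#'   labels without an entry default to 0. All values must be >= 0.
#' @param lesion_only if TRUE, all non-lesion labels (< 4) are zeroed,
#'   producing the lesion-only volume used to define lesion ROIs.
#' @return numeric 3D array of voxel activities.
#' @export
assign_activity <- function(vol, activity_by_label, lesion_only = FALSE) {
  stopifnot(inherits(vol, "phantom_volume"))
  if (length(activity_by_label) && is.null(names(activity_by_label)))
    stop("activity_by_label must be named by label value")
  if (any(activity_by_label < 0)) stop("negative activity rejected")
  present <- sort(unique(as.vector(vol$labels)))
  lut <- stats::setNames(numeric(length(present)), present)
  hit <- intersect(names(activity_by_label), names(lut))
  lut[hit] <- activity_by_label[hit]
  if (lesion_only) lut[as.numeric(names(lut)) < 4] <- 0
  out <- array(lut[as.character(vol$labels)], dim(vol$labels))
  dimnames(out) <- NULL
  out
}

#' Attenuation map for a phantom
#'
#' Uniform water-equivalent 511 keV linear attenuation inside the head,
#' zero outside.
#'
#' @param vol a `phantom_volume`.
#' @param mu_head linear attenuation coefficient, 1/mm (default 0.0096).
#' @return numeric 3D array.
#' @export
attenuation_map <- function(vol, mu_head = 0.0096) {
  stopifnot(inherits(vol, "phantom_volume"))
  out <- array(0, dim(vol$labels))
  out[vol$labels > 0L] <- mu_head
  out
}

#' Extract a transverse slice from a 3D array or phantom
#'
#' @param x `phantom_volume` (labels are taken) or 3D array.
#' @param z slice index.
#' @return 2D matrix.
#' @export
transverse_slice <- function(x, z) {
  arr <- if (inherits(x, "phantom_volume")) x$labels else x
  stopifnot(length(dim(arr)) == 3, z >= 1, z <= dim(arr)[3])
  arr[, , z]
}

#' Write a volume to NIfTI
#'
#' @param arr 3D array (integer labels or float activity).
#' @param voxel_mm isotropic voxel size in mm.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(arr, voxel_mm, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return list with `data` (array) and `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_mm = RNifti::pixdim(img)[1])
}
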