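# Confocal quantifications: thresholded innervation density, 3D puncta
# counting (26-connected components with size gates, matching common 3D
# object-counter behaviour), corrected total cell fluorescence (CTCF),
# normalised ROI signal, and cohort-level binary innervation scoring.
# ROIs are supplied as masks (regions were selected manually in the assays
# this reproduces); automatic segmentation is out of scope.

#' Construct an image stack
#'
#' @param voxels 3D numeric array of non-negative intensities, dimension
#'   order (z, y, x).
#' @param z_step z spacing in micrometres (default 0.5, the acquisition
#'   step used throughout).
#' @param pixel_size in-plane pixel size in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, z_step = 0.5, pixel_size = 1) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3D array (z, y, x)", call. = FALSE)
  if (any(voxels < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(voxels = voxels, z_step = z_step, pixel_size = pixel_size),
            class = "image_stack")
}

#' Construct an ROI mask
#'
#' @param mask logical array (2D slice or 3D volume) selecting the region.
#' @param label region label, one of `dFSB`, `vFSB`, `cell`, `background`,
#'   `reference`.
#' @param allow_empty permit an all-FALSE mask (default FALSE).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("dFSB", "vFSB", "cell", "background",
                                     "reference"),
                     allow_empty = FALSE) {
  label <- match.arg(label)
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!allow_empty && !any(mask))
    stop("ROI mask is empty", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

.roi_logical <- function(roi, target_dim) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!identical(dim(m), as.integer(target_dim)) &&
      !identical(dim(m), target_dim))
    stop("ROI mask shape does not match the image", call. = FALSE)
  m
}

#' Thresholded innervation density
#'
#' Fraction of ROI pixels at or above the intensity threshold:
#' (area occupied by supra-threshold signal) / (area of the ROI). The
#' threshold is inclusive and must be held constant across a comparison set;
#' intensities are compared raw.
#'
#' @param img an `image_stack`, or a numeric array/matrix (single section or
#'   volume).
#' @param roi an `roi_mask` (or logical array) congruent with `img`.
#' @param threshold intensity threshold (inclusive).
#' @return Fraction in `[0, 1]`.
#' @export
innervation_density <- function(img, roi, threshold) {
  v <- if (inherits(img, "image_stack")) img$voxels else img
  m <- .roi_logical(roi, dim(as.array(v)))
  n <- sum(m)
  if (n == 0)
    stop("undefined density: empty ROI", call. = FALSE)
  sum(v[m] >= threshold) / n
}

# 3D connected-component labelling of a logical array.
# 26-connectivity by default (every voxel sharing a face, edge or corner);
# 6-connectivity (faces only) available. BFS over the TRUE voxels, written
# here because no installed labeller handles 3D arrays.
label_components_3d <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(mask)
  stopifnot(length(d) == 3)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  idx <- which(mask)
  labels <- integer(length(idx))
  if (length(idx) == 0)
    return(list(labels = array(0L, d), n = 0L, sizes = integer(0)))
  pos <- array(0L, d)          # voxel linear index -> rank among TRUE voxels
  pos[idx] <- seq_along(idx)
  coord <- arrayInd(idx, d)
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    labels[s] <- ncomp
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cz <- coord[v, 1]; cy <- coord[v, 2]; cx <- coord[v, 3]
      nz <- cz + off[, 1]; ny <- cy + off[, 2]; nx <- cx + off[, 3]
      ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
      if (!any(ok)) next
      lin <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
      nb <- pos[lin]
      nb <- nb[nb > 0L]
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- ncomp
        queue <- c(queue, nb)
      }
    }
  }
  lab_arr <- array(0L, d)
  lab_arr[idx] <- labels
  list(labels = lab_arr, n = ncomp, sizes = tabulate(labels, ncomp))
}

#' Count 3D puncta inside an ROI
#'
#' Connected components (26-connectivity by default) of voxels at or above
#' the intensity threshold inside the ROI; components whose voxel count
#' lies inside the inclusive `[min_size, max_size]` gate are counted. The
#' defaults (threshold 52, sizes 2-80) match the published puncta-counting
#' settings. The ROI volume is the number of ROI voxels with intensity >= 1
#' (the published volume setting: threshold 1, minimum size 1), and density
#' is count per ROI voxel, with a micrometre-cubed conversion from the
#' stack's voxel spacing.
#'
#' @param stack an `image_stack`.
#' @param roi an `roi_mask` (or 3D logical array) congruent with the stack.
#' @param intensity_threshold inclusive intensity threshold (default 52).
#' @param min_size,max_size inclusive size gates in voxels (defaults 2, 80).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `puncta_count_result`: `count`,
#'   `roi_volume_vox`, `roi_volume_um3`, `density` (count per voxel),
#'   `density_um3`, `sizes` (all component sizes before gating).
#' @export
count_puncta_3d <- function(stack, roi, intensity_threshold = 52,
                            min_size = 2L, max_size = 80L,
                            connectivity = 26L) {
  stopifnot(inherits(stack, "image_stack"))
  if (min_size > max_size)
    stop("min_size must be <= max_size", call. = FALSE)
  m <- .roi_logical(roi, dim(stack$voxels))
  fg <- m & stack$voxels >= intensity_threshold
  cc <- label_components_3d(fg, connectivity)
  count <- sum(cc$sizes >= min_size & cc$sizes <= max_size)
  vol_vox <- sum(m & stack$voxels >= 1)
  voxel_um3 <- stack$z_step * stack$pixel_size^2
  structure(list(count = count, roi_volume_vox = vol_vox,
                 roi_volume_um3 = vol_vox * voxel_um3,
                 density = if (vol_vox > 0) count / vol_vox else NA_real_,
                 density_um3 = if (vol_vox > 0)
                   count / (vol_vox * voxel_um3) else NA_real_,
                 sizes = cc$sizes),
            class = "puncta_count_result")
}

#' @export
print.puncta_count_result <- function(x, ...) {
  cat(sprintf("<puncta_count_result> %d puncta in %d ROI voxels (%.4g per voxel)\n",
              x$count, x$roi_volume_vox, x$density))
  invisible(x)
}

#' Corrected total cell fluorescence
#'
#' CTCF = integrated density of the cell ROI minus (cell area x mean
#' background fluorescence). May be negative; reported as-is.
#'
#' @param cell_integrated_density summed intensity over the cell ROI
#'   (intensity x pixels).
#' @param cell_area cell ROI area in pixels (> 0).
#' @param background_mean mean intensity of the background ROI.
#' @return The CTCF value.
#' @export
ctcf <- function(cell_integrated_density, cell_area, background_mean) {
  if (any(cell_area <= 0))
    stop("cell area must be positive", call. = FALSE)
  cell_integrated_density - cell_area * background_mean
}

#' CTCF measured directly from an image and masks
#'
#' Convenience wrapper: integrates the cell ROI and averages the background
#' ROI on a single section (or volume), then applies [ctcf()].
#'
#' @param img numeric matrix/array of intensities.
#' @param cell_roi,background_roi `roi_mask` (or logical arrays).
#' @return A one-row `data.frame`: `integrated_density`, `area`,
#'   `background_mean`, `ctcf`.
#' @export
ctcf_from_image <- function(img, cell_roi, background_roi) {
  v <- if (inherits(img, "image_stack")) img$voxels else img
  cm <- .roi_logical(cell_roi, dim(as.array(v)))
  bm <- .roi_logical(background_roi, dim(as.array(v)))
  if (!any(cm)) stop("cell area must be positive", call. = FALSE)
  if (!any(bm)) stop("background ROI is empty", call. = FALSE)
  id <- sum(v[cm]); area <- sum(cm); bg <- mean(v[bm])
  data.frame(integrated_density = id, area = area, background_mean = bg,
             ctcf = ctcf(id, area, bg))
}

#' Normalised ROI signal
#'
#' Ratio of a mean ROI signal to a reference mean: either an adjacent
#' background ROI (activity-reporter normalisation) or a co-stain measured
#' in the same ROI (e.g. a general neuropil stain). The mode is recorded
#' for provenance.
#'
#' @param signal_mean mean intensity of the signal channel in the ROI.
#' @param reference_mean mean reference intensity (> 0).
#' @param mode `"adjacent_background"` or `"same_roi_reference"`.
#' @return A one-row `data.frame`: `ratio`, `mode`.
#' @export
normalized_roi_signal <- function(signal_mean, reference_mean,
                                  mode = c("adjacent_background",
                                           "same_roi_reference")) {
  mode <- match.arg(mode)
  if (any(reference_mean <= 0))
    stop("undefined normalisation: reference mean must be > 0",
         call. = FALSE)
  data.frame(ratio = signal_mean / reference_mean, mode = mode)
}

#' Cohort-level binary innervation scoring
#'
#' Calls each brain positive for innervation when its thresholded
#' innervation density reaches `min_fraction` (the published binary scoring
#' criterion is unstated, so `min_fraction` is an explicit, labelled
#' assumption), and reports the positive percentage with a Clopper-Pearson
#' binomial 95% CI.
#'
#' @param stacks list of `list(stack = , roi = )` pairs (or
#'   `list(img = , roi = )` with plain arrays).
#' @param threshold intensity threshold for [innervation_density()].
#' @param min_fraction minimum density to call a brain positive.
#' @return A list: `calls` (`data.frame` with `brain`, `density`,
#'   `positive`), `n`, `n_positive`, `percent_positive`, `ci_low`, `ci_high`
#'   (percent scale).
#' @export
innervation_presence <- function(stacks, threshold, min_fraction) {
  if (length(stacks) == 0)
    stop("empty cohort", call. = FALSE)
  dens <- vapply(stacks, function(s) {
    img <- if (!is.null(s$stack)) s$stack else s$img
    innervation_density(img, s$roi, threshold)
  }, numeric(1))
  pos <- dens >= min_fraction
  ci <- stats::binom.test(sum(pos), length(pos))$conf.int
  list(calls = data.frame(brain = seq_along(dens), density = dens,
                          positive = pos),
       n = length(pos), n_positive = sum(pos),
       percent_positive = 100 * mean(pos),
       ci_low = 100 * ci[1], ci_high = 100 * ci[2])
}
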