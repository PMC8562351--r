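#' Segmentation parameters for nuclear-density quantification
#'
#' @param histogram_bins Bins of the intensity histogram used for the mode
#'   estimate (default 256, spanning the image's dynamic range).
#' @param blur_sigma_px Gaussian blur sigma applied to the binary mask
#'   before morphology (default 2).
#' @param morph_radius_px Disk radius of the erosion/dilation structuring
#'   element (default 2).
#' @param watershed_min_seed_distance_px Minimum separation of
#'   distance-transform maxima treated as distinct nucleus cores
#'   (default 10).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(histogram_bins = 256,
                                blur_sigma_px = 2,
                                morph_radius_px = 2,
                                watershed_min_seed_distance_px = 10) {
  stopifnot(histogram_bins > 0, blur_sigma_px > 0, morph_radius_px > 0,
            watershed_min_seed_distance_px > 0)
  structure(list(histogram_bins = as.integer(histogram_bins),
                 blur_sigma_px = blur_sigma_px,
                 morph_radius_px = as.integer(morph_radius_px),
                 watershed_min_seed_distance_px =
                   as.integer(watershed_min_seed_distance_px)),
            class = "segmentation_params")
}

#' Threshold nuclei by histogram mode plus two standard deviations
#'
#' The threshold is the mode of the pixel-intensity histogram (argmax over
#' `histogram_bins` bins spanning the image's dynamic range, reported as the
#' bin center) plus twice the standard deviation of all pixel intensities;
#' pixels strictly above the threshold are foreground. On a field dominated
#' by background this isolates the bright nucleus stain. A constant image
#' yields an empty mask with a warning.
#'
#' @param nucleus_image Numeric matrix (single-channel intensities).
#' @param params A [segmentation_params()].
#' @return Logical matrix mask with attribute `"threshold"`.
#' @export
threshold_nuclei <- function(nucleus_image, params = segmentation_params()) {
  if (length(nucleus_image) == 0) stop("empty image")
  rng <- range(nucleus_image)
  if (diff(rng) == 0) {
    warning("constant image: empty nucleus mask")
    mask <- matrix(FALSE, nrow(nucleus_image), ncol(nucleus_image))
    attr(mask, "threshold") <- rng[1]
    return(mask)
  }
  breaks <- seq(rng[1], rng[2], length.out = params$histogram_bins + 1)
  counts <- tabulate(findInterval(nucleus_image, breaks,
                                  rightmost.closed = TRUE),
                     nbins = params$histogram_bins)
  mode_bin <- which.max(counts)
  mode_val <- (breaks[mode_bin] + breaks[mode_bin + 1]) / 2
  thr <- mode_val + 2 * stats::sd(nucleus_image)
  mask <- nucleus_image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Clean a binary mask by blurring and morphology
#'
#' Gaussian-blurs the 0/1 mask (sigma `blur_sigma_px`), re-thresholds at
#' 0.5, then applies one erosion and one dilation with a disk of radius
#' `morph_radius_px`. Objects smaller than the structuring element vanish;
#' an empty mask is a fixed point.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [segmentation_params()].
#' @return Cleaned logical matrix.
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  m <- EBImage::Image(mask * 1)
  if (!any(mask > 0)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  m <- EBImage::gblur(m, sigma = params$blur_sigma_px) > 0.5
  brush <- EBImage::makeBrush(2 * params$morph_radius_px + 1, shape = "disc")
  m <- EBImage::dilate(EBImage::erode(m, brush), brush)
  matrix(EBImage::imageData(m) > 0, nrow(mask), ncol(mask))
}

#' Separate touching nuclei by watershed on the distance transform
#'
#' Computes the Euclidean distance transform of the cleaned mask and floods
#' its negation from local maxima; maxima closer together than
#' `watershed_min_seed_distance_px` are treated as one core, so touching
#' convex blobs with distinct cores receive distinct labels.
#'
#' @param mask Cleaned logical mask.
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background).
#' @export
split_touching_nuclei <- function(mask, params = segmentation_params()) {
  if (!any(mask > 0))
    return(matrix(0L, nrow(mask), ncol(mask)))
  dist <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dist, tolerance = 1,
                            ext = params$watershed_min_seed_distance_px)
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

#' Nuclear density from a label image and a tissue channel
#'
#' The nucleus count is the number of distinct labels; the tissue area is
#' the Otsu-thresholded, hole-filled foreground of the matrix (WGA) channel
#' converted to mm^2 via the pixel size. ND is their ratio in nuclei/mm^2.
#' The Otsu step assumes the field contains both tissue and background; a
#' field that is entirely tissue should be measured with a known area
#' instead.
#'
#' @param label_image Integer label matrix from [split_touching_nuclei()].
#' @param matrix_image Numeric matrix, the extracellular-matrix channel.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A list (`nd_measurement`) with `nucleus_count`,
#'   `tissue_area_mm2` and `nd`.
#' @export
compute_nd <- function(label_image, matrix_image, pixel_size_um) {
  if (!all(dim(label_image) == dim(matrix_image)))
    stop("label image and matrix channel have different shapes")
  count <- length(setdiff(unique(as.integer(label_image)), 0L))
  mi <- matrix_image - min(matrix_image)
  if (max(mi) > 0) mi <- mi / max(mi)
  thr <- EBImage::otsu(EBImage::Image(mi), range = c(0, 1))
  tissue <- EBImage::fillHull(EBImage::Image(mi > thr))
  area_mm2 <- sum(EBImage::imageData(tissue) > 0) * (pixel_size_um / 1000)^2
  if (area_mm2 <= 0) stop("zero tissue area")
  structure(list(nucleus_count = count, tissue_area_mm2 = area_mm2,
                 nd = count / area_mm2),
            class = "nd_measurement")
}

#' Assign the three-level nuclear-density class
#'
#' Classes are the half-open intervals `[0, 2000)` = low, `[2000, 3800)` =
#' medium and `[3800, Inf)` = high nuclei/mm^2, the label scheme used to
#' train the CNN classifier.
#'
#' @param nd Nuclear density in nuclei/mm^2 (vectorized, >= 0).
#' @param boundaries Class boundaries (default `c(2000, 3800)`).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
assign_nd_class <- function(nd, boundaries = c(2000, 3800)) {
  if (any(nd < 0)) stop("nd must be non-negative")
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0)
  cut(nd, breaks = c(0, boundaries, Inf),
      labels = c("low", "medium", "high"),
      right = FALSE, include.lowest = TRUE)
}

#' Measure nuclear density of a generated or loaded field
#'
#' Runs the full segmentation chain (threshold, clean, watershed, count /
#' tissue area) on a two-channel field.
#'
#' @param nucleus_image,matrix_image Numeric intensity matrices.
#' @param pixel_size_um Pixel size in micrometres.
#' @param params A [segmentation_params()].
#' @return An `nd_measurement` list (see [compute_nd()]).
#' @export
measure_nd <- function(nucleus_image, matrix_image, pixel_size_um = 0.2,
                       params = segmentation_params()) {
  mask <- threshold_nuclei(nucleus_image, params)
  mask <- clean_mask(mask, params)
  labels <- split_touching_nuclei(mask, params)
  compute_nd(labels, matrix_image, pixel_size_um)
}
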