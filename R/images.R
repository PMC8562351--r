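#' Confocal-like image generator configuration
#'
#' Parameters for simulating DAPI/WGA-like two-channel fields: elliptical
#' nuclei of 2-5 um semi-axes on a 512 x 512 grid at 0.2 um/px, a fraction of
#' nuclei placed as touching pairs, and Poisson-plus-Gaussian intensity
#' noise. By default the tissue (matrix channel) covers the whole field; a
#' nonzero `tissue_margin_px` leaves a dark non-tissue border so that
#' Otsu-based tissue-area estimation has both classes present.
#'
#' @param pixel_size_um Pixel size in micrometres (default 0.2).
#' @param field_shape_px `c(height, width)` in pixels (default 512 x 512).
#' @param nucleus_axes_um Range of nucleus semi-axes in um (default 2-5).
#' @param touching_fraction Fraction of nuclei placed in touching pairs
#'   (default 0.15).
#' @param background_level,nucleus_level,tissue_level Channel intensities
#'   (a.u., 16-bit scale).
#' @param noise_gaussian_sd Additive Gaussian read-noise SD (default 20);
#'   photon noise is Poisson around the noiseless image. Set
#'   `noise_gaussian_sd = 0` together with `poisson_noise = FALSE` for
#'   noise-free fields.
#' @param poisson_noise Apply Poisson photon noise (default TRUE).
#' @param tissue_margin_px Dark border width in px of the matrix channel
#'   (default 0 = full-field tissue).
#' @param seed Integer seed.
#' @return An `image_gen_config` list.
#' @export
image_gen_config <- function(pixel_size_um = 0.2,
                             field_shape_px = c(512, 512),
                             nucleus_axes_um = c(2, 5),
                             touching_fraction = 0.15,
                             background_level = 300,
                             nucleus_level = 3000,
                             tissue_level = 2000,
                             noise_gaussian_sd = 20,
                             poisson_noise = TRUE,
                             tissue_margin_px = 0,
                             seed = 1L) {
  stopifnot(pixel_size_um > 0, length(field_shape_px) == 2,
            touching_fraction >= 0, touching_fraction <= 1)
  structure(as.list(environment()), class = "image_gen_config")
}

#' Area of the tissue region of a generated field, in mm^2
#' @keywords internal
field_tissue_area_mm2 <- function(gen) {
  h <- gen$field_shape_px[1] - 2 * gen$tissue_margin_px
  w <- gen$field_shape_px[2] - 2 * gen$tissue_margin_px
  h * w * (gen$pixel_size_um / 1000)^2
}

#' Paint one filled ellipse into a matrix
#' @keywords internal
paint_ellipse <- function(img, cy, cx, a_px, b_px, theta, level) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(max(a_px, b_px))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(img)
  yy <- outer(ys - cy, rep(1, length(xs)))
  xx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- pmax(sub[inside], level)
  img[ys, xs] <- sub
  img
}

#' Generate a two-channel confocal-like field with known nucleus count
#'
#' The nucleus channel contains `N ~ Poisson(ND x tissue area)` simulated
#' elliptical nuclei (with a configured fraction placed as touching pairs);
#' the matrix channel marks the tissue extent. Both channels carry Poisson
#' photon noise plus Gaussian read noise unless disabled. Deterministic
#' given `gen$seed`.
#'
#' @param meta One-row data frame (or list) with `true_nd` (nuclei/mm^2).
#' @param gen An [image_gen_config()].
#' @return A list with `nucleus` and `matrix` (numeric intensity matrices),
#'   `count` (ground-truth nucleus count) and `expected_count`
#'   (`true_nd` x tissue area).
#' @export
generate_confocal_pair <- function(meta, gen = image_gen_config()) {
  set.seed(gen$seed)
  area <- field_tissue_area_mm2(gen)
  expected <- meta$true_nd * area
  if (expected < 1)
    stop("field too small: expected nucleus count ", signif(expected, 3),
         " < 1")
  h <- gen$field_shape_px[1]; w <- gen$field_shape_px[2]
  m <- gen$tissue_margin_px
  n <- stats::rpois(1, expected)
  nuc <- matrix(gen$background_level, h, w)
  mat <- matrix(gen$background_level, h, w)
  mat[(m + 1):(h - m), (m + 1):(w - m)] <- gen$tissue_level
  ax_px <- gen$nucleus_axes_um / gen$pixel_size_um
  n_pairs <- floor(n * gen$touching_fraction / 2)
  n_single <- n - 2 * n_pairs
  draw_axes <- function() sort(stats::runif(2, ax_px[1], ax_px[2]))
  # distinct nuclei must not overlap by chance (they would merge into one
  # connected component); placements are rejection-sampled against the
  # bounding circles of everything placed so far
  placed <- matrix(numeric(0), ncol = 3)  # cy, cx, radius
  rand_center <- function(margin, radius) {
    for (try in 1:2000) {
      ctr <- c(stats::runif(1, m + margin, h - m - margin),
               stats::runif(1, m + margin, w - m - margin))
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) >
              placed[, 3] + radius + 2))
        return(ctr)
    }
    stop("field too crowded to place ", n, " non-overlapping nuclei")
  }
  objects <- c(
    lapply(seq_len(n_single), function(i) list(kind = "single",
                                               ab = draw_axes())),
    lapply(seq_len(n_pairs), function(i) list(kind = "pair",
                                              ab1 = draw_axes(),
                                              ab2 = draw_axes()))
  )
  radius_of <- function(ob) {
    if (ob$kind == "single") ob$ab[2]
    else 0.45 * (ob$ab1[2] + ob$ab2[2]) + max(ob$ab1[2], ob$ab2[2])
  }
  # place the largest objects first: random sequential packing then rarely
  # runs out of room even at the highest densities
  objects <- objects[order(-vapply(objects, radius_of, numeric(1)))]
  for (ob in objects) {
    if (ob$kind == "single") {
      ctr <- rand_center(ob$ab[2], ob$ab[2])
      placed <- rbind(placed, c(ctr, ob$ab[2]))
      nuc <- paint_ellipse(nuc, ctr[1], ctr[2], ob$ab[2], ob$ab[1],
                           stats::runif(1, 0, pi), gen$nucleus_level)
    } else {
      sep <- 0.9 * (ob$ab1[2] + ob$ab2[2])  # centers closer than a1 + a2
      rr <- radius_of(ob)
      ctr <- rand_center(rr, rr)
      placed <- rbind(placed, c(ctr, rr))
      ang <- stats::runif(1, 0, 2 * pi)
      dir <- c(sin(ang), cos(ang))
      c1 <- ctr - sep / 2 * dir
      c2 <- ctr + sep / 2 * dir
      nuc <- paint_ellipse(nuc, c1[1], c1[2], ob$ab1[2], ob$ab1[1],
                           stats::runif(1, 0, pi), gen$nucleus_level)
      nuc <- paint_ellipse(nuc, c2[1], c2[2], ob$ab2[2], ob$ab2[1],
                           stats::runif(1, 0, pi), gen$nucleus_level)
    }
  }
  add_noise <- function(img) {
    if (gen$poisson_noise)
      img <- matrix(stats::rpois(length(img), lambda = img), nrow(img))
    if (gen$noise_gaussian_sd > 0)
      img <- img + stats::rnorm(length(img), 0, gen$noise_gaussian_sd)
    pmax(img, 0)
  }
  list(nucleus = add_noise(nuc), matrix = add_noise(mat),
       count = n, expected_count = expected)
}

#' Write / read a two-channel field as 16-bit TIFF
#'
#' The nucleus channel is stored as frame 1 and the matrix channel as
#' frame 2 of a two-frame 16-bit grayscale TIFF.
#'
#' @param pair List with `nucleus` and `matrix` intensity matrices (a.u.,
#'   0-65535).
#' @param path Output path.
#' @return `read_confocal_pair()` returns a list with `nucleus` and
#'   `matrix`.
#' @export
write_confocal_pair <- function(pair, path) {
  arr <- array(c(pair$nucleus, pair$matrix),
               dim = c(dim(pair$nucleus), 2)) / 65535
  arr <- pmin(pmax(arr, 0), 1)
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_confocal_pair
#' @export
read_confocal_pair <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path)) * 65535
  list(nucleus = img[, , 1], matrix = img[, , 2])
}
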