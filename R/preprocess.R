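#' Preprocessing configuration
#'
#' Parameters of the slice-denoising and body-crop stage. Defaults follow the
#' pipeline's reference settings: Gaussian width sigma = 3 px, HU window
#' (-1000, 400), body threshold -300 HU, disk opening of radius 3 px, 8 px
#' bounding-box margin, and a 256 x 256 output frame.
#'
#' @param sigma Gaussian filter width in pixels (> 0).
#' @param body_hu_window length-2 HU clip bounds (low, high) applied before
#'   thresholding.
#' @param body_threshold HU value separating body from air.
#' @param opening_radius structuring-element (disk) radius in pixels for the
#'   morphological opening that removes thin table/blanket bridges.
#' @param margin padding in pixels added around the detected bounding box.
#' @param out_size output side length in pixels (>= 16).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(sigma = 3, body_hu_window = c(-1000, 400),
                              body_threshold = -300, opening_radius = 3,
                              margin = 8, out_size = 256) {
  check_scalar(sigma, "sigma", lower = 0, open_lower = TRUE)
  if (length(body_hu_window) != 2 || body_hu_window[1] >= body_hu_window[2])
    stop_param("body_hu_window", "must be (low, high) with low < high")
  check_scalar(body_threshold, "body_threshold")
  check_scalar(opening_radius, "opening_radius", lower = 0, integer = TRUE)
  check_scalar(margin, "margin", lower = 0, integer = TRUE)
  check_scalar(out_size, "out_size", lower = 16, integer = TRUE)
  structure(list(sigma = sigma, body_hu_window = body_hu_window,
                 body_threshold = body_threshold,
                 opening_radius = as.integer(opening_radius),
                 margin = as.integer(margin),
                 out_size = as.integer(out_size)),
            class = "preprocess_config")
}

#' Gaussian smoothing of a CT slice
#'
#' Convolves a slice with the normalized, discretely sampled 2D isotropic
#' Gaussian of width `sigma`, implemented separably with mirror padding at
#' the frame edges (so constants are preserved and no dark halo appears).
#'
#' @param slice 2D numeric matrix (HU).
#' @param sigma Gaussian width in pixels (> 0).
#' @return matrix of the same shape.
#' @export
gaussian_smooth <- function(slice, sigma = 3) {
  check_scalar(sigma, "sigma", lower = 0, open_lower = TRUE)
  if (!is.matrix(slice)) stop("slice must be a 2D matrix", call. = FALSE)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  g <- dnorm(-r:r, 0, sigma)
  g <- g / sum(g)
  smooth_1d <- function(x) {   # along rows (dim 1), columns independent
    H <- nrow(x)
    pad <- x[c(pmin(H, r:1), 1:H, pmax(1L, H:(H - r + 1))), , drop = FALSE]
    y <- stats::filter(pad, g, sides = 2)
    matrix(y[(r + 1):(r + H), ], nrow = H)
  }
  t(smooth_1d(t(smooth_1d(slice))))
}

#' @rdname gaussian_smooth
#' @param volume `ct_volume`, matrix or 3D array to smooth slice by slice.
#' @export
gaussian_smooth_volume <- function(volume, sigma = 3) {
  v <- as_voxels(volume)
  for (z in seq_len(dim(v)[3])) v[, , z] <- gaussian_smooth(v[, , z], sigma)
  if (inherits(volume, "ct_volume")) {
    volume$voxels <- v
    volume
  } else v
}

# binarized, opened body image of one slice
body_binary <- function(slice, threshold, opening_radius,
                        window = c(-1000, 400)) {
  cl <- clip(slice, window[1], window[2])
  bin <- matrix(as.numeric(cl > threshold), nrow(slice), ncol(slice))
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    bin <- EBImage::opening(bin, brush)
  }
  bin
}

#' Record of a body-region crop
#'
#' @param bbox integer length-4 vector (row_min, row_max, col_min, col_max),
#'   1-based inclusive, in original pixel coordinates.
#' @param original_size integer length-2 (rows, cols) of the uncropped frame.
#' @param out_size output side length the crop is zoomed to.
#' @return object of class `crop_transform`.
#' @export
crop_transform <- function(bbox, original_size, out_size) {
  bbox <- as.integer(bbox)
  if (bbox[1] > bbox[2] || bbox[3] > bbox[4])
    stop("bbox is empty", call. = FALSE)
  if (bbox[1] < 1 || bbox[3] < 1 ||
      bbox[2] > original_size[1] || bbox[4] > original_size[2])
    stop("bbox lies outside the original frame", call. = FALSE)
  structure(list(bbox = bbox, original_size = as.integer(original_size),
                 out_size = as.integer(out_size)),
            class = "crop_transform")
}

#' @export
print.crop_transform <- function(x, ...) {
  cat(sprintf("<crop_transform rows %d..%d cols %d..%d of %dx%d -> %d>\n",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4],
              x$original_size[1], x$original_size[2], x$out_size))
  invisible(x)
}

#' Locate the body region of a slice or volume
#'
#' Clips intensities to the configured HU window, thresholds, applies a
#' morphological disk opening, and takes the circumscribed rectangle of the
#' largest connected domain — the chest. For a volume the union of the
#' per-slice rectangles is returned so a single transform serves the whole
#' case. The box is padded by `cfg$margin` and clipped to the frame.
#'
#' @param x 2D matrix, 3D array or `ct_volume` of HU intensities.
#' @param cfg a [preprocess_config()].
#' @return a [crop_transform()].
#' @export
locate_body <- function(x, cfg = preprocess_config()) {
  v <- as_voxels(x)
  S <- dim(v)
  box <- c(Inf, -Inf, Inf, -Inf)
  found <- FALSE
  for (z in seq_len(S[3])) {
    bin <- body_binary(v[, , z], cfg$body_threshold, cfg$opening_radius,
                       cfg$body_hu_window)
    lab <- EBImage::bwlabel(bin)
    if (max(lab) == 0) next
    counts <- tabulate(lab[lab > 0])
    main <- which(lab == which.max(counts), arr.ind = TRUE)
    box <- c(min(box[1], min(main[, 1])), max(box[2], max(main[, 1])),
             min(box[3], min(main[, 2])), max(box[4], max(main[, 2])))
    found <- TRUE
  }
  if (!found) {
    id <- if (inherits(x, "ct_volume")) x$case_id else "slice"
    stop(sprintf("no body found in '%s': empty foreground after opening", id),
         call. = FALSE)
  }
  m <- cfg$margin
  box <- c(max(1L, box[1] - m), min(S[1], box[2] + m),
           max(1L, box[3] - m), min(S[2], box[4] + m))
  crop_transform(box, S[1:2], cfg$out_size)
}

resize_slice <- function(slice, w, h, nearest = FALSE) {
  out <- EBImage::resize(slice, w = w, h = h,
                         filter = if (nearest) "none" else "bilinear")
  matrix(out, nrow = w)
}

#' Crop a case to its body box and zoom to the working resolution
#'
#' Crops every slice to the transform's bounding box and resamples it to
#' `out_size` x `out_size`. Images use bilinear interpolation; masks use
#' nearest-neighbor so they stay binary.
#'
#' @param volume `ct_volume` (or array) to crop.
#' @param mask optional aligned `mask_volume` (or array) cropped with the
#'   same transform.
#' @param transform a [crop_transform()] from [locate_body()].
#' @return list with `image` (ct_volume), `mask` (mask_volume or NULL) and
#'   `transform`.
#' @export
crop_and_zoom <- function(volume, mask = NULL, transform) {
  v <- as_voxels(volume)
  if (any(dim(v)[1:2] != transform$original_size))
    stop("shape mismatch: volume does not match transform original_size",
         call. = FALSE)
  bb <- transform$bbox
  n <- dim(v)[3]
  o <- transform$out_size
  out <- array(0, c(o, o, n))
  for (z in seq_len(n))
    out[, , z] <- resize_slice(v[bb[1]:bb[2], bb[3]:bb[4], z], o, o)
  id <- if (inherits(volume, "ct_volume")) volume$case_id else "case"
  res <- list(image = ct_volume(out, case_id = id), mask = NULL,
              transform = transform)
  if (!is.null(mask)) {
    mv <- as_voxels(mask)
    check_same_shape(mv, v, "mask and volume")
    mo <- array(0, c(o, o, n))
    for (z in seq_len(n))
      mo[, , z] <- resize_slice(mv[bb[1]:bb[2], bb[3]:bb[4], z], o, o,
                                nearest = TRUE)
    res$mask <- mask_volume(mo, case_id = id)
  }
  res
}

#' Map a cropped-frame mask back to original coordinates
#'
#' Inverse of [crop_and_zoom()] for masks: the `out_size` prediction is
#' resampled (nearest-neighbor) to the bounding-box size and placed inside
#' the box of an otherwise-zero original-size volume.
#'
#' @param mask256 `mask_volume` (or array) at `out_size` resolution.
#' @param transform the [crop_transform()] used in the forward direction.
#' @return `mask_volume` at the original frame size.
#' @export
invert_transform <- function(mask256, transform) {
  mv <- as_voxels(mask256)
  if (any(dim(mv)[1:2] != transform$out_size))
    stop("shape mismatch: mask is not at transform out_size", call. = FALSE)
  bb <- transform$bbox
  n <- dim(mv)[3]
  out <- array(0, c(transform$original_size, n))
  for (z in seq_len(n))
    out[bb[1]:bb[2], bb[3]:bb[4], z] <-
      resize_slice(mv[, , z], bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L,
                   nearest = TRUE)
  id <- if (inherits(mask256, "mask_volume")) mask256$case_id else "case"
  mask_volume(out, case_id = id)
}

#' Run the full preprocessing stage on one case
#'
#' Gaussian-smooths the volume, locates the body, and crops/zooms image (and
#' mask, if given) to the working resolution.
#'
#' @param volume `ct_volume` in HU.
#' @param mask optional aligned `mask_volume`.
#' @param cfg a [preprocess_config()].
#' @return list with `image`, `mask`, `transform` as in [crop_and_zoom()].
#' @export
preprocess_case <- function(volume, mask = NULL, cfg = preprocess_config()) {
  sm <- gaussian_smooth_volume(volume, cfg$sigma)
  tf <- locate_body(sm, cfg)
  crop_and_zoom(sm, mask, tf)
}
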