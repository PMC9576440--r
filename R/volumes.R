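#' CT and mask volume containers
#'
#' A `ct_volume` is an ordered stack of axial slices stored as a 3D numeric
#' array with dimensions (row, col, slice) holding Hounsfield intensities,
#' plus optional voxel spacing and a case identifier. A `mask_volume` is the
#' binary counterpart (values in {0, 1}), aligned voxel-for-voxel with its CT.
#'
#' @param voxels 3D numeric array (row, col, slice). A matrix is promoted to
#'   a single-slice volume.
#' @param spacing optional numeric length-3 voxel spacing (z, y, x) in mm,
#'   carried through unchanged.
#' @param case_id identifier string.
#' @return object of class `ct_volume` (or `mask_volume`).
#' @export
ct_volume <- function(voxels, spacing = NULL, case_id = "case") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (row, col, slice)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, case_id = case_id),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
mask_volume <- function(voxels, case_id = "case") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (row, col, slice)", call. = FALSE)
  check_binary(voxels)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, case_id = case_id), class = "mask_volume")
}

as_voxels <- function(x) {
  if (inherits(x, c("ct_volume", "mask_volume"))) return(x$voxels)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a ct_volume, mask_volume, matrix or 3D array", call. = FALSE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume '%s': %d x %d x %d slices, HU range [%.0f, %.0f]>\n",
              x$case_id, d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume '%s': %d x %d x %d slices, %d foreground voxels>\n",
              x$case_id, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
dim.mask_volume <- function(x) dim(x$voxels)
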