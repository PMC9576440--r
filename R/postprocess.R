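#' 3D connected-component labeling of a mask volume
#'
#' Labels all maximal connected components of a binary volume under 6- or
#' 26-connectivity. Components are reported in decreasing volume order, ties
#' broken by the array-order index of the first voxel, so the ordering is
#' deterministic.
#'
#' @param mask `mask_volume` or binary 3D array.
#' @param connectivity 6 or 26 (default 26, tolerant of anisotropic slice
#'   spacing).
#' @return object of class `cc3d`: list with `labels` (integer 3D array,
#'   0 = background, components numbered 1..K by decreasing volume) and
#'   `components`, a data.frame with columns label, volume, centroid_row,
#'   centroid_col, centroid_slice and the 3D bounding box.
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  v <- as_voxels(mask)
  check_binary(v)
  if (!connectivity %in% c(6, 26))
    stop_param("connectivity", "must be 6 or 26")
  m <- v
  storage.mode(m) <- "integer"
  lab <- .cpp_label3d(m, as.integer(connectivity))
  k <- max(lab)
  if (k == 0) {
    comps <- data.frame(label = integer(), volume = integer(),
                        centroid_row = numeric(), centroid_col = numeric(),
                        centroid_slice = numeric(),
                        row_min = integer(), row_max = integer(),
                        col_min = integer(), col_max = integer(),
                        slice_min = integer(), slice_max = integer())
    return(structure(list(labels = lab, components = comps), class = "cc3d"))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  comps <- do.call(rbind, lapply(seq_len(k), function(l) {
    p <- idx[lv == l, , drop = FALSE]
    data.frame(label = l, volume = nrow(p),
               centroid_row = mean(p[, 1]), centroid_col = mean(p[, 2]),
               centroid_slice = mean(p[, 3]),
               row_min = min(p[, 1]), row_max = max(p[, 1]),
               col_min = min(p[, 2]), col_max = max(p[, 2]),
               slice_min = min(p[, 3]), slice_max = max(p[, 3]))
  }))
  structure(list(labels = lab, components = comps), class = "cc3d")
}

#' Case-based filter: keep the two largest centrally located lung volumes
#'
#' Stacks slicewise predictions into a 3D mask, labels its connected
#' components, and retains at most the two largest components whose in-plane
#' centroids fall inside the central `location_prior` fraction of the frame
#' — operationalizing the expectation that, after body cropping, the left
#' and right lungs are the two dominant central volumes while peripheral
#' blobs are table or artifact remnants. The filter only removes voxels; if
#' no component qualifies an empty mask is returned with a warning.
#'
#' @param mask `mask_volume` or binary 3D array of slicewise predictions in
#'   cropped coordinates.
#' @param location_prior central-region fraction in (0, 1\]; a component is
#'   kept only if its centroid lies within the central window spanning this
#'   fraction of rows and columns (default 0.8).
#' @param connectivity 6 or 26 (default 26).
#' @return filtered `mask_volume`; the retained components (as in
#'   [label_components_3d()]) are attached as attribute `"components"`.
#' @export
case_filter <- function(mask, location_prior = 0.8, connectivity = 26) {
  check_scalar(location_prior, "location_prior", lower = 0, upper = 1,
               open_lower = TRUE)
  v <- as_voxels(mask)
  cc <- label_components_3d(v, connectivity)
  comps <- cc$components
  d <- dim(v)
  id <- if (inherits(mask, "mask_volume")) mask$case_id else "case"
  if (nrow(comps) == 0) {
    warning(sprintf("case_filter: empty mask for '%s'", id), call. = FALSE)
    return(mask_volume(array(0, d), case_id = id))
  }
  half <- location_prior / 2
  ok <- abs(comps$centroid_row - (d[1] + 1) / 2) <= half * d[1] &
        abs(comps$centroid_col - (d[2] + 1) / 2) <= half * d[2]
  keep <- head(comps$label[ok], 2L)   # components are volume-ordered
  if (length(keep) == 0) {
    warning(sprintf(
      "case_filter: no centrally located component for '%s'", id),
      call. = FALSE)
    return(mask_volume(array(0, d), case_id = id))
  }
  out <- array(as.numeric(cc$labels %in% keep), d)
  res <- mask_volume(out, case_id = id)
  attr(res, "components") <- comps[comps$label %in% keep, ]
  res
}
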