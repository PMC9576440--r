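#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the (row, col, slice) array convention
#' of [ct_volume()].
#'
#' @param x `ct_volume` or `mask_volume`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_ct_nifti` returns a `ct_volume`; `read_mask_nifti` a
#'   `mask_volume`.
#' @export
write_volume_nifti <- function(x, path) {
  v <- as_voxels(x)
  RNifti::writeNifti(v, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param case_id identifier for the returned volume.
#' @export
read_ct_nifti <- function(path, case_id = basename(path)) {
  v <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(v)
  arr <- array(as.numeric(v), dim(v))
  ct_volume(arr, spacing = rev(pd[seq_len(min(3, length(pd)))]),
            case_id = case_id)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path, case_id = basename(path)) {
  v <- RNifti::readNifti(path)
  mask_volume(array(as.numeric(v > 0.5), dim(v)), case_id = case_id)
}

#' Write a phantom case to disk
#'
#' Writes image and mask either as a NIfTI pair (`<stem>_image.nii.gz`,
#' `<stem>_mask.nii.gz`) or as a directory of per-slice 16-bit PNGs, plus a
#' JSON sidecar with the spec and defect log.
#'
#' @param case a `phantom_case`.
#' @param stem output path stem (NIfTI) or directory (PNG).
#' @param format "nifti" or "png".
#' @return invisibly, the paths written.
#' @export
write_phantom_case <- function(case, stem, format = c("nifti", "png")) {
  format <- match.arg(format)
  side <- list(spec = unclass(case$spec), defect_log = case$defect_log)
  if (format == "nifti") {
    paths <- c(image = paste0(stem, "_image.nii.gz"),
               mask = paste0(stem, "_mask.nii.gz"),
               json = paste0(stem, ".json"))
    write_volume_nifti(case$image, paths["image"])
    write_volume_nifti(case$mask, paths["mask"])
  } else {
    dir.create(stem, showWarnings = FALSE, recursive = TRUE)
    n <- dim(case$image)[3]
    paths <- character()
    for (z in seq_len(n)) {
      # 16-bit PNG: map HU in [-1024, 3071] onto [0, 65535]
      img <- clip((as_voxels(case$image)[, , z] + 1024) / 4095, 0, 1)
      pi <- file.path(stem, sprintf("image_%03d.png", z))
      pm <- file.path(stem, sprintf("mask_%03d.png", z))
      png::writePNG(img, pi, dpi = NULL)
      png::writePNG(as_voxels(case$mask)[, , z], pm)
      paths <- c(paths, pi, pm)
    }
    paths <- c(paths, json = file.path(stem, "case.json"))
  }
  jsonlite::write_json(side, paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a per-case metrics report
#'
#' @param metrics data.frame from [metrics_table()].
#' @param path CSV output path.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
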