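#' Read an image stack from disk
#'
#' Reads a multi-slice grayscale MR stack into an [image_stack()]. NIfTI-1 is
#' the primary on-disk format; raw matrices/arrays can be wrapped directly
#' (useful in tests and scripting). DICOM directory ingest is not supported in
#' this build; convert the series to NIfTI first (e.g. with `dcm2niix`).
#'
#' For NIfTI, the data array is interpreted as `(row, col, slice)` with row 1
#' at the image top and slices ordered anterior to posterior, and the voxel
#' geometry is taken from `pixdim` unless overridden. Note that NIfTI stores
#' `pixdim` as 32-bit floats, so geometry round-trips to float32 precision
#' while the image data itself round-trips bit-exactly.
#'
#' @param path filesystem path (NIfTI), or a matrix/array for
#'   `format = "raw-array"`.
#' @param format one of `"nifti"`, `"raw-array"`, `"dicom-dir"`.
#' @param in_plane_mm,slice_thickness_mm,slice_gap_mm optional geometry
#'   overrides; for `"raw-array"` these default to 1.8 / 13 / 0 mm.
#' @param mask logical; read as a [mask_stack()] (values checked to be 0/1).
#' @return an `image_stack` (or `mask_stack` when `mask = TRUE`).
#' @seealso [write_mask()], [write_stack()]
#' @export
read_stack <- function(path, format = c("nifti", "raw-array", "dicom-dir"),
                       in_plane_mm = NULL, slice_thickness_mm = NULL,
                       slice_gap_mm = 0, mask = FALSE) {
  format <- match.arg(format)
  if (format == "dicom-dir") {
    stop("DICOM directory ingest is not supported; convert the series to NIfTI first",
         call. = FALSE)
  }
  if (format == "raw-array") {
    arr <- path
    if (!(is.matrix(arr) || (is.array(arr) && length(dim(arr)) == 3L))) {
      stop("`path` must be a matrix or 3-D array when format = 'raw-array'",
           call. = FALSE)
    }
    geom <- list(in_plane_mm %||% 1.8, slice_thickness_mm %||% 13)
  } else {
    if (!file.exists(path)) {
      stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
    }
    nii <- tryCatch(RNifti::readNifti(path), error = function(e) {
      stop(sprintf("failed to read NIfTI '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    arr <- as.array(nii)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L) {
      stop(sprintf("'%s' is %d-dimensional; expected a 2-D or 3-D volume",
                   path, length(dim(arr))), call. = FALSE)
    }
    pd <- RNifti::pixdim(nii)
    # single-slice volumes collapse to 2-D on disk and carry no slice
    # thickness in the header; fall back to the 13 mm default
    thick <- if (length(pd) >= 3L) pd[3L] else 13
    geom <- list(in_plane_mm %||% pd[1L], slice_thickness_mm %||% thick)
  }
  storage.mode(arr) <- "double"
  if (mask) {
    mask_stack(arr, in_plane_mm = geom[[1L]], slice_thickness_mm = geom[[2L]],
               slice_gap_mm = slice_gap_mm)
  } else {
    image_stack(arr, in_plane_mm = geom[[1L]], slice_thickness_mm = geom[[2L]],
                slice_gap_mm = slice_gap_mm)
  }
}

#' Write a binary mask stack to disk
#'
#' Writes a [mask_stack()] either as a NIfTI-1 volume (`uint8`, bit-exact on
#' re-read) or as one PNG per slice for quality-control overlays. The mask is
#' validated before writing; values outside \{0, 1\} are rejected.
#'
#' @param mask a `mask_stack`.
#' @param path output file (`nifti`) or directory (`png-per-slice`; files are
#'   named `slice_001.png`, ...).
#' @param format `"nifti"` or `"png-per-slice"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("nifti", "png-per-slice")) {
  format <- match.arg(format)
  if (!inherits(mask, "mask_stack")) {
    stop("`mask` must be a mask_stack", call. = FALSE)
  }
  validate_image_stack(mask)
  if (format == "nifti") {
    write_nifti_stack(mask, path, datatype = "uint8")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_len(n_slices(mask))) {
      png::writePNG(mask$slices[[k]],
                    file.path(path, sprintf("slice_%03d.png", k)))
    }
  }
  invisible(path)
}

#' Write a grayscale image stack as NIfTI
#'
#' @param stack an `image_stack`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  validate_image_stack(stack)
  write_nifti_stack(stack, path, datatype = "double")
  invisible(path)
}

write_nifti_stack <- function(stack, path, datatype) {
  arr <- stack_array(stack)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(stack$in_plane_mm, stack$in_plane_mm,
                           stack$slice_thickness_mm + stack$slice_gap_mm)
  ok <- tryCatch({
    RNifti::writeNifti(nii, path, datatype = datatype)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
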