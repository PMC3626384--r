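#' Image stacks and mask stacks
#'
#' `image_stack()` wraps an ordered list of coronal grayscale slices together
#' with the voxel geometry used for volume computations. `mask_stack()` is the
#' binary counterpart; it shares the geometry contract exactly.
#'
#' Slices are numeric matrices in `(row, col)` order, row 1 at the top of the
#' image, and are stored anterior to posterior. All slices must share the same
#' dimensions, and intensities must be finite and non-negative. Masks must be
#' strictly 0/1.
#'
#' @param slices a list of numeric matrices, a single matrix, or a 3-D array
#'   with dimensions `(n_rows, n_cols, n_slices)`.
#' @param in_plane_mm pixel edge length in mm (default 1.8, the typical
#'   in-plane resolution of coronal HP 3He acquisitions).
#' @param slice_thickness_mm slice depth in mm (default 13).
#' @param slice_gap_mm inter-slice gap in mm (default 0).
#' @return An object of class `image_stack` (or `mask_stack`, which inherits
#'   from `image_stack`): a list with elements `slices`, `n_rows`, `n_cols`,
#'   `in_plane_mm`, `slice_thickness_mm`, `slice_gap_mm`.
#' @examples
#' img <- image_stack(matrix(runif(64 * 64, 0, 100), 64, 64))
#' n_slices(img)
#' voxel_volume_mm3(img)
#' @export
image_stack <- function(slices, in_plane_mm = 1.8, slice_thickness_mm = 13,
                        slice_gap_mm = 0) {
  slices <- as_slice_list(slices)
  x <- structure(
    list(
      slices = slices,
      n_rows = nrow(slices[[1L]]),
      n_cols = ncol(slices[[1L]]),
      in_plane_mm = in_plane_mm,
      slice_thickness_mm = slice_thickness_mm,
      slice_gap_mm = slice_gap_mm
    ),
    class = "image_stack"
  )
  validate_image_stack(x)
  x
}

#' @rdname image_stack
#' @param like an `image_stack` whose geometry the mask copies. When given,
#'   the geometry arguments are ignored.
#' @export
mask_stack <- function(slices, like = NULL, in_plane_mm = 1.8,
                       slice_thickness_mm = 13, slice_gap_mm = 0) {
  if (!is.null(like)) {
    stopifnot(inherits(like, "image_stack"))
    in_plane_mm <- like$in_plane_mm
    slice_thickness_mm <- like$slice_thickness_mm
    slice_gap_mm <- like$slice_gap_mm
  }
  slices <- as_slice_list(slices)
  slices <- lapply(slices, function(s) {
    storage.mode(s) <- "integer"
    s
  })
  x <- structure(
    list(
      slices = slices,
      n_rows = nrow(slices[[1L]]),
      n_cols = ncol(slices[[1L]]),
      in_plane_mm = in_plane_mm,
      slice_thickness_mm = slice_thickness_mm,
      slice_gap_mm = slice_gap_mm
    ),
    class = c("mask_stack", "image_stack")
  )
  validate_image_stack(x)
  x
}

as_slice_list <- function(slices) {
  if (is.matrix(slices)) {
    slices <- list(slices)
  } else if (is.array(slices) && length(dim(slices)) == 3L) {
    slices <- lapply(seq_len(dim(slices)[3L]), function(k) slices[, , k])
  }
  if (!is.list(slices) || length(slices) == 0L ||
      !all(vapply(slices, is.matrix, logical(1L)))) {
    stop("`slices` must be a matrix, a 3-D array, or a non-empty list of matrices",
         call. = FALSE)
  }
  slices
}

#' Validate an image or mask stack
#'
#' Checks the stack invariants: identical slice dimensions, finite
#' non-negative intensities, positive voxel geometry, and (for masks) strictly
#' binary values. Called by the constructors; exported so readers can
#' re-validate externally produced objects.
#'
#' @param x an `image_stack` or `mask_stack`.
#' @return `x`, invisibly; errors if an invariant is violated.
#' @export
validate_image_stack <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  dims <- vapply(x$slices, dim, integer(2L))
  if (!all(dims[1L, ] == x$n_rows) || !all(dims[2L, ] == x$n_cols)) {
    stop("all slices must share identical dimensions", call. = FALSE)
  }
  for (k in seq_along(x$slices)) {
    s <- x$slices[[k]]
    if (anyNA(s) || any(!is.finite(s))) {
      stop(sprintf("slice %d contains non-finite intensities", k), call. = FALSE)
    }
    if (any(s < 0)) {
      stop(sprintf("slice %d contains negative intensities", k), call. = FALSE)
    }
    if (inherits(x, "mask_stack") && !all(s %in% c(0L, 1L))) {
      stop(sprintf("mask slice %d has values outside {0, 1}", k), call. = FALSE)
    }
  }
  if (!(x$in_plane_mm > 0) || !(x$slice_thickness_mm > 0) ||
      !(x$slice_gap_mm >= 0)) {
    stop("voxel geometry must satisfy in_plane_mm > 0, slice_thickness_mm > 0, slice_gap_mm >= 0",
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
n_slices <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  length(x$slices)
}

#' Voxel volume of a stack
#'
#' The volume of one voxel, `in_plane_mm^2 * (slice_thickness_mm +
#' slice_gap_mm)`, in cubic millimetres. With the default geometry (1.8 mm
#' in-plane, 13 mm thick, no gap) this is 42.12 mm^3.
#'
#' @param x an `image_stack` or `mask_stack`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  x$in_plane_mm^2 * (x$slice_thickness_mm + x$slice_gap_mm)
}

#' Convert a stack to a 3-D array
#'
#' @param x an `image_stack`.
#' @return a numeric array with dimensions `(n_rows, n_cols, n_slices)`.
#' @export
stack_array <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  array(unlist(x$slices, use.names = FALSE),
        dim = c(x$n_rows, x$n_cols, n_slices(x)))
}

#' @export
print.image_stack <- function(x, ...) {
  kind <- if (inherits(x, "mask_stack")) "mask_stack" else "image_stack"
  cat(sprintf("<%s> %d slice(s) of %d x %d\n", kind, n_slices(x), x$n_rows, x$n_cols))
  cat(sprintf("  voxel: %.4g x %.4g x %.4g mm (gap %.4g mm) = %.4g mm^3\n",
              x$in_plane_mm, x$in_plane_mm, x$slice_thickness_mm,
              x$slice_gap_mm, voxel_volume_mm3(x)))
  rng <- range(unlist(lapply(x$slices, range)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1L], rng[2L]))
  invisible(x)
}

# geometry equality used by contracts (dice, subtraction, refine)
same_geometry <- function(a, b) {
  inherits(a, "image_stack") && inherits(b, "image_stack") &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    n_slices(a) == n_slices(b) &&
    isTRUE(all.equal(a$in_plane_mm, b$in_plane_mm)) &&
    isTRUE(all.equal(a$slice_thickness_mm, b$slice_thickness_mm)) &&
    isTRUE(all.equal(a$slice_gap_mm, b$slice_gap_mm))
}
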