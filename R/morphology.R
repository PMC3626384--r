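#' Disk structuring element
#'
#' A binary disk: all pixels whose Euclidean distance from the centre is at
#' most `radius`. Used by [binary_erode()] / [binary_dilate()] and by
#' [morphological_cleanup()]. The element always contains its origin.
#'
#' @param radius integer radius in pixels, >= 1.
#' @return an object of class `structuring_element`: list with `shape`
#'   (`"disk"`), `radius`, `offsets` (an `n x 2` matrix of (row, col) offsets)
#'   and `kernel` (the `(2r+1) x (2r+1)` 0/1 matrix).
#' @export
disk_element <- function(radius = 2) {
  radius <- as.integer(radius)
  stopifnot(radius >= 1L)
  d <- -radius:radius
  grid <- expand.grid(dr = d, dc = d)
  keep <- grid$dr^2 + grid$dc^2 <= radius^2
  kernel <- matrix(as.integer(keep), 2L * radius + 1L, 2L * radius + 1L)
  structure(
    list(shape = "disk", radius = radius,
         offsets = as.matrix(grid[keep, c("dr", "dc")]), kernel = kernel),
    class = "structuring_element"
  )
}

# shift a matrix by (dr, dc), padding with `fill`
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binary dilation and erosion
#'
#' Set-theoretic (Minkowski) morphology on binary rasters. Dilation of mask
#' `A` by element `B` is the union of `A` translated by every offset of `B`;
#' erosion keeps the pixels whose translated copy of `B` lies entirely inside
#' `A`. Pixels outside the raster count as background, so erosion shrinks
#' regions touching the image border.
#'
#' @param mask binary matrix (0/1).
#' @param se a [disk_element()] (or any `structuring_element`).
#' @return binary matrix of the same shape.
#' @export
binary_dilate <- function(mask, se) {
  stopifnot(is.matrix(mask), inherits(se, "structuring_element"))
  acc <- matrix(FALSE, nrow(mask), ncol(mask))
  m <- mask != 0
  for (i in seq_len(nrow(se$offsets))) {
    acc <- acc | shift_matrix(m, se$offsets[i, 1L], se$offsets[i, 2L], FALSE)
  }
  matrix(as.integer(acc), nrow(mask), ncol(mask))
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, se) {
  stopifnot(is.matrix(mask), inherits(se, "structuring_element"))
  acc <- matrix(TRUE, nrow(mask), ncol(mask))
  m <- mask != 0
  for (i in seq_len(nrow(se$offsets))) {
    acc <- acc & shift_matrix(m, -se$offsets[i, 1L], -se$offsets[i, 2L], FALSE)
  }
  matrix(as.integer(acc), nrow(mask), ncol(mask))
}
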