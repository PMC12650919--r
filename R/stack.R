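#' Grayscale slice stack
#'
#' The canonical in-memory representation of a tomographic image series:
#' an ordered stack of 2D integer intensity matrices (0--255), together
#' with the voxel spacing in millimetres. Slices are ordered along the
#' scan axis (inferior to superior for a coronal sinus series).
#'
#' Internally the pixel data are stored as a 3D integer array with
#' dimensions `(rows, cols, slices)`; slice `k` is `x$data[, , k]`.
#' All voxel coordinates in this package are 1-based `(slice, row, col)`
#' triples, with the row index increasing downward in the image.
#'
#' @param data 3D numeric array `(rows, cols, slices)`, or a list of 2D
#'   matrices of identical dimensions, with integer intensities in
#'   `[0, 255]`.
#' @param spacing Numeric length-3 vector `(dz, dy, dx)`: slice thickness
#'   and in-plane pixel sizes, strictly positive. Default `c(1, 1, 1)`.
#' @param source_id Free-text provenance label.
#' @return An object of class `grayscale_stack`.
#' @seealso [mask_stack()], [read_stack()], [binarize()]
#' @export
grayscale_stack <- function(data, spacing = c(1, 1, 1), source_id = "") {
  data <- as_slice_array(data)
  if (any(data < 0) || any(data > 255) || any(data != round(data))) {
    abort("Stack intensities must be integers in [0, 255].")
  }
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive numbers (dz, dy, dx).")
  }
  structure(
    list(data = data, spacing = spacing, source_id = as.character(source_id)[1]),
    class = "grayscale_stack"
  )
}

#' Binary mask stack
#'
#' A binary volume aligned voxel-for-voxel with a [grayscale_stack()]:
#' the container for binarized images, the detected sinus, and the
#' lower/upper volumetric bound masks.
#'
#' @param data 3D array `(rows, cols, slices)` or list of 2D matrices,
#'   values 0/1 (logical arrays are accepted).
#' @return An object of class `mask_stack`.
#' @seealso [grayscale_stack()], [estimate_volume()]
#' @export
mask_stack <- function(data) {
  data <- as_slice_array(data)
  if (!all(data %in% c(0, 1))) {
    abort("Mask values must be 0/1.")
  }
  data <- data * 1L
  storage.mode(data) <- "integer"
  structure(list(data = data), class = "mask_stack")
}

as_slice_array <- function(data) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(data) == 0) abort("Empty slice list.")
    if (length(dims) != 1 || is.null(dims[[1]])) {
      abort("All slices must be matrices with identical dimensions.")
    }
    data <- array(unlist(data, use.names = FALSE),
      dim = c(dims[[1]], length(data))
    )
  }
  if (is.logical(data)) data <- data * 1L
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("Expected a (rows, cols, slices) array or a list of matrices.")
  }
  data
}

#' @export
print.grayscale_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<grayscale_stack> %d slices of %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
    d[3], d[1], d[2], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  intensity range [%d, %d]%s\n",
    min(x$data), max(x$data),
    if (nzchar(x$source_id)) paste0("  source: ", x$source_id) else ""
  ))
  invisible(x)
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mask_stack> %d slices of %d x %d, %d foreground voxels\n",
    d[3], d[1], d[2], sum(x$data)
  ))
  invisible(x)
}

#' @export
dim.grayscale_stack <- function(x) dim(x$data)

#' @export
dim.mask_stack <- function(x) dim(x$data)

#' Number of slices in a stack
#' @param x A [grayscale_stack()] or [mask_stack()].
#' @return Integer slice count.
#' @export
n_slices <- function(x) dim(x)[3]

#' Extract one slice as a matrix
#' @param x A [grayscale_stack()] or [mask_stack()].
#' @param i Slice index (1-based).
#' @return The slice as a 2D matrix.
#' @export
get_slice <- function(x, i) {
  d <- dim(x)
  if (i < 1 || i > d[3]) abort(sprintf("Slice index %d out of range [1, %d].", i, d[3]))
  x$data[, , i]
}

#' Seed voxel inside the sinus
#'
#' The starting voxel for segmentation: a `(slice, row, col)` triple
#' (1-based) asserted by the operator to lie inside the target cavity.
#' It must be foreground after binarization, which guards against a
#' mistaken threshold or polarity.
#'
#' @param slice,row,col 1-based integer indices.
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(slice, row, col) {
  v <- c(slice = slice, row = row, col = col)
  if (any(v != round(v)) || any(v < 1)) {
    abort("Seed indices must be positive integers.")
  }
  structure(as.integer(v), names = names(v), class = "seed_point")
}

#' @export
print.seed_point <- function(x, ...) {
  cat(sprintf("<seed_point> slice %d, row %d, col %d\n", x[1], x[2], x[3]))
  invisible(x)
}

check_seed_in_bounds <- function(seed, dims) {
  if (seed[1] > dims[3] || seed[2] > dims[1] || seed[3] > dims[2]) {
    abort(sprintf(
      "Seed (slice %d, row %d, col %d) outside stack of %d slices x %d x %d.",
      seed[1], seed[2], seed[3], dims[3], dims[1], dims[2]
    ))
  }
  invisible(seed)
}

as_mask_array <- function(x, arg = "mask") {
  if (inherits(x, "mask_stack")) {
    return(x$data)
  }
  if (is.logical(x)) x <- x * 1L
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (is.array(x) && length(dim(x)) == 3 && all(x %in% c(0, 1))) {
    x <- x * 1L
    storage.mode(x) <- "integer"
    return(x)
  }
  abort(sprintf("`%s` must be a mask_stack or a binary array/matrix.", arg))
}
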