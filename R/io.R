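#' Read a grayscale slice stack from disk
#'
#' Reads either a directory of 8-bit grayscale image files (PNG or TIFF,
#' one file per slice, natural-sorted by filename into slice order) or a
#' single NIfTI volume. Intensities already in `[0, 255]` pass through
#' unchanged; wider-range volumes must be windowed first (see
#' [rescale_to_8bit()]), which `window_center`/`window_width` apply
#' per slice on read.
#'
#' @param path Directory of image files, or a NIfTI file.
#' @param format `"image_directory"` or `"nifti"`.
#' @param spacing `(dz, dy, dx)` voxel spacing in millimetres; for NIfTI
#'   input the default is taken from the header, for image directories it
#'   defaults to `c(1, 1, 1)`.
#' @param window_center,window_width Optional linear window applied to
#'   raw values before conversion to 0--255 (required if the data exceed
#'   that range).
#' @return A [grayscale_stack()].
#' @export
read_stack <- function(path, format = c("image_directory", "nifti"),
                       spacing = NULL, window_center = NULL,
                       window_width = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Path does not exist: %s", path))
  if (format == "image_directory") {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    if (length(files) == 0) abort(sprintf("No PNG/TIFF files under %s", path))
    files <- files[natural_order(files)]
    slices <- lapply(file.path(path, files), read_gray_image)
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1) abort("Slices have mixed dimensions.")
    raw <- array(unlist(slices, use.names = FALSE),
      dim = c(dims[[1]], length(slices))
    )
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    src <- path
  } else {
    img <- RNifti::readNifti(path)
    raw <- as.array(img)
    if (length(dim(raw)) != 3) abort("Expected a 3D NIfTI volume.")
    # NIfTI stores (x, y, z); present as (row, col, slice)
    pix <- RNifti::pixdim(img)
    if (is.null(spacing)) spacing <- rev(pix[1:3])
    src <- path
  }
  if (!is.null(window_center) || !is.null(window_width)) {
    if (is.null(window_center) || is.null(window_width)) {
      abort("Supply both `window_center` and `window_width`, or neither.")
    }
    raw <- array(
      rescale_to_8bit(matrix(raw, nrow = dim(raw)[1]), window_center, window_width),
      dim = dim(raw)
    )
  }
  if (any(raw < 0) || any(raw > 255)) {
    abort("Intensities outside [0, 255]; supply window_center/window_width.")
  }
  grayscale_stack(round(raw), spacing = spacing, source_id = src)
}

# natural sort: compare embedded integer runs numerically so that
# slice_2 < slice_10
natural_order <- function(x) {
  keys <- regmatches(x, regexpr("[0-9]+", x))
  has_num <- grepl("[0-9]+", x)
  num <- rep(Inf, length(x))
  num[has_num] <- as.numeric(keys)
  order(num, x)
}

read_gray_image <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f)
  } else {
    tiff::readTIFF(f)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 2 &&
      !(all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3]))) {
      abort(sprintf("Not a grayscale image: %s", f))
    }
    img <- img[, , 1]
  }
  round(img * 255)
}

#' Window a raw slice to 8-bit
#'
#' Linear map of `[center - width/2, center + width/2]` onto `[0, 255]`,
#' clamped outside and rounded half-up. Needed when source volumes carry
#' a wider dynamic range than the 0--255 representation the segmentation
#' operates on.
#'
#' @param raw Numeric matrix (or vector) of raw values.
#' @param window_center,window_width Window parameters; `window_width > 0`.
#' @return Integer matrix/vector in `[0, 255]`.
#' @examples
#' rescale_to_8bit(matrix(c(-255, 0, 255), 1), 0, 510)
#' @export
rescale_to_8bit <- function(raw, window_center, window_width) {
  if (!is.numeric(window_width) || window_width <= 0) {
    abort("`window_width` must be positive.")
  }
  lo <- window_center - window_width / 2
  x <- (raw - lo) / window_width * 255
  x <- pmin(pmax(x, 0), 255)
  out <- round_half_up(x, 0)
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask stack to disk
#'
#' Persists a mask either as a directory of per-slice PNG files (0/255,
#' named `slice_0001.png`, ...) or as a single NIfTI volume. Both formats
#' round-trip losslessly through [read_mask()].
#'
#' @param mask A [mask_stack()] (or binary array).
#' @param path Output directory (`image_directory`) or file (`nifti`).
#' @param format `"image_directory"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("image_directory", "nifti")) {
  format <- match.arg(format)
  m <- as_mask_array(mask)
  if (format == "image_directory") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(dim(m)[3])) {
      png::writePNG(
        m[, , k] * 1.0, # 0/1 -> black/white
        file.path(path, sprintf("slice_%04d.png", k))
      )
    }
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(RNifti::asNifti(m * 1L), path)
  }
  invisible(path)
}

#' Read a binary mask stack from disk
#'
#' Inverse of [write_mask()]; any strictly positive stored value is
#' foreground.
#'
#' @inheritParams write_mask
#' @return A [mask_stack()].
#' @export
read_mask <- function(path, format = c("image_directory", "nifti")) {
  format <- match.arg(format)
  if (format == "image_directory") {
    s <- read_stack(path, "image_directory")
    mask_stack(s$data > 0)
  } else {
    m <- as.array(RNifti::readNifti(path))
    mask_stack(m > 0)
  }
}

#' Write a grayscale stack as an image directory
#'
#' One 8-bit PNG per slice, named in slice order; the phantom generator
#' and tests use this to exercise the on-disk pipeline.
#'
#' @param stack A [grayscale_stack()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "grayscale_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(n_slices(stack))) {
    png::writePNG(
      stack$data[, , k] / 255,
      file.path(path, sprintf("slice_%04d.png", k))
    )
  }
  invisible(path)
}
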