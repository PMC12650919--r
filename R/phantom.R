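#' Specification of a synthetic cavity phantom
#'
#' Describes a grayscale stack emulating the imaging situation the
#' segmentation targets: dark (low-intensity) ellipsoidal cavities
#' embedded in a bright (high-intensity) matrix, optionally joined by
#' thin axis-aligned channels — the invisible-septum scenario — with
#' optional additive Gaussian noise. Ellipsoids are used because their
#' analytic volumes give exact oracles.
#'
#' Default intensities (cavity 30, matrix 200) mirror a radiolucent air
#' cavity inside radiopaque bone on an 8-bit scale; the noiseless gap is
#' wide enough that any threshold between them separates the classes
#' exactly.
#'
#' @param shape `(n_slices, n_rows, n_cols)`.
#' @param cavities List of cavities, each a list with `center`
#'   `(slice, row, col)`, `semi_axes` `(a_z, a_y, a_x)` in voxels, and
#'   optional `intensity` (default 30). The first cavity is the primary
#'   (seeded) one.
#' @param channels List of channels, each a list with `from`, `to`
#'   (cavity indices), `width` (cross-section side in voxels, default 1)
#'   and optional `intensity` (default: the `from` cavity's intensity).
#'   Endpoints must share coordinates on the two non-connecting axes.
#' @param matrix_intensity Background matrix intensity (default 200).
#' @param noise_sd SD of additive Gaussian noise, rounded and clamped to
#'   `[0, 255]` (default 0).
#' @param shrink_factor Per-axis multiplier (scalar or length 3) applied
#'   to the primary cavity in the "post" member of a pre/post pair;
#'   in (0, 1].
#' @param rng_seed Integer seed for the noise; `NULL` leaves the RNG
#'   stream untouched.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, cavities, channels = list(),
                         matrix_intensity = 200, noise_sd = 0,
                         shrink_factor = 1, rng_seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    abort("`shape` must be (n_slices, n_rows, n_cols).")
  }
  if (length(cavities) < 1) abort("At least one cavity is required.")
  cavities <- lapply(cavities, function(cv) {
    cv$intensity <- cv$intensity %||% 30
    if (length(cv$center) != 3 || length(cv$semi_axes) != 3) {
      abort("Each cavity needs `center` and `semi_axes` of length 3.")
    }
    if (any(cv$center < 1) || any(cv$center > shape)) {
      abort("Cavity centre outside the stack.")
    }
    if (cv$intensity < 0 || cv$intensity > 255) abort("Intensity outside [0, 255].")
    cv
  })
  channels <- lapply(channels, function(ch) {
    ch$width <- ch$width %||% 1L
    if (is.null(ch$from) || is.null(ch$to)) abort("Channel needs `from` and `to`.")
    ch
  })
  if (matrix_intensity < 0 || matrix_intensity > 255) {
    abort("`matrix_intensity` outside [0, 255].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  shrink_factor <- as.numeric(shrink_factor)
  if (!length(shrink_factor) %in% c(1L, 3L) ||
    any(shrink_factor <= 0) || any(shrink_factor > 1)) {
    abort("`shrink_factor` must be in (0, 1] (scalar or length 3).")
  }
  structure(
    list(
      shape = shape, cavities = cavities, channels = channels,
      matrix_intensity = matrix_intensity, noise_sd = noise_sd,
      shrink_factor = shrink_factor, rng_seed = rng_seed
    ),
    class = "phantom_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binary (rows, cols, slices) array of lattice points inside the ellipsoid
ellipsoid_mask <- function(shape, center, semi_axes) {
  # shape/center are (slice, row, col); array is (row, col, slice)
  z <- (seq_len(shape[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(shape[2]) - center[2]) / semi_axes[2]
  x <- (seq_len(shape[3]) - center[3]) / semi_axes[3]
  d2 <- outer(outer(y^2, x^2, `+`), z^2, `+`)
  (d2 <= 1) * 1L
}

channel_mask <- function(shape, cavities, ch) {
  a <- cavities[[ch$from]]
  b <- cavities[[ch$to]]
  diff <- abs(a$center - b$center)
  axis <- which.max(diff)
  if (sum(diff > 0) != 1) {
    abort("Channel endpoints must differ along exactly one axis.")
  }
  w <- as.integer(ch$width)
  lo <- min(a$center[axis], b$center[axis])
  hi <- max(a$center[axis], b$center[axis])
  rng <- vector("list", 3)
  for (ax in 1:3) {
    if (ax == axis) {
      rng[[ax]] <- lo:hi
    } else {
      c0 <- a$center[ax]
      off <- seq_len(w) - 1L - (w - 1L) %/% 2L
      rng[[ax]] <- pmin(pmax(c0 + off, 1L), shape[ax])
    }
  }
  m <- array(0L, dim = c(shape[2], shape[3], shape[1]))
  m[rng[[2]], rng[[3]], rng[[1]]] <- 1L
  m
}

#' Generate a synthetic cavity phantom
#'
#' Renders a [phantom_spec()] into a grayscale stack plus ground truth:
#' channel voxels get the channel intensity, cavity voxels override
#' channels, everything else is matrix; independent rounded Gaussian
#' noise is then added and clamped to `[0, 255]`. The same spec and seed
#' always produce the identical stack.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_result`: `stack`
#'   (a [grayscale_stack()]), `truth` (primary-cavity [mask_stack()]),
#'   `truth_all` (all cavities and channels), `analytic_volume`
#'   (continuous ellipsoid volume of the primary cavity, in voxel
#'   units), `voxel_count` (exact foreground count of `truth`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  dims <- c(shape[2], shape[3], shape[1]) # (row, col, slice)
  img <- array(spec$matrix_intensity, dim = dims)
  truth_all <- array(0L, dim = dims)
  for (ch in spec$channels) {
    m <- channel_mask(shape, spec$cavities, ch)
    intensity <- ch$intensity %||% spec$cavities[[ch$from]]$intensity
    img[m == 1L] <- intensity
    truth_all <- truth_all | m
  }
  truth <- NULL
  for (i in seq_along(spec$cavities)) {
    cv <- spec$cavities[[i]]
    m <- ellipsoid_mask(shape, cv$center, cv$semi_axes)
    img[m == 1L] <- cv$intensity
    truth_all <- truth_all | m
    if (i == 1L) truth <- m
  }
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(
      spec$rng_seed,
      round(rnorm(length(img), 0, spec$noise_sd))
    )
    img <- img + noise
    img <- pmin(pmax(img, 0), 255)
    dim(img) <- dims
  }
  structure(
    list(
      stack = grayscale_stack(img, source_id = "synthetic phantom"),
      truth = mask_stack(truth),
      truth_all = mask_stack(truth_all * 1L),
      analytic_volume = 4 / 3 * pi * prod(spec$cavities[[1]]$semi_axes),
      voxel_count = sum(truth),
      spec = spec
    ),
    class = "phantom_result"
  )
}

#' @export
print.phantom_result <- function(x, ...) {
  d <- dim(x$stack$data)
  cat(sprintf(
    "<phantom_result> %d x %d x %d slices; primary cavity %d voxels (analytic %.1f)\n",
    d[1], d[2], d[3], x$voxel_count, x$analytic_volume
  ))
  invisible(x)
}

#' Generate a matched pre/post phantom pair
#'
#' Emulates the paired surgical design: the "post" phantom is identical
#' to the "pre" phantom except that the primary cavity's semi-axes are
#' scaled by `shrink_factor`. For isotropic scaling by `f` the
#' continuous relative volume change is `1 - f^3`; scaling a single axis
#' by `f` gives `1 - f` (ellipsoid volume is linear in each semi-axis).
#'
#' @param spec A [phantom_spec()] with `shrink_factor` set.
#' @return A list with `pre`, `post` ([generate_phantom()] results),
#'   `true_rel_change_continuous` and `true_rel_change_voxel` (from the
#'   exact ground-truth voxel counts).
#' @export
generate_pre_post_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- rep(spec$shrink_factor, length.out = 3)
  post_spec <- spec
  post_spec$cavities[[1]]$semi_axes <- spec$cavities[[1]]$semi_axes * f
  pre <- generate_phantom(spec)
  post <- generate_phantom(post_spec)
  list(
    pre = pre, post = post,
    true_rel_change_continuous = 1 - prod(f),
    true_rel_change_voxel = 1 - post$voxel_count / pre$voxel_count
  )
}
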