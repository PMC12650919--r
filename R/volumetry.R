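#' Lower volumetric bound mask of a slice
#'
#' Removes all boundary pixels: a pixel survives iff it and its four
#' orthogonal neighbours are all foreground (the five-term neighbourhood
#' sum equals 5). Out-of-bounds neighbours count as background, so
#' image-edge pixels never survive. Under the assumption that detection
#' errors occur only at the boundary, the surviving voxels certainly
#' belong to the cavity.
#'
#' @param mask Binary 2D matrix.
#' @return Binary matrix, subset of `mask`.
#' @export
lower_bound_mask <- function(mask) {
  mask <- check_binary_matrix(mask)
  erode4(mask)
}

#' Upper volumetric bound mask of a slice
#'
#' Adds the non-detected pixels contiguous to the boundary: a pixel is
#' set iff its five-term neighbourhood sum (itself plus four orthogonal
#' neighbours) is at least 1, extending the detected region by one
#' layer. Every cavity voxel the detection might have missed at the
#' boundary is certainly inside this mask.
#'
#' @param mask Binary 2D matrix.
#' @return Binary matrix, superset of `mask`.
#' @export
upper_bound_mask <- function(mask) {
  mask <- check_binary_matrix(mask)
  dilate4(mask)
}

#' Interval volume estimate of a mask stack
#'
#' Applies the lower and upper bound masks slice by slice, counts voxels,
#' and converts counts to volumes under the cubic-voxel model: each voxel
#' contributes `voxel_side^3`. The reported volume is the midpoint of the
#' `[lower, upper]` interval and the error its half-width, so
#' `v_mid - v_err <= true volume <= v_mid + v_err` whenever detection
#' errors are confined to the boundary.
#'
#' With `spacing` supplied, an anisotropic voxel volume
#' `dz * dy * dx` replaces `voxel_side^3`.
#'
#' @param mask A [mask_stack()] (or binary array) — the detected region.
#' @param voxel_side Cubic voxel edge length `L` (> 0). Default 1.
#' @param unit Unit label for reporting; purely descriptive. Default
#'   `"mm^3"`.
#' @param spacing Optional `(dz, dy, dx)` for anisotropic voxels.
#' @return An object of class `volume_estimate` with voxel counts
#'   (`n_lower`, `n_detected`, `n_upper`) and volumes (`v_lower`,
#'   `v_mid`, `v_upper`, `v_err`).
#' @examples
#' m <- matrix(0L, 5, 5)
#' m[2:4, 2:4] <- 1L
#' estimate_volume(mask_stack(m)) # 1 <= 9 <= 21 voxels, v = 11 +/- 10
#' @export
estimate_volume <- function(mask, voxel_side = 1, unit = "mm^3",
                            spacing = NULL) {
  m <- as_mask_array(mask)
  if (!is.numeric(voxel_side) || voxel_side <= 0) {
    abort("`voxel_side` must be positive.")
  }
  n_lower <- n_upper <- 0L
  for (k in seq_len(dim(m)[3])) {
    n_lower <- n_lower + sum(lower_bound_mask(m[, , k]))
    n_upper <- n_upper + sum(upper_bound_mask(m[, , k]))
  }
  n_det <- sum(m)
  vox <- if (is.null(spacing)) voxel_side^3 else prod(spacing)
  v_lower <- n_lower * vox
  v_upper <- n_upper * vox
  structure(
    list(
      n_lower = n_lower, n_detected = n_det, n_upper = n_upper,
      v_lower = v_lower, v_upper = v_upper,
      v_mid = (v_lower + v_upper) / 2,
      v_err = (v_upper - v_lower) / 2,
      voxel_side = voxel_side, unit = unit,
      anisotropic = !is.null(spacing)
    ),
    class = "volume_estimate"
  )
}

#' Lower/upper bound masks of a whole stack
#'
#' Convenience wrappers applying the per-slice bound rules to every
#' slice.
#'
#' @param mask A [mask_stack()] or binary array.
#' @return A [mask_stack()].
#' @export
lower_bound_stack <- function(mask) {
  m <- as_mask_array(mask)
  for (k in seq_len(dim(m)[3])) m[, , k] <- lower_bound_mask(m[, , k])
  mask_stack(m)
}

#' @rdname lower_bound_stack
#' @export
upper_bound_stack <- function(mask) {
  m <- as_mask_array(mask)
  for (k in seq_len(dim(m)[3])) m[, , k] <- upper_bound_mask(m[, , k])
  mask_stack(m)
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf(
    "<volume_estimate> V = %.1f +/- %.1f %s  (interval [%.1f, %.1f], L = %g)\n",
    x$v_mid, x$v_err, x$unit, x$v_lower, x$v_upper, x$voxel_side
  ))
  cat(sprintf(
    "  voxel counts: lower %d <= detected %d <= upper %d\n",
    x$n_lower, x$n_detected, x$n_upper
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.volume_estimate <- function(x, ...) {
  tibble(
    n_lower = x$n_lower, n_detected = x$n_detected, n_upper = x$n_upper,
    v_lower = x$v_lower, v_mid = x$v_mid, v_upper = x$v_upper,
    v_err = x$v_err, voxel_side = x$voxel_side, unit = x$unit
  )
}

#' Relative pre/post volume change
#'
#' For paired preoperative and postoperative volumes, the relative
#' change is `(v_pre - v_post) / v_pre`: the fraction of the original
#' cavity volume lost after surgery. `pct` renders it as a percentage
#' rounded half-up to one decimal.
#'
#' @param v_pre,v_post Numeric vectors of paired volumes; `v_pre > 0`.
#' @return A tibble with columns `v_pre`, `v_post`, `delta_rel`
#'   (fraction) and `pct` (percentage, one decimal).
#' @examples
#' relative_change(19734.1, 19521.9)$pct # 1.1
#' @export
relative_change <- function(v_pre, v_post) {
  if (length(v_pre) != length(v_post)) {
    abort("`v_pre` and `v_post` must have equal length.")
  }
  if (any(!is.finite(v_pre)) || any(v_pre <= 0)) {
    abort("All `v_pre` must be positive.")
  }
  delta <- (v_pre - v_post) / v_pre
  tibble(
    v_pre = as.numeric(v_pre), v_post = as.numeric(v_post),
    delta_rel = delta, pct = round_half_up(100 * delta, 1)
  )
}
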