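#' Binarize a grayscale slice
#'
#' Thresholds a 0--255 intensity matrix into a binary mask with the
#' global control parameter `k`. The default polarity marks pixels with
#' intensity at or above `k` as foreground; `"foreground_lt"` marks
#' pixels below `k`, which is the physically natural choice when the
#' target is an air-filled (radiolucent, dark) cavity inside bright
#' bone. The seed-must-be-foreground check downstream guards against a
#' mistaken polarity.
#'
#' @param image 2D integer matrix, intensities in `[0, 255]`.
#' @param k Threshold, integer in `[0, 255]`.
#' @param polarity `"foreground_geq"` (default) or `"foreground_lt"`.
#' @return Binary integer matrix of the same dimensions.
#' @examples
#' binarize(matrix(c(0, 128, 255, 64), 2, byrow = TRUE), k = 128)
#' @export
binarize <- function(image, k, polarity = c("foreground_geq", "foreground_lt")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > 255) {
    abort("`k` must be a single value in [0, 255].")
  }
  if (any(image < 0) || any(image > 255)) {
    abort("Intensities must lie in [0, 255].")
  }
  out <- if (polarity == "foreground_geq") image >= k else image < k
  out <- out * 1L
  storage.mode(out) <- "integer"
  out
}

#' Binarize a whole stack
#'
#' @param stack A [grayscale_stack()].
#' @inheritParams binarize
#' @return A [mask_stack()].
#' @export
binarize_stack <- function(stack, k, polarity = c("foreground_geq", "foreground_lt")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(stack, "grayscale_stack"))
  out <- array(0L, dim = dim(stack$data))
  for (i in seq_len(n_slices(stack))) {
    out[, , i] <- binarize(stack$data[, , i], k, polarity)
  }
  mask_stack(out)
}

#' Label the surfaces of a binary slice
#'
#' Partitions the foreground of one slice into "surfaces": equivalence
#' classes of pixels connected by chains at pairwise L1 distance 1,
#' i.e. 4-connected components. Labels are assigned deterministically by
#' the row-major position of each component's first pixel (scanning rows
#' top to bottom, left to right), so label 1 is always the component
#' whose first pixel comes earliest in reading order.
#'
#' @param mask Binary 2D matrix.
#' @return A list of class `surface_labeling` with elements `labels`
#'   (integer matrix, 0 = background) and `n_surfaces`.
#' @examples
#' label_surfaces(diag(2))$n_surfaces # diagonal pixels are d1 = 2 apart
#' @export
label_surfaces <- function(mask) {
  mask <- check_binary_matrix(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  # row-major index as initial label; iterated min over the plus
  # neighbourhood converges to the component-wise minimum, which is the
  # first pixel of the component in reading order
  rm_idx <- matrix(seq_len(nc * nr), nr, nc, byrow = TRUE)
  lab <- ifelse(mask == 1L, rm_idx, Inf)
  repeat {
    nb <- pmin(
      shift_mat(lab, 1L, 0L, Inf), shift_mat(lab, -1L, 0L, Inf),
      shift_mat(lab, 0L, 1L, Inf), shift_mat(lab, 0L, -1L, Inf)
    )
    new <- pmin(lab, nb)
    new[mask == 0L] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  fg <- mask == 1L
  labels <- matrix(0L, nr, nc)
  if (any(fg)) {
    roots <- sort(unique(lab[fg]))
    labels[fg] <- match(lab[fg], roots)
  }
  structure(
    list(labels = labels, n_surfaces = max(labels)),
    class = "surface_labeling"
  )
}

#' @export
print.surface_labeling <- function(x, ...) {
  cat(sprintf(
    "<surface_labeling> %d surface(s) over %d foreground pixels\n",
    x$n_surfaces, sum(x$labels > 0)
  ))
  invisible(x)
}

# Retain, within binary slice `bslice`, the pixels identified as sinus
# given reference pixels `ref` (binary matrix: retained sinus pixels of
# the adjacent plane(s), or the seed). Contiguity is in-plane L1
# distance <= 1 between a candidate pixel and a reference pixel, i.e.
# candidate support = ref dilated by one plus-step.
#
# With l = 0 this is plain Step-4 retention: whole surfaces touching the
# support. With l > 0 the erode-select-reconstruct septum procedure is
# applied instead: the slice is eroded l layers, only eroded components
# touching the support are selected, and exactly l bounded
# reconstruction passes restore the removed layers without re-growing
# through thin channels. If erosion leaves nothing to select while plain
# retention would (thin end-cap slices), retention falls back to the
# plain rule for that slice and the fallback is recorded.
retain_in_plane <- function(bslice, ref, l = 0L, window_halfwidth = NULL) {
  if (sum(ref) == 0L) {
    return(list(mask = matrix(0L, nrow(bslice), ncol(bslice)), fallback = FALSE))
  }
  support <- dilate4(ref)
  if (!is.null(window_halfwidth)) {
    support <- support & window_mask(ref, window_halfwidth)
  }
  plain <- surfaces_touching(bslice, support)
  if (l == 0L || sum(plain) == 0L) {
    return(list(mask = plain, fallback = FALSE))
  }
  seq <- erode_layers(bslice, l)
  eroded <- seq$levels[[l + 1L]]
  sel <- surfaces_touching(eroded, support)
  if (sum(sel) == 0L) {
    # erosion removed every candidate core: no septum removal here
    return(list(mask = plain, fallback = TRUE))
  }
  list(mask = reconstruct_layers(sel, seq), fallback = FALSE)
}

# whole 4-connected components of `mask` having a pixel under `support`
surfaces_touching <- function(mask, support) {
  lab <- label_surfaces(mask)$labels
  hit <- unique(lab[support > 0 & lab > 0L])
  out <- (lab %in% hit) * 1L
  dim(out) <- dim(mask)
  storage.mode(out) <- "integer"
  out
}

# bounding window of half-width w around the reference pixels
window_mask <- function(ref, w) {
  idx <- which(ref > 0, arr.ind = TRUE)
  out <- matrix(0L, nrow(ref), ncol(ref))
  r1 <- max(1L, min(idx[, 1]) - w)
  r2 <- min(nrow(ref), max(idx[, 1]) + w)
  c1 <- max(1L, min(idx[, 2]) - w)
  c2 <- min(ncol(ref), max(idx[, 2]) + w)
  out[r1:r2, c1:c2] <- 1L
  out
}

#' Propagate a seed surface across slices
#'
#' Initial sinus identification: in the seed's slice only the surface
#' containing the seed is retained; the stack is then swept outward in
#' both directions, and a surface in an adjacent plane is added iff it
#' contains a pixel at in-plane L1 distance at most 1 (same position or
#' 4-neighbour offset) from an already-retained pixel of the current
#' plane. A single outward pass; see [refine_detection()] for the
#' forward/reverse fixpoint iteration.
#'
#' @param binary_stack A [mask_stack()] (thresholded stack).
#' @param seed A [seed_point()]; must be foreground in `binary_stack`.
#' @param layers Layer-removal depth `l` for septum removal applied
#'   during the sweep (0 disables; see [remove_hidden_connections()]).
#' @param window_halfwidth Optional half-width of the in-plane window
#'   around reference pixels to which contiguity evaluation is
#'   restricted; defaults to `2 * layers + 1` when `layers > 0`.
#' @return A [mask_stack()] of retained voxels, with attribute
#'   `fallback_slices` listing slices where erosion emptied the
#'   candidate set and plain retention was used.
#' @export
propagate_seed <- function(binary_stack, seed, layers = 0L,
                           window_halfwidth = NULL) {
  b <- as_mask_array(binary_stack, "binary_stack")
  check_seed_in_bounds(seed, dim(b))
  if (b[seed[2], seed[3], seed[1]] != 1L) {
    abort(sprintf(
      "Seed (slice %d, row %d, col %d) is background after binarization.",
      seed[1], seed[2], seed[3]
    ))
  }
  layers <- as.integer(layers)
  if (layers > 0L && is.null(window_halfwidth)) {
    window_halfwidth <- 2L * layers + 1L
  }
  ns <- dim(b)[3]
  ret <- array(0L, dim = dim(b))
  fallback <- integer(0)

  seedm <- matrix(0L, dim(b)[1], dim(b)[2])
  seedm[seed[2], seed[3]] <- 1L
  r0 <- retain_in_plane(b[, , seed[1]], seedm, layers, window_halfwidth)
  if (r0$fallback) fallback <- c(fallback, seed[1])
  ret[, , seed[1]] <- r0$mask

  for (dir in c(1L, -1L)) {
    p <- seed[1] + dir
    while (p >= 1L && p <= ns) {
      r <- retain_in_plane(b[, , p], ret[, , p - dir], layers, window_halfwidth)
      if (r$fallback) fallback <- c(fallback, p)
      ret[, , p] <- r$mask
      if (sum(r$mask) == 0L) break
      p <- p + dir
    }
  }
  out <- mask_stack(ret)
  attr(out, "fallback_slices") <- sort(unique(fallback))
  out
}

#' Iterate forward and reverse sweeps to a fixpoint
#'
#' Volume refinement: newly retained pixels can make further surfaces in
#' adjacent slices contiguous (e.g. a second arm of a U-shaped cavity
#' reachable only through the far end), so full forward and reverse
#' passes over the stack are repeated, each adding any surface touching
#' the current retained set in a neighbouring plane, until a pass adds
#' no pixel. The result is monotone (never shrinks the initial set),
#' bounded by the foreground, and idempotent.
#'
#' @param binary_stack A [mask_stack()] (thresholded stack).
#' @param initial A [mask_stack()], subset of the foreground (typically
#'   the output of [propagate_seed()]).
#' @inheritParams propagate_seed
#' @param max_passes Safety bound on forward+reverse pass pairs; default
#'   `max(n_slices, 4)`. Exceeding it raises an error.
#' @return A [mask_stack()] with attribute `fallback_slices`.
#' @export
refine_detection <- function(binary_stack, initial, layers = 0L,
                             window_halfwidth = NULL, max_passes = NULL) {
  b <- as_mask_array(binary_stack, "binary_stack")
  ret <- as_mask_array(initial, "initial")
  if (!identical(dim(b), dim(ret))) abort("Stack shapes differ.")
  if (any(ret > b)) abort("`initial` must be a subset of the binary foreground.")
  layers <- as.integer(layers)
  if (layers > 0L && is.null(window_halfwidth)) {
    window_halfwidth <- 2L * layers + 1L
  }
  ns <- dim(b)[3]
  if (is.null(max_passes)) max_passes <- max(ns, 4L)
  fallback <- integer(0)
  passes <- 0L
  repeat {
    before <- sum(ret)
    for (p in c(seq_len(ns), rev(seq_len(ns)))) {
      ref <- matrix(0L, dim(b)[1], dim(b)[2])
      if (p > 1L) ref <- ref | ret[, , p - 1L]
      if (p < ns) ref <- ref | ret[, , p + 1L]
      ref <- ref * 1L
      if (sum(ref) == 0L) next
      r <- retain_in_plane(b[, , p], ref, layers, window_halfwidth)
      if (r$fallback) fallback <- c(fallback, p)
      grown <- (ret[, , p] | r$mask) * 1L
      ret[, , p] <- grown
    }
    passes <- passes + 1L
    if (sum(ret) == before) break
    if (passes >= max_passes) {
      abort(sprintf("Refinement did not stabilise within %d passes.", max_passes))
    }
  }
  out <- mask_stack(ret)
  attr(out, "fallback_slices") <- sort(unique(fallback))
  out
}

#' Segment the sinus from a grayscale stack
#'
#' The full detection pipeline: binarize every slice with threshold `k`,
#' retain the seed's surface, propagate it across planes with optional
#' per-plane septum removal (`layers > 0`), and iterate forward/reverse
#' refinement to a fixpoint.
#'
#' @param stack A [grayscale_stack()].
#' @param seed A [seed_point()] inside the cavity.
#' @param k Binarization threshold (0--255).
#' @inheritParams binarize
#' @inheritParams propagate_seed
#' @param max_passes See [refine_detection()].
#' @return An object of class `sinus_segmentation`: list with `mask`
#'   (a [mask_stack()]), `params`, `n_voxels`, `fallback_slices`.
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   shape = c(12, 24, 24),
#'   cavities = list(list(center = c(6, 12, 12), semi_axes = c(4, 7, 7)))
#' ))
#' seg <- segment_sinus(ph$stack, seed_point(6, 12, 12),
#'   k = 100, polarity = "foreground_lt"
#' )
#' seg$n_voxels == ph$voxel_count
#' @export
segment_sinus <- function(stack, seed, k,
                          polarity = c("foreground_geq", "foreground_lt"),
                          layers = 0L, window_halfwidth = NULL,
                          max_passes = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(stack, "grayscale_stack"))
  b <- binarize_stack(stack, k, polarity)
  if (b$data[seed[2], seed[3], seed[1]] != 1L) {
    abort(sprintf(
      paste0(
        "Seed voxel (slice %d, row %d, col %d) has intensity %d, which is ",
        "background for k = %s with polarity '%s'."
      ),
      seed[1], seed[2], seed[3], stack$data[seed[2], seed[3], seed[1]],
      format(k), polarity
    ))
  }
  init <- propagate_seed(b, seed, layers, window_halfwidth)
  final <- refine_detection(b, init, layers, window_halfwidth, max_passes)
  structure(
    list(
      mask = final,
      params = list(
        k = k, polarity = polarity, layers = as.integer(layers),
        window_halfwidth = window_halfwidth,
        seed = as.integer(seed), spacing = stack$spacing
      ),
      n_voxels = sum(final$data),
      fallback_slices = sort(unique(c(
        attr(init, "fallback_slices"), attr(final, "fallback_slices")
      )))
    ),
    class = "sinus_segmentation"
  )
}

#' @export
print.sinus_segmentation <- function(x, ...) {
  cat(sprintf(
    "<sinus_segmentation> %d voxels (k = %s, polarity = %s, layers = %d)\n",
    x$n_voxels, format(x$params$k), x$params$polarity, x$params$layers
  ))
  if (length(x$fallback_slices)) {
    cat(sprintf(
      "  septum removal fell back to plain retention in %d slice(s)\n",
      length(x$fallback_slices)
    ))
  }
  invisible(x)
}
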