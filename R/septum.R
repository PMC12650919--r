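#' Iterated layer removal of a binary slice
#'
#' Builds the nested erosion sequence used by the invisible-septum
#' procedure: level 0 is the input; each further level keeps a pixel iff
#' it and all four orthogonal neighbours are foreground at the previous
#' level (plus-shaped structuring element; out-of-bounds neighbours are
#' background, so image-edge pixels are always removed). Level `m` has
#' the `m` outermost pixel layers of every surface removed; a channel of
#' width at most `l` vanishes entirely by level `l`.
#'
#' @param mask Binary 2D matrix.
#' @param l Number of layers to remove (non-negative integer).
#' @return An object of class `erosion_sequence`: list with `levels`
#'   (list of `l + 1` nested binary matrices) and `l`.
#' @examples
#' erode_layers(matrix(1, 3, 3), 1)$levels[[2]] # only the centre survives
#' @export
erode_layers <- function(mask, l) {
  mask <- check_binary_matrix(mask)
  if (!is.numeric(l) || length(l) != 1 || l < 0 || l != round(l)) {
    abort("`l` must be a non-negative integer.")
  }
  l <- as.integer(l)
  levels <- vector("list", l + 1L)
  levels[[1L]] <- mask
  if (l > 0L) {
    for (m in seq_len(l)) {
      levels[[m + 1L]] <- erode4(levels[[m]])
    }
  }
  structure(list(levels = levels, l = l), class = "erosion_sequence")
}

#' @export
print.erosion_sequence <- function(x, ...) {
  cat(sprintf(
    "<erosion_sequence> l = %d; foreground per level: %s\n",
    x$l, paste(vapply(x$levels, sum, 0L), collapse = " > ")
  ))
  invisible(x)
}

#' Select the eroded components belonging to the sinus
#'
#' Keeps exactly the 4-connected components of the eroded slice that
#' contain, or lie at in-plane L1 distance 1 from, a reference pixel
#' (the seed, or the sinus pixels already identified in an adjacent
#' plane).
#'
#' @param eroded Binary 2D matrix (a level of an [erode_layers()]
#'   sequence).
#' @param reference_pixels Either a binary matrix of the same shape or
#'   an `n x 2` matrix of (row, col) coordinates; must be non-empty.
#' @return Binary matrix: the selected components.
#' @export
select_seed_component <- function(eroded, reference_pixels) {
  eroded <- check_binary_matrix(eroded, "eroded")
  ref <- as_reference_mask(reference_pixels, dim(eroded))
  if (sum(ref) == 0L) abort("`reference_pixels` is empty.")
  surfaces_touching(eroded, dilate4(ref))
}

as_reference_mask <- function(ref, dims) {
  if (is.matrix(ref) && ncol(ref) == 2 && !all(dim(ref) == dims)) {
    m <- matrix(0L, dims[1], dims[2])
    m[ref] <- 1L
    return(m)
  }
  check_binary_matrix(ref, "reference_pixels")
}

#' Rebuild the removed layers around a selected component
#'
#' Runs exactly `l` bounded reconstruction passes (one per removed
#' layer): in each pass every current boundary pixel — a foreground
#' pixel with fewer than four foreground orthogonal neighbours — adds
#' its orthogonal neighbours that are foreground in the original
#' (level-0) mask. Because the pass count equals the erosion depth, the
#' selected surface regains its removed layers but cannot re-grow
#' through a thin channel into the discarded cavity; unbounded geodesic
#' reconstruction would.
#'
#' @param selected Binary matrix, subset of the deepest level of
#'   `sequence`.
#' @param sequence An [erode_layers()] result.
#' @return Binary matrix `out` with `selected`, a subset of `out`, a
#'   subset of the original mask.
#' @export
reconstruct_layers <- function(selected, sequence) {
  stopifnot(inherits(sequence, "erosion_sequence"))
  selected <- check_binary_matrix(selected, "selected")
  deepest <- sequence$levels[[sequence$l + 1L]]
  if (any(selected > deepest)) {
    abort("`selected` must be a subset of the deepest erosion level.")
  }
  original <- sequence$levels[[1L]]
  cur <- selected
  for (m in seq_len(sequence$l)) {
    # interior pixels' orthogonal neighbours are already foreground, so
    # one constrained dilation step adds exactly the boundary pixels'
    # missing neighbours present in the original mask
    cur <- ((cur | (dilate4(cur) & original)) * 1L)
    storage.mode(cur) <- "integer"
  }
  cur
}

#' Sever invisible septa in one slice
#'
#' The composed erode-select-reconstruct procedure: remove the `l`
#' outermost layers of every surface (which disconnects cavities joined
#' only by a channel of width at most `l`), keep the components
#' associated with the reference pixels, then restore exactly the `l`
#' removed layers bounded by the original mask. Contiguity evaluation is
#' restricted to a window of half-width `window_halfwidth` around the
#' reference pixels. If erosion leaves no component to select (the
#' surface is thinner than `l` everywhere), the slice is returned
#' unprocessed with a warning.
#'
#' @param mask Binary 2D matrix (one binarized slice).
#' @param reference_pixels As in [select_seed_component()].
#' @param l Layer-removal depth; default 2.
#' @param window_halfwidth Window half-width in pixels; default
#'   `2 * l + 1`.
#' @return Binary matrix with spurious connections removed.
#' @examples
#' fx <- two_blob_fixture() # two blobs joined by a 1-px channel
#' out <- remove_hidden_connections(fx$mask, fx$reference, l = 2)
#' sum(out & fx$blob_b) # far blob fully removed
#' @export
remove_hidden_connections <- function(mask, reference_pixels, l = 2L,
                                      window_halfwidth = 2L * l + 1L) {
  mask <- check_binary_matrix(mask)
  ref <- as_reference_mask(reference_pixels, dim(mask))
  if (sum(ref) == 0L) abort("`reference_pixels` is empty.")
  if (l == 0L) {
    return(surfaces_touching(mask, dilate4(ref)))
  }
  support <- dilate4(ref) & window_mask(ref, window_halfwidth)
  seq <- erode_layers(mask, l)
  sel <- surfaces_touching(seq$levels[[l + 1L]], support)
  if (sum(sel) == 0L) {
    warn(sprintf(
      "Erosion depth l = %d removed every candidate surface; returning the slice unprocessed.",
      l
    ))
    return(mask)
  }
  reconstruct_layers(sel, seq)
}

#' Two-cavity test fixture with a thin connecting channel
#'
#' Builds the canonical worked example for the septum procedure: two
#' solid square blobs joined by a 1-pixel-wide channel, plus the
#' reference pixel set (the centre of blob A). Used in examples and
#' tests; erosion at `l = 2` separates the blobs and bounded
#' reconstruction restores blob A without the channel or blob B.
#'
#' @param blob_size Side of each square blob (default 7).
#' @param channel_length Length of the connecting channel (default 5).
#' @param channel_width Channel width in pixels (default 1).
#' @return List with `mask`, `reference` (coordinates of blob A's
#'   centre), `blob_a`, `blob_b`, `channel` (binary matrices).
#' @export
two_blob_fixture <- function(blob_size = 7L, channel_length = 5L,
                             channel_width = 1L) {
  pad <- 2L
  nr <- blob_size + 2L * pad
  nc <- 2L * blob_size + channel_length + 2L * pad
  blob_a <- blob_b <- channel <- matrix(0L, nr, nc)
  rows <- pad + seq_len(blob_size)
  blob_a[rows, pad + seq_len(blob_size)] <- 1L
  blob_b[rows, pad + blob_size + channel_length + seq_len(blob_size)] <- 1L
  mid <- pad + (blob_size + 1L) %/% 2L
  ch_rows <- mid + seq_len(channel_width) - 1L - (channel_width %/% 2L)
  channel[ch_rows, pad + blob_size + seq_len(channel_length)] <- 1L
  mask <- ((blob_a | blob_b | channel) * 1L)
  storage.mode(mask) <- "integer"
  list(
    mask = mask,
    reference = cbind(row = mid, col = pad + (blob_size + 1L) %/% 2L),
    blob_a = blob_a, blob_b = blob_b, channel = channel
  )
}
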