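# Shifted-matrix morphology helpers. All in-plane operations use the
# 4-neighbourhood (orthogonal neighbours, L1 distance 1); out-of-bounds
# neighbours count as `fill`.

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# number of foreground orthogonal neighbours of each pixel
nb4_sum <- function(m) {
  shift_mat(m, 1L, 0L) + shift_mat(m, -1L, 0L) +
    shift_mat(m, 0L, 1L) + shift_mat(m, 0L, -1L)
}

# one-step dilation with the plus-shaped structuring element
dilate4 <- function(m) {
  out <- (m + nb4_sum(m)) > 0
  storage.mode(out) <- "integer"
  out
}

# one-step erosion: pixel kept iff it and all four orthogonal neighbours
# are foreground (edge pixels are always removed)
erode4 <- function(m) {
  out <- (m + nb4_sum(m)) == 5
  storage.mode(out) <- "integer"
  out
}

check_binary_matrix <- function(m, arg = "mask") {
  if (!is.matrix(m)) {
    abort(sprintf("`%s` must be a matrix.", arg))
  }
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (values 0/1).", arg))
  }
  m <- m * 1L
  storage.mode(m) <- "integer"
  m
}

# round-half-up, the convention used for printed percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}
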