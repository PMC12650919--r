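# Independent brute-force oracles. These deliberately use explicit
# per-pixel loops and breadth-first traversal, sharing no code with the
# package's vectorised implementations.

# 4-connected component labelling by BFS, components numbered by first
# pixel in row-major scan order
oracle_label <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] == 1L && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(queue) > 0) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] == 1L && lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- nxt
              queue <- c(queue, list(q))
            }
          }
        }
      }
    }
  }
  lab
}

# 3D flood fill from a seed under the stack contiguity rule: in-plane
# 4-neighbours, plus same-position or 4-neighbour offsets in adjacent
# slices. `arr` is a (row, col, slice) binary array; seed is
# (slice, row, col).
oracle_flood3d <- function(arr, seed) {
  d <- dim(arr)
  vis <- array(FALSE, dim = d)
  if (arr[seed[2], seed[3], seed[1]] != 1L) {
    return(vis * 1L)
  }
  offsets <- list(
    c(0L, -1L, 0L), c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L),
    c(-1L, 0L, 0L), c(-1L, -1L, 0L), c(-1L, 1L, 0L), c(-1L, 0L, -1L), c(-1L, 0L, 1L),
    c(1L, 0L, 0L), c(1L, -1L, 0L), c(1L, 1L, 0L), c(1L, 0L, -1L), c(1L, 0L, 1L)
  ) # (dslice, drow, dcol)
  queue <- list(c(seed[1], seed[2], seed[3]))
  vis[seed[2], seed[3], seed[1]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (o in offsets) {
      q <- p + o
      if (q[1] >= 1 && q[1] <= d[3] && q[2] >= 1 && q[2] <= d[1] &&
        q[3] >= 1 && q[3] <= d[2] &&
        arr[q[2], q[3], q[1]] == 1L && !vis[q[2], q[3], q[1]]) {
        vis[q[2], q[3], q[1]] <- TRUE
        queue <- c(queue, list(q))
      }
    }
  }
  vis * 1L
}

# per-pixel five-term neighbourhood sum rules
oracle_nbsum5 <- function(mask, i, j) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  at <- function(r, c) if (r >= 1 && r <= nr && c >= 1 && c <= nc) mask[r, c] else 0L
  at(i, j) + at(i - 1, j) + at(i + 1, j) + at(i, j - 1) + at(i, j + 1)
}

oracle_erode <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == 1L && oracle_nbsum5(mask, i, j) == 5L) out[i, j] <- 1L
    }
  }
  out
}

oracle_lower <- oracle_erode

oracle_upper <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (oracle_nbsum5(mask, i, j) >= 1L) out[i, j] <- 1L
    }
  }
  out
}

# l constrained (geodesic) dilation steps of `selected` inside `original`
oracle_reconstruct <- function(selected, original, l) {
  cur <- selected
  if (l == 0) {
    return(cur)
  }
  for (step in seq_len(l)) {
    add <- matrix(0L, nrow(cur), ncol(cur))
    for (i in seq_len(nrow(cur))) {
      for (j in seq_len(ncol(cur))) {
        if (cur[i, j] == 1L && oracle_nbsum5(cur, i, j) < 5L) {
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            r <- i + d[1]
            c <- j + d[2]
            if (r >= 1 && r <= nrow(cur) && c >= 1 && c <= ncol(cur) &&
              original[r, c] == 1L) {
              add[r, c] <- 1L
            }
          }
        }
      }
    }
    cur <- pmax(cur, add)
  }
  cur
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

# voxelised sphere as a (row, col, slice) array by exhaustive lattice scan
oracle_sphere_array <- function(dims, center, r) {
  # dims/center in (slice, row, col)
  out <- array(0L, dim = c(dims[2], dims[3], dims[1]))
  for (z in seq_len(dims[1])) {
    for (y in seq_len(dims[2])) {
      for (x in seq_len(dims[3])) {
        if ((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2 <= r^2) {
          out[y, x, z] <- 1L
        }
      }
    }
  }
  out
}

# half-up rounding used to compare against printed one-decimal values
round_half_up_test <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# voxelised ellipsoid as a (row, col, slice) array by exhaustive scan;
# shape/center/semi in (slice, row, col) order
oracle_ellipsoid_array <- function(shape, center, semi) {
  out <- array(0L, dim = c(shape[2], shape[3], shape[1]))
  for (z in seq_len(shape[1])) {
    for (y in seq_len(shape[2])) {
      for (x in seq_len(shape[3])) {
        if (((z - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
          ((x - center[3]) / semi[3])^2 <= 1) {
          out[y, x, z] <- 1L
        }
      }
    }
  }
  out
}
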