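test_that("binarize applies the threshold rule under both polarities", {
  img <- matrix(c(0, 128, 255, 64), 2, 2, byrow = TRUE)
  expect_equal(binarize(img, 128), matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  expect_equal(binarize(img, 0), matrix(1L, 2, 2)) # vacuous threshold
  expect_equal(
    binarize(img, 128, "foreground_lt"),
    matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  )
  expect_error(binarize(img, 300), "255")
  # elementwise agreement with a scalar comparison loop
  set.seed(3)
  slice <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  for (k in c(0, 77, 255)) {
    ref <- matrix(0L, 8, 8)
    for (i in 1:8) for (j in 1:8) ref[i, j] <- as.integer(slice[i, j] >= k)
    expect_equal(binarize(slice, k), ref)
  }
})

test_that("label_surfaces partitions foreground into 4-connected components", {
  expect_equal(label_surfaces(diag(2))$n_surfaces, 2) # d1 = 2: not contiguous
  plus <- matrix(0L, 3, 3)
  plus[2, ] <- 1L
  plus[, 2] <- 1L
  expect_equal(label_surfaces(plus)$n_surfaces, 1)
  corners <- matrix(0L, 3, 3)
  corners[c(1, 3, 5, 7, 9)] <- 1L # four corners + centre
  expect_equal(label_surfaces(corners)$n_surfaces, 5)
  expect_error(label_surfaces(matrix(2, 2, 2)), "binary")
})

test_that("labels are numbered deterministically by row-major first pixel", {
  m <- matrix(0L, 4, 4)
  m[4, 1] <- 1L # first in column-major order ...
  m[1, 4] <- 1L # ... but second component starts earlier row-major
  lab <- label_surfaces(m)$labels
  expect_equal(lab[1, 4], 1L)
  expect_equal(lab[4, 1], 2L)
})

test_that("label_surfaces matches a breadth-first flood-fill oracle on random masks", {
  set.seed(42)
  for (trial in 1:200) {
    nr <- sample(1:32, 1)
    nc <- sample(1:32, 1)
    m <- random_mask(nr, nc, runif(1, 0.2, 0.8))
    expect_identical(label_surfaces(m)$labels, oracle_label(m))
  }
})

test_that("propagate_seed keeps exactly the surfaces reachable across planes", {
  # vertical cylinder: all discs retained
  disc <- matrix(0L, 9, 9)
  disc[3:7, 3:7] <- 1L
  cyl <- mask_stack(array(rep(disc, 5), dim = c(9, 9, 5)))
  out <- propagate_seed(cyl, seed_point(3, 5, 5))
  expect_identical(out$data, cyl$data)

  # two disjoint parallel cylinders: only the seeded one retained
  two <- matrix(0L, 9, 9)
  two[2:4, 2:4] <- 1L
  two[6:8, 6:8] <- 1L
  stack2 <- mask_stack(array(rep(two, 4), dim = c(9, 9, 4)))
  only <- matrix(0L, 9, 9)
  only[2:4, 2:4] <- 1L
  out2 <- propagate_seed(stack2, seed_point(2, 3, 3))
  expect_identical(out2$data, array(rep(only, 4), dim = c(9, 9, 4)))

  expect_error(propagate_seed(cyl, seed_point(1, 1, 1)), "background")
  expect_error(propagate_seed(cyl, seed_point(99, 5, 5)), "outside")
})

test_that("propagate_seed equals the 3D flood-fill oracle on a voxelised sphere", {
  sph <- oracle_sphere_array(c(13, 13, 13), c(7, 7, 7), 5)
  seed <- seed_point(7, 7, 7)
  out <- propagate_seed(mask_stack(sph), seed)
  expect_identical(out$data, oracle_flood3d(sph, seed))
  expect_identical(out$data, sph) # the sphere is one connected solid
})

test_that("refine_detection reaches the flood-fill fixpoint and is idempotent", {
  # U-shaped solid: two vertical arms joined only at the bottom slice
  ns <- 6
  slice_arms <- matrix(0L, 7, 9)
  slice_arms[3:5, 2:3] <- 1L
  slice_arms[3:5, 7:8] <- 1L
  slice_base <- matrix(0L, 7, 9)
  slice_base[3:5, 2:8] <- 1L
  u <- array(rep(slice_arms, ns), dim = c(7, 9, ns))
  u[, , 1] <- slice_base
  seed <- seed_point(ns, 4, 2) # top of one arm
  b <- mask_stack(u)
  init <- propagate_seed(b, seed)
  ref <- refine_detection(b, init)
  expect_identical(ref$data, oracle_flood3d(u, seed))
  expect_identical(ref$data, u) # both arms fully retained
  # idempotence
  expect_identical(refine_detection(b, ref)$data, ref$data)
  # already-maximal input is a fixpoint
  sph <- oracle_sphere_array(c(9, 11, 11), c(5, 6, 6), 4)
  full <- propagate_seed(mask_stack(sph), seed_point(5, 6, 6))
  expect_identical(refine_detection(mask_stack(sph), full)$data, full$data)
})

test_that("refine_detection is monotone in its initial set", {
  set.seed(9)
  arr <- array(as.integer(runif(8 * 8 * 5) < 0.55), dim = c(8, 8, 5))
  fg <- which(arr == 1L, arr.ind = TRUE)
  i <- fg[1, ]
  seed <- seed_point(i[3], i[1], i[2])
  small <- array(0L, dim = dim(arr))
  small[i[1], i[2], i[3]] <- 1L
  bigger <- propagate_seed(mask_stack(arr), seed)$data
  r_small <- refine_detection(mask_stack(arr), mask_stack(small))$data
  r_big <- refine_detection(mask_stack(arr), mask_stack(bigger))$data
  expect_true(all(r_small <= r_big))
  expect_true(all(r_big <= arr))
})

test_that("connected random stacks are fully recovered from any seed", {
  set.seed(21)
  for (trial in 1:25) {
    arr <- array(as.integer(runif(6 * 6 * 4) < 0.6), dim = c(6, 6, 4))
    fg <- which(arr == 1L, arr.ind = TRUE)
    if (nrow(fg) == 0) next
    pick <- fg[sample(nrow(fg), 1), ]
    seed <- seed_point(pick[3], pick[1], pick[2])
    expected <- oracle_flood3d(arr, seed)
    got <- refine_detection(
      mask_stack(arr),
      propagate_seed(mask_stack(arr), seed)
    )
    expect_identical(got$data, expected)
  }
})

test_that("single-slice stacks reduce to the seed's surface", {
  m <- matrix(0L, 5, 5)
  m[1:2, 1:2] <- 1L
  m[4:5, 4:5] <- 1L
  out <- propagate_seed(mask_stack(array(m, dim = c(5, 5, 1))), seed_point(1, 1, 1))
  expect_equal(sum(out$data), 4)
  expect_true(all(which(out$data == 1L) %in% which(array(m, dim = c(5, 5, 1)) == 1L)))
})
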