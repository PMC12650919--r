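test_that("erode_layers strips one boundary layer per level", {
  all3 <- matrix(1L, 3, 3)
  seq1 <- erode_layers(all3, 1)
  expect_equal(sum(seq1$levels[[2]]), 1)
  expect_equal(seq1$levels[[2]][2, 2], 1L)

  line <- matrix(0L, 5, 5)
  line[3, ] <- 1L
  expect_equal(sum(erode_layers(line, 1)$levels[[2]]), 0) # no interior

  rect <- matrix(1L, 7, 5)
  lev2 <- erode_layers(rect, 2)$levels[[3]]
  expect_equal(sum(lev2), 3) # 3 x 1 interior strip
  expect_equal(which(lev2 == 1L, arr.ind = TRUE)[, "col"], rep(3L, 3))

  expect_error(erode_layers(all3, -1), "non-negative")
})

test_that("erosion sequences are nested and match the brute-force oracle", {
  set.seed(5)
  for (trial in 1:100) {
    m <- random_mask(sample(4:32, 1), sample(4:32, 1), runif(1, 0.3, 0.9))
    l <- sample(0:3, 1)
    sq <- erode_layers(m, l)
    expect_length(sq$levels, l + 1)
    cur <- m
    for (lev in seq_len(l)) {
      cur <- oracle_erode(cur)
      expect_identical(sq$levels[[lev + 1]], cur)
      expect_true(all(sq$levels[[lev + 1]] <= sq$levels[[lev]]))
    }
  }
})

test_that("select_seed_component keeps exactly the referenced components", {
  m <- matrix(0L, 7, 12)
  m[2:4, 2:4] <- 1L # blob A
  m[2:4, 8:10] <- 1L # blob B
  only_a <- select_seed_component(m, cbind(3, 3))
  expect_equal(sum(only_a), 9)
  expect_true(all(only_a[2:4, 2:4] == 1L))
  # reference touching both blobs keeps both
  both <- select_seed_component(m, rbind(c(3, 5), c(3, 7)))
  expect_identical(both, m)
  expect_error(select_seed_component(m, matrix(0L, 7, 12)), "empty")
})

test_that("select_seed_component agrees with flood-fill-from-references on random masks", {
  set.seed(17)
  for (trial in 1:100) {
    m <- random_mask(sample(4:24, 1), sample(4:24, 1), runif(1, 0.3, 0.7))
    fg <- which(m == 1L, arr.ind = TRUE)
    if (nrow(fg) == 0) next
    refs <- fg[sample(nrow(fg), min(2, nrow(fg))), , drop = FALSE]
    got <- select_seed_component(m, refs)
    lab <- oracle_label(m)
    keep <- integer(0)
    for (r in seq_len(nrow(refs))) {
      for (d in list(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- refs[r, ] + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
          lab[q[1], q[2]] > 0) {
          keep <- union(keep, lab[q[1], q[2]])
        }
      }
    }
    expect_identical(got, (matrix(lab %in% keep, nrow(m)) * 1L))
  }
})

test_that("reconstruct_layers recovers blobs up to diamond-corner boundary pixels", {
  # a diamond (L1 ball) is exactly recovered: erosion shrinks its radius
  # by l and l constrained dilations restore it
  diamond <- matrix(0L, 13, 13)
  for (i in 1:13) {
    for (j in 1:13) {
      if (abs(i - 7) + abs(j - 7) <= 5) diamond[i, j] <- 1L
    }
  }
  sqd <- erode_layers(diamond, 2)
  expect_identical(reconstruct_layers(sqd$levels[[3]], sqd), diamond)

  # a Euclidean disc is recovered except for boundary-ring pixels at
  # in-mask L1 distance > l from the eroded core (diamond-corner
  # attrition of the plus-shaped rule); the oracle fixes the exact set
  disc <- matrix(0L, 13, 13)
  for (i in 1:13) {
    for (j in 1:13) {
      if ((i - 7)^2 + (j - 7)^2 <= 25) disc[i, j] <- 1L
    }
  }
  sq <- erode_layers(disc, 2)
  out <- reconstruct_layers(sq$levels[[3]], sq)
  expect_identical(out, oracle_reconstruct(sq$levels[[3]], disc, 2))
  expect_true(all(sq$levels[[3]] <= out) && all(out <= disc))
  # every unrecovered pixel lies on the boundary ring
  missing <- disc - out
  expect_true(all(missing <= disc - oracle_erode(disc)))

  # l = 0: identity
  sq0 <- erode_layers(disc, 0)
  expect_identical(reconstruct_layers(disc, sq0), disc)
  expect_error(
    reconstruct_layers(matrix(1L, 13, 13), sq),
    "subset"
  )
})

test_that("reconstruction matches the constrained-dilation oracle on random masks", {
  set.seed(23)
  for (trial in 1:100) {
    m <- random_mask(sample(6:32, 1), sample(6:32, 1), runif(1, 0.4, 0.9))
    l <- sample(1:3, 1)
    sq <- erode_layers(m, l)
    deep <- sq$levels[[l + 1]]
    if (sum(deep) == 0) next
    # select one component of the deepest level
    lab <- oracle_label(deep)
    sel <- (lab == 1L) * 1L
    got <- reconstruct_layers(sel, sq)
    expect_identical(got, oracle_reconstruct(sel, m, l))
    expect_true(all(sel <= got) && all(got <= m))
  }
})

test_that("the worked two-blob example severs the channel", {
  fx <- two_blob_fixture(blob_size = 7, channel_length = 5, channel_width = 1)
  out <- remove_hidden_connections(fx$mask, fx$reference, l = 2)
  # blob A is restored up to its boundary ring (diamond-corner pixels)
  interior_a <- oracle_erode(fx$blob_a)
  expect_true(all(out[interior_a == 1L] == 1L))
  expect_true(all((fx$blob_a - (out & fx$blob_a)) <= fx$blob_a - interior_a))
  expect_equal(sum(out & fx$blob_b), 0) # blob B absent
  expect_lte(sum(out & fx$channel), 2) # at most an l-pixel stub
  # and it agrees with the explicitly composed oracle
  sq <- erode_layers(fx$mask, 2)
  lab <- oracle_label(sq$levels[[3]])
  sel <- (lab == lab[fx$reference[1, 1], fx$reference[1, 2]]) * 1L
  expect_identical(out, oracle_reconstruct(sel, fx$mask, 2))
})

test_that("remove_hidden_connections preserves isolated blobs with inradius > l", {
  # diamond-convex blobs are exactly invariant
  diamond <- matrix(0L, 11, 11)
  for (i in 1:11) {
    for (j in 1:11) {
      if (abs(i - 6) + abs(j - 6) <= 4) diamond[i, j] <- 1L
    }
  }
  expect_identical(remove_hidden_connections(diamond, cbind(6, 6), l = 2), diamond)
  # rectangles keep everything except corner boundary pixels
  blob <- matrix(0L, 11, 11)
  blob[3:9, 2:10] <- 1L
  out <- remove_hidden_connections(blob, cbind(6, 6), l = 2)
  expect_true(all(out[oracle_erode(blob) == 1L] == 1L))
  expect_true(all(out <= blob))
  expect_identical(out, oracle_reconstruct(oracle_erode(oracle_erode(blob)), blob, 2))
})

test_that("over-deep erosion falls back to the unprocessed surface with a warning", {
  thin <- matrix(0L, 6, 6)
  thin[3:4, 2:5] <- 1L # inradius 1
  expect_warning(
    out <- remove_hidden_connections(thin, cbind(3, 3), l = 2),
    "unprocessed"
  )
  expect_identical(out, thin)
})

test_that("the septum property holds across random two-blob geometries", {
  set.seed(31)
  for (trial in 1:20) {
    fx <- two_blob_fixture(
      blob_size = sample(6:9, 1),
      channel_length = sample(5:8, 1),
      channel_width = sample(1:2, 1)
    )
    out <- remove_hidden_connections(fx$mask, fx$reference, l = 2)
    expect_equal(sum(out & fx$blob_b), 0)
    # blob A present up to boundary-ring attrition
    expect_true(all(out[oracle_erode(fx$blob_a) == 1L] == 1L))
    expect_true(all((fx$blob_a - (out & fx$blob_a)) <= fx$blob_a - oracle_erode(fx$blob_a)))
  }
})
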