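test_that("binarize applies the >= threshold convention", {
  m <- prob_map(array(c(0, 0.49, 0.5, 1), c(1, 2, 2)))
  bv <- binarize(m)
  expect_equal(as.vector(bv$mask), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(binarize(prob_map(array(0, c(1, 2, 2))))$mask))
  # image stacks default to 128
  st <- image_stack(array(c(0L, 127L, 128L, 255L), c(1, 2, 2)))
  expect_equal(as.vector(binarize(st)$mask), c(FALSE, FALSE, TRUE, TRUE))
  # multi-class maps binarize on the last (foreground) channel
  m2 <- prob_map(array(c(rep(0.9, 4), rep(0.1, 4)), c(1, 2, 2, 2)))
  expect_false(any(binarize(m2)$mask))
})

test_that("binarize at 0.5 on uniform noise hits the binomial band", {
  withr::local_seed(2)
  n <- 20^3
  m <- prob_map(array(runif(n), c(20, 20, 20)))
  fg <- sum(binarize(m, 0.5)$mask)
  expect_lt(abs(fg - 0.5 * n), 3 * sqrt(n * 0.25))
})

test_that("label3d separates corner-touching voxels only at connectivity 6", {
  m <- array(FALSE, c(1, 2, 2))
  m[1, 1, 1] <- TRUE
  m[1, 2, 2] <- TRUE
  expect_equal(max(label3d(m, 6)$labels), 2L)
  expect_equal(max(label3d(m, 26)$labels), 1L)
  expect_equal(max(label3d(array(FALSE, c(2, 2, 2)))$labels), 0L)
  boxes <- array(FALSE, c(4, 8, 8))
  boxes[, 1:3, 1:3] <- TRUE
  boxes[, 6:8, 6:8] <- TRUE
  expect_equal(max(label3d(boxes)$labels), 2L)
})

test_that("label3d matches the brute-force BFS oracle on random masks", {
  withr::local_seed(4)
  for (i in 1:15) {
    m <- array(runif(12^3) < runif(1, 0.2, 0.6), c(12, 12, 12))
    for (conn in c(6, 26)) {
      ours <- label3d(binary_volume(m), conn)$labels
      oracle <- bfs_label3d(m, conn)
      expect_true(labels_equivalent(ours, oracle),
                  info = sprintf("mask %d conn %d", i, conn))
    }
  }
})

test_that("watershed splits a fused two-sphere mask near the neck", {
  d <- c(24, 24, 48)
  zi <- slice.index(array(0, d), 1)
  yi <- slice.index(array(0, d), 2)
  xi <- slice.index(array(0, d), 3)
  s1 <- (zi - 12)^2 + (yi - 12)^2 + (xi - 14)^2 <= 64
  s2 <- (zi - 12)^2 + (yi - 12)^2 + (xi - 34)^2 <= 64
  neck <- abs(zi - 12) <= 1 & abs(yi - 12) <= 1 & xi >= 14 & xi <= 34
  mask <- s1 | s2 | neck
  ws <- watershed3d(binary_volume(mask), anisotropic = FALSE)
  sizes <- table(ws$labels[ws$labels > 0])
  expect_equal(length(sizes), 2L)
  expect_true(all(abs(sizes - sum(s1)) / sum(s1) < 0.2))
  # exact partition of the mask
  expect_equal(sum(ws$labels > 0), sum(mask))
})

test_that("explicit end markers split a 10-voxel bar 5/5", {
  bar <- array(FALSE, c(3, 3, 12))
  bar[2, 2, 2:11] <- TRUE
  mk <- array(0L, dim(bar))
  mk[2, 2, 2] <- 1L
  mk[2, 2, 11] <- 2L
  ws <- watershed3d(binary_volume(bar), label_volume(mk), anisotropic = FALSE)
  expect_equal(as.vector(ws$labels[2, 2, 2:11]), rep(c(1L, 2L), each = 5))
})

test_that("a single sphere floods to one region; empty mask to none", {
  sph <- digitized_sphere(16, 5) > 0
  ws <- watershed3d(binary_volume(sph), anisotropic = FALSE)
  expect_equal(max(ws$labels), 1L)
  expect_equal(sum(ws$labels > 0), sum(sph))
  expect_equal(max(watershed3d(binary_volume(array(FALSE, c(3, 3, 3))))$labels), 0L)
})

test_that("markers must lie within the mask", {
  bar <- array(FALSE, c(1, 1, 4))
  bar[1, 1, 2:3] <- TRUE
  mk <- array(0L, dim(bar))
  mk[1, 1, 1] <- 1L
  expect_error(watershed3d(binary_volume(bar), label_volume(mk)),
               "within the mask")
})

test_that("remove_small drops only sub-threshold objects, keeping ids", {
  lab <- array(0L, c(2, 5, 5))
  lab[1, 1:3, 1] <- 7L          # 3 voxels
  lab[, , 3:5] <- 9L            # 30 voxels
  lv <- label_volume(lab)
  expect_identical(remove_small(lv, 0)$labels, lv$labels)
  out <- remove_small(lv, 10)
  expect_setequal(unique(as.vector(out$labels)), c(0L, 9L))
  expect_equal(sum(out$labels == 9L), 30)
  one <- label_volume(array(c(rep(5L, 5), rep(0L, 3)), c(2, 2, 2)))
  expect_equal(max(remove_small(one, 6)$labels), 0L)
})

test_that("anisotropic distance transform weights the z axis", {
  m <- array(TRUE, c(5, 5, 5))
  m[1, , ] <- FALSE  # background plane at z = 1
  m[, , 1] <- FALSE  # background plane at x = 1
  d_iso <- distance_transform(binary_volume(m), anisotropic = FALSE)
  d_phys <- distance_transform(binary_volume(m, spacing = c(30, 6, 6)))
  expect_equal(d_iso[3, 3, 3], 2)    # both planes 2 voxels away
  expect_equal(d_phys[3, 3, 3], 12)  # x plane (2 * 6 nm) beats z (2 * 30 nm)
})

test_that("compact_labels renumbers to 1..K by first appearance", {
  lab <- array(c(0L, 7L, 300L, 7L), c(1, 2, 2))
  out <- compact_labels(label_volume(lab))
  expect_setequal(unique(as.vector(out$labels)), c(0L, 1L, 2L))
  expect_equal(out$labels[1, 2, 1], 1L)  # 7 appears first in scan order
})
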