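test_that("a constant slice is a CLAHE fixed point for any parameters", {
  st <- image_stack(array(77L, c(2, 40, 40)))
  for (slope in c(1, 1.5, 3, 100)) {
    out <- apply_clahe(st, block_size = 15, bins = 64, max_slope = slope)
    expect_identical(out$voxels, st$voxels)
  }
})

test_that("the headline defaults (127 / 256 / 1.50) are accepted", {
  gen <- gen_mitochondria(synth_spec(shape = c(1, 140, 140), n_objects = 2,
                                     seed = 8))
  out <- apply_clahe(gen$images)  # defaults: block 127, 256 bins, slope 1.5
  expect_equal(dim(out$voxels), dim(gen$images$voxels))
  expect_equal(out$dtype, "uint8")
  expect_true(all(out$voxels >= 0 & out$voxels <= 255))
})

test_that("a two-level checkerboard equalizes to the full dtype range", {
  m <- matrix(0L, 32, 32)
  cb <- array(as.integer((row(m) + col(m)) %% 2) * 60L + 60L, c(1, 32, 32))
  out <- apply_clahe(image_stack(cb), block_size = 15, bins = 256,
                     max_slope = 1e9)
  # oracle: direct per-block equalization of a two-level histogram sends the
  # low level to 0 and the high level to the dtype maximum in every block,
  # so the blended result is the same global two-level stretch
  expect_equal(sort(unique(as.vector(out$voxels))), c(0L, 255L))
  expect_equal(out$voxels == 255L, cb == 120L)
})

test_that("CLAHE validates its parameters", {
  st <- image_stack(array(0L, c(1, 30, 30)))
  expect_error(apply_clahe(st, block_size = 14), "odd")
  expect_error(apply_clahe(st, block_size = 31), "smaller")
  expect_error(apply_clahe(st, block_size = 15, max_slope = 0.5), "max_slope")
})

test_that("an empty chain is the identity and unknown names are rejected", {
  gen <- gen_mitochondria(synth_spec(shape = c(2, 48, 48), n_objects = 2,
                                     seed = 1))
  expect_identical(apply_filter_chain(gen$images, list())$voxels,
                   gen$images$voxels)
  expect_error(filter_spec("sobel"), "gaussian, median, clahe")
})

test_that("invert is an involution", {
  gen <- gen_mitochondria(synth_spec(shape = c(2, 48, 48), n_objects = 2,
                                     seed = 2))
  chain <- list(filter_spec("invert"), filter_spec("invert"))
  expect_identical(apply_filter_chain(gen$images, chain)$voxels,
                   gen$images$voxels)
})

test_that("chain application is bit-identical to sequential application", {
  gen <- gen_mitochondria(synth_spec(shape = c(2, 64, 64), n_objects = 3,
                                     seed = 3))
  chain <- list(filter_spec("gaussian", list(sigma = 1)),
                filter_spec("threshold", list(t = 128)))
  chained <- apply_filter_chain(gen$images, chain)
  step1 <- apply_filter_chain(gen$images, chain[1])
  step2 <- apply_filter_chain(step1, chain[2])
  expect_identical(chained$voxels, step2$voxels)
  # result is a binary mask whose foreground stays close to the unsmoothed one
  expect_setequal(unique(as.vector(chained$voxels)), c(0L, 255L))
  raw <- apply_filter_chain(gen$images, chain[2])
  n_raw <- sum(raw$voxels > 0)
  expect_lt(abs(sum(chained$voxels > 0) - n_raw) / n_raw, 0.15)
})

test_that("filters preserve shape and are deterministic", {
  gen <- gen_mitochondria(synth_spec(shape = c(2, 32, 32), n_objects = 1,
                                     seed = 4))
  for (spec in list(filter_spec("gaussian", list(sigma = 1.5)),
                    filter_spec("gaussian", list(sigma = 1), "3d"),
                    filter_spec("median", list(radius = 1)),
                    filter_spec("median", list(radius = 1), "3d"),
                    filter_spec("clahe", list(block_size = 15)),
                    filter_spec("threshold", list(t = 100)))) {
    a <- apply_filter_chain(gen$images, list(spec))
    b <- apply_filter_chain(gen$images, list(spec))
    expect_equal(dim(a$voxels), dim(gen$images$voxels), info = spec$name)
    expect_identical(a$voxels, b$voxels, info = spec$name)
  }
})
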