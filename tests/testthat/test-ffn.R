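test_that("ffn_config enforces its invariants", {
  expect_error(ffn_config(fov = c(8, 9, 9)), "odd")
  expect_error(ffn_config(fov = c(9, 9, 9), delta = c(4, 4, 4)), "delta")
  expect_error(ffn_config(move_threshold = 0.4), "move_threshold")
  expect_s3_class(ffn_config(fov = c(9, 9, 9), delta = c(3, 3, 3)),
                  "ffn_config")
})

test_that("fill fractions bucket into the expected partition classes", {
  # a volume that is entirely one object: every fraction is 1, top class
  solid <- label_volume(array(1L, c(11, 11, 11)))
  co <- partition_examples(solid, c(9, 9, 9), n_classes = 4)
  expect_true(all(co$fill_fraction == 1))
  expect_true(all(co$partition_class == 4L))
  # a single 1-voxel object in a 9^3 FOV: fraction 1/729, bottom class
  lone <- array(0L, c(11, 11, 11))
  lone[6, 6, 6] <- 1L
  co1 <- partition_examples(label_volume(lone), c(9, 9, 9), n_classes = 9)
  expect_equal(nrow(co1), 1)
  expect_equal(co1$fill_fraction, 1 / 729)
  expect_equal(co1$partition_class, 1L)
  # empty labels: warning + empty set
  expect_warning(
    empty <- partition_examples(label_volume(array(0L, c(9, 9, 9))),
                                c(5, 5, 5)),
    "no foreground")
  expect_equal(nrow(empty), 0)
})

test_that("partitioning balances classes up to availability", {
  fix <- gen_two_spheres(side = 32, radius = 6, seed = 4)
  co <- partition_examples(fix$labels, c(9, 9, 9), n_classes = 3, seed = 1)
  counts <- table(co$partition_class)
  expect_true(all(counts == min(counts)))
  # requesting more than available caps at availability
  co2 <- partition_examples(fix$labels, c(9, 9, 9), n_classes = 3,
                            n_per_class = 10^6, seed = 1)
  expect_gt(nrow(co2), nrow(co))
})

test_that("coordinate tables round-trip through HDF5", {
  fix <- gen_two_spheres(side = 24, radius = 5, seed = 2)
  co <- partition_examples(fix$labels, c(9, 9, 9), n_classes = 2, seed = 3)
  f <- tempfile(fileext = ".h5")
  ffn_write_coords(co, f)
  back <- ffn_read_coords(f)
  unlink(f)
  expect_equal(back$z, co$z)
  expect_equal(back$object_id, co$object_id)
  expect_equal(back$partition_class, co$partition_class)
})

test_that("a perfect prediction has near-zero logistic loss", {
  tgt <- array(rbinom(125, 1, 0.3), c(5, 5, 5))
  logits <- ifelse(tgt > 0, 20, -20)
  expect_lt(emsegkit:::ffn_logistic_loss(logits, tgt)$value, 1e-3)
})

test_that("FFN training is deterministic and drops bad coordinates", {
  fix <- gen_two_spheres(side = 24, radius = 5, seed = 7)
  cfg <- ffn_config(fov = c(7, 7, 7), delta = c(2, 2, 2), steps = 25,
                    filters = 4, seed = 3)
  co <- partition_examples(fix$labels, cfg$fov, n_classes = 2, seed = 3)
  t1 <- train_ffn(fix$images, fix$labels, co, cfg)
  t2 <- train_ffn(fix$images, fix$labels, co, cfg)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_length(t1$loss_history, 25)
  bad <- co
  bad$z[1] <- 1L  # FOV would leave the volume
  expect_warning(train_ffn(fix$images, fix$labels, bad, cfg),
                 "out-of-bounds")
})

test_that("seed policy ranks distance peaks deterministically", {
  fix <- gen_two_spheres(side = 32, radius = 6, seed = 1)
  d <- dim(fix$labels$labels)
  fresh <- list(labels = array(0L, d), visited = array(FALSE, d))
  cfg <- ffn_config(fov = c(9, 9, 9), delta = c(3, 3, 3))
  seeds <- seed_policy(fresh, fix$images, cfg)
  expect_gte(nrow(seeds), 2)
  # both sphere centers are found (within a voxel of the true centers)
  ctrs <- rbind(c(10, 10, 10), c(22, 22, 22))
  for (i in 1:2) {
    dist_to <- sqrt(rowSums((seeds - matrix(ctrs[i, ], nrow(seeds), 3,
                                            byrow = TRUE))^2))
    expect_lte(min(dist_to), 1.8)
  }
  # deterministic ordering: distance descending, ties by (z, y, x) ascending
  expect_identical(seeds, seed_policy(fresh, fix$images, cfg))
  # fully visited canvas -> no seeds
  done <- list(labels = array(0L, d), visited = array(TRUE, d))
  expect_equal(nrow(seed_policy(done, fix$images, cfg)), 0)
})

test_that("flood fill with a ground-truth oracle equals component labeling", {
  cfg <- ffn_config(fov = c(9, 9, 9), delta = c(2, 2, 2), seed = 1)
  gen <- gen_mitochondria(synth_spec(shape = c(14, 48, 48), n_objects = 4,
                                     seed = 21))
  seg <- flood_fill_segment(ffn_oracle(gen$labels), gen$images, cfg)
  cc <- label3d(binary_volume(gen$labels$labels > 0), 6)
  expect_true(labels_equivalent(seg$labels, cc$labels))
  expect_equal(rand_score(contingency(cc, seg, "instance"))$score, 1)
})

test_that("degenerate models segment nothing but terminate", {
  fix <- gen_two_spheres(side = 24, radius = 5, seed = 3)
  cfg <- ffn_config(fov = c(9, 9, 9), delta = c(3, 3, 3))
  zero_model <- function(intens, mask, center) array(0, dim(intens))
  expect_equal(max(flood_fill_segment(zero_model, fix$images, cfg)$labels), 0L)
  # a model that claims everything still terminates (move-location bookkeeping)
  all_model <- function(intens, mask, center) array(1, dim(intens))
  seg <- flood_fill_segment(all_model, fix$images, cfg)
  expect_true(is.array(seg$labels))
  # a min size above every object empties the output
  cfg_big <- ffn_config(fov = c(9, 9, 9), delta = c(3, 3, 3),
                        min_segment_size = 10^6)
  expect_equal(max(flood_fill_segment(ffn_oracle(fix$labels), fix$images,
                                      cfg_big)$labels), 0L)
})

test_that("no voxel is ever assigned two ids (first-come priority)", {
  fix <- gen_two_spheres(side = 24, radius = 5, seed = 5)
  cfg <- ffn_config(fov = c(9, 9, 9), delta = c(3, 3, 3))
  # oversegmenting oracle: claims the whole thresholded foreground every time
  greedy <- function(intens, mask, center) array(as.numeric(intens < 0),
                                                 dim(intens))
  seg <- flood_fill_segment(greedy, fix$images, cfg)
  expect_true(all(seg$labels >= 0))
  # single pass assigns each voxel once by construction; ids are contiguous
  ids <- setdiff(unique(as.vector(seg$labels)), 0L)
  expect_equal(sort(ids), seq_along(ids))
})

test_that("postprocessing compacts ids and renders deterministic previews", {
  lab <- array(0L, c(2, 4, 4))
  lab[1, 1, 1] <- 7L
  lab[2, 4, 4] <- 300L
  r1 <- ffn_postprocess(label_volume(lab))
  expect_setequal(unique(as.vector(r1$labels$labels)), c(0L, 1L, 2L))
  r2 <- ffn_postprocess(label_volume(lab))
  expect_identical(r1$preview$voxels, r2$preview$voxels)
  expect_equal(dim(r1$preview$voxels), c(2, 4, 4, 3))
  empty <- ffn_postprocess(label_volume(array(0L, c(1, 2, 2))))
  expect_equal(max(empty$labels$labels), 0L)
  expect_true(all(empty$preview$voxels == 0L))
})
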