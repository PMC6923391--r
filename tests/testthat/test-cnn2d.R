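small_cfg <- function(topology = "resnet", n_layers = 5, loss = "square",
                      ...) {
  cnn2d_config(topology = topology, n_layers = n_layers, loss = loss,
               patch_size = 16, base_filters = 4, seed = 2, ...)
}

test_that("models map (h, w, in) to (h, w, out) raw scores", {
  for (topo in c("resnet", "highway", "dense")) {
    mdl <- build_model(small_cfg(topo, 9))
    out <- emsegkit:::model_forward(mdl, array(0, c(16, 16, 1)))$out
    expect_equal(dim(out), c(16, 16, 1), info = topo)
    expect_true(all(is.finite(out)), info = topo)
  }
  # 16-layer variant is accepted
  expect_s3_class(build_model(small_cfg("resnet", 16)), "cnn2d_model")
  # unet on a 64-pixel patch: zeros in, finite (64, 64, out) scores out
  um <- build_model(cnn2d_config("unet", patch_size = 64, base_filters = 4))
  uo <- emsegkit:::model_forward(um, array(0, c(64, 64, 1)))$out
  expect_equal(dim(uo), c(64, 64, 1))
  expect_true(all(is.finite(uo)))
})

test_that("configuration errors are caught", {
  expect_error(cnn2d_config(topology = "vgg"), "unknown topology")
  expect_error(cnn2d_config(loss = "hinge"), "unknown loss")
  expect_error(cnn2d_config(topology = "resnet", n_layers = 2), "n_layers")
  expect_error(cnn2d_config(topology = "unet", patch_size = 40), "divisible")
  expect_error(build_model(small_cfg(loss = "softmax"), out_channels = 1),
               "softmax")
  expect_error(make_loss("softmax", out_channels = 1), "softmax")
  expect_error(make_loss("logistic", out_channels = 3), "single-channel")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("emsegkit")
  withr::local_seed(1)
  for (topo in c("resnet", "highway", "dense", "unet")) {
    cfg <- small_cfg(topo)
    mdl <- build_model(cfg)
    x <- array(rnorm(256), c(16, 16, 1))
    tgt <- array(rbinom(256, 1, 0.5), c(16, 16, 1))
    loss <- make_loss("square", 1)
    fwd <- ns$graph_forward(mdl$graph, mdl$params, x, TRUE)
    bwd <- ns$graph_backward(mdl$graph, mdl$params, fwd,
                             loss(fwd$out, tgt)$grad)
    eps <- 1e-5
    for (pi in c(1L, length(mdl$params))) {
      for (wi in 1:2) {
        p2 <- mdl$params
        p2[[pi]]$W[wi] <- p2[[pi]]$W[wi] + eps
        lp <- loss(ns$graph_forward(mdl$graph, p2, x, FALSE)$out, tgt)$value
        p2[[pi]]$W[wi] <- p2[[pi]]$W[wi] - 2 * eps
        lm <- loss(ns$graph_forward(mdl$graph, p2, x, FALSE)$out, tgt)$value
        num <- (lp - lm) / (2 * eps)
        ana <- bwd$grads[[pi]]$W[wi]
        expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-5)
      }
    }
  }
})

test_that("loss values match closed forms", {
  sq <- make_loss("square", 1)
  # sigmoid(scores) == targets exactly -> zero loss
  t_half <- array(rep(c(0, 1), each = 32), c(8, 8, 1))
  huge <- array(ifelse(t_half > 0, 50, -50), c(8, 8, 1))
  expect_lt(sq(huge, t_half)$value, 1e-12)
  # scores = 0 (sigmoid = 0.5) against half-ones target -> mean 0.25
  expect_equal(sq(array(0, c(8, 8, 1)), t_half)$value, 0.25)
  dice <- make_loss("dice", 1)
  expect_lt(dice(huge, t_half)$value, 1e-3)  # bounded by the smoothing term
  for (nm in c("entropy", "logistic")) {
    expect_lt(make_loss(nm, 1)(huge, t_half)$value, 1e-12)
  }
  sm <- make_loss("softmax", 2)
  t2 <- array(c(1 - t_half, t_half), c(8, 8, 2))
  s2 <- array(c(-25 * sign(t_half - 0.5), 25 * sign(t_half - 0.5)), c(8, 8, 2))
  expect_lt(sm(s2, t2)$value, 1e-9)
})

test_that("augmentation keeps pairs aligned and respects the dihedral group", {
  withr::local_seed(3)
  img <- matrix(rnorm(48), 6, 8)
  lab <- matrix(rbinom(48, 1, 0.5), 6, 8)
  # empty set -> identity
  a <- augment(img, lab)
  expect_identical(a$image, img)
  expect_equal(a$op, "none")
  # forced fliplr twice -> identity
  f1 <- augment(img, lab, choice = "fliplr")
  f2 <- augment(f1$image, f1$label, choice = "fliplr")
  expect_identical(f2$image, img)
  expect_identical(f2$label, lab)
  # rot90 four times -> identity (on a square patch)
  sq <- matrix(rnorm(49), 7, 7)
  r <- sq
  for (i in 1:4) r <- augment(r, r, choice = "rot90")$image
  expect_identical(r, sq)
  # closure: composing the available transforms never leaves the 8-element
  # dihedral orbit of the patch
  orbit <- list(sq)
  frontier <- list(sq)
  ops <- c("fliplr", "flipud", "rot90", "transpose")
  for (rounds in 1:3) {
    nxt <- list()
    for (m in frontier) {
      for (op in ops) {
        y <- augment(m, m, choice = op)$image
        if (!any(vapply(orbit, identical, TRUE, y))) {
          orbit <- c(orbit, list(y))
          nxt <- c(nxt, list(y))
        }
      }
    }
    frontier <- nxt
  }
  expect_lte(length(orbit), 8)
  # sampled transforms move image and label identically
  s <- augment(img, img, augmentations = ops)
  expect_identical(s$image, s$label)
})

test_that("training runs on one slice, is seeded-deterministic, and learns", {
  gen <- gen_mitochondria(synth_spec(shape = c(1, 64, 64), n_objects = 2,
                                     seed = 6))
  cfg <- cnn2d_config("resnet", 5, "square", epochs = 120, patch_size = 32,
                      base_filters = 8, seed = 4,
                      augmentations = c("fliplr", "flipud"))
  t1 <- train2d(gen$images, gen$labels, cfg)
  expect_length(t1$loss_history, 120)
  t2 <- train2d(gen$images, gen$labels, cfg)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_lt(mean(tail(t1$loss_history, 30)), mean(head(t1$loss_history, 30)))
  # default epochs follow the survey convention
  expect_equal(cnn2d_config()$epochs, 2000L)
  # all-background labels warn but run
  empty <- label_volume(array(0L, dim(gen$labels$labels)))
  expect_warning(train2d(gen$images, empty,
                         cnn2d_config("resnet", 3, epochs = 2,
                                      patch_size = 16, base_filters = 2)),
                 "no foreground")
})

test_that("a constant-score model infers a uniform sigmoid map", {
  mdl <- build_model(small_cfg("resnet", 3))
  mdl$params <- lapply(mdl$params, function(p)
    list(W = p$W * 0, b = p$b * 0))
  s <- 0.7
  mdl$params[[length(mdl$params)]]$b <- s
  st <- image_stack(array(sample(0:255, 4 * 32 * 32, TRUE), c(4, 32, 32)))
  pm <- infer2d(mdl, st, tile = 16, overlap = 4)
  expect_equal(max(abs(pm$values - 1 / (1 + exp(-s)))), 0)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
})

test_that("tiled inference equals the whole-slice forward pass in the interior", {
  ns <- asNamespace("emsegkit")
  gen <- gen_mitochondria(synth_spec(shape = c(1, 128, 128), n_objects = 3,
                                     seed = 2))
  cfg <- cnn2d_config("resnet", 9, "square", epochs = 5, patch_size = 64,
                      base_filters = 8, seed = 1)
  tm <- train2d(gen$images, gen$labels, cfg)
  tiled <- infer2d(tm, gen$images, tile = 64, overlap = 16)
  x <- ns$normalize_stack(gen$images)
  whole <- ns$apply_link(
    ns$graph_forward(tm$model$graph, tm$model$params,
                     array(x[1, , ], c(128, 128, 1)), FALSE)$out, "sigmoid")
  interior <- 29:100  # overlap + receptive field away from the border
  expect_lt(max(abs(tiled$values[1, interior, interior] -
                    whole[interior, interior, 1])), 1e-5)
  expect_error(infer2d(tm, gen$images, tile = 32, overlap = 16), "overlap")
})

test_that("checkpoints round-trip through a single file", {
  gen <- gen_mitochondria(synth_spec(shape = c(1, 32, 32), n_objects = 1,
                                     seed = 9))
  cfg <- cnn2d_config("resnet", 3, epochs = 3, patch_size = 16,
                      base_filters = 2, seed = 5)
  tm <- train2d(gen$images, gen$labels, cfg)
  f <- tempfile(fileext = ".ckpt")
  save_model(tm, f)
  back <- load_model(f)
  unlink(f)
  expect_identical(back$loss_history, tm$loss_history)
  expect_identical(back$model$params, tm$model$params)
})
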