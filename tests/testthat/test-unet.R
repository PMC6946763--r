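test_that("dice coefficient matches its closed form and bounds", {
  a <- matrix(0, 6, 6); a[1:2, 1:4] <- 1          # 8 px
  b <- matrix(0, 6, 6); b[2:3, 1:4] <- 1          # 8 px, overlap 4
  expect_equal(dice_coefficient(a, b), 2 * 4 / (8 + 8))
  expect_equal(dice_coefficient(a, a), 1)
  d <- matrix(0, 6, 6); d[5, 5] <- 1
  expect_equal(dice_coefficient(a, d), 0)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_equal(dice_coefficient(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0, 3, 3)), "shape")
  set.seed(1)
  for (i in 1:20) {
    p <- matrix(runif(36), 6, 6)
    t <- matrix(rbinom(36, 1, 0.4), 6, 6)
    v <- dice_coefficient(p, t, smooth = 1)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1))
  }
})

test_that("configs validate their invariants", {
  expect_error(unet_config(dropout_rate = 1), "dropout_rate")
  expect_error(unet_config(depth = 0), "depth")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("the network maps patches to same-shaped probability maps", {
  for (depth in 2:3) {
    m <- build_unet(unet_config(depth = depth, base_channels = 4L,
                                dropout_rate = 0), seed = 2)
    x <- matrix(runif(32 * 32), 32, 32)
    p <- predict_patch(m, x)
    expect_equal(dim(p), c(32, 32))
    expect_true(all(p > 0 & p < 1))
    expect_identical(p, predict_patch(m, x))   # inference is deterministic
  }
  m4 <- build_unet(unet_config(depth = 4), seed = 1)
  expect_error(predict_patch(m4, matrix(0.5, 100, 100)), "divisible")
  # encoder channels double per level
  expect_equal(nrow(m4$params$enc2_c1$W), 2 * nrow(m4$params$enc1_c1$W))
})

test_that("backpropagation matches numerical gradients", {
  cfg <- unet_config(depth = 2, base_channels = 2, dropout_rate = 0)
  m <- build_unet(cfg, seed = 3)
  set.seed(9)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  loss_of <- function(model) {
    p <- nervequant:::nq_unet_forward(model, x, train = FALSE)$prob
    1 - dice_coefficient(p, y, smooth = 1)
  }
  fw <- nervequant:::nq_unet_forward(m, x, train = TRUE)
  gp <- nervequant:::nq_dice_grad(fw$prob, y, smooth = 1)
  gr <- nervequant:::nq_unet_backward(m, fw$cache, gp, fw$prob)
  eps <- 1e-6
  for (nm in c("enc1_c1", "enc2_c2", "bott_c1", "dec2_up", "dec1_c2", "out")) {
    for (t in 1:4) {
      i <- sample(length(m$params[[nm]]$W), 1)
      m2 <- m; m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] + eps
      m3 <- m; m3$params[[nm]]$W[i] <- m3$params[[nm]]$W[i] - eps
      num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      expect_equal(gr[[nm]]$dW[i], num, tolerance = 1e-4)
    }
    i <- sample(length(m$params[[nm]]$b), 1)
    m2 <- m; m2$params[[nm]]$b[i] <- m2$params[[nm]]$b[i] + eps
    m3 <- m; m3$params[[nm]]$b[i] <- m3$params[[nm]]$b[i] - eps
    expect_equal(gr[[nm]]$db[i], (loss_of(m2) - loss_of(m3)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training is seeded-deterministic and validates preconditions", {
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- matrix(0L, 32, 32); y[10:20, ] <- 1L
  cfg <- unet_config(depth = 2, base_channels = 2)
  tc <- train_config(epochs = 2, batch_size = 1, seed = 99)
  r1 <- train_unet(build_unet(cfg, seed = 4), list(list(x = x, y = y)), tc)
  r2 <- train_unet(build_unet(cfg, seed = 4), list(list(x = x, y = y)), tc)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_length(r1$loss_trace, 2)
  expect_error(train_unet(build_unet(cfg), list(), tc), "empty")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("training reduces the Dice loss on a separable corpus", {
  pairs <- lapply(1:6, function(s) {
    ph <- generate_phantom(phantom_spec(image_size = 64L, n_trees = 2L,
                                        seed = s))
    list(x = ph$image$pixels, y = ph$truth$mask)
  })
  r <- train_unet(build_unet(unet_config(depth = 2, base_channels = 4),
                             seed = 1),
                  pairs, train_config(epochs = 6, batch_size = 2, seed = 1))
  expect_lt(r$loss_trace[6], r$loss_trace[1])
  # and the trained net beats an all-zero predictor on held-out phantoms
  ph <- generate_phantom(phantom_spec(image_size = 64L, n_trees = 2L,
                                      seed = 77))
  pm <- predict_patch(r$model, ph$image$pixels)
  dice_net <- dice_coefficient(matrix(as.integer(pm >= 0.5), 64, 64),
                               ph$truth$mask)
  dice_zero <- dice_coefficient(matrix(0, 64, 64), ph$truth$mask)
  expect_gt(dice_net, dice_zero)
})
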