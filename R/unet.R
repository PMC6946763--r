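#' U-Net architecture configuration
#'
#' The segmenter is a standard encoder/decoder U-Net: repeated 3x3
#' convolution + ReLU blocks, 2x2 max pooling on the way down, 2x2
#' nearest-neighbour upsampling + convolution on the way up, skip
#' connections concatenating encoder features into the decoder at matching
#' resolution, and a final 1x1 convolution with sigmoid activation.
#' Channels double at each encoder level. Dropout (default rate 0.2)
#' follows each encoder block and the bottleneck during training only.
#'
#' @param depth Number of pooling levels; the input side must be divisible
#'   by `2^depth` (128-px patches with depth 4 hold).
#' @param base_channels Channels in the first encoder block.
#' @param dropout_rate Dropout fraction in `[0, 1)`.
#' @param conv_kernel,pool_kernel Kernel sides (3 and 2; fixed by design,
#'   recorded for provenance).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 32L, dropout_rate = 0.2,
                        conv_kernel = 3L, pool_kernel = 2L) {
  nq_check(depth >= 1, "depth", "must be >= 1")
  nq_check(base_channels >= 1, "base_channels", "must be >= 1")
  nq_check(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate",
           "must be in [0, 1)")
  nq_check(conv_kernel == 3L, "conv_kernel", "only 3x3 convolutions supported")
  nq_check(pool_kernel == 2L, "pool_kernel", "only 2x2 pooling supported")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, conv_kernel = 3L,
                 pool_kernel = 2L, final_activation = "sigmoid"),
            class = "unet_config")
}

#' Training configuration
#'
#' @param epochs Training epochs (>= 1). The reference training schedule is
#'   200 epochs; the desk-scale default is 20.
#' @param batch_size Patches per gradient step.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed governing shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L, learning_rate = 1e-3,
                         seed = 42L) {
  nq_check(epochs >= 1, "epochs", "must be >= 1")
  nq_check(batch_size >= 1, "batch_size", "must be >= 1")
  nq_check(learning_rate > 0, "learning_rate", "must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss = "dice"),
            class = "train_config")
}

# parameter plan: list of conv layers with (name, cin, cout, k)
nq_unet_plan <- function(cfg) {
  d <- cfg$depth; b <- cfg$base_channels
  ch <- b * 2^(0:(d))                       # level channels, bottleneck last
  plan <- list()
  cin <- 1L
  for (l in seq_len(d)) {
    plan[[sprintf("enc%d_c1", l)]] <- c(cin, ch[l], 3L)
    plan[[sprintf("enc%d_c2", l)]] <- c(ch[l], ch[l], 3L)
    cin <- ch[l]
  }
  plan[["bott_c1"]] <- c(ch[d], ch[d + 1], 3L)
  plan[["bott_c2"]] <- c(ch[d + 1], ch[d + 1], 3L)
  up_in <- ch[d + 1]
  for (l in rev(seq_len(d))) {
    plan[[sprintf("dec%d_up", l)]] <- c(up_in, ch[l], 3L)
    plan[[sprintf("dec%d_c1", l)]] <- c(2L * ch[l], ch[l], 3L)
    plan[[sprintf("dec%d_c2", l)]] <- c(ch[l], ch[l], 3L)
    up_in <- ch[l]
  }
  plan[["out"]] <- c(ch[1], 1L, 1L)
  plan
}

#' Build a U-Net segmentation model
#'
#' Initialises weights (He normal, seeded) for the architecture described
#' in [unet_config()]. The network is fully convolutional: it maps any
#' single-channel square patch whose side is divisible by `2^depth` to a
#' same-shaped map of probabilities in `(0, 1)`.
#'
#' @param config A [unet_config].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  plan <- nq_unet_plan(config)
  set.seed(seed)
  params <- lapply(plan, function(p) {
    fan_in <- p[1] * p[3]^2
    list(W = matrix(rnorm(p[2] * fan_in, sd = sqrt(2 / fan_in)), p[2], fan_in),
         b = rep(0, p[2]), k = p[3])
  })
  structure(list(cfg = config, params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                     numeric(1)))
  cat(sprintf("<unet_model> depth %d, base %d channels, %d parameters\n",
              x$cfg$depth, x$cfg$base_channels, npar))
  invisible(x)
}

nq_as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

nq_conv_block <- function(x, p) {
  z <- .nq_conv_fwd(x, p$W, p$b, p$k, (p$k - 1L) %/% 2L)
  list(z = z, a = pmax(z, 0))
}

# forward pass; when train = TRUE dropout masks are drawn from the current
# RNG state and every intermediate needed by the backward pass is cached
nq_unet_forward <- function(model, patch, train = FALSE) {
  cfg <- model$cfg; d <- cfg$depth
  P <- model$params
  cache <- list(inputs = list(), drop = list(), pool = list(), skips = list())
  a <- nq_as_cube(patch)
  for (l in seq_len(d)) {
    for (s in 1:2) {
      nm <- sprintf("enc%d_c%d", l, s)
      cache$inputs[[nm]] <- a
      blk <- nq_conv_block(a, P[[nm]])
      cache[[paste0(nm, "_z")]] <- blk$z
      a <- blk$a
    }
    if (train && cfg$dropout_rate > 0) {
      msk <- array((runif(length(a)) >= cfg$dropout_rate) /
                     (1 - cfg$dropout_rate), dim = dim(a))
      cache$drop[[sprintf("enc%d", l)]] <- msk
      a <- a * msk
    }
    cache$skips[[l]] <- a
    pl <- .nq_pool_fwd(a)
    cache$pool[[l]] <- list(idx = pl$idx, H = dim(a)[1], W = dim(a)[2])
    a <- pl$out
  }
  for (s in 1:2) {
    nm <- sprintf("bott_c%d", s)
    cache$inputs[[nm]] <- a
    blk <- nq_conv_block(a, P[[nm]])
    cache[[paste0(nm, "_z")]] <- blk$z
    a <- blk$a
  }
  if (train && cfg$dropout_rate > 0) {
    msk <- array((runif(length(a)) >= cfg$dropout_rate) /
                   (1 - cfg$dropout_rate), dim = dim(a))
    cache$drop[["bott"]] <- msk
    a <- a * msk
  }
  for (l in rev(seq_len(d))) {
    u <- .nq_upsample_fwd(a)
    nm <- sprintf("dec%d_up", l)
    cache$inputs[[nm]] <- u
    blk <- nq_conv_block(u, P[[nm]])
    cache[[paste0(nm, "_z")]] <- blk$z
    skip <- cache$skips[[l]]
    a <- array(c(skip, blk$a), dim = c(dim(skip)[1], dim(skip)[2],
                                       dim(skip)[3] + dim(blk$a)[3]))
    for (s in 1:2) {
      nm <- sprintf("dec%d_c%d", l, s)
      cache$inputs[[nm]] <- a
      blk2 <- nq_conv_block(a, P[[nm]])
      cache[[paste0(nm, "_z")]] <- blk2$z
      a <- blk2$a
    }
  }
  cache$inputs[["out"]] <- a
  z <- .nq_conv_fwd(a, P$out$W, P$out$b, 1L, 0L)
  prob <- 1 / (1 + exp(-z[, , 1]))
  list(prob = prob, cache = if (train) cache else NULL)
}

# backward pass from d(loss)/d(prob); returns gradients named as params
nq_unet_backward <- function(model, cache, gprob, prob) {
  cfg <- model$cfg; d <- cfg$depth
  P <- model$params
  grads <- list()
  gz <- nq_as_cube(gprob * prob * (1 - prob))
  bw <- function(nm, g) {
    r <- .nq_conv_bwd(cache$inputs[[nm]], P[[nm]]$W, g, P[[nm]]$k,
                      (P[[nm]]$k - 1L) %/% 2L)
    grads[[nm]] <<- list(dW = r$dw, db = as.numeric(r$db))
    r$dx
  }
  g <- bw("out", gz)
  gskips <- vector("list", d)
  for (l in seq_len(d)) {
    for (s in 2:1) {
      nm <- sprintf("dec%d_c%d", l, s)
      g <- g * (cache[[paste0(nm, "_z")]] > 0)
      g <- bw(nm, g)
    }
    nc <- dim(cache$skips[[l]])[3]
    gskips[[l]] <- g[, , seq_len(nc), drop = FALSE]
    gup <- g[, , nc + seq_len(dim(g)[3] - nc), drop = FALSE]
    nm <- sprintf("dec%d_up", l)
    gup <- gup * (cache[[paste0(nm, "_z")]] > 0)
    g <- bw(nm, gup)
    g <- .nq_upsample_bwd(g)
  }
  if (!is.null(cache$drop[["bott"]])) g <- g * cache$drop[["bott"]]
  for (s in 2:1) {
    nm <- sprintf("bott_c%d", s)
    g <- g * (cache[[paste0(nm, "_z")]] > 0)
    g <- bw(nm, g)
  }
  for (l in rev(seq_len(d))) {
    pl <- cache$pool[[l]]
    g <- .nq_pool_bwd(pl$idx, g, pl$H, pl$W)
    g <- g + gskips[[l]]
    if (!is.null(cache$drop[[sprintf("enc%d", l)]])) {
      g <- g * cache$drop[[sprintf("enc%d", l)]]
    }
    for (s in 2:1) {
      nm <- sprintf("enc%d_c%d", l, s)
      g <- g * (cache[[paste0(nm, "_z")]] > 0)
      g <- bw(nm, g)
    }
  }
  grads
}

#' Dice similarity coefficient
#'
#' `DSC = (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) +
#' smooth)`. With `smooth = 0` and two empty rasters the coefficient is
#' defined as 1 (identical masks). The soft (differentiable) form with
#' `smooth = 1` is the training cost `1 - DSC`; the hard form
#' (`smooth = 0` on binarised predictions) is used for reporting.
#'
#' @param pred Raster of values in `[0, 1]`.
#' @param truth Binary raster of the same shape.
#' @param smooth Small positive smoothing constant (0 for the hard form).
#' @return The coefficient, a value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, smooth = 0) {
  nq_check(all(dim(pred) == dim(truth)), "pred",
           "shape mismatch between pred and truth")
  num <- 2 * sum(pred * truth) + smooth
  den <- sum(pred) + sum(truth) + smooth
  if (den == 0) return(1)
  num / den
}

nq_dice_grad <- function(pred, truth, smooth = 1) {
  num <- 2 * sum(pred * truth) + smooth
  den <- sum(pred) + sum(truth) + smooth
  # d(1 - num/den)/d pred_i = -(2 truth_i * den - num) / den^2
  -(2 * truth * den - num) / den^2
}

#' Train a U-Net on image/mask patch pairs
#'
#' Minimises the soft Dice loss `1 - DSC` with Adam. Deterministic for a
#' fixed `cfg$seed` (shuffling, dropout) and model seed (initial weights).
#'
#' @param model A [build_unet()] model.
#' @param patches List of pairs; each `list(x = image patch, y = binary
#'   mask patch)`, equal square sides divisible by `2^depth`.
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `loss_trace` (mean soft Dice
#'   loss per epoch).
#' @export
train_unet <- function(model, patches, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  nq_check(length(patches) >= 1, "patches", "empty training set")
  side <- nrow(patches[[1]]$x)
  nq_check(side %% 2^model$cfg$depth == 0, "patches",
           sprintf("patch side %d not divisible by 2^depth = %d",
                   side, 2^model$cfg$depth))
  set.seed(cfg$seed)
  opt <- list(m = lapply(model$params, function(p)
                list(W = p$W * 0, b = p$b * 0)),
              v = lapply(model$params, function(p)
                list(W = p$W * 0, b = p$b * 0)),
              t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(cfg$epochs)
  n <- length(patches)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    bstart <- seq(1, n, by = cfg$batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1, n)]
      acc <- NULL
      for (ii in seq_along(idx)) {
        pr <- patches[[idx[ii]]]
        fw <- nq_unet_forward(model, pr$x, train = TRUE)
        losses[which(ord == idx[ii])] <-
          1 - dice_coefficient(fw$prob, pr$y, smooth = 1)
        gp <- nq_dice_grad(fw$prob, pr$y, smooth = 1)
        gr <- nq_unet_backward(model, fw$cache, gp, fw$prob)
        if (is.null(acc)) {
          acc <- gr
        } else {
          for (nm in names(gr)) {
            acc[[nm]]$dW <- acc[[nm]]$dW + gr[[nm]]$dW
            acc[[nm]]$db <- acc[[nm]]$db + gr[[nm]]$db
          }
        }
      }
      opt$t <- opt$t + 1
      corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
      for (nm in names(acc)) {
        gW <- acc[[nm]]$dW / length(idx)
        gb <- acc[[nm]]$db / length(idx)
        opt$m[[nm]]$W <- b1 * opt$m[[nm]]$W + (1 - b1) * gW
        opt$m[[nm]]$b <- b1 * opt$m[[nm]]$b + (1 - b1) * gb
        opt$v[[nm]]$W <- b2 * opt$v[[nm]]$W + (1 - b2) * gW^2
        opt$v[[nm]]$b <- b2 * opt$v[[nm]]$b + (1 - b2) * gb^2
        model$params[[nm]]$W <- model$params[[nm]]$W -
          cfg$learning_rate * (opt$m[[nm]]$W / corr1) /
          (sqrt(opt$v[[nm]]$W / corr2) + eps)
        model$params[[nm]]$b <- model$params[[nm]]$b -
          cfg$learning_rate * (opt$m[[nm]]$b / corr1) /
          (sqrt(opt$v[[nm]]$b / corr2) + eps)
      }
    }
    loss_trace[ep] <- mean(losses)
  }
  list(model = model, loss_trace = loss_trace)
}

#' Predict the segmentation probability map of one patch
#'
#' @param model A (trained) [build_unet()] model.
#' @param patch Square matrix in `[0, 1]`, side divisible by `2^depth`.
#' @return Matrix of probabilities in `(0, 1)`, same shape as `patch`.
#' @export
predict_patch <- function(model, patch) {
  stopifnot(inherits(model, "unet_model"))
  nq_check(is.matrix(patch) && nrow(patch) == ncol(patch), "patch",
           "must be a square matrix")
  nq_check(nrow(patch) %% 2^model$cfg$depth == 0, "patch",
           sprintf("side %d not divisible by 2^depth = %d",
                   nrow(patch), 2^model$cfg$depth))
  nq_unet_forward(model, patch, train = FALSE)$prob
}

#' Segment a full image with one model via the patch grid
#'
#' Extracts the grid's patches, predicts each, binarises at `threshold`
#' and stitches by majority vote (or averages probabilities first when
#' `stitch_mode = "mean_prob"`).
#'
#' @param model A [build_unet()] model.
#' @param image A [ccm_image] or matrix.
#' @param patch_px,stride_px Grid geometry (see [plan_grid()]).
#' @param stitch_mode `"vote"` or `"mean_prob"`.
#' @param threshold Binarisation threshold on sigmoid output.
#' @return Integer 0/1 matrix, the image-level segmentation.
#' @export
predict_image <- function(model, image, patch_px = 128L, stride_px = 32L,
                          stitch_mode = c("vote", "mean_prob"),
                          threshold = 0.5) {
  stitch_mode <- match.arg(stitch_mode)
  px <- nq_as_raster(image)
  grid <- plan_grid(dim(px), patch_px, stride_px)
  probs <- lapply(extract_patches(px, grid), function(p)
    predict_patch(model, p))
  if (stitch_mode == "vote") {
    votes <- lapply(probs, function(p)
      matrix(as.integer(p >= threshold), nrow(p), ncol(p)))
    stitch_majority(votes, grid, mode = "vote")
  } else {
    stitch_majority(probs, grid, mode = "mean_prob", threshold = threshold)
  }
}
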