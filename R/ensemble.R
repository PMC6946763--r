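#' Ensemble configuration
#'
#' The refined segmenter trains several U-Nets on bootstrap resamples of
#' the training images (sampling with replacement at the image level, same
#' size) and fuses their image-level masks by pixel-wise majority vote. The
#' member count must be odd so no pixel tie is possible.
#'
#' @param n_members Number of member networks (odd, default 5).
#' @param member_seeds Optional integer vector of per-member seeds (length
#'   `n_members`); controls both the bootstrap resample and the member's
#'   weight initialisation. Defaults to `1000 + 1:n_members`.
#' @param bootstrap Resample the training images with replacement
#'   (`TRUE`, default) or train every member on the full set.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 5L, member_seeds = NULL,
                            bootstrap = TRUE) {
  nq_check(n_members >= 1, "n_members", "must be >= 1")
  nq_check(n_members %% 2 == 1, "n_members",
           "must be odd so the pixel majority is well-defined")
  if (is.null(member_seeds)) member_seeds <- 1000L + seq_len(n_members)
  nq_check(length(member_seeds) == n_members, "member_seeds",
           "must have one seed per member")
  if (anyDuplicated(member_seeds)) {
    warning("duplicate member seeds: members will coincide", call. = FALSE)
  }
  structure(list(n_members = as.integer(n_members),
                 member_seeds = as.integer(member_seeds),
                 bootstrap = isTRUE(bootstrap)),
            class = "ensemble_config")
}

#' Bootstrap resample a training set at the image level
#'
#' Draws `length(x)` elements i.i.d. with replacement. Resampling happens
#' at the image (not patch) level so that no test image can contribute
#' training patches.
#'
#' @param x Non-empty list (or vector) of training images/pairs.
#' @param seed Integer seed.
#' @return Resampled list of the same length.
#' @export
bootstrap_sample <- function(x, seed) {
  nq_check(length(x) >= 1, "x", "empty training set")
  set.seed(seed)
  x[sample.int(length(x), length(x), replace = TRUE)]
}

#' Train a bootstrap ensemble of U-Nets
#'
#' Member `k` is initialised with `member_seeds[k]` and trained on
#' `bootstrap_sample(pairs, member_seeds[k])` (images resampled, then cut
#' into patches), so the run is fully reproducible from the seed list.
#'
#' @param pairs List of image-level training pairs `list(x = image matrix,
#'   y = binary mask matrix)` (full frames; patches are cut per member).
#' @param unet_cfg A [unet_config()].
#' @param train_cfg A [train_config()]; `seed` is offset per member.
#' @param ens_cfg An [ensemble_config()].
#' @param patch_px,stride_px Patch geometry used to cut training patches.
#' @return An object of class `nerve_ensemble`: list of trained
#'   [build_unet()] models plus the configs and seeds (the manifest).
#' @export
train_ensemble <- function(pairs, unet_cfg = unet_config(),
                           train_cfg = train_config(),
                           ens_cfg = ensemble_config(),
                           patch_px = 128L, stride_px = 32L) {
  nq_check(length(pairs) >= 1, "pairs", "empty training set")
  models <- lapply(seq_len(ens_cfg$n_members), function(k) {
    sk <- ens_cfg$member_seeds[k]
    imgs <- if (ens_cfg$bootstrap) bootstrap_sample(pairs, sk) else pairs
    patches <- unlist(lapply(imgs, function(pr) {
      grid <- plan_grid(dim(pr$x), patch_px, stride_px)
      xs <- extract_patches(pr$x, grid)
      ys <- extract_patches(pr$y, grid)
      Map(function(x, y) list(x = x, y = y), xs, ys)
    }), recursive = FALSE)
    tc <- train_cfg
    tc$seed <- as.integer((train_cfg$seed + sk) %% .Machine$integer.max)
    train_unet(build_unet(unet_cfg, seed = sk), patches, tc)$model
  })
  structure(list(models = models, unet_cfg = unet_cfg,
                 train_cfg = train_cfg, ens_cfg = ens_cfg,
                 patch_px = as.integer(patch_px),
                 stride_px = as.integer(stride_px)),
            class = "nerve_ensemble")
}

#' @export
print.nerve_ensemble <- function(x, ...) {
  cat(sprintf("<nerve_ensemble> %d members, seeds %s\n",
              x$ens_cfg$n_members,
              paste(x$ens_cfg$member_seeds, collapse = ", ")))
  invisible(x)
}

#' Segment an image with an ensemble by pixel-wise majority vote
#'
#' Each member segments the full image (patch prediction + stitching); the
#' final mask sets a pixel iff at least `ceiling(n_members / 2)` members
#' vote for it (3 of 5 in the default configuration).
#'
#' @param ensemble A [train_ensemble()] result, or a plain list of
#'   [build_unet()] models.
#' @param image A [ccm_image] or matrix.
#' @param patch_px,stride_px Prediction grid geometry; defaults to the
#'   ensemble's training geometry when available.
#' @param threshold Per-member binarisation threshold.
#' @return Integer 0/1 matrix.
#' @export
predict_ensemble <- function(ensemble, image, patch_px = NULL,
                             stride_px = NULL, threshold = 0.5) {
  models <- if (inherits(ensemble, "nerve_ensemble")) ensemble$models
            else ensemble
  nq_check(length(models) >= 1, "ensemble", "needs at least one model")
  if (is.null(patch_px)) {
    patch_px <- if (inherits(ensemble, "nerve_ensemble")) ensemble$patch_px
                else 128L
  }
  if (is.null(stride_px)) {
    stride_px <- if (inherits(ensemble, "nerve_ensemble")) ensemble$stride_px
                 else 32L
  }
  masks <- lapply(models, function(m)
    predict_image(m, image, patch_px, stride_px, threshold = threshold))
  votes <- Reduce(`+`, masks)
  need <- ceiling(length(models) / 2)
  matrix(as.integer(votes >= need), nrow(votes), ncol(votes))
}
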