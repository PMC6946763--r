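#' Plan a patch grid over an image
#'
#' Tiles an image with fixed-size square patches anchored every `stride_px`
#' pixels per axis; if the last regular anchor does not flush the border an
#' extra anchor at `dim - patch_px` is appended so the image is fully
#' covered. The working configuration (384 px frame, 128 px patches, 32 px
#' stride) yields 9 anchors per axis, 81 patches per image.
#'
#' @param image_shape Length-2 integer `(H, W)` in pixels.
#' @param patch_px Patch side in pixels.
#' @param stride_px Anchor step in pixels.
#' @return An object of class `patch_grid`: `patch_px`, `stride_px`,
#'   `anchors` (n x 2 matrix of 0-based `(row, col)` top-left corners,
#'   row-major order) and `image_shape`.
#' @export
plan_grid <- function(image_shape, patch_px = 128L, stride_px = 32L) {
  nq_check(length(image_shape) == 2 && all(image_shape >= 1),
           "image_shape", "must be (H, W)")
  nq_check(patch_px >= 1 && patch_px <= min(image_shape), "patch_px",
           "patch larger than image")
  nq_check(stride_px >= 1, "stride_px", "must be >= 1")
  axis_anchors <- function(dim) {
    a <- seq.int(0L, dim - patch_px, by = stride_px)
    if (a[length(a)] != dim - patch_px) a <- c(a, dim - patch_px)
    a
  }
  rows <- axis_anchors(image_shape[1])
  cols <- axis_anchors(image_shape[2])
  anchors <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(patch_px = as.integer(patch_px),
                 stride_px = as.integer(stride_px),
                 anchors = anchors,
                 image_shape = as.integer(image_shape)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d px (stride %d) over %d x %d\n",
              nrow(x$anchors), x$patch_px, x$stride_px,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

nq_as_raster <- function(x) {
  if (inherits(x, "ccm_image") || inherits(x, "annotation_mask")) x$pixels
  else x
}

#' Extract the patches of a grid
#'
#' @param x A [ccm_image], [annotation_mask] or matrix whose shape matches
#'   the grid.
#' @param grid A [plan_grid] result planned on this image's shape.
#' @return List of `patch_px x patch_px` matrices, ordered as `grid$anchors`.
#' @export
extract_patches <- function(x, grid) {
  px <- nq_as_raster(x)
  nq_check(all(dim(px) == grid$image_shape), "x",
           "shape does not match the grid's image_shape")
  p <- grid$patch_px
  lapply(seq_len(nrow(grid$anchors)), function(k) {
    r <- grid$anchors[k, 1]
    c <- grid$anchors[k, 2]
    px[(r + 1):(r + p), (c + 1):(c + p), drop = FALSE]
  })
}

#' Stitch patch segmentations into a full-image mask
#'
#' Reassembles per-patch segmentations by pixel-wise voting over the patches
#' covering each pixel. In `"vote"` mode (default) each binary patch casts a
#' vote and a pixel is foreground iff positive votes reach half the coverage
#' (ties count as positive unless `tie_positive = FALSE`). In `"mean_prob"`
#' mode the patches are probability maps, averaged and thresholded.
#'
#' @param patch_masks List of patch rasters, one per grid anchor, in anchor
#'   order: binary for `"vote"`, probabilities in `[0, 1]` for `"mean_prob"`.
#' @param grid The [plan_grid] the patches came from.
#' @param mode `"vote"` or `"mean_prob"`.
#' @param tie_positive Tie-break for even coverage in vote mode.
#' @param threshold Threshold on the mean probability in `"mean_prob"` mode.
#' @return Integer 0/1 matrix of the grid's image shape.
#' @export
stitch_majority <- function(patch_masks, grid, mode = c("vote", "mean_prob"),
                            tie_positive = TRUE, threshold = 0.5) {
  mode <- match.arg(mode)
  n <- nrow(grid$anchors)
  nq_check(length(patch_masks) == n, "patch_masks",
           sprintf("expected %d patches, got %d", n, length(patch_masks)))
  p <- grid$patch_px
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  votes <- matrix(0, H, W)
  cover <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    pm <- patch_masks[[k]]
    nq_check(all(dim(pm) == c(p, p)), "patch_masks",
             sprintf("patch %d is not %d x %d", k, p, p))
    r <- grid$anchors[k, 1]; c <- grid$anchors[k, 2]
    ri <- (r + 1):(r + p); ci <- (c + 1):(c + p)
    votes[ri, ci] <- votes[ri, ci] + pm
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  out <- if (mode == "vote") {
    need <- ceiling(cover / 2)
    if (!tie_positive) need <- floor(cover / 2) + 1
    (votes >= need) & (cover > 0)
  } else {
    (votes / pmax(cover, 1L) >= threshold) & (cover > 0)
  }
  matrix(as.integer(out), H, W)
}
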