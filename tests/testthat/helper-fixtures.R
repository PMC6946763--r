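# shared fixtures, all generated in code

# draw a 1-px Y: horizontal arm meeting two diagonals at (15, 15) [1-based]
make_y_skeleton <- function() {
  y <- matrix(0L, 30, 30)
  y[cbind(15, 5:15)] <- 1L
  y[cbind(16:25, 16:25)] <- 1L
  y[cbind(14:5, 16:25)] <- 1L
  y
}

make_ring_skeleton <- function() {
  r <- matrix(0L, 40, 40)
  th <- seq(0, 2 * pi, length.out = 200)
  r[cbind(round(20 + 10 * sin(th)), round(20 + 10 * cos(th)))] <- 1L
  skeletonize(r)
}

# minimal uncompressed 8-bit greyscale BMP writer (test oracle for the
# package's BMP reader); values in [0, 1], written bottom-up
write_test_bmp <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  stride <- ((w + 3) %/% 4) * 4
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  offset <- 14 + 40 + 256 * 4
  sz <- offset + stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(sz, 0, offset)), con, size = 4)
  writeBin(as.integer(c(40, w, h)), con, size = 4)
  writeBin(as.integer(c(1, 8)), con, size = 2)
  writeBin(as.integer(c(0, stride * h, 2835, 2835, 256, 0)), con, size = 4)
  writeBin(pal, con)
  for (r in h:1) {
    row <- as.integer(round(px[r, ] * 255))
    writeBin(as.raw(c(row, rep(0, stride - w))), con)
  }
  invisible(path)
}

# memoised desk-scale training used by the learning-check tests: one
# single-net model and one 5-member ensemble, trained once per session
nq_test_cache <- new.env(parent = emptyenv())

trained_models <- function() {
  if (!is.null(nq_test_cache$models)) return(nq_test_cache$models)
  gen <- function(seeds, n_trees) lapply(seeds, function(s) {
    ph <- generate_phantom(phantom_spec(image_size = 128L, n_trees = n_trees,
                                        seed = s))
    list(x = ph$image$pixels, y = ph$truth$mask)
  })
  pairs <- gen(1:16, 3)
  ucfg <- unet_config(depth = 3L, base_channels = 8L)
  tcfg <- train_config(epochs = 12L, batch_size = 4L, seed = 7L)
  single <- train_ensemble(pairs, ucfg, tcfg,
                           ensemble_config(n_members = 1L),
                           patch_px = 128L, stride_px = 128L)
  ens <- train_ensemble(pairs, ucfg, tcfg,
                        ensemble_config(n_members = 5L),
                        patch_px = 128L, stride_px = 128L)
  nq_test_cache$models <- list(single = single, ensemble = ens,
                               heldout = lapply(101:108, function(s) {
                                 ph <- generate_phantom(phantom_spec(
                                   image_size = 128L, n_trees = 3L, seed = s))
                                 list(x = ph$image$pixels, y = ph$truth$mask)
                               }))
  nq_test_cache$models
}
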