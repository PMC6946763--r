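test_that("empty phantom (no trees) yields zero truth and an empty mask", {
  ph <- generate_phantom(phantom_spec(n_trees = 0L, image_size = 64L, seed = 5))
  expect_equal(sum(ph$truth$mask), 0)
  expect_equal(ph$truth$true_total_length_um, 0)
  expect_equal(ph$truth$true_n_branch, 0L)
  expect_equal(ph$truth$true_n_tail, 0L)
  expect_true(all(ph$image$pixels >= 0 & ph$image$pixels <= 1))
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(phantom_spec(n_trees = -1), "n_trees")
  expect_error(phantom_spec(branch_prob = 1), "branch_prob")
  expect_error(phantom_spec(fibre_width_px = 0), "fibre_width_px")
  expect_error(phantom_spec(image_size = 0), "image_size")
})

test_that("truth lengths equal the chord-sum of the generating polylines", {
  spec <- phantom_spec(seed = 21, image_size = 256L)
  ph <- generate_phantom(spec)
  chord_sum <- sum(vapply(ph$truth$centreline_polylines, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1))) * spec$pixel_size_um
  expect_equal(ph$truth$true_total_length_um, chord_sum)
  # a straight (curvature-free, branch-free) fibre: chord sum equals the
  # start-to-end distance
  spec2 <- phantom_spec(seed = 3, n_trees = 1L, branch_prob = 0,
                        curvature_sigma = 0, image_size = 256L)
  ph2 <- generate_phantom(spec2)
  p <- ph2$truth$centreline_polylines[[1]]
  expect_equal(ph2$truth$true_total_length_um,
               sqrt(sum((p[nrow(p), ] - p[1, ])^2)) * spec2$pixel_size_um,
               tolerance = 1e-12)
  expect_equal(ph2$truth$true_n_tail, 2L)
  expect_equal(ph2$truth$true_n_segments, 1L)
})

test_that("generation is deterministic per seed and varies across seeds", {
  spec <- phantom_spec(seed = 11, image_size = 128L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask, b$truth$mask)
  c <- generate_phantom(phantom_spec(seed = 12, image_size = 128L))
  expect_false(identical(a$truth$mask, c$truth$mask))
})

test_that("mask equals the centreline dilated to the stroke width", {
  spec <- phantom_spec(seed = 4, image_size = 192L)
  ph <- generate_phantom(spec)
  centre <- matrix(0L, spec$image_size, spec$image_size)
  for (p in ph$truth$centreline_polylines) {
    centre <- nervequant:::nq_rasterise_polyline(p, centre)
  }
  expect_identical(centre, ph$truth$centreline)
  brush <- EBImage::makeBrush(spec$fibre_width_px, shape = "disc")
  dil <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(centre)), brush)))
  expect_identical(matrix(as.integer(dil > 0), nrow(dil)), ph$truth$mask)
})

test_that("adding trees never decreases the true total length", {
  lens <- vapply(1:6, function(k) {
    generate_phantom(phantom_spec(seed = 31, n_trees = k,
                                  image_size = 256L))$truth$true_total_length_um
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("cohort generation contrasts groups and respects seeds", {
  h <- phantom_spec(image_size = 128L, n_trees = 4L, seed = 50)
  n <- phantom_spec(image_size = 128L, n_trees = 2L, seed = 60)
  coh <- generate_cohort(h, n, n_per_group = 8, seed = 2)
  expect_length(coh, 16)
  lens <- vapply(coh, function(r) r$truth$true_total_length_um, numeric(1))
  grp <- vapply(coh, `[[`, "", "group")
  expect_gt(mean(lens[grp == "healthy"]), mean(lens[grp == "neuropathy"]))
  # identical specs on both sides give identical truths per image index
  same <- generate_cohort(h, h, n_per_group = 2, seed = 2)
  expect_equal(same[[1]]$truth$true_total_length_um,
               same[[3]]$truth$true_total_length_um)
  expect_error(generate_cohort(h, n, n_per_group = 0), "n_per_group")
  # reproducible
  coh2 <- generate_cohort(h, n, n_per_group = 8, seed = 2)
  expect_identical(lens, vapply(coh2, function(r)
    r$truth$true_total_length_um, numeric(1)))
})

test_that("write_cohort round-trips masks and writes a manifest", {
  dir <- withr::local_tempdir()
  h <- phantom_spec(image_size = 96L, n_trees = 2L, seed = 8)
  coh <- generate_cohort(h, h, n_per_group = 1, seed = 1)
  manifest <- write_cohort(coh, dir)
  df <- read.csv(manifest)
  expect_equal(nrow(df), 2)
  expect_true(all(file.exists(df$image_path)))
  mk <- load_annotation_mask(df$mask_path[1])
  expect_identical(mk$pixels, coh[[1]]$truth$mask)
  truth <- jsonlite::read_json(sub("_mask\\.png$", "_truth.json",
                                   df$mask_path[1]))
  expect_equal(truth$true_total_length_um,
               coh[[1]]$truth$true_total_length_um, tolerance = 1e-8)
})
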