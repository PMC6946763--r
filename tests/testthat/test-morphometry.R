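test_that("thinning produces 1-px skeletons and is idempotent", {
  expect_equal(sum(skeletonize(matrix(0L, 20, 20))), 0)
  m <- matrix(0L, 60, 60); m[10:12, 5:50] <- 1L
  sk <- skeletonize(m)
  hits <- which(sk == 1, arr.ind = TRUE)
  expect_equal(unique(hits[, 1]), 11)              # centre row
  # thinning erodes blunt bar ends by up to half the stroke width
  expect_lte(abs(min(hits[, 2]) - 5), 2)
  expect_lte(abs(max(hits[, 2]) - 50), 2)
  expect_false(nervequant:::nq_has_2x2(sk))
  expect_identical(skeletonize(sk), sk)
  # output is a subset of the input's morphological neighbourhood
  expect_true(all(m[sk == 1] == 1))
  # component count preserved on a two-blob mask
  m2 <- matrix(0L, 40, 40); m2[5:7, 5:20] <- 1L; m2[25:27, 5:20] <- 1L
  sk2 <- skeletonize(m2)
  lab <- EBImage::bwlabel(EBImage::Image(t(sk2)))
  expect_equal(max(lab), 2)
})

test_that("node classification follows the 8-neighbour rules", {
  line <- matrix(0L, 20, 20); line[10, 3:17] <- 1L
  n <- classify_nodes(line)
  expect_equal(nrow(n$tail_points), 2)
  expect_equal(nrow(n$branch_points), 0)
  expect_setequal(n$tail_points[, 2], c(2, 16))    # 0-based columns
  y <- make_y_skeleton()
  ny <- classify_nodes(y)
  expect_equal(nrow(ny$tail_points), 3)
  expect_equal(nrow(ny$branch_points), 1)
  ring <- make_ring_skeleton()
  nr <- classify_nodes(ring)
  expect_equal(nrow(nr$tail_points), 0)
  expect_equal(nrow(nr$branch_points), 0)
  blob <- matrix(0L, 10, 10); blob[3:4, 3:4] <- 1L
  expect_error(classify_nodes(blob), "2x2")
})

test_that("segments partition the skeleton between nodes", {
  line <- matrix(0L, 20, 20); line[10, 3:17] <- 1L
  expect_length(extract_segments(line, classify_nodes(line)), 1)
  y <- make_y_skeleton()
  segs <- extract_segments(y, classify_nodes(y))
  expect_length(segs, 3)
  # each segment ends at the branch pixel (node-to-node paths)
  bp <- classify_nodes(y)$branch_pixels
  touches <- vapply(segs, function(s) {
    ends <- s[c(1, nrow(s)), , drop = FALSE]
    any(apply(ends, 1, function(e) any(e[1] == bp[, 1] & e[2] == bp[, 2])))
  }, logical(1))
  expect_true(all(touches))
  two <- matrix(0L, 20, 20); two[5, 2:18] <- 1L; two[15, 2:18] <- 1L
  expect_length(extract_segments(two, classify_nodes(two)), 2)
  ring <- make_ring_skeleton()
  expect_length(extract_segments(ring, classify_nodes(ring)), 1)
})

test_that("path length counts orthogonal and diagonal steps", {
  horiz <- cbind(rep(5, 10), 1:10)
  expect_equal(path_length_um(horiz, 1.04), 9 * 1.04)
  diag <- cbind(1:10, 1:10)
  expect_equal(path_length_um(diag, 1.04), 9 * sqrt(2) * 1.04)
  expect_equal(path_length_um(cbind(3, 3), 1.04), 0)
  expect_error(path_length_um(rbind(c(1, 1), c(4, 4)), 1.04), "adjacent")
  expect_error(path_length_um(rbind(c(1, 1), c(1, 1)), 1.04), "adjacent")
})

test_that("box-counting dimension hits the analytic limits", {
  ln <- matrix(0L, 128, 128); ln[64, ] <- 1L
  expect_gt(fractal_number(ln), 0.9)
  expect_lt(fractal_number(ln), 1.1)
  sq <- matrix(1L, 128, 128)
  expect_gte(fractal_number(sq), 1.9)
  expect_lte(fractal_number(sq), 2.0)
  dense <- generate_phantom(phantom_spec(seed = 2, n_trees = 8L,
                                         image_size = 256L))$truth$centreline
  sparse <- generate_phantom(phantom_spec(seed = 2, n_trees = 1L,
                                          image_size = 256L))$truth$centreline
  expect_gt(fractal_number(dense), fractal_number(sparse))
  expect_error(fractal_number(matrix(0L, 64, 64)), "empty")
})

test_that("quantify recovers generator ground truth", {
  empty <- quantify(matrix(0L, 64, 64), 1.04)
  expect_equal(empty$total_length_um, 0)
  expect_equal(empty$n_branch + empty$n_tail + empty$n_segments, 0L)
  expect_true(is.na(empty$fractal_number))
  # single straight fibre: length within 5 percent of the chord truth
  spec <- phantom_spec(seed = 3, n_trees = 1L, branch_prob = 0,
                       curvature_sigma = 0, image_size = 256L)
  ph <- generate_phantom(spec)
  q <- quantify(ph$truth$mask, spec$pixel_size_um)
  expect_lt(abs(q$total_length_um - ph$truth$true_total_length_um) /
              ph$truth$true_total_length_um, 0.05)
  expect_equal(q$n_tail, 2L)
  # branching phantom: exact branch/tail recovery on the clean mask
  spec2 <- phantom_spec(seed = 13)
  ph2 <- generate_phantom(spec2)
  q2 <- quantify(ph2$truth$mask, spec2$pixel_size_um)
  expect_equal(q2$n_branch, ph2$truth$true_n_branch)
  expect_equal(q2$n_tail, ph2$truth$true_n_tail)
  expect_equal(q2$n_segments, ph2$truth$true_n_segments)
  expect_equal(q2$mean_segment_length_um * q2$n_segments, q2$total_length_um)
  expect_error(quantify(ph2$truth$mask, NA), "pixel_size_um")
})

test_that("quantify is scale-consistent and rotation-robust", {
  ph <- generate_phantom(phantom_spec(seed = 6, image_size = 256L))
  m <- ph$truth$mask
  q1 <- quantify(m, 1.04)
  q2 <- quantify(m, 2.08)
  expect_equal(q2$total_length_um, 2 * q1$total_length_um)
  expect_equal(q2$mean_segment_length_um, 2 * q1$mean_segment_length_um)
  expect_identical(c(q2$n_branch, q2$n_tail, q2$n_segments),
                   c(q1$n_branch, q1$n_tail, q1$n_segments))
  expect_equal(q2$fractal_number, q1$fractal_number)
  rot90 <- function(x) t(x)[ncol(x):1, ]
  qr <- quantify(rot90(m), 1.04)
  expect_identical(c(qr$n_branch, qr$n_tail, qr$n_segments),
                   c(q1$n_branch, q1$n_tail, q1$n_segments))
  # thinning is not exactly rotation-equivariant; lengths agree closely
  expect_equal(qr$total_length_um, q1$total_length_um, tolerance = 0.02)
})
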