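#' Thin a binary segmentation to a 1-pixel skeleton
#'
#' Zhang-Suen parallel thinning with a final cleanup pass that dissolves any
#' residual 2x2 blocks by deleting 8-simple non-endpoint pixels, so the
#' result is strictly 1 pixel wide while preserving 8-connectivity.
#'
#' @param mask Binary matrix (or [annotation_mask]).
#' @return Integer 0/1 matrix, the skeleton.
#' @export
skeletonize <- function(mask) {
  px <- nq_as_raster(mask)
  nq_check(all(px %in% c(0, 1)), "mask", "must be binary")
  m <- matrix(as.integer(px), nrow(px), ncol(px))
  .nq_thin(m)
}

# 8-neighbour count of every pixel, by shifting a zero-padded copy
nq_neighbour_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  n <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  n
}

nq_has_2x2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 2 || W < 2) return(FALSE)
  any(m[-H, -W] & m[-1, -W] & m[-H, -1] & m[-1, -1])
}

#' Classify skeleton nodes into branch and tail points
#'
#' A tail (terminal) point has exactly one 8-neighbour on the skeleton; a
#' branch pixel has three or more. Adjacent branch pixels (as produced by
#' raster thinning at nerve crossings) are merged into a single branch
#' point, placed at the cluster member nearest the cluster centroid.
#'
#' @param skeleton 1-px-wide binary matrix from [skeletonize()].
#' @return List with `branch_points` and `tail_points` (n x 2 matrices of
#'   0-based `(row, col)`), and `branch_pixels`, the full set of raw branch
#'   pixels before cluster merging (used by [extract_segments()]).
#' @export
classify_nodes <- function(skeleton) {
  m <- nq_as_raster(skeleton)
  nq_check(all(m %in% c(0, 1)), "skeleton", "must be binary")
  nq_check(!nq_has_2x2(m), "skeleton",
           "not 1 px wide (2x2 block found); run skeletonize() first")
  n <- nq_neighbour_count(m)
  tails <- which(m == 1L & n == 1L, arr.ind = TRUE)
  raw_branch <- which(m == 1L & n >= 3L, arr.ind = TRUE)
  branch <- nq_merge_clusters(raw_branch, dim(m))
  list(branch_points = branch - 1L,
       tail_points = unname(tails) - 1L,
       branch_pixels = unname(raw_branch) - 1L)
}

# merge 8-adjacent pixels into clusters, one representative per cluster
nq_merge_clusters <- function(pix, dims) {
  if (nrow(pix) == 0) return(matrix(integer(0), 0, 2))
  key <- (pix[, 2] - 1) * dims[1] + pix[, 1]
  keyset <- new.env(hash = TRUE)
  for (k in key) assign(as.character(k), TRUE, envir = keyset)
  seen <- rep(FALSE, nrow(pix))
  names(seen) <- as.character(key)
  reps <- NULL
  for (i in seq_len(nrow(pix))) {
    k0 <- as.character(key[i])
    if (seen[k0]) next
    queue <- list(pix[i, ])
    seen[k0] <- TRUE
    members <- NULL
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, p)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        q <- c(p[1] + dr, p[2] + dc)
        kq <- as.character((q[2] - 1) * dims[1] + q[1])
        if (!is.null(keyset[[kq]]) && !isTRUE(seen[kq])) {
          seen[kq] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    cen <- colMeans(members)
    d2 <- (members[, 1] - cen[1])^2 + (members[, 2] - cen[2])^2
    reps <- rbind(reps, members[which.min(d2), ])
  }
  unname(reps)
}

#' Extract nerve segments from a skeleton
#'
#' Segments are the maximal branch-free 8-connected paths of the skeleton:
#' removing the branch pixels leaves simple paths (or node-free loops), each
#' reported once as an ordered pixel path. A path end that touches a branch
#' cluster is extended by that branch pixel, so segments run node-to-node
#' and their lengths include the step into the junction. Paths are oriented
#' from their lexicographically smaller endpoint and the list is sorted by
#' start pixel.
#'
#' @param skeleton 1-px binary matrix.
#' @param nodes Result of [classify_nodes()] on the same skeleton.
#' @return List of paths; each an n x 2 matrix of 0-based `(row, col)`
#'   pixels, consecutive pixels 8-adjacent. Loops close implicitly (the
#'   first pixel is not repeated).
#' @export
extract_segments <- function(skeleton, nodes) {
  m <- nq_as_raster(skeleton)
  work <- matrix(as.integer(m), nrow(m), ncol(m))
  bp <- nodes$branch_pixels + 1L
  if (nrow(bp) > 0) work[bp] <- 0L
  H <- nrow(work); W <- ncol(work)
  deg <- nq_neighbour_count(work) * work
  remaining <- work
  segs <- list()
  neighbours <- function(p) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W && remaining[r, c] == 1L) {
        out <- rbind(out, c(r, c))
      }
    }
    out
  }
  trace_from <- function(start) {
    path <- matrix(start, 1, 2)
    remaining[start[1], start[2]] <<- 0L
    cur <- start
    repeat {
      nb <- neighbours(cur)
      if (is.null(nb)) break
      # prefer orthogonal moves so diagonal shortcuts past the next pixel
      # cannot skip path members
      ord <- order(abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2]))
      cur <- nb[ord[1], ]
      remaining[cur[1], cur[2]] <<- 0L
      path <- rbind(path, cur)
    }
    path
  }
  # endpoints first (components with degree-<=1 pixels), then loops
  for (pass in 1:2) {
    cand <- if (pass == 1) {
      which(remaining == 1L & deg <= 1L, arr.ind = TRUE)
    } else {
      which(remaining == 1L, arr.ind = TRUE)
    }
    if (nrow(cand) == 0) next
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- unname(cand[i, ])
      if (remaining[p[1], p[2]] == 1L) segs[[length(segs) + 1]] <- trace_from(p)
    }
  }
  extend <- function(s) {
    if (nrow(bp) == 0) return(s)
    attach_node <- function(e, avoid) {
      adj <- which(abs(bp[, 1] - e[1]) <= 1 & abs(bp[, 2] - e[2]) <= 1)
      adj <- adj[!(bp[adj, 1] == avoid[1] & bp[adj, 2] == avoid[2])]
      if (length(adj) == 0) return(NULL)
      d2 <- (bp[adj, 1] - e[1])^2 + (bp[adj, 2] - e[2])^2
      bp[adj[which.min(d2)], ]
    }
    none <- c(-9L, -9L)
    head_node <- attach_node(s[1, ], none)
    tail_node <- attach_node(s[nrow(s), ],
                             if (is.null(head_node)) none else head_node)
    if (!is.null(head_node)) s <- rbind(head_node, s)
    if (!is.null(tail_node)) s <- rbind(s, tail_node)
    s
  }
  segs <- lapply(segs, function(s) {
    s <- extend(s)
    a <- s[1, ]; b <- s[nrow(s), ]
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) s <- s[nrow(s):1, , drop = FALSE]
    unname(s) - 1L
  })
  starts <- t(vapply(segs, function(s) s[1, ], numeric(2)))
  if (length(segs) > 1) segs <- segs[order(starts[, 1], starts[, 2])]
  segs
}

#' Geodesic length of a pixel path in micrometres
#'
#' Steps between 8-adjacent pixels count 1 (orthogonal) or `sqrt(2)`
#' (diagonal) pixel pitches; a single pixel has length 0.
#'
#' @param path n x 2 matrix of `(row, col)` pixels, consecutive rows
#'   8-adjacent.
#' @param pixel_size_um Pixel pitch in micrometres per pixel.
#' @return Length in micrometres.
#' @export
path_length_um <- function(path, pixel_size_um) {
  nq_check(is.matrix(path) && ncol(path) == 2, "path", "must be n x 2")
  nq_check(pixel_size_um > 0, "pixel_size_um", "must be positive")
  if (nrow(path) < 2) return(0)
  d <- abs(diff(path))
  nq_check(all(d <= 1) && all(rowSums(d) > 0), "path",
           "consecutive pixels must be distinct and 8-adjacent")
  sum(sqrt(d[, 1]^2 + d[, 2]^2)) * pixel_size_um
}

#' Box-counting fractal dimension of a binary pattern
#'
#' Counts occupied boxes on grid-aligned partitions at dyadic box sizes
#' (2, 4, ..., `min(dim)/4`) and returns the least-squares slope of
#' `log N(eps)` against `log(1/eps)`. For planar sets the value lies in
#' `[0, 2]`: a straight line scores ~1, a filled region ~2.
#'
#' @param skeleton Non-empty binary matrix (typically the skeleton).
#' @return The slope (dimensionless).
#' @export
fractal_number <- function(skeleton) {
  m <- nq_as_raster(skeleton)
  pix <- which(m == 1L, arr.ind = TRUE)
  nq_check(nrow(pix) > 0, "skeleton", "fractal dimension undefined for an empty raster")
  max_eps <- min(dim(m)) / 4
  sizes <- 2^(1:30)
  sizes <- sizes[sizes <= max_eps]
  nq_check(length(sizes) >= 2, "skeleton",
           "raster too small for box counting (need min dim >= 16)")
  counts <- vapply(sizes, function(eps) {
    length(unique((pix[, 1] - 1) %/% eps * 10^9 + (pix[, 2] - 1) %/% eps))
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Quantify clinical nerve variables from a binary segmentation
#'
#' Composes [skeletonize()], [classify_nodes()], [extract_segments()] and
#' [path_length_um()] into the per-image clinical record: total nerve fibre
#' length, branch/tail point counts, segment count, mean and SD of segment
#' length, and the box-counting fractal number of the skeleton. Nerve fibre
#' density (mm per mm^2 of field) is included as a convenience.
#'
#' Two raster artifacts are cleaned before measurement. Tiny enclosed
#' background holes (up to `fill_holes_px` pixels), which a jagged stroke
#' boundary encloses and which thinning would otherwise turn into spurious
#' skeleton loops, are filled; genuine nerve loops enclose far larger areas
#' and are untouched. Short side-spurs -- segments shorter than `prune_px`
#' running from a tail into a branch cluster -- are removed. Set either
#' parameter to 0 to disable.
#'
#' @param mask Binary matrix or [annotation_mask].
#' @param pixel_size_um Pixel pitch in micrometres per pixel (required when
#'   `mask` is a plain matrix or carries no pitch).
#' @param prune_px Spur-pruning threshold in pixels (geodesic length).
#' @param fill_holes_px Maximum area (pixels) of background holes to fill.
#' @return An object of class `morphometry_record`: `total_length_um`,
#'   `n_branch`, `n_tail`, `n_segments`, `mean_segment_length_um`,
#'   `sd_segment_length_um`, `fractal_number` (NA for an empty mask) and
#'   `density_mm_per_mm2`.
#' @export
quantify <- function(mask, pixel_size_um = NULL, prune_px = 4,
                     fill_holes_px = 16) {
  px <- nq_as_raster(mask)
  if (is.null(pixel_size_um) && inherits(mask, "annotation_mask")) {
    pixel_size_um <- mask$pixel_size_um[1]
  }
  nq_check(!is.null(pixel_size_um) && !is.na(pixel_size_um) && pixel_size_um > 0,
           "pixel_size_um", "unknown pixel pitch")
  area_mm2 <- prod(dim(px)) * (pixel_size_um / 1000)^2
  if (sum(px) == 0) {
    return(nq_record(0, 0L, 0L, 0L, 0, 0, NA_real_, 0))
  }
  px <- nq_fill_small_holes(px, fill_holes_px)
  skel <- skeletonize(px)
  skel <- nq_prune_spurs(skel, prune_px)
  nodes <- classify_nodes(skel)
  segs <- extract_segments(skel, nodes)
  lens <- vapply(segs, function(s) path_length_um(s + 1L, pixel_size_um),
                 numeric(1))
  total <- sum(lens)
  nq_record(total,
            nrow(nodes$branch_points), nrow(nodes$tail_points),
            length(segs),
            if (length(lens)) mean(lens) else 0,
            if (length(lens) > 1) sd(lens) else 0,
            fractal_number(skel),
            (total / 1000) / area_mm2)
}

# fill enclosed background components of at most max_px pixels
nq_fill_small_holes <- function(px, max_px) {
  if (max_px <= 0 || sum(px) == 0) return(px)
  m <- matrix(as.integer(px), nrow(px), ncol(px))
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m))))
  holes <- t(filled) - m
  if (sum(holes) == 0) return(m)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(holes)))))
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes <= max_px)
  m[lab %in% small & holes == 1] <- 1L
  m
}

# remove skeleton spurs: segments shorter than prune_px (geodesic, px)
# running from a tail into a branch cluster are thinning artifacts of a
# jagged mask boundary, not nerve branches
nq_prune_spurs <- function(skel, prune_px, max_iter = 4L) {
  if (prune_px <= 0) return(skel)
  for (it in seq_len(max_iter)) {
    nodes <- classify_nodes(skel)
    bp <- nodes$branch_pixels
    if (nrow(bp) == 0) break
    segs <- extract_segments(skel, nodes)
    deg <- nq_neighbour_count(skel)
    bkey <- (bp[, 2]) * nrow(skel) + bp[, 1]          # 0-based keys
    removed <- FALSE
    for (s in segs) {
      npix <- nrow(s)
      len <- if (npix >= 2) sum(sqrt(rowSums(diff(s)^2))) else 0
      if (len >= prune_px || npix < 2) next
      endeg <- deg[s[c(1, npix), , drop = FALSE] + 1L]
      # spur: runs from a tail into a branch cluster; delete the spur
      # pixels but keep the junction pixel itself
      if (any(endeg == 1) && any(endeg >= 3)) {
        is_node <- (s[, 2] * nrow(skel) + s[, 1]) %in% bkey
        drop_px <- s[!is_node, , drop = FALSE]
        if (nrow(drop_px) > 0) {
          skel[drop_px + 1L] <- 0L
          removed <- TRUE
        }
      }
    }
    if (!removed) break
    skel <- skeletonize(skel)
  }
  skel
}

nq_record <- function(total, nb, nt, ns, mu, sdv, frac, dens) {
  structure(list(total_length_um = total, n_branch = as.integer(nb),
                 n_tail = as.integer(nt), n_segments = as.integer(ns),
                 mean_segment_length_um = mu, sd_segment_length_um = sdv,
                 fractal_number = frac, density_mm_per_mm2 = dens),
            class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_record> total %.1f um | %d branch, ",
                     "%d tail, %d segments | mean seg %.1f um | fractal %s\n"),
              x$total_length_um, x$n_branch, x$n_tail, x$n_segments,
              x$mean_segment_length_um,
              ifelse(is.na(x$fractal_number), "NA",
                     sprintf("%.3f", x$fractal_number))))
  invisible(x)
}

#' @export
as.data.frame.morphometry_record <- function(x, ...) {
  data.frame(total_length_um = x$total_length_um, n_branch = x$n_branch,
             n_tail = x$n_tail, n_segments = x$n_segments,
             mean_segment_length_um = x$mean_segment_length_um,
             sd_segment_length_um = x$sd_segment_length_um,
             fractal_number = x$fractal_number,
             density_mm_per_mm2 = x$density_mm_per_mm2)
}
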