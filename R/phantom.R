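#' Specification of a CCM nerve phantom
#'
#' Parameters of the synthetic sub-basal-plexus phantom: bright curvilinear
#' branching fibres traced by a persistent random walk on a noisy,
#' non-uniformly illuminated background, with exact ground truth kept as
#' sub-pixel polylines. Walks start at random border points (nerves entering
#' the field of view) and terminate at the frame edge, when their step
#' budget runs out, or when they would come within about one fibre width of
#' a previously drawn fibre — sub-basal nerve fibres run roughly parallel
#' and rarely cross.
#'
#' @param image_size Frame side in pixels.
#' @param pixel_size_um Pixel pitch, micrometres per pixel.
#' @param n_trees Number of nerve trees to seed.
#' @param branch_prob Per-step probability of spawning a branch.
#' @param step_len_px Walk step length in pixels.
#' @param curvature_sigma SD of the per-step heading change, radians.
#' @param fibre_width_px Full stroke width in pixels (odd).
#' @param noise_sigma SD of additive Gaussian intensity noise.
#' @param illum_gradient Peak-to-trough fraction of the low-frequency
#'   illumination background.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 384L, pixel_size_um = 1.04,
                         n_trees = 5L, branch_prob = 0.05,
                         step_len_px = 2, curvature_sigma = 0.25,
                         fibre_width_px = 3L, noise_sigma = 0.08,
                         illum_gradient = 0.3, seed = 1L) {
  nq_check(image_size > 0, "image_size", "must be > 0")
  nq_check(pixel_size_um > 0, "pixel_size_um", "must be > 0")
  nq_check(n_trees >= 0, "n_trees", "must be >= 0")
  nq_check(branch_prob >= 0 && branch_prob < 1, "branch_prob",
           "must be in [0, 1)")
  nq_check(step_len_px > 0, "step_len_px", "must be > 0")
  nq_check(curvature_sigma >= 0, "curvature_sigma", "must be >= 0")
  nq_check(fibre_width_px >= 1, "fibre_width_px", "must be >= 1")
  nq_check(fibre_width_px %% 2 == 1, "fibre_width_px",
           "must be odd (symmetric stroke)")
  nq_check(noise_sigma >= 0, "noise_sigma", "must be >= 0")
  nq_check(illum_gradient >= 0 && illum_gradient <= 1, "illum_gradient",
           "must be in [0, 1]")
  nq_check(length(seed) == 1 && is.finite(seed), "seed", "must be an integer")
  structure(list(image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um, n_trees = as.integer(n_trees),
                 branch_prob = branch_prob, step_len_px = step_len_px,
                 curvature_sigma = curvature_sigma,
                 fibre_width_px = as.integer(fibre_width_px),
                 noise_sigma = noise_sigma, illum_gradient = illum_gradient,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# grow one nerve tree as a list of polylines (sub-pixel (row, col) points);
# `occupied` is the n x 2 matrix of already-drawn centreline points of
# OTHER trees; returns polylines plus the branch-event count
nq_grow_tree <- function(spec, occupied) {
  S <- spec$image_size
  # minimum centreline separation so dilated strokes stay disjoint even
  # after sub-pixel rounding: stroke width + diagonal dilation reach +
  # one-pixel clearance
  buffer <- spec$fibre_width_px + 2.5
  # an arm only counts as a branch once its tip clears the junction
  # neighbourhood (the collision-exemption zone around its spawn point)
  min_arm <- ceiling((2 * buffer + 2 * spec$step_len_px) / spec$step_len_px) + 1L
  inside <- function(p) all(p >= 0) && all(p <= S - 1)
  # seed on a random border, heading inward
  side <- sample.int(4, 1)
  u <- runif(1, 0.05, 0.95) * (S - 1)
  start <- switch(side, c(0, u), c(S - 1, u), c(u, 0), c(u, S - 1))
  heading <- switch(side, pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, 0.4)
  if (!is.null(occupied) && nrow(occupied) > 0) {
    d2 <- (occupied[, 1] - start[1])^2 + (occupied[, 2] - start[2])^2
    if (min(d2) < buffer^2) return(NULL)   # seed too close to a fibre
  }
  own <- matrix(numeric(0), 0, 2)
  own_ids <- integer(0)
  records <- list()                   # kept walker paths with lineage info
  void_ids <- integer(0)
  # walker queue; only the PARENT walker's trail near the spawn point is
  # exempt from own-tree collision (sibling arms still block each other)
  walkers <- list(list(pos = start, heading = heading,
                       budget = sample(60:150, 1), is_root = TRUE,
                       id = 1L, parent_id = 0L, spawn_row = 0L))
  next_id <- 2L
  while (length(walkers) > 0) {
    w <- walkers[[1]]; walkers <- walkers[-1]
    if (w$parent_id %in% void_ids) {  # parent arm was voided: orphan
      void_ids <- c(void_ids, w$id)
      next
    }
    path <- matrix(w$pos, 1, 2)
    pos <- w$pos; hd <- w$heading
    steps <- 0L
    spawn <- w$pos
    last_branch <- -10L
    escaped <- FALSE   # exemption only while first leaving the spawn zone
    blocked_own <- FALSE
    trail_skip <- ceiling(2 * buffer / spec$step_len_px) + 1L
    while (steps < w$budget) {
      hd <- hd + rnorm(1, 0, spec$curvature_sigma)
      nxt <- pos + spec$step_len_px * c(sin(hd), cos(hd))
      if (!inside(nxt)) break
      blocked <- FALSE
      if (nrow(occupied) > 0) {       # other trees: strict
        d2 <- (occupied[, 1] - nxt[1])^2 + (occupied[, 2] - nxt[2])^2
        if (min(d2) < buffer^2) blocked <- TRUE
      }
      if (!blocked && nrow(own) > 0) { # earlier walkers of this tree
        d2 <- (own[, 1] - nxt[1])^2 + (own[, 2] - nxt[2])^2
        exempt <- if (escaped) FALSE else {
          own_ids == w$parent_id &
            (own[, 1] - spawn[1])^2 + (own[, 2] - spawn[2])^2 < (2 * buffer)^2
        }
        if (any(d2 < buffer^2 & !exempt)) {
          blocked <- TRUE
          blocked_own <- TRUE
        }
      }
      if (!blocked && nrow(path) > trail_skip) {  # own trail, minus recent
        old <- path[seq_len(nrow(path) - trail_skip), , drop = FALSE]
        d2 <- (old[, 1] - nxt[1])^2 + (old[, 2] - nxt[2])^2
        if (min(d2) < buffer^2) blocked <- TRUE
      }
      if (blocked) break
      pos <- nxt
      path <- rbind(path, pos)
      steps <- steps + 1L
      if (!escaped &&
          sum((pos - spawn)^2) > (2 * buffer + spec$step_len_px)^2) {
        escaped <- TRUE
      }
      if (steps > 8 && steps - last_branch > 5 &&
          runif(1) < spec$branch_prob && length(walkers) < 6) {
        last_branch <- steps
        dev <- min(max(0.6 + rnorm(1, 0, 0.15), 0.45), 0.9)
        walkers[[length(walkers) + 1]] <-
          list(pos = pos, heading = hd + sample(c(-1, 1), 1) * dev,
               budget = sample(30:90, 1), is_root = FALSE,
               id = next_id, parent_id = w$id, spawn_row = nrow(path))
        next_id <- next_id + 1L
      }
    }
    # an arm absorbed by its own tree while still short never resolves as
    # a distinct branch in the raster; void it (truth and drawing alike)
    if (nrow(path) >= min_arm &&
        !(blocked_own && nrow(path) < min_arm + 4L)) {
      records[[length(records) + 1]] <-
        list(path = path, id = w$id, parent_id = w$parent_id,
             spawn_row = w$spawn_row, is_root = w$is_root)
      own <- rbind(own, path)
      own_ids <- c(own_ids, rep(w$id, nrow(path)))
    } else {
      void_ids <- c(void_ids, w$id)
    }
  }
  if (length(records) == 0) return(NULL)
  # a parent that dies within min_arm steps of its last branch spawn
  # leaves a stub that cannot resolve from the child's stroke: drop the
  # stub and splice the child onto the parent as its continuation
  # (children processed first, so merges cascade outward)
  ids <- function() vapply(records, `[[`, 0L, "id")
  for (ri in rev(seq_along(records))) {
    rec <- records[[ri]]
    if (rec$is_root) next
    pi <- which(ids() == rec$parent_id)
    if (length(pi) != 1) next
    par <- records[[pi]]
    is_last_spawn <- rec$spawn_row == max(vapply(records, function(x)
      if (!x$is_root && x$parent_id == par$id) x$spawn_row else -1L, 0L))
    if (nrow(par$path) - rec$spawn_row < min_arm && is_last_spawn) {
      records[[pi]]$path <- rbind(par$path[seq_len(rec$spawn_row), ],
                                  rec$path[-1, , drop = FALSE])
      # re-attach the spliced child's own arms to the merged polyline
      for (ci in seq_along(records)) {
        if (!records[[ci]]$is_root && records[[ci]]$parent_id == rec$id) {
          records[[ci]]$parent_id <- par$id
          records[[ci]]$spawn_row <- rec$spawn_row + records[[ci]]$spawn_row - 1L
        }
      }
      records[[ri]] <- NULL
    }
  }
  polylines <- lapply(records, `[[`, "path")
  n_branch <- sum(vapply(records, function(x) !x$is_root, logical(1)))
  list(polylines = polylines, n_branch = n_branch, points = own)
}

# Bresenham rasterisation of a polyline onto a logical raster (1-based)
nq_rasterise_polyline <- function(poly, raster) {
  pts <- round(poly) + 1L
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    nstep <- max(abs(b - a), 1)
    rr <- round(seq(a[1], b[1], length.out = nstep + 1))
    cc <- round(seq(a[2], b[2], length.out = nstep + 1))
    raster[cbind(rr, cc)] <- 1L
  }
  if (nrow(pts) == 1) raster[pts] <- 1L
  raster
}

#' Generate a CCM-like nerve phantom with exact ground truth
#'
#' Draws `n_trees` branching fibre trees, rasterises their centrelines,
#' dilates them to the stroke width for the mask, and renders an intensity
#' image as background (constant + low-frequency illumination gradient +
#' i.i.d. Gaussian noise) plus a Gaussian cross-section fibre profile,
#' clipped to `[0, 1]`. Ground-truth morphometry is computed from the
#' generating polylines, never from the raster: total length is the chord
#' sum in micrometres; each branch event contributes one branch point, two
#' extra segments and one extra tail.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (a [ccm_image]) and `truth`, a `phantom_truth`
#'   object: `mask` (0/1 matrix), `centreline` (0/1 matrix),
#'   `centreline_polylines` (list of n x 2 sub-pixel `(row, col)` matrices,
#'   0-based), `true_total_length_um`, `true_n_branch`, `true_n_tail`,
#'   `true_n_segments`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  polylines <- list()
  n_branch <- 0L
  n_tail <- 0L
  n_poly <- 0L
  occupied <- matrix(numeric(0), 0, 2)
  for (i in seq_len(spec$n_trees)) {
    set.seed((spec$seed + 104729 * i) %% .Machine$integer.max)
    tree <- nq_grow_tree(spec, occupied)
    if (is.null(tree)) next
    polylines <- c(polylines, tree$polylines)
    n_branch <- n_branch + tree$n_branch
    n_poly <- n_poly + length(tree$polylines)
    n_tail <- n_tail + length(tree$polylines) + 1L  # arms' tips + root end
    occupied <- rbind(occupied, tree$points)
  }
  n_segments <- n_poly + n_branch
  total_um <- 0
  centre <- matrix(0L, S, S)
  for (p in polylines) {
    total_um <- total_um + sum(sqrt(rowSums(diff(p)^2))) * spec$pixel_size_um
    centre <- nq_rasterise_polyline(p, centre)
  }
  mask <- if (spec$fibre_width_px > 1 && sum(centre) > 0) {
    brush <- EBImage::makeBrush(spec$fibre_width_px, shape = "disc")
    t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(centre)), brush)))
  } else {
    centre
  }
  mask <- matrix(as.integer(mask > 0), S, S)

  set.seed((spec$seed + 777777) %% .Machine$integer.max)
  rr <- matrix(seq_len(S), S, S) / S
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) / S
  phase <- runif(2, 0, 2 * pi)
  illum <- sin(2 * pi * (0.7 * rr + 0.4 * cc) + phase[1]) +
    0.5 * sin(2 * pi * (0.3 * rr - 0.6 * cc) + phase[2])
  illum <- (illum - min(illum)) / max(max(illum) - min(illum), 1e-12)
  bg <- 0.30 + spec$illum_gradient * (illum - 0.5)
  img <- bg + rnorm(S * S, 0, spec$noise_sigma)
  if (sum(centre) > 0) {
    dist <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(1 - centre)))))
    sig <- max(spec$fibre_width_px / 2, 0.8)
    img <- img + 0.45 * exp(-dist^2 / (2 * sig^2))
  }
  img <- pmin(pmax(img, 0), 1)

  truth <- structure(list(
    mask = mask, centreline = centre,
    centreline_polylines = polylines,
    true_total_length_um = total_um,
    true_n_branch = n_branch,
    true_n_tail = if (n_poly > 0) n_tail else 0L,
    true_n_segments = n_segments), class = "phantom_truth")
  list(image = ccm_image(img, spec$pixel_size_um,
                         sprintf("phantom-seed%d", spec$seed)),
       truth = truth)
}

#' Generate a labelled two-group phantom cohort
#'
#' Emulates a healthy-vs-neuropathy contrast: the neuropathy spec typically
#' uses fewer or shorter trees, so group means of true total nerve length
#' differ in the direction the specs imply (nerve loss lowers total length).
#' Per-image seeds are derived from each spec's own seed and the image
#' index, so identical specs yield identical images across groups.
#'
#' @param spec_healthy,spec_neuropathy [phantom_spec]s for the two groups.
#' @param n_per_group Images per group (>= 1).
#' @param seed Integer cohort seed folded into every per-image seed.
#' @return List of records `list(image, truth, group)` with
#'   `group` in `c("healthy", "neuropathy")`, of length `2 * n_per_group`.
#' @export
generate_cohort <- function(spec_healthy, spec_neuropathy, n_per_group,
                            seed = 1L) {
  stopifnot(inherits(spec_healthy, "phantom_spec"),
            inherits(spec_neuropathy, "phantom_spec"))
  nq_check(n_per_group >= 1, "n_per_group", "must be >= 1")
  one <- function(spec, i, group) {
    s <- spec
    s$seed <- as.integer((spec$seed + 131L * seed + 7919L * i) %%
                           .Machine$integer.max)
    ph <- generate_phantom(s)
    list(image = ph$image, truth = ph$truth, group = group)
  }
  c(lapply(seq_len(n_per_group), function(i) one(spec_healthy, i, "healthy")),
    lapply(seq_len(n_per_group), function(i)
      one(spec_neuropathy, i, "neuropathy")))
}

#' Write a phantom cohort to disk
#'
#' Writes each image as an 8-bit greyscale PNG (or TIFF), the mask as a
#' 0/255 PNG, the ground truth as a JSON sidecar, and a CSV manifest with
#' columns `image_path, mask_path, group_label`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    img_path <- file.path(dir, sprintf("phantom_%03d.%s", i, format))
    mask_path <- file.path(dir, sprintf("phantom_%03d_mask.png", i))
    write_grey_image(rec$image, img_path)
    write_grey_image(rec$truth$mask, mask_path)
    truth <- rec$truth
    jsonlite::write_json(
      list(true_total_length_um = truth$true_total_length_um,
           true_n_branch = truth$true_n_branch,
           true_n_tail = truth$true_n_tail,
           true_n_segments = truth$true_n_segments,
           pixel_size_um = rec$image$pixel_size_um[1]),
      file.path(dir, sprintf("phantom_%03d_truth.json", i)),
      auto_unbox = TRUE, digits = NA)
    data.frame(image_path = img_path, mask_path = mask_path,
               group_label = rec$group)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
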