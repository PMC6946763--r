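#' Plan a train/test split at the image level
#'
#' Seeded random permutation (R's default Mersenne-Twister generator)
#' followed by a prefix cut at `floor(fraction * n)`. When `subject_ids`
#' are supplied, whole subjects are assigned to one side so that no
#' subject contributes images to both: subjects are permuted and taken
#' into the training side while the cumulative image count stays within
#' the target.
#'
#' @param ids Character or integer image ids (n >= 2).
#' @param fraction Training fraction, strictly between 0 and 1 (~0.9).
#' @param seed Integer seed.
#' @param subject_ids Optional vector, same length as `ids`.
#' @return An object of class `split_plan`: `train_ids`, `test_ids`,
#'   `seed`, `split_fraction`.
#' @export
make_split <- function(ids, fraction = 0.9, seed = 1L, subject_ids = NULL) {
  nq_check(length(ids) >= 2, "ids", "need at least 2 images")
  nq_check(!anyDuplicated(ids), "ids", "image ids must be unique")
  nq_check(fraction > 0 && fraction < 1, "fraction", "must be in (0, 1)")
  set.seed(seed)
  n_train <- floor(fraction * length(ids))
  if (is.null(subject_ids)) {
    perm <- sample(ids)
    train <- perm[seq_len(n_train)]
  } else {
    nq_check(length(subject_ids) == length(ids), "subject_ids",
             "must match ids in length")
    subj <- sample(unique(subject_ids))
    counts <- table(subject_ids)[subj]
    keep <- subj[cumsum(counts) <= n_train]
    train <- ids[subject_ids %in% keep]
  }
  test <- setdiff(ids, train)
  nq_check(length(train) >= 1 && length(test) >= 1, "fraction",
           "fraction leaves one side of the split empty")
  structure(list(train_ids = train, test_ids = test,
                 seed = as.integer(seed), split_fraction = fraction),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (fraction %.3g, seed %d)\n",
              length(x$train_ids), length(x$test_ids),
              x$split_fraction, x$seed))
  invisible(x)
}

#' Segment and quantify a set of images
#'
#' Runs the full quantification for each image: (standardised) image ->
#' ensemble or single-model segmentation -> skeleton morphometry. Writes
#' one CSV row per image and, optionally, an overlay PNG drawing the
#' segmented centrelines (red) with branch (blue) and tail (green)
#' markers over the image.
#'
#' @param image_paths Character vector of image files, or a list of
#'   [ccm_image]s.
#' @param model A [nerve_ensemble] or single [build_unet()] model.
#' @param out_dir Output directory for `morphometry.csv` and overlays;
#'   `NULL` for no files.
#' @param pixel_size_um Pitch assumed for images that carry none.
#' @param write_overlays Write overlay PNGs next to the CSV.
#' @param ... Passed to [predict_ensemble()] / [predict_image()]
#'   (`patch_px`, `stride_px`, ...).
#' @return Data frame with `image_id` plus the morphometry columns.
#'   Unreadable images are skipped with a warning; if all fail, an error.
#' @export
run_quantify <- function(image_paths, model, out_dir = NULL,
                         pixel_size_um = 1.04, write_overlays = FALSE, ...) {
  nq_check(length(image_paths) >= 1, "image_paths", "no images supplied")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(image_paths)) {
    item <- if (is.list(image_paths)) image_paths[[i]] else image_paths[i]
    res <- tryCatch({
      img <- if (inherits(item, "ccm_image")) item
             else load_ccm_image(item)
      if (anyNA(img$pixel_size_um)) img$pixel_size_um <- rep(pixel_size_um, 2)
      mask <- if (inherits(model, "nerve_ensemble")) {
        predict_ensemble(model, img, ...)
      } else {
        predict_image(model, img, ...)
      }
      rec <- quantify(mask, img$pixel_size_um[1])
      id <- if (inherits(item, "ccm_image")) {
        if (nzchar(item$source_id)) item$source_id else sprintf("image_%03d", i)
      } else {
        tools::file_path_sans_ext(basename(item))
      }
      if (isTRUE(write_overlays) && !is.null(out_dir)) {
        nq_write_overlay(img, mask,
                         file.path(out_dir, paste0(id, "_overlay.png")))
      }
      cbind(data.frame(image_id = id), as.data.frame(rec))
    }, error = function(e) {
      warning(sprintf("skipping image %d: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  nq_check(length(rows) > 0, "image_paths", "all images failed to process")
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(out, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
  }
  out
}

# overlay in the annotation style: centrelines red, branch points blue,
# tail points green (3x3 squares)
nq_write_overlay <- function(image, mask, path) {
  px <- nq_as_raster(image)
  skel <- skeletonize(mask)
  nodes <- classify_nodes(skel)
  H <- nrow(px); W <- ncol(px)
  r <- px; g <- px; b <- px
  r[skel == 1] <- 1; g[skel == 1] <- 0; b[skel == 1] <- 0
  stamp <- function(pts, cr, cg, cb) {
    for (i in seq_len(nrow(pts))) {
      rr <- pmax(1, pmin(H, pts[i, 1] + 1 + (-1:1)))
      cc <- pmax(1, pmin(W, pts[i, 2] + 1 + (-1:1)))
      r[rr, cc] <<- cr; g[rr, cc] <<- cg; b[rr, cc] <<- cb
    }
  }
  stamp(nodes$branch_points, 0, 0, 1)
  stamp(nodes$tail_points, 0, 1, 0)
  arr <- array(c(t(r), t(g), t(b)), dim = c(W, H, 3))
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path,
                      bits.per.sample = 8L)
  invisible(path)
}

#' Validate automated quantification against manual annotation
#'
#' Joins the method's and the manual per-image tables on `image_id` and
#' reports, per variable, the error summary (RMSE/SD), ICC(2,1) with its
#' reliability band, and the Bland-Altman limits of agreement. When group
#' labels are supplied, total nerve length is additionally evaluated as a
#' neuropathy classifier (ROC/AUC with Youden cut).
#'
#' @param method_df,manual_df Data frames with `image_id` plus morphometry
#'   columns (as from [run_quantify()]).
#' @param labels_df Optional data frame with `image_id` and `group_label`
#'   (binary; the second factor level or 1 = neuropathy).
#' @param variables Morphometry columns to compare.
#' @return List with `agreement` (one row per variable: rmse, sd, icc,
#'   band, mean_diff, loa_low, loa_high, n) and `roc` (a `roc_result` or
#'   `NULL`).
#' @export
run_validate <- function(method_df, manual_df, labels_df = NULL,
                         variables = c("total_length_um",
                                       "mean_segment_length_um", "n_branch",
                                       "n_tail", "n_segments",
                                       "fractal_number")) {
  j <- merge(method_df, manual_df, by = "image_id",
             suffixes = c(".m", ".a"))
  nq_check(nrow(j) >= 3, "method_df",
           "join on image_id yields fewer than 3 rows")
  rows <- lapply(variables, function(v) {
    s <- measure_series(j[[paste0(v, ".m")]], j[[paste0(v, ".a")]], v)
    es <- error_summary(s)
    ic <- icc_absolute(s)
    ba <- bland_altman(s)
    data.frame(variable = v, n = es$n, rmse = es$rmse, sd = es$sd,
               mean_diff = ba$mean_diff, loa_low = ba$loa_low,
               loa_high = ba$loa_high, icc = ic$icc, band = ic$band)
  })
  roc <- NULL
  if (!is.null(labels_df)) {
    jl <- merge(method_df, labels_df, by = "image_id")
    roc <- roc_analysis(jl$total_length_um, jl$group_label)
  }
  list(agreement = do.call(rbind, rows), roc = roc)
}
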