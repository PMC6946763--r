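#' Paired per-image measurement series
#'
#' Holds one morphometry variable measured on the same images by an
#' automated method and by manual annotation, for agreement statistics.
#'
#' @param v_method Numeric vector, the automated method's values.
#' @param v_manual Numeric vector, the manual-annotation values (same
#'   images, same order).
#' @param variable_name Which morphometry variable the values are.
#' @return An object of class `measure_series`.
#' @export
measure_series <- function(v_method, v_manual, variable_name = "") {
  nq_check(length(v_method) == length(v_manual), "v_method",
           "method and manual series differ in length")
  nq_check(length(v_method) >= 2, "v_method", "need n >= 2")
  nq_check(!anyNA(v_method) && !anyNA(v_manual), "v_method",
           "missing values not allowed")
  structure(list(v_method = as.numeric(v_method),
                 v_manual = as.numeric(v_manual),
                 variable_name = variable_name),
            class = "measure_series")
}

#' Error summary of a method against manual annotation
#'
#' For per-image errors `V_i = v_method_i - v_manual_i`:
#' `RMSE = sqrt(mean(V^2))` and `SD = sqrt(sum((V - mean(V))^2) / (n - 1))`
#' (sample SD). Lower values indicate closer agreement with the manual
#' annotation.
#'
#' @param series A [measure_series].
#' @return An object of class `error_summary`: `rmse`, `sd`, `v_bar`
#'   (mean error), `n`.
#' @export
error_summary <- function(series) {
  stopifnot(inherits(series, "measure_series"))
  V <- series$v_method - series$v_manual
  structure(list(rmse = sqrt(mean(V^2)), sd = sd(V), v_bar = mean(V),
                 n = length(V), variable_name = series$variable_name),
            class = "error_summary")
}

#' Intraclass correlation, absolute agreement, single measures
#'
#' ICC(2,1): two-way random effects, absolute agreement, single rater,
#' computed from the ANOVA mean squares of the n x 2 (subject x rater)
#' table. Absolute agreement penalises systematic bias, unlike the
#' consistency form. The reliability band uses the conventional cut-offs:
#' below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param series A [measure_series] with n >= 3 images.
#' @return An object of class `icc_result`: `icc`, `band`, and the mean
#'   squares `msr`, `msc`, `mse`. With zero total variance the ICC is
#'   undefined and reported as `NA` with band `"undefined"`.
#' @export
icc_absolute <- function(series) {
  stopifnot(inherits(series, "measure_series"))
  m <- cbind(series$v_method, series$v_manual)
  n <- nrow(m); k <- 2
  nq_check(n >= 3, "series", "need n >= 3 subjects")
  grand <- mean(m)
  if (all(abs(m - grand) < 1e-300)) {
    return(structure(list(icc = NA_real_, band = "undefined",
                          msr = 0, msc = 0, mse = 0), class = "icc_result"))
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  band <- if (is.na(icc)) "undefined"
  else if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
  structure(list(icc = icc, band = band, msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f (%s)\n", x$icc, x$band))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences `D = method - manual`; the limits of agreement are the mean
#' difference +/- 1.96 SD of the differences. 95% CIs use the classic
#' approximations: `SE(mean) = SD / sqrt(n)` and `SE(LoA) = SD *
#' sqrt(3 / n)`, with t(n-1) quantiles.
#'
#' @param series A [measure_series] with n >= 3.
#' @return An object of class `bland_altman`: `mean_diff`, `loa_low`,
#'   `loa_high`, `sd_diff`, `ci_mean`, `ci_loa_low`, `ci_loa_high`
#'   (each CI a length-2 vector), `n`, plus `means` and `diffs` for
#'   plotting.
#' @export
bland_altman <- function(series) {
  stopifnot(inherits(series, "measure_series"))
  D <- series$v_method - series$v_manual
  n <- length(D)
  nq_check(n >= 3, "series", "need n >= 3")
  md <- mean(D); s <- sd(D)
  loa <- c(md - 1.96 * s, md + 1.96 * s)
  tq <- qt(0.975, n - 1)
  se_mean <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(mean_diff = md, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 ci_mean = md + c(-1, 1) * tq * se_mean,
                 ci_loa_low = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_high = loa[2] + c(-1, 1) * tq * se_loa,
                 n = n,
                 means = (series$v_method + series$v_manual) / 2,
                 diffs = D),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.4g [%.4g, %.4g], LoA [%.4g, %.4g]\n",
              x$mean_diff, x$ci_mean[1], x$ci_mean[2],
              x$loa_low, x$loa_high))
  invisible(x)
}

#' ROC analysis with Youden optimal cut-point
#'
#' Builds the empirical ROC over all observed thresholds, computes AUC by
#' the trapezoid rule (equal to the Mann-Whitney concordance with ties
#' counted 1/2) and picks the cut maximising the Youden index
#' `J = sensitivity + specificity - 1` (ties broken toward higher
#' specificity). When neuropathy is flagged by LOW values of the score —
#' as for total nerve length — `direction = "auto"` (default) orients the
#' score so that AUC >= 0.5 and records the orientation.
#'
#' @param scores Numeric per-subject scores (e.g. total nerve length, um).
#' @param labels Binary group labels (0/1, logical, or a 2-level factor;
#'   1 / the second level = diseased).
#' @param direction `"auto"`, `"high"` (high score indicates disease) or
#'   `"low"`.
#' @return An object of class `roc_result`: `auc`, `curve` (data frame of
#'   threshold, sensitivity, specificity), `youden_j`, `optimal_cut` (on
#'   the original score scale), `sens_at_cut`, `spec_at_cut`, `direction`.
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  if (is.character(labels)) labels <- factor(labels)
  if (is.factor(labels)) {
    nq_check(nlevels(droplevels(labels)) == 2, "labels",
             "need exactly 2 groups")
    labels <- as.integer(droplevels(labels)) - 1L
  }
  labels <- as.integer(as.logical(labels))
  nq_check(length(scores) == length(labels), "labels", "length mismatch")
  nq_check(length(unique(labels)) == 2, "labels",
           "both classes must be present")
  build <- function(sc) {
    # classify positive when score >= threshold
    th <- sort(unique(sc), decreasing = TRUE)
    P <- sum(labels == 1); N <- sum(labels == 0)
    sens <- vapply(th, function(t) sum(sc >= t & labels == 1) / P, numeric(1))
    spec <- vapply(th, function(t) sum(sc < t & labels == 0) / N, numeric(1))
    fpr <- c(0, 1 - spec, 1)
    tpr <- c(0, sens, 1)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    list(th = th, sens = sens, spec = spec, auc = auc)
  }
  r_high <- build(scores)
  use_low <- switch(direction,
                    high = FALSE, low = TRUE,
                    auto = r_high$auc < 0.5)
  r <- if (use_low) build(-scores) else r_high
  j <- r$sens + r$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(r$spec[best])]
  cut <- if (use_low) -r$th[best] else r$th[best]
  structure(list(auc = r$auc,
                 curve = data.frame(
                   threshold = if (use_low) -r$th else r$th,
                   sensitivity = r$sens, specificity = r$spec),
                 youden_j = j[best],
                 optimal_cut = cut,
                 sens_at_cut = r$sens[best], spec_at_cut = r$spec[best],
                 direction = if (use_low) "low" else "high"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.4f (%s scores indicate disease), ",
                     "Youden J %.3f at cut %.4g (sens %.3f, spec %.3f)\n"),
              x$auc, x$direction, x$youden_j, x$optimal_cut,
              x$sens_at_cut, x$spec_at_cut))
  invisible(x)
}
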