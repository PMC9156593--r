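#' Voxel-wise precision, sensitivity and Dice
#'
#' Counts true/false positives and negatives inside the valid (non-air)
#' region and reports precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)` and
#' Dice `2tp/(2tp+fp+fn)` (the harmonic mean of precision and sensitivity on
#' shared counts). When lists of masks are given, counts are pooled across
#' cases before the ratios are formed. Undefined ratios are reported as `NA`,
#' never as 0; the counts are always included.
#'
#' @param pred,truth logical arrays (or lists of arrays) on a common grid.
#' @param valid logical array (or list) marking the evaluable region.
#' @return an object of class `voxel_metrics`: list with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `sensitivity`, `dice`.
#' @export
voxel_metrics <- function(pred, truth, valid = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (!is.null(valid) && !is.list(valid)) valid <- list(valid)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    p <- as.logical(pred[[i]])
    t <- as.logical(truth[[i]])
    v <- if (is.null(valid)) rep(TRUE, length(p)) else as.logical(valid[[i]])
    if (!any(v)) stop("empty valid mask")
    p <- p[v]; t <- t[v]
    tp <- tp + sum(p & t)
    fp <- fp + sum(p & !t)
    fn <- fn + sum(!p & t)
    tn <- tn + sum(!p & !t)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = ratio(tp, tp + fp),
                 sensitivity = ratio(tp, tp + fn),
                 dice = ratio(2 * tp, 2 * tp + fp + fn)),
            class = "voxel_metrics")
}

#' @export
print.voxel_metrics <- function(x, ...) {
  cat(sprintf(
    "voxel_metrics: precision %.3f, sensitivity %.3f, Dice %.3f (tp %d fp %d fn %d)\n",
    x$precision, x$sensitivity, x$dice, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Case-level confusion metrics
#'
#' @param tp,fp,tn,fn non-negative case counts.
#' @return list with the counts plus `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
case_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("no cases")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / total,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp)),
            class = "case_metrics")
}

#' Volume-threshold ROC analysis for stroke detection
#'
#' Varies a decision threshold over the per-case largest lesion volumes
#' (classification rule: stroke when volume > threshold), computes the ROC
#' curve and its trapezoidal AUC, and selects the operating point closest to
#' the top-left corner (0, 1); at equidistant points the higher threshold
#' (fewer false positives) wins.
#'
#' @param volumes per-case largest predicted lesion volume (mL).
#' @param labels per-case stroke status (logical, or `"stroke"`/`"control"`).
#' @return an object of class `roc_result`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `optimal_threshold`, `optimal_point`.
#' @export
roc_volume_threshold <- function(volumes, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "stroke"
  labels <- as.logical(labels)
  if (length(volumes) != length(labels)) stop("length mismatch")
  if (all(labels) || !any(labels))
    stop("both classes must be present for a ROC curve")
  thr <- c(-Inf, sort(unique(volumes)), Inf)
  npos <- sum(labels)
  nneg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(volumes > t & labels) / npos, 1)
  fpr <- vapply(thr, function(t) sum(volumes > t & !labels) / nneg, 1)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  dist <- sqrt(fpr^2 + (1 - tpr)^2)
  finite_thr <- ifelse(is.finite(thr), thr, c(min(volumes) - 1, thr[-1]))
  best <- which(dist == min(dist))
  best <- best[which.max(finite_thr[best])]  # ties: prefer higher threshold
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 optimal_threshold = thr[best],
                 optimal_point = c(fpr = fpr[best], tpr = tpr[best])),
            class = "roc_result")
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples cases with replacement, each stratum separately at its original
#' size (e.g. equal numbers of strokes and nonstrokes in every resample), and
#' returns the 2.5th/97.5th percentiles of the statistic's bootstrap
#' distribution. Resamples on which the statistic is undefined (`NA` or
#' error) are skipped and counted; more than 1% skips is an error.
#'
#' @param data data frame of per-case records.
#' @param statistic function mapping a resampled data frame to one number.
#' @param reps bootstrap replicates (default 1e5).
#' @param seed RNG seed (required for determinism).
#' @param strata optional factor/vector of stratum labels (length
#'   `nrow(data)`); `NULL` for unstratified resampling.
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`, with attributes `skipped` and `reps`.
#' @export
bootstrap_ci <- function(data, statistic, reps = 1e5, seed = 1L,
                         strata = NULL, conf = 0.95) {
  n <- nrow(data)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n))
                    else split(seq_len(n), strata)
  if (any(vapply(idx_by_stratum, length, 1L) == 0))
    stop("every stratum must be nonempty")
  stats <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      pick <- unlist(lapply(idx_by_stratum, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      tryCatch(as.numeric(statistic(data[pick, , drop = FALSE]))[1],
               error = function(e) NA_real_)
    }, 1)
  })
  skipped <- sum(is.na(stats))
  if (skipped > 0.01 * reps)
    stop(sprintf("statistic undefined on %d of %d resamples (> 1%%)",
                 skipped, reps))
  a <- (1 - conf) / 2
  ci <- as.numeric(quantile(stats[!is.na(stats)], c(a, 1 - a), names = FALSE))
  names(ci) <- c("lo", "hi")
  attr(ci, "skipped") <- skipped
  attr(ci, "reps") <- reps
  ci
}

#' Volume agreement between predicted and reference volumes
#'
#' Pearson correlation plus linear regression of the reference volumes on
#' the predicted volumes with forced intersection at the origin
#' (`slope = sum(ref * pred) / sum(pred^2)`). The average relative volume
#' difference is `(slope - 1) * 100` percent, positive meaning the reference
#' source produced larger volumes. Confidence intervals come from paired
#' (unstratified) bootstrap resampling of cases.
#'
#' @param vols_pred predicted volumes (mL).
#' @param vols_ref reference volumes (mL), same length (>= 3).
#' @param seed bootstrap seed.
#' @param reps bootstrap replicates.
#' @param ci compute bootstrap confidence intervals (disable for very small
#'   samples, where degenerate resamples are frequent).
#' @return an object of class `agreement_result`: list with `pearson_r`,
#'   `r_ci`, `slope_through_origin`, `relative_difference_pct`, `rd_ci`, `n`.
#' @export
volume_agreement <- function(vols_pred, vols_ref, seed = 1L, reps = 1e5,
                             ci = TRUE) {
  if (length(vols_pred) != length(vols_ref)) stop("paired vectors required")
  n <- length(vols_pred)
  if (n < 3) stop("need at least 3 paired volumes")
  if (sd(vols_pred) == 0 || sd(vols_ref) == 0)
    stop("degenerate variance in volume vectors")
  slope_fn <- function(x, y) sum(y * x) / sum(x^2)
  r <- cor(vols_pred, vols_ref)
  slope <- slope_fn(vols_pred, vols_ref)
  df <- data.frame(pred = vols_pred, ref = vols_ref)
  r_ci <- rd_ci <- NULL
  if (ci) {
    r_ci <- bootstrap_ci(df, function(d) {
      if (sd(d$pred) == 0 || sd(d$ref) == 0) return(NA_real_)
      cor(d$pred, d$ref)
    }, reps = reps, seed = seed)
    rd_ci <- bootstrap_ci(df, function(d) {
      s <- sum(d$ref * d$pred) / sum(d$pred^2)
      (s - 1) * 100
    }, reps = reps, seed = seed + 1L)
  }
  structure(list(pearson_r = r, r_ci = r_ci,
                 slope_through_origin = slope,
                 relative_difference_pct = (slope - 1) * 100,
                 rd_ci = rd_ci, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (is.null(x$r_ci)) {
    cat(sprintf("agreement: r = %.3f, slope %.3f, rel. diff %+.1f%%\n",
                x$pearson_r, x$slope_through_origin,
                x$relative_difference_pct))
  } else {
    cat(sprintf(
      "agreement: r = %.3f (%.3f-%.3f), slope %.3f, rel. diff %+.1f%% (%+.1f to %+.1f)\n",
      x$pearson_r, x$r_ci["lo"], x$r_ci["hi"], x$slope_through_origin,
      x$relative_difference_pct, x$rd_ci["lo"], x$rd_ci["hi"]))
  }
  invisible(x)
}
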