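#' Binarize a probability map
#'
#' Inclusive thresholding: a voxel is lesion when its probability is greater
#' than or equal to `thr`.
#'
#' @param pmap a `prob_map` (or bare 3D probability array).
#' @param thr probability threshold in \[0, 1\] (default 0.5).
#' @return logical 3D array.
#' @export
binarize <- function(pmap, thr = 0.5) {
  if (!is.numeric(thr) || length(thr) != 1 || thr < 0 || thr > 1)
    stop("thr must lie in [0, 1]")
  p <- if (inherits(pmap, "prob_map")) pmap$probs else pmap
  p >= thr
}

#' Filter connected clusters by minimum volume
#'
#' Labels connected clusters of the binary mask (26-connectivity by default)
#' and removes clusters whose volume is strictly smaller than `min_ml`
#' millilitres; a cluster of exactly `min_ml` is retained. Volume is voxel
#' count times voxel volume / 1000.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel size (mm; scalar or length 3).
#' @param min_ml minimum cluster volume in mL (default 3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return an object of class `lesion_prediction`: list with `binary_mask`
#'   (filtered), `components` (data frame: `component_id`, `voxels`,
#'   `volume_ml`), `largest_volume_ml`, and `spacing_mm`.
#' @export
filter_components <- function(mask, spacing_mm, min_ml = 3,
                              connectivity = 26) {
  if (missing(spacing_mm) || is.null(spacing_mm) || any(!is.finite(spacing_mm)))
    stop("voxel spacing must be known to compute volumes")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  vox_ml <- prod(spacing_mm) / 1000
  lab <- cpp_label_components(mask, as.integer(connectivity))
  counts <- tabulate(lab)
  keep_ids <- which(counts * vox_ml >= min_ml)
  out_mask <- array(lab %in% keep_ids & lab > 0, dim(mask))
  comp <- data.frame(component_id = seq_along(keep_ids),
                     voxels = counts[keep_ids],
                     volume_ml = counts[keep_ids] * vox_ml)
  structure(list(binary_mask = out_mask, components = comp,
                 largest_volume_ml = if (nrow(comp)) max(comp$volume_ml) else 0,
                 spacing_mm = spacing_mm),
            class = "lesion_prediction")
}

#' @export
print.lesion_prediction <- function(x, ...) {
  cat(sprintf("lesion_prediction: %d component(s), largest %.2f mL\n",
              nrow(x$components), x$largest_volume_ml))
  invisible(x)
}

#' Case-level stroke call from the largest lesion volume
#'
#' Stroke when the largest connected lesion volume is strictly larger than
#' the decision threshold (default 25 mL, the ROC operating point).
#'
#' @param largest_volume_ml largest connected cluster volume (mL).
#' @param decision_ml decision threshold (mL).
#' @return logical stroke call.
#' @export
classify_stroke <- function(largest_volume_ml, decision_ml = 25) {
  if (any(largest_volume_ml < 0)) stop("volume must be non-negative")
  largest_volume_ml > decision_ml
}
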