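#' Extract the head region of a CTA volume
#'
#' Finds the most superior axial slice containing skull (bone = HU > 700 in
#' at least `min_bone_voxels` voxels, robust to noise specks) and keeps the
#' axial sub-volume from that slice down to the slice `extent_mm` inferior,
#' inclusive at both ends. Shorter volumes are clamped: everything below the
#' top bone slice is retained.
#'
#' @param vol a [ct_volume()]; the third axis must be the inferior-superior
#'   axis (orientation letter S or I).
#' @param extent_mm axial extent to keep below the skull apex (default 175).
#' @param bone_hu bone threshold (HU).
#' @param min_bone_voxels minimum bone voxels for a slice to count as skull.
#' @return the cropped `ct_volume`.
#' @export
extract_head_region <- function(vol, extent_mm = 175, bone_hu = 700,
                                min_bone_voxels = 10) {
  ax3 <- substr(vol$orientation, 3, 3)
  if (!ax3 %in% c("S", "I"))
    stop("third axis must be the inferior-superior axis (orientation S or I)")
  bone_per_slice <- apply(vol$voxels > bone_hu, 3, sum)
  has_bone <- which(bone_per_slice >= min_bone_voxels)
  if (length(has_bone) == 0) stop("no skull detected")
  sup_increasing <- ax3 == "S"
  top <- if (sup_increasing) max(has_bone) else min(has_bone)
  n_below <- floor(extent_mm / vol$spacing_mm[3])  # intervals below the apex
  if (sup_increasing) {
    lo <- max(1L, top - n_below)
    keep <- lo:top
  } else {
    hi <- min(dim(vol$voxels)[3], top + n_below)
    keep <- top:hi
  }
  out <- vol
  out$voxels <- vol$voxels[, , keep, drop = FALSE]
  out$origin_mm[3] <- vol$origin_mm[3] + (min(keep) - 1) * vol$spacing_mm[3]
  attr(out, "kept_slices") <- keep
  out
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear interpolation onto an isotropic grid of `target_mm` voxels. The
#' output shape per axis is `round(extent / target_mm)` so the physical
#' extent is preserved to within one voxel. Use `method = "nearest"` for
#' label masks.
#'
#' @param vol a [ct_volume()].
#' @param target_mm isotropic target voxel size (default 0.5).
#' @param method `"linear"` for images, `"nearest"` for masks.
#' @return the resampled `ct_volume`.
#' @export
resample_isotropic <- function(vol, target_mm = 0.5,
                               method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  d <- dim(vol$voxels)
  sp <- vol$spacing_mm
  if (all(abs(sp - target_mm) < 1e-12)) return(vol)
  nd <- pmax(1L, as.integer(round(d * sp / target_mm)))
  # centre-of-voxel alignment: new voxel j sits at (j - 0.5) * target from the
  # volume's leading edge; convert to fractional old-grid indices
  ci <- lapply(1:3, function(ax) ((seq_len(nd[ax]) - 0.5) * target_mm) / sp[ax] + 0.5)
  g <- expand.grid(x = ci[[1]], y = ci[[2]], z = ci[[3]])
  v <- if (method == "linear")
    trilinear_interp(vol$voxels, g$x, g$y, g$z, clamp = TRUE)
  else
    nearest_interp(vol$voxels, pmin(pmax(g$x, 1), d[1]),
                   pmin(pmax(g$y, 1), d[2]), pmin(pmax(g$z, 1), d[3]))
  out <- vol
  out$voxels <- array(v, dim = nd)
  out$spacing_mm <- rep(target_mm, 3)
  out
}

#' Normalize Hounsfield units to a symmetric window
#'
#' Affine map sending the window to \[-1, 1\]: `x -> (x - mid) / halfwidth`.
#' Values outside the window extend linearly beyond +/-1 - the volume is
#' shifted and rescaled, never clipped, so bone and contrast intensities stay
#' informative. The map is exactly invertible via [denormalize_hu()].
#'
#' @param vol a [ct_volume()] in HU.
#' @param window length-2 HU window (default `c(30, 60)`).
#' @return the normalized `ct_volume` (unitless voxels); the window used is
#'   attached as the `hu_window` attribute.
#' @export
normalize_hu <- function(vol, window = c(30, 60)) {
  if (length(window) != 2 || !(window[1] < window[2]))
    stop("window must satisfy lower < upper")
  mid <- mean(window)
  hw <- diff(window) / 2
  out <- vol
  out$voxels <- (vol$voxels - mid) / hw
  attr(out, "hu_window") <- window
  out
}

#' Invert [normalize_hu()]
#' @param vol a normalized `ct_volume` (with an `hu_window` attribute, or pass
#'   `window`).
#' @param window the HU window used for normalization.
#' @return the `ct_volume` back in HU.
#' @export
denormalize_hu <- function(vol, window = attr(vol, "hu_window")) {
  if (is.null(window)) stop("no hu_window attribute; supply window")
  mid <- mean(window)
  hw <- diff(window) / 2
  out <- vol
  out$voxels <- vol$voxels * hw + mid
  attr(out, "hu_window") <- NULL
  out
}

#' Tissue (non-air) mask of a CT volume
#'
#' Thresholds at `air_hu` and applies one morphological closing pass (3^3
#' structuring element) to fill the head silhouette, so background air can be
#' excluded from training and evaluation.
#'
#' @param vol a [ct_volume()] in HU.
#' @param air_hu air threshold (default -200).
#' @param closing apply the closing pass.
#' @return logical array, `TRUE` for tissue.
#' @export
compute_air_mask <- function(vol, air_hu = -200, closing = TRUE) {
  m <- vol$voxels >= air_hu
  if (closing && any(m)) m <- morph3(morph3(m, "dilate"), "erode")
  m
}

#' Normalized value of background air
#' @param window HU window.
#' @return the normalized value of -1000 HU under that window.
#' @export
normalized_air_value <- function(window = c(30, 60)) {
  (-1000 - mean(window)) / (diff(window) / 2)
}
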