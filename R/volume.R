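#' CT volume container
#'
#' A minimal 3D scalar grid in Hounsfield units with geometry metadata: voxel
#' spacing (mm per axis), origin, and an orientation code identifying the
#' anatomical direction of each index axis (e.g. `"RAS"`: first axis runs to
#' the subject's Right, second Anterior, third Superior). Exactly one axis
#' must be the left-right axis; the third axis is treated as axial
#' (inferior-superior) throughout the pipeline.
#'
#' @param voxels 3D numeric array of attenuation values (HU).
#' @param spacing_mm numeric(3), voxel edge lengths in mm (strictly positive).
#' @param origin_mm numeric(3), physical position of the first voxel.
#' @param orientation 3-character code from \{R, L, A, P, S, I\}, one per axis.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      orientation = "RAS") {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values")
  letters3 <- strsplit(toupper(orientation), "")[[1]]
  if (length(letters3) != 3 || !all(letters3 %in% c("R", "L", "A", "P", "S", "I")))
    stop("orientation must be a 3-letter code from R/L/A/P/S/I")
  if (sum(letters3 %in% c("R", "L")) != 1)
    stop("orientation must identify exactly one left-right axis")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm),
                 orientation = paste(letters3, collapse = "")),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], x$orientation))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Index of the left-right axis of a volume
#' @param vol a `ct_volume`.
#' @return integer axis index (1-3).
#' @export
lr_axis <- function(vol) {
  which(strsplit(vol$orientation, "")[[1]] %in% c("R", "L"))
}

#' Flip a volume along its left-right axis
#'
#' Reverses voxel order along the identified left-right axis and flips the
#' orientation letter accordingly. Applying the flip twice returns the
#' original array exactly.
#'
#' @param vol a `ct_volume`.
#' @return the flipped `ct_volume`.
#' @export
flip_lr <- function(vol) {
  ax <- lr_axis(vol)
  idx <- lapply(dim(vol$voxels), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  v <- do.call(`[`, c(list(vol$voxels), idx, list(drop = FALSE)))
  letters3 <- strsplit(vol$orientation, "")[[1]]
  letters3[ax] <- if (letters3[ax] == "R") "L" else "R"
  out <- vol
  out$voxels <- v
  out$orientation <- paste(letters3, collapse = "")
  out
}

#' Write a CT volume (or mask) as NIfTI
#'
#' Voxel spacing is stored in the NIfTI pixdim field. Masks are written as
#' integer 0/1 volumes.
#'
#' @param vol a `ct_volume` or a 3D array (then `spacing_mm` is required).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing when `vol` is a bare array.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = NULL) {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$voxels
    spacing_mm <- vol$spacing_mm
  } else {
    arr <- vol
    if (is.null(spacing_mm)) stop("spacing_mm required for a bare array")
    if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a CT volume
#'
#' @param path NIfTI path.
#' @param orientation orientation code to attach (NIfTI xforms are not
#'   interpreted; the caller asserts the axis meaning).
#' @return a `ct_volume`.
#' @export
read_volume <- function(path, orientation = "RAS") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim(img)[1:3]), spacing_mm = sp,
            orientation = orientation)
}
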