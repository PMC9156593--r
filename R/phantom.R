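#' Synthetic CTA head phantom specification
#'
#' Describes a digital head phantom in physical units: an ellipsoidal skull
#' shell around noisy soft-tissue parenchyma with symmetric CSF ventricles,
#' air background, and a unilateral ellipsoidal lesion in which the mean
#' attenuation is reduced by a known amount. Optional beam-hardening-like
#' banding and a rigid pose perturbation emulate common CT confounders.
#' Identical specs with identical seeds reproduce bit-identical volumes.
#'
#' The skull and brain geometry are derived from the grid so the same spec
#' scales to any resolution: the outer skull ellipsoid leaves at least a
#' 2-voxel air margin, and the brain compartment sits one skull thickness
#' (6 mm) inside it.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param spacing_mm voxel edge length(s) in mm.
#' @param skull_hu bone intensity (HU).
#' @param parenchyma_hu_mean,parenchyma_hu_sd soft-tissue intensity
#'   distribution (HU); the mean +/- 2 sd must stay inside the 10-80 HU
#'   soft-tissue band so the normalization window is meaningful.
#' @param ventricle_hu CSF intensity (HU).
#' @param lesion_center_mm ellipsoid centre in mm relative to the grid centre;
#'   the sign of the left-right component is forced to match `side`.
#' @param lesion_radii_mm ellipsoid semi-axes in mm; `NULL` for no lesion.
#' @param lesion_delta_hu attenuation decrement inside the lesion (HU,
#'   positive = darker). Default 6 HU: subtle, matching the low-contrast
#'   clinical setting.
#' @param side lesion hemisphere, `"left"` or `"right"`.
#' @param artifact_level amplitude (HU) of paired low-HU bands adjacent to
#'   the skull in the temporal/posterior regions; 0 disables.
#' @param pose numeric(6) rigid perturbation: rotations (deg, about x/y/z)
#'   then translations (mm).
#' @param noise_seed integer seed for the parenchymal noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(54, 54, 54),
                         spacing_mm = 2,
                         skull_hu = 1000,
                         parenchyma_hu_mean = 42,
                         parenchyma_hu_sd = 4,
                         ventricle_hu = 8,
                         lesion_center_mm = c(24, 0, 4),
                         lesion_radii_mm = c(12, 16, 16),
                         lesion_delta_hu = 6,
                         side = c("left", "right"),
                         artifact_level = 0,
                         pose = rep(0, 6),
                         noise_seed = 1L) {
  side <- match.arg(side)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    skull_hu = skull_hu, parenchyma_hu_mean = parenchyma_hu_mean,
    parenchyma_hu_sd = parenchyma_hu_sd, ventricle_hu = ventricle_hu,
    lesion_center_mm = lesion_center_mm, lesion_radii_mm = lesion_radii_mm,
    lesion_delta_hu = lesion_delta_hu, side = side,
    artifact_level = artifact_level, pose = as.numeric(pose),
    noise_seed = as.integer(noise_seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    stop("grid_shape must be 3 values, each >= 8")
  if (any(spec$spacing_mm <= 0)) stop("spacing_mm must be positive")
  lo <- spec$parenchyma_hu_mean - 2 * spec$parenchyma_hu_sd
  hi <- spec$parenchyma_hu_mean + 2 * spec$parenchyma_hu_sd
  if (lo < 10 || hi > 80)
    stop("parenchyma mean +/- 2 sd must stay inside the 10-80 HU soft-tissue band")
  geom <- phantom_geometry(spec$grid_shape, spec$spacing_mm)
  if (any(geom$brain_semi_mm <= 2 * spec$spacing_mm))
    stop("grid_shape too small to contain a skull shell plus 2-voxel air margin")
  if (length(spec$pose) != 6) stop("pose must have 6 components")
  invisible(spec)
}

#' Derived skull/brain geometry of a phantom grid
#'
#' @param grid_shape integer(3) voxels per axis.
#' @param spacing_mm numeric(3) voxel size.
#' @return list with `outer_semi_mm` (skull outer ellipsoid semi-axes) and
#'   `brain_semi_mm` (brain compartment semi-axes), per axis.
#' @export
phantom_geometry <- function(grid_shape, spacing_mm) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  extent <- grid_shape * spacing_mm
  margin <- pmax(2 * spacing_mm, 0.04 * extent)
  outer <- extent / 2 - margin
  skull_thickness <- 6
  list(outer_semi_mm = outer, brain_semi_mm = outer - skull_thickness)
}

# TRUE when the lesion ellipsoid lies entirely inside the brain ellipsoid
# (surface-sample check).
lesion_inside_brain <- function(center, radii, brain_semi, n = 24) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n)
  g <- expand.grid(th = th, ph = ph)
  px <- center[1] + radii[1] * sin(g$th) * cos(g$ph)
  py <- center[2] + radii[2] * sin(g$th) * sin(g$ph)
  pz <- center[3] + radii[3] * cos(g$th)
  all((px / brain_semi[1])^2 + (py / brain_semi[2])^2 +
        (pz / brain_semi[3])^2 <= 1)
}

# Squared normalized ellipsoid radius field over the grid.
ellipsoid_field <- function(xs, ys, zs, center, semi) {
  d <- c(length(xs), length(ys), length(zs))
  A <- array(((xs - center[1]) / semi[1])^2, dim = d)
  B <- array(rep(((ys - center[2]) / semi[2])^2, each = d[1]), dim = d)
  C <- array(rep(((zs - center[3]) / semi[3])^2, each = d[1] * d[2]), dim = d)
  A + B + C
}

#' Generate a synthetic CTA head phantom with a known lesion mask
#'
#' Builds the HU volume described by a [phantom_spec()]: air background at
#' -1000 HU, a bright skull shell, noisy parenchyma, a symmetric pair of CSF
#' ventricles, and (optionally) a unilateral hypoattenuating ellipsoidal
#' lesion whose exact binary mask is returned on the same grid. The noiseless
#' anatomy is mirror-symmetric about the midsagittal plane by construction;
#' noise, the lesion, and any pose perturbation are the only sources of
#' asymmetry.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [ct_volume()] in HU, orientation RAS) and
#'   `mask` (logical array, the exact lesion mask).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  geom <- phantom_geometry(d, sp)
  a_out <- geom$outer_semi_mm
  a_in <- geom$brain_semi_mm
  xs <- axis_coords(d[1], sp[1])
  ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])

  r2_out <- ellipsoid_field(xs, ys, zs, c(0, 0, 0), a_out)
  r2_in <- ellipsoid_field(xs, ys, zs, c(0, 0, 0), a_in)
  vol <- array(-1000, dim = d)
  vol[r2_out <= 1] <- spec$skull_hu
  brain <- r2_in <= 1
  vol[brain] <- spec$parenchyma_hu_mean

  # symmetric paired ventricles
  vent_semi <- 0.08 * a_in
  vent_off <- c(0.10 * a_in[1], -0.05 * a_in[2], 0.05 * a_in[3])
  for (s in c(-1, 1)) {
    vc <- c(s * vent_off[1], vent_off[2], vent_off[3])
    vent <- ellipsoid_field(xs, ys, zs, vc, vent_semi) <= 1
    vol[vent & brain] <- spec$ventricle_hu
  }

  # beam-hardening-like banding: paired low-HU bands just inside the skull in
  # the temporal (lateral) and posterior regions, modulated along z
  if (spec$artifact_level != 0) {
    rho <- sqrt(r2_in)
    sel <- brain & rho > 0.2
    Xf <- array(xs / a_in[1], dim = d)
    Yf <- array(rep(ys / a_in[2], each = d[1]), dim = d)
    Zmm <- array(rep(zs, each = d[1] * d[2]), dim = d)
    ux <- Xf[sel] / rho[sel]
    uy <- Yf[sel] / rho[sel]
    band <- exp(-((rho[sel] - 0.9) / 0.06)^2)
    ang <- pmin(pmax(abs(ux) - 0.75, 0) / 0.25 + pmax(-uy - 0.75, 0) / 0.25, 1)
    zmod <- 0.5 + 0.5 * cos(2 * pi * Zmm[sel] / 24)
    vol[sel] <- vol[sel] - spec$artifact_level * band * ang * zmod
  }

  # lesion
  mask <- array(FALSE, dim = d)
  if (!is.null(spec$lesion_radii_mm)) {
    ctr <- spec$lesion_center_mm
    lr_sign <- if (spec$side == "left") -1 else 1  # RAS: +x is subject right
    ctr[1] <- lr_sign * abs(ctr[1])
    if (!lesion_inside_brain(ctr, spec$lesion_radii_mm, a_in))
      stop("lesion ellipsoid extends outside the brain compartment")
    mask <- ellipsoid_field(xs, ys, zs, ctr, spec$lesion_radii_mm) <= 1
    vol[mask] <- vol[mask] - spec$lesion_delta_hu
  }

  # parenchymal noise (brain compartment only), seeded
  nb <- sum(brain)
  noise <- with_seed(spec$noise_seed, rnorm(nb, 0, spec$parenchyma_hu_sd))
  vol[brain] <- vol[brain] + noise

  # rigid pose perturbation
  if (any(spec$pose != 0)) {
    R <- rotation_matrix(spec$pose[1:3])
    tr <- spec$pose[4:6]
    g <- expand.grid(x = xs, y = ys, z = zs)
    p <- t(R) %*% rbind(g$x - tr[1], g$y - tr[2], g$z - tr[3])
    xi <- p[1, ] / sp[1] + (d[1] + 1) / 2
    yi <- p[2, ] / sp[2] + (d[2] + 1) / 2
    zi <- p[3, ] / sp[3] + (d[3] + 1) / 2
    vol <- array(trilinear_interp(vol, xi, yi, zi, fill = -1000), dim = d)
    mask <- array(nearest_interp(mask, xi, yi, zi, fill = 0) > 0.5, dim = d)
  }

  list(volume = ct_volume(vol, spacing_mm = sp, orientation = "RAS"),
       mask = mask)
}

#' Lesion mask volume in millilitres
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel size (mm, scalar or length 3).
#' @return volume in mL (voxel count x voxel volume / 1000).
#' @export
mask_volume_ml <- function(mask, spacing_mm) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  sum(mask) * prod(spacing_mm) / 1000
}

#' Generate a synthetic stroke/control cohort
#'
#' Stroke cases receive a unilateral lesion with a target volume drawn
#' uniformly from `volume_range_ml`; control cases have empty masks. Per-case
#' sub-seeds, lesion sides, shapes and positions are all derived
#' deterministically from `seed`, so the same call reproduces the identical
#' case list.
#'
#' @param n_stroke,n_control non-negative case counts.
#' @param volume_range_ml length-2 interval (mL) for stroke lesion volumes;
#'   may be `NULL` when `n_stroke` is 0.
#' @param seed master seed.
#' @param grid_shape,spacing_mm phantom grid (desk-scale defaults: 54^3 at
#'   2 mm isotropic).
#' @param lesion_delta_hu lesion contrast (HU); default 6 (subtle).
#' @param artifact_level beam-hardening band amplitude (HU).
#' @return list of cases; each case is a list with `case_id`, `label`
#'   (`"stroke"`/`"control"`), `volume` (a `ct_volume`), `mask`,
#'   `lesion_volume_ml` (exact mask volume) and `seed`.
#' @export
generate_cohort <- function(n_stroke, n_control, volume_range_ml = c(20, 40),
                            seed = 1L,
                            grid_shape = c(54, 54, 54), spacing_mm = 2,
                            lesion_delta_hu = 6, artifact_level = 0) {
  if (n_stroke < 0 || n_control < 0) stop("case counts must be non-negative")
  if (n_stroke > 0) {
    if (is.null(volume_range_ml) || length(volume_range_ml) != 2 ||
        diff(range(volume_range_ml)) < 0 || any(volume_range_ml <= 0))
      stop("volume_range_ml must be a positive interval when n_stroke > 0")
  }
  n <- n_stroke + n_control
  if (n == 0) return(list())
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  a_in <- phantom_geometry(grid_shape, spacing_mm)$brain_semi_mm

  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    vols = if (n_stroke > 0) runif(n_stroke, volume_range_ml[1], volume_range_ml[2]) else numeric(0),
    sides = sample(c("left", "right"), n, replace = TRUE),
    shape_jit = matrix(runif(3 * n, 0.9, 1.1), ncol = 3),
    pos_jit = matrix(runif(2 * n, -0.1, 0.1), ncol = 2)
  ))

  labels <- c(rep("stroke", n_stroke), rep("control", n_control))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (labels[i] == "stroke") {
      v_target <- draws$vols[i]
      shape <- c(0.7, 1, 1) * draws$shape_jit[i, ]
      r0 <- (3 * v_target * 1000 / (4 * pi * prod(shape)))^(1 / 3)
      radii <- shape * r0
      # find a lateral offset at which the lesion fits inside the brain
      center <- NULL
      for (f in seq(0.45, 0.20, by = -0.05)) {
        cand <- c(f * a_in[1],
                  draws$pos_jit[i, 1] * a_in[2],
                  draws$pos_jit[i, 2] * a_in[3])
        if (lesion_inside_brain(c(if (draws$sides[i] == "left") -1 else 1, 1, 1) * cand,
                                radii, a_in)) {
          center <- cand
          break
        }
      }
      if (is.null(center))
        stop("volume_range_ml too large for the phantom grid")
      spec <- phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                           lesion_center_mm = center, lesion_radii_mm = radii,
                           lesion_delta_hu = lesion_delta_hu,
                           side = draws$sides[i],
                           artifact_level = artifact_level,
                           noise_seed = draws$seeds[i])
    } else {
      spec <- phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                           lesion_radii_mm = NULL,
                           artifact_level = artifact_level,
                           noise_seed = draws$seeds[i])
    }
    ph <- generate_phantom(spec)
    out[[i]] <- list(case_id = sprintf("case%03d", i), label = labels[i],
                     volume = ph$volume, mask = ph$mask,
                     lesion_volume_ml = mask_volume_ml(ph$mask, spacing_mm),
                     seed = draws$seeds[i])
  }
  out
}

#' Write a cohort to disk (NIfTI volumes/masks + CSV manifest)
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cs) {
    vpath <- file.path(dir, paste0(cs$case_id, "_cta.nii.gz"))
    write_volume(cs$volume, vpath)
    mpath <- ""
    if (any(cs$mask)) {
      mpath <- file.path(dir, paste0(cs$case_id, "_mask.nii.gz"))
      write_volume(cs$mask, mpath, spacing_mm = cs$volume$spacing_mm)
    }
    data.frame(case_id = cs$case_id, label = cs$label,
               lesion_volume_ml = cs$lesion_volume_ml, seed = cs$seed,
               volume_path = basename(vpath),
               mask_path = basename(mpath), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
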