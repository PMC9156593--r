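#' Registration parameters for the mirror co-registration
#'
#' Defaults follow the cited operating point of the pipeline: mutual
#' information with 32 histogram bins sampled at 2048 spatial positions over
#' four resolution levels with a 500-iteration budget for the rigid stage,
#' and a 16-mm control-point grid for the deformable B-spline stage.
#'
#' @param bins histogram bins for the mutual-information metric.
#' @param samples number of spatial metric samples.
#' @param levels resolution levels (coarse to fine, halving each level).
#' @param max_iter total rigid optimizer iteration budget (split over levels).
#' @param grid_mm B-spline control grid spacing (mm).
#' @param bspline_iters gradient-descent iterations for the deformable stage.
#' @param step_mm initial deformable step length (mm).
#' @return list of parameters.
#' @export
register_params <- function(bins = 32, samples = 2048, levels = 4,
                            max_iter = 500, grid_mm = 16,
                            bspline_iters = 60, step_mm = 0.8) {
  list(bins = bins, samples = samples, levels = levels, max_iter = max_iter,
       grid_mm = grid_mm, bspline_iters = bspline_iters, step_mm = step_mm)
}

# Mutual information between two paired samples (equal-width joint histogram).
mi_metric <- function(a, b, bins = 32, lims_a = range(a), lims_b = range(b)) {
  ia <- pmin(pmax(findInterval(a, seq(lims_a[1], lims_a[2], length.out = bins + 1),
                               all.inside = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, seq(lims_b[1], lims_b[2], length.out = bins + 1),
                               all.inside = TRUE), 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(b)
  jm <- matrix(joint, bins, bins)
  pp <- outer(pa, pb)
  nz <- jm > 0 & pp > 0
  sum(jm[nz] * log(jm[nz] / pp[nz]))
}

# Mean-pool downsample a 3D array by integer factor f (trailing remainder
# voxels dropped).
downsample3 <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr) %/% f
  arr <- arr[1:(d[1] * f), 1:(d[2] * f), 1:(d[3] * f), drop = FALSE]
  a <- array(arr, c(f, d[1], f, d[2], f, d[3]))
  apply(a, c(2, 4, 6), mean)
}

# Sample a moving array at physical (centred, mm) positions under a rigid
# map T(x) = R (x - t). Positions: 3 x n matrix.
sample_rigid <- function(arr, spacing, pos, theta, fill) {
  R <- rotation_matrix(theta[1:3])
  p <- R %*% (pos - theta[4:6])
  d <- dim(arr)
  trilinear_interp(arr,
                   p[1, ] / spacing[1] + (d[1] + 1) / 2,
                   p[2, ] / spacing[2] + (d[2] + 1) / 2,
                   p[3, ] / spacing[3] + (d[3] + 1) / 2,
                   fill = fill)
}

# Multiresolution rigid registration of moving onto fixed by maximizing MI.
# Returns theta = (rot deg x3, trans mm x3).
rigid_register <- function(fixed, moving, spacing, params, fill, seed = 0L) {
  d <- dim(fixed)
  extent <- d * spacing
  pos <- with_seed(seed, {
    matrix(runif(3 * params$samples, -0.5, 0.5), nrow = 3) * extent
  })
  lims_f <- range(fixed)
  lims_m <- range(moving)
  theta <- rep(0, 6)
  factors <- rev(2^(seq_len(params$levels) - 1))  # e.g. 8,4,2,1
  factors <- factors[pmin(d[1], d[2], d[3]) %/% factors >= 16]
  if (length(factors) == 0) factors <- 1
  it_per <- max(20L, ceiling(params$max_iter / length(factors)))
  for (f in factors) {
    fx <- downsample3(fixed, f)
    mv <- downsample3(moving, f)
    sp_f <- spacing * f
    dfx <- dim(fx)
    fval <- trilinear_interp(fx,
                             pos[1, ] / sp_f[1] + (dfx[1] + 1) / 2,
                             pos[2, ] / sp_f[2] + (dfx[2] + 1) / 2,
                             pos[3, ] / sp_f[3] + (dfx[3] + 1) / 2,
                             fill = fill)
    obj <- function(th) -mi_metric(fval,
                                   sample_rigid(mv, sp_f, pos, th, fill),
                                   params$bins, lims_f, lims_m)
    # exhaustive rotation seeding: the histogram metric is locally bumpy, so
    # offer the simplex the best of a coarse rotation grid around the current
    # estimate before refining
    grid <- expand.grid(rx = theta[1] + seq(-9, 9, by = 3),
                        ry = theta[2] + seq(-9, 9, by = 3),
                        rz = theta[3] + seq(-9, 9, by = 3))
    vals <- vapply(seq_len(nrow(grid)), function(i)
      obj(c(grid$rx[i], grid$ry[i], grid$rz[i], theta[4:6])), 1)
    best <- which.min(vals)
    if (vals[best] < obj(theta))
      theta <- c(grid$rx[best], grid$ry[best], grid$rz[best], theta[4:6])
    res <- optim(theta, obj, method = "Nelder-Mead",
                 control = list(maxit = it_per,
                                parscale = c(rep(2, 3), rep(2, 3))))
    theta <- res$par
  }
  theta
}

# Cubic B-spline weights for fractional offset u in [0,1).
bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# 1D B-spline support: for each position the 0-based cell index i (controls
# i+1 .. i+4 are active) and the 4 weights.
bspline_basis_parts <- function(x, extent, h) {
  x0 <- -extent / 2
  nc <- as.integer(floor(extent / h) + 4L)
  t <- (x - x0) / h
  i <- pmin(pmax(floor(t), 0), nc - 4L)
  w <- bspline_weights(pmin(pmax(t - i, 0), 1))
  list(i = as.integer(i), w = w, nc = nc)
}

# Dense 1D B-spline basis matrix: positions x (mm, centred) against a control
# grid of spacing h covering [-extent/2, extent/2].
bspline_basis <- function(x, extent, h) {
  p <- bspline_basis_parts(x, extent, h)
  B <- matrix(0, length(x), p$nc)
  for (k in 0:3) B[cbind(seq_along(x), p$i + k + 1L)] <- p$w[, k + 1L]
  B
}

# Evaluate one displacement component on the whole grid from its control
# coefficients via separable basis application.
bspline_eval_grid <- function(coef_arr, Bx, By, Bz) {
  ncx <- ncol(Bx); ncy <- ncol(By); ncz <- ncol(Bz)
  nx <- nrow(Bx); ny <- nrow(By); nz <- nrow(Bz)
  t1 <- Bx %*% matrix(coef_arr, ncx, ncy * ncz)           # nx x (ncy*ncz)
  a1 <- aperm(array(t1, c(nx, ncy, ncz)), c(2, 1, 3))
  t2 <- By %*% matrix(a1, ncy, nx * ncz)                   # ny x (nx*ncz)
  a2 <- aperm(array(t2, c(ny, nx, ncz)), c(3, 2, 1))       # ncz x nx x ny
  t3 <- Bz %*% matrix(a2, ncz, nx * ny)                    # nz x (nx*ny)
  aperm(array(t3, c(nz, nx, ny)), c(2, 3, 1))
}

# Deformable refinement: free-form B-spline displacement optimized by
# stochastic gradient descent on the squared intensity difference, with the
# metric sample set renewed every iteration (the control grid has more
# degrees of freedom than one sample set, so a fixed set would overfit).
# Progress is monitored on a fixed held-out sample set.
bspline_refine <- function(fixed, moving, spacing, params, fill, seed = 0L) {
  d <- dim(fixed)
  extent <- d * spacing
  h <- params$grid_mm
  n <- params$samples
  nc <- vapply(1:3, function(ax) as.integer(floor(extent[ax] / h) + 4L), 1L)

  interp_at <- function(arr, pos, u = NULL, f = fill) {
    px <- pos[1, ] + (if (is.null(u)) 0 else u[, 1])
    py <- pos[2, ] + (if (is.null(u)) 0 else u[, 2])
    pz <- pos[3, ] + (if (is.null(u)) 0 else u[, 3])
    trilinear_interp(arr, px / spacing[1] + (d[1] + 1) / 2,
                     py / spacing[2] + (d[2] + 1) / 2,
                     pz / spacing[3] + (d[3] + 1) / 2, fill = f)
  }
  eval_u <- function(supp, coef) {
    u <- matrix(0, length(supp[[1]]$i), 3)
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
      wv <- supp[[1]]$w[, a] * supp[[2]]$w[, b] * supp[[3]]$w[, cc]
      col <- (supp[[1]]$i + a) + nc[1] * (supp[[2]]$i + b - 1L) +
        nc[1] * nc[2] * (supp[[3]]$i + cc - 1L)
      u <- u + wv * coef[col, , drop = FALSE]
    }
    u
  }
  parts <- function(pos) lapply(1:3, function(ax)
    bspline_basis_parts(pos[ax, ], extent[ax], h))

  # central-difference image gradient of the moving image (per mm)
  grad <- lapply(1:3, function(ax) {
    idx_hi <- idx_lo <- lapply(d, seq_len)
    idx_hi[[ax]] <- c(2:d[ax], d[ax])
    idx_lo[[ax]] <- c(1, 1:(d[ax] - 1))
    (do.call(`[`, c(list(moving), idx_hi)) -
       do.call(`[`, c(list(moving), idx_lo))) / (2 * spacing[ax])
  })

  hold_pos <- with_seed(seed + 1L,
                        matrix(runif(3 * n, -0.5, 0.5), nrow = 3) * extent)
  hold_supp <- parts(hold_pos)
  hold_f <- interp_at(fixed, hold_pos)
  holdout_sse <- function(coef) {
    u <- eval_u(hold_supp, coef)
    mean((interp_at(moving, hold_pos, u) - hold_f)^2)
  }

  coef <- matrix(0, prod(nc), 3)
  best <- list(coef = coef, sse = holdout_sse(coef))
  step <- params$step_mm
  for (it in seq_len(params$bspline_iters)) {
    pos <- with_seed(seed + 100L + it,
                     matrix(runif(3 * n, -0.5, 0.5), nrow = 3) * extent)
    supp <- parts(pos)
    fval <- interp_at(fixed, pos)
    u <- eval_u(supp, coef)
    r <- interp_at(moving, pos, u) - fval
    gk <- lapply(1:3, function(ax) r * interp_at(grad[[ax]], pos, u, f = 0))
    g <- matrix(0, prod(nc), 3)
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
      wv <- supp[[1]]$w[, a] * supp[[2]]$w[, b] * supp[[3]]$w[, cc]
      col <- (supp[[1]]$i + a) + nc[1] * (supp[[2]]$i + b - 1L) +
        nc[1] * nc[2] * (supp[[3]]$i + cc - 1L)
      for (k in 1:3) {
        agg <- rowsum(wv * gk[[k]], col)
        ix <- as.integer(rownames(agg))
        g[ix, k] <- g[ix, k] + agg[, 1]
      }
    }
    g <- g / n
    gmax <- max(abs(g))
    if (gmax < 1e-12) break
    coef <- coef - (step / gmax) * g
    step <- step * 0.97
    sse <- holdout_sse(coef)
    if (sse < best$sse) best <- list(coef = coef, sse = sse)
  }
  best
}

#' Two-channel mirrored representation of a CTA volume
#'
#' Builds the network's input representation: the original (normalized)
#' volume plus a copy that has been left-right flipped and co-registered back
#' onto the original, so each voxel is paired with its contralateral
#' counterpart. Registration runs a coarse multiresolution rigid stage
#' (mutual-information metric) followed by a free-form B-spline deformable
#' stage; if the deformable stage worsens the intensity residual it is
#' discarded and the rigid result is kept, with a warning recorded in the
#' returned provenance.
#'
#' @param vol a normalized [ct_volume()] (output of [normalize_hu()]); the
#'   `hu_window` attribute is used to derive air values and the tissue mask.
#' @param params a [register_params()] list.
#' @param seed seed for the deterministic placement of metric samples.
#' @return an object of class `two_channel_volume`: list with
#'   `channel_original` and `channel_mirrored` (arrays on the identical
#'   grid), `valid_mask` (non-air voxels), `spacing_mm`, and `provenance`
#'   (rigid parameters, residuals, warnings).
#' @export
mirror_register <- function(vol, params = register_params(), seed = 0L) {
  window <- attr(vol, "hu_window") %||% c(30, 60)
  fill <- normalized_air_value(window)
  fixed <- vol$voxels
  flipped <- flip_lr(vol)$voxels
  spacing <- vol$spacing_mm
  hu <- denormalize_hu(vol, window)
  valid <- compute_air_mask(hu)

  resid <- function(m) mean(abs(fixed[valid] - m[valid]))
  res_flip <- resid(flipped)

  theta <- rigid_register(fixed, flipped, spacing, params, fill, seed = seed)
  d <- dim(fixed)
  extent <- d * spacing
  grid_pos <- rbind(
    rep(axis_coords(d[1], spacing[1]), times = d[2] * d[3]),
    rep(rep(axis_coords(d[2], spacing[2]), each = d[1]), times = d[3]),
    rep(axis_coords(d[3], spacing[3]), each = d[1] * d[2]))
  rigid_arr <- array(sample_rigid(flipped, spacing, grid_pos, theta, fill), d)
  res_rigid <- resid(rigid_arr)

  warnings <- character(0)
  bspl <- bspline_refine(fixed, rigid_arr, spacing, params, fill, seed = seed)
  Bx <- bspline_basis(axis_coords(d[1], spacing[1]), extent[1], params$grid_mm)
  By <- bspline_basis(axis_coords(d[2], spacing[2]), extent[2], params$grid_mm)
  Bz <- bspline_basis(axis_coords(d[3], spacing[3]), extent[3], params$grid_mm)
  nc <- c(ncol(Bx), ncol(By), ncol(Bz))
  ux <- bspline_eval_grid(array(bspl$coef[, 1], nc), Bx, By, Bz)
  uy <- bspline_eval_grid(array(bspl$coef[, 2], nc), Bx, By, Bz)
  uz <- bspline_eval_grid(array(bspl$coef[, 3], nc), Bx, By, Bz)
  def_arr <- array(trilinear_interp(
    rigid_arr,
    (grid_pos[1, ] + as.numeric(ux)) / spacing[1] + (d[1] + 1) / 2,
    (grid_pos[2, ] + as.numeric(uy)) / spacing[2] + (d[2] + 1) / 2,
    (grid_pos[3, ] + as.numeric(uz)) / spacing[3] + (d[3] + 1) / 2,
    fill = fill), d)
  res_def <- resid(def_arr)

  if (res_def <= res_rigid) {
    mirrored <- def_arr
    used <- "rigid+bspline"
  } else {
    mirrored <- rigid_arr
    used <- "rigid"
    warnings <- c(warnings,
                  "deformable stage increased the residual; rigid-only result kept")
  }

  structure(list(
    channel_original = fixed,
    channel_mirrored = mirrored,
    valid_mask = valid,
    spacing_mm = spacing,
    provenance = list(rigid_theta = theta,
                      residual_flip = res_flip,
                      residual_rigid = res_rigid,
                      residual_deformable = res_def,
                      stages_used = used,
                      hu_window = window,
                      params = params, seed = seed,
                      warnings = warnings)),
    class = "two_channel_volume")
}

#' @export
print.two_channel_volume <- function(x, ...) {
  d <- dim(x$channel_original)
  cat(sprintf("two_channel_volume: %d x %d x %d @ %.3g mm, stages: %s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$provenance$stages_used))
  cat(sprintf("  residuals: flip %.4f -> rigid %.4f -> deformable %.4f\n",
              x$provenance$residual_flip, x$provenance$residual_rigid,
              x$provenance$residual_deformable))
  invisible(x)
}
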