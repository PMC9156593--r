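#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded internals never disturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trilinear interpolation into a 3D array
#'
#' Samples `arr` at fractional (1-based) voxel coordinates. Coordinates
#' outside the grid return `fill`, or are clamped to the edge when
#' `clamp = TRUE`.
#'
#' @param arr 3D numeric array.
#' @param xi,yi,zi numeric vectors of equal length, 1-based voxel coordinates.
#' @param fill value for out-of-grid samples.
#' @param clamp clamp coordinates to the grid instead of filling.
#' @return numeric vector of sampled values.
#' @keywords internal
trilinear_interp <- function(arr, xi, yi, zi, fill = 0, clamp = FALSE) {
  d <- dim(arr)
  if (clamp) {
    xi <- pmin(pmax(xi, 1), d[1])
    yi <- pmin(pmax(yi, 1), d[2])
    zi <- pmin(pmax(zi, 1), d[3])
  }
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(as.numeric(fill), length(xi))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]; zi <- zi[inside]
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  # linear index helper (1-based)
  ix <- function(a, b, cc) a + d[1] * (b - 1) + d[1] * d[2] * (cc - 1)
  v000 <- arr[ix(x0,     y0,     z0)]
  v100 <- arr[ix(x0 + 1, y0,     z0)]
  v010 <- arr[ix(x0,     y0 + 1, z0)]
  v110 <- arr[ix(x0 + 1, y0 + 1, z0)]
  v001 <- arr[ix(x0,     y0,     z0 + 1)]
  v101 <- arr[ix(x0 + 1, y0,     z0 + 1)]
  v011 <- arr[ix(x0,     y0 + 1, z0 + 1)]
  v111 <- arr[ix(x0 + 1, y0 + 1, z0 + 1)]
  v <- v000 * (1 - fx) * (1 - fy) * (1 - fz) +
       v100 * fx       * (1 - fy) * (1 - fz) +
       v010 * (1 - fx) * fy       * (1 - fz) +
       v110 * fx       * fy       * (1 - fz) +
       v001 * (1 - fx) * (1 - fy) * fz +
       v101 * fx       * (1 - fy) * fz +
       v011 * (1 - fx) * fy       * fz +
       v111 * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Nearest-neighbour interpolation into a 3D array
#' @inheritParams trilinear_interp
#' @keywords internal
nearest_interp <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  xi <- round(xi); yi <- round(yi); zi <- round(zi)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(as.numeric(fill), length(xi))
  if (any(inside))
    out[inside] <- arr[xi[inside] + d[1] * (yi[inside] - 1) +
                         d[1] * d[2] * (zi[inside] - 1)]
  out
}

# Rotation matrix from intrinsic rotations about x, y, z (degrees).
rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Physical coordinates (mm) of voxel centres relative to the grid centre,
# per axis. Grid centre is at index (n+1)/2 so index reversal mirrors the
# coordinate exactly.
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

# Binary 3^3 dilation/erosion via shifted copies (26-neighbourhood).
morph3 <- function(mask, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  pad <- array(op == "erode", dim = d + 2L)  # dilate pads FALSE, erode pads TRUE
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  acc <- NULL
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    sub <- pad[(1 + dx):(d[1] + dx), (1 + dy):(d[2] + dy), (1 + dz):(d[3] + dz)]
    if (is.null(acc)) acc <- sub
    else acc <- if (op == "dilate") acc | sub else acc & sub
  }
  acc
}
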