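#' Plan the tile layout for whole-volume inference
#'
#' Output blocks of the network's output edge tile the volume with stride
#' equal to the output edge; when an axis is not a multiple of the edge, a
#' final shifted tile covers the remainder. Each tile carries the write
#' region it is responsible for (`w1..w3` to `o + edge - 1`), and these
#' write regions partition the volume: every voxel is written exactly once.
#' Where a shifted tile's block overlaps its predecessor the overlapping
#' values are identical anyway, by the valid-padding equivalence. Input
#' corners sit `depth_C` voxels before each output corner and are satisfied
#' by padding.
#'
#' @param volume_shape integer(3) voxel grid shape.
#' @param cfg a [network_config()].
#' @return data frame of tile corners (1-based): output-block corners
#'   `o1, o2, o3`, write-region starts `w1, w2, w3`, and input corners
#'   `i1, i2, i3` (possibly non-positive; padding covers them).
#' @export
plan_tiles <- function(volume_shape, cfg) {
  if (any(volume_shape < 1)) stop("volume_shape must be positive")
  e <- output_edge(cfg)
  axis <- lapply(1:3, function(ax) {
    o <- tile_axis_corners(volume_shape[ax], e)
    w <- pmax(o, c(1L, head(o, -1) + e))  # start of uncovered remainder
    list(o = o, w = w)
  })
  g <- expand.grid(t1 = seq_along(axis[[1]]$o), t2 = seq_along(axis[[2]]$o),
                   t3 = seq_along(axis[[3]]$o))
  out <- data.frame(o1 = axis[[1]]$o[g$t1], o2 = axis[[2]]$o[g$t2],
                    o3 = axis[[3]]$o[g$t3],
                    w1 = axis[[1]]$w[g$t1], w2 = axis[[2]]$w[g$t2],
                    w3 = axis[[3]]$w[g$t3])
  out$i1 <- out$o1 - cfg$depth_C
  out$i2 <- out$o2 - cfg$depth_C
  out$i3 <- out$o3 - cfg$depth_C
  out
}

#' Seamless whole-volume prediction by tiling and stitching
#'
#' Pads the two-channel volume with the normalized air value, evaluates the
#' network on each planned tile, and writes every output block into place.
#' Because all convolutions use valid padding, the stitched map is exactly
#' the map a single whole-volume pass would produce, and its size equals the
#' input volume's.
#'
#' @param net a `cta_network`.
#' @param tc a `two_channel_volume`.
#' @param cfg the network's configuration; must match `net` (geometry is
#'   checked).
#' @return an object of class `prob_map`: list with `probs` (3D array of
#'   lesion probabilities), `spacing_mm`, and `provenance`.
#' @export
stitch_predict <- function(net, tc, cfg = net$config) {
  if (!identical(unclass(cfg), unclass(net$config)))
    stop("model/config mismatch")
  d <- dim(tc$channel_original)
  e <- output_edge(cfg)
  inlen <- e + 2L * cfg$depth_C + cfg$terminal_crop
  fill <- normalized_air_value(tc$provenance$hu_window %||% c(30, 60))
  lo <- cfg$depth_C
  hi <- cfg$depth_C + cfg$terminal_crop + max(0L, e - min(d))  # short-axis slack
  pad <- array(fill, c(d[1] + lo + hi, d[2] + lo + hi, d[3] + lo + hi, 2L))
  pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 1] <-
    tc$channel_original
  pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 2] <-
    tc$channel_mirrored
  tiles <- plan_tiles(d, cfg)
  probs <- array(NA_real_, d)
  for (t in seq_len(nrow(tiles))) {
    o <- c(tiles$o1[t], tiles$o2[t], tiles$o3[t])
    w <- c(tiles$w1[t], tiles$w2[t], tiles$w3[t])
    x <- pad[o[1] + 0:(inlen - 1L), o[2] + 0:(inlen - 1L),
             o[3] + 0:(inlen - 1L), , drop = FALSE]
    fw <- network_forward(net, x)
    hi <- pmin(o + e - 1L, d)  # crop tiles overhanging a short axis
    probs[w[1]:hi[1], w[2]:hi[2], w[3]:hi[3]] <-
      fw$probs[(w[1] - o[1] + 1L):(hi[1] - o[1] + 1L),
               (w[2] - o[2] + 1L):(hi[2] - o[2] + 1L),
               (w[3] - o[3] + 1L):(hi[3] - o[3] + 1L), 2]
  }
  structure(list(probs = probs, spacing_mm = tc$spacing_mm,
                 provenance = list(config = unclass(cfg), seed = net$seed)),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("prob_map: %d x %d x %d @ %.3g mm, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], x$spacing_mm[1], min(x$probs), max(x$probs)))
  invisible(x)
}

#' Calibrate the probability colormap from validation lesion probabilities
#'
#' The display range is the 0.05 and 0.95 quantiles of the predicted
#' probabilities inside validation lesion regions, with the lower bound cut
#' off at 0.5; degenerate ranges fall back to (0.5, 1).
#'
#' @param probs numeric vector of predicted probabilities within validation
#'   lesion masks.
#' @return an object of class `color_calibration`: list with `vmin`, `vmax`.
#' @export
calibrate_colormap <- function(probs) {
  if (length(probs) == 0) stop("empty probability sample")
  q <- as.numeric(quantile(probs, c(0.05, 0.95), names = FALSE))
  vmin <- max(0.5, q[1])
  vmax <- q[2]
  if (vmax <= vmin) {
    vmin <- 0.5
    vmax <- 1.0
  }
  structure(list(vmin = vmin, vmax = vmax), class = "color_calibration")
}

#' Render axial overlay slices of a probability map
#'
#' Grayscale base image with a perceptually uniform ("plasma") overlay of
#' probabilities at or above 0.5, scaled between the calibration bounds;
#' voxels below 0.5 are fully transparent.
#'
#' @param base a [ct_volume()] (HU) aligned with the probability map.
#' @param pmap a `prob_map`.
#' @param cal a `color_calibration`.
#' @param slices axial slice indices (default: all).
#' @param window display window (HU) for the grayscale base.
#' @param dir if non-`NULL`, write one PNG per slice into this directory.
#' @return invisibly, a list of RGB arrays (height x width x 3, values in
#'   \[0, 1\]), one per slice.
#' @export
render_overlay <- function(base, pmap, cal, slices = NULL,
                           window = c(0, 80), dir = NULL) {
  if (!identical(dim(base$voxels), dim(pmap$probs)))
    stop("geometry mismatch between base volume and probability map")
  d <- dim(base$voxels)
  if (is.null(slices)) slices <- seq_len(d[3])
  pal <- grDevices::hcl.colors(256, "plasma")
  palrgb <- t(grDevices::col2rgb(pal)) / 255
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", length(slices))
  for (k in seq_along(slices)) {
    s <- slices[k]
    g <- (base$voxels[, , s] - window[1]) / diff(window)
    g <- pmin(pmax(g, 0), 1)
    img <- array(g, c(d[1], d[2], 3))
    p <- pmap$probs[, , s]
    vis <- p >= 0.5
    if (any(vis)) {
      tpos <- (p[vis] - cal$vmin) / max(cal$vmax - cal$vmin, 1e-12)
      tpos <- pmin(pmax(tpos, 0), 1)
      ci <- 1L + as.integer(round(tpos * 255))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[vis] <- palrgb[ci, ch]
        img[, , ch] <- plane
      }
    }
    out[[k]] <- img
    if (!is.null(dir))
      png::writePNG(aperm(img, c(2, 1, 3)),
                    file.path(dir, sprintf("slice_%03d.png", s)))
  }
  invisible(out)
}
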