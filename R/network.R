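#' Configuration of the valid-padded 3D segmentation network family
#'
#' The family consists of `depth_C` stacked 3x3x3 valid-padded convolutional
#' layers of `width_F` filters with exponential-linear activation, two-layer
#' skip concatenations (layer `j >= skip_start` receives its predecessor's
#' output concatenated with the output of layer `j - 2`, the latter cropped
#' by one voxel per side to align), a 1x1x1 layer of `fc_width` filters with
#' rectified-linear activation, and a 1x1x1 softmax output layer with
#' `n_classes` filters. No pooling, dropout, or normalization layers are used
#' anywhere, so every spatial edge shrinks by exactly 2 per 3x3x3 layer and
#' tiled inference is exactly equivalent to whole-volume inference.
#'
#' `terminal_crop` voxels are removed from the high-index side of each axis
#' after the last convolution (before the 1x1x1 layers), making the default
#' geometry 107^3 -> 26^3.
#'
#' @param depth_C number of 3x3x3 convolutional layers.
#' @param width_F filters per convolutional layer.
#' @param fc_width filters in the penultimate 1x1x1 layer.
#' @param n_classes output channels (background, lesion).
#' @param skip_start index of the first layer whose input is a two-layer
#'   concatenation; `depth_C + 1` disables skips. Default 4 (clamped to
#'   `depth_C + 1` for very shallow nets).
#' @param in_channels input channels (original + mirrored).
#' @param input_patch training patch edge length (voxels).
#' @param terminal_crop voxels cropped from the high-index side per axis
#'   after the last convolution.
#' @return an object of class `network_config`.
#' @export
network_config <- function(depth_C = 40, width_F = 16, fc_width = 50,
                           n_classes = 2, skip_start = min(4, depth_C + 1),
                           in_channels = 2, input_patch = 107,
                           terminal_crop = 1) {
  cfg <- structure(list(depth_C = as.integer(depth_C),
                        width_F = as.integer(width_F),
                        fc_width = as.integer(fc_width),
                        n_classes = as.integer(n_classes),
                        skip_start = as.integer(skip_start),
                        in_channels = as.integer(in_channels),
                        input_patch = as.integer(input_patch),
                        terminal_crop = as.integer(terminal_crop)),
                   class = "network_config")
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  with(cfg, {
    if (depth_C < 1) stop("depth_C must be >= 1")
    if (width_F < 1) stop("width_F must be >= 1")
    if (fc_width < 1 || n_classes < 1 || in_channels < 1)
      stop("fc_width, n_classes and in_channels must be >= 1")
    if (terminal_crop < 0) stop("terminal_crop must be >= 0")
    if (input_patch <= 2 * depth_C + terminal_crop)
      stop("input_patch must exceed 2 * depth_C + terminal_crop")
    if (skip_start < 2 || skip_start > depth_C + 1)
      stop("skip_start must lie in [2, depth_C + 1]")
  })
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "network_config: C=%d conv layers x F=%d filters, fc %d, %d classes\n",
    x$depth_C, x$width_F, x$fc_width, x$n_classes))
  cat(sprintf(
    "  skips from layer %d, input %d^3 -> output %d^3, %s parameters\n",
    x$skip_start, x$input_patch, output_edge(x),
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Input channel count of each 3x3x3 layer under the skip topology.
layer_in_channels <- function(cfg) {
  ch_act <- c(cfg$in_channels, rep(cfg$width_F, cfg$depth_C))  # a_0 .. a_C
  vapply(seq_len(cfg$depth_C), function(j) {
    cin <- ch_act[j]                                  # channels of a_{j-1}
    if (j >= cfg$skip_start) cin <- cin + ch_act[j - 1]  # + cropped a_{j-2}
    as.integer(cin)
  }, 1L)
}

#' Trainable parameter count of a network configuration
#'
#' Sums weights and biases of every layer: `27 * c_in * F + F` per 3x3x3
#' layer (with `c_in` reflecting skip concatenations), plus the two 1x1x1
#' layers. Equals a brute-force enumeration of the built network's tensors.
#'
#' @param cfg a [network_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(cfg) {
  validate_network_config(cfg)
  cin <- layer_in_channels(cfg)
  conv <- sum(27 * cin * cfg$width_F + cfg$width_F)
  fc <- cfg$width_F * cfg$fc_width + cfg$fc_width
  out <- cfg$fc_width * cfg$n_classes + cfg$n_classes
  as.integer(conv + fc + out)
}

#' Spatial output edge of the network for a given input edge
#'
#' Valid padding shrinks every axis by 2 per 3x3x3 layer; `terminal_crop`
#' more voxels are removed from the high-index side. For the default
#' configuration, 107 -> 26.
#'
#' @param cfg a [network_config()].
#' @param input_edge input edge length (defaults to the training patch).
#' @return integer output edge.
#' @export
output_edge <- function(cfg, input_edge = cfg$input_patch) {
  min_edge <- 2 * cfg$depth_C + cfg$terminal_crop + 1
  if (input_edge < min_edge)
    stop(sprintf("input edge %d below the minimum %d for this configuration",
                 input_edge, min_edge))
  as.integer(input_edge - 2 * cfg$depth_C - cfg$terminal_crop)
}

#' Theoretical receptive field width
#'
#' `2 * depth_C + 1`: the input window that can influence one (pre-crop)
#' output voxel of a stack of `depth_C` 3x3x3 valid convolutions.
#'
#' @param cfg a [network_config()].
#' @return integer width in voxels.
#' @export
receptive_field <- function(cfg) as.integer(2 * cfg$depth_C + 1)

#' Build a trainable network from a configuration
#'
#' Initializes all weight tensors with variance-scaling (fan-in) Gaussian
#' draws and zero biases, seeded for reproducibility.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the initialization.
#' @return an object of class `cta_network`: list with `config`, `weights`
#'   (per-layer `W`/`b` tensors), and `seed`.
#' @export
build_network <- function(cfg, seed = 1L) {
  validate_network_config(cfg)
  cin <- layer_in_channels(cfg)
  weights <- with_seed(seed, {
    conv <- lapply(seq_len(cfg$depth_C), function(j) {
      fan_in <- 27 * cin[j]
      list(W = matrix(rnorm(fan_in * cfg$width_F, 0, sqrt(2 / fan_in)),
                      fan_in, cfg$width_F),
           b = numeric(cfg$width_F))
    })
    fc <- list(W = matrix(rnorm(cfg$width_F * cfg$fc_width, 0,
                                sqrt(2 / cfg$width_F)),
                          cfg$width_F, cfg$fc_width),
               b = numeric(cfg$fc_width))
    out <- list(W = matrix(rnorm(cfg$fc_width * cfg$n_classes, 0,
                                 sqrt(2 / cfg$fc_width)),
                           cfg$fc_width, cfg$n_classes),
                b = numeric(cfg$n_classes))
    list(conv = conv, fc = fc, out = out)
  })
  structure(list(config = cfg, weights = weights, seed = as.integer(seed)),
            class = "cta_network")
}

#' @export
print.cta_network <- function(x, ...) {
  cat("cta_network (seed", x$seed, ")\n")
  print(x$config)
  invisible(x)
}

#' Enumerate the trainable scalars of a built network
#'
#' Brute-force count over every tensor; the independent check of
#' [count_parameters()].
#'
#' @param net a `cta_network`.
#' @return integer total number of weight and bias scalars.
#' @export
enumerate_parameters <- function(net) {
  tensors <- c(unlist(lapply(net$weights$conv, function(l) list(l$W, l$b)),
                      recursive = FALSE),
               list(net$weights$fc$W, net$weights$fc$b,
                    net$weights$out$W, net$weights$out$b))
  as.integer(sum(vapply(tensors, length, 1)))
}

#' Save / load a network with its configuration manifest
#'
#' Weights are serialized to `<prefix>.rds`; the configuration and
#' initialization seed go to a JSON manifest at `<prefix>.json` so geometry
#' (output edge, parameter count) can be re-derived from the manifest alone.
#'
#' @param net a `cta_network`.
#' @param prefix file path prefix (no extension).
#' @return `save_network`: the prefix, invisibly; `load_network`: the
#'   `cta_network`.
#' @export
save_network <- function(net, prefix) {
  jsonlite::write_json(c(unclass(net$config), list(seed = net$seed)),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  saveRDS(net, paste0(prefix, ".rds"))
  invisible(prefix)
}

#' @rdname save_network
#' @param prefix file path prefix used at save time.
#' @export
load_network <- function(prefix) {
  net <- readRDS(paste0(prefix, ".rds"))
  manifest <- jsonlite::read_json(paste0(prefix, ".json"))
  stopifnot(manifest$depth_C == net$config$depth_C,
            manifest$width_F == net$config$width_F)
  net
}

elu <- function(z) pmax(z, 0) + expm1(pmin(z, 0))
elu_grad <- function(z) exp(pmin(z, 0))  # 1 where z > 0, exp(z) otherwise

crop1_sides <- function(a) {
  d <- dim(a)
  a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), , drop = FALSE]
}

crop_high <- function(a, k) {
  if (k == 0) return(a)
  d <- dim(a)
  a[1:(d[1] - k), 1:(d[2] - k), 1:(d[3] - k), , drop = FALSE]
}

concat4 <- function(a, b) {
  array(c(a, b), c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
}

#' Forward pass of the network
#'
#' Maps a two-channel input block of edge `n` to per-voxel class
#' probabilities of edge `n - 2 * depth_C - terminal_crop`. Accepts any input
#' at least the minimum edge (non-cubic blocks included); softmax
#' probabilities sum to 1 per voxel.
#'
#' @param net a `cta_network`.
#' @param x numeric array `[n1, n2, n3, in_channels]`.
#' @param cache keep intermediate activations for backpropagation.
#' @return list with `probs` (array `[o1, o2, o3, n_classes]`) and, when
#'   requested, `cache`.
#' @export
network_forward <- function(net, x, cache = FALSE) {
  cfg <- net$config
  if (length(dim(x)) != 4 || dim(x)[4] != cfg$in_channels)
    stop("input must be a 4D array with ", cfg$in_channels, " channels")
  min_edge <- 2 * cfg$depth_C + cfg$terminal_crop + 1
  if (any(dim(x)[1:3] < min_edge))
    stop(sprintf("input edge below the minimum %d for this configuration",
                 min_edge))
  W <- net$weights
  cc <- if (cache) list(inputs = vector("list", cfg$depth_C),
                        preact = vector("list", cfg$depth_C)) else NULL
  a_prev2 <- NULL
  a_prev <- x
  for (j in seq_len(cfg$depth_C)) {
    xin <- if (j >= cfg$skip_start) concat4(a_prev, crop1_sides(a_prev2))
           else a_prev
    z <- cpp_conv3d_forward(xin, W$conv[[j]]$W, W$conv[[j]]$b)
    if (cache) {
      cc$inputs[[j]] <- xin
      cc$preact[[j]] <- z
    }
    a <- array(elu(z), dim(z))
    a_prev2 <- a_prev
    a_prev <- a
  }
  ac <- crop_high(a_prev, cfg$terminal_crop)
  dsp <- dim(ac)[1:3]
  h <- matrix(ac, ncol = cfg$width_F)
  u <- h %*% W$fc$W
  u <- u + matrix(W$fc$b, nrow(u), cfg$fc_width, byrow = TRUE)
  r <- pmax(u, 0)
  logits <- r %*% W$out$W
  logits <- logits + matrix(W$out$b, nrow(logits), cfg$n_classes, byrow = TRUE)
  m <- logits[, 1]
  for (k in seq_len(cfg$n_classes)[-1]) m <- pmax(m, logits[, k])
  e <- exp(logits - m)
  p <- e / rowSums(e)
  probs <- array(p, c(dsp, cfg$n_classes))
  if (cache) {
    cc$h <- h; cc$u <- u; cc$r <- r; cc$p <- p
    cc$out_shape <- dsp
    list(probs = probs, cache = cc)
  } else {
    list(probs = probs)
  }
}

# Cross-entropy loss and parameter gradients for one input block.
# target: integer/logical array matching the output block (1 = lesion class).
network_backward <- function(net, fw, target) {
  cfg <- net$config
  W <- net$weights
  cc <- fw$cache
  dsp <- cc$out_shape
  N <- prod(dsp)
  y <- as.integer(as.logical(target))
  if (length(y) != N) stop("target does not match output block")
  p <- cc$p
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(N), y + 1L)], eps)))
  Y <- matrix(0, N, cfg$n_classes)
  Y[cbind(seq_len(N), y + 1L)] <- 1
  dlogits <- (p - Y) / N
  # grads mirror the weight structure (conv, fc, out) exactly
  g <- list(conv = vector("list", cfg$depth_C),
            fc = NULL, out = NULL)
  g$out <- list(W = crossprod(cc$r, dlogits), b = colSums(dlogits))
  dr <- dlogits %*% t(W$out$W)
  du <- dr * (cc$u > 0)
  g$fc <- list(W = crossprod(cc$h, du), b = colSums(du))
  dh <- du %*% t(W$fc$W)

  # gradient wrt the (cropped) final activation, embedded back uncropped
  dims_aC <- dsp + cfg$terminal_crop
  da <- vector("list", cfg$depth_C + 1)  # da[[j + 1]] = grad wrt a_j
  daC <- array(0, c(dims_aC, cfg$width_F))
  daC[seq_len(dsp[1]), seq_len(dsp[2]), seq_len(dsp[3]), ] <-
    array(dh, c(dsp, cfg$width_F))
  da[[cfg$depth_C + 1]] <- daC

  add_interior <- function(acc, delta) {
    # accumulate a one-voxel-per-side cropped gradient into the interior
    d <- dim(acc)
    acc[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), ] <-
      acc[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), , drop = FALSE] + delta
    acc
  }
  zeros_like_a <- function(j) {
    # a_j has the spatial shape of layer j's pre-activation; a_0 is the input
    if (j == 0) array(0, dim(cc$inputs[[1]])[1:3] |> c(cfg$in_channels))
    else array(0, dim(cc$preact[[j]]))
  }

  for (j in rev(seq_len(cfg$depth_C))) {
    z <- cc$preact[[j]]
    dz <- array(da[[j + 1]] * elu_grad(z), dim(z))
    bk <- cpp_conv3d_backward(cc$inputs[[j]], W$conv[[j]]$W, dz)
    g$conv[[j]] <- list(W = bk$gw, b = bk$gb)
    gx <- bk$gx
    ch_prev <- if (j == 1) cfg$in_channels else cfg$width_F
    d4 <- dim(gx)
    g_prev <- gx[, , , seq_len(ch_prev), drop = FALSE]
    if (is.null(da[[j]])) da[[j]] <- zeros_like_a(j - 1)
    da[[j]] <- da[[j]] + g_prev
    if (j >= cfg$skip_start) {
      g_skip <- gx[, , , (ch_prev + 1):d4[4], drop = FALSE]
      if (is.null(da[[j - 1]])) da[[j - 1]] <- zeros_like_a(j - 2)
      da[[j - 1]] <- add_interior(da[[j - 1]], g_skip)
    }
  }
  list(loss = loss, grads = g)
}
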