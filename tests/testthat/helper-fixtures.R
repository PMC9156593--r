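# Shared fixtures, built in code. Small grids keep unit tests fast; the
# acceptance suite uses the full desk-scale cohort conditions.

tiny_config <- function(depth_C = 3, width_F = 3, fc_width = 4,
                        input_patch = 2 * depth_C + 3, ...) {
  network_config(depth_C = depth_C, width_F = width_F, fc_width = fc_width,
                 input_patch = input_patch, ...)
}

# A two_channel_volume from bare arrays (no registration), for geometry and
# inference tests where channel content is irrelevant.
fake_tc <- function(dims, seed = 1, spacing = 1) {
  set.seed(seed)
  structure(list(channel_original = array(rnorm(prod(dims)), dims),
                 channel_mirrored = array(rnorm(prod(dims)), dims),
                 valid_mask = array(TRUE, dims),
                 spacing_mm = rep(spacing, 3),
                 provenance = list(hu_window = c(30, 60))),
            class = "two_channel_volume")
}

# Single-pass whole-volume prediction: the independent oracle for stitching.
single_pass_probs <- function(net, tc) {
  cfg <- net$config
  d <- dim(tc$channel_original)
  fill <- normalized_air_value()
  lo <- cfg$depth_C
  hi <- cfg$depth_C + cfg$terminal_crop
  pad <- array(fill, c(d + lo + hi, 2))
  pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 1] <-
    tc$channel_original
  pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 2] <-
    tc$channel_mirrored
  network_forward(net, pad)$probs[, , , 2]
}

# Brute-force pairwise concordance (Mann-Whitney with ties = 1/2): the
# independent AUC oracle.
concordance_auc <- function(volumes, labels) {
  pos <- volumes[labels]
  neg <- volumes[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

small_symmetric_phantom <- function(noise_seed = 3) {
  generate_phantom(phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = 2,
                                lesion_radii_mm = NULL,
                                noise_seed = noise_seed))
}
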