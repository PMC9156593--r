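#' Training plan
#'
#' Optimization settings for the patch-based training loop: Adam with
#' cross-entropy loss, class-balanced minibatches of `batch_pos` positive and
#' `batch_neg` negative patches (the balance contract requires them equal),
#' and early stopping when the validation loss fails to improve by more than
#' `min_delta` for `patience` consecutive epochs.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_pos,batch_neg patches per minibatch (default 4 and 4).
#' @param max_epochs maximum epochs (default 30, the full-training budget).
#' @param patience epochs without validation improvement before halting.
#' @param min_delta minimum improvement that resets the patience counter.
#' @param seed master seed for shuffles and sampling.
#' @return an object of class `train_plan`.
#' @export
train_plan <- function(learning_rate = 1e-4, batch_pos = 4, batch_neg = 4,
                       max_epochs = 30, patience = 3, min_delta = 1e-4,
                       seed = 1L) {
  if (batch_pos != batch_neg)
    stop("batch_pos must equal batch_neg (class-balance contract)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate, batch_pos = as.integer(batch_pos),
                 batch_neg = as.integer(batch_neg),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed)), class = "train_plan")
}

# Output-block corners tiling an axis of length d with blocks of edge e and
# the given stride; a final shifted corner keeps full coverage.
tile_axis_corners <- function(d, e, stride = e) {
  if (stride <= 0) stop("stride must be positive")
  if (d <= e) return(1L)
  as.integer(unique(c(seq(1L, d - e + 1L, by = stride), d - e + 1L)))
}

#' Enumerate training patches of a two-channel volume
#'
#' Tiles the volume with output blocks of the network's output edge at the
#' given stride and classifies each tile: positive when its output-aligned
#' target block contains at least `min_pos_voxels` lesion voxels, negative
#' otherwise. Tiles whose output block lies entirely outside the valid
#' (non-air) mask are discarded.
#'
#' @param tc a `two_channel_volume`.
#' @param mask lesion mask on the same grid.
#' @param cfg a [network_config()].
#' @param stride tile stride in voxels (default: the output edge, giving
#'   non-overlapping output blocks).
#' @param min_pos_voxels lesion voxels required for a positive label.
#' @return list with `positives` and `negatives` data frames (output-block
#'   corners `c1, c2, c3`, 1-based).
#' @export
enumerate_patches <- function(tc, mask, cfg,
                              stride = output_edge(cfg),
                              min_pos_voxels = 1) {
  if (!identical(dim(tc$channel_original), dim(mask)))
    stop("mask must be on the same grid as the volume")
  e <- output_edge(cfg)
  d <- dim(mask)
  cs <- lapply(1:3, function(ax) tile_axis_corners(d[ax], e, stride))
  g <- expand.grid(c1 = cs[[1]], c2 = cs[[2]], c3 = cs[[3]])
  npos <- integer(nrow(g))
  nval <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    i1 <- g$c1[i]:min(g$c1[i] + e - 1L, d[1])
    i2 <- g$c2[i]:min(g$c2[i] + e - 1L, d[2])
    i3 <- g$c3[i]:min(g$c3[i] + e - 1L, d[3])
    npos[i] <- sum(mask[i1, i2, i3])
    nval[i] <- sum(tc$valid_mask[i1, i2, i3])
  }
  keep <- nval > 0
  g <- g[keep, , drop = FALSE]
  pos <- npos[keep] >= min_pos_voxels
  list(positives = g[pos, , drop = FALSE],
       negatives = g[!pos, , drop = FALSE])
}

#' Iterations per epoch under balanced sampling
#'
#' An epoch shows every positive patch once with a matched number of
#' negatives, so it comprises `ceil(n_pos / batch_pos)` iterations (750 for
#' 3,000 positives at 4 per minibatch).
#'
#' @param n_pos number of positive patches.
#' @param batch_pos positive patches per minibatch.
#' @return integer iteration count.
#' @export
iterations_per_epoch <- function(n_pos, batch_pos = 4) {
  if (batch_pos < 1) stop("batch_pos must be >= 1")
  if (n_pos == 0) stop("no positive patches")
  as.integer(ceiling(n_pos / batch_pos))
}

#' Balanced minibatch stream
#'
#' Returns a stateful iterator over minibatches with exactly `batch_pos`
#' positives and `batch_neg` negatives. Each epoch shuffles the positives
#' (seeded) and visits every positive once; when the positive count is not a
#' multiple of the batch size, the final minibatch is topped up with
#' already-seen positives so the 50/50 balance holds exactly. Negatives are
#' sampled without replacement until the pool is exhausted, then reshuffled.
#'
#' @param positives,negatives data frames of patch indices (rows are
#'   patches); positives must be nonempty.
#' @param plan a [train_plan()].
#' @return function of no arguments; each call returns
#'   `list(pos = rows, neg = rows, epoch, iteration)`.
#' @export
balanced_batch_stream <- function(positives, negatives, plan) {
  np <- nrow(positives)
  nn <- nrow(negatives)
  if (np == 0) stop("no positive patches")
  if (nn == 0) stop("no negative patches")
  bp <- plan$batch_pos
  bn <- plan$batch_neg
  st <- new.env(parent = emptyenv())
  st$rng <- NULL
  st$epoch <- 0L
  st$iter_in_epoch <- 0L
  st$iters_per_epoch <- iterations_per_epoch(np, bp)
  st$pos_order <- integer(0)
  st$neg_pool <- integer(0)
  draw <- function(expr) {
    # run expr under the stream's private RNG state
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    if (is.null(st$rng)) set.seed(plan$seed) else
      assign(".Random.seed", st$rng, envir = globalenv())
    val <- expr
    st$rng <- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    val
  }
  function() {
    if (st$iter_in_epoch == 0L || st$iter_in_epoch >= st$iters_per_epoch) {
      if (st$iter_in_epoch >= st$iters_per_epoch) st$iter_in_epoch <- 0L
      st$epoch <- st$epoch + 1L
      st$pos_order <- draw(sample.int(np))
    }
    st$iter_in_epoch <- st$iter_in_epoch + 1L
    lo <- (st$iter_in_epoch - 1L) * bp + 1L
    hi <- min(st$iter_in_epoch * bp, np)
    pos_idx <- st$pos_order[lo:hi]
    if (length(pos_idx) < bp)
      pos_idx <- c(pos_idx, draw(sample(st$pos_order[seq_len(lo - 1L)],
                                        bp - length(pos_idx))))
    neg_idx <- integer(0)
    while (length(neg_idx) < bn) {
      if (length(st$neg_pool) == 0L) st$neg_pool <- draw(sample.int(nn))
      take <- min(bn - length(neg_idx), length(st$neg_pool))
      neg_idx <- c(neg_idx, st$neg_pool[seq_len(take)])
      st$neg_pool <- st$neg_pool[-seq_len(take)]
    }
    list(pos = positives[pos_idx, , drop = FALSE],
         neg = negatives[neg_idx, , drop = FALSE],
         epoch = st$epoch, iteration = st$iter_in_epoch)
  }
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(weights) {
  zero <- function(w) {
    if (is.list(w)) lapply(w, zero) else w * 0
  }
  list(m = zero(weights), v = zero(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- list(w = vector("list", length(w)), m = vector("list", length(w)),
                  v = vector("list", length(w)))
      names(out$w) <- names(w)
      for (k in seq_along(w)) {
        r <- upd(w[[k]], g[[k]], m[[k]], v[[k]])
        out$w[[k]] <- r$w; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(w = w - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  r <- upd(weights, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(weights = r$w, state = state)
}

scale_grads <- function(g, f) {
  if (is.list(g)) lapply(g, scale_grads, f = f) else g * f
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) Map(add_grads, a, b) else a + b
}

# ---- datasets ------------------------------------------------------------

#' Build a patch dataset from preprocessed cases
#'
#' Pads each two-channel volume for valid-convolution patch extraction,
#' enumerates positive/negative patch indices per case, and returns the
#' pooled index tables plus a patch fetcher.
#'
#' @param cases list of cases, each `list(case_id, tc, mask)` where `tc` is a
#'   `two_channel_volume` and `mask` the lesion mask (may be all-`FALSE`).
#' @param cfg a [network_config()].
#' @param stride tile stride (default: output edge).
#' @param min_pos_voxels positive-label threshold.
#' @return list with `positives`, `negatives` (data frames with `case_id`),
#'   and `fetch(row)` returning `list(x, y)` for a patch-index row.
#' @export
patch_dataset <- function(cases, cfg, stride = output_edge(cfg),
                          min_pos_voxels = 1) {
  e <- output_edge(cfg)
  inlen <- e + 2L * cfg$depth_C + cfg$terminal_crop
  fill <- normalized_air_value()
  store <- new.env(parent = emptyenv())
  pos_all <- list(); neg_all <- list()
  for (cs in cases) {
    idx <- enumerate_patches(cs$tc, cs$mask, cfg, stride = stride,
                             min_pos_voxels = min_pos_voxels)
    d <- dim(cs$mask)
    lo <- cfg$depth_C
    hi <- cfg$depth_C + cfg$terminal_crop
    pad <- array(fill, c(d[1] + lo + hi, d[2] + lo + hi, d[3] + lo + hi, 2L))
    pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 1] <-
      cs$tc$channel_original
    pad[lo + seq_len(d[1]), lo + seq_len(d[2]), lo + seq_len(d[3]), 2] <-
      cs$tc$channel_mirrored
    assign(cs$case_id, list(pad = pad, mask = cs$mask), envir = store)
    if (nrow(idx$positives)) {
      idx$positives$case_id <- cs$case_id
      pos_all[[length(pos_all) + 1]] <- idx$positives
    }
    if (nrow(idx$negatives)) {
      idx$negatives$case_id <- cs$case_id
      neg_all[[length(neg_all) + 1]] <- idx$negatives
    }
  }
  empty <- data.frame(c1 = integer(0), c2 = integer(0), c3 = integer(0),
                      case_id = character(0))
  fetch <- function(row) {
    obj <- get(row$case_id, envir = store)
    # padded coordinate of output corner c equals c for the input block start
    x <- obj$pad[row$c1 + 0:(inlen - 1L), row$c2 + 0:(inlen - 1L),
                 row$c3 + 0:(inlen - 1L), , drop = FALSE]
    d <- dim(obj$mask)
    i1 <- row$c1:min(row$c1 + e - 1L, d[1])
    i2 <- row$c2:min(row$c2 + e - 1L, d[2])
    i3 <- row$c3:min(row$c3 + e - 1L, d[3])
    y <- array(FALSE, c(e, e, e))
    y[seq_along(i1), seq_along(i2), seq_along(i3)] <-
      obj$mask[i1, i2, i3]
    list(x = x, y = y)
  }
  list(positives = if (length(pos_all)) do.call(rbind, pos_all) else empty,
       negatives = if (length(neg_all)) do.call(rbind, neg_all) else empty,
       fetch = fetch)
}

# ---- training loop -------------------------------------------------------

#' Generic epoch loop with early stopping
#'
#' Runs up to `plan$max_epochs` epochs, recording train/validation loss, and
#' halts once the validation loss has failed to improve by more than
#' `plan$min_delta` for `plan$patience` consecutive epochs. Returns the
#' snapshot taken at the best validation loss.
#'
#' @param plan a [train_plan()].
#' @param epoch_fn function(epoch) running one training epoch and returning
#'   its mean training loss.
#' @param val_fn function() returning the current validation loss.
#' @param snapshot_fn function() capturing the current weights.
#' @return list with `best` (snapshot at the best epoch), `history` (data
#'   frame of epoch, train_loss, val_loss), and `best_epoch`.
#' @export
run_train_loop <- function(plan, epoch_fn, val_fn, snapshot_fn) {
  best_loss <- Inf
  best <- NULL
  best_epoch <- NA_integer_
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (epoch in seq_len(plan$max_epochs)) {
    tr <- epoch_fn(epoch)
    vl <- val_fn()
    if (!is.finite(tr) || !is.finite(vl))
      stop(sprintf("non-finite loss at epoch %d (train %g, val %g)",
                   epoch, tr, vl))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr,
                                   val_loss = vl))
    if (vl < best_loss - plan$min_delta) {
      best_loss <- vl
      best <- snapshot_fn()
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= plan$patience) break
    }
  }
  list(best = best, history = hist, best_epoch = best_epoch)
}

# Cross-entropy of predicted probabilities against a binary target block.
ce_loss <- function(probs, y) {
  n <- length(y)
  p1 <- probs[, , , 2]
  eps <- 1e-12
  -mean(ifelse(as.logical(y), log(pmax(p1, eps)), log(pmax(1 - p1, eps))))
}

#' Train a network on a patch dataset
#'
#' Optimizes mean per-voxel cross-entropy over output blocks with Adam,
#' drawing class-balanced minibatches from the training dataset. Validation
#' loss is computed each epoch on a fixed balanced sample of the validation
#' dataset; training halts per the plan's early-stopping rule and the weights
#' with the best validation loss are returned.
#'
#' @param net a `cta_network`.
#' @param train_ds,val_ds datasets from [patch_dataset()].
#' @param plan a [train_plan()].
#' @param verbose print per-epoch losses.
#' @return list with `net` (best weights), `history`, and `best_epoch`.
#' @export
train_model <- function(net, train_ds, val_ds, plan, verbose = FALSE) {
  stream <- balanced_batch_stream(train_ds$positives, train_ds$negatives, plan)
  n_iter <- iterations_per_epoch(nrow(train_ds$positives), plan$batch_pos)
  opt <- adam_state(net$weights)

  # fixed balanced validation sample
  nvp <- nrow(val_ds$positives)
  if (nvp == 0) stop("validation set has no positive patches")
  nvn <- min(nvp, nrow(val_ds$negatives))
  val_rows <- with_seed(plan$seed + 1L, {
    vp <- val_ds$positives
    vn <- val_ds$negatives[sample.int(nrow(val_ds$negatives), nvn), ,
                           drop = FALSE]
    rbind(vp, vn)
  })
  val_samples <- lapply(seq_len(nrow(val_rows)),
                        function(i) val_ds$fetch(val_rows[i, , drop = FALSE]))

  epoch_fn <- function(epoch) {
    losses <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      batch <- stream()
      rows <- rbind(batch$pos, batch$neg)
      gacc <- NULL
      lacc <- 0
      for (i in seq_len(nrow(rows))) {
        s <- train_ds$fetch(rows[i, , drop = FALSE])
        fw <- network_forward(net, s$x, cache = TRUE)
        bk <- network_backward(net, fw, s$y)
        gacc <- add_grads(gacc, bk$grads)
        lacc <- lacc + bk$loss
      }
      g <- scale_grads(gacc, 1 / nrow(rows))
      st <- adam_step(net$weights, g, opt, plan$learning_rate)
      net$weights <<- st$weights
      opt <<- st$state
      losses[it] <- lacc / nrow(rows)
    }
    mean(losses)
  }
  val_fn <- function() {
    mean(vapply(val_samples, function(s) {
      fw <- network_forward(net, s$x)
      ce_loss(fw$probs, s$y)
    }, 1))
  }
  res <- run_train_loop(plan, epoch_fn, val_fn, function() net$weights)
  if (verbose) print(res$history)
  net$weights <- res$best
  list(net = net, history = res$history, best_epoch = res$best_epoch)
}

#' Depth-by-width hyper-parameter grid search
#'
#' Trains one network per (depth, width) combination and ranks the
#' configurations by their best validation loss.
#'
#' @param depths,widths integer vectors of candidate `depth_C` / `width_F`.
#' @param train_ds,val_ds datasets from [patch_dataset()]; patch geometry
#'   must be compatible with every candidate depth.
#' @param plan a [train_plan()].
#' @param input_patch training patch edge for the candidates.
#' @param train_fn training backend, `function(net, train_ds, val_ds, plan)`;
#'   defaults to [train_model()].
#' @param ... further arguments to [network_config()].
#' @return data frame ranked by best validation loss (best first), with the
#'   fitted models and histories attached as the `runs` attribute.
#' @export
grid_search <- function(depths, widths, train_ds, val_ds, plan,
                        input_patch = 107, train_fn = train_model, ...) {
  if (length(depths) == 0 || length(widths) == 0)
    stop("depths and widths must be nonempty")
  combos <- expand.grid(depth_C = depths, width_F = widths)
  runs <- vector("list", nrow(combos))
  best <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- network_config(depth_C = combos$depth_C[i],
                          width_F = combos$width_F[i],
                          input_patch = input_patch, ...)
    net <- build_network(cfg, seed = plan$seed + i)
    runs[[i]] <- train_fn(net, train_ds, val_ds, plan)
    best[i] <- min(runs[[i]]$history$val_loss)
  }
  combos$best_val_loss <- best
  ord <- order(best)
  out <- combos[ord, , drop = FALSE]
  attr(out, "runs") <- runs[ord]
  out
}
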