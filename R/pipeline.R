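#' Pipeline run configuration
#'
#' Aggregates every tunable of the end-to-end pipeline. The defaults
#' reproduce the published operating point: 0.5 mm working resolution,
#' 30-60 HU normalization window, 175 mm head region, probability threshold
#' 0.5, 3 mL minimum cluster volume, 25 mL stroke decision threshold, and
#' the default [network_config()] / [train_plan()].
#'
#' @param working_resolution_mm isotropic working voxel size (mm).
#' @param hu_window HU normalization window.
#' @param head_extent_mm axial head-region extent below the skull apex.
#' @param probability_threshold lesion probability threshold (inclusive).
#' @param min_component_ml minimum connected-cluster volume (mL).
#' @param decision_ml case-level stroke decision threshold (mL).
#' @param connectivity cluster connectivity (6/18/26).
#' @param network a [network_config()].
#' @param train a [train_plan()].
#' @param register a [register_params()].
#' @param bootstrap_reps bootstrap replicates used for the confidence
#'   intervals of an experiment report.
#' @param seed master seed; every downstream source of randomness derives
#'   from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(working_resolution_mm = 0.5,
                       hu_window = c(30, 60),
                       head_extent_mm = 175,
                       probability_threshold = 0.5,
                       min_component_ml = 3,
                       decision_ml = 25,
                       connectivity = 26,
                       network = network_config(),
                       train = train_plan(),
                       register = register_params(),
                       bootstrap_reps = 10000,
                       seed = 1L) {
  structure(list(working_resolution_mm = working_resolution_mm,
                 hu_window = hu_window, head_extent_mm = head_extent_mm,
                 probability_threshold = probability_threshold,
                 min_component_ml = min_component_ml,
                 decision_ml = decision_ml, connectivity = connectivity,
                 network = network, train = train, register = register,
                 bootstrap_reps = bootstrap_reps, seed = as.integer(seed)),
            class = "run_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Write / read a run configuration as YAML
#'
#' Every field round-trips unchanged, including the nested network, training
#' and registration blocks.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: the path, invisibly. `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(working_resolution_mm = y$working_resolution_mm,
             hu_window = unlist(y$hu_window),
             head_extent_mm = y$head_extent_mm,
             probability_threshold = y$probability_threshold,
             min_component_ml = y$min_component_ml,
             decision_ml = y$decision_ml,
             connectivity = y$connectivity,
             network = do.call(network_config, y$network),
             train = do.call(train_plan, y$train),
             register = do.call(register_params, y$register),
             bootstrap_reps = y$bootstrap_reps,
             seed = y$seed)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; changing any constant changes
#' the hash. Carried in every written artifact for provenance.
#'
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                           digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Preprocess one CTA volume (and optional mask) for the network
#'
#' Runs the full preprocessing chain: head-region extraction, isotropic
#' resampling (linear for the image, nearest-neighbour for the mask), HU
#' normalization, and mirror co-registration.
#'
#' @param vol a [ct_volume()] in HU.
#' @param mask optional lesion mask on the same grid.
#' @param config a [run_config()].
#' @return list with `tc` (a `two_channel_volume`), `mask` (resampled, or
#'   all-`FALSE`), and `volume_hu` (the preprocessed HU volume).
#' @export
preprocess_case <- function(vol, mask = NULL, config = run_config()) {
  head <- extract_head_region(vol, config$head_extent_mm)
  kept <- attr(head, "kept_slices")
  iso <- resample_isotropic(head, config$working_resolution_mm)
  if (!is.null(mask)) {
    mvol <- ct_volume(array(as.numeric(mask), dim(mask)),
                      spacing_mm = vol$spacing_mm,
                      orientation = vol$orientation)
    mvol$voxels <- mvol$voxels[, , kept, drop = FALSE]
    miso <- resample_isotropic(mvol, config$working_resolution_mm,
                               method = "nearest")
    mask_out <- miso$voxels > 0.5
  } else {
    mask_out <- array(FALSE, dim(iso$voxels))
  }
  norm <- normalize_hu(iso, config$hu_window)
  tc <- mirror_register(norm, params = config$register, seed = config$seed)
  list(tc = tc, mask = mask_out, volume_hu = iso)
}

#' Predict a lesion map and stroke call for one volume
#'
#' Executes preprocess, stitched network inference, and post-processing.
#' Optionally writes the probability map and binary mask as NIfTI, axial
#' overlay PNGs, and a JSON report (volumes, stroke call, provenance,
#' wall-times).
#'
#' @param vol a [ct_volume()] or a NIfTI path.
#' @param net a `cta_network` (its configuration must match
#'   `config$network`).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `pmap` (a `prob_map`), `prediction` (a
#'   `lesion_prediction`), and `report` (a list).
#' @export
run_predict <- function(vol, net, config = run_config(), out_dir = NULL) {
  if (is.character(vol)) vol <- read_volume(vol)
  if (!identical(unclass(net$config), unclass(config$network)))
    stop("network manifest does not match the configured geometry")
  t0 <- proc.time()[["elapsed"]]
  pp <- preprocess_case(vol, mask = NULL, config = config)
  t1 <- proc.time()[["elapsed"]]
  pmap <- stitch_predict(net, pp$tc, config$network)
  t2 <- proc.time()[["elapsed"]]
  bin <- binarize(pmap, config$probability_threshold)
  pred <- filter_components(bin, pmap$spacing_mm,
                            min_ml = config$min_component_ml,
                            connectivity = config$connectivity)
  call <- classify_stroke(pred$largest_volume_ml, config$decision_ml)
  t3 <- proc.time()[["elapsed"]]
  report <- list(largest_volume_ml = pred$largest_volume_ml,
                 components = pred$components,
                 stroke_call = call,
                 config_hash = config_hash(config),
                 registration = pp$tc$provenance[c("stages_used", "warnings",
                                                   "residual_rigid",
                                                   "residual_deformable")],
                 timings_s = list(preprocess = t1 - t0, inference = t2 - t1,
                                  postprocess = t3 - t2))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(array(pmap$probs, dim(pmap$probs)),
                 file.path(out_dir, "probability.nii.gz"),
                 spacing_mm = pmap$spacing_mm)
    write_volume(pred$binary_mask, file.path(out_dir, "lesion_mask.nii.gz"),
                 spacing_mm = pmap$spacing_mm)
    cal <- calibrate_colormap(pmax(pmap$probs[pred$binary_mask], 0.5))
    if (any(pred$binary_mask))
      render_overlay(pp$volume_hu, pmap, cal,
                     dir = file.path(out_dir, "overlay"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(pmap = pmap, prediction = pred, report = report)
}

#' Train and evaluate on a split cohort
#'
#' Trains on the train split (early-stopping on the validation split) and
#' evaluates the test split: pooled voxel metrics with case-level stratified
#' bootstrap CIs, volume-threshold ROC with AUC CI, case-level confusion at
#' the configured decision threshold, and volume agreement against the
#' reference lesion volumes.
#'
#' @param cohort list of cases (as from [generate_cohort()]), each carrying
#'   `case_id`, `label`, `volume`, `mask`, `lesion_volume_ml`.
#' @param splits character vector (same length) of
#'   `"train"`/`"validation"`/`"test"` assignments.
#' @param config a [run_config()].
#' @param verbose print progress.
#' @return an object of class `eval_report`.
#' @export
run_experiment <- function(cohort, splits, config = run_config(),
                           verbose = FALSE) {
  if (length(splits) != length(cohort)) stop("one split per case required")
  if (!all(c("train", "validation", "test") %in% splits))
    stop("cohort must contain train, validation and test splits")
  notices <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocessing %d cases", length(cohort))
  pp <- lapply(cohort, function(cs)
    c(list(case_id = cs$case_id, label = cs$label,
           reference_volume_ml = cs$lesion_volume_ml),
      preprocess_case(cs$volume, cs$mask, config)))

  cfg <- config$network
  train_ds <- patch_dataset(pp[splits == "train"], cfg)
  val_ds <- patch_dataset(pp[splits == "validation"], cfg)
  say("training on %d positive / %d negative patches",
      nrow(train_ds$positives), nrow(train_ds$negatives))
  net <- build_network(cfg, seed = config$seed)
  fit <- train_model(net, train_ds, val_ds, config$train)
  net <- fit$net

  test <- pp[splits == "test"]
  say("evaluating %d test cases", length(test))
  rows <- vector("list", length(test))
  counts <- vector("list", length(test))
  for (i in seq_along(test)) {
    cs <- test[[i]]
    pmap <- stitch_predict(net, cs$tc, cfg)
    bin <- binarize(pmap, config$probability_threshold)
    pred <- filter_components(bin, pmap$spacing_mm,
                              min_ml = config$min_component_ml,
                              connectivity = config$connectivity)
    vm <- voxel_metrics(pred$binary_mask, cs$mask, cs$tc$valid_mask)
    counts[[i]] <- data.frame(case_id = cs$case_id, label = cs$label,
                              tp = vm$tp, fp = vm$fp, fn = vm$fn, tn = vm$tn)
    rows[[i]] <- data.frame(case_id = cs$case_id, label = cs$label,
                            predicted_volume_ml = pred$largest_volume_ml,
                            reference_volume_ml = cs$reference_volume_ml,
                            stroke_call = classify_stroke(
                              pred$largest_volume_ml, config$decision_ml))
  }
  cases <- do.call(rbind, rows)
  counts <- do.call(rbind, counts)

  # pooled voxel metrics + case-level stratified bootstrap CI for Dice
  voxel <- NULL
  dice_ci <- NULL
  if (sum(counts$tp + counts$fn) == 0) {
    notices <- c(notices, "no lesion voxels in the test split; voxel metrics skipped")
  } else {
    tp <- sum(counts$tp); fp <- sum(counts$fp)
    fn <- sum(counts$fn); tn <- sum(counts$tn)
    voxel <- structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                            precision = tp / (tp + fp),
                            sensitivity = tp / (tp + fn),
                            dice = 2 * tp / (2 * tp + fp + fn)),
                       class = "voxel_metrics")
    dice_ci <- bootstrap_ci(counts, function(d) {
      2 * sum(d$tp) / (2 * sum(d$tp) + sum(d$fp) + sum(d$fn))
    }, reps = config$bootstrap_reps, seed = config$seed,
    strata = counts$label)
  }

  roc <- roc_volume_threshold(cases$predicted_volume_ml, cases$label)
  auc_ci <- bootstrap_ci(cases, function(d) {
    if (length(unique(d$label)) < 2) return(NA_real_)
    roc_volume_threshold(d$predicted_volume_ml, d$label)$auc
  }, reps = config$bootstrap_reps, seed = config$seed + 1L,
  strata = cases$label)

  is_stroke <- cases$label == "stroke"
  cm <- case_metrics(tp = sum(cases$stroke_call & is_stroke),
                     fp = sum(cases$stroke_call & !is_stroke),
                     tn = sum(!cases$stroke_call & !is_stroke),
                     fn = sum(!cases$stroke_call & is_stroke))
  acc_ci <- bootstrap_ci(cases, function(d) {
    mean(d$stroke_call == (d$label == "stroke"))
  }, reps = config$bootstrap_reps, seed = config$seed + 2L,
  strata = cases$label)

  agreement <- NULL
  ag_rows <- is_stroke & cases$predicted_volume_ml > 0
  if (sum(ag_rows) >= 3 && sd(cases$predicted_volume_ml[ag_rows]) > 0) {
    agreement <- volume_agreement(cases$predicted_volume_ml[ag_rows],
                                  cases$reference_volume_ml[ag_rows],
                                  seed = config$seed + 3L,
                                  reps = config$bootstrap_reps,
                                  ci = sum(ag_rows) >= 8)
  } else {
    notices <- c(notices, "too few detected stroke lesions for volume agreement")
  }

  structure(list(voxel = voxel, dice_ci = dice_ci,
                 cases = cases, case_metrics = cm, accuracy_ci = acc_ci,
                 roc = roc, auc_ci = auc_ci, agreement = agreement,
                 history = fit$history, best_epoch = fit$best_epoch,
                 notices = notices, config_hash = config_hash(config),
                 net = net),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\n")
  if (!is.null(x$voxel))
    cat(sprintf("  voxel: precision %.3f sensitivity %.3f Dice %.3f (CI %.3f-%.3f)\n",
                x$voxel$precision, x$voxel$sensitivity, x$voxel$dice,
                x$dice_ci["lo"], x$dice_ci["hi"]))
  cat(sprintf("  cases: accuracy %.3f (CI %.3f-%.3f), AUC %.3f (CI %.3f-%.3f)\n",
              x$case_metrics$accuracy, x$accuracy_ci["lo"], x$accuracy_ci["hi"],
              x$roc$auc, x$auc_ci["lo"], x$auc_ci["hi"]))
  cat(sprintf("  optimal volume threshold: %.1f mL\n", x$roc$optimal_threshold))
  if (!is.null(x$agreement)) print(x$agreement)
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  x <- report
  x$net <- NULL
  x <- lapply(unclass(x), function(el)
    if (is.object(el)) unclass(el) else el)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
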