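# Orchestration: the four-step TTA loop (augment -> predict -> dis-augment
# -> merge) around a pluggable predictor, plus batch processing with
# evaluation. The engine never inspects pixel content itself; all science
# lives in the fusion and metric modules.

#' Run configuration
#'
#' Defaults reproduce the reference settings: the six-transform
#' augmentation set, IoU matching threshold 0.5, semantic threshold 0.5,
#' and the 10-threshold metric grid.
#'
#' @param augs An [augmentation_set()]; default [default_augmentation_set()].
#' @param mode `"instance"` or `"semantic"`.
#' @param min_iou Instance matching threshold; default 0.5.
#' @param threshold Semantic binarization threshold; default 0.5.
#' @param thresholds Metric IoU grid; default [default_threshold_grid()].
#' @param seed Seed forwarded to seeded components; default 1.
#' @param keep_views Keep all per-view dis-augmented predictions in the
#'   [tta_predict()] result; default `FALSE`.
#' @return A `run_config` list.
#' @export
run_config <- function(augs = default_augmentation_set(),
                       mode = c("instance", "semantic"),
                       min_iou = 0.5, threshold = 0.5,
                       thresholds = default_threshold_grid(),
                       seed = 1L, keep_views = FALSE) {
  if (!inherits(augs, "augmentation_set")) augs <- augmentation_set(augs)
  mode <- match.arg(mode)
  stopifnot(min_iou >= 0, min_iou <= 1, threshold >= 0, threshold <= 1)
  structure(list(augs = augs, mode = mode, min_iou = min_iou,
                 threshold = threshold, thresholds = thresholds,
                 seed = as.integer(seed), keep_views = keep_views),
            class = "run_config")
}

check_prediction <- function(pred, mode, expected_dim, view, transform) {
  bad <- function(why) {
    stop("predictor contract violation at view ", view, " (", transform,
         "): ", why, call. = FALSE)
  }
  if (mode == "instance") {
    if (!inherits(pred, "instance_set")) bad("expected an instance_set")
    if (!identical(pred$dim, as.integer(expected_dim))) {
      bad(paste0("canvas ", paste(pred$dim, collapse = "x"),
                 ", expected ", paste(expected_dim, collapse = "x")))
    }
  } else {
    if (!is.matrix(pred) || !is.numeric(pred)) {
      bad("expected a numeric probability matrix")
    }
    if (!identical(as.integer(dim(pred)), as.integer(expected_dim))) {
      bad(paste0("dims ", paste(dim(pred), collapse = "x"),
                 ", expected ", paste(expected_dim, collapse = "x")))
    }
    if (anyNA(pred) || min(pred) < 0 || max(pred) > 1) {
      bad("probability values outside [0, 1]")
    }
  }
  invisible(pred)
}

#' Test-time-augmented prediction for one image
#'
#' The four-step loop: for every transform in the augmentation set, the
#' image is augmented, the predictor is invoked on the augmented image, and
#' the prediction is dis-augmented back to the original frame; the
#' per-view predictions are then merged — probability averaging plus
#' thresholding in semantic mode, IoU matching plus majority voting
#' ([merge_instances()]) in instance mode. The identity view's prediction
#' is returned alongside as the "original" (no-TTA) baseline for delta
#' reporting.
#'
#' @param image H x W matrix (or H x W x C array) — the test image. Passed
#'   through to the predictor after augmentation; the engine itself never
#'   reads pixel values.
#' @param predictor Function `(image, view, transform)` returning a
#'   probability matrix (semantic) or an [instance_set()] (instance) in the
#'   frame of its input.
#' @param config A [run_config()].
#' @return A list: `merged` and `original` (instance sets, or logical masks
#'   in semantic mode), `merged_prob`/`original_prob` (semantic mode only),
#'   and `views` (all dis-augmented predictions) when `keep_views` is set.
#' @export
tta_predict <- function(image, predictor, config = run_config()) {
  stopifnot(inherits(config, "run_config"), is.function(predictor))
  canvas <- dim(image)[1:2]
  n <- length(config$augs)
  views <- vector("list", n)
  for (v in seq_len(n)) {
    tr <- config$augs[[v]]
    timg <- apply_transform(tr, image)
    pred <- predictor(timg, v, tr)
    check_prediction(pred, config$mode, transformed_dim(tr, canvas),
                     view = v, transform = tr)
    views[[v]] <- disaugment(tr, pred, canvas = canvas)
  }
  if (config$mode == "semantic") {
    merged_prob <- merge_probmaps(views)
    out <- list(merged = binarize(merged_prob, config$threshold),
                original = binarize(views[[1L]], config$threshold),
                merged_prob = merged_prob,
                original_prob = views[[1L]])
  } else {
    out <- list(merged = merge_instances(views, min_iou = config$min_iou),
                original = views[[1L]])
  }
  if (config$keep_views) out$views <- views
  out
}

#' A predictor backed by an external command
#'
#' Adapter for models that live outside R: for each view the augmented
#' image is written to a file, `command` is invoked with the image path and
#' an output path as its two trailing arguments, and the mask it writes is
#' read back (PGM labeled mask in instance mode, [read_probmap()] text in
#' semantic mode). No deep-learning stack is imported.
#'
#' @param command Command to run (given image-path and output-path
#'   arguments).
#' @param mode `"instance"` or `"semantic"`.
#' @param dir Scratch directory for the exchange files; default `tempdir()`.
#' @return A predictor function usable with [tta_predict()].
#' @export
subprocess_predictor <- function(command, mode = c("instance", "semantic"),
                                 dir = tempdir()) {
  mode <- match.arg(mode)
  function(image, view, transform) {
    img_path <- file.path(dir, sprintf("view_%d_in.pgm", view))
    out_path <- file.path(dir, sprintf("view_%d_out.%s", view,
                                       if (mode == "instance") "pgm" else "txt"))
    write_pgm(image, img_path)
    status <- system2(command, c(img_path, out_path))
    if (!identical(status, 0L)) {
      stop("predictor command failed (exit ", status, ") at view ", view,
           call. = FALSE)
    }
    if (mode == "instance") {
      instance_set_from_labels(read_pgm(out_path), view_id = view)
    } else {
      read_probmap(out_path)
    }
  }
}

#' Batch TTA over a directory of images
#'
#' Images (`*.pgm`) are processed one by one; when a ground-truth labeled
#' mask with the same file stem exists in `gt_dir`, the image is evaluated
#' (DSB mAP in instance mode, pixel IoU of the binarized masks in semantic
#' mode) for both the merged and the original prediction. Writes per-image
#' merged/original masks, a per-image CSV of scores and deltas, and a JSON
#' summary (mean/median delta, Wilcoxon p-value).
#'
#' @param image_dir Directory of input `*.pgm` images.
#' @param predictor_for Function `(image, image_id)` returning the
#'   per-image predictor contract (a plain predictor function is also
#'   accepted and used for every image).
#' @param config A [run_config()].
#' @param gt_dir Optional directory of ground-truth labeled `*.pgm` masks.
#' @param out_dir Output directory; created if missing.
#' @param quiet Suppress per-image progress messages.
#' @return Invisibly, a list with `records` (data frame, `NULL` without
#'   ground truth), `comparison` (a [compare_scores()] result or `NULL`),
#'   and the output paths.
#' @export
run_batch <- function(image_dir, predictor_for, config = run_config(),
                      gt_dir = NULL, out_dir = file.path(image_dir, "tta_out"),
                      quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  files <- sort(list.files(image_dir, pattern = "\\.pgm$", full.names = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  if (!length(files)) {
    warning("no .pgm images found in ", image_dir, call. = FALSE)
    return(invisible(list(records = NULL, comparison = NULL,
                          out_dir = out_dir)))
  }
  orig_scores <- numeric(0)
  merged_scores <- numeric(0)
  ids <- character(0)
  for (f in files) {
    id <- sub("\\.pgm$", "", basename(f))
    img <- read_pgm(f)
    predictor <- if (length(formals(predictor_for)) >= 3L) {
      predictor_for
    } else {
      predictor_for(img, id)
    }
    res <- tta_predict(img, predictor, config)
    if (config$mode == "instance") {
      write_pgm(instance_labels(res$merged),
                file.path(out_dir, paste0(id, "_merged.pgm")))
      write_pgm(instance_labels(res$original),
                file.path(out_dir, paste0(id, "_original.pgm")))
      say(id, ": ", length(res$original), " object(s) in the original view, ",
          length(res$merged), " kept after merging")
    } else {
      write_pgm(res$merged, file.path(out_dir, paste0(id, "_merged.pgm")))
      write_pgm(res$original, file.path(out_dir, paste0(id, "_original.pgm")))
      say(id, ": merged foreground ", sum(res$merged), " px (original ",
          sum(res$original), " px)")
    }
    if (!is.null(gt_dir)) {
      gt_path <- file.path(gt_dir, paste0(id, ".pgm"))
      if (!file.exists(gt_path)) {
        warning("no ground-truth mask for ", id,
                "; image predicted but skipped from evaluation",
                call. = FALSE)
        next
      }
      gt_lab <- read_pgm(gt_path)
      if (config$mode == "instance") {
        gt_set <- instance_set_from_labels(gt_lab)
        orig_scores <- c(orig_scores,
                         dsb_map(res$original, gt_set, config$thresholds))
        merged_scores <- c(merged_scores,
                           dsb_map(res$merged, gt_set, config$thresholds))
      } else {
        gt_mask <- gt_lab > 0
        orig_scores <- c(orig_scores, pixel_iou(res$original, gt_mask))
        merged_scores <- c(merged_scores, pixel_iou(res$merged, gt_mask))
      }
      ids <- c(ids, id)
    }
  }
  comparison <- NULL
  records <- NULL
  if (length(ids)) {
    comparison <- compare_scores(orig_scores, merged_scores, ids)
    records <- comparison$records
    utils::write.csv(records, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    summary <- list(n_images = length(ids),
                    mode = config$mode,
                    mean_original = mean(orig_scores),
                    mean_merged = mean(merged_scores),
                    mean_delta = comparison$mean_delta,
                    median_delta = comparison$median_delta,
                    wilcoxon_p = comparison$p_value,
                    degenerate = comparison$degenerate)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    say("evaluated ", length(ids), " image(s): mean delta ",
        format(comparison$mean_delta, digits = 4))
  }
  invisible(list(records = records, comparison = comparison,
                 out_dir = out_dir))
}
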