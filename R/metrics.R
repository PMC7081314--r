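# Evaluation metrics: DSB-style mean average precision over IoU thresholds
# for instance segmentations, pixel-level IoU for semantic masks, and the
# paired merged-vs-original comparison (delta) with a Wilcoxon signed-rank
# test.

#' The default IoU threshold grid
#'
#' @return `seq(0.5, 0.95, by = 0.05)`: the 10 thresholds of the Data
#'   Science Bowl 2018 instance metric.
#' @export
default_threshold_grid <- function() seq(0.5, 0.95, by = 0.05)

#' DSB-style mean average precision for one image
#'
#' For each IoU threshold `t` of the grid, predicted and ground-truth
#' objects are matched one-to-one and the per-threshold score is
#' `TP / (TP + FP + FN)`, where a matched pair is a true positive iff its
#' IoU is strictly greater than `t`, unmatched predictions are false
#' positives, and unmatched ground-truth objects are false negatives. The
#' per-image score is the mean over the grid.
#'
#' Matching is greedy in descending IoU order over the full IoU table,
#' computed once (each prediction and each ground-truth object used at most
#' once); per-threshold true positives are then the matched pairs whose IoU
#' exceeds that threshold. For disjoint ground truth this reproduces the
#' Kaggle metric. Conventions for edge cases: both sets empty scores 1.0 (a
#' correct empty prediction); empty versus non-empty scores 0.0.
#'
#' @param pred,gt [instance_set()]s (or labeled matrices) on one canvas;
#'   `gt` objects must be non-overlapping.
#' @param thresholds Ascending IoU thresholds; default
#'   [default_threshold_grid()].
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 1L
#' dsb_map(gt, gt) # identical sets -> 1
dsb_map <- function(pred, gt, thresholds = default_threshold_grid()) {
  pred <- as_instance_set(pred)
  gt <- as_instance_set(gt)
  if (!identical(pred$dim, gt$dim)) {
    stop("prediction and ground truth canvases differ", call. = FALSE)
  }
  np <- length(pred$objects)
  ng <- length(gt$objects)
  if (np == 0L && ng == 0L) return(1)
  if (np == 0L || ng == 0L) return(0)

  pb <- lapply(pred$objects, idx_bbox, dim = pred$dim)
  gb <- lapply(gt$objects, idx_bbox, dim = gt$dim)
  pi_ <- integer(0)
  gi <- integer(0)
  vi <- numeric(0)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      if (!bbox_overlap(pb[[i]], gb[[j]])) next
      v <- iou_idx(pred$objects[[i]], gt$objects[[j]])
      if (v > 0) {
        pi_ <- c(pi_, i)
        gi <- c(gi, j)
        vi <- c(vi, v)
      }
    }
  }
  # Greedy one-to-one matching, descending IoU; deterministic tie-break by
  # prediction then ground-truth index.
  ord <- order(-vi, pi_, gi)
  used_p <- logical(np)
  used_g <- logical(ng)
  matched <- numeric(0)
  for (k in ord) {
    if (used_p[pi_[k]] || used_g[gi[k]]) next
    used_p[pi_[k]] <- TRUE
    used_g[gi[k]] <- TRUE
    matched <- c(matched, vi[k])
  }
  scores <- vapply(thresholds, function(t) {
    tp <- sum(matched > t)
    tp / (tp + (np - tp) + (ng - tp))
  }, numeric(1L))
  mean(scores)
}

#' Average a set of per-image scores
#'
#' @param scores Non-empty numeric vector of per-image scores.
#' @return Their arithmetic mean, the dataset-level score in `[0, 1]`.
#' @export
dataset_map <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0L) {
    stop("scores must be a non-empty numeric vector", call. = FALSE)
  }
  mean(scores)
}

#' Pixel-level intersection over union of two binary masks
#'
#' Computed by the sum-then-count procedure: add the two binary masks,
#' count pixels greater than one (the intersection) and divide by the count
#' of pixels greater than zero (the union). Two empty masks score 1.0 (a
#' correct empty prediction); empty versus non-empty scores 0.0.
#'
#' @param pred,gt Logical or 0/1 numeric matrices of identical dimensions.
#' @return IoU in `[0, 1]`; symmetric.
#' @export
pixel_iou <- function(pred, gt) {
  if (!identical(dim(pred)[1:2], dim(gt)[1:2])) {
    stop("mask dimensions differ", call. = FALSE)
  }
  s <- (pred != 0) + (gt != 0)
  uni <- sum(s > 0)
  if (uni == 0L) return(1)
  sum(s > 1) / uni
}

#' Compare merged and original per-image scores
#'
#' Builds per-image evaluation records with `delta = merged - original` and
#' runs a two-sided paired Wilcoxon signed-rank test over the pairs. With
#' fewer than 2 pairs, or when every delta is zero (no non-tied pairs), the
#' test is refused/degenerate: deltas are still reported and the p-value is
#' `NA` with `degenerate = TRUE`.
#'
#' @param original,merged Equal-length numeric vectors of per-image scores.
#' @param ids Optional image identifiers (default `1..n`).
#' @return An object of class `tta_comparison`: list with `records` (a
#'   data frame `image_id`, `original`, `merged`, `delta`), `mean_delta`,
#'   `median_delta`, `p_value`, and `degenerate`.
#' @export
#' @examples
#' compare_scores(c(0.5, 0.4), c(0.6, 0.45))$records$delta
compare_scores <- function(original, merged, ids = NULL) {
  if (length(original) != length(merged)) {
    stop("original and merged must have equal length", call. = FALSE)
  }
  n <- length(original)
  if (is.null(ids)) ids <- seq_len(n)
  delta <- merged - original
  records <- data.frame(image_id = ids, original = original,
                        merged = merged, delta = delta,
                        stringsAsFactors = FALSE)
  p <- NA_real_
  degenerate <- TRUE
  if (n >= 2L && any(delta != 0)) {
    wt <- suppressWarnings(
      stats::wilcox.test(merged, original, paired = TRUE,
                         alternative = "two.sided"))
    p <- wt$p.value
    degenerate <- FALSE
  }
  structure(list(records = records,
                 mean_delta = if (n) mean(delta) else NA_real_,
                 median_delta = if (n) stats::median(delta) else NA_real_,
                 p_value = p, degenerate = degenerate),
            class = "tta_comparison")
}

#' @export
print.tta_comparison <- function(x, ...) {
  cat("<tta_comparison> n =", nrow(x$records),
      "| mean delta =", format(x$mean_delta, digits = 4),
      "| median delta =", format(x$median_delta, digits = 4), "\n")
  if (x$degenerate) {
    cat("Wilcoxon signed-rank test: degenerate (too few pairs or all ties)\n")
  } else {
    cat("Wilcoxon signed-rank p-value:", format(x$p_value, digits = 4), "\n")
  }
  invisible(x)
}
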