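# Semantic (probability map) fusion: average the dis-augmented per-view
# probability maps, then threshold once at 0.5.

check_probmap <- function(p, what = "probability map") {
  if (!is.matrix(p) || !is.numeric(p)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(p) || min(p) < 0 || max(p) > 1) {
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Merge probability maps by element-wise averaging
#'
#' The semantic merge: the per-view foreground probability maps (already
#' dis-augmented to the original frame) are summed and averaged pixel-wise.
#' Averaging happens on the soft maps; binarization is applied once, after
#' merging (see [binarize()]).
#'
#' @param maps Non-empty list of numeric H x W matrices with values in
#'   `[0, 1]`, all of identical dimensions.
#' @return The element-wise mean, an H x W matrix in `[0, 1]`.
#' @export
#' @examples
#' merge_probmaps(list(matrix(0.2, 2, 2), matrix(0.8, 2, 2)))
merge_probmaps <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L) {
    stop("maps must be a non-empty list of probability maps", call. = FALSE)
  }
  d <- dim(maps[[1L]])
  for (p in maps) {
    check_probmap(p)
    if (!identical(dim(p), d)) {
      stop("probability maps have mismatched dimensions", call. = FALSE)
    }
  }
  Reduce(`+`, maps) / length(maps)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is `>= threshold`. The
#' inclusive boundary means an exact 0.5 tie (e.g. 3 confident views out of
#' 6) resolves to foreground, mirroring the tie-to-foreground rule of the
#' instance pixel vote.
#'
#' @param map Numeric H x W matrix in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`; default 0.5.
#' @return Logical H x W matrix (`TRUE` = foreground).
#' @export
#' @examples
#' binarize(matrix(c(0.4, 0.5, 0.6, 0.1), 2))
binarize <- function(map, threshold = 0.5) {
  check_probmap(map)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  map >= threshold
}
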