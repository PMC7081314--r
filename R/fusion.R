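# Instance-aware merging of per-view instance segmentations.
#
# Objects are matched across views by mask IoU (threshold 0.5), an object is
# kept iff it is present in a strict majority of views, and each kept match
# group is fused into one mask by per-pixel majority voting over the paired
# object masks (ties to foreground). Leftover objects of the first, second,
# ... augmented view may seed new groups for as long as a strict majority is
# still theoretically reachable (seed rounds up to floor(N/2)).

as_mask_idx <- function(x) {
  if (is.matrix(x)) {
    idx <- if (is.numeric(x) && !is.integer(x)) which(x >= 0.5) else which(x != 0)
    return(list(idx = idx, dim = as.integer(dim(x))))
  }
  stop("mask must be a matrix", call. = FALSE)
}

#' Intersection over union of two binary masks
#'
#' `IoU(A, B) = |A intersect B| / |A union B|`. Used both as the cross-view
#' object matching criterion and (per-pixel) as the semantic score.
#'
#' @param a,b Logical or numeric matrices of identical dimensions. Numeric
#'   masks are binarized at 0.5.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' a <- matrix(FALSE, 3, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 3, 4); b[1:2, 2:3] <- TRUE
#' mask_iou(a, b) # 2 px intersection / 6 px union = 1/3
mask_iou <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("mask dimensions differ", call. = FALSE)
  }
  iou_idx(as_mask_idx(a)$idx, as_mask_idx(b)$idx)
}

#' Best IoU match of a seed mask among candidates
#'
#' Returns the candidate with the highest IoU against the seed, provided
#' that IoU reaches `min_iou` (default 0.5, the minimum overlap at which two
#' detections are considered the same object). Ties are broken toward the
#' lowest candidate index.
#'
#' @param seed Logical/numeric matrix: the seed object mask.
#' @param candidates List of masks on the same canvas, or an
#'   [instance_set()].
#' @param min_iou Minimum IoU to accept a match (default 0.5).
#' @return `NULL` if no candidate reaches `min_iou`, else
#'   `list(index =, iou =)`.
#' @export
find_best_match <- function(seed, candidates, min_iou = 0.5) {
  sd <- as_mask_idx(seed)
  if (inherits(candidates, "instance_set")) {
    if (!identical(candidates$dim, sd$dim)) {
      stop("candidate canvas differs from seed canvas", call. = FALSE)
    }
    cand <- candidates$objects
  } else {
    cand <- lapply(candidates, function(m) as_mask_idx(m)$idx)
  }
  best <- -1
  best_i <- 0L
  for (i in seq_along(cand)) {
    v <- iou_idx(sd$idx, cand[[i]])
    if (v > best) {
      best <- v
      best_i <- i
    }
  }
  if (best_i == 0L || best < min_iou) return(NULL)
  list(index = best_i, iou = best)
}

# Per-pixel majority vote over the masks of one match group. A pixel is
# foreground iff it is set in at least half of the masks (ties foreground).
# Returns list(idx = voted pixels, frac = vote fraction per voted pixel).
vote_pixels <- function(idx_list) {
  n <- length(idx_list)
  all_px <- sort(unlist(idx_list, use.names = FALSE))
  runs <- rle(all_px)
  keep <- 2L * runs$lengths >= n
  list(idx = runs$values[keep], frac = runs$lengths[keep] / n)
}

#' Merge per-view instance segmentations by matching and majority voting
#'
#' The instance-aware merge. `views[[1]]` is the original (identity) view;
#' all views must already be dis-augmented to the original frame.
#'
#' Round 0 seeds one match group per object of the original view; each seed
#' greedily takes its best unconsumed IoU match (>= `min_iou`) from every
#' other view, ties toward the lower object index, each object consumed by
#' at most one group. Rounds `r = 1 .. floor(N/2)` let the remaining
#' unconsumed objects of view `r + 1` seed further groups (an object missed
#' in the original view can still be recovered); later rounds cannot reach a
#' strict majority and are not run. A group is kept iff its support (number
#' of contributing views, counting the seed) exceeds `N / 2`. Every kept
#' group emits one mask by per-pixel majority vote over its paired masks,
#' ties to foreground. Output objects are made mutually disjoint: a
#' contested pixel goes to the group with the greater vote fraction, then to
#' the larger object, then to the earlier output index; objects emptied by
#' this resolution are dropped.
#'
#' @param views Non-empty list of [instance_set()]s on one canvas, identity
#'   view first.
#' @param min_iou Matching threshold (default 0.5).
#' @param details If `TRUE`, also return the match-group bookkeeping.
#' @return An `instance_set` of disjoint, non-empty merged objects; with
#'   `details = TRUE`, `list(merged =, groups =)` where each group records
#'   `seed_view`, `seed_object`, matched `(view, object, iou)` triples,
#'   `support`, and whether it was `kept`.
#' @export
merge_instances <- function(views, min_iou = 0.5, details = FALSE) {
  if (!is.list(views) || length(views) == 0L) {
    stop("views must be a non-empty list of instance sets", call. = FALSE)
  }
  views <- lapply(views, as_instance_set)
  n <- length(views)
  dm <- views[[1L]]$dim
  for (v in views) {
    if (!identical(v$dim, dm)) {
      stop("views have inconsistent canvas dimensions", call. = FALSE)
    }
  }
  consumed <- lapply(views, function(v) rep(FALSE, length(v$objects)))
  bboxes <- lapply(views, function(v) lapply(v$objects, idx_bbox, dim = dm))

  groups <- list()
  for (r in 0:(n %/% 2L)) {
    sv <- r + 1L
    if (sv > n) break
    for (oi in seq_along(views[[sv]]$objects)) {
      if (consumed[[sv]][oi]) next
      consumed[[sv]][oi] <- TRUE
      seed_idx <- views[[sv]]$objects[[oi]]
      seed_bb <- bboxes[[sv]][[oi]]
      m_view <- integer(0)
      m_obj <- integer(0)
      m_iou <- numeric(0)
      for (w in seq_len(n)) {
        if (w == sv) next
        best <- -1
        best_j <- 0L
        for (j in seq_along(views[[w]]$objects)) {
          if (consumed[[w]][j]) next
          if (!bbox_overlap(seed_bb, bboxes[[w]][[j]])) next
          val <- iou_idx(seed_idx, views[[w]]$objects[[j]])
          if (val > best) {
            best <- val
            best_j <- j
          }
        }
        if (best_j > 0L && best >= min_iou) {
          consumed[[w]][best_j] <- TRUE
          m_view <- c(m_view, w)
          m_obj <- c(m_obj, best_j)
          m_iou <- c(m_iou, best)
        }
      }
      groups[[length(groups) + 1L]] <- list(
        seed_view = sv, seed_object = oi,
        match_view = m_view, match_object = m_obj, match_iou = m_iou,
        support = 1L + length(m_view))
    }
  }

  kept <- vapply(groups, function(g) 2L * g$support > n, logical(1L))
  voted <- lapply(groups[kept], function(g) {
    masks <- c(list(views[[g$seed_view]]$objects[[g$seed_object]]),
               Map(function(w, j) views[[w]]$objects[[j]],
                   g$match_view, g$match_object))
    vote_pixels(masks)
  })

  # Disjointness resolution over the voted masks.
  npix <- prod(dm)
  lab <- integer(npix)
  frac <- numeric(npix)
  area <- integer(npix)
  for (g in seq_along(voted)) {
    px <- voted[[g]]$idx
    fr <- voted[[g]]$frac
    ar <- length(px)
    cur <- lab[px]
    take <- cur == 0L | fr > frac[px] |
      (fr == frac[px] & ar > area[px])
    pt <- px[take]
    lab[pt] <- g
    frac[pt] <- fr[take]
    area[pt] <- ar
  }
  fg <- which(lab > 0L)
  objects <- unname(split(fg, lab[fg]))
  merged <- new_instance_set(objects, dm, view_id = "merged")

  for (i in seq_along(groups)) groups[[i]]$kept <- kept[[i]]
  if (details) list(merged = merged, groups = groups) else merged
}
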