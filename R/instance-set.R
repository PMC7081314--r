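# InstanceSet: an ordered collection of binary object masks over one canvas.
# Internally each object is stored as a sorted vector of linear pixel indices
# (column-major, i.e. which() order) which keeps IoU computation and
# morphology cheap on large canvases with small objects.

new_instance_set <- function(objects, dim, view_id = NULL) {
  structure(list(objects = objects, dim = as.integer(dim[1:2]),
                 view_id = view_id),
            class = "instance_set")
}

#' Construct an instance set
#'
#' An instance segmentation: an ordered list of non-empty binary object
#' masks over one H x W canvas. Raw detector outputs may contain mutually
#' overlapping objects; merged outputs produced by [merge_instances()] are
#' always disjoint. Soft (numeric) per-object masks are binarized at 0.5
#' (`>= 0.5` is foreground) so that IoU is set-based.
#'
#' @param objects List of object masks. Each element is either a logical /
#'   numeric matrix of the canvas size, or an integer vector of linear pixel
#'   indices (column-major) into the canvas.
#' @param dim Canvas size `c(H, W)`. May be omitted when `objects` contains
#'   at least one matrix.
#' @param view_id Optional identifier of the view that produced this set.
#' @return An object of class `instance_set`.
#' @seealso [instance_set_from_labels()], [instance_labels()]
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
#' instance_set(list(m))
instance_set <- function(objects, dim = NULL, view_id = NULL) {
  if (!is.list(objects)) stop("objects must be a list", call. = FALSE)
  if (is.null(dim)) {
    mats <- Filter(is.matrix, objects)
    if (!length(mats)) {
      stop("dim is required when no object is given as a matrix",
           call. = FALSE)
    }
    dim <- base::dim(mats[[1L]])
  }
  dim <- as.integer(dim[1:2])
  npix <- prod(dim)
  idx <- lapply(objects, function(o) {
    if (is.matrix(o)) {
      if (!identical(as.integer(base::dim(o)), dim)) {
        stop("object mask dims do not match the canvas", call. = FALSE)
      }
      if (is.numeric(o) && !is.integer(o)) {
        return(which(o >= 0.5))
      }
      return(which(o != 0))
    }
    o <- as.integer(o)
    if (any(o < 1L | o > npix)) {
      stop("pixel index out of canvas bounds", call. = FALSE)
    }
    sort(unique(o))
  })
  if (any(lengths(idx) == 0L)) {
    stop("every object mask must be non-empty", call. = FALSE)
  }
  new_instance_set(idx, dim, view_id)
}

#' Build an instance set from a labeled mask image
#'
#' @param labels Integer matrix; 0 is background, each positive label one
#'   object. Objects are ordered by increasing label.
#' @param view_id Optional view identifier.
#' @return An `instance_set`.
#' @export
instance_set_from_labels <- function(labels, view_id = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  fg <- which(labels > 0)
  objects <- unname(split(fg, labels[fg]))
  objects <- lapply(objects, sort)
  new_instance_set(objects, dim(labels), view_id)
}

#' Render an instance set as a labeled mask image
#'
#' Objects are painted in order with labels `1..K`; if input objects overlap
#' (possible for raw detector output), later objects overwrite earlier ones.
#' Merged outputs are disjoint, so rendering is lossless for them.
#'
#' @param x An `instance_set`.
#' @return Integer matrix of the canvas size.
#' @export
instance_labels <- function(x) {
  stopifnot(inherits(x, "instance_set"))
  out <- matrix(0L, x$dim[1L], x$dim[2L])
  for (i in seq_along(x$objects)) out[x$objects[[i]]] <- i
  out
}

#' Extract one object mask as a logical matrix
#'
#' @param x An `instance_set`.
#' @param i Object index.
#' @return Logical matrix of the canvas size.
#' @export
instance_mask <- function(x, i) {
  stopifnot(inherits(x, "instance_set"))
  m <- matrix(FALSE, x$dim[1L], x$dim[2L])
  m[x$objects[[i]]] <- TRUE
  m
}

#' @export
length.instance_set <- function(x) length(x$objects)

#' @export
print.instance_set <- function(x, ...) {
  cat("<instance_set> ", length(x$objects), " object(s) on ",
      x$dim[1L], "x", x$dim[2L], " canvas",
      if (!is.null(x$view_id)) paste0(" (view ", x$view_id, ")"), "\n",
      sep = "")
  invisible(x)
}

# Bounding boxes (rmin, rmax, cmin, cmax) for quick IoU rejection.
idx_bbox <- function(idx, dim) {
  h <- dim[1L]
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  c(min(r), max(r), min(cc), max(cc))
}

bbox_overlap <- function(a, b) {
  a[1L] <= b[2L] && b[1L] <= a[2L] && a[3L] <= b[4L] && b[3L] <= a[4L]
}

# IoU of two sorted unique index vectors.
iou_idx <- function(a, b) {
  ni <- length(intersect(a, b))
  un <- length(a) + length(b) - ni
  if (un == 0L) return(0)
  ni / un
}

as_instance_set <- function(x) {
  if (inherits(x, "instance_set")) return(x)
  if (is.matrix(x)) return(instance_set_from_labels(x))
  stop("expected an instance_set or a labeled matrix", call. = FALSE)
}
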