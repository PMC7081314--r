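# Dihedral transforms used for test-time augmentation.
#
# Coordinate convention (fixed, documented, and relied upon by every round
# trip): grids are row-major with the origin at the top-left; `hflip`
# reverses column order, `vflip` reverses row order, and `rot90` rotates
# counter-clockwise. All six transforms are axis-aligned permutations of
# pixels, so applying a transform and then its inverse is bit-exact on any
# grid type (integer, logical, double).

#' Names of the built-in augmentation transforms
#'
#' The six invertible, interpolation-free transforms available for test-time
#' augmentation: the identity, horizontal and vertical flips, and rotations
#' by 90, 180 and 270 degrees (counter-clockwise).
#'
#' @return Character vector of the six transform names.
#' @export
#' @examples
#' transform_names()
transform_names <- function() {
  c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")
}

check_transform <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !(name %in% transform_names())) {
    stop("unknown transform: ", paste(format(name), collapse = ", "),
         " (must be one of ", paste(transform_names(), collapse = ", "), ")",
         call. = FALSE)
  }
  name
}

#' Inverse of a transform
#'
#' Every member of the augmentation set has its inverse within the set:
#' flips and `rot180` are self-inverse, and `rot90`/`rot270` invert each
#' other.
#'
#' @param transform Transform name (see [transform_names()]).
#' @return The name of the inverse transform.
#' @export
#' @examples
#' invert_transform("rot90") # "rot270"
invert_transform <- function(transform) {
  switch(check_transform(transform),
    identity = "identity",
    hflip    = "hflip",
    vflip    = "vflip",
    rot90    = "rot270",
    rot180   = "rot180",
    rot270   = "rot90")
}

apply_transform_matrix <- function(transform, m) {
  switch(transform,
    identity = m,
    hflip  = m[, rev(seq_len(ncol(m))), drop = FALSE],
    vflip  = m[rev(seq_len(nrow(m))), , drop = FALSE],
    rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    rot90  = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
    rot270 = t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
}

# Map linear pixel indices (column-major, as produced by which()) through a
# transform of an H x W canvas. Returns sorted indices into the transformed
# canvas. Integer arithmetic only, hence exactly invertible.
transform_indices <- function(transform, idx, dim) {
  h <- dim[1L]
  w <- dim[2L]
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  res <- switch(transform,
    identity = list(r = r, c = cc, h = h),
    hflip    = list(r = r, c = w + 1L - cc, h = h),
    vflip    = list(r = h + 1L - r, c = cc, h = h),
    rot180   = list(r = h + 1L - r, c = w + 1L - cc, h = h),
    rot90    = list(r = w + 1L - cc, c = r, h = w),
    rot270   = list(r = cc, c = h + 1L - r, h = w))
  sort((res$c - 1L) * res$h + res$r)
}

transformed_dim <- function(transform, dim) {
  if (transform %in% c("rot90", "rot270")) c(dim[2L], dim[1L]) else dim[1:2]
}

#' Apply an augmentation transform to a grid or instance set
#'
#' Applies one of the six dihedral transforms to a 2-D matrix (image,
#' probability map, labeled mask), a 3-D array with a trailing channel axis
#' (each channel is transformed independently), or an [instance_set()]
#' (every object mask is transformed, object order preserved). Rotations by
#' 90/270 degrees swap height and width; rectangular grids are permitted.
#'
#' @param transform Transform name (see [transform_names()]).
#' @param x Matrix, 3-D array, or `instance_set`.
#' @return The transformed object, same type and storage mode as `x`.
#' @export
#' @examples
#' apply_transform("hflip", matrix(1:4, 2, byrow = TRUE))
apply_transform <- function(transform, x) {
  check_transform(transform)
  if (inherits(x, "instance_set")) {
    objects <- lapply(x$objects, transform_indices,
                      transform = transform, dim = x$dim)
    return(new_instance_set(objects, transformed_dim(transform, x$dim),
                            view_id = x$view_id))
  }
  if (is.matrix(x)) {
    return(apply_transform_matrix(transform, x))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    nd <- c(transformed_dim(transform, d[1:2]), d[3L])
    out <- array(vector(typeof(x), prod(nd)), dim = nd)
    for (k in seq_len(d[3L])) {
      out[, , k] <- apply_transform_matrix(transform, x[, , k])
    }
    return(out)
  }
  stop("x must be a matrix, a 3-D array, or an instance_set", call. = FALSE)
}

#' Revert a prediction to the original image frame (dis-augmentation)
#'
#' Applies the inverse of `transform`, undoing a previous [apply_transform()]
#' bit-exactly. Use on per-view predictions (probability maps or instance
#' sets) so that all views share the original frame before merging.
#'
#' @param transform The transform that produced the prediction's frame.
#' @param x Prediction: matrix, 3-D array, or `instance_set`.
#' @param canvas Optional `c(H, W)` of the original canvas; when given, the
#'   prediction's dimensions are checked against `apply_transform`'s output
#'   shape and a shape error is raised on mismatch.
#' @return `x` in the original orientation.
#' @export
#' @examples
#' p <- matrix(runif(12), 3, 4)
#' identical(disaugment("rot90", apply_transform("rot90", p)), p)
disaugment <- function(transform, x, canvas = NULL) {
  check_transform(transform)
  if (!is.null(canvas)) {
    expected <- transformed_dim(transform, canvas)
    actual <- if (inherits(x, "instance_set")) x$dim else dim(x)[1:2]
    if (!identical(as.integer(actual), as.integer(expected))) {
      stop("prediction dims (", paste(actual, collapse = "x"),
           ") inconsistent with transform ", transform, " of a ",
           paste(canvas, collapse = "x"), " canvas", call. = FALSE)
    }
  }
  apply_transform(invert_transform(transform), x)
}

#' Construct an augmentation set
#'
#' An ordered set of transform names whose first element is always the
#' identity (the "original" view). Duplicates are rejected; all counts in
#' instance voting use the set length N.
#'
#' @param transforms Character vector of transform names, `"identity"` first.
#' @return Character vector with class `augmentation_set`.
#' @seealso [default_augmentation_set()]
#' @export
augmentation_set <- function(transforms) {
  if (!is.character(transforms) || length(transforms) < 1L) {
    stop("transforms must be a non-empty character vector", call. = FALSE)
  }
  for (t in transforms) check_transform(t)
  if (transforms[1L] != "identity") {
    stop("the first transform must be 'identity' (the original view)",
         call. = FALSE)
  }
  if (anyDuplicated(transforms)) {
    stop("augmentation set contains duplicates", call. = FALSE)
  }
  structure(transforms, class = "augmentation_set")
}

#' The default six-transform augmentation set
#'
#' Identity plus horizontal/vertical flip and the three axis-aligned
#' rotations: the augmentations conventionally used for nuclei segmentation
#' training and hence reused at test time.
#'
#' @return An [augmentation_set()] of length 6, identity first.
#' @export
#' @examples
#' default_augmentation_set()
default_augmentation_set <- function() {
  augmentation_set(transform_names())
}

#' @export
print.augmentation_set <- function(x, ...) {
  cat("<augmentation_set> N =", length(x), ":",
      paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}
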