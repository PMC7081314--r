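# Synthetic nuclei-like scenes and noisy per-view predictions.
#
# The generator stands in for a trained segmentation network: ground truth
# is a set of disjoint, slightly irregular filled ellipses on a 512 x 512
# canvas (the crop size used for nuclei data), and per-view predictions are
# the ground truth corrupted independently per view — dropped objects,
# boundary dilation/erosion jitter, spurious far-away objects, and (for the
# semantic mode) Gaussian softening plus pixel noise. Independent per-view
# errors around an equivariant core are exactly the regime in which merging
# augmented views helps; a shared-noise (perfectly equivariant) mode is
# available as a negative control under which merging provably changes
# nothing.

# Evaluate code with a seeded, restored RNG state so generators are
# deterministic without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fold two seeds into one, kept well below 2^31.
mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483123)
}

#' Specification of a synthetic ground-truth scene
#'
#' @param canvas Canvas size `c(H, W)`; default `c(512, 512)`, the crop size
#'   conventional for nuclei segmentation sets.
#' @param n_objects Number of nuclei to place; default 25.
#' @param axis_range Min/max ellipse semi-axes in pixels; default `c(8, 20)`.
#' @param min_gap Minimum clearance in pixels between object envelopes;
#'   default 4.
#' @param irregularity Relative amplitude of angular boundary irregularity
#'   (0 = exact ellipses); default 0.15.
#' @param seed RNG seed; the scene is a pure function of the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(canvas = c(512L, 512L), n_objects = 25L,
                       axis_range = c(8, 20), min_gap = 4,
                       irregularity = 0.15, seed = 1L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 8),
            n_objects >= 0L, length(axis_range) == 2L,
            axis_range[1L] > 0, axis_range[2L] >= axis_range[1L],
            min_gap >= 0, irregularity >= 0)
  structure(list(canvas = as.integer(canvas), n_objects = as.integer(n_objects),
                 axis_range = axis_range, min_gap = min_gap,
                 irregularity = irregularity, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Specification of per-view prediction noise
#'
#' Models the failure modes of an imperfect segmentation network: whole
#' objects missed, spurious detections, and uncertain borders.
#'
#' @param p_missed Probability that a ground-truth object is absent from a
#'   view; default 0.15.
#' @param spurious_rate Expected number (Poisson) of false objects per view;
#'   default 0.5.
#' @param jitter_radius Maximum radius (px) of random per-object boundary
#'   dilation/erosion; default 2.
#' @param prob_blur_sigma Gaussian sigma (px) softening the semantic
#'   probability map; default 2.
#' @param prob_noise_sd Standard deviation of the per-pixel Gaussian noise
#'   added to the soft map (clipped to `[0, 1]`); default 0.1.
#' @param spurious_axis_range Semi-axis range (px) of spurious objects;
#'   default `c(4, 9)`.
#' @param spurious_gap Minimum clearance (px) between a spurious object and
#'   every ground-truth object, large enough that a spurious detection can
#'   never IoU-match a true group; default 8.
#' @param seed Noise seed; combined with a per-view seed for independent
#'   per-view corruption.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(p_missed = 0.15, spurious_rate = 0.5,
                       jitter_radius = 2, prob_blur_sigma = 2,
                       prob_noise_sd = 0.1, spurious_axis_range = c(4, 9),
                       spurious_gap = 8, seed = 1L) {
  stopifnot(p_missed >= 0, p_missed <= 1, spurious_rate >= 0,
            jitter_radius >= 0, prob_blur_sigma >= 0, prob_noise_sd >= 0,
            spurious_gap >= 0)
  structure(list(p_missed = p_missed, spurious_rate = spurious_rate,
                 jitter_radius = as.integer(round(jitter_radius)),
                 prob_blur_sigma = prob_blur_sigma,
                 prob_noise_sd = prob_noise_sd,
                 spurious_axis_range = spurious_axis_range,
                 spurious_gap = spurious_gap, seed = as.integer(seed)),
            class = "noise_spec")
}

# Rasterize one irregular ellipse as sorted linear pixel indices. The
# boundary radius in direction phi (relative to the major axis) is the
# ellipse radius modulated by low-order sinusoids with total relative
# amplitude <= irregularity, so the object stays inside its bounding circle
# of radius max(a, b) * (1 + irregularity).
rasterize_blob <- function(cy, cx, a, b, theta, irregularity, phases, dim) {
  rmax <- max(a, b) * (1 + irregularity)
  h <- dim[1L]
  w <- dim[2L]
  r0 <- max(1L, as.integer(floor(cy - rmax)))
  r1 <- min(h, as.integer(ceiling(cy + rmax)))
  c0 <- max(1L, as.integer(floor(cx - rmax)))
  c1 <- min(w, as.integer(ceiling(cx + rmax)))
  rows <- r0:r1
  cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  phi <- atan2(dy, dx) - theta
  re <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  if (irregularity > 0) {
    mod <- 0.6 * sin(2 * phi + phases[1L]) + 0.4 * sin(3 * phi + phases[2L])
    re <- re * (1 + irregularity * mod)
  }
  inside <- which(d <= re, arr.ind = TRUE)
  if (!nrow(inside)) return(integer(0))
  sort((cols[inside[, 2L]] - 1L) * h + rows[inside[, 1L]])
}

#' Generate a synthetic ground-truth scene
#'
#' Places `n_objects` mutually disjoint, slightly irregular filled ellipses
#' fully inside the canvas, each with at least 20 px area, keeping at least
#' `min_gap` pixels between object envelopes. Deterministic for a fixed
#' spec (seed included).
#'
#' @param spec A [scene_spec()].
#' @return A ground-truth [instance_set()] with attribute `"centers"` (a
#'   matrix `cy, cx, radius` of object bounding circles, used for spurious
#'   placement).
#' @export
#' @examples
#' gt <- generate_scene(scene_spec(canvas = c(96, 96), n_objects = 4,
#'                                 axis_range = c(6, 10), seed = 7))
#' length(gt)
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$canvas[1L]
    w <- spec$canvas[2L]
    n <- spec$n_objects
    objects <- list()
    centers <- matrix(numeric(0), ncol = 3L,
                      dimnames = list(NULL, c("cy", "cx", "radius")))
    tries <- 0L
    budget <- 300L * max(1L, n)
    while (length(objects) < n) {
      tries <- tries + 1L
      if (tries > budget) {
        stop("could not pack ", n, " objects on a ", h, "x", w,
             " canvas within the retry budget", call. = FALSE)
      }
      a <- stats::runif(1L, spec$axis_range[1L], spec$axis_range[2L])
      b <- stats::runif(1L, spec$axis_range[1L], spec$axis_range[2L])
      theta <- stats::runif(1L, 0, pi)
      phases <- stats::runif(2L, 0, 2 * pi)
      rmax <- max(a, b) * (1 + spec$irregularity)
      if (2 * rmax + 2 >= min(h, w)) next
      cy <- stats::runif(1L, 1 + rmax, h - rmax)
      cx <- stats::runif(1L, 1 + rmax, w - rmax)
      if (nrow(centers)) {
        d2 <- (centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2
        if (any(d2 < (centers[, 3L] + rmax + spec$min_gap)^2)) next
      }
      idx <- rasterize_blob(cy, cx, a, b, theta, spec$irregularity, phases,
                            c(h, w))
      if (length(idx) < 20L) next
      objects[[length(objects) + 1L]] <- idx
      centers <- rbind(centers, c(cy, cx, rmax))
    }
    out <- new_instance_set(objects, c(h, w), view_id = "ground_truth")
    attr(out, "centers") <- centers
    out
  })
}

# Morphological dilation (r > 0) or erosion (r < 0) of an index mask by a
# disk of radius |r|, computed on the object's padded bounding box. Pixels
# pushed outside the canvas are clipped; erosion treats out-of-canvas as
# background.
morph_idx <- function(idx, r, dim) {
  if (r == 0L || !length(idx)) return(idx)
  dilate <- r > 0L
  r <- abs(r)
  h <- dim[1L]
  w <- dim[2L]
  rw <- ((idx - 1L) %% h) + 1L
  cl <- ((idx - 1L) %/% h) + 1L
  r0 <- max(1L, min(rw) - r)
  r1 <- min(h, max(rw) + r)
  c0 <- max(1L, min(cl) - r)
  c1 <- min(w, max(cl) + r)
  sh <- r1 - r0 + 1L
  sw <- c1 - c0 + 1L
  m <- matrix(FALSE, sh, sw)
  m[cbind(rw - r0 + 1L, cl - c0 + 1L)] <- TRUE
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, , drop = FALSE]
  acc <- if (dilate) matrix(FALSE, sh, sw) else matrix(TRUE, sh, sw)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]
    dx <- offs$dx[k]
    s <- matrix(FALSE, sh, sw)
    src_r <- max(1L, 1L - dy):min(sh, sh - dy)
    src_c <- max(1L, 1L - dx):min(sw, sw - dx)
    s[src_r + dy, src_c + dx] <- m[src_r, src_c]
    acc <- if (dilate) acc | s else acc & s
  }
  hit <- which(acc, arr.ind = TRUE)
  if (!nrow(hit)) return(integer(0))
  sort((hit[, 2L] + c0 - 2L) * h + (hit[, 1L] + r0 - 1L))
}

# Bounding circles (cy, cx, radius) of each object, from stored attribute
# when present, else from the pixel indices.
object_circles <- function(iset) {
  ctr <- attr(iset, "centers")
  if (!is.null(ctr) && nrow(ctr) == length(iset$objects)) return(ctr)
  h <- iset$dim[1L]
  t(vapply(iset$objects, function(idx) {
    rw <- ((idx - 1L) %% h) + 1L
    cl <- ((idx - 1L) %/% h) + 1L
    cy <- mean(rw)
    cx <- mean(cl)
    c(cy, cx, sqrt(max((rw - cy)^2 + (cl - cx)^2)) + 1)
  }, numeric(3L)))
}

#' Corrupt a ground-truth instance set into one noisy view
#'
#' Independent per-view corruption: each object is dropped with probability
#' `p_missed`; survivors get a boundary jitter (dilation or erosion by a
#' uniform radius in `-jitter_radius .. jitter_radius`); `Poisson(spurious_rate)`
#' spurious elliptical objects are added at least `spurious_gap` px away
#' from every ground-truth object (so they can never IoU-match a true
#' group). Deterministic for fixed `(noise$seed, view_seed)`.
#'
#' @param gt Ground-truth [instance_set()].
#' @param noise A [noise_spec()].
#' @param view_seed Integer distinguishing the views.
#' @return A corrupted `instance_set` (objects emptied by erosion are
#'   dropped; spurious objects may touch each other).
#' @export
corrupt_instances <- function(gt, noise, view_seed = 0L) {
  stopifnot(inherits(gt, "instance_set"), inherits(noise, "noise_spec"))
  with_seed(mix_seed(noise$seed, view_seed), {
    h <- gt$dim[1L]
    w <- gt$dim[2L]
    out <- list()
    for (idx in gt$objects) {
      if (stats::runif(1L) < noise$p_missed) next
      r <- 0L
      if (noise$jitter_radius > 0L) {
        r <- sample.int(2L * noise$jitter_radius + 1L, 1L) -
          noise$jitter_radius - 1L
      }
      jit <- morph_idx(idx, r, gt$dim)
      if (length(jit)) out[[length(out) + 1L]] <- jit
    }
    n_sp <- stats::rpois(1L, noise$spurious_rate)
    if (n_sp > 0L) {
      circles <- object_circles(gt)
      for (s in seq_len(n_sp)) {
        for (try in 1:50) {
          a <- stats::runif(1L, noise$spurious_axis_range[1L],
                            noise$spurious_axis_range[2L])
          b <- stats::runif(1L, noise$spurious_axis_range[1L],
                            noise$spurious_axis_range[2L])
          theta <- stats::runif(1L, 0, pi)
          rmax <- max(a, b)
          if (2 * rmax + 2 >= min(h, w)) break
          cy <- stats::runif(1L, 1 + rmax, h - rmax)
          cx <- stats::runif(1L, 1 + rmax, w - rmax)
          if (nrow(circles)) {
            d2 <- (circles[, 1L] - cy)^2 + (circles[, 2L] - cx)^2
            if (any(d2 < (circles[, 3L] + rmax + noise$spurious_gap)^2)) next
          }
          idx <- rasterize_blob(cy, cx, a, b, theta, 0, c(0, 0), gt$dim)
          if (length(idx) >= 10L) {
            out[[length(out) + 1L]] <- idx
          }
          break
        }
      }
    }
    new_instance_set(out, gt$dim, view_id = view_seed)
  })
}

# Separable Gaussian blur with zero padding (objects live away from the
# canvas border, where zero padding is the correct background).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- as.integer(ceiling(3 * sigma))
  wts <- stats::dnorm(-k:k, sd = sigma)
  wts <- wts / sum(wts)
  blur_axis <- function(x, along_rows) {
    nr <- nrow(x)
    nc <- ncol(x)
    out <- matrix(0, nr, nc)
    for (t in -k:k) {
      wgt <- wts[t + k + 1L]
      if (along_rows) {
        src <- max(1L, 1L - t):min(nr, nr - t)
        out[src + t, ] <- out[src + t, ] + wgt * x[src, ]
      } else {
        src <- max(1L, 1L - t):min(nc, nc - t)
        out[, src + t] <- out[, src + t] + wgt * x[, src]
      }
    }
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

instance_foreground <- function(iset) {
  m <- matrix(0, iset$dim[1L], iset$dim[2L])
  for (idx in iset$objects) m[idx] <- 1
  m
}

#' A simulated predictor with view-independent errors
#'
#' Returns a predictor contract — a function `(image, view, transform)` —
#' that stands in for a trained network inside [tta_predict()]. It
#' transforms the ground truth by the view's transform and corrupts it with
#' view-specific randomness, so per-view errors are independent after
#' dis-augmentation (the regime in which merging helps). In `semantic`
#' mode the corrupted foreground is softened by a Gaussian of
#' `prob_blur_sigma` px, per-pixel Gaussian noise of sd `prob_noise_sd` is
#' added, and the map is clipped to `[0, 1]`.
#'
#' With `equivariant = TRUE` the corruption (and, in semantic mode, the
#' soft map) is computed once in the original frame and merely transformed
#' per view: the predictor is then perfectly equivariant, every
#' dis-augmented view is identical, and test-time augmentation provably
#' cannot change the result — a negative control.
#'
#' @param gt Ground-truth [instance_set()].
#' @param noise A [noise_spec()].
#' @param mode `"instance"` or `"semantic"`.
#' @param equivariant Share the noise across views (default `FALSE`).
#' @return A function `(image, view, transform)` returning an
#'   `instance_set` (instance mode) or a probability matrix (semantic mode)
#'   in the transformed frame, ready for dis-augmentation.
#' @export
make_equivariant_predictor <- function(gt, noise, mode = c("instance", "semantic"),
                                       equivariant = FALSE) {
  stopifnot(inherits(gt, "instance_set"), inherits(noise, "noise_spec"))
  mode <- match.arg(mode)
  semantic_map <- function(iset, seed) {
    p <- gauss_blur(instance_foreground(iset), noise$prob_blur_sigma)
    # Blurring a 0/1 image keeps values in [0, 1]; rescale so object cores
    # stay confidently foreground even for large sigma.
    if (noise$prob_blur_sigma > 0) p <- pmin(p / max(max(p), 1e-12), 1)
    if (noise$prob_noise_sd > 0) {
      p <- with_seed(seed, p + stats::rnorm(length(p), 0, noise$prob_noise_sd))
    }
    pmin(pmax(p, 0), 1)
  }
  shared <- NULL
  if (equivariant) {
    base <- corrupt_instances(gt, noise, view_seed = 0L)
    shared <- if (mode == "instance") base else
      semantic_map(base, mix_seed(noise$seed, -1L))
  }
  function(image, view, transform) {
    check_transform(transform)
    if (equivariant) {
      return(apply_transform(transform, shared))
    }
    tgt <- apply_transform(transform, gt)
    corrupted <- corrupt_instances(tgt, noise, view_seed = view)
    if (mode == "instance") {
      corrupted
    } else {
      semantic_map(corrupted, mix_seed(noise$seed, 1000L + view))
    }
  }
}
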