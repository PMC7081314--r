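# Shared fixtures and independent oracles. Oracles deliberately use dense
# logical-matrix arithmetic (not the package's index representation) so the
# two code paths share nothing but the definitions.

mk_mask <- function(dim, idx) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[idx] <- TRUE
  m
}

rect_mask <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[rows, cols] <- TRUE
  m
}

# Random labeled mask with k disjoint rectangular objects.
random_labels <- function(h, w, k) {
  lab <- matrix(0L, h, w)
  for (i in seq_len(k)) {
    r0 <- sample.int(h - 3L, 1L)
    c0 <- sample.int(w - 3L, 1L)
    lab[r0:(r0 + 2L), c0:(c0 + 2L)] <- i
  }
  lab
}

# Brute-force IoU on logical matrices.
iou_dense <- function(a, b) {
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

# Exhaustive-assignment oracle for the instance merge, valid only in the
# IoU-separated regime (every cross-view pair IoU >= hi or <= lo): objects
# are clustered by union-find over IoU >= min_iou links; every cluster must
# contain at most one object per view; clusters spanning a strict majority
# of views are kept and fused by pixel-majority voting (ties foreground).
# Returns list(masks = list of logical matrices sorted for comparison,
# supports = sorted supports, in_regime = logical).
oracle_merge <- function(views, min_iou = 0.5, lo = 0.2, hi = 0.7) {
  n <- length(views)
  flat <- list() # each: list(view, mask)
  for (v in seq_len(n)) {
    for (i in seq_len(length(views[[v]]))) {
      flat[[length(flat) + 1L]] <- list(view = v,
                                        mask = instance_mask(views[[v]], i))
    }
  }
  m <- length(flat)
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  in_regime <- TRUE
  if (m >= 2L) {
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        if (flat[[i]]$view == flat[[j]]$view) next
        v <- iou_dense(flat[[i]]$mask, flat[[j]]$mask)
        if (v > lo && v < hi) in_regime <- FALSE
        if (v >= min_iou) parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1L))
  out_masks <- list()
  supports <- integer(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    vs <- vapply(members, function(i) flat[[i]]$view, integer(1L))
    if (anyDuplicated(vs)) in_regime <- FALSE
    support <- length(unique(vs))
    if (2L * support <= n) next
    votes <- Reduce(`+`, lapply(members, function(i) flat[[i]]$mask))
    out_masks[[length(out_masks) + 1L]] <- (2L * votes) >= length(members)
    supports <- c(supports, support)
  }
  ord <- order(vapply(out_masks, function(mm) min(which(mm)), numeric(1L)))
  list(masks = out_masks[ord], supports = supports[ord], in_regime = in_regime)
}

# Canonicalize a merged instance set the same way for comparison.
canon_objects <- function(iset) {
  o <- iset$objects
  o[order(vapply(o, min, integer(1L)))]
}

# Per-threshold exhaustive matching oracle for the DSB metric: maximum
# number of one-to-one (prediction, ground truth) pairs with IoU > t, by
# recursion over predictions.
oracle_dsb_map <- function(pred, gt, thresholds = seq(0.5, 0.95, by = 0.05)) {
  pm <- lapply(seq_len(length(pred)), function(i) instance_mask(pred, i))
  gm <- lapply(seq_len(length(gt)), function(i) instance_mask(gt, i))
  np <- length(pm)
  ng <- length(gm)
  if (np == 0L && ng == 0L) return(1)
  if (np == 0L || ng == 0L) return(0)
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    iou[i, j] <- iou_dense(pm[[i]], gm[[j]])
  }
  max_tp <- function(t) {
    adj <- iou > t
    best <- 0L
    rec <- function(i, used, count) {
      if (count + (np - i + 1L) <= best) return()
      if (i > np) {
        best <<- max(best, count)
        return()
      }
      for (j in which(adj[i, ] & !used)) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
      rec(i + 1L, used, count)
    }
    rec(1L, rep(FALSE, ng), 0L)
    best
  }
  mean(vapply(thresholds, function(t) {
    tp <- max_tp(t)
    tp / (tp + (np - tp) + (ng - tp))
  }, numeric(1L)))
}

# Monte-Carlo sign-flip permutation test on paired deltas (two-sided, rank
# statistic); an independent check on the Wilcoxon signed-rank p-value.
perm_signflip_p <- function(delta, R = 4000L) {
  d <- delta[delta != 0]
  rk <- rank(abs(d))
  obs <- abs(sum(sign(d) * rk))
  hits <- 0L
  for (r in seq_len(R)) {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    if (abs(sum(s * rk)) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (R + 1)
}

# Small quick noise/scene presets for unit tests.
tiny_scene <- function(seed, n = 4L, canvas = c(96L, 96L)) {
  generate_scene(scene_spec(canvas = canvas, n_objects = n,
                            axis_range = c(6, 10), min_gap = 6, seed = seed))
}

zero_noise <- function(seed = 1L) {
  noise_spec(p_missed = 0, spurious_rate = 0, jitter_radius = 0,
             prob_blur_sigma = 0, prob_noise_sd = 0, seed = seed)
}

# Scenes guaranteed to sit in the IoU-separated oracle regime: large round
# objects, wide gaps, jitter radius 1, drop-only noise (no spurious).
regime_scene_spec <- function(seed) {
  scene_spec(canvas = c(160L, 160L), n_objects = sample.int(5L, 1L),
             axis_range = c(12, 16), min_gap = 16, irregularity = 0,
             seed = seed)
}

regime_noise <- function(seed) {
  noise_spec(p_missed = 0.35, spurious_rate = 0, jitter_radius = 1,
             seed = seed)
}
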