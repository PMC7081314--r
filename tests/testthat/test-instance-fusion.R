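test_that("mask_iou matches brute-force pixel counting", {
  d <- c(6L, 6L)
  sq <- rect_mask(d, 2:3, 2:3)
  shifted <- rect_mask(d, 2:3, 3:4)
  expect_equal(mask_iou(sq, sq), 1)
  expect_equal(mask_iou(sq, rect_mask(d, 5:6, 5:6)), 0)
  expect_equal(mask_iou(sq, shifted), 1 / 3) # inter 2 px, union 6 px
  expect_equal(mask_iou(sq, shifted), mask_iou(shifted, sq))
  expect_error(mask_iou(sq, matrix(FALSE, 3, 3)), "dimensions")
  set.seed(31)
  for (i in 1:20) {
    a <- matrix(runif(64) > 0.6, 8)
    b <- matrix(runif(64) > 0.6, 8)
    if (!any(a) && !any(b)) next
    expect_equal(mask_iou(a, b), iou_dense(a, b))
  }
})

test_that("find_best_match honors the 0.5 threshold and picks the max IoU", {
  d <- c(10L, 10L)
  seed <- rect_mask(d, 2:5, 2:5) # 16 px
  far <- rect_mask(d, 8:9, 8:9)
  close1 <- rect_mask(d, 2:5, 3:6)  # IoU 12/20 = 0.6
  close2 <- rect_mask(d, 2:5, 2:6)  # IoU 16/20 = 0.8
  expect_null(find_best_match(seed, list(far)))
  m <- find_best_match(seed, list(far, close1, close2))
  expect_identical(m$index, 3L)
  expect_equal(m$iou, 0.8)
  self <- find_best_match(seed, list(close1, seed, close2))
  expect_identical(self$index, 2L)
  expect_equal(self$iou, 1)
  # tie toward the lowest candidate index
  tie <- find_best_match(seed, list(close1, close1))
  expect_identical(tie$index, 1L)
  # threshold is configurable
  expect_null(find_best_match(seed, list(close2), min_iou = 0.9))
})

test_that("merge_instances handles the canonical support cases", {
  d <- c(24L, 24L)
  obj <- rect_mask(d, 4:9, 4:9)
  one_view <- instance_set(list(obj, rect_mask(d, 15:20, 15:20)))
  # N = 1: identity merge
  m1 <- merge_instances(list(one_view))
  expect_identical(m1$objects, one_view$objects)

  empty <- instance_set(list(), dim = d)
  # present identically in 5 of 6 views -> kept, mask unchanged
  views <- c(replicate(5, instance_set(list(obj)), simplify = FALSE),
             list(empty))
  m <- merge_instances(views)
  expect_length(m, 1L)
  expect_identical(m$objects[[1L]], which(obj))

  # present in only 2 of 6 views -> support 2 <= 3, excluded
  views2 <- c(replicate(2, instance_set(list(obj)), simplify = FALSE),
              replicate(4, empty, simplify = FALSE))
  expect_length(merge_instances(views2), 0L)

  # support exactly 4 of 6 -> strict majority, kept; pixel present in 2 of
  # the 4 masks -> foreground (tie to foreground)
  half1 <- rect_mask(d, 4:9, 4:6)
  views3 <- list(instance_set(list(obj)), instance_set(list(obj)),
                 instance_set(list(half1)), instance_set(list(half1)),
                 empty, empty)
  m3 <- merge_instances(views3)
  expect_length(m3, 1L)
  # left half voted 4/4, right half 2/4 -> both foreground
  expect_identical(m3$objects[[1L]], which(obj))

  expect_error(merge_instances(list()), "non-empty")
  expect_error(merge_instances(list(one_view, instance_set(list(), dim = c(5L, 5L)))),
               "inconsistent")
})

test_that("objects missed in the original view are recovered via seed rounds", {
  d <- c(30L, 30L)
  a <- rect_mask(d, 3:8, 3:8)
  b <- rect_mask(d, 20:26, 20:26)
  with_a <- instance_set(list(a))
  with_both <- instance_set(list(a, b))
  # b absent from the identity view but present in 4 of 6 views
  views <- list(with_a, with_both, with_both, with_both, with_both, with_a)
  res <- merge_instances(views, details = TRUE)
  expect_length(res$merged, 2L)
  supports <- vapply(res$groups, `[[`, integer(1L), "support")
  expect_setequal(supports, c(6L, 4L))
  seed_views <- vapply(res$groups, `[[`, integer(1L), "seed_view")
  expect_identical(sort(seed_views), c(1L, 2L)) # b seeded in round 1
})

test_that("unanimity: identical views merge to themselves", {
  set.seed(41)
  for (rep in 1:5) {
    gt <- tiny_scene(seed = 100 + rep)
    views <- replicate(6, gt, simplify = FALSE)
    m <- merge_instances(views, details = TRUE)
    expect_identical(canon_objects(m$merged), canon_objects(gt))
    expect_true(all(vapply(m$groups, `[[`, integer(1L), "support") == 6L))
  }
})

test_that("merged outputs are disjoint, non-empty, and never exceed consumption", {
  set.seed(51)
  for (rep in 1:10) {
    gt <- tiny_scene(seed = 200 + rep, n = 5L)
    noise <- noise_spec(p_missed = 0.3, spurious_rate = 1, jitter_radius = 2,
                        seed = rep)
    views <- lapply(1:6, function(v) corrupt_instances(gt, noise, v))
    n_in <- sum(vapply(views, length, integer(1L)))
    m <- merge_instances(views)
    expect_true(all(lengths(m$objects) > 0L))
    all_px <- unlist(m$objects)
    expect_identical(anyDuplicated(all_px), 0L) # disjoint
    expect_true(length(m) <= n_in)
  }
})

test_that("overlapping voted outputs are resolved deterministically", {
  # Two groups voting for overlapping masks: the contested pixels go to the
  # group with the larger vote fraction.
  d <- c(12L, 12L)
  left <- rect_mask(d, 4:7, 3:7)
  left_wide <- rect_mask(d, 4:7, 3:8)   # reaches one column into "right"
  right <- rect_mask(d, 4:7, 8:11)
  mk <- function(a, b) instance_set(list(a, b))
  # left object: wide mask in 3 of 6 views -> col 8 voted at fraction 1/2
  # (tie, foreground); right object covers col 8 in 6 of 6 -> fraction 1
  # wins the contested column during disjointness resolution
  views <- list(mk(left_wide, right), mk(left_wide, right),
                mk(left_wide, right), mk(left, right), mk(left, right),
                mk(left, right))
  m <- merge_instances(views)
  expect_length(m, 2L)
  lab <- instance_labels(m)
  expect_true(all(lab[4:7, 8] == 2L))
  expect_true(all(lab[4:7, 3:7] == 1L))
})
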