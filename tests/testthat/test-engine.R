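test_that("identity-only augmentation makes merged equal original in both modes", {
  gt <- tiny_scene(seed = 67, n = 4L)
  ns <- noise_spec(seed = 71)
  img <- instance_labels(gt)
  cfg_i <- run_config(augs = augmentation_set("identity"), mode = "instance")
  res <- tta_predict(img, make_equivariant_predictor(gt, ns, "instance"), cfg_i)
  expect_identical(canon_objects(res$merged), canon_objects(res$original))

  cfg_s <- run_config(augs = augmentation_set("identity"), mode = "semantic")
  rs <- tta_predict(img, make_equivariant_predictor(gt, ns, "semantic"), cfg_s)
  expect_identical(rs$merged, rs$original)
  expect_identical(rs$merged_prob, rs$original_prob)
})

test_that("a noiseless predictor reproduces ground truth end to end", {
  gt <- tiny_scene(seed = 73, n = 5L)
  img <- instance_labels(gt)
  for (augs in list(augmentation_set("identity"), default_augmentation_set())) {
    res <- tta_predict(img, make_equivariant_predictor(gt, zero_noise(), "instance"),
                       run_config(augs = augs, mode = "instance"))
    expect_identical(canon_objects(res$merged), canon_objects(gt))
    rs <- tta_predict(img, make_equivariant_predictor(gt, zero_noise(), "semantic"),
                      run_config(augs = augs, mode = "semantic"))
    expect_identical(which(rs$merged), sort(unlist(gt$objects)))
  }
})

test_that("the engine invokes the predictor once per transform, in order", {
  calls <- list()
  mock <- function(image, view, transform) {
    calls[[length(calls) + 1L]] <<- list(view = view, transform = transform,
                                         dim = dim(image))
    matrix(0.25, nrow(image), ncol(image))
  }
  img <- matrix(0L, 12, 18)
  res <- tta_predict(img, mock, run_config(mode = "semantic"))
  expect_length(calls, 6L)
  expect_identical(vapply(calls, `[[`, character(1L), "transform"),
                   transform_names())
  expect_identical(vapply(calls, `[[`, integer(1L), "view"), 1:6)
  # rotated views saw the swapped canvas
  expect_identical(calls[[4L]]$dim, c(18L, 12L))
  expect_false(any(res$merged))
})

test_that("contract violations identify the offending view", {
  img <- matrix(0L, 8, 8)
  bad_dim <- function(image, view, transform) matrix(0.5, 3, 3)
  expect_error(tta_predict(img, bad_dim, run_config(mode = "semantic")),
               "view 1")
  wrong_mode <- function(image, view, transform) {
    if (view < 3) matrix(0.5, nrow(image), ncol(image)) else "nonsense"
  }
  expect_error(tta_predict(img, wrong_mode, run_config(mode = "semantic")),
               "view 3")
  not_instance <- function(image, view, transform) matrix(0.5, 8, 8)
  expect_error(tta_predict(img, not_instance, run_config(mode = "instance")),
               "instance_set")
})

test_that("a frozen seeded run matches its golden labeled mask", {
  gt <- generate_scene(scene_spec(canvas = c(96, 96), n_objects = 6,
                                  axis_range = c(6, 11), seed = 79))
  ns <- noise_spec(seed = 83)
  res <- tta_predict(instance_labels(gt),
                     make_equivariant_predictor(gt, ns, "instance"),
                     run_config(mode = "instance"))
  golden <- read_pgm(test_path("golden_merged.pgm"))
  expect_identical(instance_labels(res$merged), golden)
})

test_that("run_batch writes masks, scores and summary; rerun is byte-identical", {
  root <- withr::local_tempdir()
  img_dir <- file.path(root, "img")
  gt_dir <- file.path(root, "gt")
  dir.create(img_dir)
  dir.create(gt_dir)
  scenes <- lapply(1:3, function(i) tiny_scene(seed = 500 + i, n = 4L))
  for (i in 1:3) {
    lab <- instance_labels(scenes[[i]])
    write_pgm(lab, file.path(img_dir, sprintf("im%d.pgm", i)))
    write_pgm(lab, file.path(gt_dir, sprintf("im%d.pgm", i)))
  }
  factory <- function(img, id) {
    i <- as.integer(sub("im", "", id))
    make_equivariant_predictor(scenes[[i]], noise_spec(seed = 600 + i),
                               "instance")
  }
  out1 <- file.path(root, "out1")
  res <- run_batch(img_dir, factory, run_config(mode = "instance"),
                   gt_dir = gt_dir, out_dir = out1, quiet = TRUE)
  expect_equal(nrow(res$records), 3L)
  expect_true(file.exists(file.path(out1, "scores.csv")))
  expect_true(file.exists(file.path(out1, "summary.json")))
  expect_true(all(file.exists(file.path(out1, paste0("im", 1:3, "_merged.pgm")))))

  out2 <- file.path(root, "out2")
  run_batch(img_dir, factory, run_config(mode = "instance"),
            gt_dir = gt_dir, out_dir = out2, quiet = TRUE)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # unpaired ground truth: warned, predicted, skipped from evaluation
  file.remove(file.path(gt_dir, "im2.pgm"))
  out3 <- file.path(root, "out3")
  expect_warning(
    res3 <- run_batch(img_dir, factory, run_config(mode = "instance"),
                      gt_dir = gt_dir, out_dir = out3, quiet = TRUE),
    "im2")
  expect_equal(nrow(res3$records), 2L)
  expect_true(file.exists(file.path(out3, "im2_merged.pgm")))

  # empty directory: warning, empty report, success
  empty_dir <- file.path(root, "none")
  dir.create(empty_dir)
  expect_warning(r0 <- run_batch(empty_dir, factory, quiet = TRUE), "no .pgm")
  expect_null(r0$records)
})

test_that("the subprocess adapter round-trips through an external command", {
  gt <- tiny_scene(seed = 89, n = 3L)
  img <- instance_labels(gt)
  # `cp` is a perfect (identity) external predictor: the labeled image is
  # its own instance prediction
  pred <- subprocess_predictor("cp", mode = "instance",
                               dir = withr::local_tempdir())
  res <- tta_predict(img, pred, run_config(mode = "instance"))
  expect_identical(canon_objects(res$merged), canon_objects(gt))
})
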