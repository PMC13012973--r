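test_that("dice coefficient behaves at the boundaries", {
  a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(dice_coef(a, a), 1)
  expect_equal(dice_coef(a, !a), 0)
  expect_equal(dice_coef(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice_coef(a, matrix(TRUE, 3, 3)),
               class = "sgpAge_invalid_input")
})

test_that("training requires masks and a non-empty sample list", {
  expect_error(train_segmenter(list()), class = "sgpAge_data_error")
  ph <- fx_tiny_segmenter()$phantoms[[1]]
  ph$masks <- NULL
  expect_error(train_segmenter(list(ph)), class = "sgpAge_data_error")
})

test_that("training is reproducible: same seed, same loss trajectory", {
  phantoms <- fx_tiny_segmenter()$phantoms[1:6]
  cfg <- seg_train_config(input_size = 32, c1 = 4L, c2 = 4L, epochs = 2,
                          seed = 31)
  m1 <- train_segmenter(phantoms, cfg)
  m2 <- train_segmenter(phantoms, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("mask prediction validates input size and never mutates the model", {
  fx <- fx_tiny_segmenter()
  model <- fx$model
  img <- fx$phantoms[[1]]$image
  expect_error(predict_masks(model, img[1:32, 1:32]),
               class = "sgpAge_invalid_input")
  before <- serialize(model, NULL)
  for (tta in c(FALSE, TRUE)) invisible(predict_masks(model, img, tta = tta))
  expect_identical(serialize(model, NULL), before)
  pm <- predict_masks(model, img)
  expect_s3_class(pm, "mask_set")
  expect_true(all(vapply(pm, is.logical, logical(1))))
})

test_that("refinement drops small and dim components and keeps real bone", {
  fx <- fx_tiny_segmenter()
  ph <- fx$phantoms[[2]]
  img <- ph$image
  cfg <- refine_config(min_area = 6, mean_intensity_min = 0.2,
                       morph_open_radius = 0, morph_close_radius = 0,
                       keep_top_k = c(shortbones = 20, carpals = 10,
                                      wrist = 4))
  raw <- ph$masks
  raw$carpals[1:2, 1:2] <- TRUE                 # 4-px speck on background
  ref <- refine_masks(raw, img, cfg)
  expect_false(any(ref$carpals[1:2, 1:2]))
  expect_gt(dice_coef(ref$carpals, ph$masks$carpals), 0.99)

  # a sizeable blob lying on dim background fails the mean-intensity rule
  dim_img <- matrix(0.05, 64, 64)
  blob <- matrix(FALSE, 64, 64); blob[20:35, 20:35] <- TRUE
  masks <- list(shortbones = blob, carpals = matrix(FALSE, 64, 64),
                wrist = matrix(FALSE, 64, 64))
  suppressWarnings(
    ref2 <- refine_masks(masks, dim_img,
                         refine_config(min_area = 10,
                                       mean_intensity_min = 0.2,
                                       morph_open_radius = 0,
                                       morph_close_radius = 0)))
  expect_false(any(ref2$shortbones))
})

test_that("refinement is a fixed point on clean masks and idempotent", {
  fx <- fx_tiny_segmenter()
  ph <- fx$phantoms[[3]]
  permissive <- refine_config(min_area = 1, mean_intensity_min = 0,
                              morph_open_radius = 0, morph_close_radius = 0,
                              keep_top_k = 50)
  ref <- refine_masks(ph$masks, ph$image, permissive)
  expect_identical(lapply(ref, unname), lapply(ph$masks, function(m) unname(m > 0)))

  cfg <- refine_config(morph_open_radius = 1, morph_close_radius = 1,
                       keep_top_k = c(shortbones = 20, carpals = 10,
                                      wrist = 4))
  for (ph in fx$phantoms[4:6]) {
    pm <- predict_masks(fx$model, ph$image)
    r1 <- suppressWarnings(refine_masks(pm, ph$image, cfg))
    r2 <- suppressWarnings(refine_masks(r1, ph$image, cfg))
    expect_identical(lapply(r1, c), lapply(r2, c))
  }
})

test_that("refinement warns and returns an empty mask when all filtered", {
  img <- matrix(0.05, 64, 64)
  speck <- matrix(FALSE, 64, 64); speck[1, 1] <- TRUE
  none <- matrix(FALSE, 64, 64)
  masks <- list(shortbones = speck, carpals = none, wrist = none)
  expect_warning(
    ref <- refine_masks(masks, img,
                        refine_config(min_area = 10, morph_open_radius = 0,
                                      morph_close_radius = 0)),
    class = "sgpAge_empty_segment")
  expect_false(any(ref$shortbones))
  # empty input masks come back empty without complaint
  expect_silent(refine_masks(list(shortbones = none, carpals = none,
                                  wrist = none), img))
})

test_that("crops mask the background, cover the bounding box and letterbox", {
  img <- matrix(runif(256 * 256), 256, 256)
  full <- matrix(TRUE, 256, 256)
  blob <- matrix(FALSE, 256, 256); blob[1:10, 247:256] <- TRUE
  masks <- structure(list(shortbones = full, carpals = blob, wrist = full),
                     class = "mask_set")
  out <- crop_segments(img, masks, out_size = 64, pad_fraction = 0)
  expect_equal(dim(out$shortbones), c(64, 64))
  # full-image mask: crop is the resized original
  expect_equal(out$shortbones, resize_to(img, 64), tolerance = 1e-10)
  # corner blob: the bounding box covers exactly that blob, so the crop is
  # the upscaled 10x10 corner patch
  expect_equal(out$carpals, resize_to(img[1:10, 247:256], 64),
               tolerance = 1e-10)
  # pixels outside the mask are exactly zero
  ph <- generate_phantom(phantom_params(image_size = 64, seed = 2),
                         default_gp_scale("male"))
  crops <- crop_segments(ph$image, ph$masks, out_size = 48)
  expect_true(all(vapply(crops, function(m) all(m >= 0), logical(1))))
  empty <- structure(list(shortbones = matrix(FALSE, 4, 4),
                          carpals = matrix(FALSE, 4, 4),
                          wrist = matrix(FALSE, 4, 4)), class = "mask_set")
  expect_error(crop_segments(matrix(0, 4, 4), empty),
               class = "sgpAge_empty_segment")
})

test_that("segmenter checkpoints round-trip with a JSON sidecar", {
  fx <- fx_tiny_segmenter()
  path <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(fx$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$input_size, fx$model$config$input_size)
  m2 <- load_segmenter(path)
  expect_identical(m2$params, fx$model$params)
  expect_error(load_segmenter("nope.rds"), class = "sgpAge_io_error")
})
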