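scale_m <- default_gp_scale("male")

# Rows with no bone pixels between the first and last occupied row of a
# zone: the total epiphyseal gap height of that zone.
gap_rows <- function(mask) {
  occ <- which(rowSums(mask) > 0)
  sum(rowSums(mask[min(occ):max(occ), , drop = FALSE]) == 0)
}

test_that("phantom generation is deterministic and well-formed", {
  p <- phantom_params(image_size = 64, fullhand_age = 120,
                      segment_offsets = c(-10, 20, 5), seed = 42)
  a <- generate_phantom(p, scale_m)
  b <- generate_phantom(p, scale_m)
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_identical(sort(names(a$segment_ages)),
                   sort(c("shortbones", "carpals", "wrist")))
  # masks pairwise disjoint and non-trivial
  expect_equal(sum(a$masks$shortbones & a$masks$carpals), 0)
  expect_equal(sum(a$masks$shortbones & a$masks$wrist), 0)
  expect_equal(sum(a$masks$carpals & a$masks$wrist), 0)
  expect_true(all(vapply(a$masks, sum, numeric(1)) >= 20))
  # labels snapped to the grid
  expect_true(all(unlist(a$segment_ages) %in% scale_m$classes))
  expect_true(a$y %in% scale_m$classes)
})

test_that("zero offsets give synchronous segment ages", {
  p <- phantom_params(image_size = 64, fullhand_age = 103, seed = 3)
  ph <- generate_phantom(p, scale_m)
  expect_true(all(unlist(ph$segment_ages) == snap_to_gp(103, scale_m)))
})

test_that("carpal ossified area grows with carpal age and saturates", {
  lo <- min(scale_m$classes)
  ages <- seq(lo, max(scale_m$classes), length.out = 12)
  areas <- vapply(ages, function(a) {
    p <- phantom_params(image_size = 128, fullhand_age = lo,
                        segment_offsets = c(0, a - lo, 0), seed = 9)
    sum(generate_phantom(p, scale_m)$masks$carpals)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  # +24 months strictly below saturation
  a0 <- phantom_params(image_size = 128, fullhand_age = 96,
                       segment_offsets = c(0, 0, 0), seed = 11)
  a24 <- phantom_params(image_size = 128, fullhand_age = 96,
                        segment_offsets = c(0, 24, 0), seed = 11)
  expect_gt(sum(generate_phantom(a24, scale_m)$masks$carpals),
            sum(generate_phantom(a0, scale_m)$masks$carpals))
})

test_that("shortbone and wrist gaps narrow monotonically with age", {
  lo <- min(scale_m$classes)
  ages <- seq(lo, max(scale_m$classes), length.out = 10)
  gaps <- vapply(ages, function(a) {
    p <- phantom_params(image_size = 96, fullhand_age = a, seed = 5)
    ph <- generate_phantom(p, scale_m)
    c(gap_rows(ph$masks$shortbones), gap_rows(ph$masks$wrist))
  }, numeric(2))
  expect_true(all(diff(gaps[1, ]) <= 0))
  expect_true(all(diff(gaps[2, ]) <= 0))
})

test_that("layout validation rejects images that are too small", {
  expect_error(phantom_params(image_size = 32), class = "sgpAge_layout_error")
})

test_that("domain shift transform follows clip(gain * x^gamma + offset)", {
  img <- matrix(runif(64), 8, 8)
  expect_equal(apply_domain_shift(img, shift_params()), img)
  cst <- matrix(0.2, 4, 4)
  expect_equal(apply_domain_shift(cst, shift_params(gain = 0.5, offset = 0.4)),
               matrix(0.5, 4, 4))
  two <- matrix(c(0.2, 0.9), 1, 2)
  expect_equal(apply_domain_shift(two, shift_params(gamma = 2)),
               matrix(c(0.04, 0.81), 1, 2))
  expect_error(shift_params(gain = 0), class = "sgpAge_invalid_input")
  expect_error(shift_params(gamma = -1), class = "sgpAge_invalid_input")
  expect_error(apply_domain_shift(img * 5, shift_params()),
               class = "sgpAge_invalid_input")
})

test_that("domain shift is invertible on the non-clipped range", {
  img <- matrix(runif(100, 0.1, 0.9), 10, 10)
  sh <- shift_params(gain = 0.8, offset = 0.05, gamma = 1.4)
  y <- apply_domain_shift(img, sh)
  back <- ((y - sh$offset) / sh$gain)^(1 / sh$gamma)
  expect_equal(back, img, tolerance = 1e-12)
})

test_that("prediction tables honour the noiseless and determinism contracts", {
  tab <- generate_prediction_table(50, alpha0 = 0.4, noise_sd_fh = 0,
                                   noise_sd_seg = 0, scale_m, seed = 8)
  expect_equal(tab$fh, tab$seg_avg)
  expect_equal(snap_to_gp(tab$fh, scale_m), tab$y)
  expect_equal(tab$seg_avg,
               rowMeans(tab[c("seg_shortbones", "seg_carpals", "seg_wrist")]))
  t1 <- generate_prediction_table(2000, 0.3, 6, 6, scale_m, seed = 13)
  t2 <- generate_prediction_table(2000, 0.3, 6, 6, scale_m, seed = 13)
  expect_identical(t1, t2)
  expect_true(all(t1$y %in% scale_m$classes))
  expect_error(generate_prediction_table(10, 0.3, -1, 6, scale_m),
               class = "sgpAge_invalid_input")
})

test_that("make_dataset writes a complete, reproducible dataset", {
  dir <- withr::local_tempdir()
  man <- make_dataset(6, scale_m, file.path(dir, "d1"), seed = 99,
                      sampler = list(image_size = 64))
  expect_equal(nrow(man), 6)
  expect_length(list.files(file.path(dir, "d1", "images")), 6)
  expect_length(list.files(file.path(dir, "d1", "masks")), 18)
  age_cols <- c("fullhand_age", "shortbones_age", "carpals_age", "wrist_age")
  expect_true(all(unlist(man[age_cols]) %in% scale_m$classes))
  make_dataset(6, scale_m, file.path(dir, "d2"), seed = 99,
               sampler = list(image_size = 64))
  expect_identical(readBin(file.path(dir, "d1", "manifest.csv"), "raw", 1e5),
                   readBin(file.path(dir, "d2", "manifest.csv"), "raw", 1e5))
  # round trip through PNG preserves labels and approximates images
  samples <- sgpAge:::load_dataset(file.path(dir, "d1", "manifest.csv"))
  expect_length(samples, 6)
  expect_equal(samples[[1]]$y, man$fullhand_age[1])
  expect_true(is.matrix(samples[[1]]$image))
  expect_true(all(vapply(samples[[1]]$masks, is.logical, logical(1))))
})
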