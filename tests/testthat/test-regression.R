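scale_m <- default_gp_scale("male")

make_cohort <- function(n, seed, shift = NULL, size = 64) {
  out <- simulate_phantom_set(n, scale_m, seed = seed,
                              sampler = default_sampler(size))
  if (!is.null(shift)) {
    out <- lapply(out, function(ph) {
      ph$image <- apply_domain_shift(ph$image, shift)
      ph
    })
  }
  out
}

test_that("base training validates inputs and records source statistics", {
  ph_m <- make_cohort(4, seed = 1)
  ph_f <- simulate_phantom_set(2, default_gp_scale("female"), seed = 2,
                               sampler = default_sampler())
  expect_error(train_base(c(ph_m, ph_f), "fullhand"),
               class = "sgpAge_data_error")
  cfg <- reg_train_config(input_size = 32, epochs = 2, seed = 5)
  m <- train_base(ph_m, "fullhand", cfg)
  x <- array(0, c(32, 32, 1, 4))
  for (i in 1:4) x[, , 1, i] <- resize_to(ph_m[[i]]$image, 32)
  expect_equal(m$norm$mean, mean(x), tolerance = 1e-6)
  expect_equal(m$norm$sd, sd(as.numeric(x)), tolerance = 1e-6)
  expect_identical(m$segment, "fullhand")
  expect_identical(m$sex, "male")
})

test_that("a small cohort can be overfit to sub-month training error", {
  s16 <- make_cohort(16, seed = 21)
  m <- train_base(s16, "fullhand",
                  reg_train_config(input_size = 48, epochs = 150, seed = 5))
  preds <- predict_age(m, lapply(s16, function(p) resize_to(p$image, 48)))
  labs <- vapply(s16, function(p) as.numeric(p$y), numeric(1))
  expect_lt(age_mad(preds, labs), 1)
  expect_true(all(abs(preds - labs) < 1))
})

test_that("prediction is deterministic, finite and clamped to [0, 300]", {
  s <- make_cohort(4, seed = 31)
  m <- train_base(s, "fullhand",
                  reg_train_config(input_size = 32, epochs = 2, seed = 5))
  img <- resize_to(s[[1]]$image, 32)
  p1 <- predict_age(m, img)
  expect_identical(p1, predict_age(m, img))
  expect_true(is.finite(p1) && p1 >= 0 && p1 <= 300)
  wild <- m
  wild$params$wh <- wild$params$wh * 1e7
  wild$params$bh <- -1e5
  p2 <- predict_age(wild, img)
  expect_true(p2 >= 0 && p2 <= 300)
  expect_error(predict_age(m, img[1:16, 1:16]),
               class = "sgpAge_invalid_input")
})

test_that("fine-tuning freezes the backbone and averages two rater columns", {
  src <- make_cohort(24, seed = 41)
  tgt <- make_cohort(10, seed = 43, shift = shift_params(gain = 0.4,
                                                         offset = 0.5))
  base <- train_base(src, "fullhand",
                     reg_train_config(input_size = 32, epochs = 4, seed = 5))
  tuned <- fine_tune_head(base, tgt)
  for (nm in setdiff(names(base$params), c("wh", "bh"))) {
    expect_identical(tuned$params[[nm]], base$params[[nm]])
  }
  expect_false(identical(tuned$params$wh, base$params$wh))
  expect_true(tuned$fine_tuned)

  # two rater columns are averaged: (84, 96) trains on 90
  r2 <- fine_tune_head(base, tgt,
                       ratings = data.frame(a = rep(84, 10), b = rep(96, 10)))
  r1 <- fine_tune_head(base, tgt, labels = rep(90, 10))
  expect_identical(r2$params, r1$params)

  broken <- base
  broken$norm <- NULL
  expect_error(fine_tune_head(broken, tgt), class = "sgpAge_state_error")
})

test_that("head-only transfer improves accuracy on a shifted cohort", {
  sh <- shift_params(gain = 0.4, offset = 0.5)
  deltas <- vapply(1:3, function(sd) {
    src <- make_cohort(32, seed = 100 + sd)
    tgt <- make_cohort(40, seed = 200 + sd, shift = sh)
    base <- train_base(src, "fullhand",
                       reg_train_config(input_size = 48, epochs = 15,
                                        seed = sd))
    tuned <- fine_tune_head(base, tgt[1:20])
    val <- lapply(tgt[21:40], function(p) resize_to(p$image, 48))
    y <- vapply(tgt[21:40], function(p) as.numeric(p$y), numeric(1))
    age_mad(predict_age(base, val), y) - age_mad(predict_age(tuned, val), y)
  }, numeric(1))
  expect_gt(median(deltas), 0)
})

test_that("regressor checkpoints round-trip with a JSON sidecar", {
  s <- make_cohort(4, seed = 51)
  m <- train_base(s, "carpals",
                  reg_train_config(input_size = 32, epochs = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_regressor(m, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$segment, "carpals")
  expect_equal(side$norm_sd, m$norm$sd)
  m2 <- load_regressor(path)
  expect_identical(m2$params, m$params)
})
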