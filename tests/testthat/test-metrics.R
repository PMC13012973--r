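scale_m <- default_gp_scale("male")

test_that("MAD and RMSE match brute-force loops on random inputs", {
  expect_equal(age_mad(c(10, 14), c(12, 12)), 2)
  expect_equal(age_mad(1:5, 1:5), 0)
  expect_error(age_mad(1:3, 1:4), class = "sgpAge_invalid_input")
  set.seed(5)
  for (rep in 1:20) {
    p <- rnorm(100, 100, 30); t <- rnorm(100, 100, 30)
    acc_m <- 0; acc_r <- 0
    for (i in seq_along(p)) {
      acc_m <- acc_m + abs(p[i] - t[i])
      acc_r <- acc_r + (p[i] - t[i])^2
    }
    expect_equal(age_mad(p, t), acc_m / 100, tolerance = 1e-12)
    expect_equal(age_rmse(p, t), sqrt(acc_r / 100), tolerance = 1e-12)
    expect_lte(age_mad(p, t), age_rmse(p, t))
  }
})

test_that("Bland-Altman limits and high-error flags follow the 2-sd rule", {
  t <- c(100, 110, 120, 130, 140)
  ba <- bland_altman(t + 3, t)
  expect_equal(ba$bias, 3)
  expect_equal(ba$loa_low, 3)
  expect_equal(ba$loa_high, 3)
  expect_length(ba$high_error_ids, 0)
  expect_equal(bland_altman(t, t)$bias, 0)

  # worked example: differences {0,0,0,0,10}
  ba2 <- bland_altman(t + c(0, 0, 0, 0, 10), t)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd, sqrt(20), tolerance = 1e-12)
  expect_equal(ba2$loa_low, 2 - 2 * sqrt(20), tolerance = 1e-12)
  expect_equal(ba2$loa_high, 2 + 2 * sqrt(20), tolerance = 1e-12)
  expect_length(ba2$high_error_ids, 0)   # 10 < 10.944 is inside the limits

  # flags are invariant under adding a constant to both vectors
  set.seed(9)
  p <- rnorm(60, 100, 20); tt <- rnorm(60, 100, 20)
  expect_identical(bland_altman(p, tt)$high_error_ids,
                   bland_altman(p + 50, tt + 50)$high_error_ids)
  expect_error(bland_altman(1, 1), class = "sgpAge_invalid_input")
})

test_that("r-squared is the squared Pearson correlation", {
  t <- seq(10, 200, length.out = 30)
  expect_equal(r_squared(2 * t + 5, t), 1)
  expect_equal(r_squared(t, t), 1)
  set.seed(13)
  p <- rnorm(200); q <- p + rnorm(200)
  num <- sum((p - mean(p)) * (q - mean(q)))
  den <- sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
  expect_equal(r_squared(p, q), (num / den)^2, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), 1:5),
               class = "sgpAge_undefined_statistic")
})

test_that("quadratic-weighted kappa matches a hand-built matrix oracle", {
  g3 <- gp_scale(c(60, 72, 84), "male")
  c1 <- 60; c2 <- 72; c3 <- 84
  a <- c(c1, c1, c2, c3)
  b <- c(c1, c2, c2, c3)
  # independent oracle: explicit O/E accumulation over index pairs
  kappa_oracle <- function(a, b, classes) {
    K <- length(classes)
    ia <- match(a, classes); ib <- match(b, classes)
    O <- matrix(0, K, K); n <- length(a)
    for (i in seq_len(n)) O[ia[i], ib[i]] <- O[ia[i], ib[i]] + 1 / n
    E <- outer(rowSums(O), colSums(O))
    num <- 0; den <- 0
    for (i in 1:K) for (j in 1:K) {
      w <- ((i - j) / (K - 1))^2
      num <- num + w * O[i, j]
      den <- den + w * E[i, j]
    }
    1 - num / den
  }
  expect_equal(weighted_kappa(a, b, g3), 0.8)
  expect_equal(weighted_kappa(a, b, g3), kappa_oracle(a, b, g3$classes))
  expect_equal(weighted_kappa(a, a, g3), 1)
  set.seed(17)
  for (rep in 1:10) {
    aa <- sample(scale_m$classes, 200, replace = TRUE)
    bb <- sample(scale_m$classes, 200, replace = TRUE)
    expect_equal(weighted_kappa(aa, bb, scale_m),
                 kappa_oracle(aa, bb, scale_m$classes), tolerance = 1e-12)
  }
  expect_error(weighted_kappa(c(61), c(60), g3),
               class = "sgpAge_invalid_input")
})

test_that("kappa of independently shuffled labels concentrates near zero", {
  set.seed(23)
  ks <- replicate(200, {
    a <- sample(scale_m$classes, 300, replace = TRUE)
    weighted_kappa(a, sample(a), scale_m)
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("class agreement counts pairs within k grid steps", {
  a <- scale_m$classes[c(3, 5, 7, 9)]
  expect_equal(class_agreement(a, a, scale_m, 0), 100)
  b <- scale_m$classes[c(4, 6, 8, 10)]     # one class off everywhere
  expect_equal(class_agreement(a, b, scale_m, 0), 0)
  expect_equal(class_agreement(a, b, scale_m, 1), 100)
  a10 <- scale_m$classes[c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)]
  b10 <- scale_m$classes[c(1, 4, 3, 4, 7, 6, 7, 8, 12, 10)]
  manual <- 100 * mean(abs(c(0, 2, 0, 0, 2, 0, 0, 0, 3, 0)) <= 1)
  expect_equal(class_agreement(a10, b10, scale_m, 1), manual)
})

test_that("the bundled report matches its individually computed parts", {
  set.seed(29)
  truth <- sample(scale_m$classes, 150, replace = TRUE)
  pred <- truth + rnorm(150, 0, 9)
  rep_ <- evaluate_agreement(pred, truth, scale_m)
  expect_equal(rep_$mad, age_mad(pred, truth))
  expect_equal(rep_$rmse, age_rmse(pred, truth))
  expect_equal(rep_$r2, r_squared(pred, truth))
  ba <- bland_altman(pred, truth)
  expect_equal(rep_$bias, ba$bias)
  expect_equal(rep_$loa_low, ba$loa_low)
  expect_identical(rep_$high_error_ids, ba$high_error_ids)
  snapped <- snap_to_gp(pred, scale_m)
  expect_equal(rep_$kappa, weighted_kappa(snapped, truth, scale_m))
  expect_equal(rep_$pct_exact, class_agreement(snapped, truth, scale_m, 0))
  expect_equal(rep_$pct_within_1, class_agreement(snapped, truth, scale_m, 1))
  expect_lte(rep_$mad, rep_$rmse)

  perfect <- evaluate_agreement(as.numeric(truth), truth, scale_m)
  expect_equal(perfect$mad, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$pct_exact, 100)
})
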