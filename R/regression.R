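#' Regressor training configuration
#'
#' @param input_size Square input resolution in pixels; must be divisible by
#'   16 (four pooling stages).
#' @param epochs,batch_size,lr Optimization settings (Adam).
#' @param loss `"L1"` (default; directly optimizes MAD) or `"L2"`.
#' @param seed Integer seed, recorded in the checkpoint.
#' @param head_refit After backbone training, recalibrate the linear head by
#'   least squares on the training features (deterministic; default `TRUE`).
#' @return A `reg_train_config` list.
#' @export
reg_train_config <- function(input_size = 48L, epochs = 30L, batch_size = 8L,
                             lr = 2e-3, loss = c("L1", "L2"), seed = 1L,
                             head_refit = TRUE) {
  loss <- match.arg(loss)
  check_number(input_size, "input_size", min = 16)
  if (input_size %% 16 != 0) {
    stop_sgp("invalid_input", "input_size must be divisible by 16")
  }
  check_number(epochs, "epochs", min = 1)
  check_number(batch_size, "batch_size", min = 1)
  check_number(lr, "lr", min = 1e-8)
  check_flag(head_refit, "head_refit")
  structure(list(input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, loss = loss,
                 seed = as.integer(seed), head_refit = head_refit),
            class = "reg_train_config")
}

sample_label <- function(s, target) {
  if (target == "fullhand") s$y else s$segment_ages[[target]]
}

# Stack sample images into a normalized [S,S,1,N] tensor.
stack_images <- function(samples, size, norm = NULL) {
  n <- length(samples)
  x <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- resize_image(samples[[i]]$image, size)
  }
  if (is.null(norm)) {
    norm <- list(mean = mean(x), sd = stats::sd(as.numeric(x)))
    if (!is.finite(norm$sd) || norm$sd <= 0) {
      stop_sgp("data_error", "training images have zero intensity variance")
    }
  }
  list(x = (x - norm$mean) / norm$sd, norm = norm)
}

refit_head <- function(params, feats, labels) {
  X <- cbind(1, feats)
  fit <- stats::lm.fit(X, labels)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  params$bh <- co[1]
  params$wh <- as.numeric(co[-1])
  params
}

# Ridge head refit with the penalty chosen by closed-form leave-one-out CV.
# Used for small target cohorts, where plain least squares on ~p samples
# interpolates and generalizes poorly. Deterministic.
refit_head_ridge <- function(params, feats, labels,
                             lambdas = 10^seq(-6, 3, by = 0.5)) {
  n <- nrow(feats)
  mu <- colMeans(feats)
  sc <- apply(feats, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  Z <- sweep(sweep(feats, 2, mu), 2, sc, "/")
  yc <- labels - mean(labels)
  sv <- svd(Z)
  d2 <- sv$d^2
  uy <- crossprod(sv$u, yc)                       # t(U) %*% yc
  best <- NULL; best_err <- Inf
  for (lam in lambdas) {
    shrink <- d2 / (d2 + lam)
    fitted <- sv$u %*% (shrink * uy)
    hat <- rowSums(sweep(sv$u^2, 2, shrink, "*")) + 1 / n
    hat <- pmin(hat, 1 - 1e-8)
    loo <- mean(((yc - fitted) / (1 - hat))^2)
    if (is.finite(loo) && loo < best_err) { best_err <- loo; best <- lam }
  }
  shrink <- sv$d / (d2 + best)
  beta_z <- sv$v %*% (shrink * uy)
  wh <- as.numeric(beta_z) / sc
  params$wh <- wh
  params$bh <- mean(labels) - sum(wh * mu)
  params
}

#' Train a base age regressor
#'
#' Trains the small CNN regressor on one sex's samples against the chosen
#' age target. Input normalization statistics (scalar mean/sd of the
#' training images) are computed here and stored in the state; they travel
#' with the model so that fine-tuning normalizes target-cohort images with
#' the *source* statistics. After gradient training the linear head is
#' recalibrated by least squares on the training features (disable via
#' `config$head_refit`).
#'
#' @param samples List of `radiograph_sample` objects (full-hand images or
#'   segment crops), all of one sex.
#' @param target `"fullhand"`, `"shortbones"`, `"carpals"` or `"wrist"` —
#'   which ground-truth age column to regress on.
#' @param config A [reg_train_config()].
#' @return An `sgp_regressor` state.
#' @export
train_base <- function(samples, target = c("fullhand", "shortbones",
                                           "carpals", "wrist"),
                       config = reg_train_config()) {
  target <- match.arg(target)
  samples <- coerce_samples(samples)
  sexes <- unique(vapply(samples, `[[`, character(1), "sex"))
  if (length(sexes) != 1L) {
    stop_sgp("data_error",
             "mixed sexes in training samples; train one model per sex")
  }
  labels <- vapply(samples, function(s) {
    v <- sample_label(s, target)
    if (is.null(v) || !is.finite(v)) {
      stop_sgp("data_error", sprintf("missing `%s` age label", target))
    }
    as.numeric(v)
  }, numeric(1))
  st <- stack_images(samples, config$input_size)
  x <- st$x
  n <- length(samples)
  with_seed(config$seed, {
    params <- regnet_init()
    opt <- adam_init(params)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- labels[idx]
        fw <- regnet_forward(params, xb, want_cache = TRUE)
        resid <- fw$pred - yb
        if (config$loss == "L1") {
          loss <- mean(abs(resid))
          dpred <- sign(resid) / length(resid)
        } else {
          loss <- mean(resid^2)
          dpred <- 2 * resid / length(resid)
        }
        grads <- regnet_backward(params, fw$cache, fw$feats, dpred)
        stp <- adam_step(params, grads, opt, config$lr)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      loss_hist[ep] <- ep_loss / nb
    }
    if (config$head_refit) {
      feats <- regnet_features(params, x)$feats
      params <- refit_head(params, feats, labels)
    }
    structure(list(params = params, norm = st$norm, segment = target,
                   sex = sexes, config = config, fine_tuned = FALSE,
                   loss_history = loss_hist),
              class = "sgp_regressor")
  })
}

#' @export
print.sgp_regressor <- function(x, ...) {
  cat(sprintf("<sgp_regressor> %s / %s%s, input %dpx, norm mean %.3f sd %.3f\n",
              x$segment, x$sex, if (x$fine_tuned) " (fine-tuned)" else "",
              x$config$input_size, x$norm$mean, x$norm$sd))
  invisible(x)
}

#' Fine-tune only the regression head on a target cohort
#'
#' Same-domain transfer: every backbone parameter of the base model is
#' frozen (returned byte-identical); only the final linear layer is refitted,
#' by ridge least squares on the frozen features of the target images, with
#' the penalty chosen by closed-form leave-one-out cross-validation (target
#' cohorts are small, so an unpenalized refit would interpolate). Target
#' images are normalized with the *base* model's stored source statistics,
#' not target-domain statistics. When a `ratings` data frame with two rater
#' columns is supplied, the training label is their per-sample mean;
#' otherwise labels come from the samples' own age fields (or a supplied
#' numeric vector).
#'
#' @param base A trained `sgp_regressor`.
#' @param samples Target-cohort samples (same sex and segment semantics as
#'   the base model).
#' @param labels Optional numeric label vector overriding the samples' ages.
#' @param ratings Optional data frame of one or two rater columns (months);
#'   two columns are averaged.
#' @return A new `sgp_regressor` with `fine_tuned = TRUE`.
#' @export
fine_tune_head <- function(base, samples, labels = NULL, ratings = NULL) {
  stopifnot(inherits(base, "sgp_regressor"))
  if (is.null(base$norm) || !is.finite(base$norm$sd) || base$norm$sd <= 0) {
    stop_sgp("state_error", "base model has no valid normalization stats")
  }
  samples <- coerce_samples(samples)
  sexes <- unique(vapply(samples, `[[`, character(1), "sex"))
  if (length(sexes) != 1L || sexes != base$sex) {
    stop_sgp("data_error", "target samples must match the base model's sex")
  }
  if (!is.null(ratings)) {
    ratings <- as.data.frame(ratings)
    if (ncol(ratings) == 2L) {
      labels <- rowMeans(ratings)
    } else if (ncol(ratings) == 1L) {
      labels <- ratings[[1]]
    } else {
      stop_sgp("data_error", "ratings must have one or two columns")
    }
  }
  if (is.null(labels)) {
    labels <- vapply(samples, function(s) {
      as.numeric(sample_label(s, base$segment))
    }, numeric(1))
  }
  if (length(labels) != length(samples) || !all(is.finite(labels))) {
    stop_sgp("data_error", "labels must be finite, one per sample")
  }
  st <- stack_images(samples, base$config$input_size, norm = base$norm)
  feats <- regnet_features(base$params, st$x)$feats
  out <- base
  out$params <- refit_head_ridge(base$params, feats, labels)
  out$fine_tuned <- TRUE
  out
}

#' Predict an age in months
#'
#' Deterministic evaluation-mode prediction, clamped to the physically
#' plausible `[0, 300]` month range.
#'
#' @param state An `sgp_regressor`.
#' @param image Matrix matching the state's input size, or a list of such
#'   matrices / `radiograph_sample` objects.
#' @return Numeric vector of continuous ages in months.
#' @export
predict_age <- function(state, image) {
  stopifnot(inherits(state, "sgp_regressor"))
  imgs <- if (is.matrix(image)) list(image) else image
  S <- state$config$input_size
  n <- length(imgs)
  x <- array(0, c(S, S, 1, n))
  for (i in seq_len(n)) {
    im <- imgs[[i]]
    if (inherits(im, "radiograph_sample")) im <- im$image
    if (!is.matrix(im) || nrow(im) != S || ncol(im) != S) {
      stop_sgp("invalid_input",
               sprintf("image %d must be a %dx%d matrix", i, S, S))
    }
    x[, , 1, i] <- im
  }
  x <- (x - state$norm$mean) / state$norm$sd
  pred <- regnet_forward(state$params, x)$pred
  pmin(300, pmax(0, pred))
}

#' Save / load a regressor checkpoint
#'
#' Single-file serialized state plus a JSON sidecar recording segment, sex,
#' normalization statistics, config and seed.
#'
#' @param state An `sgp_regressor`.
#' @param path Checkpoint file path.
#' @return `save_regressor` returns `path` invisibly; `load_regressor`
#'   returns the state.
#' @export
save_regressor <- function(state, path) {
  stopifnot(inherits(state, "sgp_regressor"))
  saveRDS(state, path)
  sidecar <- list(kind = "sgp_regressor", segment = state$segment,
                  sex = state$sex, fine_tuned = state$fine_tuned,
                  norm_mean = state$norm$mean, norm_sd = state$norm$sd,
                  input_size = state$config$input_size,
                  seed = state$config$seed, loss = state$config$loss)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  if (!file.exists(path)) {
    stop_sgp("io_error", sprintf("checkpoint not found: %s", path))
  }
  m <- readRDS(path)
  if (!inherits(m, "sgp_regressor")) {
    stop_sgp("io_error", "file is not an sgp_regressor checkpoint")
  }
  m
}
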