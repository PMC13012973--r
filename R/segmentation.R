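as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# Aspect-preserving resize helpers (bilinear for images, nearest for masks).
resize_image <- function(img, size, nearest = FALSE) {
  if (nrow(img) == size && ncol(img) == size) return(img)
  filt <- if (nearest) "none" else "bilinear"
  as_plain_matrix(EBImage::resize(img, w = size, h = size, filter = filt))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical (or 0/1) matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coef <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!identical(dim(a), dim(b))) {
    stop_sgp("invalid_input", "masks must have identical shapes")
  }
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Segmenter training configuration
#'
#' @param input_size Square input resolution (must be even; images and masks
#'   are resized to it).
#' @param c1,c2 Channel widths of the encoder-decoder.
#' @param epochs,batch_size,lr Optimization settings (Adam).
#' @param pos_weight Weight on positive (bone) pixels in the cross-entropy;
#'   counteracts the foreground/background imbalance of radiograph masks.
#' @param seed Integer seed; training is reproducible in single-threaded mode.
#' @return A `seg_train_config` list.
#' @export
seg_train_config <- function(input_size = 64L, c1 = 8L, c2 = 16L,
                             epochs = 12L, batch_size = 8L, lr = 1e-2,
                             pos_weight = 5, seed = 1L) {
  check_number(input_size, "input_size", min = 16)
  if (input_size %% 2 != 0) {
    stop_sgp("invalid_input", "input_size must be even")
  }
  check_number(epochs, "epochs", min = 1)
  check_number(batch_size, "batch_size", min = 1)
  check_number(lr, "lr", min = 1e-8)
  check_number(pos_weight, "pos_weight", min = 1)
  structure(list(input_size = as.integer(input_size), c1 = as.integer(c1),
                 c2 = as.integer(c2), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "seg_train_config")
}

coerce_samples <- function(x, need_masks = FALSE) {
  if (is.character(x) || is.data.frame(x)) x <- load_dataset(x)
  if (!is.list(x) || length(x) == 0L ||
      !all(vapply(x, inherits, logical(1), "radiograph_sample"))) {
    stop_sgp("data_error",
             "expected a non-empty list of radiograph_sample objects or a manifest")
  }
  if (need_masks && any(vapply(x, function(s) is.null(s$masks), logical(1)))) {
    stop_sgp("data_error", "every sample must carry ground-truth masks")
  }
  x
}

#' Train the phantom segmenter
#'
#' Trains the small encoder-decoder network against per-pixel sigmoid
#' cross-entropy on three mask channels (shortbones, carpals, wrist).
#' Images and masks are resized to `config$input_size`. Training is seeded
#' and single-threaded-reproducible.
#'
#' @param samples A list of `radiograph_sample` objects with masks, a
#'   manifest data frame, or a manifest CSV path.
#' @param config A [seg_train_config()].
#' @return An `sgp_segmenter` model state (parameters, batch-norm running
#'   statistics, config, per-epoch loss history).
#' @export
train_segmenter <- function(samples, config = seg_train_config()) {
  samples <- coerce_samples(samples, need_masks = TRUE)
  S <- config$input_size
  n <- length(samples)
  x <- array(0, c(S, S, 1, n))
  t3 <- array(0, c(S, S, 3, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- resize_image(samples[[i]]$image, S)
    for (k in 1:3) {
      t3[, , k, i] <- resize_image(samples[[i]]$masks[[segment_names()[k]]] * 1,
                                   S, nearest = TRUE) > 0.5
    }
  }
  with_seed(config$seed, {
    net <- segnet_init(config$c1, config$c2)
    params <- net$params
    running <- net$running
    opt <- adam_init(params)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        xb <- x[, , , idx, drop = FALSE]
        tb <- t3[, , , idx, drop = FALSE]
        fw <- segnet_forward(params, running, xb, "train")
        running <- fw$running
        wts <- 1 + (config$pos_weight - 1) * tb
        loss <- bce_loss(fw$logits, tb, wts)
        grads <- segnet_backward(params, fw$cache,
                                 bce_grad(fw$logits, tb, wts))
        st <- adam_step(params, grads, opt, config$lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      loss_hist[ep] <- ep_loss / nb
    }
    structure(list(params = params, running = running, config = config,
                   loss_history = loss_hist),
              class = "sgp_segmenter")
  })
}

#' @export
print.sgp_segmenter <- function(x, ...) {
  cat(sprintf("<sgp_segmenter> input %dpx, channels %d/%d, final loss %.4f\n",
              x$config$input_size, x$config$c1, x$config$c2,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict segment masks for one image
#'
#' Runs the segmenter in evaluation mode. With `tta = FALSE` the batch-norm
#' layers use the running statistics stored at training time; with
#' `tta = TRUE` (test-time adaptation) each normalization layer recomputes
#' its statistics from the current input alone, which makes the thresholded
#' masks invariant to positive affine intensity transforms of the input and
#' robust to global domain shift. Neither mode updates any stored parameter.
#'
#' @param model An `sgp_segmenter`.
#' @param image Numeric matrix; must already match the model's input size
#'   (resizing is the caller's responsibility).
#' @param tta Logical; enable test-time adaptation.
#' @param threshold Sigmoid probability threshold for binarization.
#' @return A `mask_set`: named list of three logical matrices with the
#'   probability array attached as attribute `prob`.
#' @export
predict_masks <- function(model, image, tta = FALSE, threshold = 0.5) {
  stopifnot(inherits(model, "sgp_segmenter"))
  check_flag(tta, "tta")
  S <- model$config$input_size
  if (!is.matrix(image) || nrow(image) != S || ncol(image) != S) {
    stop_sgp("invalid_input",
             sprintf("image must be a %dx%d matrix matching the model input",
                     S, S))
  }
  x <- array(image, c(S, S, 1, 1))
  fw <- segnet_forward(model$params, model$running, x,
                       if (tta) "tta" else "eval")
  prob <- sigmoid(fw$logits[, , , 1])
  masks <- lapply(1:3, function(k) prob[, , k] >= threshold)
  names(masks) <- segment_names()
  structure(masks, class = "mask_set", prob = prob)
}

#' Mask refinement configuration
#'
#' Thresholds for [refine_masks()]. `min_area = NULL` resolves to 0.1% of
#' the image area at refinement time.
#'
#' @param min_area Minimum connected-component area in pixels (or `NULL`).
#' @param mean_intensity_min Minimum mean underlying image intensity of a
#'   component, in `[0, 1]`.
#' @param morph_open_radius,morph_close_radius Disc radii (pixels) for
#'   morphological opening then closing; 0 disables the step.
#' @param keep_top_k Number of largest components kept per segment (can be a
#'   named vector with entries `shortbones`, `carpals`, `wrist`).
#' @return A `refine_config` list.
#' @export
refine_config <- function(min_area = NULL, mean_intensity_min = 0.15,
                          morph_open_radius = 2L, morph_close_radius = 2L,
                          keep_top_k = 1L) {
  if (!is.null(min_area)) check_number(min_area, "min_area", min = 0)
  check_number(mean_intensity_min, "mean_intensity_min", min = 0, max = 1)
  check_number(morph_open_radius, "morph_open_radius", min = 0)
  check_number(morph_close_radius, "morph_close_radius", min = 0)
  if (any(keep_top_k < 1)) {
    stop_sgp("invalid_input", "keep_top_k must be >= 1")
  }
  structure(list(min_area = min_area,
                 mean_intensity_min = mean_intensity_min,
                 morph_open_radius = as.integer(morph_open_radius),
                 morph_close_radius = as.integer(morph_close_radius),
                 keep_top_k = keep_top_k),
            class = "refine_config")
}

top_k_for <- function(cfg, segment) {
  k <- cfg$keep_top_k
  if (!is.null(names(k)) && segment %in% names(k)) k <- k[[segment]]
  max(1L, as.integer(k))
}

#' Refine raw segment masks
#'
#' Per mask: morphological opening then closing with disc structuring
#' elements, connected-component labeling, removal of components smaller
#' than `min_area` or with mean underlying image intensity below
#' `mean_intensity_min`, retention of the `keep_top_k` largest remaining
#' components, and finally pairwise-disjointness enforcement (a pixel claimed
#' by several segments goes to the larger component; ties to the first
#' segment in shortbones, carpals, wrist order). If every component of a
#' mask is filtered out, an `empty_segment` warning is raised and an empty
#' mask returned.
#'
#' @param masks A `mask_set` (or named list of binary matrices).
#' @param image The underlying grayscale image (same shape), used for the
#'   mean-intensity rule.
#' @param cfg A [refine_config()].
#' @return A refined `mask_set`.
#' @export
refine_masks <- function(masks, image, cfg = refine_config()) {
  stopifnot(is.list(masks), all(segment_names() %in% names(masks)))
  raw_nonempty <- vapply(segment_names(), function(s) any(masks[[s]] > 0),
                         logical(1))
  cur <- lapply(segment_names(), function(s) masks[[s]] > 0)
  names(cur) <- segment_names()
  # disjointness trimming can leave jags the morphology would re-shave, so
  # the pass is iterated to its fixed point (reached after 1-2 extra passes
  # in practice) — this is what makes refinement idempotent
  for (it in 1:4) {
    nxt <- refine_pass(cur, image, cfg)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  for (s in segment_names()) {
    if (raw_nonempty[[s]] && !any(cur[[s]])) {
      warn_sgp("empty_segment",
               sprintf("all components filtered out for segment `%s`", s))
    }
  }
  structure(cur, class = "mask_set")
}

refine_pass <- function(masks, image, cfg) {
  dims <- dim(masks[[segment_names()[1]]])
  min_area <- if (is.null(cfg$min_area)) 0.001 * prod(dims) else cfg$min_area
  lab_list <- list(); area_list <- list()
  for (s in segment_names()) {
    m <- masks[[s]] > 0
    if (any(m) && cfg$morph_open_radius > 0) {
      kern <- EBImage::makeBrush(2L * cfg$morph_open_radius + 1L, "disc")
      m <- as_plain_matrix(EBImage::opening(m * 1, kern)) > 0.5
    }
    if (any(m) && cfg$morph_close_radius > 0) {
      kern <- EBImage::makeBrush(2L * cfg$morph_close_radius + 1L, "disc")
      m <- as_plain_matrix(EBImage::closing(m * 1, kern)) > 0.5
    }
    lab <- as_plain_matrix(EBImage::bwlabel(m * 1))
    keep_area <- numeric(0)
    if (max(lab) >= 1) {
      sel <- lab > 0
      areas <- tabulate(lab[sel], nbins = max(lab))
      msum <- as.numeric(rowsum(image[sel], lab[sel]))
      mean_int <- msum / areas
      ok <- which(areas >= min_area & mean_int >= cfg$mean_intensity_min)
      ok <- ok[order(areas[ok], decreasing = TRUE)]
      ok <- utils::head(ok, top_k_for(cfg, s))
      lab[!(lab %in% ok)] <- 0
      keep_area <- areas
    }
    lab_list[[s]] <- lab
    area_list[[s]] <- keep_area
  }
  # disjointness: contested pixels go to the larger component
  A <- vapply(segment_names(), function(s) {
    lab <- lab_list[[s]]
    a <- matrix(0, dims[1], dims[2])
    sel <- lab > 0
    if (any(sel)) a[sel] <- area_list[[s]][lab[sel]]
    a
  }, matrix(0, dims[1], dims[2]))
  maxA <- pmax(A[, , 1], A[, , 2], A[, , 3])
  out <- list()
  claimed <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_along(segment_names())) {
    s <- segment_names()[k]
    keep <- lab_list[[s]] > 0 & A[, , k] >= maxA & !claimed
    claimed <- claimed | keep
    out[[s]] <- keep
  }
  out
}

#' Crop masked segment images
#'
#' For each segment: tight bounding box of the mask, expanded by
#' `pad_fraction` of the box size (clipped to the image), pixels outside the
#' mask zeroed, then aspect-preserving resize with zero letterboxing to a
#' square of side `out_size`. Bounding boxes use 1-based inclusive row/column
#' indices.
#'
#' @param image Grayscale matrix.
#' @param masks A `mask_set` with non-empty masks.
#' @param out_size Output side in pixels.
#' @param pad_fraction Fractional bounding-box expansion per side.
#' @return Named list of three `out_size` x `out_size` matrices.
#' @export
crop_segments <- function(image, masks, out_size = 64L, pad_fraction = 0.05) {
  check_number(out_size, "out_size", min = 8)
  check_number(pad_fraction, "pad_fraction", min = 0)
  out <- list()
  for (s in segment_names()) {
    m <- masks[[s]] > 0
    if (!any(m)) {
      stop_sgp("empty_segment",
               sprintf("cannot crop empty segment mask `%s`", s))
    }
    w <- which(m, arr.ind = TRUE)
    r0 <- min(w[, 1]); r1 <- max(w[, 1])
    c0 <- min(w[, 2]); c1 <- max(w[, 2])
    pr <- round(pad_fraction * (r1 - r0 + 1))
    pc <- round(pad_fraction * (c1 - c0 + 1))
    r0 <- max(1L, r0 - pr); r1 <- min(nrow(image), r1 + pr)
    c0 <- max(1L, c0 - pc); c1 <- min(ncol(image), c1 + pc)
    crop <- image[r0:r1, c0:c1, drop = FALSE] * m[r0:r1, c0:c1, drop = FALSE]
    h <- nrow(crop); wd <- ncol(crop)
    sc <- out_size / max(h, wd)
    nh <- max(1L, as.integer(round(h * sc)))
    nw <- max(1L, as.integer(round(wd * sc)))
    rs <- as_plain_matrix(EBImage::resize(crop, w = nh, h = nw))
    canvas <- matrix(0, out_size, out_size)
    ro <- (out_size - nh) %/% 2L
    co <- (out_size - nw) %/% 2L
    canvas[ro + seq_len(nh), co + seq_len(nw)] <- rs
    out[[s]] <- canvas
  }
  out
}

#' Save / load a segmenter checkpoint
#'
#' Single-file serialized state plus a JSON sidecar (`<path>.json`) recording
#' the architecture, input size and training config.
#'
#' @param model An `sgp_segmenter`.
#' @param path Checkpoint file path.
#' @return `save_segmenter` returns `path` invisibly; `load_segmenter`
#'   returns the model.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "sgp_segmenter"))
  saveRDS(model, path)
  sidecar <- list(kind = "sgp_segmenter", architecture = "small-unet",
                  input_size = model$config$input_size,
                  channels = c(model$config$c1, model$config$c2),
                  seed = model$config$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  if (!file.exists(path)) {
    stop_sgp("io_error", sprintf("checkpoint not found: %s", path))
  }
  m <- readRDS(path)
  if (!inherits(m, "sgp_segmenter")) {
    stop_sgp("io_error", "file is not an sgp_segmenter checkpoint")
  }
  m
}
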