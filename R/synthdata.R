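#' Phantom generator parameters
#'
#' Parameters for one synthetic hand phantom. The phantom is a stylized
#' radiograph whose three anatomical regions carry independently controllable
#' maturity signals: short bones (four finger rays whose epiphyseal gaps
#' narrow with short-bone age), carpals (a blob cluster whose total ossified
#' area grows with carpal age, saturating at the top of the grid), and wrist
#' (two bone shafts whose epiphyseal gap narrows with wrist age). Segment
#' ages are `fullhand_age + segment_offsets`, clipped to the GP grid range,
#' realizing the asynchronous maturation the segmental method targets.
#'
#' @param image_size Side of the square image in pixels (>= 64).
#' @param sex `"male"` or `"female"`; affects the GP grid used for label
#'   snapping and a global bone-width factor.
#' @param fullhand_age Full-hand age in months.
#' @param segment_offsets Numeric length-3 vector (shortbones, carpals,
#'   wrist), signed offsets in months added to `fullhand_age`.
#' @param noise_sd Additive Gaussian intensity noise (image is in `[0, 1]`).
#' @param seed Integer; fully determines the phantom.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(image_size = 128, sex = c("male", "female"),
                           fullhand_age = 120,
                           segment_offsets = c(0, 0, 0),
                           noise_sd = 0.02, seed = 1L) {
  sex <- match.arg(sex)
  check_number(image_size, "image_size", min = 1)
  if (image_size < 64) {
    stop_sgp("layout_error", "image_size must be at least 64 pixels")
  }
  check_number(fullhand_age, "fullhand_age", min = 0)
  if (!is.numeric(segment_offsets) || length(segment_offsets) != 3L ||
      anyNA(segment_offsets)) {
    stop_sgp("invalid_input", "segment_offsets must be 3 finite numbers")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed")
  structure(list(image_size = as.integer(image_size), sex = sex,
                 fullhand_age = fullhand_age,
                 segment_offsets = as.numeric(segment_offsets),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

segment_names <- function() c("shortbones", "carpals", "wrist")

# Maturity in [0,1] of an age relative to the grid span.
maturity_of <- function(age, scale) {
  g <- scale$classes
  m <- (age - min(g)) / (max(g) - min(g))
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

draw_block <- function(canvas, r0, r1, c0, c1, value) {
  r <- max(1L, r0):min(nrow(canvas), r1)
  cc <- max(1L, c0):min(ncol(canvas), c1)
  canvas[r, cc] <- value
  canvas
}

#' Generate a synthetic hand phantom
#'
#' Renders the phantom described in [phantom_params()] and returns the image
#' together with exact ground-truth masks and GP-snapped segment labels.
#' The geometry layout is fixed (only texture noise and 1-pixel placement
#' jitter are random) so masks are exact by construction, and the same seed
#' always yields a bit-identical sample.
#'
#' @param params A [phantom_params()].
#' @param scale A [gp_scale()] for the phantom's sex.
#' @return A `radiograph_sample`: list with `image` (matrix in `[0, 1]`),
#'   `sex`, `y` (GP-snapped full-hand age), `segment_ages` (named list),
#'   `masks` (named list of logical matrices, pairwise disjoint), `id`.
#' @examples
#' sc <- default_gp_scale("male")
#' ph <- generate_phantom(phantom_params(image_size = 64, seed = 7), sc)
#' range(ph$image)
#' @export
generate_phantom <- function(params, scale) {
  stopifnot(inherits(params, "phantom_params"))
  check_scale(scale)
  if (scale$sex != params$sex) {
    stop_sgp("data_error", "scale sex does not match phantom sex")
  }
  S <- params$image_size
  f <- if (params$sex == "male") 1.0 else 0.94
  g <- scale$classes
  seg_age_cont <- pmin(max(g), pmax(min(g),
                       params$fullhand_age + params$segment_offsets))
  names(seg_age_cont) <- segment_names()
  m <- maturity_of(seg_age_cont, scale)

  with_seed(params$seed, {
    img <- matrix(0.06, S, S)
    masks <- lapply(segment_names(), function(s) matrix(FALSE, S, S))
    names(masks) <- segment_names()
    px <- function(fr) as.integer(round(fr * S))

    ## Short bones: 4 rays, 3 phalanx blocks each, 2 gaps that narrow with age
    sb_top <- px(0.08); sb_bot <- px(0.50)
    gmax_sb <- max(3L, px(0.08))
    gap_sb <- max(1L, as.integer(round((1 - m[["shortbones"]]) * gmax_sb)))
    half_w <- max(2L, as.integer(round(0.030 * S * f)))
    for (k in 1:4) {
      cc <- px(0.2 * k) + sample(-1:1, 1)
      len <- sb_bot - sb_top
      gc1 <- sb_top + as.integer(round(len / 3))
      gc2 <- sb_top + as.integer(round(2 * len / 3))
      rows <- sb_top:sb_bot
      in_gap <- (rows >= gc1 & rows < gc1 + gap_sb) |
                (rows >= gc2 & rows < gc2 + gap_sb)
      bone_rows <- rows[!in_gap]
      cols <- max(1L, cc - half_w):min(S, cc + half_w)
      val <- 0.80 * (1 + stats::rnorm(1, 0, 0.02))
      img[bone_rows, cols] <- val
      masks$shortbones[bone_rows, cols] <- TRUE
    }

    ## Carpals: up to 7 blobs; staggered appearance, radii grow with age
    cent <- rbind(c(0.58, 0.33), c(0.58, 0.47), c(0.58, 0.61),
                  c(0.70, 0.30), c(0.70, 0.44), c(0.70, 0.58), c(0.70, 0.72))
    # two blobs are always ossified (negative onset); radii saturate only at
    # the top of the grid, so area grows strictly below saturation
    appear <- c(-0.2, -0.1, 0, 0.1, 0.25, 0.4, 0.55)
    rmin <- max(1.5, 0.02 * S)
    rmax <- 0.055 * S * f
    ii <- matrix(seq_len(S), S, S)
    jj <- matrix(seq_len(S), S, S, byrow = TRUE)
    mc <- m[["carpals"]]
    for (k in 1:7) {
      if (mc <= appear[k]) next
      r <- rmin + (rmax - rmin) * min(1, (mc - appear[k]) / (1 - appear[k]))
      ci <- cent[k, 1] * S + sample(-1:1, 1)
      cj <- cent[k, 2] * S + sample(-1:1, 1)
      blob <- (ii - ci)^2 + (jj - cj)^2 <= r^2
      img[blob] <- 0.75 * (1 + stats::rnorm(1, 0, 0.02))
      masks$carpals[blob] <- TRUE
    }

    ## Wrist: radius and ulna shafts with an epiphyseal gap that narrows
    w_top <- px(0.79); w_bot <- px(0.95)
    epi_bot <- px(0.83)
    gmax_w <- max(3L, px(0.07))
    gap_w <- max(1L, as.integer(round((1 - m[["wrist"]]) * gmax_w)))
    wr_spec <- list(list(c = 0.38, hw = 0.050), list(c = 0.62, hw = 0.038))
    for (b in wr_spec) {
      cc <- px(b$c) + sample(-1:1, 1)
      hw <- max(2L, as.integer(round(b$hw * S * f)))
      cols <- max(1L, cc - hw):min(S, cc + hw)
      val <- 0.85 * (1 + stats::rnorm(1, 0, 0.02))
      # epiphysis
      img[w_top:epi_bot, cols] <- val
      masks$wrist[w_top:epi_bot, cols] <- TRUE
      # shaft below the gap
      sh_top <- min(w_bot, epi_bot + gap_w + 1L)
      img[sh_top:w_bot, cols] <- val
      masks$wrist[sh_top:w_bot, cols] <- TRUE
    }

    img <- img + matrix(stats::rnorm(S * S, 0, params$noise_sd), S, S)
    img <- clip01(img)

    structure(list(
      image = img,
      sex = params$sex,
      y = snap_to_gp(params$fullhand_age, scale),
      segment_ages = as.list(snap_to_gp(seg_age_cont, scale)),
      masks = masks,
      id = sprintf("phantom_%s_s%d", params$sex, params$seed),
      params = params
    ), class = "radiograph_sample")
  })
}

#' Domain-shift transform parameters
#'
#' A global intensity/contrast transform emulating the acquisition-statistics
#' mismatch between a source and a target cohort of radiographs:
#' `clip(gain * image^gamma + offset, 0, 1)`. On the non-clipped range the
#' transform is invertible whenever `gain > 0` and `gamma > 0`.
#'
#' @param gain Positive multiplicative gain.
#' @param offset Additive offset.
#' @param gamma Positive gamma exponent.
#' @param seed Unused by the deterministic transform; kept for config
#'   completeness.
#' @return A `shift_params` list.
#' @export
shift_params <- function(gain = 1, offset = 0, gamma = 1, seed = NULL) {
  check_number(gain, "gain")
  check_number(gamma, "gamma")
  check_number(offset, "offset")
  if (gain <= 0) stop_sgp("invalid_input", "gain must be positive")
  if (gamma <= 0) stop_sgp("invalid_input", "gamma must be positive")
  structure(list(gain = gain, offset = offset, gamma = gamma, seed = seed),
            class = "shift_params")
}

#' Apply a domain-shift transform to an image
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param shift A [shift_params()].
#' @return The transformed image, clipped back to `[0, 1]`.
#' @examples
#' img <- matrix(0.2, 4, 4)
#' apply_domain_shift(img, shift_params(gain = 0.5, offset = 0.4))[1, 1]
#' @export
apply_domain_shift <- function(image, shift) {
  stopifnot(inherits(shift, "shift_params"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_sgp("invalid_input", "image must be a numeric matrix")
  }
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop_sgp("invalid_input", "image values must lie in [0, 1]")
  }
  clip01(shift$gain * image^shift$gamma + shift$offset)
}

#' Generate a synthetic prediction table with a known fusion weight
#'
#' Simulates per-image model outputs around a latent continuous age drawn
#' uniformly over the GP grid span. Ground truth is the GP-snapped latent
#' age. Each record carries a shared "segmental disagreement" draw
#' `delta ~ N(0, s)` with `s = disagreement_scale * mean(noise sds)`:
#' the full-hand output is `latent - alpha0 * delta + noise` and each segment
#' output is `latent + (1 - alpha0) * delta + noise`, so the convex
#' combination at `alpha0` is exactly unbiased for the latent age — the
#' generative fusion weight a downstream sweep should recover. With both
#' noise sds zero all outputs equal the latent age.
#'
#' @param n Number of records (>= 1).
#' @param alpha0 Generative fusion weight in `[0, 1]`.
#' @param noise_sd_fh,noise_sd_seg Gaussian noise sds (months) on the
#'   full-hand and segment outputs.
#' @param scale A [gp_scale()].
#' @param seed Integer seed.
#' @param disagreement_scale Multiplier linking the segmental-disagreement sd
#'   to the noise level (default 4).
#' @return A data frame with columns
#'   `id, sex, fh, seg_shortbones, seg_carpals, seg_wrist, seg_avg, y`.
#' @export
generate_prediction_table <- function(n, alpha0, noise_sd_fh, noise_sd_seg,
                                      scale, seed = 1L,
                                      disagreement_scale = 4) {
  check_number(n, "n", min = 1)
  check_number(alpha0, "alpha0", min = 0, max = 1)
  check_number(noise_sd_fh, "noise_sd_fh")
  check_number(noise_sd_seg, "noise_sd_seg")
  if (noise_sd_fh < 0 || noise_sd_seg < 0) {
    stop_sgp("invalid_input", "noise sds must be non-negative")
  }
  check_scale(scale)
  n <- as.integer(n)
  g <- scale$classes
  with_seed(seed, {
    latent <- stats::runif(n, min(g), max(g))
    s_d <- disagreement_scale * (noise_sd_fh + noise_sd_seg) / 2
    delta <- stats::rnorm(n, 0, s_d)
    fh <- latent - alpha0 * delta + stats::rnorm(n, 0, noise_sd_fh)
    segs <- vapply(1:3, function(k) {
      latent + (1 - alpha0) * delta + stats::rnorm(n, 0, noise_sd_seg)
    }, numeric(n))
    if (n == 1L) segs <- matrix(segs, nrow = 1)
    df <- data.frame(
      id = sprintf("rec_%05d", seq_len(n)),
      sex = scale$sex,
      fh = fh,
      seg_shortbones = segs[, 1],
      seg_carpals = segs[, 2],
      seg_wrist = segs[, 3],
      stringsAsFactors = FALSE
    )
    df$seg_avg <- rowMeans(segs)
    df$y <- snap_to_gp(latent, scale)
    df
  })
}

#' Write a phantom dataset to disk
#'
#' Generates `n` phantoms and writes them as 8-bit grayscale PNGs with 0/255
#' mask PNGs and a CSV manifest. Full-hand ages are sampled uniformly over
#' the grid span and snapped to the grid; segment offsets are Gaussian.
#' Deterministic under `seed` (byte-identical manifest on re-run).
#'
#' @param n Number of phantoms.
#' @param scale A [gp_scale()]; the dataset is single-sex.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param sampler List of generator settings: `image_size` (default 128),
#'   `offset_sd` (months, default 6), `noise_sd` (default 0.02),
#'   `fullhand_range` (default the grid span).
#' @return The manifest data frame (invisibly written to
#'   `out_dir/manifest.csv`) with columns `id, sex, fullhand_age,
#'   shortbones_age, carpals_age, wrist_age, image_path, mask_shortbones,
#'   mask_carpals, mask_wrist`.
#' @export
make_dataset <- function(n, scale, out_dir, seed = 1L, sampler = list()) {
  check_number(n, "n", min = 1)
  check_scale(scale)
  smp <- utils::modifyList(list(image_size = 128, offset_sd = 6,
                                noise_sd = 0.02, fullhand_range = NULL),
                           sampler)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_sgp("io_error", sprintf("cannot create output directory %s", out_dir))
  }
  samples <- simulate_phantom_set(n, scale, seed = seed, sampler = smp)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- samples[[i]]
    id <- sprintf("ph_%s_%04d", scale$sex, i)
    img_path <- file.path("images", paste0(id, ".png"))
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    png::writePNG(ph$image, file.path(out_dir, img_path))
    mpaths <- vapply(segment_names(), function(s) {
      p <- file.path("masks", paste0(id, "_", s, ".png"))
      png::writePNG(ph$masks[[s]] * 1.0, file.path(out_dir, p))
      p
    }, character(1))
    rows[[i]] <- data.frame(
      id = id, sex = ph$sex, fullhand_age = ph$y,
      shortbones_age = ph$segment_ages$shortbones,
      carpals_age = ph$segment_ages$carpals,
      wrist_age = ph$segment_ages$wrist,
      image_path = img_path,
      mask_shortbones = mpaths[["shortbones"]],
      mask_carpals = mpaths[["carpals"]],
      mask_wrist = mpaths[["wrist"]],
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a set of in-memory phantoms with sampled ages
#'
#' Draws full-hand ages uniformly over the grid span (snapped to the grid)
#' and Gaussian per-segment offsets, and renders one phantom per draw.
#' Shared by [make_dataset()] and [run_pipeline()]; useful directly when no
#' disk round-trip is wanted.
#'
#' @inheritParams make_dataset
#' @return List of `radiograph_sample` objects.
#' @export
simulate_phantom_set <- function(n, scale, seed = 1L, sampler = list()) {
  smp <- utils::modifyList(list(image_size = 128, offset_sd = 6,
                                noise_sd = 0.02, fullhand_range = NULL),
                           sampler)
  g <- scale$classes
  rng <- smp$fullhand_range
  if (is.null(rng)) rng <- c(min(g), max(g))
  with_seed(seed, {
    lat <- stats::runif(n, rng[1], rng[2])
    offs <- matrix(stats::rnorm(3L * n, 0, smp$offset_sd), ncol = 3)
    seeds <- sample.int(2147480000L, n)
    lapply(seq_len(n), function(i) {
      p <- phantom_params(image_size = smp$image_size, sex = scale$sex,
                          fullhand_age = snap_to_gp(lat[i], scale),
                          segment_offsets = offs[i, ],
                          noise_sd = smp$noise_sd, seed = seeds[i])
      ph <- generate_phantom(p, scale)
      ph$id <- sprintf("ph_%s_%04d", scale$sex, i)
      ph
    })
  })
}

# Read a dataset written by make_dataset back into radiograph_sample objects.
load_dataset <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  needed <- c("id", "sex", "fullhand_age", "shortbones_age", "carpals_age",
              "wrist_age", "image_path")
  miss <- setdiff(needed, names(manifest))
  if (length(miss)) {
    stop_sgp("schema_error",
             sprintf("manifest missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- png::readPNG(file.path(dir, row$image_path))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    masks <- NULL
    mcols <- paste0("mask_", segment_names())
    if (all(mcols %in% names(manifest))) {
      masks <- lapply(segment_names(), function(s) {
        m <- png::readPNG(file.path(dir, row[[paste0("mask_", s)]]))
        if (length(dim(m)) == 3L) m <- m[, , 1]
        m > 0.5
      })
      names(masks) <- segment_names()
    }
    structure(list(image = img, sex = row$sex, y = row$fullhand_age,
                   segment_ages = list(shortbones = row$shortbones_age,
                                       carpals = row$carpals_age,
                                       wrist = row$wrist_age),
                   masks = masks, id = row$id),
              class = "radiograph_sample")
  })
}
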