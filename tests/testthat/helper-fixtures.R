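# Shared fixtures. Heavyweight objects (trained networks, multi-seed
# pipeline runs) are built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

default_sampler <- function(image_size = 64) {
  list(image_size = image_size, offset_sd = 6, noise_sd = 0.02)
}

# Phantom cohort + segmenter trained at reduced resolution: 200 training and
# 50 held-out phantoms, the desk-scale segmentation study.
fx_segmentation_study <- function() {
  if (is.null(.fx$seg_study)) {
    scale <- default_gp_scale("male")
    phantoms <- simulate_phantom_set(250, scale, seed = 4021,
                                     sampler = default_sampler())
    model <- train_segmenter(phantoms[1:200],
                             seg_train_config(input_size = 64, epochs = 12,
                                              seed = 977))
    .fx$seg_study <- list(model = model, train = phantoms[1:200],
                          heldout = phantoms[201:250], scale = scale)
  }
  .fx$seg_study
}

# A deliberately tiny segmenter for API-level tests.
fx_tiny_segmenter <- function() {
  if (is.null(.fx$tiny_seg)) {
    scale <- default_gp_scale("male")
    phantoms <- simulate_phantom_set(10, scale, seed = 55,
                                     sampler = default_sampler())
    .fx$tiny_seg <- list(
      model = train_segmenter(phantoms,
                              seg_train_config(input_size = 64, c1 = 4L,
                                               c2 = 8L, epochs = 2,
                                               seed = 7)),
      phantoms = phantoms, scale = scale)
  }
  .fx$tiny_seg
}

# Five end-to-end pipeline runs under the default small configuration.
fx_pipeline_runs <- function() {
  if (is.null(.fx$pipe_runs)) {
    .fx$pipe_runs <- lapply(1:5, function(sd) {
      suppressMessages(run_pipeline(pipeline_config(seed = sd)))
    })
  }
  .fx$pipe_runs
}

mean_dice <- function(model, phantoms, tta = FALSE,
                      shift = NULL) {
  vals <- vapply(phantoms, function(ph) {
    img <- ph$image
    if (!is.null(shift)) img <- apply_domain_shift(img, shift)
    pm <- predict_masks(model, img, tta = tta)
    mean(vapply(c("shortbones", "carpals", "wrist"), function(s) {
      dice_coef(pm[[s]], ph$masks[[s]])
    }, numeric(1)))
  }, numeric(1))
  mean(vals)
}

resize_to <- function(img, size) sgpAge:::resize_image(img, size)
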