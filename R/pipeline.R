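#' End-to-end pipeline configuration
#'
#' Settings for [run_pipeline()], the scaled-down analogue of the full
#' segmental workflow: simulate a source cohort and a domain-shifted target
#' cohort of phantoms, train the segmenter on the source, segment the target
#' with test-time adaptation, train base age regressors on the source,
#' fine-tune their heads on the target training split, build prediction
#' tables on the target validation split, fit the fusion weight per sex and
#' evaluate everything.
#'
#' @param seed Root seed; every stage derives a named substream from it.
#' @param sexes Character vector, subset of `c("male", "female")`.
#' @param scale_file Optional GP grid CSV; default the shipped grid.
#' @param image_size Phantom side in pixels.
#' @param n_source_train Source-cohort phantoms per sex (base training).
#' @param n_target Target-cohort phantoms per sex, split by `target_split`.
#' @param target_split Named fractions `c(train = ..., val = ...)`; must sum
#'   to 1.
#' @param offset_sd Sd (months) of the per-segment age offsets.
#' @param noise_sd Phantom intensity noise sd.
#' @param shift A [shift_params()] applied to every target image.
#' @param seg_config A [seg_train_config()] (its seed is overridden by the
#'   stage substream).
#' @param reg_config A [reg_train_config()] (ditto).
#' @param refine A [refine_config()]; the default keeps several components
#'   for multi-bone segments.
#' @param grid_step Fusion sweep resolution.
#' @param fit_split `"validation"` (default) or `"train"` — which target
#'   split the fusion weight is fitted on.
#' @param out_dir Optional output directory for artifacts and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sexes = c("male", "female"),
                            scale_file = NULL,
                            image_size = 64L,
                            n_source_train = 40L,
                            n_target = 64L,
                            target_split = c(train = 0.5, val = 0.5),
                            offset_sd = 6,
                            noise_sd = 0.02,
                            shift = shift_params(gain = 0.4, offset = 0.5),
                            seg_config = seg_train_config(input_size = 64L,
                                                          epochs = 8L),
                            reg_config = reg_train_config(input_size = 48L,
                                                          epochs = 20L),
                            refine = refine_config(
                              morph_open_radius = 1L, morph_close_radius = 1L,
                              keep_top_k = c(shortbones = 20, carpals = 10,
                                             wrist = 4)),
                            grid_step = 0.01,
                            fit_split = c("validation", "train"),
                            out_dir = NULL) {
  fit_split <- match.arg(fit_split)
  stopifnot(all(sexes %in% c("male", "female")), length(sexes) >= 1)
  if (abs(sum(target_split) - 1) > 1e-9) {
    stop_sgp("config_error", "target_split fractions must sum to 1")
  }
  if (!is.null(scale_file) && !file.exists(scale_file)) {
    stop_sgp("config_error", sprintf("scale_file not found: %s", scale_file))
  }
  structure(list(seed = as.integer(seed), sexes = sexes,
                 scale_file = scale_file,
                 image_size = as.integer(image_size),
                 n_source_train = as.integer(n_source_train),
                 n_target = as.integer(n_target),
                 target_split = target_split,
                 offset_sd = offset_sd, noise_sd = noise_sd, shift = shift,
                 seg_config = seg_config, reg_config = reg_config,
                 refine = refine, grid_step = grid_step,
                 fit_split = fit_split, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_scale <- function(cfg, sex) {
  if (is.null(cfg$scale_file)) default_gp_scale(sex)
  else load_gp_scale(cfg$scale_file, sex)
}

# Crop one sample's segments to regressor input size, preferring refined
# predicted masks, falling back to the raw prediction and finally to the
# whole image if a segment vanished.
segment_crops <- function(image, masks_pred, refine_cfg, out_size) {
  refined <- suppressWarnings(refine_masks(masks_pred, image, refine_cfg))
  fallbacks <- 0L
  full <- matrix(TRUE, nrow(image), ncol(image))
  ms <- list()
  for (s in segment_names()) {
    m <- refined[[s]]
    if (!any(m)) m <- masks_pred[[s]] > 0
    if (!any(m)) { m <- full; fallbacks <- fallbacks + 1L }
    ms[[s]] <- m
  }
  crops <- crop_segments(image, structure(ms, class = "mask_set"),
                         out_size = out_size)
  list(crops = crops, fallbacks = fallbacks)
}

crop_sample <- function(sample, crop, target) {
  structure(list(image = crop, sex = sample$sex, y = sample$y,
                 segment_ages = sample$segment_ages, masks = NULL,
                 id = paste0(sample$id, "_", target)),
            class = "radiograph_sample")
}

#' Run the end-to-end segmental pipeline
#'
#' Executes simulate, segment (with test-time adaptation on the shifted
#' target cohort), train, fine-tune, predict, fuse and evaluate, and returns
#' a run manifest. Fully reproducible from `(config, seed)`: all randomness
#' flows from the root seed through named per-stage substreams. If
#' `cfg$out_dir` is set, model checkpoints, prediction tables, reports and
#' the manifest JSON are written there; on a stage failure the partial
#' manifest is persisted before the error (carrying the stage name)
#' propagates.
#'
#' @param cfg A [pipeline_config()].
#' @return The run manifest: a list with the echoed config, per-sex fusion
#'   weights, agreement reports (`fullhand`, `shortbones`, `carpals`,
#'   `wrist`, `sgp` per sex), prediction tables, and artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(config = unclass_config(cfg), seed = cfg$seed,
                   stages = character(0), sexes = list())
  persist <- function() {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest_to_json(manifest),
                           file.path(cfg$out_dir, "run_manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest$stages <<- c(manifest$stages, paste0(name, ":FAILED"))
      persist()
      stop_sgp("stage_error",
               sprintf("pipeline stage `%s` failed: %s", name,
                       conditionMessage(e)))
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  log_line <- function(...) {
    message(sprintf("[sgpAge %5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(...)))
  }

  scales <- lapply(cfg$sexes, function(sx) pipeline_scale(cfg, sx))
  names(scales) <- cfg$sexes
  smp <- list(image_size = cfg$image_size, offset_sd = cfg$offset_sd,
              noise_sd = cfg$noise_sd)

  ## simulate: source and target cohorts per sex
  cohorts <- stage("simulate", {
    lapply(cfg$sexes, function(sx) {
      src <- simulate_phantom_set(cfg$n_source_train, scales[[sx]],
                                  seed = substream(cfg$seed,
                                                   paste0("src_", sx)),
                                  sampler = smp)
      tgt <- simulate_phantom_set(cfg$n_target, scales[[sx]],
                                  seed = substream(cfg$seed,
                                                   paste0("tgt_", sx)),
                                  sampler = smp)
      tgt <- lapply(tgt, function(ph) {
        ph$image <- apply_domain_shift(ph$image, cfg$shift)
        ph
      })
      n_tr <- round(cfg$target_split[["train"]] * cfg$n_target)
      list(source = src, target_train = tgt[seq_len(n_tr)],
           target_val = tgt[(n_tr + 1L):cfg$n_target])
    })
  })
  names(cohorts) <- cfg$sexes
  log_line("simulated %d source + %d target phantoms per sex",
           cfg$n_source_train, cfg$n_target)

  ## segmenter on pooled source images (masks are sex-agnostic geometry)
  segmenter <- stage("train_segmenter", {
    sc <- cfg$seg_config
    sc$seed <- substream(cfg$seed, "segmenter")
    train_segmenter(unlist(lapply(cohorts, `[[`, "source"),
                           recursive = FALSE), sc)
  })
  log_line("segmenter trained (final loss %.4f)",
           utils::tail(segmenter$loss_history, 1))

  reg_size <- cfg$reg_config$input_size
  crop_target <- function(samples) {
    fb <- 0L
    out <- lapply(samples, function(ph) {
      img <- resize_image(ph$image, segmenter$config$input_size)
      pm <- predict_masks(segmenter, img, tta = TRUE)
      sc <- segment_crops(img, pm, cfg$refine, reg_size)
      fb <<- fb + sc$fallbacks
      sc$crops
    })
    list(crops = out, fallbacks = fb)
  }

  results <- list()
  for (sx in cfg$sexes) {
    co <- cohorts[[sx]]
    scale <- scales[[sx]]

    tgt_tr_crops <- stage(paste0("segment_target_train_", sx),
                          crop_target(co$target_train))
    tgt_val_crops <- stage(paste0("segment_target_val_", sx),
                           crop_target(co$target_val))
    log_line("%s: target segmented (%d + %d whole-image fallbacks)", sx,
             tgt_tr_crops$fallbacks, tgt_val_crops$fallbacks)

    ## base models on the source cohort (ground-truth masks for crops)
    models <- list()
    for (target in c("fullhand", segment_names())) {
      rc <- cfg$reg_config
      rc$seed <- substream(cfg$seed, paste0("base_", target, "_", sx))
      train_set <- if (target == "fullhand") {
        co$source
      } else {
        lapply(co$source, function(ph) {
          crop <- crop_segments(ph$image, ph$masks, out_size = reg_size)
          crop_sample(ph, crop[[target]], target)
        })
      }
      models[[target]] <- stage(paste0("train_base_", target, "_", sx),
                                train_base(train_set, target, rc))
    }
    log_line("%s: base models trained", sx)

    ## fine-tune heads on the target training split
    tuned <- list()
    for (target in c("fullhand", segment_names())) {
      ft_set <- lapply(seq_along(co$target_train), function(i) {
        ph <- co$target_train[[i]]
        if (target == "fullhand") {
          ph$image <- resize_image(ph$image, reg_size)
          ph
        } else {
          crop_sample(ph, tgt_tr_crops$crops[[i]][[target]], target)
        }
      })
      tuned[[target]] <- stage(paste0("fine_tune_", target, "_", sx),
                               fine_tune_head(models[[target]], ft_set))
    }
    log_line("%s: heads fine-tuned", sx)

    ## prediction tables on both target splits
    build_table <- function(samples, crops) {
      fh_imgs <- lapply(samples, function(ph) resize_image(ph$image, reg_size))
      fh <- predict_age(tuned$fullhand, fh_imgs)
      segp <- lapply(segment_names(), function(s) {
        predict_age(tuned[[s]], lapply(crops$crops, `[[`, s))
      })
      df <- data.frame(
        id = vapply(samples, `[[`, character(1), "id"),
        sex = sx, fh = fh,
        seg_shortbones = segp[[1]], seg_carpals = segp[[2]],
        seg_wrist = segp[[3]],
        stringsAsFactors = FALSE)
      df$seg_avg <- rowMeans(df[seg_cols()])
      df$y <- vapply(samples, function(ph) as.numeric(ph$y), numeric(1))
      df
    }
    tab_train <- stage(paste0("predict_train_", sx),
                       build_table(co$target_train, tgt_tr_crops))
    tab_val <- stage(paste0("predict_val_", sx),
                     build_table(co$target_val, tgt_val_crops))

    fit_tab <- if (cfg$fit_split == "validation") tab_val else tab_train
    fus <- stage(paste0("fit_alpha_", sx),
                 fit_alpha(fit_tab, scale, cfg$grid_step))
    sgp <- stage(paste0("sgp_", sx), sgp_predict(tab_val, fus))
    log_line("%s: alpha* = %.2f", sx, fus$alpha_star)

    reports <- stage(paste0("evaluate_", sx), {
      rep <- list(
        fullhand = evaluate_agreement(tab_val$fh, tab_val$y, scale),
        sgp = evaluate_agreement(sgp, tab_val$y, scale, snap_pred = TRUE))
      for (s in segment_names()) {
        seg_truth <- vapply(co$target_val, function(ph) {
          as.numeric(ph$segment_ages[[s]])
        }, numeric(1))
        rep[[s]] <- evaluate_agreement(tab_val[[paste0("seg_", s)]],
                                       seg_truth, scale)
      }
      rep
    })
    log_line("%s: MAD fullhand %.2f | sgp %.2f", sx,
             reports$fullhand$mad, reports$sgp$mad)

    paths <- list()
    if (!is.null(cfg$out_dir)) {
      dir.create(file.path(cfg$out_dir, sx), recursive = TRUE,
                 showWarnings = FALSE)
      pth <- function(...) file.path(cfg$out_dir, sx, ...)
      for (target in names(tuned)) {
        save_regressor(models[[target]], pth(paste0("base_", target, ".rds")))
        save_regressor(tuned[[target]], pth(paste0("tuned_", target, ".rds")))
      }
      save_fusion_model(fus, pth("fusion.json"))
      write_prediction_table(tab_train, pth("predictions_train.csv"))
      write_prediction_table(tab_val, pth("predictions_val.csv"))
      jsonlite::write_json(lapply(reports, report_to_list),
                           pth("reports.json"), auto_unbox = TRUE,
                           digits = NA)
      paths <- list(dir = pth(""))
    }

    results[[sx]] <- list(
      alpha_star = fus$alpha_star, fusion = fus, models = tuned,
      base_models = models, table_train = tab_train, table_val = tab_val,
      reports = reports,
      fallbacks = tgt_tr_crops$fallbacks + tgt_val_crops$fallbacks,
      paths = paths)
    manifest$sexes[[sx]] <- list(
      alpha_star = fus$alpha_star,
      n_models = length(tuned), n_reports = length(reports),
      mad = lapply(reports, `[[`, "mad"), paths = paths)
  }

  if (!is.null(cfg$out_dir)) {
    save_segmenter(segmenter, file.path(cfg$out_dir, "segmenter.rds"))
  }
  manifest$segmenter_final_loss <- utils::tail(segmenter$loss_history, 1)
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$results <- results
  manifest$segmenter <- segmenter
  persist()
  class(manifest) <- "sgp_run_manifest"
  manifest
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$shift <- unclass(out$shift)
  out$seg_config <- unclass(out$seg_config)
  out$reg_config <- unclass(out$reg_config)
  out$refine <- unclass(out$refine)
  out
}

# JSON-safe view of the manifest (drops in-memory model objects).
manifest_to_json <- function(manifest) {
  list(config = manifest$config, seed = manifest$seed,
       stages = manifest$stages, sexes = manifest$sexes,
       segmenter_final_loss = manifest$segmenter_final_loss,
       elapsed_s = manifest$elapsed_s)
}

#' @export
print.sgp_run_manifest <- function(x, ...) {
  cat(sprintf("<sgp_run_manifest> seed %d, %d stages, %.1fs\n",
              x$seed, length(x$stages), x$elapsed_s %||% NA_real_))
  for (sx in names(x$sexes)) {
    cat(sprintf("  %s: alpha* = %.2f, MAD fullhand %.2f / sgp %.2f\n", sx,
                x$sexes[[sx]]$alpha_star, x$sexes[[sx]]$mad$fullhand,
                x$sexes[[sx]]$mad$sgp))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
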