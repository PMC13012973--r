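#' Convex combination of segment-average and full-hand ages
#'
#' `C = alpha * seg_avg + (1 - alpha) * fh`; the combined age always lies
#' between the two inputs and is affine in both.
#'
#' @param fh Full-hand prediction(s), months.
#' @param seg_avg Segment-average prediction(s), months.
#' @param alpha Weight in `[0, 1]` on the segment average.
#' @return Combined continuous age(s) in months.
#' @examples
#' combine_ages(100, 110, 0.5)
#' @export
combine_ages <- function(fh, seg_avg, alpha) {
  check_number(alpha, "alpha", min = 0, max = 1)
  if (!is.numeric(fh) || !is.numeric(seg_avg) ||
      length(fh) != length(seg_avg)) {
    stop_sgp("invalid_input", "fh and seg_avg must be numeric, equal length")
  }
  alpha * seg_avg + (1 - alpha) * fh
}

seg_cols <- function() paste0("seg_", segment_names())

validate_records <- function(records, scale = NULL, require_y = TRUE) {
  needed <- c("fh", seg_cols(), if (require_y) "y")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop_sgp("schema_error",
             sprintf("prediction table missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0L) {
    stop_sgp("data_error", "prediction table is empty")
  }
  if ("sex" %in% names(records) && length(unique(records$sex)) > 1L) {
    stop_sgp("data_error", "prediction table mixes sexes")
  }
  sa <- rowMeans(records[seg_cols()])
  if (!is.null(records$seg_avg) &&
      max(abs(records$seg_avg - sa)) > 1e-6) {
    stop_sgp("consistency_error",
             "stored seg_avg disagrees with the mean of the segment columns")
  }
  records$seg_avg <- sa
  if (require_y && !is.null(scale)) {
    gp_class_index(records$y, scale)  # errors if y is off the grid
  }
  records
}

# Sweep loss: sum over records of (snap(C(alpha)) - y)^2.
sweep_loss <- function(records, scale, alphas) {
  fh <- records$fh
  d <- records$seg_avg - fh
  y <- records$y
  vapply(alphas, function(a) {
    sum((snap_to_gp(fh + a * d, scale) - y)^2)
  }, numeric(1))
}

#' Fit the segmental fusion weight by grid sweep
#'
#' Sweeps `alpha` over `{0, grid_step, ..., 1}`; for each candidate the
#' convex combination of each record is snapped to the nearest GP class and
#' the summed squared error against the GP ground truth `y` accumulated. The
#' weight with minimal loss is returned, ties broken toward the smallest
#' `alpha` (the snapped loss is piecewise constant, so plateaus are common).
#' The full loss curve is retained for optimization-landscape plots.
#'
#' @param records Prediction table (data frame with `fh`, the three
#'   `seg_*` columns, `y`, and optionally `sex`/`seg_avg`), single sex.
#' @param scale The [gp_scale()] for that sex.
#' @param grid_step Sweep resolution (default 0.01).
#' @return A `fusion_model`: list with `sex`, `alpha_star`, `grid_step`,
#'   `scale`, and `loss_curve` (data frame of `alpha`, `sse`).
#' @export
fit_alpha <- function(records, scale, grid_step = 0.01) {
  check_scale(scale)
  check_number(grid_step, "grid_step", min = 1e-6, max = 1)
  if ("sex" %in% names(records) && nrow(records) > 0 &&
      !all(records$sex == scale$sex)) {
    stop_sgp("data_error", "records' sex does not match the scale's sex")
  }
  records <- validate_records(records, scale)
  n_steps <- as.integer(round(1 / grid_step))
  alphas <- pmin(1, (0:n_steps) * grid_step)
  alphas[n_steps + 1L] <- 1
  sse <- sweep_loss(records, scale, alphas)
  best <- which.min(sse)  # first minimum = smallest alpha on ties
  structure(list(sex = scale$sex, alpha_star = alphas[best],
                 grid_step = grid_step, scale = scale,
                 loss_curve = data.frame(alpha = alphas, sse = sse)),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s: alpha* = %.2f (%d-point sweep, min SSE %.1f)\n",
              x$sex, x$alpha_star, nrow(x$loss_curve),
              min(x$loss_curve$sse)))
  invisible(x)
}

#' Segmental Greulich-Pyle prediction
#'
#' Applies a fitted fusion model: each record's convex combination at
#' `alpha_star` is snapped to the nearest GP class. The output is always a
#' member of the model's GP grid.
#'
#' @param records Prediction table (same schema as [fit_alpha()]; `y` not
#'   required).
#' @param model A fitted `fusion_model`.
#' @return Numeric vector of SGP ages in months.
#' @export
sgp_predict <- function(records, model) {
  stopifnot(inherits(model, "fusion_model"))
  records <- validate_records(records, require_y = FALSE)
  if ("sex" %in% names(records) && records$sex[1] != model$sex) {
    stop_sgp("data_error", "records' sex does not match the fusion model")
  }
  snap_to_gp(combine_ages(records$fh, records$seg_avg, model$alpha_star),
             model$scale)
}

#' Save / load a fusion model as JSON
#'
#' @param model A `fusion_model`.
#' @param path JSON file path.
#' @return `save_fusion_model` returns `path` invisibly; `load_fusion_model`
#'   returns the model (the GP scale is reconstructed from the stored grid).
#' @export
save_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  obj <- list(sex = model$sex, alpha_star = model$alpha_star,
              grid_step = model$grid_step,
              scale_name = model$scale$name,
              scale_classes = model$scale$classes,
              loss_curve = model$loss_curve)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fusion_model
#' @export
load_fusion_model <- function(path) {
  if (!file.exists(path)) {
    stop_sgp("io_error", sprintf("fusion model not found: %s", path))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sex = obj$sex, alpha_star = obj$alpha_star,
                 grid_step = obj$grid_step,
                 scale = gp_scale(obj$scale_classes, obj$sex,
                                  name = obj$scale_name),
                 loss_curve = as.data.frame(obj$loss_curve)),
            class = "fusion_model")
}
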