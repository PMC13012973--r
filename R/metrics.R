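check_paired <- function(pred, truth, min_n = 1L) {
  if (!is.numeric(pred) || !is.numeric(truth) ||
      length(pred) != length(truth)) {
    stop_sgp("invalid_input", "pred and truth must be numeric, equal length")
  }
  if (length(pred) < min_n) {
    stop_sgp("invalid_input", sprintf("need at least %d pairs", min_n))
  }
  invisible(length(pred))
}

#' Mean absolute difference (MAD) in months
#'
#' The standard bone-age accuracy metric: the mean of `|pred - truth|`.
#'
#' @param pred,truth Numeric vectors of equal non-zero length (months).
#' @return MAD in months.
#' @examples
#' age_mad(c(10, 14), c(12, 12))
#' @export
age_mad <- function(pred, truth) {
  check_paired(pred, truth)
  mean(abs(pred - truth))
}

#' Root mean squared error in months
#'
#' @inheritParams age_mad
#' @return RMSE in months (always >= the MAD).
#' @export
age_rmse <- function(pred, truth) {
  check_paired(pred, truth)
  sqrt(mean((pred - truth)^2))
}

#' Squared Pearson correlation
#'
#' The r-squared reported from correlation plots: the square of the Pearson
#' correlation coefficient between predictions and reference ages. Note this
#' is not the regression coefficient of determination — the two differ for
#' biased predictors.
#'
#' @inheritParams age_mad
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(pred, truth) {
  check_paired(pred, truth, min_n = 2L)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop_sgp("undefined_statistic",
             "r_squared undefined: zero variance in pred or truth")
  }
  stats::cor(pred, truth)^2
}

#' Bland-Altman agreement analysis
#'
#' Differences are `pred - truth` (a positive bias means overprediction —
#' this sign convention is the package's and is stated here because prose
#' conventions vary). Bias is the mean difference; limits of agreement are
#' `bias +/- k_sd * sd` with the sample (n-1) standard deviation. Records
#' with differences strictly outside the limits are flagged as high-error
#' cases.
#'
#' @inheritParams age_mad
#' @param k_sd Width of the limits in standard deviations (default 2).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, and
#'   `high_error_ids` (integer indices of flagged records).
#' @export
bland_altman <- function(pred, truth, k_sd = 2) {
  check_paired(pred, truth, min_n = 2L)
  check_number(k_sd, "k_sd", min = 0)
  d <- pred - truth
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - k_sd * s
  loa_high <- bias + k_sd * s
  list(bias = bias, sd = s, loa_low = loa_low, loa_high = loa_high,
       high_error_ids = which(d < loa_low | d > loa_high))
}

#' Quadratic-weighted Cohen's kappa over GP classes
#'
#' Chance-corrected agreement for ordered categories. Weights are computed
#' over class *indices* in the ordered GP grid (so unequal class spacing in
#' months does not distort penalties): the disagreement weight between
#' classes `i` and `j` is `((i - j) / (K - 1))^2` with `K` the grid size.
#' `kappa = 1 - sum(w * O) / sum(w * E)` with observed (`O`) and
#' marginal-product expected (`E`) proportion matrices.
#'
#' @param a,b Vectors of GP ages (months); every entry must be a member of
#'   the grid.
#' @param scale A [gp_scale()].
#' @param weighting Only `"quadratic"` is implemented.
#' @return Kappa in `[-1, 1]`; 1 iff perfect agreement.
#' @export
weighted_kappa <- function(a, b, scale, weighting = c("quadratic")) {
  weighting <- match.arg(weighting)
  check_scale(scale)
  check_paired(a, b)
  ia <- gp_class_index(a, scale)
  ib <- gp_class_index(b, scale)
  K <- length(scale$classes)
  if (K < 2) stop_sgp("invalid_input", "kappa needs at least 2 classes")
  O <- table(factor(ia, levels = seq_len(K)),
             factor(ib, levels = seq_len(K))) / length(ia)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(K)
  W <- outer(idx, idx, function(i, j) ((i - j) / (K - 1))^2)
  den <- sum(W * E)
  if (den == 0) {
    # all mass in one class for both raters: perfect if identical
    return(if (all(ia == ib)) 1 else 0)
  }
  1 - sum(W * O) / den
}

#' Agreement within k GP classes
#'
#' Percentage of pairs whose grid-index distance is at most `k`; `k = 0`
#' gives exact agreement.
#'
#' @inheritParams weighted_kappa
#' @param k Maximum class distance counted as agreement.
#' @return Percentage in `[0, 100]`.
#' @export
class_agreement <- function(a, b, scale, k = 0L) {
  check_scale(scale)
  check_paired(a, b)
  check_number(k, "k", min = 0)
  ia <- gp_class_index(a, scale)
  ib <- gp_class_index(b, scale)
  100 * mean(abs(ia - ib) <= k)
}

#' Full agreement report
#'
#' Bundles the evaluation suite: MAD, RMSE and r-squared on the (optionally
#' GP-snapped) predictions, Bland-Altman bias/limits with high-error
#' flagging, and the ordinal statistics (quadratic-weighted kappa, exact and
#' within-1-class agreement) which are always computed on GP-snapped
#' predictions against GP ground truth.
#'
#' @param pred Continuous predictions in months.
#' @param truth GP ground-truth ages (members of the grid).
#' @param scale A [gp_scale()].
#' @param snap_pred If `TRUE`, snap predictions to the grid before computing
#'   the continuous metrics too (as for SGP output, which is already
#'   discrete); if `FALSE` MAD/RMSE/r2/Bland-Altman use the raw predictions.
#' @param k_sd Bland-Altman limit width.
#' @return An `agreement_report` list with fields `n`, `mad`, `rmse`, `r2`,
#'   `r2_snapped`, `bias`, `loa_low`, `loa_high`, `high_error_ids`, `kappa`,
#'   `pct_exact`, `pct_within_1`.
#' @export
evaluate_agreement <- function(pred, truth, scale, snap_pred = FALSE,
                               k_sd = 2) {
  check_scale(scale)
  check_paired(pred, truth, min_n = 2L)
  check_flag(snap_pred, "snap_pred")
  snapped <- snap_to_gp(pred, scale)
  p <- if (snap_pred) snapped else pred
  ba <- bland_altman(p, truth, k_sd = k_sd)
  r2s <- tryCatch(r_squared(snapped, truth), sgpAge_error = function(e) NA_real_)
  structure(list(
    n = length(pred),
    mad = age_mad(p, truth),
    rmse = age_rmse(p, truth),
    r2 = r_squared(p, truth),
    r2_snapped = r2s,
    bias = ba$bias,
    loa_low = ba$loa_low,
    loa_high = ba$loa_high,
    high_error_ids = ba$high_error_ids,
    kappa = weighted_kappa(snapped, truth, scale),
    pct_exact = class_agreement(snapped, truth, scale, k = 0),
    pct_within_1 = class_agreement(snapped, truth, scale, k = 1)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> n=%d\n",
    "  MAD %.2f mo | RMSE %.2f mo | r2 %.3f\n",
    "  bias %+.2f mo (LoA %.2f .. %.2f, %d high-error)\n",
    "  kappa %.3f | exact %.1f%% | within +/-1 class %.1f%%\n"),
    x$n, x$mad, x$rmse, x$r2, x$bias, x$loa_low, x$loa_high,
    length(x$high_error_ids), x$kappa, x$pct_exact, x$pct_within_1))
  invisible(x)
}

report_to_list <- function(r) {
  out <- unclass(r)
  out$high_error_ids <- as.integer(out$high_error_ids)
  out
}
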