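#' Greulich-Pyle age grid
#'
#' A `gp_scale` holds the ordered set of discrete Greulich-Pyle (GP) atlas
#' ages, in months, for one sex. Continuous age estimates are reported
#' clinically as the nearest member of this grid; [snap_to_gp()] performs that
#' mapping. The package ships an editable illustrative grid (see
#' [default_gp_scale()]); it is not the published clinical atlas.
#'
#' @param classes Strictly increasing numeric vector of ages in months; all
#'   values must be positive and at most 300.
#' @param sex `"male"` or `"female"`.
#' @param name Free-text provenance label for the grid.
#'
#' @return An object of class `gp_scale` with fields `classes`, `sex`, `name`.
#' @examples
#' sc <- gp_scale(c(96, 108, 126), "male")
#' snap_to_gp(110, sc)
#' @export
gp_scale <- function(classes, sex = c("male", "female"), name = "unnamed") {
  sex <- match.arg(sex)
  if (!is.numeric(classes) || length(classes) == 0L || anyNA(classes)) {
    stop_sgp("validation_error", "GP grid must be a non-empty numeric vector")
  }
  classes <- as.numeric(classes)
  if (any(diff(classes) <= 0)) {
    stop_sgp("validation_error", "GP grid must be strictly increasing")
  }
  if (any(classes <= 0) || any(classes > 300)) {
    stop_sgp("validation_error", "GP grid ages must lie in (0, 300] months")
  }
  structure(list(classes = classes, sex = sex, name = name),
            class = "gp_scale")
}

#' @export
print.gp_scale <- function(x, ...) {
  cat(sprintf("<gp_scale> %s (%s): %d classes, %g-%g months\n",
              x$name, x$sex, length(x$classes), min(x$classes), max(x$classes)))
  invisible(x)
}

is_gp_scale <- function(x) inherits(x, "gp_scale")

check_scale <- function(scale) {
  if (!is_gp_scale(scale)) {
    stop_sgp("invalid_input", "`scale` must be a gp_scale object")
  }
  invisible(scale)
}

#' Snap continuous ages to the nearest GP class
#'
#' Maps each continuous age estimate to the closest member of the GP grid,
#' `argmin over g in G of |value - g|`. Exact midpoint ties are broken toward
#' the *lower* (younger) class, a conservative choice. Snapping is idempotent
#' on grid members and its output always lies in `[min(G), max(G)]`.
#'
#' @param value Numeric vector of ages in months; must be finite.
#' @param scale A [gp_scale()].
#' @return Numeric vector of the same length, every element a member of
#'   `scale$classes`.
#' @examples
#' sc <- gp_scale(c(96, 108, 126), "male")
#' snap_to_gp(c(110, 126, 90), sc)
#' @export
snap_to_gp <- function(value, scale) {
  check_scale(scale)
  if (!is.numeric(value) || length(value) == 0L || !all(is.finite(value))) {
    stop_sgp("invalid_input", "`value` must be finite numeric")
  }
  g <- scale$classes
  k <- length(g)
  if (k == 1L) return(rep(g, length(value)))
  # index of the largest class <= value (0 if below the grid)
  lo <- findInterval(value, g)
  lo[lo == 0L] <- 1L
  lo[lo == k] <- k - 1L
  d_lo <- value - g[lo]
  d_hi <- g[lo + 1L] - value
  # tie (d_lo == d_hi) goes to the lower class
  ifelse(d_hi < d_lo, g[lo + 1L], g[lo])
}

# Grid index (1-based) of each age; errors if an age is not on the grid.
gp_class_index <- function(value, scale) {
  check_scale(scale)
  idx <- match(round(value, 9), round(scale$classes, 9))
  if (anyNA(idx)) {
    stop_sgp("invalid_input",
             sprintf("age(s) not on the GP grid: %s",
                     paste(utils::head(value[is.na(idx)], 3), collapse = ", ")))
  }
  idx
}

#' Load a GP grid from a CSV file
#'
#' The file must have a header `sex,age_months` with one row per class; rows
#' for both sexes may share a file.
#'
#' @param path Path to the CSV file.
#' @param sex Which sex's grid to extract.
#' @param name Provenance label; defaults to the file name.
#' @return A [gp_scale()].
#' @export
load_gp_scale <- function(path, sex = c("male", "female"), name = NULL) {
  sex <- match.arg(sex)
  if (!file.exists(path)) {
    stop_sgp("config_error", sprintf("GP grid file not found: %s", path))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_sgp("config_error",
                            sprintf("cannot read GP grid file %s: %s",
                                    path, conditionMessage(e)))
                 })
  if (!all(c("sex", "age_months") %in% names(df))) {
    stop_sgp("config_error",
             "GP grid file must have columns `sex` and `age_months`")
  }
  ages <- df$age_months[df$sex == sex]
  if (length(ages) == 0L) {
    stop_sgp("config_error",
             sprintf("GP grid file has no rows for sex `%s`", sex))
  }
  gp_scale(ages, sex, name = if (is.null(name)) basename(path) else name)
}

#' Built-in illustrative GP grid
#'
#' Returns the grid shipped in `inst/extdata/gp_grid_default.csv`. The values
#' are an illustrative, editable stand-in spanning infancy to skeletal
#' maturity with the denser spacing around puberty typical of atlas
#' standards; they are *not* the published clinical atlas ages.
#'
#' @param sex `"male"` or `"female"`.
#' @return A [gp_scale()].
#' @export
default_gp_scale <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", "gp_grid_default.csv", package = "sgpAge",
                      mustWork = TRUE)
  load_gp_scale(path, sex, name = "illustrative-default")
}
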