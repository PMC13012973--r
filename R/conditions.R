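# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish configuration/schema problems from data and numerical errors.

stop_sgp <- function(class, msg, call. = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("sgpAge_", class), "sgpAge_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

warn_sgp <- function(class, msg) {
  cond <- structure(
    class = c(paste0("sgpAge_", class), "sgpAge_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_sgp("invalid_input", sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_sgp("invalid_input", sprintf("`%s` must be a single finite number", name))
  }
  if (x < min || x > max) {
    stop_sgp("invalid_input",
             sprintf("`%s` must be in [%g, %g], got %g", name, min, max, x))
  }
  invisible(x)
}

# Clamp values to [0, 1] preserving dim attributes.
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
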