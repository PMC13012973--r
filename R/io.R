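#' Read and write prediction tables
#'
#' The prediction-table CSV schema is
#' `id,sex,fh,seg_shortbones,seg_carpals,seg_wrist,seg_avg,y`
#' (`seg_avg` and `y` optional on read; unknown columns are preserved).
#' `seg_avg` is recomputed on read and, when present in the file, checked
#' against the stored values to 1e-6. Numeric columns are written with six
#' decimals, so a write/read round trip is lossless at that precision.
#'
#' @param path CSV file path.
#' @return `read_prediction_table` returns the validated data frame.
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) {
    stop_sgp("io_error", sprintf("prediction table not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "sex", "fh", seg_cols())
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop_sgp("schema_error",
             sprintf("prediction table missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  sa <- rowMeans(df[seg_cols()])
  if ("seg_avg" %in% names(df)) {
    if (max(abs(df$seg_avg - sa)) > 1e-6) {
      stop_sgp("consistency_error",
               "stored seg_avg disagrees with the mean of the segment columns")
    }
  }
  df$seg_avg <- sa
  df
}

#' @param records Prediction table data frame.
#' @rdname read_prediction_table
#' @export
write_prediction_table <- function(records, path) {
  needed <- c("id", "sex", "fh", seg_cols())
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop_sgp("schema_error",
             sprintf("prediction table missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  out <- records
  if (is.null(out$seg_avg)) out$seg_avg <- rowMeans(out[seg_cols()])
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 6))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Import a DICOM file as an 8-bit grayscale matrix
#'
#' Convenience layer: windows the stored pixel data to `[0, 1]` by min-max
#' (or an explicit window) and returns a plain matrix suitable for the
#' pipeline, which otherwise speaks PNG + CSV only. Only uncompressed
#' little-endian single-frame grayscale DICOM is supported.
#'
#' @param path DICOM file path.
#' @param window Optional `c(low, high)` stored-value window.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_dicom_image <- function(path, window = NULL) {
  if (!file.exists(path)) {
    stop_sgp("io_error", sprintf("DICOM file not found: %s", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  if (length(hdr) < 132 || rawToChar(hdr[129:132]) != "DICM") {
    stop_sgp("io_error", "not a DICOM part-10 file")
  }
  rows <- cols <- bits <- NULL
  pixel <- NULL
  repeat {
    tag <- readBin(con, "integer", 2, size = 2, signed = FALSE,
                   endian = "little")
    if (length(tag) < 2) break
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    if (length(len) < 1 || is.na(len) || len < 0) break
    key <- sprintf("%04x,%04x", tag[1], tag[2])
    if (key == "0028,0010") {
      rows <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = "little")
    } else if (key == "0028,0011") {
      cols <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = "little")
    } else if (key == "0028,0100") {
      bits <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = "little")
    } else if (key == "7fe0,0010") {
      sz <- if (identical(bits, 8L)) 1L else 2L
      pixel <- readBin(con, "integer", len / sz, size = sz,
                       signed = FALSE, endian = "little")
      break
    } else {
      readBin(con, "raw", len)
    }
  }
  if (is.null(pixel) || is.null(rows) || is.null(cols)) {
    stop_sgp("io_error", "unsupported or truncated DICOM pixel data")
  }
  img <- matrix(pixel, nrow = rows, ncol = cols, byrow = TRUE)
  if (is.null(window)) window <- range(img)
  if (window[2] <= window[1]) window[2] <- window[1] + 1
  clip01((img - window[1]) / (window[2] - window[1]))
}
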