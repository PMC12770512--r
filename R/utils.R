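#' @importFrom rlang abort .data
#' @importFrom stats runif rnorm sd quantile
#' @importFrom utils head tail
NULL

# Single rounding convention for the whole pipeline: half away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

abort_config <- function(msg) abort(msg, class = "cytopipe_config_error")
abort_input <- function(msg) abort(msg, class = "cytopipe_input_error")
abort_data <- function(msg) abort(msg, class = "cytopipe_data_error")
abort_dependency <- function(msg) abort(msg, class = "cytopipe_dependency_error")
abort_stats <- function(msg) abort(msg, class = "cytopipe_stats_error")

#' Validate a grayscale image matrix
#'
#' A grayscale image is a plain numeric matrix of integer-valued intensities
#' in `[0, 255]` (rows = image rows, columns = image columns).
#'
#' @param img Object to validate.
#' @param arg Name used in error messages.
#' @return The image, invisibly.
#' @export
assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort_input(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    abort_input(sprintf("`%s` must be non-empty", arg))
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    abort_input(sprintf("`%s` must have intensities in [0, 255]", arg))
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_input(sprintf("`%s` must be a logical matrix", arg))
  }
  invisible(mask)
}

assert_same_shape <- function(...) {
  mats <- list(...)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L) {
    abort_input(sprintf("inputs must share one shape, got: %s",
                        paste(unique(dims), collapse = ", ")))
  }
  invisible(TRUE)
}

# Seed derivation: one global seed fans out to per-stage seeds deterministically.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}

#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' @param path PNG file path.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) {
    # drop alpha if present, then convert colour planes by luma weighting
    if (dim(p)[3] >= 3L) {
      return(to_grayscale(round_half_away(p[, , 1:3] * 255)))
    }
    p <- p[, , 1]
  }
  round_half_away(p * 255)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param img Grayscale image matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  assert_gray_image(img)
  ok <- tryCatch({
    png::writePNG(img / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_data(sprintf("failed to write PNG: %s", path))
  invisible(path)
}
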