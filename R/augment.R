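#' Augmentation configuration
#'
#' The seeded affine transform stack applied on-the-fly to training images
#' (never to validation or test images): rotation, per-axis translation,
#' shear, isotropic zoom, horizontal flipping, and the model-input rescale
#' to `[0, 1]`.
#'
#' @param rotation_range_deg Rotation sampled from
#'   `U(-rotation_range_deg, rotation_range_deg)` degrees (default 20).
#' @param width_shift_frac Horizontal shift sampled from
#'   `U(-f, f) * width` (default 0.3).
#' @param height_shift_frac Vertical shift sampled from `U(-f, f) * height`
#'   (default 0.3).
#' @param shear_range Shear-angle range in radians, sampled from
#'   `U(-s, s)` (default 0.2).
#' @param zoom_range Zoom `z` sampled from `U(1 - z, 1 + z)` (default 0.2).
#' @param horizontal_flip Allow mirroring with probability 1/2
#'   (default `TRUE`).
#' @param rescale Multiplicative model-input rescale (default `1/255`).
#' @param fill_mode Border policy for sampling outside the image; only
#'   `"nearest"` (edge replication) is provided.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation_range_deg = 20, width_shift_frac = 0.3,
                           height_shift_frac = 0.3, shear_range = 0.2,
                           zoom_range = 0.2, horizontal_flip = TRUE,
                           rescale = 1 / 255, fill_mode = "nearest") {
  vals <- c(rotation_range_deg, width_shift_frac, height_shift_frac,
            shear_range, zoom_range)
  if (any(vals < 0)) abort_config("augmentation ranges must be >= 0")
  if (rescale <= 0) abort_config("`rescale` must be positive")
  if (!identical(fill_mode, "nearest")) {
    abort_config("only fill_mode = 'nearest' is supported")
  }
  structure(list(rotation_range_deg = rotation_range_deg,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 shear_range = shear_range, zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 rescale = rescale, fill_mode = fill_mode),
            class = "augment_config")
}

#' Identity augmentation (no-op stack)
#' @return An [augment_config()] whose sampled transforms are always the
#'   identity.
#' @export
augment_identity <- function() {
  augment_config(rotation_range_deg = 0, width_shift_frac = 0,
                 height_shift_frac = 0, shear_range = 0, zoom_range = 0,
                 horizontal_flip = FALSE)
}

#' Sample one affine transform
#'
#' Draws rotation, shifts (per axis, independently), shear, zoom and flip
#' from the configured ranges using the current RNG state, and composes them
#' into a single affine map about the image centre.
#'
#' @param config An [augment_config()].
#' @param image_size `c(height, width)` the transform will be applied to.
#' @param seed Optional integer seed for a self-contained draw.
#' @return List of class `affine_params` with the sampled scalars and the
#'   forward 2x2 matrix `A` plus offset `b` (output = A %*% x + b, in
#'   (row, col) coordinates about the centre).
#' @export
sample_transform <- function(config = augment_config(), image_size = c(224, 224),
                             seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            sample_transform(config, image_size)))
  }
  h <- image_size[1]; w <- image_size[2]
  angle <- runif(1, -config$rotation_range_deg, config$rotation_range_deg)
  ty <- runif(1, -config$height_shift_frac, config$height_shift_frac) * h
  tx <- runif(1, -config$width_shift_frac, config$width_shift_frac) * w
  shear <- runif(1, -config$shear_range, config$shear_range)
  zoom <- runif(1, 1 - config$zoom_range, 1 + config$zoom_range)
  flip <- config$horizontal_flip && runif(1) < 0.5
  affine_params(angle, tx, ty, shear, zoom, flip)
}

#' Build affine parameters explicitly
#'
#' @param angle Rotation in degrees (counter-clockwise).
#' @param tx,ty Translation in pixels (columns, rows).
#' @param shear Shear angle in radians (horizontal shear).
#' @param zoom Isotropic scale factor.
#' @param flip Horizontal mirror flag.
#' @return List of class `affine_params`.
#' @export
affine_params <- function(angle = 0, tx = 0, ty = 0, shear = 0, zoom = 1,
                          flip = FALSE) {
  th <- angle * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # (row, col) basis
  shm <- matrix(c(1, 0, tan(shear), 1), 2)                   # col += tan(s)*row
  zm <- diag(c(zoom, zoom))
  fl <- diag(c(1, if (flip) -1 else 1))
  a <- rot %*% shm %*% zm %*% fl
  structure(list(angle = angle, tx = tx, ty = ty, shear = shear, zoom = zoom,
                 flip = flip, A = a, b = c(ty, tx)),
            class = "affine_params")
}

is_identity_transform <- function(params, tol = 1e-12) {
  max(abs(params$A - diag(2))) < tol && max(abs(params$b)) < tol
}

#' Apply an affine transform to a grayscale image
#'
#' Inverse-warps the output grid through the affine map about the image
#' centre and samples the input bilinearly; coordinates outside the image
#' replicate the nearest edge pixel (`fill_mode = "nearest"`). Output has
#' the input's shape.
#'
#' @param img Grayscale image matrix.
#' @param params An [affine_params()].
#' @return Transformed grayscale image matrix.
#' @export
apply_transform <- function(img, params) {
  assert_gray_image(img)
  if (!inherits(params, "affine_params")) {
    abort_input("`params` must be affine parameters from sample_transform()")
  }
  if (is_identity_transform(params)) return(img)
  d <- det(params$A)
  if (!is.finite(d) || abs(d) < 1e-12) {
    abort(sprintf("singular affine matrix (det = %g)", d),
          class = "cytopipe_transform_error")
  }
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a_inv <- solve(params$A)

  # output grid, centred coordinates
  ry <- seq_len(h) - cy
  rx <- seq_len(w) - cx
  yy <- matrix(ry, h, w)
  xx <- matrix(rx, h, w, byrow = TRUE)
  sy <- yy - params$b[1]
  sx <- xx - params$b[2]
  iy <- a_inv[1, 1] * sy + a_inv[1, 2] * sx + cy
  ix <- a_inv[2, 1] * sy + a_inv[2, 2] * sx + cx

  # bilinear sample with edge replication
  iy <- pmin(pmax(iy, 1), h)
  ix <- pmin(pmax(ix, 1), w)
  y0 <- floor(iy); x0 <- floor(ix)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- iy - y0; fx <- ix - x0
  at <- function(r, c) matrix(img[cbind(as.vector(r), as.vector(c))], h, w)
  out <- at(y0, x0) * (1 - fy) * (1 - fx) + at(y1, x0) * fy * (1 - fx) +
    at(y0, x1) * (1 - fy) * fx + at(y1, x1) * fy * fx
  clamp255(round_half_away(out))
}

#' Rescale intensities to the unit interval
#'
#' @param img Grayscale image matrix.
#' @return Real-valued matrix `img / 255` in `[0, 1]`.
#' @export
rescale_to_unit <- function(img) {
  assert_gray_image(img)
  img / 255
}
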