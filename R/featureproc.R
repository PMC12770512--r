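#' Feature-processing configuration
#'
#' Bundles the tunable parameters of the feature-processing stage: the dark
#' pre-mapping threshold, the minimum connected-component size retained after
#' foreground cleanup, whether background holes are filled (they are not, by
#' default: small bright structures inside cells are themselves features),
#' the midtone-lightening gain/offset, and the pixel connectivity used for
#' component labelling.
#'
#' @param dark_threshold Intensities at or below this value are pre-mapped to
#'   black and flagged (default 60).
#' @param min_object_px Foreground components smaller than this many pixels
#'   are removed; components exactly this size are kept (default 30).
#' @param fill_holes Whether to fill background holes inside foreground
#'   components (default `FALSE`).
#' @param alpha Midtone-lightening gain (default 1.3).
#' @param beta Midtone-lightening offset (default 0).
#' @param connectivity Pixel adjacency for labelling, 4 or 8 (default 8).
#' @param otsu_exclude_dark If `TRUE`, dark-flagged pixels are excluded from
#'   the Otsu histogram (sensitivity analysis); the default `FALSE` computes
#'   the histogram on the pre-mapped image, zeros included.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(dark_threshold = 60, min_object_px = 30,
                           fill_holes = FALSE, alpha = 1.3, beta = 0,
                           connectivity = 8, otsu_exclude_dark = FALSE) {
  if (dark_threshold < 0 || dark_threshold > 255) {
    abort_config("`dark_threshold` must be in [0, 255]")
  }
  if (min_object_px < 0) abort_config("`min_object_px` must be >= 0")
  if (alpha <= 0) abort_config("`alpha` must be positive")
  if (!connectivity %in% c(4, 8)) abort_config("`connectivity` must be 4 or 8")
  structure(list(dark_threshold = dark_threshold,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes),
                 alpha = alpha, beta = beta,
                 connectivity = as.integer(connectivity),
                 otsu_exclude_dark = isTRUE(otsu_exclude_dark)),
            class = "feature_config")
}

#' Pre-map dark pixels to black
#'
#' Pixels at or below the dark threshold are set to 0 and flagged as
#' potential fluid accumulations; all other pixels pass through unchanged.
#'
#' @param img Grayscale image matrix.
#' @param config A [feature_config()].
#' @return List with `image` (pre-mapped matrix) and `dark_mask` (logical
#'   matrix, `TRUE` exactly where a pixel was zeroed).
#' @export
premap_dark <- function(img, config = feature_config()) {
  assert_gray_image(img)
  dark <- img <= config$dark_threshold
  out <- img
  out[dark] <- 0
  list(image = out, dark_mask = dark)
}

#' Otsu threshold by exhaustive between-class variance maximisation
#'
#' Scans every candidate threshold `t` in 0..255, splitting pixels into the
#' classes `v <= t` and `v > t`, and returns the smallest `t` maximising the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2`. A single-valued image
#' returns that value by convention.
#'
#' @param img Grayscale image matrix.
#' @return List of class `otsu_result` with elements `threshold` (integer in
#'   0..255) and `curve` (between-class variance at each of the 256
#'   candidates).
#' @export
otsu_threshold <- function(img) {
  assert_gray_image(img)
  v <- as.vector(img)
  h <- tabulate(v + 1L, 256L)
  n <- sum(h)
  p <- h / n
  levels_present <- which(h > 0L) - 1L
  if (length(levels_present) == 1L) {
    return(structure(list(threshold = levels_present,
                          curve = numeric(256)),
                     class = "otsu_result"))
  }
  w0 <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- w0 * (1 - w0)
  curve <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, 0)
  structure(list(threshold = which.max(curve) - 1L, curve = curve),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold: %d (peak between-class variance %.3f)\n",
              x$threshold, max(x$curve)))
  invisible(x)
}

#' Binarise tissue/fluid foreground
#'
#' Foreground is everything at or below the threshold (tissue and fluid are
#' darker than the near-white background), background everything above it.
#'
#' @param img Grayscale image matrix.
#' @param threshold Intensity threshold in `[0, 255]`, or an `otsu_result`.
#' @return Logical foreground mask.
#' @export
binarize_foreground <- function(img, threshold) {
  assert_gray_image(img)
  if (inherits(threshold, "otsu_result")) threshold <- threshold$threshold
  if (threshold < 0 || threshold > 255) abort_input("`threshold` must be in [0, 255]")
  img <= threshold
}

# Label connected components of a logical mask via igraph; returns an integer
# matrix (0 = background, 1..n = component ids).
label_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) return(labels)
  id <- matrix(0L, h, w)
  id[fg] <- seq_along(fg)

  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * h + r2[ok]
    both <- id[nb] > 0L
    if (!any(both)) next
    edges[[length(edges) + 1L]] <- cbind(id[fg[ok]][both], id[nb][both])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  labels[fg] <- comp$membership
  labels
}

#' Remove small foreground components
#'
#' Connected components (4- or 8-adjacency) smaller than `min_object_px`
#' pixels are deleted; components at or above the size floor are retained
#' verbatim. Background holes are never filled unless `fill_holes` is set,
#' in which case background components not touching the image border are
#' turned into foreground.
#'
#' @param mask Logical foreground mask.
#' @param config A [feature_config()].
#' @return Cleaned logical mask.
#' @export
remove_small_components <- function(mask, config = feature_config()) {
  assert_mask(mask)
  labels <- label_components(mask, config$connectivity)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= config$min_object_px)
    mask <- matrix(labels %in% keep, nrow(mask), ncol(mask))
  }
  if (config$fill_holes) {
    # complement components not touching the border become foreground
    bg_labels <- label_components(!mask, config$connectivity)
    if (max(bg_labels) > 0L) {
      border <- unique(c(bg_labels[1, ], bg_labels[nrow(mask), ],
                         bg_labels[, 1], bg_labels[, ncol(mask)]))
      hole <- bg_labels > 0L & !(bg_labels %in% border)
      mask[hole] <- TRUE
    }
  }
  mask
}

#' Compose the final feature image
#'
#' Per-pixel rule, in priority order: dark-flagged pixels stay black
#' (preserving fluid pockets), non-foreground pixels are masked to white,
#' and everything else keeps its enhanced grey value.
#'
#' @param enhanced Enhanced grayscale image matrix.
#' @param foreground Logical foreground mask.
#' @param dark_mask Logical dark-flag mask.
#' @return Composed grayscale image matrix.
#' @export
compose_final <- function(enhanced, foreground, dark_mask) {
  assert_gray_image(enhanced)
  assert_mask(foreground); assert_mask(dark_mask)
  assert_same_shape(enhanced, foreground, dark_mask)
  out <- enhanced
  out[!foreground] <- 255
  out[dark_mask] <- 0
  out
}

#' Midtone lightening
#'
#' Saturating affine intensity map `v -> min(255, round(alpha * v + beta))`
#' (rounding half away from zero). With the default gain 1.3 this brightens
#' mid-grey fluid areas towards white while leaving deep black (0) and true
#' background white (255) fixed.
#'
#' @param img Grayscale image matrix.
#' @param config A [feature_config()] supplying `alpha` and `beta`.
#' @return Lightened grayscale image matrix.
#' @export
midtone_lighten <- function(img, config = feature_config()) {
  assert_gray_image(img)
  clamp255(round_half_away(config$alpha * img + config$beta))
}

#' Enhancement quality metrics
#'
#' Reports two proxies, each evaluated on the `before` and `after` images
#' with a shared region decomposition:
#' * `snr_proxy`: `|mean(foreground) - mean(background)| / sd(background)`;
#' * `midtone_contrast`: standard deviation over the pixels whose *before*
#'   value lies in the 100-180 midtone band.
#'
#' Metrics whose defining region is empty or whose denominator is zero are
#' reported as `NA` (undefined), never as an error.
#'
#' @param before,after Grayscale image matrices of one shape.
#' @param foreground Logical foreground mask.
#' @param dark_mask Logical dark-flag mask (part of the foreground region).
#' @return A tibble with columns `metric`, `before`, `after`, `rel_change`.
#' @export
quality_metrics <- function(before, after, foreground, dark_mask = NULL) {
  assert_gray_image(before); assert_gray_image(after)
  assert_mask(foreground)
  if (is.null(dark_mask)) dark_mask <- matrix(FALSE, nrow(before), ncol(before))
  assert_same_shape(before, after, foreground, dark_mask)

  fg <- foreground | dark_mask
  bg <- !fg
  snr <- function(x) {
    if (!any(fg) || !any(bg)) return(NA_real_)
    s <- stats::sd(x[bg])
    if (!is.finite(s) || s == 0) return(NA_real_)
    abs(mean(x[fg]) - mean(x[bg])) / s
  }
  mid <- before >= 100 & before <= 180
  midc <- function(x) {
    if (sum(mid) < 2L) return(NA_real_)
    stats::sd(x[mid])
  }
  rows <- tibble::tibble(
    metric = c("snr_proxy", "midtone_contrast"),
    before = c(snr(before), midc(before)),
    after = c(snr(after), midc(after))
  )
  dplyr::mutate(rows, rel_change = (.data$after - .data$before) / .data$before)
}

#' Run the full feature-processing stage on one enhanced image
#'
#' Chains dark pre-mapping, Otsu thresholding (on the pre-mapped image by
#' default), foreground binarisation, small-component cleanup and the final
#' three-way composition.
#'
#' @param enhanced Enhanced (CLAHE + median) grayscale image matrix.
#' @param config A [feature_config()].
#' @return List with `image` (composed result), `premapped`, `dark_mask`,
#'   `foreground`, and `otsu` (the `otsu_result`).
#' @export
extract_features <- function(enhanced, config = feature_config()) {
  pm <- premap_dark(enhanced, config)
  otsu_input <- pm$image
  if (config$otsu_exclude_dark) {
    keep <- !pm$dark_mask
    if (!any(keep)) {
      otsu <- otsu_threshold(pm$image)
    } else {
      otsu <- otsu_threshold(matrix(pm$image[keep], nrow = 1))
    }
  } else {
    otsu <- otsu_threshold(otsu_input)
  }
  fg <- binarize_foreground(pm$image, otsu$threshold)
  fg <- remove_small_components(fg, config)
  list(image = compose_final(pm$image, fg, pm$dark_mask),
       premapped = pm$image,
       dark_mask = pm$dark_mask,
       foreground = fg,
       otsu = otsu)
}
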