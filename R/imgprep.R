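#' Convert an image to grayscale
#'
#' Three-channel input is collapsed with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114), rounded half away from zero; grayscale input is
#' returned unchanged.
#'
#' @param img Either a grayscale matrix or an `H x W x 3` array of
#'   intensities in `[0, 255]`.
#' @return Grayscale image matrix.
#' @export
#' @examples
#' rgb <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' to_grayscale(rgb) # 141
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    return(assert_gray_image(img))
  }
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    out <- matrix(clamp255(round_half_away(y)), dim(img)[1], dim(img)[2])
    return(assert_gray_image(out))
  }
  abort_input("image must have 1 or 3 channels")
}

# Separable bilinear sampling grid for one axis: source coordinates (0-based)
# for `n_out` samples over `n_in` pixels, textbook corner-aligned convention.
bilinear_axis <- function(n_in, n_out) {
  if (n_out == 1L) return((n_in - 1) / 2)
  (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
}

#' Resize a grayscale image with bilinear interpolation
#'
#' Corner-aligned bilinear interpolation followed by rounding half away from
#' zero. Resizing to the current size is an exact identity.
#'
#' @param img Grayscale image matrix.
#' @param target Integer vector `c(height, width)` (default `c(224, 224)`).
#' @return Resized grayscale image matrix.
#' @export
resize_image <- function(img, target = c(224, 224)) {
  assert_gray_image(img)
  target <- as.integer(target)
  if (length(target) != 2L || any(is.na(target)) || any(target < 1L)) {
    abort_config("`target` must be two positive integers")
  }
  h <- nrow(img); w <- ncol(img)
  if (h == target[1] && w == target[2]) return(img)

  rs <- bilinear_axis(h, target[1])
  cs <- bilinear_axis(w, target[2])
  r0 <- pmin(floor(rs), h - 1); r1 <- pmin(r0 + 1, h - 1); fr <- rs - r0
  c0 <- pmin(floor(cs), w - 1); c1 <- pmin(c0 + 1, w - 1); fc <- cs - c0

  m00 <- img[r0 + 1, c0 + 1, drop = FALSE]
  m10 <- img[r1 + 1, c0 + 1, drop = FALSE]
  m01 <- img[r0 + 1, c1 + 1, drop = FALSE]
  m11 <- img[r1 + 1, c1 + 1, drop = FALSE]

  out <- m00 * ((1 - fr) %o% (1 - fc)) + m10 * (fr %o% (1 - fc)) +
    m01 * ((1 - fr) %o% fc) + m11 * (fr %o% fc)
  clamp255(round_half_away(out))
}

#' Clip a 256-bin histogram and redistribute the excess
#'
#' Counts above `clip_count` are truncated and the excess mass is spread
#' uniformly over all 256 bins, conserving the total count. An infinite
#' `clip_count` disables clipping.
#'
#' @param h Numeric vector of 256 bin counts.
#' @param clip_count Clipping ceiling per bin.
#' @return Clipped histogram (possibly fractional counts), same total.
#' @export
clip_histogram <- function(h, clip_count) {
  stopifnot(length(h) == 256L)
  if (!is.finite(clip_count)) return(h)
  excess <- sum(pmax(h - clip_count, 0))
  pmin(h, clip_count) + excess / 256
}

# Equalisation mapping for one histogram: v -> round(255 * cdf(v)).
equalize_map <- function(h) {
  n <- sum(h)
  clamp255(round_half_away(255 * cumsum(h) / n))
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' The image is partitioned into a `tile_grid` of near-equal tiles; each
#' tile's 256-bin histogram is clipped at `clip_limit * tile_pixels / 256`
#' with the excess redistributed uniformly, then turned into an equalisation
#' mapping `v -> round(255 * cdf(v))`. Per-pixel output bilinearly
#' interpolates the mappings of the four surrounding tile centres (edge tiles
#' are replicated beyond the outermost centres).
#'
#' With a single tile and an infinite clip limit this reduces exactly to
#' plain global histogram equalisation.
#'
#' @param img Grayscale image matrix.
#' @param clip_limit Contrast clip limit (default 2); `Inf` disables clipping.
#' @param tile_grid Integer vector `c(rows, cols)` of tiles (default `c(8, 8)`).
#' @return Enhanced grayscale image matrix.
#' @export
apply_clahe <- function(img, clip_limit = 2, tile_grid = c(8, 8)) {
  assert_gray_image(img)
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L)) {
    abort_config("`tile_grid` must be two positive integers")
  }
  if (!is.numeric(clip_limit) || clip_limit <= 0) {
    abort_config("`clip_limit` must be positive")
  }
  h <- nrow(img); w <- ncol(img)
  gr <- tile_grid[1]; gc <- tile_grid[2]
  if (h < gr || w < gc) abort_config("image is smaller than the tile grid")

  row_edges <- round(seq(0, h, length.out = gr + 1))
  col_edges <- round(seq(0, w, length.out = gc + 1))

  maps <- matrix(0, nrow = 256, ncol = gr * gc)
  centers_r <- numeric(gr); centers_c <- numeric(gc)
  for (j in seq_len(gc)) {
    cols <- (col_edges[j] + 1):col_edges[j + 1]
    centers_c[j] <- (col_edges[j] + 1 + col_edges[j + 1]) / 2
    for (i in seq_len(gr)) {
      rows <- (row_edges[i] + 1):row_edges[i + 1]
      centers_r[i] <- (row_edges[i] + 1 + row_edges[i + 1]) / 2
      vals <- img[rows, cols]
      hist_t <- tabulate(vals + 1L, 256L)
      clip_count <- clip_limit * length(vals) / 256
      maps[, (j - 1L) * gr + i] <- equalize_map(clip_histogram(hist_t, clip_count))
    }
  }

  # per-axis interpolation indices and weights between tile centres
  interp_axis <- function(n, centers, g) {
    pos <- seq_len(n)
    if (g == 1L) {
      return(list(i0 = rep(1L, n), i1 = rep(1L, n), w = rep(0, n)))
    }
    i0 <- findInterval(pos, centers)
    i0 <- pmin(pmax(i0, 1L), g - 1L)
    i1 <- i0 + 1L
    w <- (pos - centers[i0]) / (centers[i1] - centers[i0])
    list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
  }
  ay <- interp_axis(h, centers_r, gr)
  ax <- interp_axis(w, centers_c, gc)

  v <- img + 1L
  wy <- matrix(ay$w, h, w)
  wx <- matrix(ax$w, h, w, byrow = TRUE)
  iy0 <- matrix(ay$i0, h, w); iy1 <- matrix(ay$i1, h, w)
  ix0 <- matrix(ax$i0, h, w, byrow = TRUE); ix1 <- matrix(ax$i1, h, w, byrow = TRUE)

  lookup <- function(iy, ix) {
    matrix(maps[cbind(as.vector(v), as.vector((ix - 1L) * gr + iy))], h, w)
  }
  out <- (1 - wy) * (1 - wx) * lookup(iy0, ix0) +
    wy * (1 - wx) * lookup(iy1, ix0) +
    (1 - wy) * wx * lookup(iy0, ix1) +
    wy * wx * lookup(iy1, ix1)
  clamp255(round_half_away(out))
}

# sort2 step of the 9-element median network: min into slot i, max into slot j
.mn_sort2 <- function(p, i, j) {
  a <- pmin(p[[i]], p[[j]])
  p[[j]] <- pmax(p[[i]], p[[j]])
  p[[i]] <- a
  p
}

#' Median denoising with edge replication
#'
#' Every output pixel is the median of its `kernel x kernel` neighbourhood;
#' pixels beyond the border are taken from the nearest edge pixel. The 3x3
#' case runs through a vectorised median-of-nine exchange network.
#'
#' @param img Grayscale image matrix.
#' @param kernel Odd kernel width, at least 3 (default 3).
#' @return Denoised grayscale image matrix.
#' @export
median_denoise <- function(img, kernel = 3) {
  assert_gray_image(img)
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 3L || kernel %% 2L == 0L) {
    abort_config("`kernel` must be an odd integer >= 3")
  }
  h <- nrow(img); w <- ncol(img)
  r <- kernel %/% 2L
  ridx <- pmin(pmax(seq(1 - r, h + r), 1L), h)
  cidx <- pmin(pmax(seq(1 - r, w + r), 1L), w)
  pad <- img[ridx, cidx, drop = FALSE]

  if (kernel == 3L) {
    p <- vector("list", 9L)
    s <- 1L
    for (dc in 0:2) {
      for (dr in 0:2) {
        p[[s]] <- pad[(1 + dr):(h + dr), (1 + dc):(w + dc), drop = FALSE]
        s <- s + 1L
      }
    }
    # Devillard's 19-exchange median-of-9 selection network
    for (pr in list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
                    c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
                    c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
                    c(5, 3))) {
      p <- .mn_sort2(p, pr[1], pr[2])
    }
    return(p[[5]])
  }

  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- stats::median(pad[i:(i + 2L * r), j:(j + 2L * r)])
    }
  }
  out
}

#' Standardise and enhance one image
#'
#' Convenience wrapper running the enhancement chain in its canonical order:
#' grayscale conversion, bilinear resize, CLAHE, 3x3 median denoising. The
#' `order` argument allows stage reordering or omission.
#'
#' @param img Grayscale matrix or 3-channel array.
#' @param target Output size `c(height, width)`.
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param kernel Median kernel width.
#' @param order Character vector of stages to run, a subset of
#'   `c("grayscale", "resize", "clahe", "median")`, executed in the given order.
#' @return Enhanced grayscale image matrix.
#' @export
preprocess_image <- function(img, target = c(224, 224), clip_limit = 2,
                             tile_grid = c(8, 8), kernel = 3,
                             order = c("grayscale", "resize", "clahe", "median")) {
  bad <- setdiff(order, c("grayscale", "resize", "clahe", "median"))
  if (length(bad) > 0L) {
    abort_config(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  for (stage in order) {
    img <- switch(stage,
      grayscale = to_grayscale(img),
      resize = resize_image(img, target),
      clahe = apply_clahe(img, clip_limit, tile_grid),
      median = median_denoise(img, kernel)
    )
  }
  img
}
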