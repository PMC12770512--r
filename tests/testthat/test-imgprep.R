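test_that("grayscale conversion follows the luma weights exactly", {
  expect_equal(to_grayscale(array(c(255, 255, 255), c(1, 1, 3)))[1, 1], 255)
  expect_equal(to_grayscale(array(c(0, 0, 0), c(1, 1, 3)))[1, 1], 0)
  # round(0.299*100 + 0.587*150 + 0.114*200) = round(141.25) = 141
  expect_equal(to_grayscale(array(c(100, 150, 200), c(1, 1, 3)))[1, 1], 141)
  gray <- matrix(7, 4, 5)
  expect_identical(to_grayscale(gray), gray)
  expect_error(to_grayscale(array(0, c(2, 2, 4))), class = "cytopipe_input_error")
})

test_that("bilinear resize matches hand-computed values and fixed points", {
  img <- matrix(50, 7, 9)
  expect_identical(resize_image(img, c(7, 9)), img)            # identity
  expect_true(all(resize_image(img, c(12, 4)) == 50))           # constant
  # 2x2 checker columns to 4x4: source cols 0, 1/3, 2/3, 1 of [0, 255]
  out <- resize_image(matrix(c(0, 0, 255, 255), 2, 2), c(4, 4))
  expect_equal(out, matrix(rep(c(0, 85, 170, 255), each = 4), 4, 4))
  expect_error(resize_image(img, c(0, 4)), class = "cytopipe_config_error")
})

test_that("single-tile unclipped CLAHE equals global histogram equalisation", {
  set.seed(11)
  for (rep in 1:3) {
    img <- matrix(sample(0:255, 48 * 40, replace = TRUE, prob = runif(256)),
                  48, 40)
    expect_equal(apply_clahe(img, clip_limit = Inf, tile_grid = c(1, 1)),
                 oracle_global_he(img))
  }
})

test_that("CLAHE preserves constants, conserves mass, and maps monotonically", {
  expect_equal(length(unique(as.vector(apply_clahe(matrix(128, 32, 32))))), 1L)
  # clipped histogram keeps the pixel count
  set.seed(12)
  h <- tabulate(sample(1:256, 500, TRUE), 256)
  clipped <- clip_histogram(h, 4)
  expect_equal(sum(clipped), sum(h))
  expect_true(all(clipped <= 4 + sum(pmax(h - 4, 0)) / 256 + 1e-9))
  # equalisation mappings are non-decreasing
  cdf_map <- cumsum(clipped) / sum(clipped)
  expect_true(all(diff(cdf_map) >= 0))
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  out <- apply_clahe(img)
  expect_true(all(out >= 0 & out <= 255))
  expect_error(apply_clahe(matrix(1, 4, 4), tile_grid = c(8, 8)),
               class = "cytopipe_config_error")
})

test_that("median filter matches the naive sorted-neighbourhood oracle", {
  expect_identical(median_denoise(matrix(9, 8, 8)), matrix(9, 8, 8))
  salt <- matrix(0, 9, 9); salt[5, 5] <- 255
  expect_true(all(median_denoise(salt) == 0))
  set.seed(13)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_identical(median_denoise(img), oracle_median3(img))
  }
  expect_error(median_denoise(matrix(1, 8, 8), kernel = 4),
               class = "cytopipe_config_error")
})

test_that("median filter is idempotent on coarse piecewise-constant images", {
  img <- matrix(40, 24, 24)
  img[1:12, ] <- 200
  once <- median_denoise(img)
  expect_identical(median_denoise(once), once)
})

test_that("median filtering removes nearly all impulse noise", {
  cfg <- small_synth_config(noise_fraction = 0.01, illumination_amplitude = 0,
                            background_range = c(230, 250))
  hits <- 0; total <- 0
  for (s in 1:5) {
    img <- generate_image("neuroendocrine", cfg, seed = 60 + s)
    noise <- attr(img, "noise")
    den <- median_denoise(img)
    hits <- hits + sum(den[noise] %in% c(0, 255))
    total <- total + sum(noise)
  }
  expect_lt(hits / total, 0.05)
})

test_that("every enhancement op maps [0,255] into [0,255]", {
  set.seed(14)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
    for (out in list(resize_image(img, c(17, 23)), apply_clahe(img),
                     median_denoise(img))) {
      expect_true(all(out >= 0 & out <= 255 & out == round(out)))
    }
  }
})
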