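test_that("dark pre-mapping zeroes and flags exactly the at-threshold pixels", {
  img <- matrix(c(59, 60, 61, 255), 2, 2)
  pm <- premap_dark(img, feature_config())
  expect_equal(pm$image, matrix(c(0, 0, 61, 255), 2, 2))
  expect_equal(pm$dark_mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  all_white <- matrix(255, 3, 3)
  pm2 <- premap_dark(all_white, feature_config())
  expect_identical(pm2$image, all_white)
  expect_false(any(pm2$dark_mask))
})

test_that("Otsu picks the smallest maximiser and handles degeneracy", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(img)
  expect_equal(res$threshold, 10L)            # flat-maximal on [10, 199]
  expect_equal(res$threshold, oracle_otsu(img))
  expect_equal(otsu_threshold(matrix(112, 5, 5))$threshold, 112L)
  expect_length(res$curve, 256L)
  expect_true(all(res$curve >= 0))
})

test_that("Otsu equals the brute-force scan on random images", {
  set.seed(21)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_equal(otsu_threshold(img)$threshold, oracle_otsu(img))
  }
})

test_that("foreground binarisation keeps tissue at or below the threshold", {
  img <- matrix(c(0, 112, 113, 240), 2, 2)
  fg <- binarize_foreground(img, 112)
  expect_equal(fg, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_true(all(binarize_foreground(matrix(50, 3, 3), 112)))
})

test_that("small-component removal honours the strict size floor", {
  cfg <- feature_config()                      # min 30 px, 8-connectivity
  mask <- matrix(FALSE, 20, 20)
  mask[2:30] <- TRUE                           # 29-pixel column strip
  expect_false(any(remove_small_components(mask, cfg)))
  mask30 <- matrix(FALSE, 20, 20)
  mask30[2:31] <- TRUE                         # exactly 30 pixels
  expect_equal(sum(remove_small_components(mask30, cfg)), 30L)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(remove_small_components(empty, cfg), empty)
})

test_that("component removal matches a BFS flood-fill oracle, never adds, and is idempotent", {
  set.seed(22)
  for (rep in 1:10) {
    mask <- matrix(runif(16 * 16) < 0.4, 16, 16)
    for (conn in c(4, 8)) {
      cfg <- feature_config(min_object_px = 5, connectivity = conn)
      got <- remove_small_components(mask, cfg)
      expect_identical(got, oracle_remove_small(mask, 5, conn))
      expect_true(all(!got | mask))                      # never adds pixels
      expect_identical(remove_small_components(got, cfg), got)
    }
  }
})

test_that("composition follows the dark > background > foreground priority", {
  one <- function(v, fg, dark) {
    compose_final(matrix(v, 1, 1), matrix(fg, 1, 1), matrix(dark, 1, 1))[1, 1]
  }
  expect_equal(one(0, TRUE, TRUE), 0)       # dark stays black
  expect_equal(one(180, FALSE, FALSE), 255) # background to white
  expect_equal(one(140, TRUE, FALSE), 140)  # foreground passes through
  # exhaustive three-way partition over every value and flag combination
  v <- rep(0:255, times = 4)
  fg <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 256)
  dark <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 256)
  out <- compose_final(matrix(v, 32), matrix(fg, 32), matrix(dark, 32))
  expected <- ifelse(dark, 0, ifelse(!fg, 255, v))
  expect_equal(as.vector(out), as.vector(expected))
  expect_error(compose_final(matrix(0, 2, 2), matrix(TRUE, 2, 3),
                             matrix(FALSE, 2, 2)),
               class = "cytopipe_input_error")
})

test_that("midtone lightening saturates correctly and preserves order", {
  cfg <- feature_config()                     # alpha = 1.3, beta = 0
  img <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_equal(midtone_lighten(img, cfg), matrix(c(0, 130, 255, 255), 2, 2))
  vals <- midtone_lighten(matrix(0:255, 16), cfg)
  expect_true(all(diff(as.vector(vals)) >= 0))  # order-preserving
})

test_that("quality metrics report identity, guards, and directional change", {
  base <- matrix(c(rep(40, 50), rep(240, 50)), 10, 10)
  fg <- base <= 112
  set.seed(23)
  noisy_bg <- base
  noisy_bg[!fg] <- noisy_bg[!fg] + sample(-5:5, sum(!fg), TRUE)
  q_same <- quality_metrics(noisy_bg, noisy_bg, fg)
  expect_equal(q_same$rel_change, c(0, NA))   # no midtone pixels here -> NA
  q_const <- quality_metrics(base, base, fg)
  expect_true(is.na(q_const$before[q_const$metric == "snr_proxy"]))
  # darkening foreground increases separation at fixed background spread
  better <- noisy_bg
  better[fg] <- 0
  q <- quality_metrics(noisy_bg, better, fg)
  expect_gt(q$rel_change[q$metric == "snr_proxy"], 0)
})

test_that("full feature extraction is deterministic and self-consistent", {
  cfg <- small_synth_config()
  img <- generate_image("adenocarcinoma", cfg, seed = 31)
  enhanced <- median_denoise(apply_clahe(img))
  f1 <- extract_features(enhanced)
  f2 <- extract_features(enhanced)
  expect_identical(f1$image, f2$image)
  # every output pixel is 0, 255, or the premapped input value
  ok <- f1$image == 0 | f1$image == 255 | f1$image == f1$premapped
  expect_true(all(ok))
  expect_true(all(f1$image[f1$dark_mask] == 0))
  expect_true(all(f1$image[!f1$foreground & !f1$dark_mask] == 255))
})
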