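test_that("background-only image with no noise or gradient is constant", {
  cfg <- small_synth_config(noise_fraction = 0, illumination_amplitude = 0)
  img <- generate_image(NULL, cfg, seed = 1)
  expect_equal(length(unique(as.vector(img))), 1L)
  expect_true(all(img >= cfg$background_range[1] & img <= cfg$background_range[2]))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- small_synth_config()
  a <- generate_image("squamous", cfg, seed = 7)
  b <- generate_image("squamous", cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_image("squamous", cfg, seed = 8)))
})

test_that("impulse-noise count matches the binomial model", {
  # background plus gradient bounded away from 0/255 so noise pixels are
  # identifiable
  cfg <- synth_config(image_size = c(224, 224), background_range = c(225, 240),
                      noise_fraction = 0.01, illumination_amplitude = 10)
  n_px <- 224 * 224
  exp_mean <- n_px * 0.01
  exp_sd <- sqrt(n_px * 0.01 * 0.99)
  for (s in 1:5) {
    img <- generate_image("adenocarcinoma", cfg, seed = 40 + s)
    outside <- !attr(img, "painted")
    extreme <- sum(img[outside] %in% c(0, 255))
    frac_outside <- mean(outside)
    # binomial bound on the pixels we can observe unambiguously
    expect_lt(abs(extreme - exp_mean * frac_outside),
              3 * sqrt(n_px * frac_outside * 0.01 * 0.99) + 1)
    expect_true(all(img[attr(img, "noise")] %in% c(0, 255)))
  }
})

test_that("dataset generation writes balanced PNGs with a faithful manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_synth_config(seed = 3)
  manifest <- generate_dataset(cfg, dir, counts = c(2, 2, 2))
  expect_equal(nrow(manifest), 6L)
  expect_equal(as.integer(table(manifest$label)), rep(2L, 3))
  expect_true(all(file.exists(manifest$path)))
  # PNG round trip is lossless
  img <- read_gray_png(manifest$path[1])
  expect_true(all(img == round(img)) && max(img) <= 255 && min(img) >= 0)
  # identical config reproduces identical bytes
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir2, counts = c(2, 2, 2))
  h1 <- unname(tools::md5sum(sort(list.files(dir, "png$", full.names = TRUE))))
  h2 <- unname(tools::md5sum(sort(list.files(dir2, "png$", full.names = TRUE))))
  expect_identical(h1, h2)
})

test_that("degenerate dataset counts are handled", {
  dir <- withr::local_tempdir()
  m1 <- generate_dataset(small_synth_config(), file.path(dir, "one"),
                         counts = c(1, 1, 1))
  expect_equal(nrow(m1), 3L)
  expect_setequal(m1$label, synth_classes())
  m0 <- generate_dataset(small_synth_config(), file.path(dir, "zero"),
                         counts = c(0, 0, 0))
  expect_equal(nrow(m0), 0L)
  expect_false(dir.exists(file.path(dir, "zero")))
})

test_that("class motifs separate under a nearest-centroid radial classifier", {
  cfg <- small_synth_config(noise_fraction = 0, illumination_amplitude = 0)
  n_per <- 20L
  labels <- rep(synth_classes(), each = n_per)
  profiles <- t(vapply(seq_along(labels), function(i) {
    radial_profile(generate_image(labels[i], cfg, seed = 500 + i))
  }, numeric(16)))
  centroids <- vapply(synth_classes(), function(cl) {
    colMeans(profiles[labels == cl, , drop = FALSE])
  }, numeric(16))
  pred <- synth_classes()[apply(profiles, 1, function(p) {
    which.min(colSums((centroids - p)^2))
  })]
  expect_gt(mean(pred == labels), 0.9)
})

test_that("default images exercise the dark and midtone intensity bands", {
  cfg <- synth_config()  # default 224x224
  for (i in seq_along(synth_classes())) {
    img <- generate_image(synth_classes()[i], cfg, seed = 90 + i)
    expect_gte(mean(img <= 60), 0.01)
    expect_gte(mean(img >= 100 & img <= 180), 0.05)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(noise_fraction = 0.5), class = "cytopipe_config_error")
  expect_error(synth_config(background_range = c(250, 230)),
               class = "cytopipe_config_error")
  expect_error(synth_config(nucleus_range = c(-5, 60)),
               class = "cytopipe_config_error")
  expect_error(generate_image("not-a-class", small_synth_config()),
               class = "cytopipe_config_error")
})
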