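small_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_size = c(32, 32), resnet_base_filters = 2,
         unet_base_filters = 2, head_units = 16),
    list(...))
  do.call(desk_model_config, args)
}

test_that("a zero-weight bottleneck block is the identity on non-negative input", {
  set.seed(1)
  blk <- residual_block(4, 2, 4, stride = 1L)       # no projection path
  for (nm in c("conv1", "conv2", "conv3")) {
    blk[[nm]]$W[] <- 0; blk[[nm]]$b[] <- 0
  }
  x <- array(abs(rnorm(2 * 8 * 8 * 4)), c(2, 8, 8, 4))
  out <- cytopipe:::nn_forward(blk, x, training = FALSE)
  expect_equal(out, x, tolerance = 1e-8)
})

test_that("the full-scale stage plan counts fifty trainable layers", {
  expect_equal(residual_layer_count(c(3, 4, 6, 3)), 50L)
  # count convolutions in an actually built branch (widths do not matter)
  br <- build_residual_branch(model_config(input_size = c(64, 64),
                                           resnet_plan = c(3, 4, 6, 3),
                                           resnet_base_filters = 2,
                                           unet_depth = 2, unet_base_filters = 2))
  n_conv <- 1L                                        # stem
  for (l in br$net$layers) {
    if (inherits(l, "nn_residual_block")) n_conv <- n_conv + 3L
  }
  expect_equal(n_conv + 1L, 50L)                      # + classification dense
})

test_that("branch feature dimensions honour the declared contract", {
  cfg <- small_cfg()
  res <- build_residual_branch(cfg)
  att <- build_attention_branch(cfg)
  x <- array(runif(2 * 32 * 32), c(2, 32, 32, 1))
  fr <- cytopipe:::nn_forward(res$net, x)
  fa <- cytopipe:::attn_branch_forward(att, x)
  expect_equal(dim(fr), c(2L, res$out_dim))
  expect_equal(dim(fa), c(2L, att$out_dim))
  expect_equal(length(att$gates), att$depth)          # one gate per skip
  expect_equal(length(att$enc), length(att$dec))      # symmetric levels
})

test_that("attention coefficients live in (0,1) with exact suppression limits", {
  set.seed(2)
  x <- array(rnorm(2 * 8 * 8 * 4), c(2, 8, 8, 4))
  g <- array(rnorm(2 * 8 * 8 * 6), c(2, 8, 8, 6))
  free <- attention_gate(x, g)
  expect_true(all(free$alpha > 0 & free$alpha < 1))
  expect_equal(dim(free$out), dim(x))
  off <- attention_gate(x, g, psi_bias = -50)
  expect_true(all(abs(off$out) < 1e-12))              # alpha ~ 0 suppresses
  on <- attention_gate(x, g, psi_bias = 50)
  expect_equal(on$out, x, tolerance = 1e-6)           # alpha ~ 1 passes through
  expect_error(attention_gate(x, array(0, c(2, 4, 4, 6))),
               class = "cytopipe_config_error")
})

test_that("hybrid head obeys softmax and parameter arithmetic", {
  cfg <- small_cfg(head_units = 512)
  m <- build_hybrid(cfg)
  set.seed(3)
  imgs <- lapply(1:5, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  m$classes <- synth_classes()
  pred <- predict_model(m, imgs)
  probs <- as.matrix(pred[, synth_classes()])
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-6)
  # duplicated image gives identical probability rows
  pred2 <- predict_model(m, list(imgs[[1]], imgs[[1]]))
  expect_equal(pred2[1, ], pred2[2, ])
  # fused width is the sum of the branch widths
  expect_equal(m$fused_dim, m$res$out_dim + m$att$out_dim)
  # head parameters: dense(fused -> 512) + BN(2*512) + dense(512 -> 3)
  head_params <- sum(vapply(cytopipe:::nn_collect(m$head), function(l) {
    sum(vapply(l$params, function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
  expect_equal(head_params,
               (m$fused_dim + 1) * 512 + 2 * 512 + (512 + 1) * 3)
})

test_that("softmax probabilities are valid across many random logit rows", {
  set.seed(4)
  logits <- matrix(rnorm(3000, sd = 5), 1000, 3)
  p <- cytopipe:::softmax_rows(logits)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 1000), tolerance = 1e-6)
})

test_that("zero learning rate leaves trainable weights untouched", {
  cfg <- small_cfg(epochs = 1, batch_size = 4)
  m <- build_hybrid(cfg)
  set.seed(5)
  imgs <- lapply(1:8, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  labs <- rep(synth_classes(), length.out = 8)
  before <- get_model_state(m)
  m <- train_model(m, imgs, labs, learning_rate = 0)
  after <- get_model_state(m)
  for (i in seq_along(before)) {
    for (nm in setdiff(names(before[[i]]), c("run_mean", "run_var"))) {
      expect_equal(after[[i]][[nm]], before[[i]][[nm]], tolerance = 1e-12)
    }
  }
  expect_equal(nrow(m$history), 1L)
})

test_that("one Adam step on one batch decreases the loss", {
  set.seed(6)
  imgs <- lapply(1:6, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  labs <- rep(synth_classes(), 2)
  ok <- FALSE
  for (attempt in 1:3) {
    m <- build_hybrid(small_cfg(seed = 100 + attempt))
    m$classes <- synth_classes()
    y <- match(labs, m$classes)
    x <- cytopipe:::stack_batch(imgs)
    loss0 <- cytopipe:::softmax_ce(
      cytopipe:::hybrid_forward(m, x, training = FALSE)$logits, y)$loss
    fwd <- cytopipe:::hybrid_forward(m, x, training = TRUE)
    sm <- cytopipe:::softmax_ce(fwd$logits, y)
    cytopipe:::hybrid_backward(m, fwd, sm$dlogits)
    cytopipe:::adam_step(m$layer_envs, 1e-4, 1)
    loss1 <- cytopipe:::softmax_ce(
      cytopipe:::hybrid_forward(m, x, training = FALSE)$logits, y)$loss
    if (loss1 < loss0) { ok <- TRUE; break }
  }
  expect_true(ok)
})

test_that("history length equals the configured epoch count and training is reproducible", {
  set.seed(7)
  imgs <- lapply(1:6, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  labs <- rep(synth_classes(), 2)
  run <- function() {
    m <- build_hybrid(small_cfg(seed = 21, epochs = 3, batch_size = 3))
    train_model(m, imgs, labs)$history
  }
  h1 <- run(); h2 <- run()
  expect_equal(nrow(h1), 3L)
  expect_equal(h1$train_loss, h2$train_loss)
  expect_equal(h1$train_accuracy, h2$train_accuracy)
})

test_that("model configuration guards reject impossible settings", {
  expect_error(desk_model_config(input_size = c(16, 16)),
               class = "cytopipe_config_error")
  expect_error(model_config(num_classes = 1), class = "cytopipe_config_error")
  expect_error(model_config(branch_dropout = 1), class = "cytopipe_config_error")
  m <- build_hybrid(small_cfg())
  expect_error(predict_model(m, list(matrix(0, 16, 16))),
               class = "cytopipe_input_error")
  expect_error(train_model(m, list(), character(0)),
               class = "cytopipe_data_error")
})
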