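#' Hybrid model configuration
#'
#' Describes the two-branch classifier: a residual (bottleneck-block) global
#' feature branch, an attention-gated encoder-decoder spatial branch, and a
#' dense fusion head (`dense 512 ReLU + L2 -> batch norm -> dropout 0.25 ->
#' dense softmax`). The default mirrors the full-scale architecture
#' (224x224 input, stage plan `[3, 4, 6, 3]`); [desk_model_config()] gives a
#' small configuration trainable on a single CPU.
#'
#' @param input_size `c(height, width)` of the grayscale input.
#' @param resnet_plan Blocks per residual stage (full plan `c(3, 4, 6, 3)`).
#' @param resnet_base_filters Width of the first residual stage's bottleneck.
#' @param unet_depth Number of encoder levels in the attention branch.
#' @param unet_base_filters Channels of the first encoder level.
#' @param branch_dropout Dropout rate inside both branches (default 0.3).
#' @param head_units Fusion dense width (default 512).
#' @param head_l2 L2 penalty coefficient on the fusion dense weights
#'   (default 1e-4).
#' @param head_dropout Dropout rate after the fusion dense (default 0.25).
#' @param num_classes Output classes (default 3).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 25).
#' @param batch_size Minibatch size (default 32).
#' @param seed Seed for weight initialisation and training shuffles.
#' @param unet_readout `"decoder"` (global average pooling of the final
#'   decoder map, default) or `"bottleneck"` (pooling of the bottleneck map).
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = c(224, 224), resnet_plan = c(3, 4, 6, 3),
                         resnet_base_filters = 64, unet_depth = 4,
                         unet_base_filters = 16, branch_dropout = 0.3,
                         head_units = 512, head_l2 = 1e-4, head_dropout = 0.25,
                         num_classes = 3, learning_rate = 1e-4, epochs = 25,
                         batch_size = 32, seed = 1, unet_readout = "decoder") {
  if (num_classes < 2) abort_config("`num_classes` must be >= 2")
  if (branch_dropout < 0 || branch_dropout >= 1 ||
      head_dropout < 0 || head_dropout >= 1) {
    abort_config("dropout rates must be in [0, 1)")
  }
  if (learning_rate < 0) abort_config("`learning_rate` must be >= 0")
  if (!unet_readout %in% c("decoder", "bottleneck")) {
    abort_config("`unet_readout` must be 'decoder' or 'bottleneck'")
  }
  input_size <- as.integer(input_size)
  min_div <- 2^(length(resnet_plan) + 1L)  # stem pool + strided stages
  if (any(input_size < min_div)) {
    abort_config(sprintf("input %dx%d is smaller than the total downsampling factor %d",
                         input_size[1], input_size[2], min_div))
  }
  if (any(input_size < 2^unet_depth)) {
    abort_config("`unet_depth` exceeds the input resolution")
  }
  structure(list(input_size = input_size,
                 resnet_plan = as.integer(resnet_plan),
                 resnet_base_filters = as.integer(resnet_base_filters),
                 unet_depth = as.integer(unet_depth),
                 unet_base_filters = as.integer(unet_base_filters),
                 branch_dropout = branch_dropout, head_units = as.integer(head_units),
                 head_l2 = head_l2, head_dropout = head_dropout,
                 num_classes = as.integer(num_classes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 unet_readout = unet_readout),
            class = "model_config")
}

#' Desk-scale model configuration
#'
#' A single-CPU configuration: 64x64 input, one bottleneck block per stage
#' at reduced widths, a two-level attention branch, and a longer schedule
#' (50 epochs) with a larger step size to compensate for the tiny data.
#'
#' @param ... Overrides passed to [model_config()].
#' @export
desk_model_config <- function(...) {
  defaults <- list(input_size = c(64, 64), resnet_plan = c(1, 1, 1, 1),
                   resnet_base_filters = 4, unet_depth = 2,
                   unet_base_filters = 6, head_units = 64,
                   learning_rate = 1e-3, epochs = 50, batch_size = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Trainable-layer count of the residual branch plan
#'
#' Convolutional layers are the stem plus three per bottleneck block; used
#' standalone as a classifier the final dense layer is added, giving the
#' canonical 50 for the plan `c(3, 4, 6, 3)`.
#'
#' @param plan Blocks per stage.
#' @param standalone Count the final dense layer too (default `TRUE`).
#' @return Integer layer count.
#' @export
residual_layer_count <- function(plan = c(3, 4, 6, 3), standalone = TRUE) {
  1L + 3L * sum(as.integer(plan)) + if (standalone) 1L else 0L
}

#' Build the residual global-feature branch
#'
#' Stem convolution + max-pool, then stages of bottleneck [residual_block()]s
#' (stride-2 entry from the second stage on), batch normalisation and ReLU
#' throughout, dropout after each stage, global average pooling at the end.
#'
#' @param config A [model_config()].
#' @return Branch object with fields `net` and `out_dim`.
#' @export
build_residual_branch <- function(config = desk_model_config()) {
  b <- config$resnet_base_filters
  mids <- b * 2^(seq_along(config$resnet_plan) - 1L)
  outs <- 4L * mids
  layers <- list(nn_conv2d(1L, b, 3L, 1L), nn_batchnorm(b), nn_relu(),
                 nn_maxpool2())
  in_c <- b
  for (stage in seq_along(config$resnet_plan)) {
    stride <- if (stage == 1L) 1L else 2L
    for (blk in seq_len(config$resnet_plan[stage])) {
      layers <- c(layers, list(residual_block(
        in_c, mids[stage], outs[stage], if (blk == 1L) stride else 1L)))
      in_c <- outs[stage]
    }
    layers <- c(layers, list(nn_dropout(config$branch_dropout)))
  }
  layers <- c(layers, list(nn_gap()))
  structure(list(net = nn_seq(layers), out_dim = in_c,
                 input_size = config$input_size),
            class = "residual_branch")
}

#' Additive attention gate
#'
#' Computes per-position coefficients
#' `alpha = sigmoid(psi(relu(theta_x(x) + phi_g(g))))` in `(0, 1)` and
#' returns `x * alpha`; `x` are skip features and `g` a gating signal at the
#' same spatial size.
#'
#' @param x Skip-feature array `(N, H, W, Cx)`.
#' @param g Gating array `(N, H, W, Cg)`.
#' @param gate Optional gate layer (created to match shapes if omitted).
#' @param psi_bias Optional override of the `psi` bias (used to force the
#'   suppression/pass-through limits).
#' @return List with `out` (gated features, shape of `x`) and `alpha`
#'   (`(N, H, W, 1)` coefficients).
#' @export
attention_gate <- function(x, g, gate = NULL, psi_bias = NULL) {
  if (length(dim(x)) != 4L || length(dim(g)) != 4L ||
      !all(dim(x)[1:3] == dim(g)[1:3])) {
    abort_config("x and g must be 4-d arrays aligned on (N, H, W)")
  }
  if (is.null(gate)) {
    gate <- nn_attn_gate(dim(x)[4], dim(g)[4], max(dim(x)[4] %/% 2L, 1L))
  }
  if (!is.null(psi_bias)) gate$psi$b <- psi_bias
  nn_forward(gate, list(x = x, g = g), training = FALSE)
}

#' Build the attention-gated encoder-decoder branch
#'
#' A U-Net-style encoder (two 3x3 conv + batch-norm + ReLU layers and
#' dropout per level, max-pooled between levels) and a mirrored decoder
#' whose skip connections pass through additive attention gates before
#' concatenation. The classification read-out is global average pooling of
#' the final decoder map (or of the bottleneck, per `unet_readout`).
#'
#' @param config A [model_config()].
#' @return Branch object with fields `enc`, `bottleneck`, `dec`, `gates`,
#'   `out_dim`.
#' @export
build_attention_branch <- function(config = desk_model_config()) {
  u <- config$unet_base_filters
  depth <- config$unet_depth
  widths <- u * 2^(seq_len(depth) - 1L)

  conv_block <- function(in_c, out_c) {
    nn_seq(list(nn_conv2d(in_c, out_c, 3L, 1L), nn_batchnorm(out_c), nn_relu(),
                nn_conv2d(out_c, out_c, 3L, 1L), nn_batchnorm(out_c), nn_relu(),
                nn_dropout(config$branch_dropout)))
  }

  enc <- vector("list", depth)
  in_c <- 1L
  for (i in seq_len(depth)) {
    enc[[i]] <- conv_block(in_c, widths[i])
    in_c <- widths[i]
  }
  bottleneck_c <- u * 2^depth
  bottleneck <- conv_block(in_c, bottleneck_c)

  pools <- lapply(seq_len(depth), function(i) nn_maxpool2())
  ups <- vector("list", depth)
  gates <- vector("list", depth)
  dec <- vector("list", depth)
  g_c <- bottleneck_c
  for (i in rev(seq_len(depth))) {
    ups[[i]] <- nn_upsample2()
    gates[[i]] <- nn_attn_gate(widths[i], g_c, max(widths[i] %/% 2L, 1L))
    dec[[i]] <- conv_block(widths[i] + g_c, widths[i])
    g_c <- widths[i]
  }
  out_dim <- if (config$unet_readout == "bottleneck") bottleneck_c else widths[1]
  structure(list(enc = enc, pools = pools, bottleneck = bottleneck, ups = ups,
                 gates = gates, dec = dec, gap = nn_gap(),
                 readout = config$unet_readout, depth = depth,
                 out_dim = out_dim, input_size = config$input_size),
            class = "attention_branch")
}

attn_branch_forward <- function(br, x, training = FALSE) {
  skips <- vector("list", br$depth)
  h <- x
  for (i in seq_len(br$depth)) {
    h <- nn_forward(br$enc[[i]], h, training)
    skips[[i]] <- h
    h <- nn_forward(br$pools[[i]], h, training)
  }
  h <- nn_forward(br$bottleneck, h, training)
  bottleneck_out <- h
  for (i in rev(seq_len(br$depth))) {
    g <- nn_forward(br$ups[[i]], h, training)
    gated <- nn_forward(br$gates[[i]], list(x = skips[[i]], g = g), training)
    cat_in <- abind4(gated$out, g)
    h <- nn_forward(br$dec[[i]], cat_in, training)
  }
  feat_src <- if (br$readout == "bottleneck") bottleneck_out else h
  nn_forward(br$gap, feat_src, training)
}

attn_branch_backward <- function(br, dfeat) {
  if (br$readout == "bottleneck") {
    abort_config("backward pass implemented for the decoder read-out only")
  }
  dh <- nn_backward(br$gap, dfeat)
  dskips <- vector("list", br$depth)
  for (i in seq_len(br$depth)) {
    dcat <- nn_backward(br$dec[[i]], dh)
    cx <- dim(nn_gate_cache_x(br$gates[[i]]))[4]
    dgated <- dcat[, , , seq_len(cx), drop = FALSE]
    dg_cat <- dcat[, , , -seq_len(cx), drop = FALSE]
    gb <- nn_backward(br$gates[[i]], dgated)
    dskips[[i]] <- gb$dx
    dh <- nn_backward(br$ups[[i]], gb$dg + dg_cat)
  }
  dh <- nn_backward(br$bottleneck, dh)
  for (i in rev(seq_len(br$depth))) {
    dh <- nn_backward(br$pools[[i]], dh)
    dh <- dh + dskips[[i]]
    dh <- nn_backward(br$enc[[i]], dh)
  }
  dh
}

nn_gate_cache_x <- function(gate) gate$cache$x

# concatenate two (N,H,W,C) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Build the hybrid two-branch classifier
#'
#' Both branches read the same grayscale input; their pooled feature vectors
#' are concatenated and passed through the dense fusion head
#' (`dense(head_units), ReLU, L2` -> batch norm -> dropout -> softmax
#' output). Weights are seeded He-normal draws (no pretrained weights are
#' downloaded); [set_model_state()] accepts externally supplied weights.
#'
#' @param config A [model_config()].
#' @return Object of class `hybrid_model`.
#' @export
build_hybrid <- function(config = desk_model_config()) {
  withr::with_seed(config$seed, {
    res <- build_residual_branch(config)
    att <- build_attention_branch(config)
    fused <- res$out_dim + att$out_dim
    head <- nn_seq(list(
      nn_dense(fused, config$head_units, l2 = config$head_l2),
      nn_relu(),
      nn_batchnorm(config$head_units),
      nn_dropout(config$head_dropout),
      nn_dense(config$head_units, config$num_classes)))
    model <- structure(
      list(config = config, res = res, att = att, head = head,
           fused_dim = fused, classes = NULL),
      class = "hybrid_model")
    model$layer_envs <- hybrid_layers(model)
    model
  })
}

hybrid_layers <- function(model) {
  c(nn_collect(model$res$net),
    unlist(lapply(c(model$att$enc, list(model$att$bottleneck),
                    model$att$gates, model$att$dec),
                  nn_collect), recursive = FALSE),
    nn_collect(model$head))
}

hybrid_forward <- function(model, x, training = FALSE) {
  fr <- nn_forward(model$res$net, x, training)
  fa <- attn_branch_forward(model$att, x, training)
  fused <- cbind(fr, fa)
  logits <- nn_forward(model$head, fused, training)
  list(logits = logits, fused = fused, dim_r = ncol(fr))
}

hybrid_backward <- function(model, fwd, dlogits) {
  dfused <- nn_backward(model$head, dlogits)
  dr <- dfused[, seq_len(fwd$dim_r), drop = FALSE]
  da <- dfused[, -seq_len(fwd$dim_r), drop = FALSE]
  nn_backward(model$res$net, dr)
  attn_branch_backward(model$att, da)
  invisible(NULL)
}

#' Count trainable parameters
#' @param model A `hybrid_model`.
#' @return Integer count of trainable parameter values.
#' @export
count_trainable_params <- function(model) {
  sum(vapply(model$layer_envs, function(l) {
    sum(vapply(l$params, function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

#' Get / set the full model state (weights and batch-norm statistics)
#' @param model A `hybrid_model`.
#' @return For `get_model_state`, a plain list snapshot.
#' @export
get_model_state <- function(model) nn_state_get(model$layer_envs)

#' @rdname get_model_state
#' @param state A snapshot from [get_model_state()] (or externally supplied
#'   weights of identical shapes).
#' @export
set_model_state <- function(model, state) {
  nn_state_set(model$layer_envs, state)
  invisible(model)
}

# assemble (N,H,W,1) batch from a list of [0,255] matrices
stack_batch <- function(images, rescale = 1 / 255) {
  n <- length(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, c(n, h, w, 1L))
  for (i in seq_len(n)) x[i, , , 1L] <- images[[i]] * rescale
  x
}

#' Train the hybrid model
#'
#' Seeded minibatch training with Adam and categorical cross-entropy;
#' augmentation (when supplied) is applied on the fly to training images
#' only. The epoch with the best validation accuracy (training accuracy if
#' no validation set is given) is checkpointed and kept in
#' `model$best_state`.
#'
#' @param model A `hybrid_model` from [build_hybrid()].
#' @param images List of grayscale matrices at the model input size.
#' @param labels Character or factor labels, one per image.
#' @param augment An [augment_config()] or `NULL` for no augmentation.
#' @param val_images,val_labels Optional held-out set evaluated per epoch.
#' @param epochs,batch_size,learning_rate Optional overrides of the model
#'   config.
#' @param early_stop_accuracy Optional training-accuracy level at which to
#'   stop before the full epoch budget (default `NULL`: train all epochs).
#' @param verbose Print per-epoch progress.
#' @return The model, with `history` (tibble of per-epoch `train_loss`,
#'   `train_accuracy`, `val_loss`, `val_accuracy`) and `best_state` attached.
#' @export
train_model <- function(model, images, labels, augment = NULL,
                        val_images = NULL, val_labels = NULL,
                        epochs = NULL, batch_size = NULL,
                        learning_rate = NULL, early_stop_accuracy = NULL,
                        verbose = FALSE) {
  if (length(images) == 0L) abort_data("empty training set")
  if (length(images) != length(labels)) {
    abort_data("images and labels must have equal length")
  }
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate

  classes <- model$classes %||% sort(unique(as.character(labels)))
  model$classes <- classes
  y <- match(as.character(labels), classes)
  if (anyNA(y)) abort_data("labels outside the model's class set")

  layers <- model$layer_envs
  n <- length(images)
  hist_rows <- vector("list", epochs)
  best_metric <- -Inf
  t_step <- 0L

  withr::with_seed(cfg$seed + 17L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L; n_batches <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        imgs <- images[idx]
        if (!is.null(augment) && !inherits(augment, "augment_config")) {
          abort_config("`augment` must be an augment_config or NULL")
        }
        if (!is.null(augment)) {
          imgs <- lapply(imgs, function(im) {
            apply_transform(im, sample_transform(augment, dim(im)))
          })
        }
        x <- stack_batch(imgs)
        fwd <- hybrid_forward(model, x, training = TRUE)
        sm <- softmax_ce(fwd$logits, y[idx])
        hybrid_backward(model, fwd, sm$dlogits)
        t_step <- t_step + 1L
        adam_step(layers, lr, t_step)
        ep_loss <- ep_loss + sm$loss + l2_penalty(layers)
        ep_correct <- ep_correct +
          sum(max.col(sm$probs, ties.method = "first") == y[idx])
        n_batches <- n_batches + 1L
      }
      train_loss <- ep_loss / n_batches
      train_acc <- ep_correct / n
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(val_images)) {
        ev <- evaluate_batch(model, val_images,
                             match(as.character(val_labels), classes))
        val_loss <- ev$loss; val_acc <- ev$accuracy
      }
      metric <- if (!is.null(val_images)) val_acc else train_acc
      if (metric > best_metric) {
        best_metric <- metric
        model$best_state <- get_model_state(model)
        model$best_epoch <- ep
      }
      hist_rows[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = train_loss, train_accuracy = train_acc,
        val_loss = val_loss, val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, train_loss, train_acc))
      }
      if (!is.null(early_stop_accuracy) && train_acc >= early_stop_accuracy) {
        break
      }
    }
  })
  model$history <- structure(dplyr::bind_rows(hist_rows),
                             class = c("training_history", class(tibble::tibble())))
  model
}

evaluate_batch <- function(model, images, y) {
  x <- stack_batch(images)
  fwd <- hybrid_forward(model, x, training = FALSE)
  sm <- softmax_ce(fwd$logits, y)
  list(loss = sm$loss,
       accuracy = mean(max.col(sm$probs, ties.method = "first") == y))
}

#' Predict class probabilities and labels
#'
#' Runs the model in inference mode (batch-norm running statistics, no
#' dropout). Ties in the probability vector break towards the
#' lowest-indexed class.
#'
#' @param model Trained `hybrid_model`.
#' @param images List of grayscale matrices at the model input size.
#' @param batch_size Inference batch size.
#' @return Tibble with one row per image: `label` plus one probability
#'   column per class.
#' @export
predict_model <- function(model, images, batch_size = 32L) {
  if (length(images) == 0L) abort_input("no images to predict")
  sz <- model$config$input_size
  for (im in images) {
    if (nrow(im) != sz[1] || ncol(im) != sz[2]) {
      abort_input(sprintf("image size %dx%d does not match model input %dx%d",
                          nrow(im), ncol(im), sz[1], sz[2]))
    }
  }
  classes <- model$classes %||% paste0("class", seq_len(model$config$num_classes))
  probs <- matrix(0, length(images), model$config$num_classes)
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    x <- stack_batch(images[idx])
    fwd <- hybrid_forward(model, x, training = FALSE)
    probs[idx, ] <- softmax_rows(fwd$logits)
  }
  colnames(probs) <- classes
  out <- tibble::as_tibble(as.data.frame(probs))
  out$label <- classes[max.col(probs, ties.method = "first")]
  dplyr::relocate(out, "label")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Hybrid two-branch classifier\n",
    "  input: %dx%d grayscale; classes: %d\n",
    "  residual branch: plan [%s], feature dim %d\n",
    "  attention branch: depth %d, feature dim %d\n",
    "  fused dim %d -> dense %d -> %d\n",
    "  trainable parameters: %s\n"),
    x$config$input_size[1], x$config$input_size[2], x$config$num_classes,
    paste(x$config$resnet_plan, collapse = ","), x$res$out_dim,
    x$att$depth, x$att$out_dim, x$fused_dim, x$config$head_units,
    x$config$num_classes,
    format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}
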