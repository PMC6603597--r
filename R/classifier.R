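# 1D VGG-style classification model: blocks of kernel-3 convolutions (each
# with batch normalization and a Leaky ReLU), max-pooling after every block,
# adaptive average pooling, and a single fully connected layer onto the
# class scores.

#' Leaky rectified linear unit
#'
#' `f(x) = x` for `x > 0`, otherwise `lambda * x`.
#'
#' @param x numeric input.
#' @param lambda negative-side slope, in (0, 1); default 0.01.
#' @export
leaky_relu <- function(x, lambda = 0.01) {
  if (!(lambda > 0 && lambda < 1)) stop_config("lambda must be in (0, 1)")
  ifelse(x > 0, x, lambda * x)
}

#' Describe a convolutional architecture
#'
#' @param blocks list of integer vectors; one vector per block, giving the
#'   output channels of each kernel-3 convolution in that block. Blocks
#'   nearer the output must have at least as many convolution layers as
#'   earlier blocks. Every block is followed by 2x max-pooling.
#' @param batch_norm add a batch-normalization layer after each convolution.
#' @param activation `"leaky_relu"` or `"relu"`.
#' @param lambda Leaky ReLU negative-side slope.
#' @param adaptive_pool per-channel output size of the adaptive average
#'   pooling layer between the convolutional part and the fully connected
#'   part, or `NULL` to omit it. With adaptive pooling the network has
#'   exactly one fully connected layer.
#' @param fc_layers hidden fully connected sizes used only when
#'   `adaptive_pool` is `NULL` (the final class layer is appended
#'   automatically).
#' @return object of class `slr_arch_spec`.
#' @export
architecture_spec <- function(blocks, batch_norm = TRUE,
                              activation = c("leaky_relu", "relu"),
                              lambda = 0.01, adaptive_pool = 2L,
                              fc_layers = c(2048L, 512L)) {
  if (length(blocks) == 0L) stop_config("blocks must be non-empty")
  depths <- lengths(blocks)
  if (any(diff(depths) < 0)) {
    stop_config("blocks nearer the output must have at least as many ",
                "convolution layers as earlier blocks")
  }
  structure(list(blocks = lapply(blocks, as.integer),
                 batch_norm = isTRUE(batch_norm),
                 activation = match.arg(activation), lambda = lambda,
                 adaptive_pool = if (is.null(adaptive_pool)) NULL
                                 else as.integer(adaptive_pool),
                 fc_layers = as.integer(fc_layers)),
            class = "slr_arch_spec")
}

# Named structures A-E. A and C have equal total convolution counts; B and D
# share a layout at different widths; E adds a block to D.
vgg_preset <- function(name) {
  blocks <- switch(toupper(name),
    A = list(64, 128, c(256, 256)),
    B = list(64, 128, c(256, 256), c(256, 256)),
    C = list(64, 128, 256, 512),
    D = list(64, 128, c(256, 256), c(512, 512)),
    E = list(64, 128, c(256, 256), c(512, 512), c(512, 512)),
    stop_config("unknown structure name: ", name)
  )
  architecture_spec(blocks)
}

#' Build a classification network
#'
#' @param arch a structure name (`"A"` to `"E"`) or an
#'   [architecture_spec()].
#' @param n_classes number of output classes.
#' @param input_channels,input_length input sample shape (14 x 64).
#' @param init_sd standard deviation of the normal weight initialization;
#'   drawn from the current RNG state.
#' @return object of class `slr_network`: the layer list plus bookkeeping
#'   (flatten position, feature size).
#' @export
build_architecture <- function(arch = "D", n_classes,
                               input_channels = 14L, input_length = 64L,
                               init_sd = 0.02) {
  spec <- if (inherits(arch, "slr_arch_spec")) arch else vgg_preset(arch)
  n_classes <- as.integer(n_classes)
  layers <- list()
  c_in <- input_channels
  len <- input_length
  for (blk in spec$blocks) {
    for (c_out in blk) {
      layers[[length(layers) + 1L]] <- nn_conv(c_in, c_out, init_sd)
      if (spec$batch_norm) layers[[length(layers) + 1L]] <- nn_bn(c_out)
      layers[[length(layers) + 1L]] <-
        nn_act(spec$activation, lambda = spec$lambda)
      c_in <- c_out
    }
    if (len %% 2L != 0L) stop_config("too many pooling stages for the input")
    layers[[length(layers) + 1L]] <- nn_maxpool()
    len <- len %/% 2L
  }
  if (!is.null(spec$adaptive_pool)) {
    if (len < spec$adaptive_pool) {
      stop_config("convolutional output shorter than the adaptive pool size")
    }
    layers[[length(layers) + 1L]] <- nn_apool(spec$adaptive_pool)
    feature_size <- c_in * spec$adaptive_pool
    layers[[length(layers) + 1L]] <- nn_flatten()
    flatten_idx <- length(layers)
    layers[[length(layers) + 1L]] <- nn_fc(feature_size, n_classes, init_sd)
  } else {
    feature_size <- c_in * len
    layers[[length(layers) + 1L]] <- nn_flatten()
    flatten_idx <- length(layers)
    d_in <- feature_size
    for (h in spec$fc_layers) {
      layers[[length(layers) + 1L]] <- nn_fc(d_in, h, init_sd)
      layers[[length(layers) + 1L]] <-
        nn_act(spec$activation, lambda = spec$lambda)
      d_in <- h
    }
    layers[[length(layers) + 1L]] <- nn_fc(d_in, n_classes, init_sd)
  }
  structure(list(layers = layers, n_classes = n_classes, spec = spec,
                 flatten_idx = flatten_idx, feature_size = feature_size,
                 input_channels = input_channels,
                 input_length = input_length),
            class = "slr_network")
}

#' @export
print.slr_network <- function(x, ...) {
  depths <- lengths(x$spec$blocks)
  cat(sprintf(
    "slr_network: %d blocks (%s convs), feature size %d, %d classes\n",
    length(depths), paste(depths, collapse = "+"), x$feature_size,
    x$n_classes))
  invisible(x)
}

#' Classifier training configuration
#'
#' Adam with a normal-distribution weight initialization, batches of 128 and
#' an initial learning rate of 1e-4 scaled by 0.1 every 10 epochs.
#'
#' @param batch_size samples per batch.
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param init_sd weight initialization standard deviation.
#' @param seed RNG seed covering initialization and batch shuffling.
#' @export
train_config <- function(batch_size = 128L, lr = 1e-4, epochs = 20L,
                         init_sd = 0.02, seed = 1L) {
  if (batch_size < 1L || lr <= 0 || epochs < 1L || init_sd <= 0) {
    stop_config("train_config values must be positive")
  }
  list(batch_size = as.integer(batch_size), lr = lr,
       epochs = as.integer(epochs), init_sd = init_sd,
       seed = as.integer(seed))
}

#' Train the classification model
#'
#' Softmax cross-entropy training of a [build_architecture()] network on the
#' training split of a preprocessed dataset. The log records, per epoch, the
#' mean training loss, held-out accuracy and the train/test wall times.
#'
#' @param ppdata an `slr_pp_dataset` from [preprocess_dataset()].
#' @param arch structure name or [architecture_spec()].
#' @param cfg a [train_config()].
#' @return object of class `slr_classifier` carrying the trained network,
#'   the training log and the preprocessing/normalization context needed to
#'   classify raw windows online.
#' @export
train_classifier <- function(ppdata, arch = "D", cfg = train_config()) {
  labels <- ppdata$labels
  tr <- ppdata$train_idx
  if (length(tr) == 0L) stop_config("empty training split")
  if (any(table(labels[tr]) < 2L)) {
    stop_config("every class needs at least 2 training samples")
  }
  with_seed(cfg$seed, {
    net <- build_architecture(arch, n_classes = ppdata$n_classes,
                              init_sd = cfg$init_sd)
    layers <- net$layers
    state <- adam_init(layers)
    step <- 0L
    log <- data.frame()
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg$lr, epoch)
      idx <- sample(tr)
      t0 <- proc.time()[["elapsed"]]
      losses <- c()
      for (b0 in seq(1L, length(idx), by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1L, length(idx))]
        X <- ppdata$x[, , bi, drop = FALSE]
        fw <- net_forward(layers, X, training = TRUE)
        layers <- fw$layers
        ce <- softmax_ce(fw$out, labels[bi])
        losses <- c(losses, ce$loss)
        bw <- net_backward(layers, fw$caches, ce$dlogits)
        step <- step + 1L
        up <- adam_step(layers, bw$grads, state, lr, step)
        layers <- up$layers
        state <- up$state
      }
      train_time <- proc.time()[["elapsed"]] - t0
      t0 <- proc.time()[["elapsed"]]
      acc <- net_accuracy(layers, ppdata$x[, , ppdata$test_idx, drop = FALSE],
                          labels[ppdata$test_idx])
      test_time <- proc.time()[["elapsed"]] - t0
      log <- rbind(log, data.frame(
        epoch = epoch, lr = lr, loss = mean(losses), test_accuracy = acc,
        train_time = train_time, test_time = test_time))
    }
    net$layers <- layers
    structure(list(
      network = net, n_classes = ppdata$n_classes,
      empty_class = ppdata$empty_class, stats = ppdata$stats,
      smoother = ppdata$smoother, wavelet = ppdata$wavelet,
      log = log, cfg = cfg
    ), class = "slr_classifier")
  })
}

# Accuracy of a layer stack on a preprocessed array (inference mode).
net_accuracy <- function(layers, x, labels, batch = 512L) {
  if (length(labels) == 0L) return(NA_real_)
  pred <- integer(length(labels))
  for (b0 in seq(1L, length(labels), by = batch)) {
    bi <- b0:min(b0 + batch - 1L, length(labels))
    out <- net_forward(layers, x[, , bi, drop = FALSE], training = FALSE)$out
    pred[bi] <- apply(out, 2, which.max)
  }
  mean(pred == labels)
}

#' @export
print.slr_classifier <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "slr_classifier: %d classes, %d epochs, final loss %.4f, test accuracy %.3f\n",
    x$n_classes, nrow(x$log), last$loss, last$test_accuracy))
  invisible(x)
}

#' Classify preprocessed samples
#'
#' @param object a trained `slr_classifier`.
#' @param x one 14 x 64 matrix or a 14 x 64 x N array of preprocessed,
#'   normalized samples.
#' @param ... unused.
#' @return for a single sample, a list with `class_id` and the softmax
#'   `posterior`; for a batch, `class_id` is a vector and `posterior` a
#'   classes x N matrix.
#' @export
predict.slr_classifier <- function(object, x, ...) {
  single <- length(dim(x)) == 2L
  if (single) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  net <- object$network
  if (d[1] != net$input_channels || d[2] != net$input_length) {
    stop_config("sample shape must be ", net$input_channels, " x ",
                net$input_length)
  }
  out <- net_forward(net$layers, x, training = FALSE)$out
  post <- softmax_probs(out)
  cls <- apply(post, 2, which.max)
  if (single) list(class_id = cls[1], posterior = post[, 1]) else
    list(class_id = cls, posterior = post)
}
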